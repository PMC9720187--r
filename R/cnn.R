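# Compact convolutional network for searchlight images, implemented directly
# in R (forward + backward passes, Adam optimizer). Architecture: input
# n1 x n1, one convolution layer (kernel k x k, `filters` maps, zero padding
# preserving n1 x n1), ReLU, 2 x 2 max pooling (stride 2), a fully connected
# layer with one unit per class, softmax. Trained full-batch; deterministic
# given the spec's seed.

# (N*n1*n1) x (k*k) patch matrix of zero-padded images; column-major over
# (row, col) image positions, matching array vectorization
im2col <- function(images, k) {
  n <- dim(images)[1]; n1 <- dim(images)[2]
  p <- (k - 1L) %/% 2L
  pad <- array(0, c(n, n1 + 2L * p, n1 + 2L * p))
  pad[, p + seq_len(n1), p + seq_len(n1)] <- images
  cols <- matrix(0, n * n1 * n1, k * k)
  m <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    m <- m + 1L
    cols[, m] <- as.vector(pad[, di + 0:(n1 - 1L), dj + 0:(n1 - 1L)])
  }
  cols
}

cnn_forward <- function(cols, n, n1, po, par) {
  zc <- sweep(cols %*% par$w1, 2, par$b1, `+`)
  a1 <- array(pmax(zc, 0), c(n, n1, n1, dim(par$w1)[2]))
  ev <- seq(1L, 2L * po, 2L)
  s <- list(a1[, ev, ev, , drop = FALSE], a1[, ev + 1L, ev, , drop = FALSE],
            a1[, ev, ev + 1L, , drop = FALSE], a1[, ev + 1L, ev + 1L, , drop = FALSE])
  mx <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  aflat <- matrix(mx, n)
  z2 <- sweep(aflat %*% par$w2, 2, par$b2, `+`)
  z2 <- z2 - apply(z2, 1, max)
  p <- exp(z2); p <- p / rowSums(p)
  list(zc = zc, s = s, mx = mx, aflat = aflat, prob = p)
}

#' CNN decoding of one train/test split
#'
#' Trains the compact convolutional network described in
#' [classifier_spec()] on the training searchlight images and predicts the
#' test images. Training is full-batch Adam for `spec$epochs` epochs;
#' results are reproducible given `spec$seed`.
#'
#' @param train_images,test_images `trials x n1 x n1` arrays.
#' @param train_y class labels for the training images.
#' @param spec a [classifier_spec()] with `kind = "cnn"`.
#' @return Predicted labels for the test images.
#' @export
cnn_decode <- function(train_images, train_y, test_images,
                       spec = classifier_spec("cnn")) {
  n1 <- dim(train_images)[2]
  if (n1 < 2L)
    sl_stop("CNN stream needs a grid of at least 2 cells per side",
            "surflight_invalid_parameter")
  classes <- sort(unique(train_y))
  if (length(classes) < 2L)
    sl_stop("training labels contain a single class", "surflight_degenerate_design")
  k <- spec$kernel
  nf <- spec$filters
  po <- n1 %/% 2L
  nc <- length(classes)
  n <- dim(train_images)[1]
  y <- match(train_y, classes)
  yhot <- matrix(0, n, nc); yhot[cbind(seq_len(n), y)] <- 1

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  d2 <- po * po * nf
  par <- list(w1 = matrix(rnorm(k * k * nf, sd = sqrt(2 / (k * k))), k * k),
              b1 = numeric(nf),
              w2 = matrix(rnorm(d2 * nc, sd = sqrt(2 / d2)), d2),
              b2 = numeric(nc))
  adam <- lapply(par, function(p) list(m = p * 0, v = p * 0))
  b1c <- 0.9; b2c <- 0.999; eps <- 1e-8

  cols <- im2col(train_images, k)
  ev <- seq(1L, 2L * po, 2L)
  for (epoch in seq_len(spec$epochs)) {
    fw <- cnn_forward(cols, n, n1, po, par)
    dz2 <- (fw$prob - yhot) / n
    g <- list(w1 = NULL, b1 = NULL,
              w2 = crossprod(fw$aflat, dz2), b2 = colSums(dz2))
    dmx <- array(dz2 %*% t(par$w2), dim(fw$mx))
    da1 <- array(0, c(n, n1, n1, nf))
    taken <- array(FALSE, dim(fw$mx))
    off <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    for (q in 1:4) {
      sel <- (fw$s[[q]] == fw$mx) & !taken
      taken <- taken | sel
      da1[, ev + off[[q]][1], ev + off[[q]][2], ] <-
        da1[, ev + off[[q]][1], ev + off[[q]][2], , drop = FALSE] + dmx * sel
    }
    dzc <- matrix(da1, n * n1 * n1, nf) * (fw$zc > 0)
    g$w1 <- crossprod(cols, dzc)
    g$b1 <- colSums(dzc)
    for (nm in names(par)) {
      adam[[nm]]$m <- b1c * adam[[nm]]$m + (1 - b1c) * g[[nm]]
      adam[[nm]]$v <- b2c * adam[[nm]]$v + (1 - b2c) * g[[nm]]^2
      mh <- adam[[nm]]$m / (1 - b1c^epoch)
      vh <- adam[[nm]]$v / (1 - b2c^epoch)
      par[[nm]] <- par[[nm]] - spec$lr * mh / (sqrt(vh) + eps)
    }
  }
  nte <- dim(test_images)[1]
  fw <- cnn_forward(im2col(test_images, k), nte, n1, po, par)
  classes[max.col(fw$prob, ties.method = "first")]
}
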