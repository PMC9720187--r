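#' Classifier specification
#'
#' The SVM stream fits a linear-kernel support vector machine
#' (regularization constant `cost`, one-vs-one for more than two classes) on
#' flattened searchlight vectors; features are used raw (no standardization).
#' The CNN stream trains a compact convolutional network on the `n1 x n1`
#' searchlight images: convolution (`kernel x kernel`, `filters` maps,
#' output-preserving padding), ReLU, 2 x 2 max pooling, a fully connected
#' layer with one unit per class, and softmax; trained full-batch with Adam.
#'
#' @param kind `"svm"` or `"cnn"`.
#' @param cost SVM regularization constant.
#' @param kernel CNN convolution kernel side (odd).
#' @param filters CNN convolution maps.
#' @param epochs CNN training epochs (full-batch).
#' @param lr CNN Adam learning rate.
#' @param seed CNN weight-initialization seed (decoding is deterministic
#'   given the seed).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("svm", "cnn"), cost = 1,
                            kernel = 3L, filters = 8L, epochs = 150L,
                            lr = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, cost = cost, kernel = as.integer(kernel),
                 filters = as.integer(filters), epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Leave-one-run-out cross-validation folds
#'
#' One fold per run: that run is the test set, all remaining runs the
#' training set, so each run serves as the test set exactly once.
#'
#' @param runs vector of run identifiers (one per trial, or the unique ids).
#' @return List of folds, each `list(train = ids, test = id)`.
#' @export
loro_folds <- function(runs) {
  ids <- unique(runs)
  if (length(ids) < 2L)
    sl_stop("leave-one-run-out needs at least 2 runs", "surflight_invalid_design")
  lapply(ids, function(r) list(train = setdiff(ids, r), test = r))
}

#' Linear SVM decoding of one train/test split
#'
#' @param train_x,test_x numeric matrices (trials x features), e.g. flattened
#'   searchlight vectors.
#' @param train_y class labels for the training rows.
#' @param spec a [classifier_spec()] (the `cost` field is used).
#' @return Predicted labels for `test_x` rows (same type as `train_y`).
#' @export
svm_decode <- function(train_x, train_y, test_x, spec = classifier_spec("svm")) {
  yf <- factor(train_y)
  if (nlevels(yf) < 2L)
    sl_stop("training labels contain a single class", "surflight_degenerate_design")
  fit <- e1071::svm(x = train_x, y = yf, kernel = "linear",
                    cost = spec$cost, scale = FALSE)
  pred <- stats::predict(fit, test_x)
  out <- as.character(pred)
  if (is.numeric(train_y)) as.numeric(out) else out
}

#' Per-subject searchlight accuracy map
#'
#' For every downsampled vertex: build the searchlight images of all trials,
#' run leave-one-run-out cross-validation with the requested classifier, and
#' record the mean fold accuracy (folds weighted equally). The chance level
#' is `1 / number of (super)classes`.
#'
#' @param trials a `trial_set` covering all runs ([bind_trials()]), or a list
#'   of per-run `trial_set`s.
#' @param layout a [build_layout()] searchlight layout.
#' @param contrast a [parse_contrast()] result or contrast string; `NULL`
#'   decodes all observed non-baseline codes as separate classes.
#' @param spec a [classifier_spec()].
#' @param mask a [circular_mask()]; defaults to the layout's grid size.
#' @param subject_id identifier stored in the result.
#' @param vertices subset of downsampled vertices to decode (default all).
#' @return An `accuracy_map`: list with `accuracy` (length `V_low`, `NA`
#'   outside `vertices`), `chance`, `contrast`, `subject_id`, `n_folds`.
#' @export
subject_accuracy_map <- function(trials, layout, contrast = NULL,
                                 spec = classifier_spec("svm"),
                                 mask = circular_mask(layout$spec$n1),
                                 subject_id = NA, vertices = NULL) {
  if (!inherits(trials, "trial_set")) trials <- bind_trials(trials)
  if (is.character(contrast)) contrast <- parse_contrast(contrast)
  if (is.null(contrast)) {
    codes <- sort(unique(trials$labels[trials$labels != 0L]))
    if (length(codes) < 2L)
      sl_stop("fewer than 2 condition codes present", "surflight_contrast_error")
    contrast <- structure(lapply(codes, identity), chance = 1 / length(codes))
  }
  if (!all(unlist(contrast) %in% trials$labels))
    sl_stop("contrast names condition codes absent from the data",
            "surflight_contrast_error")
  cls <- contrast_classes(trials$labels, contrast)
  keep <- !is.na(cls)
  patterns <- trials$patterns[keep, , drop = FALSE]
  cls <- cls[keep]
  runs <- trials$runs[keep]
  if (ncol(patterns) != layout$template$v_high)
    sl_stop("trial patterns do not match the layout's high-res template",
            "surflight_dimension_mismatch")
  folds <- loro_folds(runs)
  n1 <- layout$spec$n1
  v_low <- length(layout$records)
  if (is.null(vertices)) vertices <- seq_len(v_low)
  acc <- rep(NA_real_, v_low)
  for (v in vertices) {
    flat <- cell_average(patterns, layout$records[[v]], mask, n1)
    # all-zero columns (masked or empty cells) do not change a linear-kernel
    # solution; dropping them saves most of the per-fit overhead
    nz <- which(colSums(abs(flat)) > 0)
    if (length(nz) == 0L) nz <- 1L
    fold_acc <- vapply(folds, function(f) {
      tr <- runs %in% f$train
      te <- runs == f$test
      pred <- if (spec$kind == "svm") {
        svm_decode(flat[tr, nz, drop = FALSE], cls[tr],
                   flat[te, nz, drop = FALSE], spec)
      } else {
        cnn_decode(flat_to_images(flat[tr, , drop = FALSE], n1), cls[tr],
                   flat_to_images(flat[te, , drop = FALSE], n1), spec)
      }
      mean(pred == cls[te])
    }, numeric(1))
    acc[v] <- mean(fold_acc)
  }
  structure(list(accuracy = acc, chance = attr(contrast, "chance"),
                 contrast = contrast, subject_id = subject_id,
                 n_folds = length(folds)),
            class = "accuracy_map")
}

# inverse of flatten(): trials x n1^2 -> trials x n1 x n1
flat_to_images <- function(flat, n1) {
  arr <- array(0, c(nrow(flat), n1, n1))
  for (i0 in 0:(n1 - 1L))
    arr[, i0 + 1L, ] <- flat[, cell_linear(i0, 0:(n1 - 1L), n1), drop = FALSE]
  arr
}
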