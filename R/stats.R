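#' Threshold specification for group inference
#'
#' @param vertexwise vertex-wise threshold as `-log10(p)` (default 3, i.e.
#'   one-tailed p < 0.001).
#' @param fwe_alpha family-wise error rate (default 0.01).
#' @param n_perm number of sign-flip permutations (default 2000).
#' @param seed permutation RNG seed.
#' @return A `threshold_spec` list. The FWE rank is
#'   `round(fwe_alpha * n_perm)` (20 for the defaults); `fwe_alpha * n_perm`
#'   must be at least 1.
#' @export
threshold_spec <- function(vertexwise = 3, fwe_alpha = 0.01, n_perm = 2000L,
                           seed = 1L) {
  if (vertexwise <= 0)
    sl_stop("vertexwise must be positive", "surflight_invalid_parameter")
  if (fwe_alpha <= 0 || fwe_alpha >= 1)
    sl_stop("fwe_alpha must be in (0, 1)", "surflight_invalid_parameter")
  if (fwe_alpha * n_perm < 1)
    sl_stop("fwe_alpha * n_perm must be >= 1 (the FWE rank would be 0)",
            "surflight_invalid_parameter")
  structure(list(vertexwise = vertexwise, fwe_alpha = fwe_alpha,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "threshold_spec")
}

#' Group one-sample t-test of accuracy maps against chance
#'
#' Per vertex: `t = mean(acc - chance) / (sd(acc) / sqrt(n))` with
#' `df = n - 1`; the alternative is one-tailed, accuracy above chance.
#' Vertices where all subjects have identical accuracy get `t = +Inf` (mean
#' above chance), `-Inf` (below), or `0` (equal) — a documented convention,
#' not an error, since separable synthetic data can saturate accuracy.
#'
#' @param maps list of per-subject `accuracy_map`s ([subject_accuracy_map()]),
#'   or a `subjects x V` accuracy matrix.
#' @param chance chance level; taken from the maps when omitted.
#' @return A `tmap`: list with `t` (length `V`), `df`, `chance`, `n`.
#' @export
group_ttest <- function(maps, chance = NULL) {
  if (is.matrix(maps)) {
    a <- maps
    if (is.null(chance))
      sl_stop("chance must be given with a plain matrix", "surflight_invalid_parameter")
  } else {
    chances <- unique(vapply(maps, `[[`, numeric(1), "chance"))
    if (length(chances) != 1L)
      sl_stop("accuracy maps have differing chance levels (different contrasts?)",
              "surflight_invalid_design")
    if (is.null(chance)) chance <- chances
    a <- do.call(rbind, lapply(maps, `[[`, "accuracy"))
  }
  n <- nrow(a)
  if (n < 2L)
    sl_stop("group test needs at least 2 subjects", "surflight_invalid_design")
  m <- colMeans(a) - chance
  s <- apply(a, 2, sd)
  t <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0)))
  structure(list(t = t, df = n - 1L, chance = chance, n = n), class = "tmap")
}

#' Vertex-wise thresholding of a t-map
#'
#' Marks vertices whose one-tailed p-value is below `10^(-vertexwise)`
#' (default 3, p < 0.001).
#'
#' @param tmap a [group_ttest()] result.
#' @param vertexwise `-log10(p)` threshold.
#' @return Logical vector over vertices.
#' @export
threshold_map <- function(tmap, vertexwise = 3) {
  tcrit <- stats::qt(10^(-vertexwise), df = tmap$df, lower.tail = FALSE)
  tmap$t > tcrit
}

#' Connected clusters of marked vertices
#'
#' Groups marked vertices into connected components under mesh-edge
#' adjacency. The traversal uses an explicit stack (depth-first), matching
#' the recursive grouping semantics without recursion-depth limits: an
#' ungrouped marked vertex seeds a new cluster which is grown through marked
#' neighbors until exhausted.
#'
#' @param marked logical vector over vertices ([threshold_map()]).
#' @param adjacency [build_adjacency()] list.
#' @param tmap optional [group_ttest()] result used to fill peak statistics.
#' @return List of clusters, each
#'   `list(vertices, size, peak_t, peak_vertex)`; peaks are `NA` without
#'   `tmap`. Peak ties are broken by the lowest vertex index.
#' @export
find_clusters <- function(marked, adjacency, tmap = NULL) {
  clusters <- list()
  seen <- !marked                          # unmarked counts as visited
  for (seed in which(marked)) {
    if (seen[seed]) next
    stack <- seed
    seen[seed] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, v)
      nb <- adjacency[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      stack <- c(stack, new)
    }
    members <- sort(members)
    peak_t <- NA_real_; peak_v <- NA_integer_
    if (!is.null(tmap)) {
      tv <- tmap$t[members]
      peak_v <- members[which.max(tv)]
      peak_t <- max(tv)
    }
    clusters[[length(clusters) + 1L]] <-
      list(vertices = members, size = length(members),
           peak_t = peak_t, peak_vertex = peak_v)
  }
  clusters
}

# size of the largest connected marked component; 0 if none
max_cluster_size <- function(marked, adjacency) {
  best <- 0L
  seen <- !marked
  for (seed in which(marked)) {
    if (seen[seed]) next
    stack <- seed
    seen[seed] <- TRUE
    size <- 0L
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      nb <- adjacency[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      stack <- c(stack, new)
    }
    if (size > best) best <- size
  }
  best
}

#' Sign-flip max-cluster-size null distribution
#'
#' Builds the permutation null for cluster-level FWE correction: in each of
#' `n_perm` permutations the sign of every vertex's t value is independently
#' flipped with probability 1/2, the flipped map is thresholded with the same
#' one-tailed vertex-wise rule, and the size of the largest surviving cluster
#' is recorded (0 if none). The recorded maxima are sorted in descending
#' order; the FWE size threshold is the value at rank
#' `round(fwe_alpha * n_perm)`.
#'
#' The default flips the per-vertex t statistic itself. `method = "subject"`
#' is the standard alternative: subject-level accuracy-minus-chance signs are
#' flipped and the t-map recomputed per permutation (requires `maps`).
#'
#' @param tmap a [group_ttest()] result.
#' @param adjacency [build_adjacency()] list.
#' @param spec a [threshold_spec()].
#' @param method `"tmap"` (flip t signs) or `"subject"` (flip subject
#'   effects and recompute t).
#' @param maps subject accuracy maps or matrix, needed for
#'   `method = "subject"`.
#' @param flip_prob per-vertex flip probability; 1/2 for inference (values
#'   other than 1/2 exist for verification, e.g. 0 reproduces the observed
#'   map in every permutation).
#' @return A `null_distribution`: list with `max_sizes` (descending),
#'   `threshold_rank`, `threshold_size`.
#' @export
signflip_null <- function(tmap, adjacency, spec, method = c("tmap", "subject"),
                          maps = NULL, flip_prob = 0.5) {
  method <- match.arg(method)
  v <- length(tmap$t)
  tcrit <- stats::qt(10^(-spec$vertexwise), df = tmap$df, lower.tail = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  if (method == "subject") {
    if (is.null(maps))
      sl_stop("method = 'subject' needs the per-subject maps", "surflight_invalid_parameter")
    a <- if (is.matrix(maps)) maps else do.call(rbind, lapply(maps, `[[`, "accuracy"))
    eff <- a - tmap$chance
    n <- nrow(eff)
    css <- colSums(eff^2)                  # invariant under sign flips
    signs <- matrix(ifelse(runif(n * spec$n_perm) < flip_prob, -1, 1),
                    n, spec$n_perm)
    ms <- crossprod(signs, eff) / n        # n_perm x V flipped means
  } else {
    pos <- tmap$t > tcrit                  # marked when not flipped
    neg <- -tmap$t > tcrit                 # marked when flipped
  }
  max_sizes <- integer(spec$n_perm)
  for (i in seq_len(spec$n_perm)) {
    if (method == "tmap") {
      flip <- runif(v) < flip_prob
      marked <- ifelse(flip, neg, pos)
    } else {
      m <- ms[i, ]
      s2 <- pmax(css - n * m^2, 0) / (n - 1)
      tf <- ifelse(s2 > 0, m / sqrt(s2 / n),
                   ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0)))
      marked <- tf > tcrit
    }
    max_sizes[i] <- max_cluster_size(marked, adjacency)
  }
  max_sizes <- sort(max_sizes, decreasing = TRUE)
  rank <- as.integer(round(spec$fwe_alpha * spec$n_perm))
  structure(list(max_sizes = max_sizes, threshold_rank = rank,
                 threshold_size = max_sizes[rank]),
            class = "null_distribution")
}

#' Retain clusters surviving the FWE size threshold
#'
#' A cluster survives only if its size is strictly greater than the null
#' distribution's threshold size (the `round(fwe_alpha * n_perm)`-th largest
#' permutation maximum — the 20th of 2,000 sorted maxima for the defaults,
#' FWE < 0.01).
#'
#' @param clusters [find_clusters()] result.
#' @param null a [signflip_null()] result.
#' @param spec the [threshold_spec()] used to build `null`.
#' @return The surviving subset of `clusters`.
#' @export
fwe_filter <- function(clusters, null, spec) {
  if (spec$fwe_alpha * spec$n_perm < 1)
    sl_stop("fwe_alpha * n_perm must be >= 1", "surflight_invalid_parameter")
  Filter(function(cl) cl$size > null$threshold_size, clusters)
}

#' Cluster summary table
#'
#' @param clusters clusters ([find_clusters()] or [fwe_filter()] output).
#' @param tmap the [group_ttest()] result they came from.
#' @param template the downsampled sphere ([subdivide()]), for peak
#'   coordinates.
#' @param area_per_vertex optional per-vertex areas ([vertex_areas()]) for
#'   mm^2 sizes.
#' @return Data frame sorted by size (descending): `size_vertices`,
#'   `peak_t`, `peak_vertex`, `peak_alpha`, `peak_beta`, and `size_mm2` when
#'   areas are supplied.
#' @export
cluster_report <- function(clusters, tmap, template = NULL,
                           area_per_vertex = NULL) {
  if (length(clusters) == 0L) {
    out <- data.frame(size_vertices = integer(0), peak_t = numeric(0),
                      peak_vertex = integer(0), peak_alpha = numeric(0),
                      peak_beta = numeric(0))
    if (!is.null(area_per_vertex)) out$size_mm2 <- numeric(0)
    return(out)
  }
  peak_v <- vapply(clusters, function(cl) {
    if (is.na(cl$peak_vertex)) cl$vertices[which.max(tmap$t[cl$vertices])]
    else cl$peak_vertex
  }, integer(1))
  out <- data.frame(
    size_vertices = vapply(clusters, `[[`, integer(1), "size"),
    peak_t = tmap$t[peak_v],
    peak_vertex = peak_v,
    peak_alpha = NA_real_, peak_beta = NA_real_)
  if (!is.null(template)) {
    cc <- cart_to_sph(template$vertices[peak_v, , drop = FALSE])
    out$peak_alpha <- cc[, 1]; out$peak_beta <- cc[, 2]
  }
  if (!is.null(area_per_vertex))
    out$size_mm2 <- vapply(clusters, function(cl)
      sum(area_per_vertex[cl$vertices]), numeric(1))
  out <- out[order(-out$size_vertices), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full group-level inference
#'
#' Convenience wrapper chaining [group_ttest()], [threshold_map()],
#' [find_clusters()], [signflip_null()], [fwe_filter()] and
#' [cluster_report()].
#'
#' @inheritParams group_ttest
#' @inheritParams signflip_null
#' @param template optional downsampled sphere for peak coordinates.
#' @param area_per_vertex optional per-vertex areas for mm^2 sizes.
#' @return List with `tmap`, `marked`, `clusters`, `null`, `surviving`,
#'   `report` (the surviving-cluster table).
#' @export
group_inference <- function(maps, adjacency, spec = threshold_spec(),
                            chance = NULL, method = "tmap",
                            template = NULL, area_per_vertex = NULL) {
  tmap <- group_ttest(maps, chance = chance)
  marked <- threshold_map(tmap, spec$vertexwise)
  clusters <- find_clusters(marked, adjacency, tmap)
  null <- signflip_null(tmap, adjacency, spec, method = method,
                        maps = if (identical(method, "subject")) maps else NULL)
  surviving <- fwe_filter(clusters, null, spec)
  list(tmap = tmap, marked = marked, clusters = clusters, null = null,
       surviving = surviving,
       report = cluster_report(surviving, tmap, template, area_per_vertex))
}
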