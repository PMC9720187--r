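#' Read a stimulus paradigm file
#'
#' Paradigm files are whitespace-delimited text with four numeric columns:
#' stimulus onset (seconds), condition code (non-negative integer, 0 =
#' baseline), duration (seconds), and weight. Onsets must be non-negative and
#' strictly increasing within a run.
#'
#' @param path path to the paradigm file.
#' @return Data frame with columns `onset`, `code`, `duration`, `weight`,
#'   one row per event in file order.
#' @export
read_paradigm <- function(path) {
  if (!file.exists(path))
    sl_stop(sprintf("paradigm file '%s' not found", path), "surflight_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(onset = numeric(0), code = integer(0),
                      duration = numeric(0), weight = numeric(0)))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    sl_stop(sprintf("line %d of '%s': expected 4 columns, found %d",
                    bad[1], path, lengths(fields)[bad[1]]),
            "surflight_format_error")
  num <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 4, byrow = TRUE))
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1, any))[1]
    sl_stop(sprintf("line %d of '%s': non-numeric field", bad, path),
            "surflight_format_error")
  }
  if (any(num[, 1] < 0))
    sl_stop(sprintf("line %d of '%s': negative onset",
                    which(num[, 1] < 0)[1], path), "surflight_format_error")
  if (any(diff(num[, 1]) <= 0))
    sl_stop(sprintf("line %d of '%s': onsets must be strictly increasing",
                    which(diff(num[, 1]) <= 0)[1] + 1L, path),
            "surflight_format_error")
  if (any(num[, 2] < 0 | num[, 2] != round(num[, 2])))
    sl_stop(sprintf("line %d of '%s': condition code must be a non-negative integer",
                    which(num[, 2] < 0 | num[, 2] != round(num[, 2]))[1], path),
            "surflight_format_error")
  data.frame(onset = num[, 1], code = as.integer(num[, 2]),
             duration = num[, 3], weight = num[, 4])
}

#' Write a stimulus paradigm file
#'
#' @param events data frame as returned by [read_paradigm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paradigm <- function(events, path) {
  write.table(events[, c("onset", "code", "duration", "weight")], path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a per-run surface time series
#'
#' @param data `timepoints x V` numeric matrix (one hemisphere).
#' @param tr repetition time in seconds.
#' @param run_id run identifier.
#' @return A `run_series` list.
#' @export
run_series <- function(data, tr, run_id = NA) {
  data <- as.matrix(data)
  if (nrow(data) < 1L)
    sl_stop("a run needs at least one timepoint", "surflight_invalid_parameter")
  if (!is.numeric(tr) || tr <= 0)
    sl_stop("tr must be positive", "surflight_invalid_parameter")
  structure(list(data = data, tr = tr, run_id = run_id), class = "run_series")
}

# largest divisor of v not exceeding cap (NIfTI dim fields are int16)
nifti_first_dim <- function(v, cap = 32767L) {
  if (v <= cap) return(as.integer(v))
  for (d in seq(cap, 1L)) if (v %% d == 0L) return(as.integer(d))
  1L
}

#' Write a surface time series as surface-encoded NIfTI
#'
#' Vertices are stored along the spatial axes (split over the first two when
#' the count exceeds the NIfTI dimension limit) and time along the fourth,
#' following the FreeSurfer surface-encoding convention.
#'
#' @param series a [run_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_surface_series <- function(series, path) {
  v <- ncol(series$data)
  tp <- nrow(series$data)
  d1 <- nifti_first_dim(v)
  arr <- array(t(series$data), dim = c(d1, v %/% d1, 1L, tp))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, series$tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a surface-encoded functional time series
#'
#' Accepts surface-encoded NIfTI (`.nii`, `.nii.gz`; vertices along the
#' spatial axes, time along the fourth) or ASCII GIFTI functional files
#' (`.func.gii`; one data array per timepoint).
#'
#' @param path input file.
#' @param expected_vertices template vertex count to validate against
#'   (optional).
#' @param tr repetition time override in seconds; by default taken from the
#'   file header (NIfTI `pixdim[4]`).
#' @param run_id run identifier attached to the result.
#' @return A [run_series()] with a `timepoints x V` matrix.
#' @export
read_surface_series <- function(path, expected_vertices = NULL, tr = NULL,
                                run_id = NA) {
  if (!file.exists(path))
    sl_stop(sprintf("series file '%s' not found", path), "surflight_io_error")
  if (grepl("\\.gii$", path)) {
    mat <- read_gifti_func(path)
    if (is.null(tr)) tr <- 1
  } else {
    img <- tryCatch(RNifti::readNifti(path), error = function(e)
      sl_stop(sprintf("cannot read '%s': %s", path, conditionMessage(e)),
              "surflight_io_error"))
    d <- dim(img)
    if (length(d) < 4L) d <- c(d, rep(1L, 4L - length(d)))
    v <- prod(d[1:3])
    tp <- d[4]
    mat <- t(matrix(as.vector(img), nrow = v, ncol = tp))
    if (is.null(tr)) {
      px <- RNifti::pixdim(img)
      tr <- if (length(px) >= 4 && px[4] > 0) px[4] else 1
    }
  }
  if (!is.null(expected_vertices) && ncol(mat) != expected_vertices)
    sl_stop(sprintf("'%s' has %d vertices; template expects %d",
                    path, ncol(mat), expected_vertices),
            "surflight_dimension_mismatch")
  run_series(mat, tr = tr, run_id = run_id)
}

#' Extract per-trial vertex patterns at a fixed post-onset latency
#'
#' For every paradigm event the pattern is the single volume sampled
#' `timepoint_s` seconds after stimulus onset: volume index
#' `round((onset + timepoint_s) / tr)` (0-based, round-half-to-even).
#' Baseline events (code 0) are excluded unless `include_baseline = TRUE`.
#'
#' @param run a [run_series()].
#' @param events paradigm data frame ([read_paradigm()]).
#' @param timepoint_s latency after onset in seconds (>= 0).
#' @param include_baseline keep code-0 events?
#' @return A `trial_set`: list with `patterns` (`trials x V`), `labels`,
#'   `runs`, `timepoint`.
#' @export
extract_trials <- function(run, events, timepoint_s, include_baseline = FALSE) {
  if (timepoint_s < 0)
    sl_stop("timepoint_s must be non-negative", "surflight_invalid_parameter")
  keep <- if (include_baseline) rep(TRUE, nrow(events)) else events$code != 0L
  ev <- events[keep, , drop = FALSE]
  idx0 <- round((ev$onset + timepoint_s) / run$tr)   # 0-based volume index
  over <- which(idx0 + 1L > nrow(run$data) | idx0 < 0)
  if (length(over))
    sl_stop(sprintf(
      "event at onset %gs samples volume %d but run '%s' has %d volumes",
      ev$onset[over[1]], idx0[over[1]], as.character(run$run_id),
      nrow(run$data)), "surflight_out_of_range")
  structure(list(
    patterns = run$data[idx0 + 1L, , drop = FALSE],
    labels = ev$code,
    runs = rep(run$run_id, nrow(ev)),
    timepoint = timepoint_s
  ), class = "trial_set")
}

#' Combine trial sets across runs
#'
#' @param ... `trial_set` objects (or a single list of them).
#' @return A single `trial_set` with rows stacked in argument order.
#' @export
bind_trials <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "trial_set"))
    sets <- sets[[1]]
  structure(list(
    patterns = do.call(rbind, lapply(sets, `[[`, "patterns")),
    labels = unlist(lapply(sets, `[[`, "labels")),
    runs = unlist(lapply(sets, `[[`, "runs")),
    timepoint = sets[[1]]$timepoint
  ), class = "trial_set")
}

#' Read and validate a slice-delay file
#'
#' One fraction of a TR per slice, each in `[-0.5, +0.5]`. The file is only
#' parsed and validated; slice-timing correction itself is part of upstream
#' preprocessing and out of scope here.
#'
#' @param path input file.
#' @return Numeric vector of per-slice delays.
#' @export
read_delay_file <- function(path) {
  x <- suppressWarnings(as.numeric(readLines(path, warn = FALSE)))
  x <- x[!is.na(x)]
  if (length(x) == 0L || any(x < -0.5 | x > 0.5))
    sl_stop(sprintf("'%s' is not a valid delay file (one value per slice in [-0.5, 0.5])",
                    path), "surflight_format_error")
  x
}
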