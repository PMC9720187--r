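#' Parse an MVPA contrast string
#'
#' Accepted formats mirror the usual toolbox conventions: `"1 vs 4"` (two
#' classes), `"2 3 vs 1 4"` (two superclasses, codes pooled), and
#' `"0 1 2 3 4"` (one class per code). The decoding chance level is
#' `1 / number of (super)classes`.
#'
#' @param text contrast string.
#' @return List of integer vectors (one per superclass) with attribute
#'   `chance`.
#' @export
parse_contrast <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    sl_stop("contrast must be a non-empty string", "surflight_parse_error")
  sides <- strsplit(text, "(?i)\\bvs\\.?\\b", perl = TRUE)[[1]]
  parse_side <- function(s) {
    toks <- strsplit(trimws(s), "[[:space:],]+")[[1]]
    toks <- toks[nzchar(toks)]
    codes <- suppressWarnings(as.integer(toks))
    if (length(codes) == 0L || anyNA(codes) || any(codes < 0))
      sl_stop(sprintf("cannot parse contrast side '%s'", s),
              "surflight_parse_error")
    if (anyDuplicated(codes))
      sl_stop(sprintf("duplicate code in contrast side '%s'", s),
              "surflight_parse_error")
    codes
  }
  groups <- if (length(sides) == 1L) {
    lapply(parse_side(sides[1]), identity)   # one class per code
  } else {
    lapply(sides, parse_side)
  }
  if (length(groups) < 2L)
    sl_stop("a contrast needs at least 2 classes", "surflight_parse_error")
  all_codes <- unlist(groups)
  if (anyDuplicated(all_codes))
    sl_stop("condition codes may not appear in more than one superclass",
            "surflight_parse_error")
  structure(groups, chance = 1 / length(groups))
}

# map condition codes to superclass indices; NA for codes outside the contrast
contrast_classes <- function(labels, contrast) {
  cls <- rep(NA_integer_, length(labels))
  for (g in seq_along(contrast)) cls[labels %in% contrast[[g]]] <- g
  cls
}
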