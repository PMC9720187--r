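#' Grid specification for searchlights
#'
#' A searchlight is an `n1 x n1` grid of square angular cells centered on a
#' downsampled vertex after that vertex has been rotated to the spherical
#' origin. Defaults follow the method's standard settings: cells of 1/35
#' radians and 11 cells per side.
#'
#' @param cell_size angular size of one cell in radians (> 0).
#' @param n1 odd positive integer, cells per grid side.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(cell_size = 1 / 35, n1 = 11L) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    sl_stop("cell_size must be a positive number", "surflight_invalid_parameter")
  if (length(n1) != 1L || n1 < 1 || n1 != round(n1) || n1 %% 2 == 0)
    sl_stop("n1 must be an odd positive integer", "surflight_invalid_parameter")
  structure(list(cell_size = cell_size, n1 = as.integer(n1)),
            class = "grid_spec")
}

#' Searchlight radius on a sphere of given radius
#'
#' The angular half-width of the grid is `cell_size * n1 / 2`; on a sphere of
#' radius `sphere_radius` (mm for cortical templates) the searchlight radius
#' is `sphere_radius * cell_size * n1 / 2`. With the defaults and a 100 mm
#' sphere this is 100 * (1/35) * (11/2), approximately 15.7 mm.
#'
#' @param spec a [grid_spec()].
#' @param sphere_radius sphere radius in the desired length unit.
#' @return Numeric radius in the same unit.
#' @export
searchlight_radius <- function(spec, sphere_radius = 100) {
  sphere_radius * spec$cell_size * spec$n1 / 2
}

#' Circular mask over the searchlight grid
#'
#' Keeps cells whose center lies within `n1/2` cell units of the grid center;
#' everything outside the circle is zeroed in searchlight images. The center
#' cell is always kept and the mask is 4-fold symmetric.
#'
#' @param n1 odd positive integer.
#' @return A `circular_mask`: logical `n1 x n1` matrix (`TRUE` = keep).
#' @export
circular_mask <- function(n1) {
  if (length(n1) != 1L || n1 < 1 || n1 != round(n1) || n1 %% 2 == 0)
    sl_stop("n1 must be an odd positive integer", "surflight_invalid_parameter")
  n1 <- as.integer(n1)
  centers <- seq_len(n1) - 0.5 - n1 / 2          # cell-center offsets
  d <- sqrt(outer(centers^2, centers^2, `+`))
  structure(d <= n1 / 2, class = c("circular_mask", "matrix"))
}

# linear cell index (row-major) for 0-based grid coordinates
cell_linear <- function(i0, j0, n1) i0 * n1 + j0 + 1L

#' Build the per-vertex grid searchlight layout
#'
#' For every downsampled vertex `p`: rotate the sphere so `p` sits at the
#' spherical origin ([rotation_to_origin()]), express all high-resolution
#' vertices in rotated spherical coordinates `(a, b)`, and bin them into grid
#' cells with `i = floor(a/cell_size + n1/2)`, `j = floor(b/cell_size + n1/2)`
#' (cells indexed 0-based; vertices falling outside the grid are omitted).
#' Each layout record also stores the vertex's spherical coordinate, the
#' high-resolution vertices grouped to it (its own members), and its
#' mesh-edge neighbors — `n1^2 + 3` fields per record, i.e. 124 for the
#' default 11-cell grid.
#'
#' @param high high-resolution [subdivide()] sphere (pattern space).
#' @param low downsampled sphere (searchlight centers).
#' @param mapping [nearest_assignment()] of `high` onto `low`.
#' @param adjacency [build_adjacency()] of `low`.
#' @param spec a [grid_spec()].
#' @return A `searchlight_layout`: list with `records` (length `V_low`),
#'   `spec`, and `template` metadata. Each record is a list
#'   `(coord, cells, own, neighbors)` where `cells` has `n1^2` integer
#'   vectors in row-major cell order.
#' @export
build_layout <- function(high, low, mapping, adjacency, spec) {
  H <- high$vertices
  Lv <- low$vertices
  vl <- nrow(Lv)
  if (length(mapping$assignment) != nrow(H) || length(mapping$groups) != vl ||
        length(adjacency) != vl)
    sl_stop("mapping/adjacency sizes do not match the meshes",
            "surflight_dimension_mismatch")
  n1 <- spec$n1
  cs <- spec$cell_size
  hw <- cs * n1 / 2                       # grid half-width, radians
  dot_min <- cos(hw)^2 - 1e-12            # cos(d) >= cos(a)cos(b) >= cos^2(hw)
  half <- n1 / 2
  ncell <- n1 * n1
  records <- vector("list", vl)
  coords <- cart_to_sph(Lv)
  for (p in seq_len(vl)) {
    ctr <- Lv[p, ]
    cand <- which(as.vector(H %*% ctr) >= dot_min)
    R <- rotation_to_origin(coords[p, ])
    rot <- H[cand, , drop = FALSE] %*% t(R)
    ab <- cart_to_sph(rot)
    i0 <- floor(ab[, 1] / cs + half)
    j0 <- floor(ab[, 2] / cs + half)
    ok <- i0 >= 0 & i0 < n1 & j0 >= 0 & j0 < n1
    cells <- rep(list(integer(0)), ncell)
    if (any(ok)) {
      lin <- cell_linear(i0[ok], j0[ok], n1)
      filled <- split(cand[ok], lin)
      cells[as.integer(names(filled))] <- filled
    }
    records[[p]] <- list(coord = coords[p, ], cells = cells,
                         own = mapping$groups[[p]],
                         neighbors = adjacency[[p]])
  }
  structure(list(
    records = records, spec = spec,
    template = list(
      high_div = high$n_div %||% NA_integer_,
      low_div = low$n_div %||% NA_integer_,
      v_high = nrow(H), v_low = vl
    ),
    version = 1L
  ), class = "searchlight_layout")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.searchlight_layout <- function(x, ...) {
  cat(sprintf(
    "<searchlight_layout> %d records x %d fields (grid %dx%d, cell %.5f rad)\n",
    length(x$records), x$spec$n1^2 + 3L, x$spec$n1, x$spec$n1,
    x$spec$cell_size))
  invisible(x)
}

# trials x n1^2 matrix of masked cell means (row-major cell order); the
# workhorse behind searchlight_image and the decoding stream
cell_average <- function(patterns, record, mask, n1) {
  ncell <- n1 * n1
  keep <- as.vector(t(unclass(mask)))     # row-major linearization
  out <- matrix(0, nrow(patterns), ncell)
  len <- lengths(record$cells)
  use <- which(len > 0L & keep)
  if (length(use)) {
    members <- unlist(record$cells[use], use.names = FALSE)
    grp <- rep.int(use, len[use])
    sums <- t(rowsum(t(patterns[, members, drop = FALSE]), group = grp))
    out[, sort(unique(grp))] <- sweep(sums, 2, len[sort(unique(grp))], `/`)
  }
  out
}

#' Searchlight image for one downsampled vertex
#'
#' Averages the pattern values of the high-resolution vertices in each grid
#' cell, producing one `n1 x n1` image per trial. Cells outside the circular
#' mask and cells with no member vertices are 0.
#'
#' @param patterns `trials x V_high` numeric matrix.
#' @param layout a [build_layout()] result.
#' @param vertex downsampled vertex index.
#' @param mask a [circular_mask()]; defaults to the layout's grid size.
#' @return A `searchlight_image`: `trials x n1 x n1` array.
#' @export
searchlight_image <- function(patterns, layout, vertex,
                              mask = circular_mask(layout$spec$n1)) {
  if (vertex < 1 || vertex > length(layout$records))
    sl_stop("vertex index out of range", "surflight_index_error")
  if (ncol(patterns) != layout$template$v_high)
    sl_stop("pattern columns do not match the layout's high-res template",
            "surflight_dimension_mismatch")
  n1 <- layout$spec$n1
  flat <- cell_average(patterns, layout$records[[vertex]], mask, n1)
  arr <- array(0, c(nrow(patterns), n1, n1))
  for (i0 in 0:(n1 - 1L))
    arr[, i0 + 1L, ] <- flat[, cell_linear(i0, 0:(n1 - 1L), n1), drop = FALSE]
  structure(arr, class = "searchlight_image")
}

#' Flatten searchlight images to feature vectors
#'
#' Row-major flattening: cell `(i, j)` of the image maps to column
#' `(i-1)*n1 + j`. The inverse reshaping recovers the image exactly.
#'
#' @param image a [searchlight_image()] (`trials x n1 x n1` array).
#' @return `trials x n1^2` numeric matrix.
#' @export
flatten <- function(image) {
  d <- dim(image)
  n1 <- d[2]
  out <- matrix(0, d[1], n1 * n1)
  for (i0 in 0:(n1 - 1L))
    out[, cell_linear(i0, 0:(n1 - 1L), n1)] <- image[, i0 + 1L, ]
  out
}

#' File stem encoding a grid specification
#'
#' Layouts are cached in files named `<round(1/cell_size)>_<n1>` (plus a
#' hemisphere tag where relevant), e.g. `35_11` for the defaults.
#'
#' @param spec a [grid_spec()].
#' @return Character stem.
#' @export
layout_stem <- function(spec) {
  sprintf("%d_%d", as.integer(round(1 / spec$cell_size)), spec$n1)
}

#' Save / load a searchlight layout
#'
#' Layouts are written as versioned serialized R objects; loading validates
#' the header and structure and fails with a format error on corrupt,
#' truncated, or incompatible files. The round trip is lossless.
#'
#' @param layout a [build_layout()] result.
#' @param path file path (conventionally `<layout_stem(spec)>_<hemi>.rds`).
#' @return `save_layout` returns `path` invisibly; `load_layout` the layout.
#' @export
save_layout <- function(layout, path) {
  if (!inherits(layout, "searchlight_layout"))
    sl_stop("not a searchlight_layout", "surflight_invalid_parameter")
  saveRDS(layout, path, version = 2)
  invisible(path)
}

#' @rdname save_layout
#' @export
load_layout <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    sl_stop(sprintf("cannot read layout file '%s': %s", path,
                    conditionMessage(e)), "surflight_format_error"))
  if (!inherits(obj, "searchlight_layout") || is.null(obj$version) ||
        obj$version != 1L || !is.list(obj$records))
    sl_stop(sprintf("'%s' is not a valid layout file", path),
            "surflight_format_error")
  obj
}
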