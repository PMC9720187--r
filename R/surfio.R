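#' Read a FreeSurfer binary surface file
#'
#' Supports the triangle-format binary surfaces FreeSurfer writes (e.g.
#' `lh.sphere`, `lh.sphere.reg`). Vertex order of the file is preserved, so a
#' real template sphere can stand in for the generated high-resolution
#' geodesic sphere. Coordinates are normalized to the unit sphere.
#'
#' @param path surface file path.
#' @return A [trimesh()].
#' @export
read_freesurfer_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 3, size = 1, signed = FALSE)
  if (!identical(as.integer(magic), c(255L, 255L, 254L)))
    sl_stop(sprintf("'%s' is not a FreeSurfer triangle surface", path),
            "surflight_format_error")
  # comment line terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0L)
      sl_stop(sprintf("'%s' is truncated", path), "surflight_format_error")
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", 1, size = 4, endian = "big")
  nf <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (is.na(nv) || is.na(nf) || nv < 3L || nf < 1L)
    sl_stop(sprintf("'%s' has an invalid header", path), "surflight_format_error")
  v <- readBin(con, "numeric", nv * 3L, size = 4, endian = "big")
  f <- readBin(con, "integer", nf * 3L, size = 4, endian = "big")
  if (length(v) != nv * 3L || length(f) != nf * 3L)
    sl_stop(sprintf("'%s' is truncated", path), "surflight_format_error")
  trimesh(matrix(v, ncol = 3, byrow = TRUE),
          matrix(f, ncol = 3, byrow = TRUE) + 1L)
}

#' Write a FreeSurfer binary surface file
#'
#' @param mesh a [trimesh()]; coordinates are written as given (unit sphere).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freesurfer_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255, 255, 254)), con)
  writeBin(charToRaw("created by surflight\n\n"), con)
  writeBin(c(nrow(mesh$vertices), nrow(mesh$faces)), con, size = 4,
           endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4, endian = "big")
  invisible(path)
}

gifti_header <- paste0(
  '<?xml version="1.0" encoding="UTF-8"?>\n',
  '<GIFTI Version="1.0" NumberOfDataArrays="%d">\n')

gifti_array <- function(intent, datatype, dims, values, fmt) {
  dimattr <- paste(sprintf('Dim%d="%d"', seq_along(dims) - 1L, dims),
                   collapse = " ")
  paste0(sprintf(
    '<DataArray Intent="%s" DataType="%s" ArrayIndexingOrder="RowMajorOrder" Dimensionality="%d" %s Encoding="ASCII" Endian="LittleEndian">\n<Data>',
    intent, datatype, length(dims), dimattr),
    paste(sprintf(fmt, values), collapse = " "), "</Data>\n</DataArray>\n")
}

#' Write a mesh as an ASCII GIFTI surface file
#'
#' Emits a minimal GIFTI file with a `NIFTI_INTENT_POINTSET` and a
#' `NIFTI_INTENT_TRIANGLE` data array (ASCII encoding) for inspection in
#' standard surface viewers.
#'
#' @param mesh a [trimesh()].
#' @param path output path (`.surf.gii`).
#' @return `path`, invisibly.
#' @export
write_gifti_surface <- function(mesh, path) {
  txt <- paste0(
    sprintf(gifti_header, 2L),
    gifti_array("NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                dim(mesh$vertices), t(mesh$vertices), "%.9g"),
    gifti_array("NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                dim(mesh$faces), t(mesh$faces) - 1L, "%d"),
    "</GIFTI>\n")
  writeLines(txt, path)
  invisible(path)
}

# pull <Data> payloads and their Intent/Dim attributes from an ASCII GIFTI
parse_gifti_ascii <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("<GIFTI", txt, fixed = TRUE))
    sl_stop(sprintf("'%s' is not a GIFTI file", path), "surflight_format_error")
  starts <- gregexpr("<DataArray[^>]*>", txt)[[1]]
  if (starts[1] == -1L)
    sl_stop(sprintf("'%s' has no data arrays", path), "surflight_format_error")
  heads <- regmatches(txt, gregexpr("<DataArray[^>]*>", txt))[[1]]
  datas <- regmatches(txt, gregexpr("<Data>[^<]*</Data>", txt))[[1]]
  if (length(heads) != length(datas))
    sl_stop(sprintf("'%s' is malformed", path), "surflight_format_error")
  lapply(seq_along(heads), function(k) {
    h <- heads[k]
    attr1 <- function(name) {
      m <- regmatches(h, regexpr(sprintf('%s="[^"]*"', name), h))
      if (length(m) == 0L) return(NA_character_)
      sub(sprintf('%s="([^"]*)"', name), "\\1", m)
    }
    if (!identical(attr1("Encoding"), "ASCII"))
      sl_stop(sprintf("'%s': only ASCII-encoded GIFTI is supported", path),
              "surflight_format_error")
    dims <- as.integer(c(attr1("Dim0"), attr1("Dim1")))
    payload <- gsub("</?Data>", "", datas[k])
    vals <- as.numeric(strsplit(trimws(payload), "[[:space:]]+")[[1]])
    list(intent = attr1("Intent"), dims = dims[!is.na(dims)], values = vals)
  })
}

#' Read an ASCII GIFTI surface file
#'
#' @param path `.surf.gii` file written by [write_gifti_surface()] or any
#'   ASCII-encoded GIFTI surface.
#' @return A [trimesh()].
#' @export
read_gifti_surface <- function(path) {
  arrays <- parse_gifti_ascii(path)
  pts <- Filter(function(a) identical(a$intent, "NIFTI_INTENT_POINTSET"), arrays)
  tri <- Filter(function(a) identical(a$intent, "NIFTI_INTENT_TRIANGLE"), arrays)
  if (length(pts) != 1L || length(tri) != 1L)
    sl_stop(sprintf("'%s' lacks pointset/triangle arrays", path),
            "surflight_format_error")
  v <- matrix(pts[[1]]$values, ncol = 3, byrow = TRUE)
  f <- matrix(as.integer(tri[[1]]$values), ncol = 3, byrow = TRUE) + 1L
  trimesh(v, f)
}

#' Write a functional matrix as an ASCII GIFTI file
#'
#' One `NIFTI_INTENT_TIME_SERIES` data array per timepoint, each of length
#' `V`.
#'
#' @param mat `timepoints x V` matrix.
#' @param path output path (`.func.gii`).
#' @return `path`, invisibly.
#' @export
write_gifti_func <- function(mat, path) {
  arrays <- vapply(seq_len(nrow(mat)), function(t)
    gifti_array("NIFTI_INTENT_TIME_SERIES", "NIFTI_TYPE_FLOAT32",
                ncol(mat), mat[t, ], "%.9g"), character(1))
  writeLines(paste0(sprintf(gifti_header, nrow(mat)),
                    paste(arrays, collapse = ""), "</GIFTI>\n"), path)
  invisible(path)
}

# timepoints x V matrix from an ASCII functional GIFTI
read_gifti_func <- function(path) {
  arrays <- parse_gifti_ascii(path)
  lens <- vapply(arrays, function(a) length(a$values), integer(1))
  if (length(unique(lens)) != 1L)
    sl_stop(sprintf("'%s': data arrays have unequal lengths", path),
            "surflight_format_error")
  do.call(rbind, lapply(arrays, `[[`, "values"))
}

#' Per-vertex surface areas of a sphere mesh
#'
#' One third of the summed areas of a vertex's incident triangles, scaled to
#' a sphere of the given radius. Used to report cluster sizes in mm^2.
#'
#' @param mesh a [trimesh()].
#' @param radius sphere radius (mm); default 100, the conventional scale of
#'   spherical cortical templates.
#' @return Numeric vector of length `V`; sums to the total mesh area.
#' @export
vertex_areas <- function(mesh, radius = 100) {
  v <- mesh$vertices * radius
  f <- mesh$faces
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  fa <- 0.5 * sqrt(rowSums(cr^2))
  acc <- rowsum(rep(fa / 3, 3L), group = c(f[, 1], f[, 2], f[, 3]))
  out <- numeric(nrow(mesh$vertices))
  out[as.integer(rownames(acc))] <- acc
  out
}
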