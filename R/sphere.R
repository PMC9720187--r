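# Internal condition helper: all package errors carry a condition class so
# callers can distinguish usage errors from data errors.
sl_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "surflight_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Construct a triangulated sphere mesh
#'
#' A `trimesh` is a closed triangulation of the unit sphere: a `V x 3` matrix
#' of unit vertex coordinates and an `F x 3` integer matrix of vertex-index
#' triples. Edges are derived with [mesh_edges()].
#'
#' @param vertices numeric `V x 3` matrix; rows are normalized to unit length.
#' @param faces integer `F x 3` matrix of 1-based vertex indices.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L)
    sl_stop("vertices must be a V x 3 matrix", "surflight_invalid_parameter")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    sl_stop("face indices out of range", "surflight_invalid_parameter")
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
    sl_stop("degenerate face (repeated vertex index)", "surflight_invalid_parameter")
  nrm <- sqrt(rowSums(vertices^2))
  if (any(nrm == 0))
    sl_stop("zero-length vertex cannot be projected to the sphere",
            "surflight_invalid_input")
  structure(list(vertices = vertices / nrm, faces = faces),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<%s> %d vertices, %d faces, %d edges\n",
              paste(class(x), collapse = "/"),
              nrow(x$vertices), nrow(x$faces), nrow(mesh_edges(x))))
  invisible(x)
}

#' Undirected edge set of a triangulated mesh
#'
#' @param mesh a [trimesh()].
#' @return Integer `E x 2` matrix, each row a sorted vertex-index pair,
#'   rows in lexicographic order.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' The regular icosahedron on the unit sphere
#'
#' Base solid for geodesic subdivision: 12 vertices, 30 edges, 20 faces,
#' all vertices at unit radius and all edges the same length.
#'
#' @return A [trimesh()] with 12 vertices and 20 faces.
#' @export
base_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  trimesh(v, f)
}

# local linear index of barycentric grid point (i, j), 0 <= j <= i <= n
bary_index <- function(i, j) i * (i + 1L) / 2L + j + 1L

#' Geodesic sphere by icosahedron edge subdivision
#'
#' Each edge of the base triangulation is divided into `n_div` equal parts,
#' each face is triangulated into `n_div^2` subfaces, points shared between
#' faces (corners and edge points) are identified exactly, and all points are
#' projected to the unit sphere. The result has `10 * n_div^2 + 2` vertices,
#' `30 * n_div^2` edges and `20 * n_div^2` faces.
#'
#' Vertex order is deterministic: the 12 base vertices first, then edge points
#' grouped by sorted edge (oriented low index to high index), then interior
#' points grouped by face.
#'
#' @param base a [trimesh()], normally [base_icosahedron()].
#' @param n_div positive integer, number of equal parts per edge.
#' @return A `geodesic_sphere`: a [trimesh()] with an `n_div` field.
#' @examples
#' subdivide(base_icosahedron(), 4) # 162 vertices
#' @export
subdivide <- function(base, n_div) {
  if (length(n_div) != 1L || is.na(n_div) || n_div < 1 || n_div != round(n_div))
    sl_stop("n_div must be a positive integer", "surflight_invalid_parameter")
  n <- as.integer(n_div)
  if (n == 1L) {
    out <- trimesh(base$vertices, base$faces)
    out$n_div <- 1L
    class(out) <- c("geodesic_sphere", "trimesh")
    return(out)
  }
  V0 <- base$vertices
  F0 <- base$faces
  nv0 <- nrow(V0)
  E0 <- mesh_edges(base)
  ne0 <- nrow(E0)
  ekey <- (E0[, 1] - 1) * nv0 + E0[, 2]

  n_edge_pts <- ne0 * (n - 1L)
  n_int <- (n - 1L) * (n - 2L) / 2L              # interior points per face
  n_total <- nv0 + n_edge_pts + nrow(F0) * n_int

  verts <- matrix(0, n_total, 3)
  verts[seq_len(nv0), ] <- V0
  # edge points, edge-major, fraction k/n from the low- to the high-index end
  w <- rep(seq_len(n - 1L) / n, times = ne0)
  ia <- rep(E0[, 1], each = n - 1L)
  ib <- rep(E0[, 2], each = n - 1L)
  verts[nv0 + seq_len(n_edge_pts), ] <- (1 - w) * V0[ia, ] + w * V0[ib, ]

  edge_start <- nv0 + (seq_len(ne0) - 1L) * (n - 1L)   # offset before point k

  # barycentric grid templates (shared across faces)
  ii_up <- rep(0:(n - 1L), times = seq_len(n))
  jj_up <- sequence(seq_len(n)) - 1L
  ii_dn <- rep(seq_len(n - 1L), times = seq_len(n - 1L))
  jj_dn <- sequence(seq_len(n - 1L)) - 1L
  if (n_int > 0L) {
    ii_in <- rep(2:(n - 1L), times = seq_len(n - 2L))
    jj_in <- sequence(seq_len(n - 2L))
  }

  faces <- matrix(0L, nrow(F0) * n^2, 3)
  n_up <- length(ii_up)
  for (f in seq_len(nrow(F0))) {
    v1 <- F0[f, 1]; v2 <- F0[f, 2]; v3 <- F0[f, 3]
    idx <- integer(bary_index(n, n))
    idx[bary_index(0L, 0L)] <- v1
    idx[bary_index(n, 0L)] <- v2
    idx[bary_index(n, n)] <- v3
    k <- seq_len(n - 1L)
    edge_pts <- function(a, b) {
      if (a < b) edge_start[match((a - 1) * nv0 + b, ekey)] + k
      else edge_start[match((b - 1) * nv0 + a, ekey)] + (n - k)
    }
    idx[bary_index(k, 0L)] <- edge_pts(v1, v2)
    idx[bary_index(k, k)] <- edge_pts(v1, v3)
    idx[bary_index(n, k)] <- edge_pts(v2, v3)
    if (n_int > 0L) {
      g0 <- nv0 + n_edge_pts + (f - 1L) * n_int
      loc <- (ii_in - 2L) * (ii_in - 1L) / 2L + jj_in
      idx[bary_index(ii_in, jj_in)] <- g0 + loc
      verts[g0 + loc, ] <- ((n - ii_in) * V0[rep(v1, n_int), ] +
                              (ii_in - jj_in) * V0[rep(v2, n_int), ] +
                              jj_in * V0[rep(v3, n_int), ]) / n
    }
    block <- (f - 1L) * n^2
    faces[block + seq_len(n_up), ] <- cbind(
      idx[bary_index(ii_up, jj_up)],
      idx[bary_index(ii_up + 1L, jj_up)],
      idx[bary_index(ii_up + 1L, jj_up + 1L)]
    )
    faces[block + n_up + seq_len(n^2 - n_up), ] <- cbind(
      idx[bary_index(ii_dn, jj_dn)],
      idx[bary_index(ii_dn + 1L, jj_dn + 1L)],
      idx[bary_index(ii_dn, jj_dn + 1L)]
    )
  }
  out <- trimesh(verts, faces)
  out$n_div <- n
  class(out) <- c("geodesic_sphere", "trimesh")
  out
}

#' Cartesian to spherical coordinates
#'
#' Convention: longitude `alpha = atan2(y, x)` in `[-pi, pi)`, latitude
#' `beta = asin(z)` in `[-pi/2, pi/2]`; the spherical origin `(0, 0)` is the
#' Cartesian point `(1, 0, 0)`. At the poles `alpha` is set to 0.
#'
#' @param v unit 3-vector, or an `N x 3` matrix of unit rows.
#' @return Named numeric vector `c(alpha, beta)`, or an `N x 2` matrix.
#' @export
cart_to_sph <- function(v) {
  if (is.matrix(v)) {
    nrm <- sqrt(rowSums(v^2))
    if (any(nrm < 1e-12))
      sl_stop("zero vector has no spherical coordinates", "surflight_invalid_input")
    a <- atan2(v[, 2], v[, 1])
    b <- asin(pmin(1, pmax(-1, v[, 3] / nrm)))
    a[abs(abs(b) - pi / 2) < 1e-12] <- 0
    return(cbind(alpha = a, beta = b))
  }
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12)
    sl_stop("zero vector has no spherical coordinates", "surflight_invalid_input")
  b <- asin(min(1, max(-1, v[3] / nrm)))
  a <- if (abs(abs(b) - pi / 2) < 1e-12) 0 else atan2(v[2], v[1])
  c(alpha = a, beta = b)
}

#' Spherical to Cartesian coordinates
#'
#' Inverse of [cart_to_sph()] under the same convention.
#'
#' @param coord numeric `c(alpha, beta)` or an `N x 2` matrix.
#' @return Unit 3-vector or `N x 3` matrix.
#' @export
sph_to_cart <- function(coord) {
  if (is.matrix(coord)) {
    a <- coord[, 1]; b <- coord[, 2]
    return(cbind(x = cos(b) * cos(a), y = cos(b) * sin(a), z = sin(b)))
  }
  a <- coord[1]; b <- coord[2]
  c(x = cos(b) * cos(a), y = cos(b) * sin(a), z = sin(b))
}

#' Rotation carrying a spherical point to the origin
#'
#' Returns the rotation matrix `R = Ry(beta) %*% Rz(-alpha)` that maps the
#' point at spherical coordinates `(alpha, beta)` to the spherical origin
#' `(1, 0, 0)`. The composition first removes the longitude, then the
#' latitude, which fixes the in-plane (roll) orientation of the rotated frame
#' to zero so searchlight grids are reproducible.
#'
#' @param coord numeric `c(alpha, beta)`.
#' @return A 3 x 3 orthogonal matrix with determinant +1.
#' @export
rotation_to_origin <- function(coord) {
  a <- coord[1]; b <- coord[2]
  rz <- rbind(c(cos(a), sin(a), 0), c(-sin(a), cos(a), 0), c(0, 0, 1))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  ry %*% rz
}

#' Group high-resolution vertices to their nearest downsampled vertices
#'
#' Every vertex of the high-resolution sphere is assigned to the
#' low-resolution vertex at minimal angular (equivalently Euclidean) distance,
#' partitioning the high-resolution template into patches around the
#' downsampled vertices. Ties are broken by the lowest low-resolution index.
#'
#' @param high,low meshes on the unit sphere ([subdivide()] results or any
#'   [trimesh()]).
#' @return A `vertex_mapping`: list with `assignment` (integer of length
#'   `V_high`) and `groups` (list of length `V_low` of high-res indices).
#' @export
nearest_assignment <- function(high, low) {
  H <- high$vertices
  L <- t(low$vertices)
  vh <- nrow(H)
  assignment <- integer(vh)
  chunk <- 4096L
  for (s in seq(1L, vh, by = chunk)) {
    e <- min(s + chunk - 1L, vh)
    d <- H[s:e, , drop = FALSE] %*% L      # cosine similarity; max = nearest
    # lowest-index tie-break with a tolerance: symmetric meshes put many
    # vertices exactly equidistant from two candidates
    best <- d[cbind(seq_len(nrow(d)), max.col(d, ties.method = "first"))]
    assignment[s:e] <- max.col(d >= best - 1e-9, ties.method = "first")
  }
  groups <- split(seq_len(vh), factor(assignment, levels = seq_len(ncol(L))))
  names(groups) <- NULL
  structure(list(assignment = assignment, groups = groups),
            class = "vertex_mapping")
}

#' Mesh-edge adjacency of a sphere template
#'
#' Neighbors of each vertex are the vertices sharing a mesh edge with it.
#' This is the adjacency used to trace clusters of significant vertices.
#'
#' @param mesh a [trimesh()].
#' @return List of length `V`; element `i` is the sorted integer vector of
#'   neighbors of vertex `i`.
#' @export
build_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  v <- nrow(mesh$vertices)
  nb <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(v)))
  nb <- lapply(nb, function(x) sort(unique(x)))
  names(nb) <- NULL
  nb
}

#' Angular distance between unit vectors
#'
#' @param a,b unit 3-vectors or `N x 3` matrices.
#' @return Angle(s) in radians.
#' @keywords internal
angular_distance <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- if (is.matrix(a)) a else matrix(a, nrow(b), 3, byrow = TRUE)
    b <- if (is.matrix(b)) b else matrix(b, nrow(a), 3, byrow = TRUE)
    return(acos(pmin(1, pmax(-1, rowSums(a * b)))))
  }
  acos(min(1, max(-1, sum(a * b))))
}
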