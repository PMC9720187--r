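test_that("circular mask keeps exactly the cells within radius n1/2", {
  expect_equal(sum(circular_mask(1)), 1)
  expect_equal(sum(circular_mask(3)), 9)   # max center distance sqrt(2) < 1.5
  m11 <- circular_mask(11)
  ctr <- (1:11) - 0.5 - 5.5
  oracle <- outer(ctr, ctr, function(a, b) sqrt(a^2 + b^2)) <= 5.5
  expect_equal(unclass(m11), oracle, ignore_attr = TRUE)
  expect_true(m11[6, 6])
  expect_equal(unclass(m11), unclass(m11)[11:1, ])   # 4-fold symmetry
  expect_equal(unclass(m11), t(unclass(m11)))
  expect_error(circular_mask(4), class = "surflight_invalid_parameter")
  expect_error(circular_mask(-1), class = "surflight_invalid_parameter")
})

test_that("layout records have n1^2+3 fields and the center vertex lands in the center cell", {
  lay <- fx_layout()
  n1 <- lay$spec$n1
  expect_equal(length(lay$records), 42)
  rec <- lay$records[[5]]
  expect_equal(length(rec$cells), n1^2)
  expect_equal(length(rec) + n1^2 - 1L, n1^2 + 3L)  # coord+cells+own+neighbors
  # cells of one record are pairwise disjoint
  for (r in lay$records) expect_false(any(duplicated(unlist(r$cells))))
  # identity template: every vertex appears in its own center cell
  low <- fx_low()
  adj <- build_adjacency(low)
  lay_id <- build_layout(low, low, nearest_assignment(low, low), adj,
                         grid_spec())
  center_cell <- (n1 - 1) / 2 * n1 + (n1 - 1) / 2 + 1
  for (p in seq_len(42))
    expect_true(p %in% lay_id$records[[p]]$cells[[center_cell]])
})

test_that("cell assignment equals an independent rotation + floor-binning recomputation", {
  lay <- fx_layout()
  high <- fx_high(); low <- fx_low()
  cs <- lay$spec$cell_size; n1 <- lay$spec$n1
  for (p in c(1, 7, 23, 42)) {
    R <- rotation_to_origin(cart_to_sph(low$vertices[p, ]))
    ab <- cart_to_sph(high$vertices %*% t(R))
    i0 <- floor(ab[, 1] / cs + n1 / 2)
    j0 <- floor(ab[, 2] / cs + n1 / 2)
    ok <- i0 >= 0 & i0 < n1 & j0 >= 0 & j0 < n1
    expected <- split(which(ok), i0[ok] * n1 + j0[ok] + 1)
    got <- lay$records[[p]]$cells
    expect_equal(sum(lengths(got)), sum(ok))
    for (nm in names(expected))
      expect_equal(got[[as.integer(nm)]], expected[[nm]])
  }
})

test_that("searchlight members stay within the grid circumradius of the center", {
  lay <- fx_layout()
  high <- fx_high(); low <- fx_low()
  bound <- lay$spec$cell_size * lay$spec$n1 * sqrt(2) / 2 + 1e-9
  for (p in seq_len(42)) {
    mem <- unlist(lay$records[[p]]$cells)
    if (length(mem))
      expect_true(all(angular_distance(high$vertices[mem, , drop = FALSE],
                                       low$vertices[p, ]) <= bound))
  }
})

test_that("assigned vertex counts are monotone in grid size", {
  high <- fx_high(); low <- fx_low()
  m <- fx_mapping(); adj <- build_adjacency(low)
  tot <- sapply(c(5, 7, 11), function(n1) {
    lay <- build_layout(high, low, m, adj, grid_spec(1 / 35, n1))
    sum(vapply(lay$records, function(r) sum(lengths(r$cells)), numeric(1)))
  })
  expect_true(all(diff(tot) >= 0))
})

test_that("searchlight images are per-cell means, zero outside the mask, linear", {
  lay <- fx_layout()
  mask <- circular_mask(11)
  set.seed(42)
  X <- matrix(rnorm(6 * 642), 6)
  img <- searchlight_image(X, lay, 7)
  expect_equal(dim(img), c(6, 11, 11))
  fl <- flatten(img)
  cells <- lay$records[[7]]$cells
  keep <- as.vector(t(unclass(mask)))
  for (c in which(lengths(cells) > 0 & keep))
    expect_equal(fl[, c], rowMeans(X[, cells[[c]], drop = FALSE]))
  expect_true(all(fl[, !keep | lengths(cells) == 0] == 0))
  # constant input: every nonempty kept cell equals the constant
  img1 <- flatten(searchlight_image(matrix(3.5, 2, 642), lay, 7))
  expect_true(all(img1[, lengths(cells) > 0 & keep] == 3.5))
  # linearity
  Y <- matrix(rnorm(6 * 642), 6)
  lhs <- flatten(searchlight_image(2 * X - 5 * Y, lay, 7))
  rhs <- 2 * fl - 5 * flatten(searchlight_image(Y, lay, 7))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(searchlight_image(X, lay, 99), class = "surflight_index_error")
})

test_that("flatten is the row-major order and reshaping inverts it", {
  lay <- fx_layout()
  set.seed(9)
  X <- matrix(rnorm(3 * 642), 3)
  img <- searchlight_image(X, lay, 11)
  fl <- flatten(img)
  expect_equal(ncol(fl), 121)
  for (i in 1:11) for (j in 1:11)
    expect_equal(fl[, (i - 1) * 11 + j], img[, i, j])
})

test_that("layout building is deterministic and serialization round-trips", {
  high <- fx_high(); low <- fx_low()
  m <- fx_mapping(); adj <- build_adjacency(low)
  a <- build_layout(high, low, m, adj, grid_spec())
  b <- build_layout(high, low, m, adj, grid_spec())
  expect_identical(a, b)
  path <- file.path(tempdir(), paste0(layout_stem(a$spec), "_lh.rds"))
  expect_equal(layout_stem(a$spec), "35_11")
  save_layout(a, path)
  expect_identical(load_layout(path), a)
  # truncated file is a format error
  raw <- readBin(path, "raw", file.size(path))
  trunc <- tempfile(fileext = ".rds")
  writeBin(raw[1:20], trunc)
  expect_error(load_layout(trunc), class = "surflight_format_error")
  # wrong object type is a format error
  other <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_layout(other), class = "surflight_format_error")
})
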