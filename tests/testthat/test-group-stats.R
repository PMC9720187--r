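test_that("group t-test matches the textbook formula and reference routine", {
  tm <- group_ttest(matrix(c(0.6, 0.7, 0.8), 3, 1), chance = 0.5)
  expect_equal(tm$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(tm$df, 2)

  set.seed(21)
  a <- matrix(runif(6 * 40, 0.2, 0.9), 6)
  tm2 <- group_ttest(a, chance = 0.5)
  ref <- apply(a, 2, function(x)
    unname(stats::t.test(x, mu = 0.5, alternative = "greater")$statistic))
  expect_lt(max(abs(tm2$t - ref)), 1e-9)

  # zero-variance conventions
  tm3 <- group_ttest(matrix(c(.9, .9, .5, .5, .1, .1), 2), chance = 0.5)
  expect_equal(tm3$t, c(Inf, 0, -Inf))
  expect_error(group_ttest(matrix(0.5, 1, 3), chance = 0.5),
               class = "surflight_invalid_design")
})

test_that("vertex-wise thresholding marks p < 10^-threshold, one-tailed, monotone", {
  set.seed(3)
  a <- matrix(runif(8 * 100, 0.3, 0.95), 8)
  tm <- group_ttest(a, chance = 0.5)
  p <- stats::pt(tm$t, df = tm$df, lower.tail = FALSE)
  expect_equal(threshold_map(tm, 3), p < 1e-3)
  expect_equal(threshold_map(tm, 1), p < 0.1)
  # monotone: stricter threshold marks a subset
  expect_true(all(which(threshold_map(tm, 3)) %in% which(threshold_map(tm, 2))))
  # all-zero t marks nothing; +Inf is always marked
  tm0 <- list(t = rep(0, 5), df = 7, chance = .5)
  expect_false(any(threshold_map(tm0, 3)))
  tmi <- list(t = c(Inf, -Inf, 0), df = 7, chance = .5)
  expect_equal(threshold_map(tmi, 3), c(TRUE, FALSE, FALSE))
})

test_that("cluster detection equals a union-find oracle on random maps", {
  s4 <- fx_sphere4(); adj <- fx_adj4()
  edges <- mesh_edges(s4)
  expect_length(find_clusters(rep(FALSE, 162), adj), 0)
  all_cl <- find_clusters(rep(TRUE, 162), adj)
  expect_length(all_cl, 1)
  expect_equal(all_cl[[1]]$size, 162)
  set.seed(33)
  for (rep in 1:100) {
    marked <- runif(162) < runif(1, 0.05, 0.6)
    cl <- find_clusters(marked, adj)
    expect_equal(sort(vapply(cl, `[[`, integer(1), "size")),
                 uf_cluster_sizes(marked, edges))
    expect_equal(sum(vapply(cl, function(c) length(c$vertices), integer(1))),
                 sum(marked))
  }
})

test_that("cluster vertices partition the marked set and stay connected", {
  adj <- fx_adj4()
  set.seed(14)
  marked <- runif(162) < 0.4
  cl <- find_clusters(marked, adj)
  all_v <- unlist(lapply(cl, `[[`, "vertices"))
  expect_setequal(all_v, which(marked))
  expect_false(any(duplicated(all_v)))
  for (c in cl) {
    if (c$size == 1) next
    # each member reaches another member through the adjacency
    expect_true(all(vapply(c$vertices, function(v)
      any(adj[[v]] %in% c$vertices), logical(1))))
  }
})

test_that("sign-flip null is seeded-reproducible and identity at flip probability 0", {
  adj <- fx_adj4()
  tm <- list(t = ifelse(seq_len(162) %in% c(3, 4, 10, 11), 12, 0.1),
             df = 7, chance = 0.5)
  sp <- threshold_spec(3, 0.05, 200, seed = 17)
  n1 <- signflip_null(tm, adj, sp)
  n2 <- signflip_null(tm, adj, sp)
  expect_identical(n1, n2)
  expect_equal(n1$threshold_rank, 10)
  obs <- max_cluster_size(threshold_map(tm, 3), adj)
  n0 <- signflip_null(tm, adj, sp, flip_prob = 0)
  expect_true(all(n0$max_sizes == obs))
  # nothing over threshold in either sign: all maxima zero
  tmz <- list(t = rep(0.5, 162), df = 7, chance = 0.5)
  expect_true(all(signflip_null(tmz, adj, sp)$max_sizes == 0))
})

test_that("null distribution is symmetric under global sign inversion of the t-map", {
  adj <- fx_adj4()
  set.seed(25)
  tvals <- rnorm(162, sd = 4)              # symmetric synthetic t-map
  sp <- threshold_spec(2, 0.05, 400, seed = 5)
  n_pos <- signflip_null(list(t = tvals, df = 7, chance = .5), adj, sp)
  n_neg <- signflip_null(list(t = -tvals, df = 7, chance = .5), adj,
                         threshold_spec(2, 0.05, 400, seed = 6))
  # same distribution within Monte-Carlo error
  expect_lt(abs(mean(n_pos$max_sizes) - mean(n_neg$max_sizes)),
            4 * sd(n_pos$max_sizes) / sqrt(400) * 2 + 0.5)
  expect_lt(abs(stats::median(n_pos$max_sizes) -
                  stats::median(n_neg$max_sizes)), 2)
})

test_that("FWE filtering keeps clusters strictly larger than the ranked null size", {
  sp <- threshold_spec()                   # defaults: alpha .01, 2000 perms
  expect_equal(round(sp$fwe_alpha * sp$n_perm), 20)
  cl <- list(list(vertices = 1:4, size = 4L, peak_t = 5, peak_vertex = 1),
             list(vertices = 10:16, size = 7L, peak_t = 6, peak_vertex = 10))
  null <- list(max_sizes = rep(4L, 100), threshold_rank = 20L,
               threshold_size = 4L)
  surv <- fwe_filter(cl, null, sp)
  expect_length(surv, 1)                   # size == threshold is removed
  expect_equal(surv[[1]]$size, 7)
  null0 <- list(max_sizes = rep(0L, 100), threshold_rank = 20L,
                threshold_size = 0L)
  expect_length(fwe_filter(cl, null0, sp), 2)
  expect_error(threshold_spec(3, 0.001, 100),
               class = "surflight_invalid_parameter")
})

test_that("cluster reports carry peaks, coordinates, and additive mm^2 sizes", {
  s4 <- fx_sphere4(); adj <- fx_adj4()
  set.seed(41)
  a <- matrix(0.5 + rnorm(8 * 162, sd = 0.05), 8)
  a[, c(2, 3, 4)] <- 0.95                  # one strong patch
  tm <- group_ttest(a, chance = 0.5)
  cl <- find_clusters(threshold_map(tm, 3), adj, tm)
  areas <- vertex_areas(s4, 100)
  rep_tab <- cluster_report(cl, tm, s4, areas)
  expect_true(all(diff(rep_tab$size_vertices) <= 0))
  expect_equal(sum(rep_tab$size_vertices),
               sum(vapply(cl, `[[`, integer(1), "size")))
  for (k in seq_len(nrow(rep_tab))) {
    match_cl <- cl[[which(vapply(cl, function(c)
      c$peak_vertex == rep_tab$peak_vertex[k], logical(1)))[1]]]
    expect_equal(rep_tab$peak_t[k], max(tm$t[match_cl$vertices]))
    expect_equal(rep_tab$size_mm2[k], sum(areas[match_cl$vertices]))
  }
  expect_equal(nrow(cluster_report(list(), tm, s4)), 0)
})

test_that("subject-level sign-flip inference controls FWE on smooth null maps", {
  adj <- fx_adj4()
  smooth1 <- function(x) vapply(seq_along(adj), function(v)
    mean(x[c(v, adj[[v]])]), numeric(1))
  set.seed(2024)
  vw <- -log10(0.05)
  hits <- 0
  n_data <- 200
  for (d in seq_len(n_data)) {
    noise <- t(apply(matrix(rnorm(8 * 162, sd = 0.08), 8), 1, smooth1))
    a <- 0.5 + noise                       # signal-free, spatially smooth
    tm <- group_ttest(a, chance = 0.5)
    sp <- threshold_spec(vw, 0.05, 500, seed = 9000 + d)
    cl <- find_clusters(threshold_map(tm, vw), adj, tm)
    null <- signflip_null(tm, adj, sp, method = "subject", maps = a)
    hits <- hits + (length(fwe_filter(cl, null, sp)) > 0)
  }
  half <- 2.576 * sqrt(0.05 * 0.95 / n_data)
  expect_gte(hits / n_data, 0.05 - half)
  expect_lte(hits / n_data, 0.05 + half)
})

test_that("per-vertex t-flip inference stays below the FWE ceiling under spatial independence", {
  adj <- fx_adj4()
  set.seed(2025)
  vw <- -log10(0.05)
  hits <- 0
  n_data <- 200
  for (d in seq_len(n_data)) {
    a <- 0.5 + matrix(rnorm(8 * 162, sd = 0.08), 8)
    tm <- group_ttest(a, chance = 0.5)
    sp <- threshold_spec(vw, 0.05, 500, seed = 19000 + d)
    cl <- find_clusters(threshold_map(tm, vw), adj, tm)
    null <- signflip_null(tm, adj, sp)
    hits <- hits + (length(fwe_filter(cl, null, sp)) > 0)
  }
  expect_lte(hits / n_data, 0.05 + 2.576 * sqrt(0.05 * 0.95 / n_data))
})

test_that("monotonicity: stricter vertex-wise thresholds never enlarge clusters", {
  adj <- fx_adj4()
  set.seed(55)
  a <- matrix(0.5 + rnorm(8 * 162, sd = 0.1), 8)
  tm <- group_ttest(a, chance = 0.5)
  for (vw in c(0.5, 1, 1.5)) {
    cl_loose <- find_clusters(threshold_map(tm, vw), adj)
    cl_strict <- find_clusters(threshold_map(tm, vw + 0.5), adj)
    # every strict cluster fits inside some loose cluster
    for (cs in cl_strict) {
      containing <- Filter(function(cl) all(cs$vertices %in% cl$vertices),
                           cl_loose)
      expect_gte(length(containing), 1)
      expect_lte(cs$size, max(vapply(cl_loose, `[[`, integer(1), "size")))
    }
  }
})
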