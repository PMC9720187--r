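test_that("leave-one-run-out folds cover each run as test exactly once", {
  f3 <- loro_folds(c("001", "001", "002", "002", "003"))
  expect_length(f3, 3)
  expect_setequal(vapply(f3, `[[`, character(1), "test"),
                  c("001", "002", "003"))
  for (f in f3) {
    expect_false(f$test %in% f$train)
    expect_length(f$train, 2)
  }
  f2 <- loro_folds(c("a", "b"))
  expect_length(f2, 2)
  expect_error(loro_folds(c("a", "a")), class = "surflight_invalid_design")
})

test_that("linear SVM decodes separable data perfectly and shuffled labels at chance", {
  set.seed(31)
  x <- matrix(rnorm(40 * 6), 40)
  x[1:20, 1] <- x[1:20, 1] + 8
  x[21:40, 1] <- x[21:40, 1] - 8
  y <- rep(c(1, 2), each = 20)
  expect_equal(mean(svm_decode(x, y, x) == y), 1)          # train = test
  xt <- matrix(rnorm(20 * 6), 20)
  xt[1:10, 1] <- xt[1:10, 1] + 8
  xt[11:20, 1] <- xt[11:20, 1] - 8
  expect_equal(mean(svm_decode(x, y, xt) == rep(c(1, 2), each = 10)), 1)
  expect_error(svm_decode(x, rep(1, 40), xt),
               class = "surflight_degenerate_design")

  # labels independent of features: accuracy inside the 99% binomial band
  set.seed(77)
  n <- 200
  xs <- matrix(rnorm(n * 10), n)
  ys <- sample(rep(1:2, each = n / 2))
  tr <- 1:150
  acc <- mean(svm_decode(xs[tr, ], ys[tr], xs[-tr, ]) == ys[-tr])
  half_width <- 2.576 * sqrt(0.25 / 50)
  expect_gt(acc, 0.5 - half_width)
  expect_lt(acc, 0.5 + half_width)
})

test_that("CNN stream learns separable images, is seeded-deterministic, covers all classes", {
  n1 <- 11
  imgs <- array(0, c(30, n1, n1))
  imgs[1:10, , ] <- 1
  imgs[11:20, , ] <- -1
  imgs[21:30, 4:6, ] <- 2                  # third pattern
  y <- rep(1:3, each = 10)
  pred <- cnn_decode(imgs, y, imgs, classifier_spec("cnn"))
  expect_equal(mean(pred == y), 1)
  expect_setequal(unique(pred), 1:3)       # one output unit per class in use
  pred2 <- cnn_decode(imgs, y, imgs, classifier_spec("cnn"))
  expect_identical(pred, pred2)
  expect_error(cnn_decode(imgs, rep(1, 30), imgs),
               class = "surflight_degenerate_design")
})

test_that("accuracy maps sit at chance without information and above it inside the patch", {
  lay <- fx_layout()
  # no-information: identical features for every trial
  n_tr <- 8
  flatpat <- matrix(1, n_tr * 3, 642)
  ts <- structure(list(patterns = flatpat,
                       labels = rep(c(1L, 2L), n_tr * 3 / 2),
                       runs = rep(1:3, each = n_tr), timepoint = 7),
                  class = "trial_set")
  m <- subject_accuracy_map(ts, lay, contrast = "1 vs 2")
  expect_equal(m$chance, 0.5)
  expect_true(all(abs(m$accuracy - 0.5) <= 0.5))  # in [0,1]
  expect_lt(max(abs(m$accuracy - 0.5)), 0.3)      # no systematic information

  # informative patch at the standard desk scale
  cfg <- sim_config(n_subjects = 1, seed = 5)
  sub <- simulate_subject(cfg, 555, fx_high16(), fx_sphere4())
  trials <- bind_trials(lapply(1:3, function(r)
    extract_trials(sub$runs[[r]], sub$paradigms[[r]], cfg$timepoint)))
  adj <- fx_adj4()
  inside <- c(cfg$patch_center, adj[[cfg$patch_center]])
  dist_to_patch <- graph_distances(adj, cfg$patch_center)
  outside <- which(dist_to_patch >= 4)[1:20]
  am <- subject_accuracy_map(trials, fx_layout164(), contrast = "1 vs 2",
                             vertices = c(inside, outside))
  expect_gt(mean(am$accuracy[inside]), mean(am$accuracy[outside]))
})

test_that("accuracy maps are invariant to trial order and vertex partitioning", {
  cfg <- sim_config(high_div = 8, low_div = 2, n_subjects = 1, n_runs = 2,
                    trials_per_condition_per_run = 5, effect_size = 1.5,
                    seed = 6)
  high <- fx_high(); low <- fx_low()
  sub <- simulate_subject(cfg, 99, high, low)
  trials <- bind_trials(lapply(1:2, function(r)
    extract_trials(sub$runs[[r]], sub$paradigms[[r]], cfg$timepoint)))
  lay <- build_layout(high, low, nearest_assignment(high, low),
                      build_adjacency(low), grid_spec())
  base <- subject_accuracy_map(trials, lay, contrast = "1 vs 2")

  # permute trials within runs
  set.seed(8)
  perm <- order(trials$runs, runif(length(trials$runs)))
  shuf <- structure(list(patterns = trials$patterns[perm, ],
                         labels = trials$labels[perm],
                         runs = trials$runs[perm], timepoint = 7),
                    class = "trial_set")
  expect_equal(subject_accuracy_map(shuf, lay, contrast = "1 vs 2")$accuracy,
               base$accuracy)

  # decode vertices in two batches: identical values wherever computed
  m1 <- subject_accuracy_map(trials, lay, contrast = "1 vs 2",
                             vertices = 1:20)
  m2 <- subject_accuracy_map(trials, lay, contrast = "1 vs 2",
                             vertices = 21:42)
  expect_equal(c(m1$accuracy[1:20], m2$accuracy[21:42]), base$accuracy)
})

test_that("superclass contrasts pool codes and set chance to 1/k", {
  c2 <- parse_contrast("1 3 vs 2 4")
  lay <- fx_layout()
  set.seed(12)
  ts <- structure(list(patterns = matrix(rnorm(24 * 642), 24),
                       labels = rep(c(1L, 2L, 3L, 4L, 5L, 1L), 4),
                       runs = rep(1:2, each = 12), timepoint = 7),
                  class = "trial_set")
  m <- subject_accuracy_map(ts, lay, contrast = c2, vertices = 1:2)
  expect_equal(m$chance, 0.5)
  # a code absent from the data is a contrast error
  expect_error(
    subject_accuracy_map(ts, lay, contrast = "1 vs 9", vertices = 1),
    class = "surflight_contrast_error")
})
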