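test_that("cumulative performance is the empirical found-at distribution", {
  expect_equal(cumulative_performance(rep(1L, 10), n_max = 3)$cumulative, rep(1, 3))
  half <- cumulative_performance(c(2L, 2L, NA, NA), n_max = 4)
  expect_equal(half$cumulative, c(0, 0.5, 0.5, 0.5))
  # conservation: sum p(n) + fraction unfound = 1
  set.seed(71)
  fa <- sample(c(1:8, NA), 200, replace = TRUE)
  pc <- cumulative_performance(fa, n_max = 8)
  expect_equal(sum(pc$p) + mean(is.na(fa)), 1)
  expect_true(all(diff(pc$cumulative) >= 0))
})

test_that("array search reaches 100% cumulative performance at fixation six", {
  trials <- synth_array_trials(12, geometry = small_geometry(), box_px = 40, seed = 72)
  res <- lapply(trials, run_search, backbone = test_backbone(),
                config = search_config(ior_window = 12))
  pc <- cumulative_performance(res, n_max = 6)
  expect_equal(pc$cumulative[6], 1)
})

test_that("scanpath similarity is 1 for self, 0 for disjoint clusters", {
  sA <- fixation_sequence(data.frame(index = 1:4, row = c(10, 100, 200, 10),
                                     col = c(10, 100, 200, 10)), trial_id = "a")
  expect_equal(scanpath_similarity(sA, sA)$value, 1)
  sB <- fixation_sequence(data.frame(index = 1:3, row = c(500, 600, 700),
                                     col = c(500, 600, 700)), trial_id = "b")
  expect_equal(scanpath_similarity(sA, sB)$value, 0)
})

test_that("the alignment score is the worked dynamic-programming value", {
  # "ABC" vs "ABD": two matches over length three
  expect_equal(nw_align_score(c("A", "B", "C"), c("A", "B", "D")), 2)
  expect_equal(nw_align_score(character(0), c("A")), 0)
})

test_that("alignment equals exhaustive enumeration for strings up to length six", {
  set.seed(73)
  for (rep in 1:12) {
    a <- sample(1:4, sample(1:6, 1), replace = TRUE)
    b <- sample(1:4, sample(1:6, 1), replace = TRUE)
    expect_equal(nw_align_score(a, b), brute_align_score(a, b))
  }
})

test_that("scanpath similarity is symmetric and bounded", {
  set.seed(74)
  for (rep in 1:10) {
    fa <- data.frame(index = 1:5, row = runif(5, 1, 500), col = runif(5, 1, 500))
    fb <- data.frame(index = 1:7, row = runif(7, 1, 500), col = runif(7, 1, 500))
    sA <- fixation_sequence(fa, trial_id = "a")
    sB <- fixation_sequence(fb, trial_id = "b")
    v1 <- scanpath_similarity(sA, sB)$value
    v2 <- scanpath_similarity(sB, sA)$value
    expect_equal(v1, v2)
    expect_gte(v1, 0); expect_lte(v1, 1)
  }
})

test_that("mean-shift clusters nearby fixations together and far ones apart", {
  pts <- rbind(matrix(rnorm(40, 100, 5), 20, 2), matrix(rnorm(40, 400, 5), 20, 2))
  cl <- mean_shift_clusters(pts, bandwidth = 32)
  expect_equal(length(unique(cl$assignment[1:20])), 1)
  expect_equal(length(unique(cl$assignment[21:40])), 1)
  expect_false(cl$assignment[1] == cl$assignment[21])
})

test_that("fixation-count consistency pairs shared found trials", {
  a <- stats::setNames(c(2L, 3L, 5L, NA), sprintf("t%d", 1:4))
  b <- stats::setNames(c(2L, 3L, 5L, 4L), sprintf("t%d", 1:4))
  same <- fixation_count_pairs(a, b)
  expect_equal(same$rho, 1)
  expect_equal(same$n, 3) # the NA trial is excluded
  expect_error(fixation_count_pairs(a, stats::setNames(1L, "zz")), "no shared")
  # correlation equals a direct recomputation from the emitted pairs
  set.seed(75)
  x <- stats::setNames(sample(1:20, 30, replace = TRUE), sprintf("t%d", 1:30))
  y <- stats::setNames(sample(1:20, 30, replace = TRUE), sprintf("t%d", 1:30))
  fc <- fixation_count_pairs(x, y)
  expect_equal(fc$rho, cor(fc$pairs$found_A, fc$pairs$found_B, method = "spearman"))
})

test_that("never-revisiting scanpaths yield a zero revisit curve", {
  geom <- display_geometry()
  sp <- scanpath_spec(n_sequences = 30, mean_length = 12, revisit_radius_deg = 3,
                      seed = 76)
  rc <- estimate_revisit_curve(synth_scanpaths(sp, geom),
                               revisit_radius_px = 96, max_lag = 8)
  expect_true(all(rc$p[rc$n_pairs > 0] == 0))
  short <- list(fixation_sequence(data.frame(index = 1, row = 1, col = 1)))
  expect_error(estimate_revisit_curve(short, 96, 8), "fewer than 2")
})

test_that("the subject split holds out the right number of subjects", {
  geom <- display_geometry()
  a <- 0.9; tau <- 3
  sp <- scanpath_spec(n_sequences = 60, mean_length = 40,
                      revisit_prob_by_lag = function(l) 0.6 * (1 - a * exp(-l / tau)),
                      max_lag = 10, revisit_radius_deg = 1.5, seed = 77)
  seqs <- synth_scanpaths(sp, geom)
  subjects <- rep(sprintf("s%02d", 1:15), each = 4)
  set.seed(77)
  fit <- fit_memory_params(seqs, revisit_radius_px = 48, max_lag = 10,
                           subjects = subjects, n_train = 7)
  expect_length(fit$train_subjects, 7)
  expect_length(fit$test_subjects, 8)
  expect_length(intersect(fit$train_subjects, fit$test_subjects), 0)
})

test_that("saccade amplitudes convert to degrees and ignore singletons", {
  geom <- display_geometry()
  two <- fixation_sequence(data.frame(index = 1:2, row = c(100, 196), col = c(50, 50)))
  st <- saccade_size_stats(list(two), geom)
  expect_equal(st$amplitudes_deg, 3) # 96 px at 32 px/deg
  one <- fixation_sequence(data.frame(index = 1, row = 1, col = 1))
  st2 <- saccade_size_stats(list(one, two), geom)
  expect_equal(st2$n, 1)
})

test_that("object distances are normalized, symmetric and bounded", {
  black <- matrix(0, 30, 30); white <- matrix(1, 40, 40)
  expect_equal(object_similarity(black, black), 0)
  expect_equal(object_similarity(black, white), 1)
  set.seed(78)
  a <- matrix(runif(900), 30, 30); b <- matrix(runif(400), 20, 20)
  expect_equal(object_similarity(a, b), object_similarity(b, a))
  expect_lte(object_similarity(a, b), 1)
})
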