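test_that("winner-take-all picks the global maximum with row-major ties", {
  m <- matrix(0, 20, 30); m[10, 20] <- 5
  expect_equal(unname(wta_next_fixation(attention_map(m))), c(10, 20))
  m2 <- matrix(0, 6, 6); m2[1, 5] <- 1; m2[4, 2] <- 1
  expect_equal(unname(wta_next_fixation(attention_map(m2))), c(1, 5))
  set.seed(41)
  for (rep in 1:100) { # linear-scan oracle
    m <- matrix(rnorm(35), 5, 7)
    got <- wta_next_fixation(attention_map(m))
    best <- c(Inf, Inf); bv <- -Inf
    for (i in 1:5) for (j in 1:7) if (m[i, j] > bv) { bv <- m[i, j]; best <- c(i, j) }
    expect_equal(unname(got), best)
  }
  expect_error(wta_next_fixation(attention_map(matrix(-Inf, 2, 2))), "exhausted")
})

test_that("infinite inhibition masks the right cells and exhausts a map", {
  m <- attention_map(matrix(1, 7, 7))
  masked <- apply_infinite_ior(m, c(4, 4), 3)
  expect_equal(sum(!is.finite(unclass(masked))), 9)
  corner <- apply_infinite_ior(m, c(1, 1), 3)
  expect_equal(sum(!is.finite(unclass(corner))), ceiling(3 / 2)^2)
  # repeated WTA + IOR visits every cell of a 6-cell map exactly once
  set.seed(42)
  m6 <- attention_map(matrix(runif(6), 2, 3))
  seen <- character(0)
  for (t in 1:6) {
    fx <- wta_next_fixation(m6)
    seen <- c(seen, paste(fx, collapse = ","))
    m6 <- apply_infinite_ior(m6, fx, 1)
  }
  expect_length(unique(seen), 6)
  expect_error(wta_next_fixation(m6), "exhausted")
})

test_that("the memory function has the stated closed form and limits", {
  expect_equal(memory_weight(1:10, memory_params(a = 0, tau = 5)), rep(1, 10))
  expect_gt(memory_weight(1, memory_params(a = 1, tau = 1e-6)), 1 - 1e-9)
  expect_equal(memory_weight(2, memory_params(a = 1, tau = 2)), 1 - exp(-1))
  expect_equal(memory_weight(3, memory_params(a = 0.8, tau = 2)),
               1 - 0.8 * exp(-1.5))
})

test_that("finite inhibition weights revisited regions and recovers the map", {
  m <- attention_map(matrix(runif(400, 0.5, 1), 20, 20))
  empty <- data.frame(index = integer(), row = numeric(), col = numeric())
  expect_equal(unclass(apply_finite_ior(m, empty, memory_params(0.9, 2, 3), 1)),
               unclass(m))
  h <- data.frame(index = 1L, row = 10, col = 10)
  A <- apply_finite_ior(m, h, memory_params(a = 0.8, tau = 2, revisit_radius_px = 3), 4)
  w_expect <- 1 - 0.8 * exp(-1.5) # lag 3
  expect_equal(unclass(A)[10, 10], unclass(m)[10, 10] * w_expect)
  expect_equal(unclass(A)[10, 14], unclass(m)[10, 14]) # outside the radius
})

test_that("finite IOR with a = 1 and huge tau reproduces infinite IOR sequences", {
  m <- matrix(0, 60, 60)
  pts <- rbind(c(10, 10), c(10, 50), c(30, 30), c(50, 10), c(50, 50))
  for (i in 1:5) m[pts[i, 1], pts[i, 2]] <- 1 - i * 0.1 # isolated, ordered peaks
  mm <- attention_map(m)
  mp <- memory_params(a = 1, tau = 1e9, revisit_radius_px = 5)
  inf_seq <- list(); fin_seq <- list()
  m_inf <- mm
  hist <- data.frame(index = integer(), row = numeric(), col = numeric())
  for (t in 1:5) {
    fi <- wta_next_fixation(m_inf); inf_seq[[t]] <- fi
    m_inf <- apply_infinite_ior(m_inf, fi, 5)
    ff <- wta_next_fixation(apply_finite_ior(mm, hist, mp, t)); fin_seq[[t]] <- ff
    hist <- rbind(hist, data.frame(index = t, row = ff[1], col = ff[2]))
  }
  expect_identical(inf_seq, fin_seq)
})

test_that("the saccade-size constraint is a radial gamma with unit peak", {
  geom <- display_geometry()
  p <- saccade_size_params(shape = 2, scale = 1.5, geometry = geom)
  m <- size_constraint_map(c(201, 201), c(101, 101), p)
  expect_equal(max(m), 1)
  # radial symmetry
  expect_equal(m[101, 181], m[101, 21], tolerance = 1e-9)
  expect_equal(m[21, 101], m[181, 101], tolerance = 1e-9)
  # peak ring at the gamma mode, (shape-1)*scale = 1.5 deg = 48 px
  mode_px <- round((2 - 1) * 1.5 * geom$px_per_deg)
  ring_val <- m[101, 101 + mode_px]
  expect_gt(ring_val, m[101, 105])  # near the current fixation
  expect_gt(ring_val, m[101, 201])  # far in the periphery
  expect_equal(ring_val, 1, tolerance = 0.01)
})

test_that("the size constraint combines as a weighted sum", {
  a <- attention_map(matrix(runif(100), 10, 10))
  b <- matrix(runif(100), 10, 10)
  expect_equal(unclass(combine_size_constraint(a, b, w = 1)), unclass(a),
               ignore_attr = TRUE)
  expect_equal(unclass(combine_size_constraint(a, b, w = 0)), b,
               ignore_attr = TRUE)
  mixed <- combine_size_constraint(a, b, w = 0.2346)
  expect_equal(unclass(mixed)[3, 7], 0.2346 * unclass(a)[3, 7] + (1 - 0.2346) * b[3, 7])
  expect_error(combine_size_constraint(a, matrix(0, 2, 2), 0.5), "shapes differ")
})

test_that("the oracle accepts fixations in the detection window only", {
  box <- bounding_box(100, 200, 50, 50) # centre (124.5, 224.5) -> rounded (124, 224)
  expect_true(oracle_check(box_center(box), box, NULL))
  expect_true(oracle_check(c(124, 224), box, 45))
  # 45-px window rows: 124 - 22 .. 124 + 22
  expect_true(oracle_check(c(102, 224), box, 45))
  expect_false(oracle_check(c(101, 224), box, 45)) # 1 px outside
  expect_true(oracle_check(c(124, 246), box, 45))
  expect_false(oracle_check(c(124, 247), box, 45))
  # window NULL: the box itself
  expect_true(oracle_check(c(100, 200), box, NULL))
  expect_false(oracle_check(c(99, 200), box, NULL))
})

test_that("recognition compares normalized descriptors with a strict threshold", {
  bb <- test_backbone()
  set.seed(43)
  tgt <- matrix(runif(40 * 40), 40, 40)
  scene <- matrix(0.5, 120, 120)
  scene[41:80, 41:80] <- tgt
  # crop pixel-identical to the target -> distance 0 -> found
  expect_true(recognition_check(bb, scene, c(60.5, 60.5), tgt, 40))
  # strictness: distance 0 is NOT below a threshold of 0
  expect_false(recognition_check(bb, scene, c(60.5, 60.5), tgt, 40, threshold = 0))
  # a zero crop has a zero descriptor: distance 1 >= 0.9 -> not found
  dark <- matrix(0, 120, 120)
  expect_false(recognition_check(bb, dark, c(60, 60), tgt, 40))
  expect_error(recognition_check(bb, scene, c(500, 500), tgt, 40), "outside")
})

test_that("a pixel-identical planted target is found at the first fixation", {
  tr <- planted_trial()
  res <- run_search(tr, test_backbone(), search_config(ior_window = 40))
  expect_equal(res$found_at, 1L)
})

test_that("object arrays are solved within six fixations by any backbone", {
  trials <- synth_array_trials(6, geometry = small_geometry(), box_px = 40, seed = 44)
  for (bb in list(test_backbone(), make_random_weights_backbone(seed = 3))) {
    found <- vapply(trials, function(tr)
      run_search(tr, bb, search_config(ior_window = 12))$found_at, integer(1))
    expect_true(all(found >= 1 & found <= 6))
  }
})

test_that("the fixation cap is honoured when the target is never found", {
  tr <- planted_trial()
  # an unfindable target: oracle window far from any attention maximum
  tr$target_box <- bounding_box(1, 1, 4, 4)
  res <- run_search(tr, test_backbone(),
                    search_config(ior_window = 4, max_fixations = 7))
  expect_true(is.na(res$found_at))
  expect_equal(nrow(res$fixations), 7)
})

test_that("the full pipeline is deterministic given weights, trial and config", {
  tr <- synth_array_trials(1, geometry = small_geometry(), box_px = 40, seed = 45)[[1]]
  r1 <- run_search(tr, test_backbone(), search_config(ior_window = 12))
  r2 <- run_search(tr, test_backbone(), search_config(ior_window = 12))
  expect_identical(r1$fixations, r2$fixations)
  expect_identical(r1$found_at, r2$found_at)
})

test_that("infinite IOR keeps fixations apart in pixel mode", {
  tr <- planted_trial()
  tr$target_box <- bounding_box(1, 1, 4, 4) # never found: full trajectory
  res <- run_search(tr, test_backbone(),
                    search_config(ior_window = 20, max_fixations = 10))
  f <- res$fixations
  for (i in seq_len(nrow(f) - 1)) {
    for (j in (i + 1):nrow(f)) {
      dr <- f$row[j] - f$row[i]; dc <- f$col[j] - f$col[i]
      inside <- dr >= -10 && dr <= 9 && dc >= -10 && dc <= 9 # half-open 20-px window
      expect_false(inside)
    }
  }
})
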