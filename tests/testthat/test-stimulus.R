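test_that("object normalization produces a tight box of the requested size", {
  set.seed(1)
  # 312 x 156 content: scaled by 0.5 to 156 x 78, padded to square
  obj <- matrix(0.5, 400, 200)
  obj[45:356, 23:178] <- runif(312 * 156)
  out <- normalize_object_image(obj, box_px = 156)
  expect_equal(dim(out), c(156, 156))
  mask <- abs(out - 0.5) > 1e-3
  rr <- range(which(rowSums(mask) > 0)); cc <- range(which(colSums(mask) > 0))
  expect_equal(diff(rr) + 1, 156)
  expect_true(abs((diff(cc) + 1) - 78) <= 2) # rescale rounding
  expect_error(normalize_object_image(matrix(0.3, 10, 10)), "constant")
})

test_that("histogram equalization flattens intensities and is stable on uniform input", {
  set.seed(2)
  v <- rbeta(5000, 5, 1.5) # skewed
  e <- equalize_hist(v)
  expect_true(max(abs(sort(e) - (seq_along(e) / length(e)))) < 0.02)
  u <- (seq_len(4096) - 0.5) / 4096 # already uniform
  expect_true(max(abs(equalize_hist(u) - u)) < 1 / 256 + 1e-9) # quantization only
})

test_that("rotation is the identity at 0 degrees and composes", {
  set.seed(3)
  img <- normalize_object_image(planted_trial()$target_cue, box_px = 40, bg = NULL)
  expect_identical(rotate_object(img, 0), img)
  r90twice <- rotate_object(rotate_object(img, 90), 90)
  r180 <- rotate_object(img, 180)
  expect_equal(dim(r90twice), dim(r180))
  expect_lt(mean(abs(r90twice - r180)), 0.02) # interpolation tolerance
})

test_that("object arrays place six objects on the eccentricity circle", {
  set.seed(4)
  geom <- small_geometry() # 8 px/deg
  objs <- replicate(6, normalize_object_image(matrix(runif(1600), 40, 40),
                                              box_px = 40, bg = NULL),
                    simplify = FALSE)
  tr <- compose_object_array(objs, target_index = 2, geometry = geom)
  r_px <- 10.5 * geom$px_per_deg
  ctr <- c((geom$height_px + 1) / 2, (geom$width_px + 1) / 2)
  d <- sqrt((tr$object_centers[, 1] - ctr[1])^2 + (tr$object_centers[, 2] - ctr[2])^2)
  expect_true(all(abs(d - r_px) <= 1)) # equidistant to within 1 px
  # the six placed patches are pixel-identical for identical objects
  same <- replicate(6, objs[[1]], simplify = FALSE)
  tr2 <- compose_object_array(same, target_index = 1, geometry = geom)
  patches <- lapply(seq_len(6), function(k) {
    r0 <- round(tr2$object_centers[k, 1] - 19.5); c0 <- round(tr2$object_centers[k, 2] - 19.5)
    tr2$search_image[r0:(r0 + 39), c0:(c0 + 39)]
  })
  for (k in 2:6) expect_identical(patches[[k]], patches[[1]])
  # oversized objects are rejected
  big <- replicate(6, matrix(0.4, 120, 120), simplify = FALSE)
  expect_error(compose_object_array(big, 1, geom), "spacing")
})

test_that("target slots are uniform over the six positions", {
  set.seed(5)
  geom <- display_geometry(64, 80, 32, 40) # tiny canvas, 2 px/deg
  obj <- normalize_object_image(matrix(runif(64), 8, 8), box_px = 8, bg = NULL)
  objs <- replicate(6, obj, simplify = FALSE)
  slots <- vapply(seq_len(3000), function(i) {
    tr <- compose_object_array(objs, geometry = geom)
    d <- (tr$object_centers[, 1] - box_center(tr$target_box)[1])^2 +
         (tr$object_centers[, 2] - box_center(tr$target_box)[2])^2
    which.min(d)
  }, integer(1))
  expect_gt(chisq.test(tabulate(slots, 6))$p.value, 0.01)
})

test_that("cluttered scenes plant an exact target findable by template matching", {
  set.seed(6)
  tgt <- matrix(runif(28 * 28), 28, 28)
  geom <- display_geometry(160, 200, 20, 25)
  tr <- synth_cluttered_scene(tgt, geom, transform = list(), noise = 0)
  tm <- template_matching_map(tgt, tr$search_image)
  fix <- wta_next_fixation(tm)
  ctr <- box_center(tr$target_box)
  expect_true(all(abs(fix - ctr) <= 1))
  # halving the scale halves the box (+- 1 px rounding)
  tr2 <- synth_cluttered_scene(tgt, geom, transform = list(scale = 0.5), noise = 0)
  expect_true(abs(tr2$target_box$height - 14) <= 1)
  expect_true(abs(tr2$target_box$width - 14) <= 1)
  # seeded generation is byte-identical
  set.seed(99); a <- synth_cluttered_scene(tgt, geom, noise = 0.05)
  set.seed(99); b <- synth_cluttered_scene(tgt, geom, noise = 0.05)
  expect_identical(a$search_image, b$search_image)
  expect_identical(a$target_box, b$target_box)
})

test_that("procedural objects are category-structured and reproducible", {
  set.seed(7)
  out <- generate_procedural_objects(n = 12, n_categories = 6, box_px = 40)
  expect_length(out$images, 12)
  expect_equal(sort(unique(out$category)), 1:6)
  set.seed(7)
  out2 <- generate_procedural_objects(n = 12, n_categories = 6, box_px = 40)
  expect_identical(out$images, out2$images)
  d <- function(i, j) object_similarity(out$images[[i]], out$images[[j]], side = 40)
  within <- c(); between <- c()
  for (i in 1:11) for (j in (i + 1):12) {
    if (out$category[i] == out$category[j]) within <- c(within, d(i, j))
    else between <- c(between, d(i, j))
  }
  expect_lt(mean(within), mean(between))
})

test_that("synthetic scanpaths honour the no-revisit guarantee and the seed", {
  geom <- display_geometry()
  sp <- scanpath_spec(n_sequences = 40, mean_length = 15,
                      revisit_radius_deg = 3, seed = 11)
  seqs <- synth_scanpaths(sp, geom)
  rad <- deg_px_convert(3, geom, "deg2px")
  for (s in seqs) {
    f <- s$fixations
    d <- as.matrix(dist(cbind(f$row, f$col)))
    diag(d) <- Inf
    expect_gt(min(d), rad) # revisit_prob == 0: no two fixations within radius
  }
  seqs2 <- synth_scanpaths(sp, geom)
  expect_identical(lapply(seqs, `[[`, "fixations"), lapply(seqs2, `[[`, "fixations"))
})

test_that("saccade amplitudes follow the requested gamma distribution", {
  geom <- display_geometry()
  # small revisit radius: the spacing constraint then leaves amplitudes intact
  sp <- scanpath_spec(n_sequences = 500, mean_length = 21, saccade_shape = 2,
                      saccade_scale = 3.8, revisit_radius_deg = 0.5, seed = 12)
  st <- saccade_size_stats(synth_scanpaths(sp, geom), geom)
  expect_equal(st$n, 10000)
  expect_lt(abs(st$mean - 7.6), 3 * st$sd / sqrt(st$n) + 0.15)
  expect_gt(stats::ks.test(st$amplitudes_deg, stats::pgamma,
                           shape = 2, scale = 3.8)$p.value, 0.01)
})

test_that("trial manifests round-trip through PNG + CSV", {
  set.seed(13)
  geom <- display_geometry(64, 80, 8, 10)
  tgt <- matrix(runif(100), 10, 10)
  trials <- list(synth_cluttered_scene(tgt, geom, noise = 0, trial_id = "t1"),
                 synth_cluttered_scene(tgt, geom, noise = 0.05, trial_id = "t2"))
  dir <- withr::local_tempdir()
  manifest <- write_trial_manifest(trials, dir)
  back <- read_trial_manifest(manifest)
  expect_length(back, 2)
  expect_equal(back[[1]]$trial_id, "t1")
  expect_equal(back[[2]]$target_box, trials[[2]]$target_box)
  # 8-bit PNG round-trip: intensities within one quantization step
  expect_lt(max(abs(back[[1]]$search_image - trials[[1]]$search_image)), 1 / 255 + 1e-9)
})
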