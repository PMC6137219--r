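#' Normalize an object image for array stimuli
#'
#' Reproduces the standard object-array preprocessing: the object's content
#' (non-background pixels) is cropped to its tight bounding box, rescaled so
#' its larger side equals `box_px` while preserving aspect ratio, histogram
#' equalized (global, 256 bins, content pixels only), and centred on a
#' `box_px` x `box_px` mid-gray canvas.
#'
#' @param img gray image matrix.
#' @param box_px side of the output bounding box in pixels (default 156).
#' @param bg background intensity treated as non-content (default mid-gray
#'   0.5); set `NULL` to treat the whole image as content.
#' @param bg_tol tolerance around `bg` for the content mask.
#' @return gray image matrix `box_px` x `box_px`.
#' @examples
#' obj <- matrix(0.5, 60, 30); obj[10:50, 5:25] <- runif(41 * 21)
#' norm <- normalize_object_image(obj, box_px = 40)
#' dim(norm) # 40 40
#' @export
normalize_object_image <- function(img, box_px = 156, bg = 0.5, bg_tol = 1e-3) {
  img <- as_gray_image(img)
  if (max(img) - min(img) < 1e-12) {
    stop("constant image: histogram equalization is undefined")
  }
  if (is.null(bg)) {
    mask <- matrix(TRUE, nrow(img), ncol(img))
  } else {
    mask <- abs(img - bg) > bg_tol
    if (!any(mask)) stop("image has no content pixels distinct from the background")
  }
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  content <- img[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  cmask <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]

  sc <- box_px / max(nrow(content), ncol(content))
  nh <- max(1L, round(nrow(content) * sc))
  nw <- max(1L, round(ncol(content) * sc))
  content <- resize_gray(content, nh, nw)
  cmask <- resize_gray(cmask * 1, nh, nw) > 0.5

  if (any(cmask)) content[cmask] <- equalize_hist(content[cmask])
  bgfill <- if (is.null(bg)) 0.5 else bg
  out <- matrix(bgfill, box_px, box_px)
  r0 <- floor((box_px - nh) / 2); c0 <- floor((box_px - nw) / 2)
  patch <- out[r0 + seq_len(nh), c0 + seq_len(nw)]
  patch[cmask] <- content[cmask]
  out[r0 + seq_len(nh), c0 + seq_len(nw)] <- patch
  as_gray_image(out)
}

#' Global 256-bin histogram equalization of an intensity vector
#'
#' Maps intensities through their empirical 256-bin cumulative distribution
#' so the output histogram is approximately uniform on \[0,1\].
#'
#' @param v numeric vector of intensities in \[0,1\].
#' @param n_bins number of histogram bins (default 256).
#' @return equalized vector, same length.
#' @export
equalize_hist <- function(v, n_bins = 256L) {
  bins <- pmin(n_bins, floor(v * n_bins) + 1L)
  cnt <- tabulate(bins, nbins = n_bins)
  cdf <- cumsum(cnt) / length(v)
  cdf[bins]
}

#' Rotate an object image about its centre
#'
#' Bilinear rotation; the canvas is enlarged as needed and filled with a
#' constant background.
#'
#' @param img gray image matrix.
#' @param angle_deg rotation angle in degrees, in \[0, 360).
#' @param bg background fill intensity.
#' @return rotated gray image matrix.
#' @export
rotate_object <- function(img, angle_deg, bg = 0.5) {
  img <- as_gray_image(img)
  stopifnot(angle_deg >= 0, angle_deg < 360)
  if (angle_deg == 0) return(img)
  out <- .uneb(EBImage::rotate(.eb(img), angle = angle_deg, bg.col = bg,
                               filter = "bilinear"))
  as_gray_image(pmin(pmax(out, 0), 1))
}

#' Compose a six-object circular search array
#'
#' Places six normalized objects uniformly on a circle of the given
#' eccentricity around the canvas centre (positions at `k*60 + phase`
#' degrees), with the target at a chosen or uniformly random slot.
#'
#' @param objects list of exactly 6 gray images, all the same square size.
#' @param target_index slot of the target, 1..6, or `NULL` to draw uniformly.
#' @param geometry a [display_geometry()].
#' @param radius_deg circle radius in degrees of visual angle (default 10.5).
#' @param phase_deg angular offset of the first slot (default 0 = 3 o'clock).
#' @param cue target cue image; defaults to the target object itself.
#' @param bg canvas background intensity.
#' @param trial_id character id.
#' @return a [search_trial()] in array mode (`object_centers` set).
#' @export
compose_object_array <- function(objects, target_index = NULL,
                                 geometry = display_geometry(),
                                 radius_deg = 10.5, phase_deg = 0,
                                 cue = NULL, bg = 0.5, trial_id = "array") {
  stopifnot(length(objects) == 6L)
  objects <- lapply(objects, as_gray_image)
  sides <- vapply(objects, function(o) c(nrow(o), ncol(o)), numeric(2))
  if (length(unique(as.vector(sides))) != 1L) {
    stop("all 6 objects must be square and of identical size")
  }
  obj_px <- nrow(objects[[1]])
  if (is.null(target_index)) target_index <- sample.int(6L, 1L)
  stopifnot(target_index >= 1, target_index <= 6)

  H <- geometry$height_px; W <- geometry$width_px
  r_px <- deg_px_convert(radius_deg, geometry, "deg2px")
  spacing <- 2 * r_px * sin(pi / 6) # chord between neighbouring slots
  if (obj_px > spacing) stop("objects larger than the inter-position spacing")
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ang <- (phase_deg + 60 * (0:5)) * pi / 180
  centers <- cbind(row = cy - r_px * sin(ang), col = cx + r_px * cos(ang))

  canvas <- matrix(bg, H, W)
  half <- (obj_px - 1) / 2
  boxes <- vector("list", 6L)
  for (k in 1:6) {
    r0 <- round(centers[k, "row"] - half); c0 <- round(centers[k, "col"] - half)
    if (r0 < 1 || c0 < 1 || r0 + obj_px - 1 > H || c0 + obj_px - 1 > W) {
      stop("object does not fit on the canvas at the requested eccentricity")
    }
    canvas[r0:(r0 + obj_px - 1), c0:(c0 + obj_px - 1)] <- objects[[k]]
    boxes[[k]] <- bounding_box(r0, c0, obj_px, obj_px)
  }
  centers <- t(vapply(boxes, box_center, numeric(2)))
  colnames(centers) <- c("row", "col")
  search_trial(
    target_cue = if (is.null(cue)) objects[[target_index]] else as_gray_image(cue),
    search_image = canvas,
    target_box = boxes[[target_index]],
    geometry = geometry,
    object_centers = centers,
    object_px = obj_px,
    trial_id = trial_id
  )
}

#' Generate procedural object images with category structure
#'
#' Builds simple part-based objects: each category is defined by a random
#' arrangement of geometric parts (ellipses and oriented bars); instances
#' within a category jitter the part positions, sizes and intensities. All
#' objects are passed through [normalize_object_image()].
#'
#' @param n number of objects.
#' @param n_categories number of categories (`n >= n_categories`).
#' @param box_px normalized object side in pixels.
#' @param jitter within-category relative jitter of part geometry.
#' @return list with elements `images` (list of gray images) and `category`
#'   (integer vector of labels).
#' @export
generate_procedural_objects <- function(n, n_categories, box_px = 156,
                                        jitter = 0.08) {
  stopifnot(n >= n_categories, n_categories >= 1)
  side <- max(48L, as.integer(box_px))
  protos <- lapply(seq_len(n_categories), function(k) {
    n_parts <- sample(3:5, 1)
    data.frame(
      type = sample(c("ellipse", "bar"), n_parts, replace = TRUE),
      r = runif(n_parts, 0.25, 0.75), c = runif(n_parts, 0.25, 0.75),
      a = runif(n_parts, 0.10, 0.28), b = runif(n_parts, 0.04, 0.18),
      th = runif(n_parts, 0, pi), val = runif(n_parts, 0.05, 0.95)
    )
  })
  category <- rep(seq_len(n_categories), length.out = n)
  images <- lapply(seq_len(n), function(i) {
    p <- protos[[category[i]]]
    p$r <- pmin(0.9, pmax(0.1, p$r + rnorm(nrow(p), 0, jitter)))
    p$c <- pmin(0.9, pmax(0.1, p$c + rnorm(nrow(p), 0, jitter)))
    p$a <- pmax(0.03, p$a * exp(rnorm(nrow(p), 0, jitter)))
    p$b <- pmax(0.02, p$b * exp(rnorm(nrow(p), 0, jitter)))
    p$val <- pmin(1, pmax(0, p$val + rnorm(nrow(p), 0, jitter / 2)))
    img <- render_parts(p, side)
    normalize_object_image(img, box_px = box_px)
  })
  list(images = images, category = category)
}

# paint part primitives onto a mid-gray canvas
render_parts <- function(parts, side) {
  img <- matrix(0.5, side, side)
  rows <- matrix(seq_len(side), side, side) / side
  cols <- matrix(seq_len(side), side, side, byrow = TRUE) / side
  for (i in seq_len(nrow(parts))) {
    dr <- rows - parts$r[i]; dc <- cols - parts$c[i]
    u <- dr * cos(parts$th[i]) + dc * sin(parts$th[i])
    v <- -dr * sin(parts$th[i]) + dc * cos(parts$th[i])
    inside <- if (parts$type[i] == "ellipse") {
      (u / parts$a[i])^2 + (v / parts$b[i])^2 <= 1
    } else {
      abs(u) <= parts$a[i] & abs(v) <= parts$b[i]
    }
    img[inside] <- parts$val[i]
  }
  img
}

#' Synthesize a cluttered scene with one embedded target
#'
#' Builds a search image whose background is either blank mid-gray or a
#' texture of rotated distractor objects plus band-limited noise, with one
#' transformed copy of the target embedded at a random location.
#'
#' @param target gray image of the target object.
#' @param geometry a [display_geometry()] describing the canvas.
#' @param transform list with elements `scale`, `angle_deg`, `contrast`
#'   applied to the target before embedding (defaults: identity).
#' @param distractors optional list of gray images tiled (rotated) as clutter.
#' @param noise sd of the band-limited background noise (0 = none).
#' @param cue target cue for the produced trial; defaults to `target`.
#' @param trial_id character id.
#' @return a [search_trial()] in free mode.
#' @export
synth_cluttered_scene <- function(target, geometry = display_geometry(),
                                  transform = list(), distractors = NULL,
                                  noise = 0.05, cue = NULL, trial_id = "scene") {
  target <- as_gray_image(target)
  tf <- utils::modifyList(list(scale = 1, angle_deg = 0, contrast = 1), transform)
  H <- geometry$height_px; W <- geometry$width_px
  canvas <- matrix(0.5, H, W)

  if (!is.null(distractors)) {
    for (d in distractors) {
      d <- as_gray_image(d)
      n_copies <- max(1L, floor(H * W / (nrow(d) * ncol(d) * 2 * length(distractors))))
      for (i in seq_len(n_copies)) {
        dr <- rotate_object(d, runif(1, 0, 359.9))
        r0 <- sample.int(max(1L, H - nrow(dr) + 1L), 1L)
        c0 <- sample.int(max(1L, W - ncol(dr) + 1L), 1L)
        rr <- r0:min(H, r0 + nrow(dr) - 1L); cc <- c0:min(W, c0 + ncol(dr) - 1L)
        canvas[rr, cc] <- dr[seq_along(rr), seq_along(cc)]
      }
    }
  }
  if (noise > 0) {
    # band-limited noise: coarse white noise upsampled to canvas size
    coarse <- matrix(rnorm(ceiling(H / 16) * ceiling(W / 16), 0, noise),
                     ceiling(H / 16), ceiling(W / 16))
    canvas <- pmin(pmax(canvas + resize_gray(pmin(pmax(coarse + 0.5, 0), 1),
                                             H, W) - 0.5, 0), 1)
  }

  emb <- target
  if (tf$scale != 1) {
    emb <- resize_gray(emb, max(1L, round(nrow(emb) * tf$scale)),
                       max(1L, round(ncol(emb) * tf$scale)))
  }
  if (tf$angle_deg != 0) emb <- rotate_object(emb, tf$angle_deg)
  if (tf$contrast != 1) emb <- pmin(pmax(0.5 + (emb - 0.5) * tf$contrast, 0), 1)
  th <- nrow(emb); tw <- ncol(emb)
  if (th > H || tw > W) stop("transformed target does not fit on the canvas")
  r0 <- sample.int(H - th + 1L, 1L); c0 <- sample.int(W - tw + 1L, 1L)
  canvas[r0:(r0 + th - 1L), c0:(c0 + tw - 1L)] <- emb

  search_trial(
    target_cue = if (is.null(cue)) target else as_gray_image(cue),
    search_image = canvas,
    target_box = bounding_box(r0, c0, th, tw),
    geometry = geometry,
    trial_id = trial_id
  )
}

#' Generate a batch of six-object array trials
#'
#' Convenience generator pairing [generate_procedural_objects()] with
#' [compose_object_array()]: each trial draws one object per category (six
#' categories), rotates them randomly, and places the target (a different
#' instance of the target category, also randomly rotated, as the cue) at a
#' uniformly random slot.
#'
#' @param n_trials number of trials.
#' @param geometry a [display_geometry()].
#' @param box_px object side in pixels (156 at the default 32 px/deg).
#' @param radius_deg array eccentricity in degrees.
#' @param seed optional integer seed (uses the session RNG when `NULL`).
#' @return list of [search_trial()] objects.
#' @export
synth_array_trials <- function(n_trials, geometry = display_geometry(),
                               box_px = 156, radius_deg = 10.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  objs <- generate_procedural_objects(n = 12L, n_categories = 6L, box_px = box_px)
  by_cat <- split(objs$images, objs$category)
  lapply(seq_len(n_trials), function(i) {
    target_cat <- sample.int(6L, 1L)
    rot_norm <- function(img) { # rotation grows the canvas; re-normalize to the box
      normalize_object_image(rotate_object(img, runif(1, 0, 359.9)), box_px = box_px)
    }
    slot_objs <- lapply(1:6, function(k) {
      rot_norm(by_cat[[k]][[sample.int(length(by_cat[[k]]), 1L)]])
    })
    cue <- rot_norm(by_cat[[target_cat]][[sample.int(length(by_cat[[target_cat]]), 1L)]])
    compose_object_array(slot_objs, target_index = sample.int(6L, 1L),
                         geometry = geometry, radius_deg = radius_deg,
                         cue = cue, trial_id = sprintf("array_%03d", i))
  })
}

#' Scanpath generator specification
#'
#' Parameters of the synthetic scanpath generator: sequence count and
#' length, a revisit-probability-by-lag function, and the gamma saccade
#' amplitude distribution (in degrees of visual angle).
#'
#' @param n_sequences number of scanpaths.
#' @param mean_length fixations per scanpath (>= 2).
#' @param revisit_prob_by_lag function lag -> probability in \[0,1\] that a
#'   step revisits the location fixated `lag` steps earlier (a candidate lag
#'   is drawn uniformly on `1..max_lag` at each step).
#' @param saccade_shape,saccade_scale gamma parameters of the saccade
#'   amplitude distribution, in degrees (defaults shape 2, scale 3.8: mean
#'   7.6 deg, matching typical human free-viewing amplitudes).
#' @param max_lag largest revisit lag considered.
#' @param revisit_radius_deg radius within which a fixation counts as a
#'   revisit (default 3 deg, about eye-tracker precision x3).
#' @param seed optional integer seed.
#' @return object of class `scanpath_spec`.
#' @export
scanpath_spec <- function(n_sequences = 100, mean_length = 20,
                          revisit_prob_by_lag = function(lag) 0 * lag,
                          saccade_shape = 2, saccade_scale = 3.8,
                          max_lag = 10L, revisit_radius_deg = 3,
                          seed = NULL) {
  stopifnot(saccade_shape > 0, saccade_scale > 0, mean_length >= 2,
            is.function(revisit_prob_by_lag))
  p <- revisit_prob_by_lag(seq_len(max_lag))
  if (any(p < 0 | p > 1)) stop("revisit probabilities must lie in [0,1]")
  structure(list(n_sequences = n_sequences, mean_length = mean_length,
                 revisit_prob_by_lag = revisit_prob_by_lag,
                 saccade_shape = saccade_shape, saccade_scale = saccade_scale,
                 max_lag = as.integer(max_lag),
                 revisit_radius_deg = revisit_radius_deg, seed = seed),
            class = "scanpath_spec")
}

#' Generate synthetic fixation sequences
#'
#' Random scanpaths with controlled revisit behaviour and gamma-distributed
#' saccade amplitudes. At each step `t` a candidate lag is drawn uniformly
#' on `2..max_lag`; with probability `revisit_prob_by_lag(lag)` (and
#' provided the candidate is itself a fresh fixation, a lag-independent
#' condition) the new fixation lands inside the revisit radius of the
#' location visited `lag` steps earlier while staying outside the radius of
#' every other fixation. Otherwise a fresh location is
#' placed one gamma-distributed saccade away from the current fixation,
#' rejection-sampled (direction first, so the amplitude is preserved)
#' outside the revisit radius of every earlier fixation. The probability
#' that an ordered fixation pair at lag L lies within the revisit radius is
#' therefore proportional to `revisit_prob_by_lag(L)`, which is what
#' [estimate_revisit_curve()] + [fit_memory_params()] recover. Because
#' fresh placements avoid all earlier fixations, saccades shorter than the
#' revisit radius are excluded: keep `revisit_radius_deg` small relative to
#' the gamma scale when amplitude fidelity matters.
#'
#' @param spec a [scanpath_spec()].
#' @param geometry a [display_geometry()] giving the canvas.
#' @return list of `fixation_sequence` objects (see [fixation_sequence()]).
#' @export
synth_scanpaths <- function(spec, geometry = display_geometry()) {
  stopifnot(inherits(spec, "scanpath_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  H <- geometry$height_px; W <- geometry$width_px
  radius <- deg_px_convert(spec$revisit_radius_deg, geometry, "deg2px")
  lapply(seq_len(spec$n_sequences), function(s) {
    n <- spec$mean_length
    rows <- numeric(n); cols <- numeric(n)
    fresh <- logical(n) # fresh fixations are eligible revisit targets
    rows[1] <- runif(1, 1, H); cols[1] <- runif(1, 1, W); fresh[1] <- TRUE
    for (t in 2:n) {
      lag <- if (spec$max_lag >= 2L) sample(2:spec$max_lag, 1L) else 0L
      j <- t - lag
      revisited <- FALSE
      if (lag >= 2L && j >= 1 && fresh[j] &&
          runif(1) < spec$revisit_prob_by_lag(lag)) {
        # land inside the revisit radius of j but outside the radius of every
        # other fixation, so the planned pair is the only within-radius pair
        others <- setdiff(seq_len(t - 1L), j)
        for (try in 1:80) {
          a <- runif(1, 0, 2 * pi); rr <- runif(1, 0.4, 0.9) * radius
          r2 <- rows[j] + rr * sin(a); c2 <- cols[j] + rr * cos(a)
          if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
          if (!length(others) ||
              min((rows[others] - r2)^2 + (cols[others] - c2)^2) > radius^2) {
            rows[t] <- r2; cols[t] <- c2
            fresh[t] <- FALSE
            revisited <- TRUE
            break
          }
        }
      }
      if (!revisited) {
        amp_px <- deg_px_convert(
          stats::rgamma(1, shape = spec$saccade_shape, scale = spec$saccade_scale),
          geometry, "deg2px")
        placed <- FALSE
        for (try_amp in 1:50) {
          for (try_dir in 1:60) {
            a <- runif(1, 0, 2 * pi)
            r2 <- rows[t - 1] + amp_px * sin(a)
            c2 <- cols[t - 1] + amp_px * cos(a)
            if (r2 < 1 || r2 > H || c2 < 1 || c2 > W) next
            d2 <- (rows[1:(t - 1)] - r2)^2 + (cols[1:(t - 1)] - c2)^2
            if (min(d2) > radius^2) { placed <- TRUE; break }
          }
          if (placed) break
          amp_px <- deg_px_convert(
            stats::rgamma(1, shape = spec$saccade_shape, scale = spec$saccade_scale),
            geometry, "deg2px")
        }
        if (!placed) { rows <- rows[1:(t - 1)]; cols <- cols[1:(t - 1)]; break }
        rows[t] <- r2; cols[t] <- c2; fresh[t] <- TRUE
      }
    }
    n_eff <- length(rows)
    fixation_sequence(
      data.frame(index = seq_len(n_eff), row = rows, col = cols,
                 duration_ms = stats::rgamma(n_eff, shape = 8, scale = 30),
                 onset_ms = cumsum(c(250, rep(300, n_eff - 1)))),
      found_at = NA_integer_, trial_id = sprintf("synthetic_%04d", s))
  })
}

#' Write / read a trial manifest
#'
#' Writes each trial's target cue and search image as PNG files plus a CSV
#' manifest (trial_id, target/search paths, target box, mode); the reader
#' reconstructs the trials.
#'
#' @param trials list of [search_trial()] objects.
#' @param dir output directory (created if needed).
#' @return `write_trial_manifest` returns the manifest path; `read_trial_manifest`
#'   returns a list of trials.
#' @export
write_trial_manifest <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(trials, function(tr) {
    tp <- file.path(dir, paste0(tr$trial_id, "_target.png"))
    sp <- file.path(dir, paste0(tr$trial_id, "_search.png"))
    write_gray_image(tr$target_cue, tp)
    write_gray_image(tr$search_image, sp)
    data.frame(trial_id = tr$trial_id, target_path = basename(tp),
               search_path = basename(sp),
               box_row = tr$target_box$row, box_col = tr$target_box$col,
               box_height = tr$target_box$height, box_width = tr$target_box$width,
               height_px = tr$geometry$height_px, width_px = tr$geometry$width_px,
               height_deg = tr$geometry$height_deg, width_deg = tr$geometry$width_deg,
               mode = if (is.null(tr$object_centers)) "free" else "array",
               object_rows = if (is.null(tr$object_centers)) "" else
                 paste(tr$object_centers[, 1], collapse = ";"),
               object_cols = if (is.null(tr$object_centers)) "" else
                 paste(tr$object_centers[, 2], collapse = ";"),
               object_px = if (is.null(tr$object_px)) NA_real_ else tr$object_px,
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  manifest
}

#' @rdname write_trial_manifest
#' @param manifest path to a manifest CSV.
#' @export
read_trial_manifest <- function(manifest) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(df)), function(i) {
    centers <- NULL
    if (identical(df$mode[i], "array") && nzchar(df$object_rows[i])) {
      centers <- cbind(row = as.numeric(strsplit(df$object_rows[i], ";")[[1]]),
                       col = as.numeric(strsplit(df$object_cols[i], ";")[[1]]))
    }
    search_trial(
      target_cue = read_gray_image(file.path(dir, df$target_path[i])),
      search_image = read_gray_image(file.path(dir, df$search_path[i])),
      target_box = bounding_box(df$box_row[i], df$box_col[i],
                                df$box_height[i], df$box_width[i]),
      geometry = display_geometry(df$height_px[i], df$width_px[i],
                                  df$height_deg[i], df$width_deg[i]),
      object_centers = centers,
      object_px = if (is.na(df$object_px[i])) NULL else df$object_px[i],
      trial_id = df$trial_id[i])
  })
}
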