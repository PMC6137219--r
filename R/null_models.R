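#' Chance search model
#'
#' Random exploration baseline. In array mode each repetition is a uniform
#' random permutation of the six object slots (infinite object-wise IOR);
#' the expected number of fixations to the target is (6 + 1) / 2 = 3.5 and
#' the first-fixation hit rate 1/6. In free mode each fixation is drawn
#' uniformly over the image; the target is detected when the `ior_window`
#' square centred at the fixation overlaps the target bounding box
#' (`detection = "overlap"`, the default) or contains its centre
#' (`"center"`), and the same window sets the inhibition region: subsequent
#' fixations are rejection-sampled outside all inhibited windows.
#'
#' @param trial a [search_trial()].
#' @param config a [search_config()] (uses `ior_window`, `max_fixations`).
#' @param reps number of repetitions (default 100).
#' @param detection free-mode detection rule.
#' @param keep_sequences return full per-rep scanpaths (default only when
#'   `reps <= 1000`; `found_at` is always returned).
#' @return object of class `null_model_result`: list with `found_at`
#'   (integer vector, `NA` when never found), `sequences` (list of
#'   [fixation_sequence()] or `NULL`), `model`, `reps`.
#' @export
chance_search <- function(trial, config = search_config(), reps = 100,
                          detection = c("overlap", "center"),
                          keep_sequences = reps <= 1000) {
  detection <- match.arg(detection)
  stopifnot(reps >= 1)
  if (!is.null(trial$object_centers) && config$snap_to_objects) {
    n_obj <- nrow(trial$object_centers)
    ctr <- t(vapply(seq_len(n_obj), function(k) trial$object_centers[k, ],
                    numeric(2)))
    d2 <- (ctr[, 1] - box_center(trial$target_box)[1])^2 +
          (ctr[, 2] - box_center(trial$target_box)[2])^2
    target_slot <- which.min(d2)
    perms <- matrix(vapply(seq_len(reps), function(i) sample.int(n_obj),
                           integer(n_obj)), nrow = n_obj)
    found_at <- apply(perms == target_slot, 2, which)
    seqs <- NULL
    if (keep_sequences) {
      seqs <- lapply(seq_len(reps), function(i) {
        k <- found_at[i]
        fixation_sequence(
          data.frame(index = seq_len(k),
                     row = ctr[perms[seq_len(k), i], 1],
                     col = ctr[perms[seq_len(k), i], 2]),
          found_at = k, trial_id = sprintf("%s_chance_%d", trial$trial_id, i))
      })
    }
    return(structure(list(found_at = as.integer(found_at), sequences = seqs,
                          model = "chance_array", reps = reps),
                     class = "null_model_result"))
  }

  H <- nrow(trial$search_image); W <- ncol(trial$search_image)
  w <- config$ior_window
  max_fix <- config$max_fixations %||% 45L
  box <- trial$target_box
  hit <- function(fr, fc) {
    if (detection == "overlap") {
      (fr - w / 2 <= box$row + box$height - 1) & (fr + w / 2 >= box$row) &
        (fc - w / 2 <= box$col + box$width - 1) & (fc + w / 2 >= box$col)
    } else {
      ctr <- box_center(box)
      (abs(fr - ctr[1]) <= w / 2) & (abs(fc - ctr[2]) <= w / 2)
    }
  }

  if (max_fix == 1L) { # vectorized single-fixation path
    fr <- runif(reps, 1, H); fc <- runif(reps, 1, W)
    found <- hit(fr, fc)
    found_at <- ifelse(found, 1L, NA_integer_)
    seqs <- NULL
    if (keep_sequences) {
      seqs <- lapply(seq_len(reps), function(i) {
        fixation_sequence(data.frame(index = 1L, row = fr[i], col = fc[i]),
                          found_at = found_at[i],
                          trial_id = sprintf("%s_chance_%d", trial$trial_id, i))
      })
    }
    return(structure(list(found_at = found_at, sequences = seqs,
                          model = "chance_free", reps = reps),
                     class = "null_model_result"))
  }

  found_at <- rep(NA_integer_, reps)
  seqs <- if (keep_sequences) vector("list", reps) else NULL
  for (i in seq_len(reps)) {
    rows <- numeric(0); cols <- numeric(0)
    for (t in seq_len(max_fix)) {
      for (try in 1:1000) { # rejection against the inhibited windows
        fr <- runif(1, 1, H); fc <- runif(1, 1, W)
        if (!length(rows) ||
            all(abs(rows - fr) > w / 2 | abs(cols - fc) > w / 2)) break
        if (try == 1000) fr <- NA
      }
      if (is.na(fr)) break # image exhausted by IOR
      rows <- c(rows, fr); cols <- c(cols, fc)
      if (hit(fr, fc)) { found_at[i] <- t; break }
    }
    if (keep_sequences) {
      seqs[[i]] <- fixation_sequence(
        data.frame(index = seq_along(rows), row = rows, col = cols),
        found_at = found_at[i],
        trial_id = sprintf("%s_chance_%d", trial$trial_id, i))
    }
  }
  structure(list(found_at = found_at, sequences = seqs,
                 model = "chance_free", reps = reps),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("<null_model_result> %s, %d rep(s): mean found_at %.3f, found %.1f%%\n",
              x$model, x$reps, mean(x$found_at, na.rm = TRUE),
              100 * mean(!is.na(x$found_at))))
  invisible(x)
}

#' Sliding-window search
#'
#' Deterministic raster scan: fixations at the centres of `window_px`
#' windows advancing from the top-left corner with the given stride (a
#' final flush-to-edge position is added when the stride does not divide
#' exactly), detection by [oracle_check()]. In array mode the model visits
#' the six objects in slot order instead.
#'
#' @param trial a [search_trial()].
#' @param window_px window side in pixels.
#' @param stride raster stride in pixels (default 28).
#' @return a [fixation_sequence()].
#' @export
sliding_window_search <- function(trial, window_px, stride = 28) {
  stopifnot(stride >= 1)
  if (!is.null(trial$object_centers)) {
    ctr <- trial$object_centers
    found_at <- NA_integer_
    for (k in seq_len(nrow(ctr))) {
      if (oracle_check(c(ctr[k, 1], ctr[k, 2]), trial$target_box, window_px)) {
        found_at <- k; break
      }
    }
    n <- if (is.na(found_at)) nrow(ctr) else found_at
    return(fixation_sequence(
      data.frame(index = seq_len(n), row = ctr[seq_len(n), 1], col = ctr[seq_len(n), 2]),
      found_at = found_at, trial_id = paste0(trial$trial_id, "_sw")))
  }
  H <- nrow(trial$search_image); W <- ncol(trial$search_image)
  offs <- function(extent) {
    o <- seq(0L, extent - window_px, by = stride)
    if (o[length(o)] < extent - window_px) o <- c(o, extent - window_px)
    o
  }
  rows <- numeric(0); cols <- numeric(0); found_at <- NA_integer_
  t <- 0L
  for (r0 in offs(H)) {
    for (c0 in offs(W)) {
      t <- t + 1L
      fr <- r0 + (window_px + 1) / 2; fc <- c0 + (window_px + 1) / 2
      rows <- c(rows, fr); cols <- c(cols, fc)
      if (oracle_check(c(fr, fc), trial$target_box, window_px)) {
        found_at <- t; break
      }
    }
    if (!is.na(found_at)) break
  }
  fixation_sequence(data.frame(index = seq_along(rows), row = rows, col = cols),
                    found_at = found_at, trial_id = paste0(trial$trial_id, "_sw"))
}

#' Number of sliding-window scan positions along one dimension
#'
#' @param extent image extent in pixels.
#' @param window_px window side.
#' @param stride raster stride.
#' @return integer count.
#' @export
sliding_window_positions <- function(extent, window_px, stride = 28) {
  o <- seq(0L, extent - window_px, by = stride)
  if (o[length(o)] < extent - window_px) length(o) + 1L else length(o)
}

#' Pixel template-matching attention map
#'
#' The target is resized to a canonical `template_px` square and slid over
#' the search image; the map value at each position is the negative sum of
#' squared differences between the template and the underlying patch
#' ('same' zero padding), or the normalized cross-correlation when
#' `score = "ncc"`. The map is consumed by the standard WTA/IOR engine.
#'
#' @param target gray image of the target.
#' @param search gray search image (must be larger than the template).
#' @param template_px canonical template side (default 28).
#' @param score `"ssd"` (negative SSD, default) or `"ncc"`.
#' @return an [attention_map()] over the search image.
#' @export
template_matching_map <- function(target, search, template_px = 28,
                                  score = c("ssd", "ncc")) {
  score <- match.arg(score)
  search <- as_gray_image(search)
  if (nrow(search) < template_px || ncol(search) < template_px) {
    stop("search image must be larger than the template")
  }
  tmpl <- resize_gray(as_gray_image(target), template_px, template_px)
  ones <- matrix(1, template_px, template_px)
  cross <- xcorr2_same(search, tmpl)
  p2 <- xcorr2_same(search^2, ones)
  if (score == "ssd") {
    v <- -(p2 - 2 * cross + sum(tmpl^2))
  } else {
    denom <- sqrt(pmax(p2, 0) * sum(tmpl^2))
    v <- ifelse(denom > 0, cross / denom, 0)
  }
  attention_map(v, provenance = list(model = "template_matching",
                                     template_px = template_px, score = score))
}

#' Minimal bottom-up saliency map
#'
#' A small center-surround saliency baseline with no target information:
#' intensity center-surround contrast across a dyadic pyramid plus oriented
#' edge energy at four orientations, each channel normalized to \[0,1\] and
#' summed. Identical for any target cue by construction.
#'
#' @param search gray search image.
#' @param n_levels pyramid depth (auto-reduced for small images).
#' @return an [attention_map()] normalized to \[0,1\].
#' @export
bottom_up_saliency_map <- function(search, n_levels = 4L) {
  search <- as_gray_image(search)
  H <- nrow(search); W <- ncol(search)
  n_levels <- max(2L, min(n_levels, floor(log2(min(H, W))) - 2L))
  pyr <- vector("list", n_levels)
  pyr[[1]] <- search
  for (k in 2:n_levels) {
    pyr[[k]] <- resize_gray(pyr[[k - 1]],
                            max(1, ceiling(nrow(pyr[[k - 1]]) / 2)),
                            max(1, ceiling(ncol(pyr[[k - 1]]) / 2)))
  }
  norm_or_zero <- function(m) {
    rng <- range(m)
    if (diff(rng) < 1e-12) matrix(0, nrow(m), ncol(m)) else (m - rng[1]) / diff(rng)
  }
  total <- matrix(0, H, W)
  # intensity centre-surround: fine level vs blurred coarse level
  for (c in seq_len(max(1L, n_levels - 2L))) {
    s <- min(c + 2L, n_levels)
    surround <- upsample_bilinear(pyr[[s]], nrow(pyr[[c]]), ncol(pyr[[c]]))
    cs <- abs(pyr[[c]] - surround)
    total <- total + norm_or_zero(upsample_bilinear(cs, H, W))
  }
  # oriented edge energy at four orientations
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  kerns <- list(kx, t(kx),
                matrix(c(0, 1, 2, -1, 0, 1, -2, -1, 0), 3, 3, byrow = TRUE),
                matrix(c(2, 1, 0, 1, 0, -1, 0, -1, -2), 3, 3, byrow = TRUE))
  for (k in kerns) {
    lev <- min(2L, n_levels)
    e <- abs(xcorr2_same(pyr[[lev]], k))
    # zero the 1-px border: padding would otherwise fake edge energy there
    e[c(1L, nrow(e)), ] <- 0
    e[, c(1L, ncol(e))] <- 0
    total <- total + norm_or_zero(upsample_bilinear(e, H, W))
  }
  normalize01(attention_map(total, provenance = list(model = "bottom_up_saliency")))
}
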