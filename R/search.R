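#' Search configuration
#'
#' Bundles the knobs of the fixation-generation loop. The inhibition-of-
#' return window defaults follow the convention of sizing the window to the
#' average object: 45 px for object arrays, 200 px for natural scenes,
#' 100 px for dense cartoon scenes (at 32 px/deg).
#'
#' @param ior_window side of the square inhibition window, pixels.
#' @param ior_mode `"infinite"` (permanent masking) or `"finite"` (memory
#'   function, requires `memory_params`).
#' @param decision_mode `"oracle"` (ground-truth box check) or
#'   `"recognition"` (descriptor distance at the fixated crop).
#' @param recognition_threshold strict upper bound on the normalized
#'   descriptor distance for a detection (default 0.9).
#' @param layer_pair backbone layer pair, or `NULL` for the default.
#' @param max_fixations cap on the number of fixations (`NULL`: 6 in
#'   object-array mode, 45 otherwise).
#' @param memory_params a [memory_params()] for finite IOR.
#' @param size_constraint a [saccade_size_params()] to penalize large
#'   saccades, or `NULL` (off).
#' @param size_weight weight `w` of the feature map in the weighted sum
#'   `w * M_f + (1 - w) * M_sc` (default 0.2346).
#' @param snap_to_objects in array mode, snap fixations to object centres
#'   and apply IOR object-wise (default `TRUE`).
#' @param seed optional integer seed recorded in provenance.
#' @return object of class `search_config`.
#' @export
search_config <- function(ior_window = 45, ior_mode = c("infinite", "finite"),
                          decision_mode = c("oracle", "recognition"),
                          recognition_threshold = 0.9, layer_pair = NULL,
                          max_fixations = NULL, memory_params = NULL,
                          size_constraint = NULL, size_weight = 0.2346,
                          snap_to_objects = TRUE, seed = NULL) {
  ior_mode <- match.arg(ior_mode)
  decision_mode <- match.arg(decision_mode)
  stopifnot(ior_window > 0, size_weight >= 0, size_weight <= 1,
            is.null(max_fixations) || max_fixations >= 1)
  if (ior_mode == "finite" && is.null(memory_params)) {
    stop("finite inhibition of return requires memory_params")
  }
  structure(list(ior_window = ior_window, ior_mode = ior_mode,
                 decision_mode = decision_mode,
                 recognition_threshold = recognition_threshold,
                 layer_pair = layer_pair, max_fixations = max_fixations,
                 memory_params = memory_params,
                 size_constraint = size_constraint, size_weight = size_weight,
                 snap_to_objects = snap_to_objects, seed = seed),
            class = "search_config")
}

#' Winner-take-all fixation selection
#'
#' Returns the location of the global maximum of the attention map. Ties
#' are broken by the lowest row-major index (top row first, then leftmost
#' column).
#'
#' @param map an [attention_map()] or numeric matrix.
#' @return integer vector `c(row, col)`.
#' @export
wta_next_fixation <- function(map) {
  v <- unclass(map)
  fin <- is.finite(v)
  if (!any(fin)) stop("attention map exhausted: no finite values remain")
  mx <- max(v[fin])
  idx <- which(v == mx & fin, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  c(row = unname(idx[1, 1]), col = unname(idx[1, 2]))
}

#' Infinite inhibition of return
#'
#' Permanently masks a square window centred on the fixation (clipped at the
#' image borders). The mask value is `-Inf` rather than a literal zero so
#' that masked cells can never win the WTA even on maps with zero-valued
#' background.
#'
#' @param map an [attention_map()] or numeric matrix.
#' @param fix fixation `c(row, col)`.
#' @param window_px side of the square inhibition window.
#' @return the masked [attention_map()].
#' @export
apply_infinite_ior <- function(map, fix, window_px) {
  v <- unclass(map)
  w <- ior_window_indices(fix, window_px, nrow(v), ncol(v))
  v[w$rows, w$cols] <- -Inf
  attention_map(v, provenance = attr(map, "provenance") %||% list())
}

# half-open w-px window centred on a pixel, clipped to the image
ior_window_indices <- function(fix, window_px, H, W) {
  r0 <- round(fix[1]) - floor(window_px / 2)
  c0 <- round(fix[2]) - floor(window_px / 2)
  list(rows = max(1L, r0):min(H, r0 + window_px - 1L),
       cols = max(1L, c0):min(W, c0 + window_px - 1L))
}

#' Memory-function parameters for finite inhibition of return
#'
#' The memory function gives the revisit-permission weight
#' `M_m(lag) = 1 - a * exp(-lag / tau)` applied to a previously visited
#' location `lag` fixations after the visit: full inhibition depth `a` at
#' lag 0+, exponential recovery with timescale `tau` (in fixation lags).
#'
#' @param a inhibition depth in \[0, 1\].
#' @param tau recovery timescale (> 0), in fixations.
#' @param revisit_radius_px radius defining "the same location", pixels
#'   (default 96 px = 3 deg at 32 px/deg).
#' @return object of class `memory_params`.
#' @export
memory_params <- function(a, tau, revisit_radius_px = 96) {
  stopifnot(a >= 0, a <= 1, tau > 0, revisit_radius_px > 0)
  structure(list(a = a, tau = tau, revisit_radius_px = revisit_radius_px),
            class = "memory_params")
}

#' Memory weight at a given lag
#'
#' @param lag fixation lag (>= 1).
#' @param params a [memory_params()].
#' @return weight in \[0, 1\].
#' @examples
#' memory_weight(2, memory_params(a = 1, tau = 2)) # 1 - exp(-1)
#' @export
memory_weight <- function(lag, params) {
  stopifnot(all(lag >= 1))
  1 - params$a * exp(-lag / params$tau)
}

#' Finite inhibition of return
#'
#' Multiplies the feature attention map by the memory field: every pixel
#' within the revisit radius of a previously visited location (using the
#' most recent visit, at ordinal `j`) is weighted by
#' [memory_weight()]`(t - j)`; pixels never visited are unchanged.
#'
#' @param M_f the feature attention map (matrix or [attention_map()]).
#' @param history data frame of past fixations with columns `index`, `row`,
#'   `col` (may be empty).
#' @param params a [memory_params()].
#' @param t current fixation ordinal (> max(history$index)).
#' @return weighted [attention_map()].
#' @export
apply_finite_ior <- function(M_f, history, params, t) {
  v <- unclass(M_f)
  if (is.null(history) || nrow(history) == 0L) {
    return(attention_map(v, provenance = attr(M_f, "provenance") %||% list()))
  }
  H <- nrow(v); W <- ncol(v)
  weights <- matrix(NA_real_, H, W)
  rad <- params$revisit_radius_px
  # latest visit wins: walk from most recent to oldest, first write sticks
  for (i in order(history$index, decreasing = TRUE)) {
    fr <- history$row[i]; fc <- history$col[i]
    rr <- max(1L, floor(fr - rad)):min(H, ceiling(fr + rad))
    cc <- max(1L, floor(fc - rad)):min(W, ceiling(fc + rad))
    d2 <- outer((rr - fr)^2, (cc - fc)^2, "+")
    inside <- d2 <= rad^2 & is.na(weights[rr, cc])
    sub <- weights[rr, cc]
    sub[inside] <- memory_weight(t - history$index[i], params)
    weights[rr, cc] <- sub
  }
  weights[is.na(weights)] <- 1
  attention_map(v * weights, provenance = attr(M_f, "provenance") %||% list())
}

#' Saccade-size constraint parameters
#'
#' @param shape,scale gamma parameters of the preferred saccade amplitude
#'   distribution, in degrees of visual angle.
#' @param geometry a [display_geometry()] for the pixel conversion.
#' @return object of class `saccade_size_params`.
#' @export
saccade_size_params <- function(shape = 2, scale = 3.8,
                                geometry = display_geometry()) {
  stopifnot(shape > 0, scale > 0)
  structure(list(shape = shape, scale = scale, geometry = geometry),
            class = "saccade_size_params")
}

#' Saccade-size constraint map
#'
#' Radially symmetric map whose value at each pixel is the gamma density of
#' that pixel's distance (in degrees) from the current fixation, rescaled so
#' the maximum is exactly 1. For `shape > 1` the map peaks on a ring at the
#' gamma mode, `(shape - 1) * scale` degrees.
#'
#' @param dims `c(height, width)` of the map in pixels.
#' @param current current fixation `c(row, col)`.
#' @param params a [saccade_size_params()].
#' @return numeric matrix in \[0, 1\] with max 1.
#' @export
size_constraint_map <- function(dims, current, params) {
  H <- dims[1]; W <- dims[2]
  stopifnot(current[1] >= 1, current[1] <= H, current[2] >= 1, current[2] <= W)
  d_px <- sqrt(outer((seq_len(H) - current[1])^2, (seq_len(W) - current[2])^2, "+"))
  d_deg <- d_px / params$geometry$px_per_deg
  m <- stats::dgamma(d_deg, shape = params$shape, scale = params$scale)
  mx <- max(m[is.finite(m)])
  if (mx <= 0) return(matrix(0, H, W))
  m <- m / mx
  m[!is.finite(m)] <- 1
  m
}

#' Combine feature attention with the saccade-size constraint
#'
#' `A_f = w * M_f + (1 - w) * M_sc`, both inputs expected in \[0, 1\].
#'
#' @param M_f_norm normalized feature attention map.
#' @param M_sc size-constraint map from [size_constraint_map()].
#' @param w feature-map weight in \[0, 1\] (default 0.2346).
#' @return combined [attention_map()].
#' @export
combine_size_constraint <- function(M_f_norm, M_sc, w = 0.2346) {
  stopifnot(w >= 0, w <= 1)
  a <- unclass(M_f_norm); b <- unclass(M_sc)
  if (!all(dim(a) == dim(b))) stop("map shapes differ")
  out <- w * a + (1 - w) * b
  out[!is.finite(a)] <- -Inf # masked cells stay masked
  attention_map(out, provenance = c(attr(M_f_norm, "provenance") %||% list(),
                                    list(size_weight = w)))
}

#' Oracle target-presence decision
#'
#' Idealized detection: the fixation counts as a hit if it falls inside a
#' `window_px` square centred on the target box centre (half-open: rows
#' `center - floor(w/2)` through `center - floor(w/2) + w - 1`), or inside
#' the target box itself when `window_px` is `NULL`.
#'
#' @param fix fixation `c(row, col)`.
#' @param target_box the ground-truth [bounding_box()].
#' @param window_px detection window side, or `NULL` to use the box.
#' @return logical: target found.
#' @export
oracle_check <- function(fix, target_box, window_px = NULL) {
  if (is.null(window_px)) {
    return(fix[1] >= target_box$row &
           fix[1] <= target_box$row + target_box$height - 1 &
           fix[2] >= target_box$col &
           fix[2] <= target_box$col + target_box$width - 1)
  }
  ctr <- round(box_center(target_box))
  r0 <- ctr[1] - floor(window_px / 2)
  c0 <- ctr[2] - floor(window_px / 2)
  fix[1] >= r0 & fix[1] <= r0 + window_px - 1 &
    fix[2] >= c0 & fix[2] <= c0 + window_px - 1
}

#' Recognition-based target-presence decision
#'
#' Crops a `window_px` square centred on the fixation (clipped at borders,
#' padded with mid-gray), extracts the backbone's final-layer descriptor of
#' the crop and of the target image, L2-normalizes both and declares the
#' target found iff their Euclidean distance is strictly below the
#' threshold.
#'
#' @param backbone an `ivsn_backbone`.
#' @param search_img the search image.
#' @param fix fixation `c(row, col)`.
#' @param target_img the target cue image.
#' @param window_px crop side in pixels.
#' @param threshold strict detection threshold on the normalized distance
#'   (default 0.9).
#' @return logical: target found.
#' @export
recognition_check <- function(backbone, search_img, fix, target_img,
                              window_px, threshold = 0.9) {
  search_img <- as_gray_image(search_img)
  H <- nrow(search_img); W <- ncol(search_img)
  r0 <- round(fix[1]) - floor(window_px / 2)
  c0 <- round(fix[2]) - floor(window_px / 2)
  if (r0 + window_px - 1 < 1 || r0 > H || c0 + window_px - 1 < 1 || c0 > W) {
    stop("crop window lies fully outside the search image")
  }
  crop <- matrix(0.5, window_px, window_px)
  rr <- max(1L, r0):min(H, r0 + window_px - 1L)
  cc <- max(1L, c0):min(W, c0 + window_px - 1L)
  crop[rr - r0 + 1L, cc - c0 + 1L] <- search_img[rr, cc]
  top_id <- backbone$layer_ids[length(backbone$layer_ids)]
  desc <- function(img) {
    v <- as.vector(extract_feature_stack(
      backbone, pad_resize_square(img, backbone$input_side), top_id)$maps)
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  }
  d <- sqrt(sum((desc(crop) - desc(target_img))^2))
  d < threshold
}

#' Run a full search trial
#'
#' Orchestrates the loop: build the attention map, select fixations by
#' winner-take-all, decide target presence (oracle or recognition), apply
#' inhibition of return, and stop at detection or the fixation cap. In array
#' mode (trials with `object_centers`, and `snap_to_objects = TRUE`)
#' fixations are snapped to object centres and IOR is applied object-wise,
#' so no object is visited twice and the target is always reached within
#' one pass over the array.
#'
#' @param trial a [search_trial()].
#' @param backbone an `ivsn_backbone`.
#' @param config a [search_config()].
#' @return object of class `ivsn_search`: list with `fixations` (data frame
#'   `index`, `row`, `col`), `found_at` (ordinal or `NA`), `attention` (the
#'   unmodified feature attention map), `trial_id`, `config`, `provenance`.
#' @export
run_search <- function(trial, backbone, config = search_config()) {
  stopifnot(inherits(trial, "search_trial"), inherits(config, "search_config"))
  M_f <- attention_for_image(backbone, trial$target_cue, trial$search_image,
                             layer_pair = config$layer_pair %||%
                               default_layer_pair(backbone))
  array_mode <- !is.null(trial$object_centers) && config$snap_to_objects
  max_fix <- config$max_fixations %||% (if (array_mode) nrow(trial$object_centers) else 45L)

  decide <- function(fix) {
    if (config$decision_mode == "oracle") {
      oracle_check(fix, trial$target_box, config$ior_window)
    } else {
      recognition_check(backbone, trial$search_image, fix, trial$target_cue,
                        config$ior_window, config$recognition_threshold)
    }
  }

  fixations <- data.frame(index = integer(), row = numeric(), col = numeric())
  found_at <- NA_integer_

  if (array_mode) {
    centers <- trial$object_centers
    half <- (trial$object_px - 1) / 2
    pri <- vapply(seq_len(nrow(centers)), function(k) {
      rr <- max(1, round(centers[k, 1] - half)):min(nrow(M_f), round(centers[k, 1] + half))
      cc <- max(1, round(centers[k, 2] - half)):min(ncol(M_f), round(centers[k, 2] + half))
      max(M_f[rr, cc])
    }, numeric(1))
    ord <- order(-pri, centers[, 1], centers[, 2])
    for (t in seq_len(min(max_fix, length(ord)))) {
      fix <- c(row = centers[ord[t], 1], col = centers[ord[t], 2])
      fixations <- rbind(fixations,
                         data.frame(index = t, row = unname(fix[1]),
                                    col = unname(fix[2])))
      if (decide(fix)) { found_at <- t; break }
    }
  } else {
    M_work <- M_f
    history <- fixations
    for (t in seq_len(max_fix)) {
      A <- if (config$ior_mode == "finite") {
        apply_finite_ior(M_f, history, config$memory_params, t)
      } else {
        M_work
      }
      if (!is.null(config$size_constraint) && t > 1L) {
        M_sc <- size_constraint_map(dim(unclass(A)),
                                    c(history$row[t - 1L], history$col[t - 1L]),
                                    config$size_constraint)
        A <- combine_size_constraint(normalize01(A), M_sc, config$size_weight)
      }
      fix <- wta_next_fixation(A)
      history <- rbind(history, data.frame(index = t, row = unname(fix[1]),
                                           col = unname(fix[2])))
      if (decide(fix)) { found_at <- t; break }
      if (config$ior_mode == "infinite") {
        M_work <- apply_infinite_ior(M_work, fix, config$ior_window)
      }
    }
    fixations <- history
  }

  structure(list(fixations = fixations, found_at = found_at,
                 attention = M_f, trial_id = trial$trial_id, config = config,
                 provenance = list(backbone = backbone$weights_fingerprint,
                                   array_mode = array_mode,
                                   max_fixations = max_fix)),
            class = "ivsn_search")
}

#' @export
print.ivsn_search <- function(x, ...) {
  res <- if (is.na(x$found_at)) "target not found" else
    sprintf("target found at fixation %d", x$found_at)
  cat(sprintf("<ivsn_search> '%s': %d fixation(s), %s\n",
              x$trial_id, nrow(x$fixations), res))
  invisible(x)
}

#' @export
plot.ivsn_search <- function(x, ...) {
  plot(x$attention, ...)
  H <- nrow(x$attention); W <- ncol(x$attention)
  graphics::lines((x$fixations$col - 0.5) / W, 1 - (x$fixations$row - 0.5) / H,
                  col = "red", type = "o", pch = 16)
  graphics::text((x$fixations$col - 0.5) / W, 1 - (x$fixations$row - 0.5) / H,
                 labels = x$fixations$index, col = "yellow", pos = 3)
  invisible(x)
}
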