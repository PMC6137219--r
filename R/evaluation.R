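#' Cumulative search performance curve
#'
#' Empirical distribution p(n) of the fixation ordinal at which the target
#' was found, with its running sum. Trials where the target was never found
#' contribute to no bin, so the cumulative curve plateaus below 1.
#'
#' @param results integer vector of `found_at` ordinals (`NA` = never
#'   found), or a list of `ivsn_search` / [fixation_sequence()] /
#'   `null_model_result` objects.
#' @param n_max largest ordinal on the curve (default: largest observed).
#' @return object of class `performance_curve`: data frame with columns
#'   `n`, `p`, `cumulative`, plus attributes `n_trials` and `n_unfound`.
#' @export
cumulative_performance <- function(results, n_max = NULL) {
  found_at <- extract_found_at(results)
  n_trials <- length(found_at)
  if (n_trials == 0L) stop("no trials supplied")
  if (is.null(n_max)) n_max <- max(c(found_at, 1L), na.rm = TRUE)
  p <- vapply(seq_len(n_max), function(n)
    sum(found_at == n, na.rm = TRUE) / n_trials, numeric(1))
  out <- data.frame(n = seq_len(n_max), p = p, cumulative = cumsum(p))
  attr(out, "n_trials") <- n_trials
  attr(out, "n_unfound") <- sum(is.na(found_at) | found_at > n_max)
  class(out) <- c("performance_curve", "data.frame")
  out
}

extract_found_at <- function(results) {
  if (is.numeric(results)) return(as.integer(results))
  if (inherits(results, "null_model_result")) return(results$found_at)
  as.integer(vapply(results, function(r) {
    if (inherits(r, "null_model_result")) stop("flatten null_model_result first")
    as.integer(r$found_at %||% NA_integer_)
  }, integer(1)))
}

#' @export
print.performance_curve <- function(x, ...) {
  cat(sprintf("<performance_curve> %d trials (%d unfound); cumulative[%d] = %.1f%%\n",
              attr(x, "n_trials"), attr(x, "n_unfound"), nrow(x),
              100 * x$cumulative[nrow(x)]))
  invisible(x)
}

#' @export
plot.performance_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  if (!add) {
    graphics::plot(x$n, 100 * x$cumulative, type = "o", pch = 16, col = col,
                   xlab = "fixation number", ylab = "cumulative performance (%)",
                   ylim = c(0, 100), ...)
  } else {
    graphics::lines(x$n, 100 * x$cumulative, type = "o", pch = 16, col = col, ...)
  }
  invisible(x)
}

#' Mean-shift clustering of fixation locations
#'
#' Flat-kernel mean shift: each point is iteratively moved to the mean of
#' all points within the bandwidth until convergence; converged modes
#' closer than half a bandwidth are merged. Used to quantize fixations into
#' the character alphabet of the scanpath similarity score.
#'
#' @param points n x 2 matrix (row, col) of fixation locations.
#' @param bandwidth kernel radius in pixels (default 32 px = 1 deg at
#'   32 px/deg, about eye-tracker precision).
#' @return list with `modes` (k x 2 matrix) and `assignment` (integer
#'   vector mapping each point to a mode).
#' @export
mean_shift_clusters <- function(points, bandwidth = 32) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 1)
  n <- nrow(points)
  shifted <- points
  for (i in seq_len(n)) {
    x <- points[i, ]
    for (iter in 1:100) {
      d2 <- (points[, 1] - x[1])^2 + (points[, 2] - x[2])^2
      nb <- d2 <= bandwidth^2
      nx <- c(mean(points[nb, 1]), mean(points[nb, 2]))
      if (sum((nx - x)^2) < 1e-6) break
      x <- nx
    }
    shifted[i, ] <- x
  }
  modes <- matrix(numeric(0), 0, 2)
  assignment <- integer(n)
  for (i in seq_len(n)) {
    if (nrow(modes)) {
      d2 <- (modes[, 1] - shifted[i, 1])^2 + (modes[, 2] - shifted[i, 2])^2
      j <- which(d2 <= (bandwidth / 2)^2)
    } else j <- integer(0)
    if (length(j)) {
      assignment[i] <- j[1]
    } else {
      modes <- rbind(modes, shifted[i, ])
      assignment[i] <- nrow(modes)
    }
  }
  list(modes = modes, assignment = assignment)
}

#' Needleman-Wunsch alignment score for scanpath strings
#'
#' Global alignment with match = 1, mismatch = 0, gap = 0; with this
#' scoring the optimal alignment score equals the length of the longest
#' common subsequence.
#'
#' @param a,b integer or character vectors (cluster label strings).
#' @return integer alignment score.
#' @export
nw_align_score <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) return(0L)
  prev <- integer(lb + 1L)
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    for (j in seq_len(lb)) {
      cur[j + 1L] <- max(prev[j + 1L], cur[j],
                         prev[j] + as.integer(a[i] == b[j]))
    }
    prev <- cur
  }
  prev[lb + 1L]
}

#' Scanpath similarity score
#'
#' Spatiotemporal similarity of two fixation sequences: all fixations used
#' for clustering (by default the pooled fixations of the two sequences)
#' are mean-shift clustered and each fixation mapped to its cluster's
#' character; the two character strings (truncated to `max_length`) are
#' aligned by Needleman-Wunsch (match 1, mismatch 0, gap 0) and the score
#' normalized by the longer string's length. The score is symmetric, lies
#' in \[0, 1\], equals 1 for identical strings and 0 when the sequences
#' share no cluster.
#'
#' @param seqA,seqB [fixation_sequence()] objects (or data frames with
#'   `row`, `col`).
#' @param all_fixations optional n x 2 matrix of fixations defining the
#'   clustering (e.g. all human fixations on that image).
#' @param max_length compare only the first `max_length` fixations.
#' @param bandwidth mean-shift bandwidth in pixels.
#' @return object of class `scanpath_score`: list with `value`,
#'   `stringA`, `stringB`, `n_clusters`, `bandwidth`, `max_length`.
#' @export
scanpath_similarity <- function(seqA, seqB, all_fixations = NULL,
                                max_length = Inf, bandwidth = 32) {
  fa <- seq_coords(seqA); fb <- seq_coords(seqB)
  if (!nrow(fa) || !nrow(fb)) stop("empty fixation sequence")
  fa <- fa[seq_len(min(nrow(fa), max_length)), , drop = FALSE]
  fb <- fb[seq_len(min(nrow(fb), max_length)), , drop = FALSE]
  pool <- if (is.null(all_fixations)) rbind(fa, fb) else as.matrix(all_fixations)
  cl <- mean_shift_clusters(pool, bandwidth = bandwidth)
  label <- function(f) {
    vapply(seq_len(nrow(f)), function(i) {
      d2 <- (cl$modes[, 1] - f[i, 1])^2 + (cl$modes[, 2] - f[i, 2])^2
      which.min(d2)
    }, integer(1))
  }
  sa <- label(fa); sb <- label(fb)
  value <- nw_align_score(sa, sb) / max(length(sa), length(sb))
  structure(list(value = value, stringA = sa, stringB = sb,
                 n_clusters = nrow(cl$modes), bandwidth = bandwidth,
                 max_length = max_length),
            class = "scanpath_score")
}

seq_coords <- function(s) {
  f <- if (inherits(s, "fixation_sequence")) s$fixations else as.data.frame(s)
  cbind(row = f$row, col = f$col)
}

#' @export
print.scanpath_score <- function(x, ...) {
  cat(sprintf("<scanpath_score> %.3f (%d clusters, bandwidth %g px)\n",
              x$value, x$n_clusters, x$bandwidth))
  invisible(x)
}

#' Per-trial fixation-count consistency
#'
#' Pairs the number of fixations needed to find the target across two sets
#' of results sharing trial ids, restricted to trials found by both, and
#' reports a Spearman rank correlation (counts are heavy-tailed) with an
#' approximate Fisher-z 95% confidence interval.
#'
#' @param resultsA,resultsB named integer vectors of `found_at` by trial id,
#'   or lists of objects with `trial_id` and `found_at`.
#' @return list with `pairs` (data frame `trial_id`, `found_A`, `found_B`),
#'   `rho`, `ci` and `n`.
#' @export
fixation_count_pairs <- function(resultsA, resultsB) {
  a <- named_found_at(resultsA); b <- named_found_at(resultsB)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stop("no shared trial ids")
  a <- a[shared]; b <- b[shared]
  keep <- !is.na(a) & !is.na(b) # only trials found by both sides
  if (!any(keep)) stop("no trial was found by both sides")
  pairs <- data.frame(trial_id = shared[keep], found_A = a[keep],
                      found_B = b[keep], row.names = NULL)
  n <- nrow(pairs)
  rho <- if (n >= 2 && stats::sd(pairs$found_A) > 0 && stats::sd(pairs$found_B) > 0) {
    stats::cor(pairs$found_A, pairs$found_B, method = "spearman")
  } else NA_real_
  ci <- if (!is.na(rho) && n > 3 && abs(rho) < 1) {
    z <- atanh(rho); hw <- 1.96 / sqrt(n - 3)
    tanh(c(z - hw, z + hw))
  } else c(NA_real_, NA_real_)
  list(pairs = pairs, rho = rho, ci = ci, n = n)
}

named_found_at <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    storage.mode(x) <- "integer"
    return(x)
  }
  stats::setNames(vapply(x, function(r) as.integer(r$found_at %||% NA_integer_),
                         integer(1)),
                  vapply(x, function(r) r$trial_id, character(1)))
}

#' Empirical revisit probability by fixation lag
#'
#' For every ordered fixation pair (j, i), i > j, within a sequence, a
#' revisit occurs when the two fixations are within `revisit_radius_px` of
#' each other; the curve gives the fraction of pairs at each lag i - j.
#'
#' @param seqs list of [fixation_sequence()] objects (>= 1, with >= 2
#'   fixations in at least one).
#' @param revisit_radius_px revisit radius in pixels (default 96 = 3 deg at
#'   32 px/deg).
#' @param max_lag largest lag on the curve (default 20).
#' @return data frame with columns `lag`, `p`, `n_pairs`.
#' @export
estimate_revisit_curve <- function(seqs, revisit_radius_px = 96, max_lag = 20L) {
  if (inherits(seqs, "fixation_sequence")) seqs <- list(seqs)
  hits <- integer(max_lag); tot <- integer(max_lag)
  r2 <- revisit_radius_px^2
  for (s in seqs) {
    f <- seq_coords(s)
    n <- nrow(f)
    if (n < 2) next
    for (lag in seq_len(min(max_lag, n - 1L))) {
      i <- (lag + 1L):n
      j <- i - lag
      d2 <- (f[i, 1] - f[j, 1])^2 + (f[i, 2] - f[j, 2])^2
      hits[lag] <- hits[lag] + sum(d2 <= r2)
      tot[lag] <- tot[lag] + length(i)
    }
  }
  if (sum(tot > 0) < 2) stop("fewer than 2 lags observed")
  data.frame(lag = seq_len(max_lag), p = ifelse(tot > 0, hits / tot, NA_real_),
             n_pairs = tot)
}

#' Fit the memory function to an empirical revisit curve
#'
#' Bounded least squares of the model `P(lag) = c * (1 - a * exp(-lag/tau))`
#' to the empirical revisit probabilities: the revisit probability is
#' proportional to the memory recovery weight `M_m(lag) = 1 - a*exp(-lag/tau)`,
#' with the free scale `c` absorbing the overall revisit rate. When subject
#' ids are supplied, a random train subset (default 7 of them) is used for
#' the fit and the rest held out, mirroring the usual cross-validated
#' fitting protocol.
#'
#' @param seqs list of [fixation_sequence()] objects, or an
#'   already-computed curve from [estimate_revisit_curve()].
#' @param revisit_radius_px revisit radius in pixels.
#' @param max_lag largest lag used in the fit (default 20; the fit uses
#'   lags `min_lag..max_lag` with observed pairs).
#' @param min_lag smallest lag used in the fit (default 2: at lag 1 a short
#'   saccade is indistinguishable from a deliberate return, so lag-1 pairs
#'   are excluded).
#' @param subjects optional character vector, one subject id per sequence.
#' @param n_train number of subjects in the training split (default 7).
#' @return object of class `memory_fit`: list with `params` (a
#'   [memory_params()]), `scale`, `curve`, `train_subjects`,
#'   `test_subjects`, `sse`.
#' @export
fit_memory_params <- function(seqs, revisit_radius_px = 96, max_lag = 20L,
                              min_lag = 2L, subjects = NULL, n_train = 7L) {
  train_subjects <- test_subjects <- NULL
  if (is.data.frame(seqs)) {
    curve <- seqs
  } else {
    fit_seqs <- seqs
    if (!is.null(subjects)) {
      stopifnot(length(subjects) == length(seqs))
      ids <- unique(subjects)
      n_train <- min(n_train, length(ids))
      train_subjects <- sample(ids, n_train)
      test_subjects <- setdiff(ids, train_subjects)
      fit_seqs <- seqs[subjects %in% train_subjects]
    }
    curve <- estimate_revisit_curve(fit_seqs, revisit_radius_px, max_lag)
  }
  obs <- curve[!is.na(curve$p) & curve$n_pairs > 0 & curve$lag >= min_lag, ]
  if (nrow(obs) < 3) stop("need at least 3 observed lags to fit")
  w <- obs$n_pairs # binomial precision weighting
  loss <- function(par) {
    pred <- par[3] * (1 - par[1] * exp(-obs$lag / par[2]))
    sum(w * (pred - obs$p)^2)
  }
  best <- NULL
  for (tau0 in c(1, 2, 3, 5, 8)) { # restarts: the surface has a shallow valley
    fit <- stats::optim(c(0.8, tau0, max(obs$p, 0.01)), loss,
                        method = "L-BFGS-B",
                        lower = c(0, 1e-3, 1e-6), upper = c(1, 50, 1))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(list(params = memory_params(best$par[1], best$par[2],
                                        revisit_radius_px),
                 scale = best$par[3], curve = curve,
                 train_subjects = train_subjects, test_subjects = test_subjects,
                 sse = best$value),
            class = "memory_fit")
}

#' @export
coef.memory_fit <- function(object, ...) {
  c(a = object$params$a, tau = object$params$tau, scale = object$scale)
}

#' @export
print.memory_fit <- function(x, ...) {
  cat(sprintf("<memory_fit> a = %.3f, tau = %.3f lags, scale = %.4f (sse %.3g)\n",
              x$params$a, x$params$tau, x$scale, x$sse))
  if (!is.null(x$train_subjects)) {
    cat(sprintf("  fitted on %d subjects, held out %d\n",
                length(x$train_subjects), length(x$test_subjects)))
  }
  invisible(x)
}

#' Saccade amplitude statistics and gamma fit
#'
#' Computes inter-fixation Euclidean distances converted to degrees of
#' visual angle and fits a gamma distribution by maximum likelihood
#' (sequences with fewer than 2 fixations contribute no amplitudes).
#'
#' @param seqs list of [fixation_sequence()] objects.
#' @param geometry a [display_geometry()].
#' @return object of class `gamma_saccade_fit`: list with `amplitudes_deg`,
#'   `shape`, `scale`, `mean`, `sd`, `n`.
#' @export
saccade_size_stats <- function(seqs, geometry = display_geometry()) {
  if (inherits(seqs, "fixation_sequence")) seqs <- list(seqs)
  amps <- unlist(lapply(seqs, function(s) {
    f <- seq_coords(s)
    if (nrow(f) < 2) return(numeric(0))
    sqrt(diff(f[, 1])^2 + diff(f[, 2])^2)
  }))
  amps <- deg_px_convert(amps, geometry, "px2deg")
  amps <- amps[amps > 0]
  fit <- if (length(amps) >= 10) {
    est <- MASS::fitdistr(amps, "gamma")$estimate
    c(shape = unname(est["shape"]), scale = 1 / unname(est["rate"]))
  } else c(shape = NA_real_, scale = NA_real_)
  structure(list(amplitudes_deg = amps, shape = fit[["shape"]],
                 scale = fit[["scale"]], mean = mean(amps), sd = stats::sd(amps),
                 n = length(amps)),
            class = "gamma_saccade_fit")
}

#' @export
coef.gamma_saccade_fit <- function(object, ...) {
  c(shape = object$shape, scale = object$scale)
}

#' @export
print.gamma_saccade_fit <- function(x, ...) {
  cat(sprintf("<gamma_saccade_fit> n = %d amplitudes: mean %.2f deg (SD %.2f); gamma shape %.3f, scale %.3f deg\n",
              x$n, x$mean, x$sd, x$shape, x$scale))
  invisible(x)
}

#' Normalized Euclidean distance between two object images
#'
#' Both images are resized to a common square side, flattened, and the
#' Euclidean distance is divided by `sqrt(pixel count) * intensity range`,
#' so identical images score 0 and an all-black vs all-white pair scores 1.
#' Symmetric by construction.
#'
#' @param imgA,imgB gray image matrices.
#' @param side common resize side (default 64).
#' @return normalized distance in \[0, 1\].
#' @export
object_similarity <- function(imgA, imgB, side = 64L) {
  a <- resize_gray(as_gray_image(imgA), side, side)
  b <- resize_gray(as_gray_image(imgB), side, side)
  sqrt(sum((a - b)^2)) / (sqrt(side * side) * 1)
}
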