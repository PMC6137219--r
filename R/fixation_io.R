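#' Fixation sequence container
#'
#' An ordered scanpath for one trial: a data frame of fixations (columns
#' `index`, `row`, `col`, optionally `duration_ms` and `onset_ms`), the
#' ordinal at which the target was found (`NA` if never), and the trial id.
#' Indices must be consecutive from 1.
#'
#' @param fixations data frame with at least `index`, `row`, `col`.
#' @param found_at ordinal of the detecting fixation, or `NA`.
#' @param trial_id character id.
#' @return object of class `fixation_sequence`.
#' @export
fixation_sequence <- function(fixations, found_at = NA_integer_,
                              trial_id = "trial") {
  stopifnot(is.data.frame(fixations),
            all(c("index", "row", "col") %in% names(fixations)))
  n <- nrow(fixations)
  if (n > 0 && !identical(as.integer(fixations$index), seq_len(n))) {
    stop("fixation indices must be consecutive from 1")
  }
  if (!is.na(found_at) && (found_at < 1 || found_at > n)) {
    stop("found_at must be a fixation ordinal within the sequence")
  }
  structure(list(fixations = fixations, found_at = as.integer(found_at),
                 trial_id = as.character(trial_id)),
            class = "fixation_sequence")
}

#' @export
print.fixation_sequence <- function(x, ...) {
  res <- if (is.na(x$found_at)) "not found" else sprintf("found at %d", x$found_at)
  cat(sprintf("<fixation_sequence> '%s': %d fixations, target %s\n",
              x$trial_id, nrow(x$fixations), res))
  invisible(x)
}

#' @export
length.fixation_sequence <- function(x) nrow(x$fixations)

.raw_cols <- c("trial_id", "onset_ms", "duration_ms", "x", "y")

#' Read a raw fixation table
#'
#' Reads a CSV with header `trial_id,onset_ms,duration_ms,x,y` (`x` = column,
#' `y` = row, screen pixels). Malformed rows (non-numeric fields, negative
#' durations) are reported with their row numbers. Off-image coordinates are
#' not dropped at read time.
#'
#' @param path CSV path.
#' @return data frame of raw fixations.
#' @export
read_fixation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(.raw_cols, names(df))
  if (length(missing)) {
    stop("fixation table is missing columns: ", paste(missing, collapse = ", "))
  }
  df <- df[, .raw_cols]
  if (nrow(df) == 0L) {
    return(data.frame(trial_id = character(), onset_ms = numeric(),
                      duration_ms = numeric(), x = numeric(), y = numeric()))
  }
  for (col in c("onset_ms", "duration_ms", "x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric '%s' in row(s): %s", col,
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
    df[[col]] <- v
  }
  bad <- which(df$duration_ms < 0)
  if (length(bad)) {
    stop("negative duration_ms in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  df
}

#' Write fixations to a raw fixation table
#'
#' Accepts either a raw data frame (columns as in [read_fixation_table()])
#' or a list of [fixation_sequence()] objects. Round-trips through
#' [read_fixation_table()] without loss.
#'
#' @param seqs raw data frame or list of sequences.
#' @param path output CSV path.
#' @export
write_fixation_table <- function(seqs, path) {
  df <- if (is.data.frame(seqs)) seqs[, .raw_cols] else sequences_to_raw(seqs)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

sequences_to_raw <- function(seqs) {
  if (inherits(seqs, "fixation_sequence")) seqs <- list(seqs)
  do.call(rbind, lapply(seqs, function(s) {
    f <- s$fixations
    data.frame(trial_id = s$trial_id,
               onset_ms = if ("onset_ms" %in% names(f)) f$onset_ms else
                 cumsum(c(0, rep(300, nrow(f) - 1))),
               duration_ms = if ("duration_ms" %in% names(f)) f$duration_ms else 200,
               x = f$col, y = f$row)
  }))
}

raw_to_sequences <- function(df) {
  lapply(split(df, df$trial_id), function(d) {
    d <- d[order(d$onset_ms), ]
    fixation_sequence(data.frame(index = seq_len(nrow(d)), row = d$y, col = d$x,
                                 duration_ms = d$duration_ms, onset_ms = d$onset_ms),
                      trial_id = d$trial_id[1])
  })
}

#' Preprocess raw fixations: cluster and drop short fixations
#'
#' Merges runs of consecutive fixations that stay within a
#' `cluster_box_px` square of the running duration-weighted centroid
#' (durations summed, onset taken from the first member), then drops merged
#' fixations whose total duration does not exceed `min_duration_ms`.
#' Ordinals are reassigned; temporal order is never changed. The operation
#' is idempotent.
#'
#' @param raw raw fixation data frame (see [read_fixation_table()]) or a
#'   list of [fixation_sequence()] objects.
#' @param min_duration_ms fixations at or below this duration are dropped
#'   (default 50 ms).
#' @param cluster_box_px side of the clustering box, pixels (default 45).
#' @return named list of [fixation_sequence()] objects, one per trial.
#' @export
preprocess_raw_fixations <- function(raw, min_duration_ms = 50,
                                     cluster_box_px = 45) {
  df <- if (is.data.frame(raw)) raw else sequences_to_raw(raw)
  half <- cluster_box_px / 2

  merge_pass <- function(d) {
    cl <- d[0, , drop = FALSE]
    cur <- NULL
    flush <- function() if (!is.null(cur)) cl <<- rbind(cl, cur)
    for (i in seq_len(nrow(d))) {
      if (!is.null(cur) &&
          abs(d$y[i] - cur$y) <= half && abs(d$x[i] - cur$x) <= half) {
        tot <- cur$duration_ms + d$duration_ms[i]
        if (tot > 0) { # duration-weighted running centroid
          cur$y <- (cur$y * cur$duration_ms + d$y[i] * d$duration_ms[i]) / tot
          cur$x <- (cur$x * cur$duration_ms + d$x[i] * d$duration_ms[i]) / tot
        }
        cur$duration_ms <- tot
      } else {
        flush()
        cur <- d[i, , drop = FALSE]
      }
    }
    flush()
    cl
  }

  out <- lapply(split(df, df$trial_id), function(d) {
    d <- d[order(d$onset_ms), ]
    # iterate merge + drop to a fixed point: successive cluster centroids can
    # themselves fall within the box, and dropping a short fixation can make
    # its neighbours adjacent, so one pass alone is not idempotent
    repeat {
      n_in <- nrow(d)
      repeat {
        merged <- merge_pass(d)
        if (nrow(merged) == nrow(d)) break
        d <- merged
      }
      d <- d[d$duration_ms > min_duration_ms, , drop = FALSE]
      if (nrow(d) == n_in) break
    }
    keep <- rep(TRUE, nrow(d))
    n <- sum(keep)
    fixation_sequence(
      data.frame(index = seq_len(n), row = d$y[keep], col = d$x[keep],
                 duration_ms = d$duration_ms[keep], onset_ms = d$onset_ms[keep]),
      trial_id = d$trial_id[1])
  })
  out
}

#' Keep only fixations landing on array objects
#'
#' Removes fixations falling outside every object's acceptance box
#' (`accept_box_px` square centred on each object centre) and reports the
#' discarded fraction.
#'
#' @param seq a [fixation_sequence()].
#' @param object_centers n x 2 matrix (row, col) of object centres.
#' @param accept_box_px acceptance box side in pixels.
#' @return list with `sequence` (filtered, ordinals reassigned),
#'   `discarded` (count) and `fraction_discarded`.
#' @export
filter_array_fixations <- function(seq, object_centers, accept_box_px) {
  stopifnot(inherits(seq, "fixation_sequence"))
  f <- seq$fixations
  half <- accept_box_px / 2
  ok <- vapply(seq_len(nrow(f)), function(i) {
    any(abs(object_centers[, 1] - f$row[i]) <= half &
        abs(object_centers[, 2] - f$col[i]) <= half)
  }, logical(1))
  kept <- f[ok, , drop = FALSE]
  if (nrow(kept)) kept$index <- seq_len(nrow(kept))
  list(sequence = fixation_sequence(kept, trial_id = seq$trial_id),
       discarded = sum(!ok),
       fraction_discarded = if (nrow(f)) sum(!ok) / nrow(f) else 0)
}
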