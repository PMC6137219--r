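# shared fixtures: a small display geometry (8 px/deg) and a cached test
# backbone so the seeded weights are built once per run

small_geometry <- function() display_geometry(256, 320, 32, 40)

.fixture_env <- new.env(parent = emptyenv())

test_backbone <- function(padding = "same") {
  key <- paste0("bb_", padding)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- load_backbone("test", padding = padding)
  }
  .fixture_env[[key]]
}

# a blank scene with one pixel-identical planted target, plus its trial
planted_trial <- function(seed = 5, target_px = 40, H = 192, W = 256) {
  set.seed(seed)
  tgt <- matrix(runif(target_px^2), target_px, target_px)
  scene <- matrix(0.5, H, W)
  r0 <- 73; c0 <- 141
  scene[r0:(r0 + target_px - 1), c0:(c0 + target_px - 1)] <- tgt
  search_trial(tgt, scene, bounding_box(r0, c0, target_px, target_px),
               display_geometry(H, W, H / 8, W / 8), trial_id = "planted")
}

# brute-force 'same' zero-padded cross-correlation (independent of the
# implementation: explicit triple loop over kernel cells and channels)
brute_xcorr_same <- function(x, k) {
  H <- nrow(x); W <- ncol(x); kh <- nrow(k); kw <- ncol(k)
  ocr <- (kh - 1L) %/% 2L; occ <- (kw - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (u in seq_len(kh)) {
        for (v in seq_len(kw)) {
          r <- i + u - 1L - ocr; c <- j + v - 1L - occ
          if (r >= 1 && r <= H && c >= 1 && c <= W) acc <- acc + k[u, v] * x[r, c]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# exhaustive global-alignment enumeration (match 1, mismatch 0, gap 0)
brute_align_score <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  s1 <- brute_align_score(a[-1], b)
  s2 <- brute_align_score(a, b[-1])
  s3 <- brute_align_score(a[-1], b[-1]) + as.integer(a[1] == b[1])
  max(s1, s2, s3)
}
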