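#' Attention map container
#'
#' A scalar priority map over the search-image pixel grid. Values may be
#' `-Inf` where inhibition of return has permanently masked a region.
#'
#' @param values numeric matrix over the search-image pixels.
#' @param provenance optional list recording how the map was produced.
#' @return object of class `attention_map` (a matrix with attributes).
#' @export
attention_map <- function(values, provenance = list()) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values)) stop("attention map contains NA")
  fin <- values[is.finite(values)]
  structure(values, provenance = provenance,
            raw_range = if (length(fin)) range(fin) else c(NA_real_, NA_real_),
            class = c("attention_map", "matrix", "array"))
}

#' @export
print.attention_map <- function(x, ...) {
  rr <- attr(x, "raw_range")
  cat(sprintf("<attention_map> %d x %d px, raw range [%.4g, %.4g], %d masked px\n",
              nrow(x), ncol(x), rr[1], rr[2], sum(!is.finite(x))))
  invisible(x)
}

#' @export
plot.attention_map <- function(x, ...) {
  v <- unclass(normalize01(x))
  v[!is.finite(v)] <- 0
  graphics::image(t(v)[, nrow(v):1], col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(v) / ncol(v), ...)
  invisible(x)
}

#' Target modulation of a search feature stack
#'
#' The core top-down step: the target's stored template is applied as a 2D
#' convolution kernel (deep-learning convention, i.e. cross-correlation, no
#' kernel flip) over the search image's feature stack, summing over
#' channels, with 'same' zero padding. The result is a single-channel
#' feature-space priority map.
#'
#' @param search_stack a `feature_stack` from [extract_feature_stack()].
#' @param kernel a `target_kernel` from [target_template()].
#' @param flip if `TRUE`, flip the kernel (true convolution) instead of
#'   correlating; provided for fidelity checks.
#' @return numeric matrix in feature space (rows x cols of the search stack).
#' @export
modulate <- function(search_stack, kernel, flip = FALSE) {
  stopifnot(inherits(search_stack, "feature_stack"), inherits(kernel, "target_kernel"))
  sm <- search_stack$maps; km <- kernel$kernel
  if (dim(sm)[3] != dim(km)[3]) {
    stop(sprintf("channel mismatch: search stack has %d channels, kernel %d",
                 dim(sm)[3], dim(km)[3]))
  }
  out <- matrix(0, dim(sm)[1], dim(sm)[2])
  for (ch in seq_len(dim(sm)[3])) {
    k <- matrix(km[, , ch], dim(km)[1], dim(km)[2])
    if (flip) k <- k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]
    out <- out + xcorr2_same(matrix(sm[, , ch], dim(sm)[1], dim(sm)[2]), k)
  }
  out
}

#' Full-image attention map with tiling
#'
#' Large search images are partitioned into a non-overlapping grid of
#' square tiles of the backbone's input side; right/bottom remainder tiles
#' are zero-padded, the model is run on each tile, and the per-tile
#' feature-space maps are upsampled to pixel space (bilinear, feature cells
#' anchored at their receptive-field centres) and concatenated in grid
#' order. The padded region falls outside the image and is cropped away.
#'
#' @param backbone an `ivsn_backbone`.
#' @param target_img gray image of the target cue.
#' @param search_img gray image to search.
#' @param layer_pair `c(top_id, mod_id)`; default [default_layer_pair()].
#' @param tile_px tile side; defaults to `backbone$input_side`.
#' @return an [attention_map()] the size of `search_img`.
#' @export
attention_for_image <- function(backbone, target_img, search_img,
                                layer_pair = default_layer_pair(backbone),
                                tile_px = backbone$input_side) {
  search_img <- as_gray_image(search_img)
  kernel <- target_template(backbone, target_img, layer_pair)
  H <- nrow(search_img); W <- ncol(search_img)
  nty <- ceiling(H / tile_px); ntx <- ceiling(W / tile_px)
  padded <- matrix(0, nty * tile_px, ntx * tile_px)
  padded[seq_len(H), seq_len(W)] <- search_img
  out <- matrix(0, nty * tile_px, ntx * tile_px)
  for (ty in seq_len(nty)) {
    for (tx in seq_len(ntx)) {
      rr <- (ty - 1L) * tile_px + seq_len(tile_px)
      cc <- (tx - 1L) * tile_px + seq_len(tile_px)
      stack <- extract_feature_stack(backbone, padded[rr, cc], kernel$mod_layer_id)
      m <- modulate(stack, kernel)
      out[rr, cc] <- upsample_bilinear(m, tile_px, tile_px,
                                       stride = stack$stride_px,
                                       offset = stack$offset_px)
    }
  }
  attention_map(out[seq_len(H), seq_len(W), drop = FALSE],
                provenance = list(backbone = backbone$weights_fingerprint,
                                  layer_pair = c(kernel$source_layer_id,
                                                 kernel$mod_layer_id),
                                  tile_px = tile_px,
                                  tiles = c(nty, ntx)))
}

# bilinear upsampling of a feature map to H x W pixels; feature cell i
# (1-based) is anchored at its receptive-field centre, pixel
# offset + (i - 0.5) * stride
upsample_bilinear <- function(m, H, W, stride = NULL, offset = 0) {
  A <- interp_weights(nrow(m), H, stride, offset)
  B <- interp_weights(ncol(m), W, stride, offset)
  A %*% m %*% t(B)
}

interp_weights <- function(n_src, n_out, stride = NULL, offset = 0) {
  if (is.null(stride)) stride <- n_out / n_src
  # continuous source index (1-based) of each output pixel centre
  pos <- ((seq_len(n_out) - 0.5 - offset) / stride) + 0.5
  pos <- pmin(pmax(pos, 1), n_src)
  lo <- pmin(floor(pos), n_src - ifelse(n_src > 1, 1, 0))
  lo <- pmax(lo, 1)
  hi <- pmin(lo + 1, n_src)
  w_hi <- pos - lo
  A <- matrix(0, n_out, n_src)
  A[cbind(seq_len(n_out), lo)] <- 1 - w_hi
  A[cbind(seq_len(n_out), hi)] <- A[cbind(seq_len(n_out), hi)] + w_hi
  A
}

#' Normalize an attention map to \[0, 1\]
#'
#' Affine rescale so the finite values span \[0, 1\]; a constant map maps to
#' all zeros by convention. Masked (`-Inf`) cells are preserved. The argmax
#' is invariant under this monotone transform.
#'
#' @param map an [attention_map()] or numeric matrix.
#' @return an [attention_map()] with finite values in \[0, 1\].
#' @export
normalize01 <- function(map) {
  v <- unclass(map)
  fin <- is.finite(v)
  rng <- range(v[fin])
  if (diff(rng) < .Machine$double.eps) {
    v[fin] <- 0
  } else {
    v[fin] <- (v[fin] - rng[1]) / (rng[2] - rng[1])
  }
  attention_map(v, provenance = attr(map, "provenance") %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an attention map as a 16-bit PNG
#'
#' Writes the normalized map (masked cells as 0).
#'
#' @param map an [attention_map()].
#' @param path output PNG path.
#' @export
write_attention_png <- function(map, path) {
  v <- unclass(normalize01(map))
  v[!is.finite(v)] <- 0
  EBImage::writeImage(EBImage::Image(t(v)), path, bits.per.sample = 16L)
  invisible(path)
}
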