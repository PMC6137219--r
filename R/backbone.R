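#' Convolutional feature backbones ("ventral stream")
#'
#' The search model is agnostic to the particular feature hierarchy: any
#' feed-forward convolutional network exposing addressable layers satisfies
#' the backbone contract. The package ships a small fully-deterministic
#' architecture, `tinynet`: three blocks of 3x3 convolution (bias-free) +
#' ReLU + 2x2 max pooling, with layer ids `conv1_relu, pool1, ..., pool3`.
#' Large published classification networks (e.g. a 16-layer VGG-style net,
#' whose top-level feature vector has 512 channels) honour the same contract
#' when their weights are available; `weights_mode = "pretrained"` errors
#' with instructions because no pretrained weights ship with the package.
#'
#' @param name architecture name; `"test"` and `"tinynet"` are registered.
#' @param weights_mode `"test"` (fixed seeded weights), `"random"` (Gaussian
#'   weights, see [make_random_weights_backbone()]) or `"pretrained"`.
#' @param input_side nominal square input side in pixels; `tinynet` is fully
#'   convolutional so this only sets the default tile size (default 64).
#' @param channels integer vector of output channels per block.
#' @param padding `"same"` (zero padding) or `"valid"` (no padding).
#' @param seed seed for `weights_mode = "random"`.
#' @param sd weight standard deviation for `weights_mode = "random"`.
#' @return object of class `ivsn_backbone` with fields `name`, `layer_ids`,
#'   `input_side`, `weights_fingerprint`.
#' @examples
#' bb <- load_backbone("test")
#' bb$layer_ids
#' @export
load_backbone <- function(name = "test",
                          weights_mode = c("test", "random", "pretrained"),
                          input_side = 64L, channels = c(4L, 8L, 16L),
                          padding = c("same", "valid"), seed = 1L, sd = 0.25) {
  weights_mode <- match.arg(weights_mode)
  padding <- match.arg(padding)
  if (!name %in% c("test", "tinynet")) {
    stop(sprintf("unknown backbone '%s'; registered: 'test', 'tinynet'", name))
  }
  if (weights_mode == "pretrained") {
    stop("no pretrained weights are bundled with this package; ",
         "use weights_mode = 'test' for the seeded offline backbone, ",
         "or weights_mode = 'random' for Gaussian random weights")
  }
  if (weights_mode == "test") {
    # fixed internal seed: the test backbone is identical across sessions
    seed <- 20181115L
    sd <- 0.25
  }
  weights <- tinynet_weights(channels, seed = seed, sd = sd)
  new_backbone(name = name, weights = weights, channels = channels,
               input_side = as.integer(input_side), padding = padding)
}

#' Random-weight backbone
#'
#' Same architecture as [load_backbone()], but with all convolution weights
#' drawn iid Gaussian with mean 0 and the given standard deviation
#' (default 1000, the standard random-weight control for feature networks).
#'
#' @param arch architecture name.
#' @param seed integer seed for the weight draw.
#' @param sd weight standard deviation (default 1000).
#' @inheritParams load_backbone
#' @return an `ivsn_backbone`.
#' @export
make_random_weights_backbone <- function(arch = "tinynet", seed, sd = 1000,
                                         input_side = 64L,
                                         channels = c(4L, 8L, 16L),
                                         padding = c("same", "valid")) {
  stopifnot(sd > 0)
  load_backbone(arch, weights_mode = "random", input_side = input_side,
                channels = channels, padding = match.arg(padding),
                seed = seed, sd = sd)
}

tinynet_weights <- function(channels, seed, sd) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  cin <- 1L
  ws <- vector("list", length(channels))
  for (b in seq_along(channels)) {
    ws[[b]] <- array(stats::rnorm(3 * 3 * cin * channels[b], 0, sd),
                     dim = c(3L, 3L, cin, channels[b]))
    cin <- channels[b]
  }
  ws
}

new_backbone <- function(name, weights, channels, input_side, padding) {
  n_blocks <- length(channels)
  layer_ids <- as.vector(rbind(sprintf("conv%d_relu", seq_len(n_blocks)),
                               sprintf("pool%d", seq_len(n_blocks))))
  strides <- as.vector(rbind(2^(seq_len(n_blocks) - 1), 2^seq_len(n_blocks)))
  structure(list(name = name, weights = weights, channels = channels,
                 layer_ids = layer_ids,
                 layer_strides = stats::setNames(strides, layer_ids),
                 input_side = input_side, padding = padding,
                 weights_fingerprint = fingerprint_weights(weights)),
            class = "ivsn_backbone")
}

fingerprint_weights <- function(weights) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(lapply(weights, function(w) signif(w, 12)), con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' @export
print.ivsn_backbone <- function(x, ...) {
  cat(sprintf("<ivsn_backbone> '%s' (%s padding), input side %d px\n",
              x$name, x$padding, x$input_side))
  cat("  layers:", paste(x$layer_ids, collapse = ", "), "\n")
  cat("  fingerprint:", x$weights_fingerprint, "\n")
  invisible(x)
}

#' Default and variant layer pairs
#'
#' A layer pair `(top_id, mod_id)` names the layer whose response to the
#' target acts as the stored template (`top_id`) and the layer of the search
#' image it modulates (`mod_id`, immediately below `top_id`). The default
#' for `tinynet` is the deepest pair `("pool3", "conv3_relu")`; shallower
#' variants pair each pooling layer with the convolution directly beneath
#' it, mirroring the layer-pair variants studied for deep classification
#' networks.
#'
#' @param backbone an `ivsn_backbone`.
#' @param depth which pair, counted from the deepest (1 = default).
#' @return character vector `c(top_id, mod_id)`.
#' @export
default_layer_pair <- function(backbone, depth = 1L) {
  n_blocks <- length(backbone$channels)
  b <- n_blocks - depth + 1L
  if (b < 1L) stop("no such layer pair")
  c(sprintf("pool%d", b), sprintf("conv%d_relu", b))
}

#' Extract a feature stack from a backbone layer
#'
#' Runs the image through the backbone and returns the activation stack at
#' the requested layer, with the layer's pixel stride recorded.
#'
#' @param backbone an `ivsn_backbone`.
#' @param img gray image matrix (any size; the net is fully convolutional).
#' @param layer_id one of `backbone$layer_ids`.
#' @return object of class `feature_stack`: list with `maps` (array
#'   height x width x channels), `layer_id`, `stride_px`.
#' @export
extract_feature_stack <- function(backbone, img, layer_id) {
  stopifnot(inherits(backbone, "ivsn_backbone"))
  if (!layer_id %in% backbone$layer_ids) {
    stop(sprintf("layer '%s' not in backbone (have: %s)", layer_id,
                 paste(backbone$layer_ids, collapse = ", ")))
  }
  img <- as_gray_image(img)
  x <- array(img, dim = c(nrow(img), ncol(img), 1L))
  out <- NULL
  stride <- 1
  offset <- 0 # centre of the first cell sits at offset + stride/2 pixels
  for (b in seq_along(backbone$channels)) {
    x <- conv2d_forward(x, backbone$weights[[b]], padding = backbone$padding)
    if (backbone$padding == "valid") offset <- offset + stride # 3x3 trims one cell
    x <- pmax(x, 0) # ReLU
    id_conv <- sprintf("conv%d_relu", b)
    if (layer_id == id_conv) { out <- x; break }
    x <- maxpool2(x)
    stride <- stride * 2 # pooling doubles the stride, offset unchanged
    id_pool <- sprintf("pool%d", b)
    if (layer_id == id_pool) { out <- x; break }
  }
  structure(list(maps = out, layer_id = layer_id,
                 stride_px = unname(backbone$layer_strides[layer_id]),
                 offset_px = offset),
            class = "feature_stack")
}

# multi-channel 2D convolution (correlation, the deep-learning convention)
conv2d_forward <- function(x, w, padding = "same") {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  stopifnot(dim(x)[3] == cin)
  H <- dim(x)[1]; W <- dim(x)[2]
  if (padding == "same") { oh <- H; ow <- W } else { oh <- H - kh + 1L; ow <- W - kw + 1L }
  if (oh < 1L || ow < 1L) stop("input smaller than kernel under 'valid' padding")
  out <- array(0, dim = c(oh, ow, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(0, oh, ow)
    for (ci in seq_len(cin)) {
      if (padding == "same") {
        acc <- acc + xcorr2_same(x[, , ci], w[, , ci, co])
      } else {
        acc <- acc + xcorr2_valid(x[, , ci], w[, , ci, co])
      }
    }
    out[, , co] <- acc
  }
  out
}

# 'same' zero-padded 2D cross-correlation (kernel anchored at its centre,
# centre index floor((k-1)/2) from the top/left for even kernels)
xcorr2_same <- function(x, k) {
  H <- nrow(x); W <- ncol(x); kh <- nrow(k); kw <- ncol(k)
  ocr <- (kh - 1L) %/% 2L; occ <- (kw - 1L) %/% 2L
  xp <- matrix(0, H + kh - 1L, W + kw - 1L)
  xp[(ocr + 1L):(ocr + H), (occ + 1L):(occ + W)] <- x
  out <- matrix(0, H, W)
  for (u in seq_len(kh)) {
    for (v in seq_len(kw)) {
      kv <- k[u, v]
      if (kv != 0) {
        out <- out + kv * xp[u:(u + H - 1L), v:(v + W - 1L), drop = FALSE]
      }
    }
  }
  out
}

# 'valid' 2D cross-correlation (no padding)
xcorr2_valid <- function(x, k) {
  H <- nrow(x); W <- ncol(x); kh <- nrow(k); kw <- ncol(k)
  oh <- H - kh + 1L; ow <- W - kw + 1L
  out <- matrix(0, oh, ow)
  for (u in seq_len(kh)) {
    for (v in seq_len(kw)) {
      kv <- k[u, v]
      if (kv != 0) {
        out <- out + kv * x[u:(u + oh - 1L), v:(v + ow - 1L), drop = FALSE]
      }
    }
  }
  out
}

# 2x2 max pooling, stride 2 (odd trailing row/col dropped)
maxpool2 <- function(x) {
  H <- dim(x)[1] %/% 2L; W <- dim(x)[2] %/% 2L; C <- dim(x)[3]
  if (H < 1L || W < 1L) stop("feature map too small to pool")
  r1 <- seq_len(H) * 2L - 1L; c1 <- seq_len(W) * 2L - 1L
  out <- array(0, dim = c(H, W, C))
  for (ch in seq_len(C)) {
    m <- x[, , ch]
    out[, , ch] <- pmax(m[r1, c1, drop = FALSE], m[r1 + 1L, c1, drop = FALSE],
                        m[r1, c1 + 1L, drop = FALSE], m[r1 + 1L, c1 + 1L, drop = FALSE])
  }
  out
}

#' Resize an image to the backbone's square input with aspect-preserving padding
#'
#' Scales the image so its larger side equals `side`, then pads to a square
#' canvas with a constant fill.
#'
#' @param img gray image matrix.
#' @param side output side in pixels.
#' @param fill pad intensity (default mid-gray 0.5).
#' @return `side` x `side` gray image.
#' @export
pad_resize_square <- function(img, side, fill = 0.5) {
  img <- as_gray_image(img)
  if (nrow(img) == side && ncol(img) == side) return(img)
  sc <- side / max(nrow(img), ncol(img))
  nh <- max(1L, round(nrow(img) * sc)); nw <- max(1L, round(ncol(img) * sc))
  small <- resize_gray(img, nh, nw)
  out <- matrix(fill, side, side)
  r0 <- floor((side - nh) / 2); c0 <- floor((side - nw) / 2)
  out[r0 + seq_len(nh), c0 + seq_len(nw)] <- small
  out
}

#' Target template: the stored top-level representation of the target
#'
#' Extracts the target image's activation stack at the top layer of a layer
#' pair; that stack acts as the convolution kernel modulating the search
#' image's features at the layer below. The target is first resized
#' (aspect-preserving, padded to square) to the backbone's input side.
#'
#' @param backbone an `ivsn_backbone`.
#' @param target_img gray image of the target cue.
#' @param layer_pair character `c(top_id, mod_id)`; default
#'   [default_layer_pair()].
#' @return object of class `target_kernel`: list with `kernel` (array
#'   kh x kw x channels) and `source_layer_id`.
#' @export
target_template <- function(backbone, target_img,
                            layer_pair = default_layer_pair(backbone)) {
  stopifnot(length(layer_pair) == 2L)
  if (!all(layer_pair %in% backbone$layer_ids)) stop("invalid layer pair for backbone")
  top <- extract_feature_stack(
    backbone, pad_resize_square(target_img, backbone$input_side), layer_pair[1])
  structure(list(kernel = top$maps, source_layer_id = layer_pair[1],
                 mod_layer_id = layer_pair[2]),
            class = "target_kernel")
}
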