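#' Grayscale image utilities
#'
#' Images throughout the package are plain numeric matrices with intensities
#' in \[0, 1\], rows indexed top-to-bottom (y) and columns left-to-right (x),
#' 1-based as usual in R. These helpers validate and construct such matrices.
#'
#' @param pixels numeric matrix of intensities.
#' @return `as_gray_image()` returns the validated matrix (invisibly classed
#'   checks only, no attributes are added).
#' @examples
#' img <- as_gray_image(matrix(runif(12), 3, 4))
#' @export
as_gray_image <- function(pixels) {
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    # collapse RGB planes with the usual luma weights
    if (dim(pixels)[3] >= 3L) {
      pixels <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
    } else {
      pixels <- pixels[, , 1]
    }
  }
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("a gray image must be a numeric matrix")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1x1")
  if (anyNA(pixels) || any(!is.finite(pixels))) stop("image contains non-finite values")
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    stop("image intensities must lie in [0, 1]")
  }
  pmin(pmax(pixels, 0), 1)
}

#' Read a raster image file as a gray image matrix
#'
#' @param path PNG/JPEG/TIFF file.
#' @return numeric matrix in \[0,1\].
#' @export
read_gray_image <- function(path) {
  im <- EBImage::readImage(path)
  d <- dim(im)
  a <- EBImage::imageData(im)
  if (length(d) == 3L) {
    m <- if (d[3] >= 3L) 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3] else a[, , 1]
  } else {
    m <- a
  }
  as_gray_image(t(m)) # EBImage stores x in dim 1
}

#' Write a gray image matrix to a PNG file
#'
#' @param img gray image matrix.
#' @param path output path.
#' @export
write_gray_image <- function(img, path) {
  img <- as_gray_image(img)
  EBImage::writeImage(EBImage::Image(t(img)), path)
  invisible(path)
}

# EBImage round-trips: the package keeps images as [row, col] matrices while
# EBImage uses [x, y]; transpose at the boundary.
.eb <- function(img) EBImage::Image(t(img))
.uneb <- function(im) t(EBImage::imageData(im))

#' Resize a gray image with bilinear interpolation
#'
#' @param img gray image matrix.
#' @param height,width output size in pixels.
#' @return resized matrix, clipped back to \[0,1\].
#' @export
resize_gray <- function(img, height, width) {
  img <- as_gray_image(img)
  out <- .uneb(EBImage::resize(.eb(img), w = as.integer(width), h = as.integer(height)))
  pmin(pmax(out, 0), 1)
}

#' Bounding box
#'
#' A box is described by its top-left corner (`row`, `col`, 1-based) and its
#' `height` and `width` in pixels. Non-integer sizes are allowed for
#' continuous-geometry computations (e.g. chance-model analyses); boxes that
#' index pixels are integral.
#'
#' @param row,col top-left corner (1-based pixels).
#' @param height,width box size in pixels (>= 1).
#' @return an object of class `bounding_box`.
#' @export
bounding_box <- function(row, col, height, width) {
  stopifnot(height >= 1, width >= 1)
  structure(list(row = row, col = col, height = height, width = width),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> top-left (%.6g, %.6g), %.6g x %.6g px\n",
              x$row, x$col, x$height, x$width))
  invisible(x)
}

#' Centre of a bounding box
#' @param box a `bounding_box`.
#' @return numeric `c(row, col)` of the box centre.
#' @export
box_center <- function(box) {
  c(row = box$row + (box$height - 1) / 2, col = box$col + (box$width - 1) / 2)
}

#' Clip a bounding box to image bounds
#' @param box a `bounding_box`.
#' @param height,width image size.
#' @return clipped `bounding_box`.
#' @export
clip_box <- function(box, height, width) {
  r1 <- max(1, box$row); c1 <- max(1, box$col)
  r2 <- min(height, box$row + box$height - 1)
  c2 <- min(width, box$col + box$width - 1)
  if (r2 < r1 || c2 < c1) stop("box lies fully outside the image")
  bounding_box(r1, c1, r2 - r1 + 1, c2 - c1 + 1)
}

#' Display geometry: pixels and degrees of visual angle
#'
#' Encodes the monitor geometry used to convert between pixels and degrees.
#' The default matches a 1024 x 1280 display subtending ~32 x 40 degrees
#' (32 px/deg). Vertical and horizontal pixel densities must agree within
#' 10%.
#'
#' @param height_px,width_px display size in pixels.
#' @param height_deg,width_deg display size in degrees of visual angle.
#' @return an object of class `display_geometry` with a `px_per_deg` field.
#' @examples
#' geom <- display_geometry()
#' geom$px_per_deg # 32
#' @export
display_geometry <- function(height_px = 1024, width_px = 1280,
                             height_deg = 32, width_deg = 40) {
  stopifnot(height_px >= 1, width_px >= 1, height_deg > 0, width_deg > 0)
  ppd_h <- height_px / height_deg
  ppd_w <- width_px / width_deg
  if (abs(ppd_h - ppd_w) / max(ppd_h, ppd_w) > 0.10) {
    stop("vertical and horizontal px/deg differ by more than 10%")
  }
  structure(list(height_px = as.integer(height_px), width_px = as.integer(width_px),
                 height_deg = height_deg, width_deg = width_deg,
                 px_per_deg = (ppd_h + ppd_w) / 2),
            class = "display_geometry")
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf("<display_geometry> %d x %d px, %.3g x %.3g deg (%.4g px/deg)\n",
              x$height_px, x$width_px, x$height_deg, x$width_deg, x$px_per_deg))
  invisible(x)
}

#' Convert between pixels and degrees of visual angle
#'
#' Linear conversion at the geometry's pixels-per-degree; the two directions
#' compose to the identity.
#'
#' @param value numeric values to convert.
#' @param geometry a [display_geometry()].
#' @param direction `"deg2px"` or `"px2deg"`.
#' @return converted numeric vector.
#' @examples
#' geom <- display_geometry()
#' deg_px_convert(3, geom, "deg2px") # 96 px
#' @export
deg_px_convert <- function(value, geometry, direction = c("deg2px", "px2deg")) {
  direction <- match.arg(direction)
  stopifnot(inherits(geometry, "display_geometry"))
  if (direction == "deg2px") value * geometry$px_per_deg else value / geometry$px_per_deg
}

#' Search trial container
#'
#' One unit of work for the search engine: a target cue image, a search
#' image, the ground-truth target box, the display geometry and, for
#' object-array stimuli, the six object centres.
#'
#' @param target_cue,search_image gray image matrices.
#' @param target_box `bounding_box` of the target within `search_image`.
#' @param geometry a [display_geometry()].
#' @param object_centers optional n x 2 matrix (row, col) of array object
#'   centres (array mode).
#' @param object_px object box side in pixels (array mode).
#' @param trial_id character id.
#' @return object of class `search_trial`.
#' @export
search_trial <- function(target_cue, search_image, target_box, geometry,
                         object_centers = NULL, object_px = NULL,
                         trial_id = "trial") {
  search_image <- as_gray_image(search_image)
  target_cue <- as_gray_image(target_cue)
  stopifnot(inherits(target_box, "bounding_box"), inherits(geometry, "display_geometry"))
  if (target_box$row < 1 || target_box$col < 1 ||
      target_box$row + target_box$height - 1 > nrow(search_image) + 1e-9 ||
      target_box$col + target_box$width - 1 > ncol(search_image) + 1e-9) {
    stop("target_box must lie inside the search image")
  }
  structure(list(target_cue = target_cue, search_image = search_image,
                 target_box = target_box, geometry = geometry,
                 object_centers = object_centers, object_px = object_px,
                 trial_id = as.character(trial_id)),
            class = "search_trial")
}

#' @export
print.search_trial <- function(x, ...) {
  mode <- if (is.null(x$object_centers)) "free" else
    sprintf("array (%d objects)", nrow(x$object_centers))
  cat(sprintf("<search_trial> '%s': search %d x %d px, cue %d x %d px, %s mode\n",
              x$trial_id, nrow(x$search_image), ncol(x$search_image),
              nrow(x$target_cue), ncol(x$target_cue), mode))
  cat("  target "); print(x$target_box)
  invisible(x)
}
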