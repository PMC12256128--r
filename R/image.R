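# Image representation: numeric array height x width x 3, values in [0, 1],
# as returned by png::readPNG. EBImage stores images width-first, so the
# helpers below transpose at the boundary.

#' Read an image file
#'
#' @param path PNG file path.
#' @return numeric array `height x width x 3` with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop_invalid_argument(sprintf("image file not found: %s", path))
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  } else if (dim(img)[3] == 4) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

#' Write an image to a PNG file
#'
#' @param img numeric array `height x width x 3` in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

image_height <- function(img) dim(img)[1]
image_width <- function(img) dim(img)[2]

to_ebimage <- function(img) aperm(img, c(2, 1, 3))
from_ebimage <- function(x) aperm(x, c(2, 1, 3))

#' Axis-aligned bounding box
#'
#' Boxes are 0-based and half-open: pixel columns `x_min .. x_max - 1` and
#' rows `y_min .. y_max - 1` are inside the box.
#'
#' @param x_min,y_min,x_max,y_max integer pixel coordinates with
#'   `x_min < x_max` and `y_min < y_max`.
#' @return an object of class `"bbox"`.
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  if (x_min < 0 || y_min < 0 || x_max <= x_min || y_max <= y_min) {
    stop_invalid_argument("bbox requires 0 <= x_min < x_max and 0 <= y_min < y_max")
  }
  structure(
    list(x_min = as.integer(x_min), y_min = as.integer(y_min),
         x_max = as.integer(x_max), y_max = as.integer(y_max)),
    class = "bbox"
  )
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox [%d,%d) x [%d,%d)>\n", x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

bbox_width <- function(box) box$x_max - box$x_min
bbox_height <- function(box) box$y_max - box$y_min
bbox_area <- function(box) bbox_width(box) * bbox_height(box)

# Tight bounding box of TRUE cells in a height x width logical matrix;
# NULL when the mask is empty.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  bbox(
    x_min = min(idx[, 2]) - 1L, y_min = min(idx[, 1]) - 1L,
    x_max = max(idx[, 2]), y_max = max(idx[, 1])
  )
}

#' Crop an image to a bounding box
#'
#' @param img image array.
#' @param box a [bbox()] within the image bounds.
#' @return the cropped image array.
#' @export
crop_image <- function(img, box) {
  h <- image_height(img); w <- image_width(img)
  if (box$x_max > w || box$y_max > h) {
    stop_invalid_argument("bbox extends beyond image bounds")
  }
  img[(box$y_min + 1):box$y_max, (box$x_min + 1):box$x_max, , drop = FALSE]
}

# Expand a box by round(margin_fraction * side length) pixels per side,
# clipped to the image bounds.
expand_bbox <- function(box, margin_fraction, width, height) {
  mx <- round_half_up(margin_fraction * bbox_width(box))
  my <- round_half_up(margin_fraction * bbox_height(box))
  bbox(
    x_min = max(0, box$x_min - mx), y_min = max(0, box$y_min - my),
    x_max = min(width, box$x_max + mx), y_max = min(height, box$y_max + my)
  )
}

# Rescale a box from one image size to another (both height, width pairs);
# used to map specimen boxes into classifier input coordinates.
scale_bbox <- function(box, from_dim, to_dim) {
  sy <- to_dim[1] / from_dim[1]
  sx <- to_dim[2] / from_dim[2]
  bbox(
    x_min = floor(box$x_min * sx), y_min = floor(box$y_min * sy),
    x_max = max(floor(box$x_min * sx) + 1, ceiling(box$x_max * sx)),
    y_max = max(floor(box$y_min * sy) + 1, ceiling(box$y_max * sy))
  )
}

#' Resize an image with bilinear interpolation
#'
#' @param img image array.
#' @param height,width target size in pixels.
#' @return resized image array.
#' @export
resize_image <- function(img, height, width) {
  out <- EBImage::resize(to_ebimage(img), w = width, h = height,
                         filter = "bilinear")
  from_ebimage(EBImage::imageData(out))
}

# Rotation (degrees, anticlockwise) and zoom about the image centre with a
# constant fill colour; output size equals input size. The fill colour is
# quantised to 8 bits, matching PNG precision.
transform_image <- function(img, angle = 0, zoom = 1, bg = c(0, 0, 0)) {
  h <- image_height(img); w <- image_width(img)
  theta <- angle * pi / 180
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  a <- zoom * rot
  centre <- c((w + 1) / 2, (h + 1) / 2)
  shift <- centre - as.vector(a %*% centre)
  m <- rbind(t(a), shift)
  eb <- EBImage::Image(to_ebimage(img), colormode = "Color")
  tr <- EBImage::affine(eb, m, filter = "bilinear",
                        bg.col = grDevices::rgb(bg[1], bg[2], bg[3]))
  from_ebimage(EBImage::imageData(tr))
}

# Most frequent colour in the image (channels rounded to 1/255), as an
# RGB triple; a cheap, robust background estimate for uniform backgrounds.
estimate_background <- function(img) {
  q <- round(img * 255)
  key <- q[, , 1] * 65536 + q[, , 2] * 256 + q[, , 3]
  tab <- table(key)
  top <- as.numeric(names(tab)[which.max(tab)])
  c(top %/% 65536, (top %/% 256) %% 256, top %% 256) / 255
}

#' Flatten images into a feature matrix
#'
#' Resizes each image to a square `input_size` and flattens the RGB values
#' into one row per image, the input representation used by the bundled
#' classifier.
#'
#' @param images list of image arrays.
#' @param input_size side length in pixels of the square model input.
#' @return numeric matrix with one row per image and
#'   `input_size^2 * 3` columns.
#' @export
image_features <- function(images, input_size) {
  feat <- matrix(0, nrow = length(images), ncol = input_size^2 * 3)
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (image_height(im) != input_size || image_width(im) != input_size) {
      im <- resize_image(im, input_size, input_size)
    }
    feat[i, ] <- as.vector(im)
  }
  feat
}
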