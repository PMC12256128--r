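# Detection-based cropping, training-set augmentation and the attention
# quality-control metric. The detector contract is pluggable: any function
# image -> list of (box, confidence) can stand in for a trained object
# detector; the default below exploits the uniform background of desk-scale
# synthetic imagery.

#' Default specimen detector for uniform-background images
#'
#' Segments every pixel that differs from the dominant background colour by
#' more than `background_tolerance` in any channel, labels connected
#' components, and returns the tight bounding box of each component with
#' confidence equal to the component area divided by the image area.
#' Components are ordered by area (largest first), with ties broken by the
#' top-left-most box.
#'
#' @param image image array.
#' @param background_tolerance per-channel absolute tolerance in `[0, 1]`.
#' @return list of detections, each a list with `box` (a [bbox()]) and
#'   `confidence`; empty list when no foreground is found.
#' @export
default_detector <- function(image, background_tolerance = 0.06) {
  bg <- estimate_background(image)
  diff <- pmax(abs(image[, , 1] - bg[1]), abs(image[, , 2] - bg[2]),
               abs(image[, , 3] - bg[3]))
  mask <- diff > background_tolerance
  if (!any(mask)) return(list())
  labels <- EBImage::bwlabel(mask)
  areas <- tabulate(labels[labels > 0])
  comps <- lapply(seq_along(areas), function(k) {
    box <- mask_bbox(labels == k)
    list(box = box, confidence = areas[k] / length(mask), area = areas[k])
  })
  ord <- order(-vapply(comps, `[[`, numeric(1), "area"),
               vapply(comps, function(c) c$box$y_min, integer(1)),
               vapply(comps, function(c) c$box$x_min, integer(1)))
  lapply(comps[ord], function(c) c[c("box", "confidence")])
}

#' Detect the specimen and crop to it
#'
#' Crops the image to the highest-confidence detection expanded by
#' `margin_fraction` of the box side per side and clipped to the image
#' bounds. Ties on confidence go to the larger box, then the top-left-most.
#' When the detector returns nothing the full image is returned and the
#' provenance record carries `fallback = TRUE`.
#'
#' @param image image array.
#' @param detector a detector function (default [default_detector()]).
#' @param margin_fraction non-negative margin per side, as a fraction of
#'   the box width/height.
#' @return list with `image` (the crop) and `provenance` (list: `box` used
#'   for the crop, `raw_box`, `confidence`, `fallback`).
#' @export
detect_and_crop <- function(image, detector = default_detector,
                            margin_fraction = 0.05) {
  if (margin_fraction < 0) {
    stop_invalid_argument("margin_fraction must be >= 0")
  }
  detections <- detector(image)
  if (length(detections) == 0) {
    return(list(image = image,
                provenance = list(box = NULL, raw_box = NULL,
                                  confidence = NA_real_, fallback = TRUE)))
  }
  ord <- order(
    -vapply(detections, `[[`, numeric(1), "confidence"),
    -vapply(detections, function(d) bbox_area(d$box), integer(1)),
    vapply(detections, function(d) d$box$y_min, integer(1)),
    vapply(detections, function(d) d$box$x_min, integer(1))
  )
  best <- detections[[ord[1]]]
  box <- expand_bbox(best$box, margin_fraction,
                     width = image_width(image), height = image_height(image))
  list(image = crop_image(image, box),
       provenance = list(box = box, raw_box = best$box,
                         confidence = best$confidence, fallback = FALSE))
}

#' Augmentation parameter ranges
#'
#' Each augmented copy draws an independent rotation (uniform +/- 15
#' degrees), zoom (uniform 0.9-1.1) and brightness multiplier (uniform
#' 1.0-1.2, an increase only). Rotation and zoom fill exposed borders with
#' the estimated background colour.
#'
#' @format named list of `c(min, max)` ranges.
#' @export
augment_ranges <- list(
  rotation_deg = c(-15, 15),
  zoom = c(0.9, 1.1),
  brightness = c(1.0, 1.2)
)

#' Randomly augment an image
#'
#' @param image image array.
#' @param rng_state integer seed; identical seeds give identical outputs.
#' @param n_copies number of augmented copies (0 gives an empty list).
#' @param ranges augmentation ranges, see [augment_ranges].
#' @return list of `n_copies` image arrays, each the same size as the
#'   input with values clipped to `[0, 1]`.
#' @export
augment <- function(image, rng_state, n_copies = 4, ranges = augment_ranges) {
  if (n_copies < 0) stop_invalid_argument("n_copies must be >= 0")
  if (n_copies == 0) return(list())
  bg <- estimate_background(image)
  with_seed(rng_state, {
    lapply(seq_len(n_copies), function(i) {
      angle <- runif(1, ranges$rotation_deg[1], ranges$rotation_deg[2])
      zoom <- runif(1, ranges$zoom[1], ranges$zoom[2])
      bright <- runif(1, ranges$brightness[1], ranges$brightness[2])
      out <- transform_image(image, angle = angle, zoom = zoom, bg = bg)
      pmin(pmax(out * bright, 0), 1)
    })
  })
}

#' Fraction of saliency mass inside the specimen box
#'
#' Formalises the heat-map check that a trained model attends to the
#' specimen rather than to labels or background: the sum of saliency values
#' inside the specimen bounding box divided by the total sum, or 0 when the
#' map is all zero. The saliency map itself can come from any
#' class-activation or gradient method; see [gradient_saliency()] for the
#' bundled one.
#'
#' @param saliency_map numeric matrix of non-negative saliency values.
#' @param specimen_box a [bbox()] within the map bounds.
#' @return fraction in `[0, 1]`.
#' @export
attention_on_specimen_fraction <- function(saliency_map, specimen_box) {
  if (any(saliency_map < 0)) {
    stop_invalid_argument("saliency values must be non-negative")
  }
  if (specimen_box$x_max > ncol(saliency_map) ||
      specimen_box$y_max > nrow(saliency_map)) {
    stop_invalid_argument("specimen_box extends beyond the saliency map")
  }
  total <- sum(saliency_map)
  if (total == 0) return(0)
  inside <- saliency_map[(specimen_box$y_min + 1):specimen_box$y_max,
                         (specimen_box$x_min + 1):specimen_box$x_max]
  sum(inside) / total
}
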