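# Procedural specimen images: mirrored wing ellipses with a sinusoidal
# stripe texture on a uniform background, optionally with a text-like label
# strip below the specimen. Species identity is carried by body hue, stripe
# frequency, wing aspect and nominal size; confusable species pairs differ
# only slightly in the appearance parameters.

#' Rendering and jitter constants for the synthetic generator
#'
#' A single documented constants block. Per-image jitter: rotation +/- 5
#' degrees, linear scale +/- 10%, hue +/- 5 degrees. `bbox_area_band` is the
#' guaranteed band for the rendered bounding-box area as a multiple of
#' `(nominal_scale * canvas_size)^2`, wide enough to absorb scale jitter,
#' rotation growth and pixel quantisation. Confusable partners differ by
#' `confusable_delta` (hue degrees, stripe-frequency ratio, wing-aspect
#' ratio, nominal-scale ratio); the large scale ratio emulates species that
#' look alike but differ in size, a cue that detection-based cropping plus
#' model-input resizing deliberately destroys.
#'
#' @format a named list.
#' @export
syn_constants <- list(
  background = c(0.84, 0.82, 0.78),
  rotation_jitter_deg = 5,
  scale_jitter = 0.10,
  hue_jitter_deg = 5,
  bbox_area_band = c(0.70, 1.45),
  strip_height_frac = 0.07,
  strip_width_frac = c(0.10, 0.65),
  # stripe_ratio must be read jointly with scale_ratio: stripe frequency is
  # defined per canvas width, so detection-cropping and resizing divide the
  # observed frequency by the specimen's relative size; the post-crop
  # frequency ratio between partners is stripe_ratio / scale_ratio (~1.23),
  # keeping partners separable by pattern after size is discarded
  confusable_delta = list(hue_deg = 12, stripe_ratio = 1.60,
                          aspect_ratio = 1.08, scale_ratio = 1.30),
  confusable_partner_prob = 0.8,
  nominal_scale_range = c(0.38, 0.66),
  wing_aspect_range = c(1.05, 1.55),
  stripe_freq_range = c(3, 8)
)

#' Generate a set of synthetic species specifications
#'
#' Species are spread evenly around the hue circle with randomised stripe
#' frequency, wing aspect and nominal size. The first `2 * n_confusable_pairs`
#' species form confusable pairs: the partner's appearance parameters differ
#' only by the small deltas in [syn_constants] (its nominal size differs
#' substantially, but size is discarded by cropping).
#'
#' @param n_species number of species, at least 2.
#' @param n_confusable_pairs number of confusable pairs;
#'   `2 * n_confusable_pairs <= n_species`.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return a data frame with one row per species and columns
#'   `species_name`, `body_hue`, `stripe_frequency`, `wing_aspect`,
#'   `nominal_scale`, `confusable_with`.
#' @export
make_species_set <- function(n_species, n_confusable_pairs = 0, seed = 1) {
  if (n_species < 2) stop_invalid_argument("n_species must be at least 2")
  if (2 * n_confusable_pairs > n_species) {
    stop_invalid_argument("need 2 * n_confusable_pairs <= n_species")
  }
  k <- syn_constants
  with_seed(seed, {
    # one hue slot per lineage: each confusable pair shares a slot
    n_slots <- n_species - n_confusable_pairs
    slot_hues <- (360 * (seq_len(n_slots) - 1) / n_slots +
                    runif(1, 0, 360 / n_slots)) %% 360
    specs <- data.frame(
      species_name = sprintf("species_%02d", seq_len(n_species)),
      body_hue = NA_real_, stripe_frequency = NA_real_,
      wing_aspect = NA_real_, nominal_scale = NA_real_,
      confusable_with = NA_character_,
      stringsAsFactors = FALSE
    )
    slot <- 1
    i <- 1
    while (i <= n_species) {
      hue <- slot_hues[slot]
      f <- runif(1, k$stripe_freq_range[1], k$stripe_freq_range[2])
      a <- runif(1, k$wing_aspect_range[1], k$wing_aspect_range[2])
      s <- runif(1, k$nominal_scale_range[1], k$nominal_scale_range[2])
      specs$body_hue[i] <- hue
      specs$stripe_frequency[i] <- f
      specs$wing_aspect[i] <- a
      specs$nominal_scale[i] <- s
      if (i %% 2 == 1 && (i + 1) / 2 <= n_confusable_pairs) {
        d <- k$confusable_delta
        j <- i + 1
        specs$body_hue[j] <- (hue + d$hue_deg) %% 360
        specs$stripe_frequency[j] <- f * d$stripe_ratio
        specs$wing_aspect[j] <- min(a * d$aspect_ratio, k$wing_aspect_range[2])
        specs$nominal_scale[j] <- min(s * d$scale_ratio,
                                      k$nominal_scale_range[2] * 1.1)
        specs$confusable_with[i] <- specs$species_name[j]
        specs$confusable_with[j] <- specs$species_name[i]
        i <- i + 2
      } else {
        i <- i + 1
      }
      slot <- slot + 1
    }
    specs
  })
}

#' Appearance distance between two species specifications
#'
#' Distance over the cropping-invariant appearance parameters: circular hue
#' difference (scaled by 30 degrees), log stripe-frequency ratio and log
#' wing-aspect ratio. Nominal scale is excluded because the pipeline resizes
#' every cropped image to the model input size, discarding absolute size.
#' Confusable pairs score well below unrelated species under this distance.
#'
#' @param spec_a,spec_b single rows of a [make_species_set()] data frame.
#' @return non-negative scalar distance.
#' @export
species_distance <- function(spec_a, spec_b) {
  dh <- abs(spec_a$body_hue - spec_b$body_hue) %% 360
  dh <- min(dh, 360 - dh)
  dh / 30 +
    abs(log(spec_a$stripe_frequency / spec_b$stripe_frequency)) +
    abs(log(spec_a$wing_aspect / spec_b$wing_aspect))
}

# Vectorised HSV -> RGB for hue in degrees, returning an n x 3 matrix.
hsv_to_rgb <- function(h, s, v) {
  hex <- grDevices::hsv((h %% 360) / 360, s, v)
  t(grDevices::col2rgb(hex)) / 255
}

#' Render one synthetic specimen image
#'
#' Draws mirrored fore/hind wing ellipses and a body on a uniform
#' background, applying the per-image jitter in [syn_constants] (rotation,
#' scale, hue, stripe phase). The exact axis-aligned bounding box of the
#' rendered foreground is returned alongside the image; outside that box no
#' pixel differs from the background except, when requested, the label
#' strip drawn below the specimen.
#'
#' @param spec one row of a [make_species_set()] data frame (or an
#'   equivalent list).
#' @param seed integer seed controlling all jitter draws; identical seeds
#'   give identical images.
#' @param canvas_size square canvas side in pixels, at least 32.
#' @param with_label_strip draw a text-like label strip under the specimen.
#' @return list with elements `image` (array `canvas x canvas x 3`) and
#'   `box` (the specimen [bbox()]).
#' @export
render_specimen <- function(spec, seed, canvas_size = 64,
                            with_label_strip = TRUE) {
  if (canvas_size < 32) stop_invalid_argument("canvas_size must be >= 32")
  k <- syn_constants
  S <- canvas_size
  with_seed(seed, {
    theta <- runif(1, -k$rotation_jitter_deg, k$rotation_jitter_deg) * pi / 180
    scale_jit <- runif(1, 1 - k$scale_jitter, 1 + k$scale_jitter)
    hue <- (spec$body_hue + runif(1, -k$hue_jitter_deg, k$hue_jitter_deg)) %% 360
    # wing-pattern layout is species-characteristic (anatomically fixed),
    # so the stripe phase is a deterministic function of the species
    # parameters with only a small per-specimen wobble
    phase <- 2 * pi * ((spec$body_hue * 13 + spec$stripe_frequency * 101) %% 360) / 360 +
      runif(1, -0.2, 0.2)

    strip_h <- max(3L, as.integer(round(k$strip_height_frac * S)))
    strip_top <- S - strip_h - 1L  # 0-based row where the strip starts

    s_len <- spec$nominal_scale * S * scale_jit
    w_half <- min(s_len / 2 * sqrt(spec$wing_aspect), 0.49 * S)
    h_half <- min(s_len / 2 / sqrt(spec$wing_aspect), strip_top / 2 - 2)
    cx <- 0.5 * S
    cy <- if (with_label_strip) strip_top / 2 else 0.5 * S

    # pixel-centre coordinates rotated into the specimen frame
    xs <- matrix(rep(seq_len(S) - 0.5 - cx, each = S), nrow = S)
    ys <- matrix(rep(seq_len(S) - 0.5 - cy, times = S), nrow = S)
    u <- xs * cos(theta) + ys * sin(theta)
    v <- -xs * sin(theta) + ys * cos(theta)

    in_ellipse <- function(ucen, vcen, ua, va) {
      ((u - ucen) / ua)^2 + ((v - vcen) / va)^2 <= 1
    }
    wings <-
      in_ellipse(-0.52 * w_half, -0.35 * h_half, 0.48 * w_half, 0.62 * h_half) |
      in_ellipse(0.52 * w_half, -0.35 * h_half, 0.48 * w_half, 0.62 * h_half) |
      in_ellipse(-0.38 * w_half, 0.45 * h_half, 0.34 * w_half, 0.55 * h_half) |
      in_ellipse(0.38 * w_half, 0.45 * h_half, 0.34 * w_half, 0.55 * h_half)
    body <- in_ellipse(0, 0, 0.10 * w_half, 0.80 * h_half)
    fg <- wings | body

    img <- array(rep(k$background, each = S * S), dim = c(S, S, 3))
    idx <- which(fg)
    if (length(idx) > 0) {
      stripe <- sin(2 * pi * spec$stripe_frequency * (xs[idx] + cx) / S + phase)
      val <- 0.50 + 0.28 * stripe
      sat <- rep(0.78, length(idx))
      body_idx <- body[idx]
      val[body_idx] <- val[body_idx] * 0.45
      sat[body_idx] <- 0.9
      rgb <- hsv_to_rgb(rep(hue, length(idx)), sat, val)
      n_px <- S * S
      img[idx] <- rgb[, 1]
      img[idx + n_px] <- rgb[, 2]
      img[idx + 2 * n_px] <- rgb[, 3]
    }

    if (with_label_strip) {
      x0 <- as.integer(round(k$strip_width_frac[1] * S))
      x1 <- as.integer(round(k$strip_width_frac[2] * S))
      rows <- (strip_top + 1):(strip_top + strip_h)
      cols <- (x0 + 1):x1
      img[rows, cols, ] <- 0.97
      # two dashed "text" lines of random ink
      for (line in 1:2) {
        r <- strip_top + 1 + line * max(1L, strip_h %/% 3)
        dash <- runif(length(cols)) < 0.45
        if (any(dash)) img[r, cols[dash], ] <- 0.15
      }
    }

    list(image = img, box = mask_bbox(fg))
  })
}

#' Generate a synthetic specimen dataset with injected mislabels
#'
#' Renders `n_per_species` images per species, writes them as PNG files
#' with a catalog CSV, and reassigns `round(mislabel_rate * total)` catalog
#' labels to a different species. A mislabelled specimen keeps its true
#' appearance; only its catalog label is swapped, preferring the confusable
#' partner (probability `syn_constants$confusable_partner_prob`) when one
#' exists, emulating realistic confusions between lookalike species.
#'
#' @param specs data frame from [make_species_set()].
#' @param n_per_species images per species, at least 1.
#' @param mislabel_rate fraction of specimens whose catalog label is
#'   swapped, in `[0, 1)`.
#' @param seed integer seed; output files are byte-identical for identical
#'   seeds.
#' @param out_dir output directory (created if needed); images go to
#'   `out_dir/images/`, the catalog to `out_dir/catalog.csv` and the ground
#'   truth to `out_dir/ground_truth.json`.
#' @param canvas_size canvas side in pixels.
#' @param with_label_strip draw label strips (see [render_specimen()]).
#' @return invisibly, a list with `catalog_path`, `ground_truth_path`,
#'   `ground_truth` (data frame: `specimen_id`, `true_label`,
#'   `assigned_label`, `injected`) and `specs`.
#' @export
generate_dataset <- function(specs, n_per_species, mislabel_rate, seed,
                             out_dir, canvas_size = 64,
                             with_label_strip = TRUE) {
  if (n_per_species < 1) stop_invalid_argument("n_per_species must be >= 1")
  if (mislabel_rate < 0 || mislabel_rate >= 1) {
    stop_invalid_argument("mislabel_rate must be in [0, 1)")
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  n_total <- nrow(specs) * n_per_species
  ids <- sprintf("SYN%05d", seq_len(n_total))
  true_label <- rep(specs$species_name, each = n_per_species)

  for (i in seq_len(n_total)) {
    sp <- specs[specs$species_name == true_label[i], ]
    rendered <- render_specimen(sp, seed = derive_seed(seed, i),
                                canvas_size = canvas_size,
                                with_label_strip = with_label_strip)
    write_image(rendered$image,
                file.path(out_dir, "images", paste0(ids[i], ".png")))
  }

  n_inject <- as.integer(round_half_up(mislabel_rate * n_total))
  assigned <- true_label
  injected <- rep(FALSE, n_total)
  if (n_inject > 0) {
    with_seed(derive_seed(seed, 909091), {
      pick <- sample(n_total, n_inject)
      for (i in pick) {
        sp <- specs[specs$species_name == true_label[i], ]
        partner <- sp$confusable_with
        others <- setdiff(specs$species_name, true_label[i])
        assigned[i] <-
          if (!is.na(partner) &&
              runif(1) < syn_constants$confusable_partner_prob) {
            partner
          } else {
            others[sample.int(length(others), 1)]
          }
      }
      injected[pick] <- TRUE
    })
  }

  catalog <- data.frame(
    specimen_id = ids,
    current_label = assigned,
    image_path = file.path("images", paste0(ids, ".png")),
    group = "synthetic",
    stringsAsFactors = FALSE
  )
  catalog_path <- file.path(out_dir, "catalog.csv")
  write.csv(catalog, catalog_path, row.names = FALSE, quote = FALSE)

  gt <- data.frame(specimen_id = ids, true_label = true_label,
                   assigned_label = assigned, injected = injected,
                   stringsAsFactors = FALSE)
  gt_path <- file.path(out_dir, "ground_truth.json")
  gt_list <- lapply(seq_len(n_total), function(i) {
    list(true_label = true_label[i], assigned_label = assigned[i])
  })
  names(gt_list) <- ids
  jsonlite::write_json(gt_list, gt_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(catalog_path = catalog_path, ground_truth_path = gt_path,
                 ground_truth = gt, specs = specs))
}

#' Read a ground-truth JSON file back into a data frame
#'
#' @param path path to a `ground_truth.json` written by
#'   [generate_dataset()].
#' @return data frame with `specimen_id`, `true_label`, `assigned_label`,
#'   `injected`.
#' @export
load_ground_truth <- function(path) {
  x <- jsonlite::read_json(path)
  data.frame(
    specimen_id = names(x),
    true_label = vapply(x, function(e) e$true_label, character(1)),
    assigned_label = vapply(x, function(e) e$assigned_label, character(1)),
    injected = vapply(x, function(e) e$true_label != e$assigned_label,
                      logical(1)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
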