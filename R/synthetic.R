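#' Morphology parameters for the synthetic generator
#'
#' Per-class geometry of the planted cells. The numbers are generator
#' defaults chosen for realism and class separability, not measured values:
#' what *is* anchored in cell-death morphology is their qualitative
#' structure — apoptotic cells are shrunken, blebbed and optically taller
#' (chromatin condensation raises refractive index); necroptotic cells are
#' swollen smooth domes that are optically flatter (membrane pores lower
#' the contrast with the medium); alive cells are spread, irregular and of
#' intermediate height. `height_scale` encodes that ordering and is
#' validated: apoptosis above alive, necroptosis below.
#'
#' @param alive,apoptosis,necroptosis Per-class parameter lists with fields
#'   `body_radius_px` (range), `peak_height_um` (range), `profile`
#'   (`"spread"` or `"dome"`), `height_scale`, and for apoptosis `n_blebs`
#'   (range) and `bleb_radius_px` (range). `boundary_irregularity` sets the
#'   amplitude of the angular radius modulation of spread cells.
#'
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(
    alive = list(
      body_radius_px = c(8, 10), peak_height_um = c(2.5, 4),
      profile = "spread", height_scale = 1.0, boundary_irregularity = 0.25
    ),
    apoptosis = list(
      body_radius_px = c(6, 8), peak_height_um = c(2.5, 4),
      profile = "dome", height_scale = 1.6,
      n_blebs = c(3, 6), bleb_radius_px = c(2, 3)
    ),
    necroptosis = list(
      body_radius_px = c(11.5, 13), peak_height_um = c(2.5, 4),
      profile = "dome", height_scale = 0.55
    )) {
  morph <- list(alive = alive, apoptosis = apoptosis,
                necroptosis = necroptosis)
  for (cls in CONDITIONS) {
    p <- morph[[cls]]
    check_that(all(p$body_radius_px > 0) && all(p$peak_height_um > 0),
               sprintf("%s: radii and heights must be positive.", cls))
    check_that(p$height_scale > 0,
               sprintf("%s: height_scale must be positive.", cls))
  }
  check_that(
    apoptosis$height_scale > alive$height_scale,
    "Apoptotic optical height must exceed alive height (chromatin condensation)."
  )
  check_that(
    necroptosis$height_scale < alive$height_scale,
    "Necroptotic optical height must be below alive height (membrane pore formation)."
  )
  structure(morph, class = "morphology_params")
}

#' Scene specification for a synthetic capture
#'
#' @param image_shape Capture dimensions `(rows, cols)` in pixels.
#' @param n_cells Number of cells to place.
#' @param class_mix Named fractions over `alive`/`apoptosis`/`necroptosis`;
#'   must sum to 1. Counts per class follow largest-remainder rounding, so
#'   integer-divisible mixes are hit exactly.
#' @param noise_sd_rad Standard deviation of the additive Gaussian
#'   background phase noise, radians.
#' @param min_separation_px Minimum distance between cell centres.
#' @param seed Integer seed; the capture is a pure function of the spec.
#' @param condition Condition label recorded on the capture; defaults to
#'   the class with the largest mix fraction. Captures emulate one-inducer
#'   experiments, so an apoptosis-condition capture may legitimately
#'   contain alive cells (that impurity is what the SAD filter removes).
#' @param time_post_induction_min Optional time metadata.
#'
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(384L, 384L),
                       n_cells = 25L,
                       class_mix = c(alive = 1, apoptosis = 0, necroptosis = 0),
                       noise_sd_rad = 0.05,
                       min_separation_px = 40,
                       seed = 1L,
                       condition = NULL,
                       time_post_induction_min = NULL) {
  check_that(length(image_shape) == 2L && all(image_shape >= 66),
             "`image_shape` must be two dimensions of at least 66 px.")
  check_that(is_count(n_cells) && n_cells >= 0,
             "`n_cells` must be a non-negative whole number.")
  check_that(
    all(CONDITIONS %in% names(class_mix)) &&
      abs(sum(class_mix) - 1) < 1e-8 && all(class_mix >= 0),
    "`class_mix` must be named fractions over the three classes summing to 1."
  )
  check_that(noise_sd_rad >= 0, "`noise_sd_rad` must be non-negative.")
  if (is.null(condition)) {
    condition <- CONDITIONS[which.max(class_mix[CONDITIONS])]
  }
  check_condition(condition)
  structure(
    list(
      image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
      class_mix = class_mix[CONDITIONS], noise_sd_rad = noise_sd_rad,
      min_separation_px = min_separation_px, seed = as.integer(seed),
      condition = condition,
      time_post_induction_min = time_post_induction_min
    ),
    class = "scene_spec"
  )
}

# Largest-remainder apportionment of n cells over the class mix; exact for
# integer-divisible mixes.
mix_counts <- function(n, class_mix) {
  raw <- n * class_mix
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(class_mix))
}

#' Generate one synthetic cell as a height patch
#'
#' Draws the class geometry from `morph` using the current RNG stream and
#' renders a small optical-height patch: alive cells are spread,
#' irregular-boundary plateaus; apoptotic cells are shrunken domes studded
#' with `n_blebs` small high-curvature blebs and scaled up in height;
#' necroptotic cells are large smooth domes scaled down. The returned mask
#' is the ground-truth footprint used for area accounting.
#'
#' @param class One of `"alive"`, `"apoptosis"`, `"necroptosis"`.
#' @param morph A [morphology_params()].
#'
#' @return List with `height` (numeric matrix, micrometres), `mask`
#'   (logical footprint), `area_px` (footprint pixel count) and `class`.
#' @export
generate_cell_height <- function(class, morph = morphology_params()) {
  check_condition(class)
  p <- morph[[class]]
  radius <- stats::runif(1, p$body_radius_px[1], p$body_radius_px[2])
  peak <- stats::runif(1, p$peak_height_um[1], p$peak_height_um[2]) *
    p$height_scale

  pad <- if (identical(class, "apoptosis")) max(p$bleb_radius_px) + 2 else 3
  half <- ceiling(radius * 1.3 + pad)
  side <- 2L * half + 1L
  ctr <- half + 1
  rr <- matrix(seq_len(side), side, side) - ctr
  cc <- t(rr)
  d <- sqrt(rr^2 + cc^2)

  if (identical(p$profile, "spread")) {
    # irregular boundary: low-order angular modulation of the radius
    irr <- p$boundary_irregularity
    theta <- atan2(cc, rr)
    amp <- stats::runif(3, 0.3, 1)
    ph <- stats::runif(3, 0, 2 * pi)
    mod <- 1 + irr * (amp[1] * cos(2 * theta + ph[1]) +
                        amp[2] * cos(3 * theta + ph[2]) +
                        amp[3] * cos(5 * theta + ph[3])) / sum(amp)
    reff <- radius * mod
    height <- peak * exp(-(d / reff)^6) # flat-topped spread profile
    mask <- d <= reff
  } else {
    height <- peak * pmax(1 - (d / radius)^2, 0) # parabolic dome
    mask <- d <= radius
  }

  if (identical(class, "apoptosis")) {
    n_blebs <- sample(seq(p$n_blebs[1], p$n_blebs[2]), 1)
    if (n_blebs > 0) {
      for (b in seq_len(n_blebs)) {
        ang <- stats::runif(1, 0, 2 * pi)
        dist <- radius * stats::runif(1, 0.75, 1.05)
        br <- stats::runif(1, p$bleb_radius_px[1], p$bleb_radius_px[2])
        bh <- peak * stats::runif(1, 0.45, 0.75)
        db <- sqrt((rr - dist * cos(ang))^2 + (cc - dist * sin(ang))^2)
        height <- height + bh * exp(-(db / br)^2)
        mask <- mask | db <= br
      }
    }
  }
  height[!mask & height < 0.02 * peak] <- 0
  list(height = height, mask = mask, area_px = sum(mask), class = class)
}

#' Generate a synthetic full field-of-view capture
#'
#' Places `n_cells` synthetic cells (classes apportioned by `class_mix`)
#' at rejection-sampled positions at least `min_separation_px` apart,
#' renders their optical heights, converts to phase via the phase/height
#' relation and adds Gaussian background phase noise. The capture is a
#' deterministic function of the spec (seeded); annotations record exact
#' ground truth.
#'
#' @param spec A [scene_spec()].
#' @param morph A [morphology_params()].
#' @param optics An [optical_params()].
#'
#' @return List with `capture` (a [phase_capture()]) and `annotations`
#'   (tibble `row`, `col`, `class`, `area_px`).
#' @export
generate_capture <- function(spec, morph = morphology_params(),
                             optics = optical_params()) {
  check_that(inherits(spec, "scene_spec"), "`spec` must be a `scene_spec`.")
  with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    counts <- mix_counts(spec$n_cells, spec$class_mix)
    classes <- sample(rep(names(counts), counts))
    margin <- 36 # keeps most crop boxes inside the border
    centers <- matrix(numeric(0), 0, 2)
    for (i in seq_along(classes)) {
      placed <- FALSE
      for (try in seq_len(5000L)) {
        r <- stats::runif(1, margin, nr - margin)
        c <- stats::runif(1, margin, nc - margin)
        if (nrow(centers) == 0L ||
            min(sqrt((centers[, 1] - r)^2 + (centers[, 2] - c)^2)) >=
            spec$min_separation_px) {
          centers <- rbind(centers, c(r, c))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        rlang::abort(sprintf(
          "Could not place %d cells with min_separation_px = %g in a %d x %d field.",
          spec$n_cells, spec$min_separation_px, nr, nc
        ), class = "phasedeath_placement_error")
      }
    }
    height <- matrix(0, nr, nc)
    ann <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      cell <- generate_cell_height(classes[i], morph)
      half <- (nrow(cell$height) - 1L) %/% 2L
      r <- round(centers[i, 1]); c <- round(centers[i, 2])
      rs <- (r - half):(r + half); cs <- (c - half):(c + half)
      ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
      height[rs[ok_r], cs[ok_c]] <- height[rs[ok_r], cs[ok_c]] +
        cell$height[ok_r, ok_c]
      ann[[i]] <- tibble::tibble(
        row = r, col = c, class = classes[i], area_px = cell$area_px
      )
    }
    phase <- height_to_phase(height, optics)
    if (spec$noise_sd_rad > 0) {
      phase <- phase + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd_rad),
                              nr, nc)
    }
    list(
      capture = phase_capture(
        phase, spec$condition,
        capture_id = sprintf("syn_%s_s%d", spec$condition, spec$seed),
        optics = optics,
        time_post_induction_min = spec$time_post_induction_min
      ),
      annotations = dplyr::bind_rows(ann)
    )
  })
}

#' Generate a balanced labeled crop dataset
#'
#' Renders `n_per_class` single-cell crops per class directly on
#' `crop_size` canvases (cell centred with a small jitter, Gaussian phase
#' noise added), bypassing capture-level segmentation. Ground truth
#' (`true_class`, footprint area) is exact; areas falling outside the
#' strict (80, 600) px segmentation window trigger a warning reporting the
#' offending fraction.
#'
#' @param n_per_class Crops per class.
#' @param morph A [morphology_params()].
#' @param optics An [optical_params()].
#' @param seed Integer seed.
#' @param noise_sd_rad Gaussian phase noise standard deviation, radians.
#' @param crop_size Canvas side in pixels.
#' @param id_prefix Prefix for generated crop/capture ids.
#'
#' @return A crop tibble with the same columns as [crop_cells()] output,
#'   `condition` and `true_class` both set to the planted class.
#' @export
generate_labeled_dataset <- function(n_per_class,
                                     morph = morphology_params(),
                                     optics = optical_params(),
                                     seed = 1L,
                                     noise_sd_rad = 0.05,
                                     crop_size = 66L,
                                     id_prefix = "syn") {
  check_that(is_count(n_per_class) && n_per_class >= 1,
             "`n_per_class` must be a positive whole number.")
  with_seed(seed, {
    ctr <- (crop_size %/% 2L) + 1L
    rows <- vector("list", 3L * n_per_class)
    k <- 0L
    for (cls in CONDITIONS) {
      for (i in seq_len(n_per_class)) {
        cell <- generate_cell_height(cls, morph)
        canvas <- matrix(0, crop_size, crop_size)
        half <- (nrow(cell$height) - 1L) %/% 2L
        jr <- ctr + sample(-3:3, 1); jc <- ctr + sample(-3:3, 1)
        rs <- (jr - half):(jr + half); cs <- (jc - half):(jc + half)
        ok_r <- rs >= 1 & rs <= crop_size; ok_c <- cs >= 1 & cs <= crop_size
        canvas[rs[ok_r], cs[ok_c]] <- cell$height[ok_r, ok_c]
        phase <- height_to_phase(canvas, optics) +
          matrix(stats::rnorm(crop_size^2, 0, noise_sd_rad),
                 crop_size, crop_size)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          crop_id = sprintf("%s_%s_%04d", id_prefix, cls, i),
          capture_id = sprintf("%s_%s_%04d", id_prefix, cls, i),
          condition = cls,
          row = jr, col = jc,
          area_px = cell$area_px,
          time_post_induction_min = NA_real_,
          true_class = cls,
          pixels = list(phase)
        )
      }
    }
    crops <- dplyr::bind_rows(rows)
    out_of_filter <- crops$area_px <= 80 | crops$area_px >= 600
    if (any(out_of_filter)) {
      rlang::warn(sprintf(
        "%.1f%% of generated crops have footprint areas outside the strict (80, 600) px segmentation window.",
        100 * mean(out_of_filter)
      ))
      attr(crops, "rejected_fraction") <- mean(out_of_filter)
    }
    crops
  })
}
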