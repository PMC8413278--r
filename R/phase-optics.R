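#' Optical parameters of a holographic acquisition
#'
#' Bundles the three quantities that relate phase delay to optical height:
#' the illumination wavelength \eqn{\lambda} and the refractive indices of
#' the cell interior (\eqn{\eta_i}) and of the culture medium
#' (\eqn{\eta_{media}}). The defaults (532 nm green illumination,
#' \eqn{\eta_{media} = 1.333} for aqueous medium, \eqn{\eta_i = 1.380} for
#' cytoplasm) are conventional values for live-cell quantitative phase
#' imaging; none of them is measured by this package and all can be
#' overridden per capture.
#'
#' @param wavelength_um Illumination wavelength in micrometres. Must be
#'   positive.
#' @param eta_cell Mean refractive index of the cell (dimensionless).
#' @param eta_media Refractive index of the medium (dimensionless). Must
#'   differ from `eta_cell`: the phase/height conversion is undefined when
#'   the refractive-index contrast vanishes.
#'
#' @return An object of class `optical_params`.
#' @examples
#' optical_params()
#' optical_params(wavelength_um = 0.633)
#' @export
optical_params <- function(wavelength_um = 0.532,
                           eta_cell = 1.380,
                           eta_media = 1.333) {
  check_that(
    is.numeric(wavelength_um) && length(wavelength_um) == 1L &&
      is.finite(wavelength_um) && wavelength_um > 0,
    "`wavelength_um` must be a single positive number."
  )
  check_that(
    is.numeric(eta_cell) && length(eta_cell) == 1L && is.finite(eta_cell),
    "`eta_cell` must be a single finite number."
  )
  check_that(
    is.numeric(eta_media) && length(eta_media) == 1L && is.finite(eta_media),
    "`eta_media` must be a single finite number."
  )
  check_that(
    eta_cell != eta_media,
    "`eta_cell` must differ from `eta_media`: zero refractive-index contrast makes the phase/height conversion degenerate.",
    class = "phasedeath_degenerate_optics"
  )
  structure(
    list(
      wavelength_um = wavelength_um,
      eta_cell = eta_cell,
      eta_media = eta_media
    ),
    class = "optical_params"
  )
}

#' @export
print.optical_params <- function(x, ...) {
  cat(sprintf(
    "<optical_params> lambda = %.4g um, eta_cell = %.4g, eta_media = %.4g (contrast %.4g)\n",
    x$wavelength_um, x$eta_cell, x$eta_media, x$eta_cell - x$eta_media
  ))
  invisible(x)
}

#' A full field-of-view quantitative phase capture
#'
#' A capture is one quantitative phase image (per-pixel phase delay
#' \eqn{\Delta\varphi} in radians) acquired under a single experimental
#' condition, together with its acquisition metadata. One condition per
#' capture is enforced: captures are the unit of train/holdout separation.
#'
#' @param phase Numeric matrix of phase delays in radians. All values must
#'   be finite and both dimensions at least `min_dim` so that fixed-size
#'   single-cell crops fit inside the field of view.
#' @param condition Experimental condition, one of `"alive"`,
#'   `"apoptosis"`, `"necroptosis"`.
#' @param capture_id Character identifier, unique per acquisition.
#' @param optics An [optical_params()] object.
#' @param time_post_induction_min Optional time since cell-death induction,
#'   in minutes.
#' @param min_dim Minimum allowed dimension; defaults to the 66-pixel crop
#'   box used downstream.
#'
#' @return An object of class `phase_capture`.
#' @examples
#' cap <- phase_capture(matrix(0, 80, 80), "alive", "demo")
#' dim(cap$phase)
#' @export
phase_capture <- function(phase, condition, capture_id,
                          optics = optical_params(),
                          time_post_induction_min = NULL,
                          min_dim = 66L) {
  check_that(is.matrix(phase) && is.numeric(phase),
             "`phase` must be a numeric matrix.")
  check_that(all(is.finite(phase)),
             "`phase` must contain only finite values.")
  check_that(
    nrow(phase) >= min_dim && ncol(phase) >= min_dim,
    sprintf(
      "`phase` must be at least %d x %d pixels so that %d-pixel crops fit; got %d x %d.",
      min_dim, min_dim, min_dim, nrow(phase), ncol(phase)
    )
  )
  check_condition(condition)
  check_that(length(condition) == 1L, "`condition` must be a single value.")
  check_that(
    is.character(capture_id) && length(capture_id) == 1L &&
      nzchar(capture_id),
    "`capture_id` must be a non-empty string."
  )
  check_that(inherits(optics, "optical_params"),
             "`optics` must be an `optical_params` object.")
  if (!is.null(time_post_induction_min)) {
    check_that(
      is.numeric(time_post_induction_min) &&
        length(time_post_induction_min) == 1L &&
        is.finite(time_post_induction_min),
      "`time_post_induction_min` must be a single finite number or NULL."
    )
  }
  structure(
    list(
      phase = phase,
      condition = condition,
      capture_id = capture_id,
      optics = optics,
      time_post_induction_min = time_post_induction_min
    ),
    class = "phase_capture"
  )
}

#' @export
print.phase_capture <- function(x, ...) {
  cat(sprintf(
    "<phase_capture> '%s': %d x %d px, condition = %s, phase range [%.3g, %.3g] rad\n",
    x$capture_id, nrow(x$phase), ncol(x$phase), x$condition,
    min(x$phase), max(x$phase)
  ))
  invisible(x)
}

#' Convert phase delay to optical height
#'
#' The phase delay accumulated by light crossing a transparent specimen is
#' \deqn{\Delta\varphi = \frac{2\pi}{\lambda}(\eta_i - \eta_{media})\,h,}
#' so the apparent ("optical") height follows by rearrangement as
#' \deqn{h = \frac{\Delta\varphi\,\lambda}{2\pi\,(\eta_i - \eta_{media})}.}
#' Optical height conflates physical thickness with refractive-index
#' contrast: chromatin condensation in apoptosis raises it, membrane pore
#' formation in necroptosis lowers it, which is exactly the morphology
#' signal the classifier exploits.
#'
#' @param phase A [phase_capture()] (its optics are used) or a numeric
#'   matrix of phase delays in radians (then `optics` is required).
#' @param optics An [optical_params()] object; ignored when `phase` is a
#'   `phase_capture`.
#'
#' @return Numeric matrix of optical heights in micrometres, same shape as
#'   the input phase grid.
#' @seealso [height_to_phase()] for the exact inverse.
#' @examples
#' h <- phase_to_height(matrix(2 * pi, 3, 3),
#'                      optical_params(0.532, 1.383, 1.333))
#' h[1, 1] # 0.532 / 0.05 = 10.64 um
#' @export
phase_to_height <- function(phase, optics = NULL) {
  if (inherits(phase, "phase_capture")) {
    optics <- phase$optics
    phase <- phase$phase
  }
  check_that(inherits(optics, "optical_params"),
             "`optics` must be an `optical_params` object (or pass a `phase_capture`).")
  check_that(is.numeric(phase), "`phase` must be numeric.")
  check_that(all(is.finite(phase)), "`phase` must be finite.")
  phase * optics$wavelength_um /
    (2 * pi * (optics$eta_cell - optics$eta_media))
}

#' Convert optical height to phase delay
#'
#' Forward form of the phase/height relation,
#' \eqn{\Delta\varphi = (2\pi/\lambda)(\eta_i - \eta_{media})\,h}. Used by
#' the synthetic generator to turn planted height morphologies into phase
#' images; exact inverse of [phase_to_height()].
#'
#' @param height_um Numeric matrix of heights in micrometres.
#' @param optics An [optical_params()] object.
#'
#' @return Numeric matrix of phase delays in radians, same shape.
#' @export
height_to_phase <- function(height_um, optics = optical_params()) {
  check_that(inherits(optics, "optical_params"),
             "`optics` must be an `optical_params` object.")
  check_that(is.numeric(height_um), "`height_um` must be numeric.")
  check_that(all(is.finite(height_um)), "`height_um` must be finite.")
  height_um * 2 * pi * (optics$eta_cell - optics$eta_media) /
    optics$wavelength_um
}

#' Write a phase capture to disk
#'
#' Writes a single-channel 32-bit float TIFF plus a JSON metadata sidecar
#' (same path with extension `.json`). Because the TIFF writer stores
#' samples on a \[0, 1\] scale, the phase grid is min-max normalised before
#' writing and the affine range (`phase_min`, `phase_range`) is recorded in
#' the sidecar; [read_capture()] undoes the mapping, so the round trip is
#' lossless at 32-bit float precision.
#'
#' @param capture A [phase_capture()].
#' @param path Output TIFF path (`.tif`/`.tiff`).
#'
#' @return `path`, invisibly.
#' @export
write_capture <- function(capture, path) {
  check_that(inherits(capture, "phase_capture"),
             "`capture` must be a `phase_capture`.")
  check_that(grepl("\\.tiff?$", path, ignore.case = TRUE),
             "`path` must end in .tif or .tiff.")
  phase <- capture$phase
  lo <- min(phase)
  rng <- max(phase) - lo
  norm <- if (rng > 0) (phase - lo) / rng else array(0, dim(phase))
  suppressWarnings(tiff::writeTIFF(norm, path, bits.per.sample = 32L))
  meta <- list(
    format_version = 1L,
    capture_id = capture$capture_id,
    condition = capture$condition,
    wavelength_um = capture$optics$wavelength_um,
    eta_cell = capture$optics$eta_cell,
    eta_media = capture$optics$eta_media,
    time_post_induction_min = capture$time_post_induction_min,
    phase_min = lo,
    phase_range = rng
  )
  jsonlite::write_json(meta, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a phase capture from disk
#'
#' Counterpart of [write_capture()]: reads the float TIFF and its JSON
#' sidecar and rebuilds the [phase_capture()]. The image must be single
#' channel and at least 66 x 66 pixels; the sidecar must carry a known
#' condition and valid optics.
#'
#' @param path Path to the capture TIFF.
#'
#' @return A [phase_capture()].
#' @export
read_capture <- function(path) {
  check_that(file.exists(path), sprintf("No such file: '%s'.", path))
  side <- sidecar_path(path)
  check_that(file.exists(side),
             sprintf("Missing metadata sidecar '%s'.", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (field in c("capture_id", "condition", "wavelength_um", "eta_cell",
                  "eta_media", "phase_min", "phase_range")) {
    check_that(!is.null(meta[[field]]),
               sprintf("Sidecar is missing required field '%s'.", field))
  }
  img <- tiff::readTIFF(path)
  check_that(
    length(dim(img)) == 2L,
    sprintf("Capture TIFF must be single-channel; got %s.",
            paste(dim(img), collapse = " x ")),
    class = "phasedeath_format_error"
  )
  phase <- img * meta$phase_range + meta$phase_min
  tpi <- meta$time_post_induction_min
  if (!is.null(tpi) && (length(tpi) == 0L || is.na(tpi))) tpi <- NULL
  phase_capture(
    phase = phase,
    condition = meta$condition,
    capture_id = meta$capture_id,
    optics = optical_params(
      wavelength_um = meta$wavelength_um,
      eta_cell = meta$eta_cell,
      eta_media = meta$eta_media
    ),
    time_post_induction_min = tpi
  )
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
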