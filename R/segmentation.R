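#' Segmentation parameters
#'
#' Controls cell localisation and cropping: the fixed crop box (66 px), the
#' strict connected-component area window (more than 80 and fewer than
#' 600 above-threshold pixels), the threshold rule and the pixel
#' connectivity.
#'
#' @param crop_size_px Side of the square crop box, in pixels.
#' @param area_min_px Exclusive lower area bound: components must have
#'   *more* than this many pixels.
#' @param area_max_px Exclusive upper area bound: components must have
#'   *fewer* than this many pixels.
#' @param threshold_method `"otsu"` (parameter-free, computed per capture on
#'   the phase image) or `"fixed"`.
#' @param fixed_threshold Phase threshold in radians, required when
#'   `threshold_method = "fixed"`.
#' @param connectivity Pixel neighbourhood for connected components: 8
#'   (default, diagonals connect) or 4.
#'
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(crop_size_px = 66L,
                                area_min_px = 80,
                                area_max_px = 600,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                connectivity = 8L) {
  threshold_method <- match.arg(threshold_method)
  check_that(is_count(crop_size_px) && crop_size_px >= 1,
             "`crop_size_px` must be a positive whole number.")
  check_that(
    is.numeric(area_min_px) && is.numeric(area_max_px) &&
      area_min_px >= 0 && area_min_px < area_max_px,
    "Need 0 <= area_min_px < area_max_px."
  )
  check_that(connectivity %in% c(4L, 8L),
             "`connectivity` must be 4 or 8.")
  if (threshold_method == "fixed") {
    check_that(
      is.numeric(fixed_threshold) && length(fixed_threshold) == 1L &&
        is.finite(fixed_threshold),
      "`fixed_threshold` must be a single finite number when threshold_method = 'fixed'."
    )
  }
  structure(
    list(
      crop_size_px = as.integer(crop_size_px),
      area_min_px = area_min_px,
      area_max_px = area_max_px,
      threshold_method = threshold_method,
      fixed_threshold = fixed_threshold,
      connectivity = as.integer(connectivity)
    ),
    class = "segmentation_params"
  )
}

# Threshold rule shared by detect_cells() and the manifest writer.
segmentation_threshold <- function(phase, params) {
  if (params$threshold_method == "fixed") return(params$fixed_threshold)
  rng <- range(phase)
  if (diff(rng) == 0) return(Inf) # flat image: nothing above threshold
  EBImage::otsu(EBImage::Image(phase), range = rng, levels = 256L)
}

# 8-connectivity labelling: EBImage::bwlabel() is 4-connectivity, so labels
# touching only diagonally are merged with a small union-find pass.
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]   # down-right diagonal pairs
    a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]  # up-right diagonal pairs
    pa <- c(a1, a2); pb <- c(b1, b2)
    sel <- pa > 0L & pb > 0L & pa != pb
    if (any(sel)) {
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      pairs <- unique(cbind(pa[sel], pb[sel]))
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      compact <- match(root, sort(unique(root)))
      lab[lab > 0L] <- compact[lab[lab > 0L]]
    }
  }
  lab
}

#' Detect cells in a capture by thresholding
#'
#' Thresholds the phase image (Otsu by default) and returns one detection
#' per connected component of the above-threshold mask, with no area or
#' border filtering at this stage — that is [crop_cells()]'s job. Centroids
#' are the rounded pixel-coordinate means of each component, 1-based.
#'
#' @param capture A [phase_capture()].
#' @param params A [segmentation_params()].
#'
#' @return A tibble with one row per component: `label_id`, `row`, `col`
#'   (rounded centroid), `area_px`. Zero rows when nothing is above
#'   threshold.
#' @export
detect_cells <- function(capture, params = segmentation_params()) {
  check_that(inherits(capture, "phase_capture"),
             "`capture` must be a `phase_capture`.")
  check_that(inherits(params, "segmentation_params"),
             "`params` must be a `segmentation_params`.")
  thr <- segmentation_threshold(capture$phase, params)
  mask <- capture$phase > thr
  if (!any(mask)) {
    return(tibble::tibble(
      label_id = integer(), row = integer(), col = integer(),
      area_px = integer()
    ))
  }
  lab <- label_components(mask, params$connectivity)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  tibble::tibble(
    label_id = sort(unique(labs)),
    row = as.integer(round(tapply(rows, labs, mean))),
    col = as.integer(round(tapply(cols, labs, mean))),
    area_px = as.integer(tapply(labs, labs, length))
  )
}

#' Crop fixed-size single-cell patches around detections
#'
#' For each detection whose component area lies strictly inside
#' `(area_min_px, area_max_px)` and whose crop box fits entirely inside the
#' capture, emits one crop of `crop_size_px` x `crop_size_px` phase pixels.
#' The box around centroid `(r, c)` spans rows `(r - s/2) .. (r + s/2 - 1)`
#' for even side `s` (i.e. half-open centring), so a centroid closer than
#' `s/2 + 1` pixels to the top/left or `s/2` to the bottom/right is
#' discarded as a border crossing. Every discarded detection is logged with
#' its reason in the `"discards"` attribute.
#'
#' @param capture A [phase_capture()].
#' @param detections Tibble from [detect_cells()] on the same capture.
#' @param params A [segmentation_params()].
#'
#' @return A tibble of kept crops: `crop_id`, `capture_id`, `condition`,
#'   `row`, `col`, `area_px`, `time_post_induction_min`, `true_class`
#'   (`NA` unless synthetic ground truth is attached later) and `pixels`, a
#'   list-column of numeric matrices. The attribute `"discards"` is a
#'   tibble `label_id`, `row`, `col`, `area_px`, `reason` with reasons
#'   `"area_small"`, `"area_large"` or `"border"`.
#' @export
crop_cells <- function(capture, detections, params = segmentation_params()) {
  check_that(inherits(capture, "phase_capture"),
             "`capture` must be a `phase_capture`.")
  check_that(
    is.data.frame(detections) &&
      all(c("label_id", "row", "col", "area_px") %in% names(detections)),
    "`detections` must be a tibble from detect_cells()."
  )
  s <- params$crop_size_px
  half_lo <- s %/% 2L                 # pixels before the centroid row/col
  half_hi <- s - half_lo - 1L         # pixels after it
  nr <- nrow(capture$phase); nc <- ncol(capture$phase)

  reason <- rep(NA_character_, nrow(detections))
  reason[detections$area_px <= params$area_min_px] <- "area_small"
  reason[is.na(reason) &
           detections$area_px >= params$area_max_px] <- "area_large"
  r0 <- detections$row - half_lo; r1 <- detections$row + half_hi
  c0 <- detections$col - half_lo; c1 <- detections$col + half_hi
  reason[is.na(reason) & (r0 < 1L | c0 < 1L | r1 > nr | c1 > nc)] <- "border"

  keep <- is.na(reason)
  kept <- detections[keep, , drop = FALSE]
  crops <- tibble::tibble(
    crop_id = sprintf("%s_c%04d", capture$capture_id, kept$label_id),
    capture_id = capture$capture_id,
    condition = capture$condition,
    row = kept$row,
    col = kept$col,
    area_px = kept$area_px,
    time_post_induction_min =
      if (is.null(capture$time_post_induction_min)) NA_real_
      else capture$time_post_induction_min,
    true_class = NA_character_,
    pixels = purrr::map2(
      kept$row, kept$col,
      function(r, c) {
        capture$phase[(r - half_lo):(r + half_hi),
                      (c - half_lo):(c + half_hi), drop = FALSE]
      }
    )
  )
  attr(crops, "discards") <- tibble::tibble(
    label_id = detections$label_id[!keep],
    row = detections$row[!keep],
    col = detections$col[!keep],
    area_px = detections$area_px[!keep],
    reason = reason[!keep]
  )
  crops
}

#' Write a crop batch to disk
#'
#' Serialises a crop tibble as a directory of float32 TIFF patches plus a
#' `manifest.csv` (one row per kept crop and, when present, per discarded
#' detection with its reason), mirroring the capture file dialect.
#'
#' @param crops Crop tibble from [crop_cells()] (or bound rows of several).
#' @param dir Output directory; created if missing.
#'
#' @return The manifest path, invisibly.
#' @export
write_crops <- function(crops, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(crops))) {
    px <- crops$pixels[[i]]
    lo <- min(px); rng <- max(px) - lo
    norm <- if (rng > 0) (px - lo) / rng else array(0, dim(px))
    suppressWarnings(tiff::writeTIFF(
      norm, file.path(dir, paste0(crops$crop_id[i], ".tif")),
      bits.per.sample = 32L
    ))
  }
  manifest <- dplyr::bind_rows(
    dplyr::mutate(
      crops[, c("capture_id", "crop_id", "row", "col", "area_px",
                "condition")],
      kept = TRUE, discard_reason = NA_character_
    ),
    {
      d <- attr(crops, "discards")
      if (is.null(d) || nrow(d) == 0L) NULL
      else tibble::tibble(
        capture_id = NA_character_,
        crop_id = NA_character_,
        row = d$row, col = d$col, area_px = d$area_px,
        condition = NA_character_,
        kept = FALSE, discard_reason = d$reason
      )
    }
  )
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
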