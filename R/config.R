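#' Preprocessing configuration for en-face angiograms
#'
#' Collects every tunable used by the axial (en-face) feature extractors.
#' The two printed device-calibrated thresholds are 48 for the vessel mask
#' and 178 for the reduced-vessel-density mask; the FAZ-side threshold on the
#' negative image defaults to their complement, `255 - 48 = 207`, so the FAZ
#' and vessel segmentations partition the intensity axis consistently.
#'
#' @param crop_mode `"auto"` (trim low-variance borders), `"fixed"`
#'   (apply `crop_box`), or `"none"`.
#' @param crop_box Integer vector `c(row0, row1, col0, col1)` for
#'   `crop_mode = "fixed"`.
#' @param crop_var_floor Variance floor (intensity units squared) below which
#'   a border row/column counts as content-free in `"auto"` mode.
#' @param vessel_threshold Intensity threshold for the vessel mask
#'   (default 48, on the original image).
#' @param faz_threshold Intensity threshold applied to the negative image
#'   when isolating the foveal avascular zone (default 207).
#' @param rvda_threshold Intensity threshold applied to the negative image
#'   for the reduced-vessel-density-area mask (default 178).
#' @param open_radius_px,close_radius_px Disc radii (pixels) for the
#'   opening/closing pass of FAZ segmentation. Defaults of 5 px at the
#'   nominal 600 x 600 resolution close inter-capillary gaps (~10 px)
#'   without eroding a FAZ of radius >= 30 px.
#' @param rvda_open_radius_px Disc radius for the single opening applied to
#'   the RVDA mask (default 3 px; removes speckle below capillary spacing).
#' @param rvda_exclude_faz If `TRUE`, the FAZ disk is removed from the RVDA
#'   support before normalising to percent. Off by default: the avascular
#'   zone is itself vessel-poor area.
#' @return A list with class `"preprocess_config"`.
#' @export
preprocess_config <- function(crop_mode = c("auto", "fixed", "none"),
                              crop_box = NULL,
                              crop_var_floor = 0.5,
                              vessel_threshold = 48,
                              faz_threshold = 255 - 48,
                              rvda_threshold = 178,
                              open_radius_px = 5,
                              close_radius_px = 5,
                              rvda_open_radius_px = 3,
                              rvda_exclude_faz = FALSE) {
  crop_mode <- match.arg(crop_mode)
  for (th in c(vessel_threshold, faz_threshold, rvda_threshold)) {
    if (th < 0 || th > 255) stop("thresholds must lie in [0, 255]", call. = FALSE)
  }
  structure(
    list(crop_mode = crop_mode, crop_box = crop_box,
         crop_var_floor = crop_var_floor,
         vessel_threshold = vessel_threshold,
         faz_threshold = faz_threshold,
         rvda_threshold = rvda_threshold,
         open_radius_px = open_radius_px,
         close_radius_px = close_radius_px,
         rvda_open_radius_px = rvda_open_radius_px,
         rvda_exclude_faz = rvda_exclude_faz),
    class = "preprocess_config"
  )
}

#' Configuration for B-scan thickness extraction
#'
#' @param lateral_threshold `"otsu"` for an automatic global threshold on the
#'   B-scan, or a numeric intensity in `[0, 255]`.
#' @param start_threshold Intensity level whose upward crossing on the depth
#'   profile marks the inner retinal surface (default 48).
#' @param rise_threshold Intensity level whose second upward crossing, after
#'   the profile has fallen back below `start_threshold`, marks the deeper
#'   bright band (default 48).
#' @param smoothing_width Odd width of the moving-average filter applied to
#'   the depth profile before landmark search; 1 disables smoothing.
#' @param open_radius_px,close_radius_px Disc radii for the morphological
#'   cleanup of the B-scan mask.
#' @param pixel_scale_mm Millimetres per pixel used to convert thickness to
#'   physical units (default 0.05 mm/px, i.e. 30 mm over 600 pixels).
#' @param pit_sense Whether the foveal landmark is the `"deepest"` (default)
#'   or `"shallowest"` point of the upper tissue boundary.
#' @return A list with class `"thickness_config"`.
#' @export
thickness_config <- function(lateral_threshold = "otsu",
                             start_threshold = 48,
                             rise_threshold = 48,
                             smoothing_width = 3,
                             open_radius_px = 2,
                             close_radius_px = 2,
                             pixel_scale_mm = 0.05,
                             pit_sense = c("deepest", "shallowest")) {
  pit_sense <- match.arg(pit_sense)
  if (!identical(lateral_threshold, "otsu") &&
      (!is.numeric(lateral_threshold) || lateral_threshold < 0 ||
       lateral_threshold > 255)) {
    stop("lateral_threshold must be 'otsu' or an intensity in [0, 255]",
         call. = FALSE)
  }
  if (start_threshold < 0 || start_threshold > 255 ||
      rise_threshold < 0 || rise_threshold > 255) {
    stop("profile thresholds must lie in [0, 255]", call. = FALSE)
  }
  if (smoothing_width < 1 || smoothing_width %% 2 == 0) {
    stop("smoothing_width must be a positive odd integer", call. = FALSE)
  }
  structure(
    list(lateral_threshold = lateral_threshold,
         start_threshold = start_threshold,
         rise_threshold = rise_threshold,
         smoothing_width = smoothing_width,
         open_radius_px = open_radius_px,
         close_radius_px = close_radius_px,
         pixel_scale_mm = pixel_scale_mm,
         pit_sense = pit_sense),
    class = "thickness_config"
  )
}
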