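#' Segment tissue in a lateral (B-scan) image
#'
#' Thresholds the B-scan (Otsu's method by default, since B-scan brightness
#' varies more across devices than en-face brightness) and cleans the mask
#' with morphological opening and closing.
#'
#' @param lateral Cropped B-scan intensity matrix.
#' @param cfg A [thickness_config()].
#' @return A 0/1 mask with tissue as foreground.
#' @export
segment_lateral <- function(lateral, cfg = thickness_config()) {
  .check_gray(lateral)
  thr <- cfg$lateral_threshold
  if (identical(thr, "otsu")) {
    thr <- 255 * EBImage::otsu(EBImage::Image(lateral / 255))
  }
  mask <- binarize(lateral, thr)
  mask <- morph_open_close(mask, cfg$open_radius_px, cfg$close_radius_px)
  if (sum(mask) == 0) {
    stop("lateral segmentation produced an empty tissue mask", call. = FALSE)
  }
  mask
}

#' Largest background region of a tissue mask
#'
#' Labels the 8-connected components of the background (tissue = 0) and
#' returns the largest one. Area ties are broken in favour of the component
#' whose first pixel comes earliest in row-major scan order.
#'
#' @param mask A 0/1 tissue mask.
#' @return A 0/1 mask of the selected background zone.
#' @export
find_background_zone <- function(mask) {
  .check_mask(mask)
  bg <- 1 - mask
  if (sum(bg) == 0) stop("mask has no background pixels", call. = FALSE)
  lab <- label_components(bg)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  best <- which.max(areas)  # first (lowest label = earliest first pixel) wins ties
  (lab == best) * 1
}

#' Locate the foveal pit column
#'
#' For the background zone above the retina, the boundary with the tissue in
#' each column is its lowest background row. The foveal pit is the column
#' where this boundary is deepest (or shallowest, per `pit_sense`). A smooth
#' pit rasterises to a plateau of equally extreme columns, so ties are
#' resolved to the median tied column, which is unbiased for a symmetric
#' pit; a completely flat boundary therefore returns the middle column. The
#' choice of extremum corresponds to the minimal boundary coordinate of the
#' upper retinal surface in a fovea-centred scan.
#'
#' @param bg_zone A 0/1 mask of the background zone above the tissue.
#' @param pit_sense `"deepest"` (default) or `"shallowest"`.
#' @return Integer column index of the pit.
#' @export
locate_fovea_column <- function(bg_zone, pit_sense = c("deepest", "shallowest")) {
  .check_mask(bg_zone)
  pit_sense <- match.arg(pit_sense)
  j <- nrow(bg_zone)
  cols <- which(colSums(bg_zone) > 0)
  if (length(cols) == 0) stop("background zone is empty", call. = FALSE)
  depth <- vapply(cols, function(cc) max(which(bg_zone[, cc] == 1)), numeric(1))
  valid <- depth < j  # tissue must exist below the zone in that column
  if (!any(valid)) {
    stop("background zone touches the image bottom everywhere; no tissue below",
         call. = FALSE)
  }
  cols <- cols[valid]; depth <- depth[valid]
  target <- if (pit_sense == "deepest") max(depth) else min(depth)
  tied <- cols[depth == target]
  as.integer(tied[ceiling(length(tied) / 2)])
}

#' Retinal thickness from a depth intensity profile
#'
#' Extracts the grayscale intensity profile top-to-bottom at `col`, smooths
#' it with a moving average of `cfg$smoothing_width` (replicated ends), and
#' searches for two landmarks: the starting point, where the profile first
#' rises from below `start_threshold` to at or above it (the inner retinal
#' surface), and the ending point, where -- after the profile has fallen
#' back below `start_threshold` -- it rises again past `rise_threshold`
#' (the top of the deeper bright band). Thickness is the row distance
#' between the two.
#'
#' @param lateral Cropped B-scan intensity matrix.
#' @param col Column index of the profile (typically from
#'   [locate_fovea_column()]).
#' @param cfg A [thickness_config()].
#' @return One-row tibble: `rt_px`, `rt_mm`, `fovea_col`, `start_row`,
#'   `end_row`.
#' @export
measure_thickness <- function(lateral, col, cfg = thickness_config()) {
  .check_gray(lateral)
  j <- nrow(lateral)
  if (col < 1 || col > ncol(lateral)) stop("column out of image", call. = FALSE)
  p <- lateral[, col]
  w <- cfg$smoothing_width
  if (w > 1) {
    h <- (w - 1) %/% 2
    idx <- pmin(pmax(seq(1 - h, j + h), 1), j)
    p <- as.vector(stats::filter(p[idx], rep(1 / w, w), sides = 2))
    p <- p[(h + 1):(h + j)]
  }
  up_cross <- function(level, from) {
    i <- from
    # skip any initial stretch already at/above the level
    while (i <= j && p[i] >= level) i <- i + 1
    while (i <= j && p[i] < level) i <- i + 1
    if (i > j) NA_integer_ else i
  }
  start_row <- up_cross(cfg$start_threshold, 1L)
  if (is.na(start_row)) {
    stop("no retinal surface: profile never rises past the start threshold",
         call. = FALSE)
  }
  # fall back below the start threshold, then a second rise past rise_threshold
  fall <- start_row
  while (fall <= j && p[fall] >= cfg$start_threshold) fall <- fall + 1
  if (fall > j) {
    stop("no deep band: profile never falls back below the start threshold",
         call. = FALSE)
  }
  end_row <- fall
  while (end_row <= j && p[end_row] < cfg$rise_threshold) end_row <- end_row + 1
  if (end_row > j) {
    stop("no deep band: no second intensity rise found", call. = FALSE)
  }
  rt_px <- end_row - start_row
  tibble::tibble(
    rt_px = rt_px,
    rt_mm = pixels_to_mm(rt_px, cfg$pixel_scale_mm),
    fovea_col = as.integer(col),
    start_row = as.integer(start_row),
    end_row = as.integer(end_row)
  )
}

#' Convert a pixel length to millimetres
#'
#' @param px Length in pixels.
#' @param scale Millimetres per pixel (> 0); the device default used here is
#'   0.05 mm/px.
#' @return Length in millimetres (`px * scale`).
#' @export
pixels_to_mm <- function(px, scale) {
  if (!is.numeric(scale) || any(scale <= 0)) {
    stop("pixel scale must be positive", call. = FALSE)
  }
  px * scale
}
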