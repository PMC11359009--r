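#' Normalised binary image moment
#'
#' For a binary image \eqn{F} with \eqn{J} rows and \eqn{K} columns the
#' moment of order \eqn{(m, n)} is
#' \deqn{M(m,n) = \frac{1}{J^m K^n} \sum_{x=1}^{J} \sum_{y=1}^{K}
#'       x^m y^n F(x,y),}
#' with \eqn{x} the 1-based row index and \eqn{y} the 1-based column index.
#' \eqn{M(0,0)} is the foreground pixel count; the centroid in pixels is
#' \eqn{(J\,M(1,0)/M(0,0),\; K\,M(0,1)/M(0,0))}.
#'
#' @param mask A 0/1 matrix.
#' @param m,n Non-negative integer orders (row and column respectively).
#' @return The scalar moment value.
#' @export
#' @examples
#' compute_moment(matrix(1, 2, 2), 0, 0)  # 4 pixels
#' compute_moment(matrix(1, 2, 2), 1, 0)  # (1/2) * (1+1+2+2) = 3
compute_moment <- function(mask, m, n) {
  .check_mask(mask)
  if (m < 0 || n < 0 || m != round(m) || n != round(n)) {
    stop("moment orders must be non-negative integers", call. = FALSE)
  }
  j <- nrow(mask); k <- ncol(mask)
  x <- seq_len(j); y <- seq_len(k)
  sum((x^m) * (mask %*% (y^n))) / (j^m * k^n)
}

#' Segment the foveal avascular zone from an en-face angiogram
#'
#' The angiogram is inverted so avascular tissue becomes bright, thresholded
#' at `cfg$faz_threshold`, and cleaned with morphological opening then
#' closing, which removes the thin inter-capillary background corridors and
#' leaves compact avascular blobs. Among the surviving 8-connected
#' components the one whose centroid lies nearest the image centre is taken
#' as the FAZ (the scan is fovea-centred), and its interior holes are
#' filled.
#'
#' @param axial Cropped en-face intensity matrix.
#' @param cfg A [preprocess_config()].
#' @return A 0/1 mask of the FAZ.
#' @export
segment_faz <- function(axial, cfg = preprocess_config()) {
  .check_gray(axial)
  neg <- to_negative(axial)
  mask <- binarize(neg, cfg$faz_threshold)
  mask <- morph_open_close(mask, cfg$open_radius_px, cfg$close_radius_px)
  lab <- label_components(mask)
  n_comp <- max(lab)
  if (n_comp == 0L) {
    stop("FAZ not found: no avascular component survives cleanup",
         call. = FALSE)
  }
  j <- nrow(axial); k <- ncol(axial)
  centre <- c((1 + j) / 2, (1 + k) / 2)
  cent <- t(vapply(seq_len(n_comp), function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  d2 <- (cent[, 1] - centre[1])^2 + (cent[, 2] - centre[2])^2
  best <- which.min(d2)
  # the FAZ must be roughly foveal: centroid within the central third
  if (abs(cent[best, 1] - centre[1]) > j / 6 ||
      abs(cent[best, 2] - centre[2]) > k / 6) {
    stop("FAZ not found: no component centred in the central third of the scan",
         call. = FALSE)
  }
  fill_holes((lab == best) * 1)
}

#' FAZ geometry from a binary mask
#'
#' Area is the zero-order moment \eqn{M(0,0)}; the centroid is the ratio of
#' first- to zero-order moments, de-normalised back to pixel units. The
#' boundary is the mask minus its erosion by a disc of radius one pixel, so
#' every boundary pixel is a mask pixel with at least one background
#' 8-neighbour. The average radius is the mean Euclidean distance from the
#' boundary pixels to the centroid and later serves as the inner radius of
#' the sector grid.
#'
#' @param faz_mask A 0/1 FAZ mask with at least one foreground pixel.
#' @return An object of class `"faz_result"`: a list with `area_px`,
#'   `centroid` (`c(row, col)`), `boundary_px` (two-column matrix of
#'   `(row, col)`), `avg_radius_px`, and the input `mask`.
#' @export
faz_metrics <- function(faz_mask) {
  .check_mask(faz_mask)
  area <- compute_moment(faz_mask, 0, 0)
  if (area == 0) stop("empty FAZ mask", call. = FALSE)
  j <- nrow(faz_mask); k <- ncol(faz_mask)
  centroid <- c(
    row = j * compute_moment(faz_mask, 1, 0) / area,
    col = k * compute_moment(faz_mask, 0, 1) / area
  )
  boundary <- faz_mask - .erode(faz_mask, 1)
  bpx <- which(boundary == 1, arr.ind = TRUE)
  colnames(bpx) <- c("row", "col")
  avg_radius <- mean(sqrt((bpx[, 1] - centroid[1])^2 +
                          (bpx[, 2] - centroid[2])^2))
  structure(
    list(area_px = area, centroid = centroid, boundary_px = bpx,
         avg_radius_px = avg_radius, mask = faz_mask),
    class = "faz_result"
  )
}

#' @export
print.faz_result <- function(x, ...) {
  cat("FAZ: area", x$area_px, "px, centroid (",
      round(x$centroid[1], 1), ",", round(x$centroid[2], 1),
      "), avg radius", round(x$avg_radius_px, 2), "px\n")
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.faz_result <- function(x, ...) {
  tibble::tibble(
    faz_area_px = x$area_px,
    faz_centroid_row = unname(x$centroid[1]),
    faz_centroid_col = unname(x$centroid[2]),
    faz_avg_radius_px = x$avg_radius_px,
    n_boundary_px = nrow(x$boundary_px)
  )
}

#' Build the five-sector analysis grid
#'
#' An ETDRS-like grid anchored on the FAZ: zone 1 is the central disc whose
#' radius equals the FAZ average radius; the outer radius is three times the
#' inner; zones 2--5 are the annulus between them cut into superior, nasal,
#' inferior and temporal quadrants by the two diagonals at +/-45 degrees
#' through the centre. The five masks are pairwise disjoint, zones 2--5
#' exactly tile the annulus, and pixels outside the image are excluded.
#'
#' @param faz A `"faz_result"` (or any list with `centroid` and
#'   `avg_radius_px`).
#' @param shape Image shape `c(J, K)`.
#' @return An object of class `"sector_zones"`: list with `center`,
#'   `inner_radius_px`, `outer_radius_px` and `zone_masks` (list of 5
#'   0/1 matrices).
#' @export
build_sector_zones <- function(faz, shape) {
  centre <- faz$centroid
  r_in <- faz$avg_radius_px
  if (!is.finite(r_in) || r_in <= 0) {
    stop("inner radius must be positive", call. = FALSE)
  }
  j <- shape[1]; k <- shape[2]
  r_out <- 3 * r_in
  dr <- matrix(seq_len(j) - centre[1], j, k)
  dc <- matrix(seq_len(k) - centre[2], j, k, byrow = TRUE)
  d2 <- dr^2 + dc^2
  inner <- d2 <= r_in^2
  annulus <- d2 <= r_out^2 & !inner
  # quadrants split on the +/-45 degree diagonals; ties assigned
  # deterministically (superior first, then inferior, then nasal/temporal)
  sup <- annulus & (-dr >= abs(dc))
  inf <- annulus & !sup & (dr >= abs(dc))
  nas <- annulus & !sup & !inf & (dc > 0)
  tem <- annulus & !sup & !inf & !nas
  zones <- list(
    central  = inner * 1,
    superior = sup * 1,
    nasal    = nas * 1,
    inferior = inf * 1,
    temporal = tem * 1
  )
  structure(
    list(center = centre, inner_radius_px = r_in, outer_radius_px = r_out,
         zone_masks = zones),
    class = "sector_zones"
  )
}

#' @export
print.sector_zones <- function(x, ...) {
  cat("Five-sector grid: centre (", round(x$center[1], 1), ",",
      round(x$center[2], 1), "), radii", round(x$inner_radius_px, 1), "/",
      round(x$outer_radius_px, 1), "px\n")
  invisible(x)
}

#' Vessel density per sector zone
#'
#' Vessel density of a zone is the percentage of vessel-mask foreground
#' pixels among the zone's pixels; the summary `vd_mean` is the arithmetic
#' mean of the five zone values.
#'
#' @param vessel_mask A 0/1 mask from thresholding the en-face image at the
#'   vessel threshold (48 by default).
#' @param zones A `"sector_zones"` object of matching shape.
#' @return One-row tibble with `vd_z1`..`vd_z5` (central, superior, nasal,
#'   inferior, temporal) and `vd_mean`, all percentages.
#' @export
vessel_density <- function(vessel_mask, zones) {
  .check_mask(vessel_mask)
  vals <- vapply(seq_along(zones$zone_masks), function(i) {
    zm <- zones$zone_masks[[i]]
    npx <- sum(zm)
    if (npx == 0) {
      stop("zone ", i, " (", names(zones$zone_masks)[i],
           ") contains no pixels after clipping", call. = FALSE)
    }
    100 * sum(vessel_mask * zm) / npx
  }, numeric(1))
  out <- tibble::tibble(
    vd_z1 = vals[1], vd_z2 = vals[2], vd_z3 = vals[3],
    vd_z4 = vals[4], vd_z5 = vals[5], vd_mean = mean(vals)
  )
  out
}

#' Reduced vessel density area (RVDA)
#'
#' Fraction of the scan that is locally vessel-poor. The angiogram is
#' inverted, thresholded at `cfg$rvda_threshold` (pixels at or above the
#' threshold in the negative, i.e. dark in the original, become foreground),
#' and a morphological opening removes the thin inter-capillary corridors,
#' so only extended avascular area survives. The result is the surviving
#' foreground as a percentage of the image area.
#'
#' @param axial Cropped en-face intensity matrix.
#' @param cfg A [preprocess_config()]. With `rvda_exclude_faz = TRUE` the
#'   FAZ disc (segmented internally) is removed from both numerator and
#'   denominator.
#' @return One-row tibble with column `rvda_pct`.
#' @export
compute_rvda <- function(axial, cfg = preprocess_config()) {
  .check_gray(axial)
  neg <- to_negative(axial)
  mask <- binarize(neg, cfg$rvda_threshold)
  mask <- .open(mask, cfg$rvda_open_radius_px)
  support <- matrix(1, nrow(axial), ncol(axial))
  if (isTRUE(cfg$rvda_exclude_faz)) {
    faz <- segment_faz(axial, cfg)
    support <- support * (1 - faz)
    mask <- mask * support
  }
  tibble::tibble(rvda_pct = 100 * sum(mask) / sum(support))
}
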