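#' Specification for a synthetic en-face angiogram phantom
#'
#' The phantom emulates the geometry the extractors rely on: bright
#' curvilinear vessels on a dark background, a central avascular ellipse of
#' known pixel area, and controllable per-zone vessel coverage. Vessels are
#' drawn as a family of parallel wavy strokes with a fixed spatial period,
#' which keeps the inter-vessel gaps narrow (below the morphological opening
#' discs) the way inter-capillary spacing is in a real deep-plexus scan.
#' Coverage is then adjusted pixel-wise per sector zone so the generator can
#' report exact ground truth.
#'
#' @param size Image shape `c(J, K)` (default 600 x 600, the native export
#'   resolution).
#' @param faz_semi_axes Ellipse semi-axes `c(a, b)` in pixels (rows, cols).
#' @param faz_center Ellipse centre `c(row, col)`; default image centre.
#' @param target_coverage Vessel fraction in `[0, 0.9]`, a scalar or a
#'   length-5 vector (one per sector zone), defined over the perfused
#'   support (outside the avascular ellipse and patches).
#' @param vessel_intensity_mean,vessel_intensity_sd Vessel pixel intensity
#'   model (defaults 180 and 20; the broad vessel spread diffuses the
#'   vessel-edge contribution to the range-filter histogram so the
#'   background peak stays the dominant mode, and the defaults keep both
#'   tails clear of the 0/255 clip).
#' @param background_intensity_mean,background_intensity_sd Background pixel
#'   intensity model (defaults 10 and 6). The background spread is the
#'   texture knob: widening it broadens the range-filter histogram and with
#'   it FC and FWHM, which is how the cohort generator realises the
#'   histogram disease effect.
#' @param noise_sd Additive global Gaussian noise (default 5).
#' @param stroke_period_px Spatial period of the vessel strokes (default 8
#'   px, i.e. inter-vessel gaps stay below 7 px at any coverage).
#' @param wave_amplitude,wave_length_px Amplitude and wavelength of the
#'   stroke waviness.
#' @param avascular_patches Optional data frame with columns
#'   `row, col, height, width`: rectangular vessel-free patches (reduced
#'   vessel density regions).
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   phantom.
#' @return A list with class `"axial_phantom_spec"`.
#' @export
axial_phantom_spec <- function(size = c(600, 600),
                               faz_semi_axes = c(55, 45),
                               faz_center = NULL,
                               target_coverage = 0.45,
                               vessel_intensity_mean = 180,
                               vessel_intensity_sd = 20,
                               background_intensity_mean = 10,
                               background_intensity_sd = 6,
                               noise_sd = 5,
                               stroke_period_px = 8,
                               wave_amplitude = 5,
                               wave_length_px = 150,
                               avascular_patches = NULL,
                               seed = 1) {
  if (any(target_coverage < 0) || any(target_coverage > 0.9)) {
    stop("target_coverage above 0.9 is unreachable for a vessel phantom",
         call. = FALSE)
  }
  if (!length(target_coverage) %in% c(1L, 5L)) {
    stop("target_coverage must be a scalar or one value per zone (5)",
         call. = FALSE)
  }
  if (is.null(faz_center)) faz_center <- (1 + size) / 2
  a <- faz_semi_axes[1]; b <- faz_semi_axes[2]
  if (faz_center[1] - a < 1 || faz_center[1] + a > size[1] ||
      faz_center[2] - b < 1 || faz_center[2] + b > size[2]) {
    stop("FAZ ellipse must lie inside the image", call. = FALSE)
  }
  structure(
    list(size = size, faz_semi_axes = faz_semi_axes, faz_center = faz_center,
         target_coverage = target_coverage,
         vessel_intensity_mean = vessel_intensity_mean,
         vessel_intensity_sd = vessel_intensity_sd,
         background_intensity_mean = background_intensity_mean,
         background_intensity_sd = background_intensity_sd,
         noise_sd = noise_sd, stroke_period_px = stroke_period_px,
         wave_amplitude = wave_amplitude, wave_length_px = wave_length_px,
         avascular_patches = avascular_patches, seed = as.integer(seed)),
    class = "axial_phantom_spec"
  )
}

#' Generate a synthetic en-face angiogram with ground truth
#'
#' @param spec An [axial_phantom_spec()].
#' @return A list with class `"octa_phantom"`: `image` (intensity matrix),
#'   and `truth`, a list holding the exact rasterised FAZ pixel area,
#'   centroid and average boundary radius, the exact per-zone vessel
#'   fractions (`vd_zone`, percent, over the same five-sector grid the
#'   extractor builds), overall coverage, and the vessel mask itself.
#' @export
generate_axial <- function(spec) {
  stopifnot(inherits(spec, "axial_phantom_spec"))
  withr::with_seed(spec$seed, {
    j <- spec$size[1]; k <- spec$size[2]
    t_zone <- rep(spec$target_coverage, length.out = 5)
    s <- spec$stroke_period_px
    w <- mean(t_zone) * s
    rows <- seq_len(j)
    phase1 <- stats::runif(1, 0, 2 * pi)
    phase2 <- stats::runif(1, 0, 2 * pi)
    f <- spec$wave_amplitude * sin(2 * pi * rows / spec$wave_length_px + phase1) +
      0.4 * spec$wave_amplitude *
        sin(2 * pi * rows / (spec$wave_length_px / 2.6) + phase2)
    colm <- matrix(seq_len(k), j, k, byrow = TRUE)
    stroke <- ((colm - f) %% s < w) * 1

    # avascular geometry: FAZ ellipse plus optional rectangular patches
    dr <- matrix(rows - spec$faz_center[1], j, k)
    dc <- matrix(seq_len(k) - spec$faz_center[2], j, k, byrow = TRUE)
    faz <- ((dr / spec$faz_semi_axes[1])^2 +
            (dc / spec$faz_semi_axes[2])^2 <= 1) * 1
    avascular <- faz
    if (!is.null(spec$avascular_patches)) {
      p <- spec$avascular_patches
      for (i in seq_len(nrow(p))) {
        r0 <- max(1, p$row[i]); c0 <- max(1, p$col[i])
        r1 <- min(j, p$row[i] + p$height[i] - 1)
        c1 <- min(k, p$col[i] + p$width[i] - 1)
        avascular[r0:r1, c0:c1] <- 1
      }
    }
    stroke[avascular == 1] <- 0

    # ground-truth sector grid from the true FAZ geometry
    faz_truth <- faz_metrics(faz)
    zones <- build_sector_zones(faz_truth, c(j, k))
    support <- avascular == 0

    # per-zone pixel adjustment to hit the coverage target exactly over the
    # perfused support
    for (z in 1:5) {
      zi <- zones$zone_masks[[z]] == 1 & support
      n_sup <- sum(zi)
      if (n_sup == 0) next
      target_n <- round(t_zone[z] * n_sup)
      cur <- sum(stroke[zi])
      if (cur > target_n) {
        on_idx <- which(zi & stroke == 1)
        stroke[sample(on_idx, cur - target_n)] <- 0
      } else if (cur < target_n) {
        off_idx <- which(zi & stroke == 0)
        stroke[sample(off_idx, min(target_n - cur, length(off_idx)))] <- 1
      }
    }

    vd_zone <- vapply(zones$zone_masks, function(zm) {
      100 * sum(stroke * zm) / sum(zm)
    }, numeric(1))

    img <- spec$background_intensity_mean +
      spec$background_intensity_sd * stats::rnorm(j * k)
    img <- matrix(img, j, k)
    nves <- sum(stroke)
    img[stroke == 1] <- spec$vessel_intensity_mean +
      spec$vessel_intensity_sd * stats::rnorm(nves)
    img <- img + spec$noise_sd * stats::rnorm(j * k)
    img <- round(pmin(pmax(img, 0), 255))

    structure(
      list(
        image = img,
        truth = list(
          faz_area_px = faz_truth$area_px,
          faz_centroid = faz_truth$centroid,
          faz_avg_radius_px = faz_truth$avg_radius_px,
          vd_zone = vd_zone,
          vd_mean = mean(vd_zone),
          coverage_overall = mean(stroke),
          avascular_area_px = sum(avascular),
          vessel_mask = stroke
        )
      ),
      class = "octa_phantom"
    )
  })
}

#' Specification for a synthetic lateral (B-scan) phantom
#'
#' Two bright horizontal bands on a dark background model the inner retinal
#' surface and a deeper reflective layer. A smooth Gaussian-profile pit of
#' `pit_depth_px` at `pit_col` displaces the upper band downwards, thinning
#' the gap the way the fovea thins the retina; ground-truth thickness is the
#' band separation at the pit column.
#'
#' @param size Image shape `c(J, K)`.
#' @param band1_top_row,band2_top_row Top rows of the two bands (upper band
#'   before pit displacement).
#' @param band_thickness_px Thickness of each band.
#' @param pit_depth_px,pit_col,pit_sigma_px Pit depth, centre column and
#'   Gaussian width.
#' @param band_intensity_mean,band_intensity_sd,background_intensity_mean
#'   Intensity model.
#' @param noise_sd Additive Gaussian noise (0 makes landmarks exact).
#' @param seed Integer seed.
#' @return A list with class `"lateral_phantom_spec"`.
#' @export
lateral_phantom_spec <- function(size = c(600, 600),
                                 band1_top_row = 320,
                                 band2_top_row = 347,
                                 band_thickness_px = 6,
                                 pit_depth_px = 12,
                                 pit_col = NULL,
                                 pit_sigma_px = 30,
                                 band_intensity_mean = 200,
                                 band_intensity_sd = 8,
                                 background_intensity_mean = 10,
                                 noise_sd = 5,
                                 seed = 1) {
  if (is.null(pit_col)) pit_col <- round((1 + size[2]) / 2)
  if (band1_top_row >= band2_top_row) {
    stop("band 1 must lie above band 2", call. = FALSE)
  }
  if (band1_top_row + pit_depth_px + band_thickness_px - 1 >= band2_top_row) {
    stop("bands overlap at the pit; reduce pit depth or band thickness",
         call. = FALSE)
  }
  if (band2_top_row + band_thickness_px - 1 > size[1]) {
    stop("bands must lie inside the image", call. = FALSE)
  }
  structure(
    list(size = size, band1_top_row = band1_top_row,
         band2_top_row = band2_top_row,
         band_thickness_px = band_thickness_px,
         pit_depth_px = pit_depth_px, pit_col = pit_col,
         pit_sigma_px = pit_sigma_px,
         band_intensity_mean = band_intensity_mean,
         band_intensity_sd = band_intensity_sd,
         background_intensity_mean = background_intensity_mean,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "lateral_phantom_spec"
  )
}

#' Generate a synthetic B-scan with ground truth
#'
#' @param spec A [lateral_phantom_spec()].
#' @return A list with class `"octa_phantom"`: `image` and `truth`
#'   (`thickness_px` = band separation at the pit column, `pit_col`,
#'   and the per-column top row of the displaced upper band).
#' @export
generate_lateral <- function(spec) {
  stopifnot(inherits(spec, "lateral_phantom_spec"))
  withr::with_seed(spec$seed, {
    j <- spec$size[1]; k <- spec$size[2]
    cols <- seq_len(k)
    d <- round(spec$pit_depth_px *
                 exp(-(cols - spec$pit_col)^2 / (2 * spec$pit_sigma_px^2)))
    band1_top <- spec$band1_top_row + d
    img <- matrix(spec$background_intensity_mean, j, k)
    rowm <- matrix(seq_len(j), j, k)
    topm <- matrix(band1_top, j, k, byrow = TRUE)
    in_band1 <- rowm >= topm & rowm <= topm + spec$band_thickness_px - 1
    in_band2 <- rowm >= spec$band2_top_row &
      rowm <= spec$band2_top_row + spec$band_thickness_px - 1
    nb <- sum(in_band1) + sum(in_band2)
    img[in_band1 | in_band2] <- spec$band_intensity_mean +
      spec$band_intensity_sd * stats::rnorm(nb)
    img <- img + spec$noise_sd * stats::rnorm(j * k)
    img <- round(pmin(pmax(img, 0), 255))
    structure(
      list(
        image = img,
        truth = list(
          thickness_px = spec$band2_top_row -
            (spec$band1_top_row + d[spec$pit_col]),
          pit_col = spec$pit_col,
          band1_top_rows = spec$band1_top_row + d
        )
      ),
      class = "octa_phantom"
    )
  })
}

#' Specification for a synthetic labelled cohort
#'
#' Emulates the shape of the study population (99 normal, 22 MCI, 28 AD)
#' with class-conditional disease effects in the directions reported for
#' cognitive impairment: lower vessel coverage, an enlarged avascular zone,
#' a rougher angiogram texture (which widens the range-filter histogram and
#' its FWHM), and a thinner retina. MCI receives `mci_effect_scale` of the
#' full AD effect. Effect magnitudes are phantom parameters, not claims
#' about pathology.
#'
#' @param n_normal,n_mci,n_ad Class sizes (defaults 99/22/28).
#' @param size Image shape for both views.
#' @param base_coverage,coverage_sd Normal-class vessel coverage model.
#' @param base_faz_semi_axes,faz_jitter_sd Normal-class FAZ ellipse model.
#' @param base_texture_sd,texture_jitter_sd Normal-class background texture
#'   spread (the `background_intensity_sd` of the en-face phantom).
#' @param base_separation_px,separation_sd Normal-class band separation
#'   (retinal thickness) model, pixels.
#' @param delta_coverage Coverage reduction for full-effect disease
#'   (fraction; default 0.15).
#' @param faz_scale FAZ semi-axis multiplier for disease (default 1.5).
#' @param delta_texture_sd Extra background texture spread for disease
#'   (default 6); this widens the range-filter histogram (larger FWHM and
#'   FC) without touching the segmentation thresholds.
#' @param delta_thickness_px Retinal thinning for disease (default 5).
#' @param mci_effect_scale Fraction of the AD effect applied to MCI.
#' @param seed Integer master seed; each subject derives its own stream.
#' @return A list with class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_normal = 99, n_mci = 22, n_ad = 28,
                        size = c(600, 600),
                        base_coverage = 0.45, coverage_sd = 0.03,
                        base_faz_semi_axes = c(55, 45), faz_jitter_sd = 3,
                        base_texture_sd = 6, texture_jitter_sd = 0.5,
                        base_separation_px = 16, separation_sd = 1.5,
                        delta_coverage = 0.15,
                        faz_scale = 1.5,
                        delta_texture_sd = 6,
                        delta_thickness_px = 5,
                        mci_effect_scale = 0.5,
                        seed = 1) {
  if (n_normal < 0 || n_mci < 0 || n_ad < 0) {
    stop("class sizes must be non-negative", call. = FALSE)
  }
  if (sum(c(n_normal, n_mci, n_ad) > 0) < 2) {
    stop("at least two classes must be non-empty", call. = FALSE)
  }
  structure(
    list(n_normal = n_normal, n_mci = n_mci, n_ad = n_ad, size = size,
         base_coverage = base_coverage, coverage_sd = coverage_sd,
         base_faz_semi_axes = base_faz_semi_axes,
         faz_jitter_sd = faz_jitter_sd,
         base_texture_sd = base_texture_sd,
         texture_jitter_sd = texture_jitter_sd,
         base_separation_px = base_separation_px,
         separation_sd = separation_sd,
         delta_coverage = delta_coverage, faz_scale = faz_scale,
         delta_texture_sd = delta_texture_sd,
         delta_thickness_px = delta_thickness_px,
         mci_effect_scale = mci_effect_scale, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Deterministic per-subject phantom pair. Subject i's parameter stream is
# derived from the master seed so subjects are independent of generation
# order.
.cohort_subject <- function(spec, i) {
  labels <- c(rep("normal", spec$n_normal), rep("mci", spec$n_mci),
              rep("ad", spec$n_ad))
  label <- labels[i]
  eff <- switch(label, normal = 0, mci = spec$mci_effect_scale, ad = 1)
  sseed <- as.integer((as.numeric(spec$seed) * 10007 + i) %% 2147483629)
  j <- spec$size[1]; k <- spec$size[2]
  params <- withr::with_seed(sseed, {
    coverage <- min(max(stats::rnorm(1, spec$base_coverage -
                                       eff * spec$delta_coverage,
                                     spec$coverage_sd), 0.12), 0.8)
    ax <- spec$base_faz_semi_axes * spec$faz_scale^eff +
      stats::rnorm(2, 0, spec$faz_jitter_sd)
    ax <- pmax(ax, 20)
    centre <- (1 + spec$size) / 2 + stats::rnorm(2, 0, 4)
    texture <- max(1, stats::rnorm(1, spec$base_texture_sd +
                                     eff * spec$delta_texture_sd,
                                   spec$texture_jitter_sd))
    sep <- max(9, round(stats::rnorm(1, spec$base_separation_px -
                                       eff * spec$delta_thickness_px,
                                     spec$separation_sd)))
    pit_col <- round((1 + k) / 2 + stats::rnorm(1, 0, 10))
    list(coverage = coverage, ax = ax, centre = centre, texture = texture,
         sep = sep, pit_col = pit_col)
  })
  axial <- generate_axial(axial_phantom_spec(
    size = spec$size, faz_semi_axes = params$ax, faz_center = params$centre,
    target_coverage = params$coverage,
    background_intensity_sd = params$texture,
    seed = (sseed + 1) %% 2147483629
  ))
  pit_depth <- 12
  band1_top <- round(0.53 * j)  # upper band sits just past mid-depth
  lateral <- generate_lateral(lateral_phantom_spec(
    size = spec$size,
    band1_top_row = band1_top,
    band2_top_row = band1_top + pit_depth + params$sep,
    band_thickness_px = 6,
    pit_depth_px = pit_depth, pit_col = params$pit_col,
    seed = (sseed + 2) %% 2147483629
  ))
  truth <- tibble::tibble(
    subject_id = sprintf("S%03d", i),
    label = label,
    coverage_target = params$coverage,
    texture_sd = params$texture,
    faz_semi_a = params$ax[1], faz_semi_b = params$ax[2],
    faz_area_px = axial$truth$faz_area_px,
    vd_mean_truth = axial$truth$vd_mean,
    thickness_px_truth = lateral$truth$thickness_px,
    pit_col = params$pit_col
  )
  list(axial = axial, lateral = lateral, truth = truth, label = label)
}

#' Generate a labelled synthetic cohort
#'
#' Draws one en-face angiogram and one B-scan per subject with
#' class-conditional parameters, and returns the label manifest and the
#' ground-truth table. Images are written as PNGs when `out_dir` is given
#' (`<id>_axial.png`, `<id>_lateral.png`, plus `manifest.csv` and
#' `truth.csv`), and kept in memory only when `keep_images = TRUE` --
#' for feature extraction prefer the streaming
#' [extract_cohort_features()], which never holds more than one subject.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional output directory for PNGs and CSVs.
#' @param keep_images Keep the image matrices in the returned object.
#' @return A list with class `"octa_cohort"`: `manifest` (tibble
#'   `subject_id`, `label`), `truth` (tibble of per-subject ground truth),
#'   and optionally `images` (list of `list(axial, lateral)`).
#' @export
generate_cohort <- function(spec, out_dir = NULL, keep_images = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_normal + spec$n_mci + spec$n_ad
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  truth <- vector("list", n)
  images <- if (keep_images) vector("list", n) else NULL
  for (i in seq_len(n)) {
    subj <- .cohort_subject(spec, i)
    truth[[i]] <- subj$truth
    if (!is.null(out_dir)) {
      write_image(subj$axial$image,
                  file.path(out_dir, sprintf("S%03d_axial.png", i)))
      write_image(subj$lateral$image,
                  file.path(out_dir, sprintf("S%03d_lateral.png", i)))
    }
    if (keep_images) {
      images[[i]] <- list(axial = subj$axial$image,
                          lateral = subj$lateral$image)
    }
  }
  truth <- dplyr::bind_rows(truth)
  manifest <- truth[, c("subject_id", "label")]
  if (!is.null(out_dir)) {
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  }
  structure(list(manifest = manifest, truth = truth, images = images,
                 spec = spec),
            class = "octa_cohort")
}
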