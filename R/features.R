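#' Extract all en-face (axial) features from one angiogram
#'
#' Runs the full axial pipeline: optional border cropping, vessel-mask
#' thresholding, FAZ segmentation and moment-based geometry, the
#' five-sector grid, per-zone vessel density, the reduced-vessel-density
#' area, and the range-filter histogram features.
#'
#' @param img En-face intensity matrix (or a path readable by
#'   [load_image()]).
#' @param cfg A [preprocess_config()].
#' @param window Range-filter window (default 3).
#' @return One-row tibble: `vd_z1`..`vd_z5`, `vd_mean`, `faz_area_px`,
#'   `faz_avg_radius_px`, `faz_centroid_row`, `faz_centroid_col`,
#'   `rvda_pct`, `fc`, `fwhm`.
#' @export
extract_axial_features <- function(img, cfg = preprocess_config(),
                                   window = 3) {
  if (is.character(img)) img <- load_image(img)
  img <- crop_auto(img, cfg)
  vessel_mask <- binarize(img, cfg$vessel_threshold)
  faz_mask <- segment_faz(img, cfg)
  faz <- faz_metrics(faz_mask)
  zones <- build_sector_zones(faz, dim(img))
  vd <- vessel_density(vessel_mask, zones)
  rvda <- compute_rvda(img, cfg)
  hh <- extract_fc_fwhm(intensity_histogram(range_filter(img, window)))
  dplyr::bind_cols(
    vd,
    tibble::tibble(
      faz_area_px = faz$area_px,
      faz_avg_radius_px = faz$avg_radius_px,
      faz_centroid_row = unname(faz$centroid[1]),
      faz_centroid_col = unname(faz$centroid[2])
    ),
    rvda,
    hh[, c("fc", "fwhm")]
  )
}

#' Extract the thickness features from one B-scan
#'
#' Segments the B-scan, selects the background zone above the retina
#' (largest background component; if that component does not touch the top
#' of the image, the largest top-touching component is used instead),
#' locates the foveal pit column, and measures thickness on the intensity
#' profile at that column.
#'
#' @param img B-scan intensity matrix (or a path readable by
#'   [load_image()]).
#' @param cfg A [thickness_config()].
#' @return One-row tibble: `rt_px`, `rt_mm`, `fovea_col`, `start_row`,
#'   `end_row`.
#' @export
extract_lateral_features <- function(img, cfg = thickness_config()) {
  if (is.character(img)) img <- load_image(img)
  mask <- segment_lateral(img, cfg)
  zone <- find_background_zone(mask)
  if (!any(zone[1, ] == 1)) {
    # pick the largest background component that touches the image top
    lab <- label_components(1 - mask)
    top_labels <- setdiff(unique(lab[1, ]), 0)
    if (length(top_labels) == 0) {
      stop("no background zone above the retina", call. = FALSE)
    }
    areas <- vapply(top_labels, function(l) sum(lab == l), numeric(1))
    zone <- (lab == top_labels[which.max(areas)]) * 1
  }
  col <- locate_fovea_column(zone, cfg$pit_sense)
  measure_thickness(img, col, cfg)
}

#' Join per-eye feature rows with a label manifest
#'
#' @param axial_features Tibble of axial feature rows with a `subject_id`
#'   column (one row per subject).
#' @param lateral_features Tibble of lateral feature rows with
#'   `subject_id`.
#' @param manifest Data frame with `subject_id` and `label`
#'   (`normal`/`mci`/`ad`).
#' @return A tibble with one complete feature vector per subject; rows with
#'   any missing feature are dropped with a warning stating the count.
#' @export
assemble_features <- function(axial_features, lateral_features, manifest) {
  for (d in list(axial_features, lateral_features, manifest)) {
    if (!"subject_id" %in% names(d)) {
      stop("all inputs need a subject_id column", call. = FALSE)
    }
  }
  for (nm in c("axial", "lateral", "manifest")) {
    d <- switch(nm, axial = axial_features, lateral = lateral_features,
                manifest = manifest)
    dup <- d$subject_id[duplicated(d$subject_id)]
    if (length(dup) > 0) {
      stop("duplicate subject ids in ", nm, " table: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
  }
  bad <- setdiff(unique(manifest$label), c("normal", "mci", "ad"))
  if (length(bad) > 0) {
    stop("unknown labels in manifest: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  missing_ids <- setdiff(manifest$subject_id,
                         intersect(axial_features$subject_id,
                                   lateral_features$subject_id))
  if (length(missing_ids) > 0) {
    stop("manifest ids without feature rows: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  out <- manifest |>
    dplyr::inner_join(axial_features, by = "subject_id") |>
    dplyr::inner_join(lateral_features, by = "subject_id") |>
    tibble::as_tibble()
  complete <- stats::complete.cases(out)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) dropped for missing features",
            call. = FALSE)
    out <- out[complete, ]
  }
  out
}

#' Simulate a cohort and extract its feature table in one pass
#'
#' Streams through the cohort subject by subject -- generate the two
#' phantoms, extract features, discard the images -- so memory stays flat
#' regardless of cohort size. This is the end-to-end path used to exercise
#' the classifier without clinical data.
#'
#' @param spec A [cohort_spec()].
#' @param cfg A [preprocess_config()].
#' @param tcfg A [thickness_config()].
#' @return A tibble with `subject_id`, `label`, the axial feature columns
#'   and the lateral feature columns.
#' @export
extract_cohort_features <- function(spec, cfg = preprocess_config(),
                                    tcfg = thickness_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_normal + spec$n_mci + spec$n_ad
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- .cohort_subject(spec, i)
    ax <- extract_axial_features(subj$axial$image, cfg)
    lt <- extract_lateral_features(subj$lateral$image, tcfg)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = subj$truth$subject_id, label = subj$label),
      ax, lt
    )
  }
  dplyr::bind_rows(rows)
}
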