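# Smaller-than-default phantoms keep these structural checks fast; the
# full-size study conditions are exercised by the acceptance suite.

test_that("axial phantoms are seed-deterministic with exact reported truth", {
  sp <- axial_phantom_spec(size = c(300, 300), faz_semi_axes = c(40, 32),
                           seed = 17)
  a <- generate_axial(sp)
  b <- generate_axial(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$vd_zone, b$truth$vd_zone)

  # reported per-zone coverage equals the brute-force mask fraction
  faz_truth <- list(centroid = a$truth$faz_centroid,
                    avg_radius_px = a$truth$faz_avg_radius_px)
  zones <- build_sector_zones(faz_truth, c(300, 300))
  for (z in 1:5) {
    zm <- zones$zone_masks[[z]]
    expect_equal(unname(a$truth$vd_zone[z]),
                 100 * sum(a$truth$vessel_mask * zm) / sum(zm))
  }
})

test_that("axial truth area matches the analytic ellipse area", {
  sp <- axial_phantom_spec(faz_semi_axes = c(50, 40), seed = 2)
  ph <- generate_axial(sp)
  expect_lt(abs(ph$truth$faz_area_px - pi * 50 * 40) / (pi * 50 * 40), 0.02)
})

test_that("zero coverage gives a pure-background image", {
  sp <- axial_phantom_spec(size = c(200, 200), faz_semi_axes = c(30, 25),
                           target_coverage = 0, seed = 5)
  ph <- generate_axial(sp)
  expect_equal(sum(ph$truth$vessel_mask), 0)
  expect_lt(max(ph$image), 100)
})

test_that("phantom specs validate their geometry", {
  expect_error(axial_phantom_spec(target_coverage = 0.95), "unreachable")
  expect_error(axial_phantom_spec(size = c(100, 100),
                                  faz_semi_axes = c(60, 40)), "inside")
  expect_error(lateral_phantom_spec(band1_top_row = 300, band2_top_row = 310,
                                    pit_depth_px = 10,
                                    band_thickness_px = 6), "overlap")
  expect_error(lateral_phantom_spec(band2_top_row = 599,
                                    band_thickness_px = 6), "inside")
  expect_error(cohort_spec(n_normal = 5, n_mci = 0, n_ad = 0),
               "two classes")
})

test_that("lateral phantoms are deterministic and noise-free ones are exact", {
  sp <- lateral_phantom_spec(noise_sd = 0, seed = 12)
  a <- generate_lateral(sp)
  expect_identical(a$image, generate_lateral(sp)$image)
  expect_equal(a$truth$thickness_px,
               sp$band2_top_row - (sp$band1_top_row + sp$pit_depth_px))
  lf <- extract_lateral_features(a$image)
  expect_equal(lf$rt_px, a$truth$thickness_px)
})

test_that("cohort defaults reproduce the study shape", {
  spec <- cohort_spec(seed = 3)
  expect_equal(spec$n_normal + spec$n_mci + spec$n_ad, 149)
  # manifest without materialising 149 full-size image pairs
  labels <- c(rep("normal", spec$n_normal), rep("mci", spec$n_mci),
              rep("ad", spec$n_ad))
  expect_equal(sum(labels == "normal"), 99)
  small <- generate_cohort(cohort_spec(n_normal = 3, n_mci = 2, n_ad = 2,
                                       size = c(220, 220),
                                       base_faz_semi_axes = c(30, 25),
                                       faz_scale = 1.2, seed = 3))
  expect_equal(nrow(small$manifest), 7)
  expect_equal(sum(small$manifest$label == "normal"), 3)
  expect_true(all(c("coverage_target", "faz_area_px", "thickness_px_truth")
                  %in% names(small$truth)))
})

test_that("a null cohort has identical class-conditional truth", {
  spec0 <- cohort_spec(n_normal = 12, n_mci = 0, n_ad = 12,
                       size = c(220, 220), base_faz_semi_axes = c(30, 25),
                       delta_coverage = 0, faz_scale = 1,
                       delta_texture_sd = 0, delta_thickness_px = 0,
                       seed = 9)
  co <- generate_cohort(spec0)
  agg <- co$truth |>
    dplyr::group_by(label) |>
    dplyr::summarise(cov = mean(coverage_target), faz = mean(faz_area_px),
                     th = mean(thickness_px_truth))
  expect_lt(abs(diff(agg$cov)), 0.03)
  expect_lt(abs(diff(agg$faz)) / mean(agg$faz), 0.10)
  expect_lt(abs(diff(agg$th)), 1.5)
})

test_that("a larger coverage effect lowers extracted disease vessel density", {
  base <- list(n_normal = 2, n_mci = 0, n_ad = 5, size = c(360, 360),
               base_faz_semi_axes = c(40, 34), faz_scale = 1.2, seed = 21)
  f_small <- extract_cohort_features(do.call(cohort_spec,
                                             c(base, delta_coverage = 0.05)))
  f_large <- extract_cohort_features(do.call(cohort_spec,
                                             c(base, delta_coverage = 0.15)))
  vd_small <- mean(f_small$vd_mean[f_small$label == "ad"])
  vd_large <- mean(f_large$vd_mean[f_large$label == "ad"])
  expect_lt(vd_large, vd_small)
})

test_that("written cohorts round-trip through PNG and CSV", {
  dir <- tempfile("cohort")
  co <- generate_cohort(cohort_spec(n_normal = 2, n_mci = 0, n_ad = 1,
                                    size = c(220, 220),
                                    base_faz_semi_axes = c(30, 25),
                                    faz_scale = 1.2, seed = 4),
                        out_dir = dir, keep_images = TRUE)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  img <- load_image(file.path(dir, "S001_axial.png"))
  expect_equal(img, co$images[[1]]$axial)
})
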