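test_that("moments reproduce hand-evaluated and brute-force values", {
  ones2 <- matrix(1, 2, 2)
  expect_equal(compute_moment(ones2, 0, 0), 4)
  expect_equal(compute_moment(ones2, 1, 0), 3)  # (1/2)(1+1+2+2)
  expect_equal(compute_moment(ones2, 0, 1), 3)

  set.seed(21)
  for (i in 1:20) {
    m <- random_mask(11, 17, runif(1, 0.1, 0.9))
    expect_true(compute_moment(m, 0, 0) == sum(m))
    expect_equal(compute_moment(m, 2, 1), oracle_moment(m, 2, 1))
  }
})

test_that("faz_metrics recovers area, centroid and radius of known shapes", {
  r <- faz_metrics(matrix(1, 2, 2))
  expect_equal(unname(r$centroid), c(1.5, 1.5))
  expect_equal(r$area_px, 4)

  disk <- raster_disk(101, 101, 51, 51, 30)
  d <- faz_metrics(disk)
  expect_lt(abs(d$area_px - pi * 900) / (pi * 900), 0.03)
  expect_equal(unname(d$centroid), c(51, 51))
  expect_lt(abs(d$avg_radius_px - 29.5), 1)

  # boundary pixels all belong to the mask and touch background
  b <- d$boundary_px
  expect_true(all(disk[b] == 1))
  has_bg_neighbour <- vapply(seq_len(nrow(b)), function(i) {
    rr <- b[i, 1] + (-1:1); cc <- b[i, 2] + (-1:1)
    rr <- rr[rr >= 1 & rr <= 101]; cc <- cc[cc >= 1 & cc <= 101]
    any(disk[rr, cc] == 0)
  }, logical(1))
  expect_true(all(has_bg_neighbour))

  expect_error(faz_metrics(matrix(0, 4, 4)), "empty")
})

test_that("centroid from de-normalised moments equals the coordinate mean", {
  set.seed(33)
  for (i in 1:100) {
    m <- random_mask(32, 32, runif(1, 0.05, 0.95))
    if (sum(m) == 0) next
    f <- faz_metrics(m)
    px <- which(m == 1, arr.ind = TRUE)
    expect_equal(unname(f$centroid), c(mean(px[, 1]), mean(px[, 2])),
                 tolerance = 1e-9)
  }
})

test_that("segment_faz finds a central avascular ellipse on phantoms", {
  ph <- generate_axial(axial_phantom_spec(faz_semi_axes = c(50, 40), seed = 3))
  mask <- segment_faz(ph$image)
  truth_area <- ph$truth$faz_area_px
  expect_lt(abs(sum(mask) - truth_area) / truth_area, 0.10)
  f <- faz_metrics(mask)
  expect_lt(max(abs(f$centroid - c(300.5, 300.5))), 5)

  # vessels everywhere: nothing avascular to find
  bright <- matrix(180, 200, 200)
  expect_error(segment_faz(bright), "FAZ not found")

  # dark blob far from the centre is rejected
  off <- matrix(180, 300, 300)
  off[1:60, 1:60] <- 5
  expect_error(segment_faz(off), "central third")
})

test_that("sector zones partition the annulus and clip at image borders", {
  faz <- list(centroid = c(row = 150, col = 150), avg_radius_px = 50)
  z <- build_sector_zones(faz, c(300, 300))
  expect_equal(z$outer_radius_px, 150)
  expect_lt(abs(sum(z$zone_masks[[1]]) - pi * 2500) / (pi * 2500), 0.02)

  annulus <- raster_disk(300, 300, 150, 150, 150) -
    raster_disk(300, 300, 150, 150, 50)
  quad_sum <- Reduce(`+`, z$zone_masks[2:5])
  expect_equal(quad_sum, annulus)

  # pairwise disjoint
  for (i in 1:4) for (jj in (i + 1):5) {
    expect_equal(sum(z$zone_masks[[i]] * z$zone_masks[[jj]]), 0)
  }

  clipped <- build_sector_zones(list(centroid = c(30, 30),
                                     avg_radius_px = 25), c(200, 200))
  expect_true(all(vapply(clipped$zone_masks, function(m) {
    all(dim(m) == c(200, 200))
  }, logical(1))))
  expect_lt(sum(clipped$zone_masks[[1]]), pi * 625)  # truncated disk

  expect_error(build_sector_zones(list(centroid = c(10, 10),
                                       avg_radius_px = 0), c(50, 50)),
               "positive")
})

test_that("vessel density counts zone foreground fractions", {
  faz <- list(centroid = c(row = 100, col = 100), avg_radius_px = 30)
  z <- build_sector_zones(faz, c(200, 200))
  allwhite <- matrix(1, 200, 200)
  vd <- vessel_density(allwhite, z)
  expect_true(all(abs(unlist(vd[1, 1:5]) - 100) < 1e-12))
  expect_equal(vd$vd_mean, 100)

  checker <- (outer(1:200, 1:200, `+`) %% 2) * 1
  vdc <- vessel_density(checker, z)
  expect_true(all(abs(unlist(vdc[1, 1:5]) - 50) <= 1))

  tiny <- build_sector_zones(list(centroid = c(1, 1), avg_radius_px = 3),
                             c(50, 50))
  expect_error(vessel_density(allwhite[1:50, 1:50], tiny), "zone")
})

test_that("vd_mean equals the mean of the five zone densities", {
  ph <- generate_axial(axial_phantom_spec(seed = 14))
  fx <- extract_axial_features(ph$image)
  expect_equal(fx$vd_mean,
               mean(c(fx$vd_z1, fx$vd_z2, fx$vd_z3, fx$vd_z4, fx$vd_z5)))
})

test_that("RVDA covers degenerate images and avascular patches", {
  expect_equal(compute_rvda(matrix(255, 50, 50))$rvda_pct, 0)
  expect_equal(compute_rvda(matrix(0, 50, 50))$rvda_pct, 100)

  patches <- data.frame(row = 80, col = 80, height = 100, width = 100)
  ph <- generate_axial(axial_phantom_spec(avascular_patches = patches,
                                          seed = 6))
  rv <- compute_rvda(ph$image)$rvda_pct
  expected <- 100 * ph$truth$avascular_area_px / (600 * 600)
  expect_lt(abs(rv - expected) / expected, 0.15)
})

test_that("raising a threshold never raises density or RVDA", {
  ph <- generate_axial(axial_phantom_spec(seed = 8))
  img <- ph$image
  faz <- faz_metrics(segment_faz(img))
  zones <- build_sector_zones(faz, dim(img))
  prev <- rep(Inf, 5)
  for (thr in c(30, 48, 70, 120)) {
    vd <- unlist(vessel_density(binarize(img, thr), zones)[1, 1:5])
    expect_true(all(vd <= prev + 1e-12))
    prev <- vd
  }
  prev_rvda <- Inf
  for (thr in c(150, 178, 210, 240)) {
    rv <- compute_rvda(img, preprocess_config(rvda_threshold = thr))$rvda_pct
    expect_lte(rv, prev_rvda)
    prev_rvda <- rv
  }
})
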