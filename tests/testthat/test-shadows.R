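test_that("MBCV threshold separates two pure modes and matches the scan oracle", {
  v <- c(rep(0, 500), rep(255, 500))
  thr <- mbcv_threshold(v)
  expect_gt(thr, 0); expect_lt(thr, 255)
  expect_true(all(v[v > thr] == 255))
  expect_true(all(v[v <= thr] == 0))
  expect_error(mbcv_threshold(rep(3, 10)), "constant")

  set.seed(41)
  for (rep in 1:4) {
    v <- c(rnorm(300, 60, 20), rnorm(200, 180, 25))
    lvl <- oracle_mbcv_level(v)
    rng <- range(v)
    expect_equal(mbcv_threshold(v),
                 rng[1] + (lvl + 1) / 256 * (rng[2] - rng[1]),
                 tolerance = 1e-10)
  }
})

test_that("MBCV agrees with an independent Otsu implementation", {
  set.seed(61)
  v <- c(rnorm(3000, 60, 12), rnorm(2000, 190, 18))
  v01 <- (v - min(v)) / (max(v) - min(v))
  ref <- EBImage::otsu(EBImage::Image(matrix(v01, 50, 100)),
                       range = c(0, 1), levels = 256)
  ours <- (mbcv_threshold(v) - min(v)) / (max(v) - min(v))
  expect_lt(abs(ours - ref), 1 / 256)
})

test_that("MBCV misclassifies < 1% of a well-separated Gaussian mixture", {
  set.seed(99)
  lab <- rep(c(0, 1), each = 5000)
  v <- c(rnorm(5000, 50, 10), rnorm(5000, 200, 10))
  thr <- mbcv_threshold(v)
  pred <- as.integer(v > thr)
  expect_lt(mean(pred != lab), 0.01)
})

test_that("shadow mask removes vegetation and water but keeps cast shadow", {
  spec <- random_scene_spec(n_buildings = 5, nrow = 140, ncol = 140,
                            seed = 12, n_patches = 1)
  r <- render_scene(spec)
  sc <- r$scene
  mask <- shadow_mask(msi(sc), compute_ndvi(sc), compute_ndwi(sc))
  ndwi <- compute_ndwi(sc)$values
  expect_true(all(!mask[ndwi > 0.3]))               # water removed
  ndvi <- compute_ndvi(sc)$values
  expect_true(all(!mask[ndvi > 0.5]))               # vegetation removed
  expect_gte(mean(mask[r$truth$shadow]), 0.95)      # shadows retained
})

test_that("component filter drops speckles and road-like strips", {
  m <- matrix(FALSE, 50, 80)
  m[5, 5] <- TRUE                # 1-pixel speckle (6.25 m2)
  m[20:21, 10:49] <- TRUE        # 2x40 road strip, lw = 20
  m[30:41, 30:37] <- TRUE        # 12x8 plausible shadow
  out <- component_filter(m, pixel_size = 2.5, min_area_m2 = 50,
                          max_lw_ratio = 8)
  expect_false(out[5, 5])
  expect_false(any(out[20:21, 10:49]))
  expect_true(all(out[30:41, 30:37]))
  expect_equal(sum(out), 12L * 8L)
})

test_that("CIIT route composes c3, local variance, threshold and filtering", {
  z <- matrix(100, 20, 20)
  flat <- msp_scene(z, z, z, z)
  # flat image: local variance is constant -> MBCV has no modes
  expect_error(mbcv_threshold(cpp_local_variance3(c3_index(flat)$values)),
               "constant")
  # step edge in blue only: variance (and hence the mask) localises there
  b2 <- z; b2[, 11:20] <- 220
  sc <- msp_scene(b2, z, z, z)
  v <- cpp_local_variance3(c3_index(sc)$values)
  expect_true(all(v[, c(1:8, 13:20)] < max(v) / 2))
  # stage-by-stage composition equals the pipeline call
  spec <- random_scene_spec(n_buildings = 4, nrow = 120, ncol = 120, seed = 6)
  scn <- render_scene(spec)$scene
  m1 <- ciit_shadow(scn)
  v2 <- cpp_local_variance3(c3_index(scn)$values)
  m2 <- component_filter(
    shadow_mask(v2, compute_ndvi(scn), compute_ndwi(scn)),
    scn$pixel_size, 50, 8)
  expect_equal(m1, m2)
})

test_that("shadow length follows the scan-line geometry", {
  solar <- solar_geometry(68.68, 180)   # shadow due north
  g <- expand.grid(row = 11:20, col = 5:8)  # 10 pixels long, 4 wide
  sl <- dasypop:::scanline_lengths(g$row, g$col, solar, 2.5)
  expect_equal(sl, rep(25, 4))
  expect_equal(dasypop:::scanline_lengths(5, 5, solar, 2.5), 2.5)

  # rotated rectangular shadow at 30 degrees: median line length within one
  # pixel of the true side length
  th <- 30 * pi / 180
  gg <- expand.grid(u = seq(0, 20, by = 0.25), v = seq(0, 5, by = 0.25))
  rows <- round(40 - gg$u * cos(th) + gg$v * sin(th))
  cols <- round(10 + gg$u * sin(th) + gg$v * cos(th))
  pix <- unique(cbind(rows, cols))
  sol30 <- solar_geometry(60, (30 + 180) %% 360)  # shadow direction 30 deg
  L <- stats::median(dasypop:::scanline_lengths(pix[, 1], pix[, 2], sol30, 2.5))
  expect_lt(abs(L - 21 * 2.5), 2.5)
})

test_that("height model is H = L tan(beta), monotone and exact at 45 deg", {
  expect_equal(building_height(0, solar_geometry(50, 0)), 0)
  expect_equal(building_height(10, solar_geometry(45, 0)), 10)
  expect_equal(building_height(5, solar_geometry(68.68, 0)), 12.8111,
               tolerance = 1e-4)
  L <- seq(0, 30, by = 5)
  H <- building_height(L, solar_geometry(68.68, 0))
  expect_true(all(diff(H) > 0))
  betas <- c(10, 30, 45, 60, 80)
  Hb <- sapply(betas, function(b) building_height(10, solar_geometry(b, 0)))
  expect_true(all(diff(Hb) > 0))
  expect_error(building_height(5, list(altitude_deg = 95)), "solar_geometry")
})

test_that("height assignment anchors at the sun side and interpolates", {
  solar <- solar_geometry(45, 180)
  # one building, one adjacent shadow of L = 10 m -> BH = 10
  mask <- matrix(FALSE, 30, 30)
  mask[11:14, 10:15] <- TRUE   # 4 rows x 6 cols; L = 4 * 2.5 = 10
  comps <- shadow_components(mask, solar, 2.5)
  expect_equal(comps$L, 10)
  # sun-side anchor is on the southern (building-facing) edge
  expect_equal(comps$anchor_row, 13.5)
  b <- data.frame(centroid_row = 17, centroid_col = 12.5)
  b <- assign_heights(b, comps, solar, 2.5)
  expect_equal(b$BH_m, 10)

  # two buildings equidistant from two samples of 8 and 12 m -> midpoint 10
  comps2 <- comps[c(1, 1), ]
  comps2$L <- c(8, 12)
  comps2$anchor_row <- c(10, 10); comps2$anchor_col <- c(0, 20)
  b2 <- data.frame(centroid_row = c(10, 10), centroid_col = c(10, 10))
  b2 <- assign_heights(b2, comps2, solar, 2.5)
  expect_equal(b2$BH_m, c(10, 10))

  expect_warning(
    b3 <- assign_heights(b2, comps[0, ], solar, 2.5, default_height_m = 7),
    "no shadow")
  expect_equal(b3$BH_m, c(7, 7))
})

test_that("height error table bins at 2.5 m and reproduces the printed split", {
  t0 <- height_error_table(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t0$table$count[t0$table$bin == "[0, 2.5)"], 3L)
  expect_equal(t0$rmse, 0)

  # printed CIIT error distribution: counts -> percentages
  counts <- c(208, 124, 93, 66, 58, 25)
  pct <- 100 * counts / 574
  expect_equal(round(pct, 2), c(36.24, 21.60, 16.20, 11.50, 10.10, 4.36))

  set.seed(55)
  err <- runif(200, 0, 15)
  ht <- height_error_table(err, rep(0, 200))
  manual <- table(cut(err, c(0, 2.5, 5, 7.5, 10, 12.5, Inf), right = FALSE))
  expect_equal(ht$table$count, as.integer(manual))
  expect_equal(ht$rmse, sqrt(mean(err^2)))
})
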