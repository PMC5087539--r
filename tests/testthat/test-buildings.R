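test_that("shape descriptors match hand counts", {
  sq <- expand.grid(row = 1:4, col = 1:4)
  expect_equal(shape_index(sq$row, sq$col), 1)          # 16 / (4 * 4)
  rect <- expand.grid(row = 1:2, col = 1:8)
  expect_equal(shape_index(rect$row, rect$col), 1.25)   # 20 / (4 * 4)
  line <- expand.grid(row = 1, col = 1:10)
  expect_equal(shape_index(line$row, line$col), 22 / (4 * sqrt(10)))

  expect_equal(length_width_ratio(sq$row, sq$col), 1)
  r39 <- expand.grid(row = 1:9, col = 1:3)
  expect_equal(length_width_ratio(r39$row, r39$col), 3)

  expect_equal(rectangular_fit(sq$row, sq$col), 1)
  # plus-shaped pentomino vs a direct enumeration oracle: dense-angle
  # minimum-area box, equal-area rectangle at the centroid, count of pixel
  # centres inside
  plus <- rbind(c(1, 2), c(2, 1), c(2, 2), c(2, 3), c(3, 2))
  oracle_rf <- function(rows, cols) {
    x <- c(cols - 1, cols, cols - 1, cols)
    y <- c(rows - 1, rows - 1, rows, rows)
    best <- Inf; ang <- 0; asp <- 1
    for (a in seq(0, 90, by = 0.05) * pi / 180) {
      du <- diff(range(x * cos(a) + y * sin(a)))
      dv <- diff(range(-x * sin(a) + y * cos(a)))
      if (du * dv < best) {
        best <- du * dv
        ang <- if (du >= dv) a else a + pi / 2
        asp <- max(du, dv) / min(du, dv)
      }
    }
    n <- length(rows)
    w <- sqrt(n / asp); l <- asp * w
    cx <- mean(cols - 0.5); cy <- mean(rows - 0.5)
    pu <- (cols - 0.5 - cx) * cos(ang) + (rows - 0.5 - cy) * sin(ang)
    pv <- -(cols - 0.5 - cx) * sin(ang) + (rows - 0.5 - cy) * cos(ang)
    sum(abs(pu) <= l / 2 & abs(pv) <= w / 2) / n
  }
  rf <- rectangular_fit(plus[, 1], plus[, 2])
  expect_equal(rf, oracle_rf(plus[, 1], plus[, 2]))
  expect_gt(rf, 0)
  # L-shape is strictly below 1
  L <- rbind(c(1, 1), c(2, 1), c(3, 1), c(3, 2), c(3, 3))
  expect_lt(rectangular_fit(L[, 1], L[, 2]), 1)
})

test_that("length/width ratio agrees with a dense angle-sweep oracle", {
  set.seed(31)
  for (rep in 1:4) {
    # random convex-ish blob: pixels inside a random ellipse
    a <- runif(1, 3, 8); b <- runif(1, 2, a)
    th <- runif(1, 0, pi)
    g <- expand.grid(row = 1:20, col = 1:20)
    x <- (g$col - 10.5) * cos(th) + (g$row - 10.5) * sin(th)
    y <- -(g$col - 10.5) * sin(th) + (g$row - 10.5) * cos(th)
    keep <- (x / a)^2 + (y / b)^2 <= 1
    rows <- g$row[keep]; cols <- g$col[keep]
    expect_equal(length_width_ratio(rows, cols),
                 oracle_lw_ratio(rows, cols), tolerance = 0.02)
  }
})

test_that("classification applies every rule conjunctively and monotonically", {
  rules <- classification_rules("MBI")
  obj <- data.frame(mean_index = 7, mean_brightness = 150, mean_ndvi = 0,
                    lw_ratio = 2, rect_fit = 0.9, shape_index = 1.2)
  expect_true(classify_buildings(obj, rules)$building)
  bad <- obj; bad$mean_ndvi <- 0.3
  expect_false(classify_buildings(bad, rules)$building)

  # sweep: conjunction oracle over randomised feature vectors
  set.seed(17)
  objs <- data.frame(mean_index = runif(50, 0, 12),
                     mean_brightness = runif(50, 0, 255),
                     mean_ndvi = runif(50, -0.5, 0.5),
                     lw_ratio = runif(50, 1, 6),
                     rect_fit = runif(50, 0.2, 1),
                     shape_index = runif(50, 1, 4))
  got <- classify_buildings(objs, rules)$building
  want <- objs$mean_index >= 6 & objs$mean_brightness >= 136 &
    objs$mean_ndvi < 0.1 & objs$lw_ratio >= 1.5 & objs$lw_ratio <= 4.5 &
    objs$rect_fit >= 0.6 & objs$shape_index <= 2.6
  expect_identical(got, want)
  # relaxing a threshold never removes a labelled building
  relaxed <- classification_rules("MBI", index_min = 4, brightness_min = 100,
                                  ndvi_max = 0.2, lw_ratio_range = c(1, 5),
                                  rect_fit_min = 0.5, shape_index_max = 3)
  expect_true(all(classify_buildings(objs, relaxed)$building[want]))
})

test_that("segmentation finds the rendered objects", {
  sc <- toy_scene(30, 30, rects = list(c(4, 9, 4, 9), c(18, 25, 15, 22)))
  idx <- index_raster((compute_brightness(sc)$values > 100) * 10, "MBI")
  objs <- segment_objects(sc, idx, classification_rules("MBI", index_min = 5))
  expect_equal(nrow(objs), 2L)
  expect_equal(sort(objs$n_pixels), c(36L, 64L))
  expect_equal(objs$area_m2, objs$n_pixels * 2.5^2)

  none <- segment_objects(sc, index_raster(matrix(0, 30, 30), "MBI"),
                          classification_rules("MBI", index_min = 5))
  expect_equal(nrow(none), 0L)
})

test_that("hole filling closes small enclosed holes only, never merging", {
  m <- matrix(FALSE, 12, 12)
  m[3:9, 3:9] <- TRUE
  expect_equal(fill_holes(m, 5), m)          # solid mask unchanged
  ring <- m; ring[5:7, 5:7] <- FALSE
  expect_equal(fill_holes(ring, 5), m)       # 3x3 hole filled
  big <- matrix(FALSE, 15, 15)
  big[2:14, 2:14] <- TRUE; big[4:12, 4:12] <- FALSE  # 9x9 hole > box
  expect_equal(fill_holes(big, 5), big)
  # never shrinks
  set.seed(2)
  rnd <- matrix(runif(400) > 0.6, 20, 20)
  filled <- fill_holes(rnd, 5)
  expect_true(all(filled[rnd]))
  # a gap between two distinct objects is not filled
  two <- matrix(FALSE, 9, 9)
  two[2:8, 2:4] <- TRUE; two[2:8, 6:8] <- TRUE
  expect_equal(fill_holes(two, 5), two)
})

test_that("residential refinement keeps nearest-residential buildings", {
  b <- data.frame(x = c(0, 100), y = c(0, 0))
  pois <- data.frame(x = c(10, 120, 140), y = c(0, 0, 0),
                     category = c("residential", "commercial", "residential"))
  kept <- refine_residential(b, pois, radius_m = 50)
  # building 1: nearest POI at 10 m is residential -> kept
  # building 2: nearest POI at 20 m is commercial (residential at 40 m) -> dropped
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$x, 0)
  expect_warning(out <- refine_residential(b, pois[0, ], 50), "empty POI")
  expect_equal(nrow(out), 0L)

  # agreement with an exhaustive nearest-neighbour scan on a random layout
  set.seed(23)
  b <- data.frame(x = runif(30, 0, 500), y = runif(30, 0, 500))
  pois <- data.frame(x = runif(40, 0, 500), y = runif(40, 0, 500),
                     category = sample(c("residential", "commercial",
                                         "financial"), 40, replace = TRUE))
  kept <- refine_residential(b, pois, 80)
  want <- sapply(seq_len(30), function(i) {
    d <- sqrt((pois$x - b$x[i])^2 + (pois$y - b$y[i])^2)
    j <- which.min(d)
    d[j] <= 80 && pois$category[j] == "residential"
  })
  expect_equal(nrow(kept), sum(want))
})
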