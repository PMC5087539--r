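test_that("GLCM matches hand enumeration on tiny windows", {
  # constant window: all mass at P(c, c)
  g <- glcm(matrix(3L, 2, 2), c(0, 1), levels = 8)
  expect_equal(unclass(g)[4, 4], 1)
  expect_equal(sum(g), 1)

  # [[0,1],[0,1]] horizontally: the two pairs are (0,1) and (0,1)
  w <- rbind(c(0L, 1L), c(0L, 1L))
  g <- glcm(w, c(0, 1), levels = 2)
  expect_equal(unclass(g), matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # symmetrised GLCM equals that of the mirrored window at the opposite
  # displacement
  set.seed(2)
  w <- matrix(sample(0:3, 25, replace = TRUE), 5, 5)
  g1 <- glcm(w, c(0, 1), levels = 4)
  g2 <- glcm(w[, 5:1], c(0, -1), levels = 4)
  expect_equal(unclass(g1), unclass(g2))

  expect_error(glcm(matrix(0L, 1, 1), c(0, 1), levels = 2), "no co-occurring")
})

test_that("GLCM and contrast agree with the brute-force pair oracle", {
  set.seed(7)
  for (rep in 1:5) {
    w <- matrix(sample(0:7, 25, replace = TRUE), 5, 5)
    d <- rbind(c(0, 1), c(1, 0), c(1, 1), c(2, -1))[sample(4, 1), ]
    p <- glcm(w, d, levels = 8)
    expect_equal(unclass(p), oracle_glcm(w, d, 8))
    expect_equal(glcm_contrast(p), oracle_contrast(oracle_glcm(w, d, 8)))
  }
  # two-level checkerboard-ish window: all co-occurring pairs differ by one
  w <- rbind(c(0L, 1L), c(0L, 1L))
  expect_equal(glcm_contrast(glcm(w, c(0, 1), levels = 2)), 1)
  expect_equal(glcm_contrast(glcm(matrix(5L, 3, 3), c(1, 0), levels = 8)), 0)
})

test_that("PanTex raster equals the direct per-window oracle", {
  set.seed(21)
  img <- matrix(sample(0:15, 225, replace = TRUE), 15, 15)
  cfg <- glcm_config(levels = 16, window_size = 7)
  got <- pantex_raster(img, cfg, quantize = FALSE)$values
  want <- oracle_pantex(img, 7, cfg$displacements, 16)
  expect_equal(got, want)
})

test_that("PanTex invariants: constancy, locality, rotation, gray shifts", {
  cfg <- glcm_config(levels = 16, window_size = 5)
  expect_equal(pantex_raster(matrix(7L, 12, 12), cfg, quantize = FALSE)$values,
               matrix(0, 12, 12))

  # a single bright pixel only influences pixels within window reach
  img <- matrix(1L, 15, 15); img[8, 8] <- 14L
  p <- pantex_raster(img, cfg, quantize = FALSE)$values
  far <- p[abs(row(p) - 8) > 3 & abs(col(p) - 8) > 3]
  expect_true(all(far == 0))
  expect_gt(p[8, 8], 0)

  # default displacement set is closed under 90-degree rotation (up to sign)
  set.seed(4)
  img <- matrix(sample(0:15, 144, replace = TRUE), 12, 12)
  p1 <- pantex_raster(img, cfg, quantize = FALSE)$values
  rot <- t(img)[ncol(img):1, ]           # 90-degree rotation
  p2 <- pantex_raster(rot, cfg, quantize = FALSE)$values
  expect_equal(p2, t(p1)[ncol(p1):1, ])

  # constant gray offset without requantisation leaves PanTex unchanged
  p3 <- pantex_raster(img + 1L, glcm_config(levels = 17, window_size = 5),
                      quantize = FALSE)$values
  expect_equal(p3, p1)
})

test_that("glcm_config rejects degenerate displacement sets", {
  expect_error(glcm_config(displacements = rbind(c(0, 0), c(0, 1))),
               "non-zero")
  expect_error(glcm_config(displacements = rbind(c(0, 1), c(0, -1))),
               "distinct")
  expect_error(pantex_raster(matrix(0L, 3, 3),
                             glcm_config(levels = 4, window_size = 5),
                             quantize = FALSE),
               "window larger")
})
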