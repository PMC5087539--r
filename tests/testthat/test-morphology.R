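test_that("linear structuring elements rasterise correctly", {
  expect_equal(nrow(linear_se(1, 0)), 1L)
  h <- linear_se(3, 0)
  expect_setequal(h[, "dcol"], -1:1)
  expect_true(all(h[, "drow"] == 0))
  v <- linear_se(3, 90)
  expect_setequal(v[, "drow"], -1:1)
  d <- linear_se(5, 45)
  expect_equal(nrow(d), 5L)
  # a 45-degree digital line: |drow| == |dcol| on every pixel
  expect_true(all(abs(d[, "drow"]) == abs(d[, "dcol"])))
  expect_equal(sort(d[, "dcol"]), -2:2)
})

test_that("opening/closing by reconstruction match the fixpoint oracle", {
  # flat image is a fixed point
  flat <- matrix(5, 6, 6)
  se <- linear_se(3, 0)
  expect_equal(opening_by_reconstruction(flat, se), flat)
  expect_equal(closing_by_reconstruction(flat, se), flat)

  # bright 3x3 square vs a horizontal SE of length 7: fully removed
  img <- matrix(10, 10, 10); img[4:6, 4:6] <- 50
  op <- opening_by_reconstruction(img, linear_se(7, 0))
  expect_equal(op, matrix(10, 10, 10))

  set.seed(13)
  for (rep in 1:4) {
    img <- matrix(sample(0:20, 144, replace = TRUE), 12, 12)
    se <- linear_se(sample(c(3, 5), 1), sample(c(0, 45, 90, 135), 1))
    marker <- erode_flat(img, se)
    expect_equal(cpp_reconstruct_dilate(marker, img),
                 oracle_reconstruct(marker, img))
    # anti-extensivity / extensivity
    expect_true(all(opening_by_reconstruction(img, se) <= img))
    expect_true(all(closing_by_reconstruction(img, se) >= img))
  }
})

test_that("top-hats isolate small structures and ignore offsets", {
  expect_equal(white_top_hat(matrix(3, 8, 8), 5, 0), matrix(0, 8, 8))
  img <- matrix(10, 12, 12); img[5:7, 5:7] <- 60
  th <- white_top_hat(img, 9, 0)
  expect_equal(th[6, 6], 50)
  expect_equal(th[1, 1], 0)
  # additive invariance
  expect_equal(white_top_hat(img + 17, 9, 0), th)
  # black top-hat of b equals white top-hat of the inverted image
  set.seed(3)
  img <- matrix(runif(100, 0, 255), 10, 10)
  expect_equal(black_top_hat(img, 5, 45),
               white_top_hat(255 - img, 5, 45))
})

test_that("MBI/MSI scale list, positivity and duality", {
  cfg <- morph_config()
  expect_equal(cfg$scales, c(2, 9, 16, 23, 30, 37, 44, 51, 58, 65))
  expect_equal(cfg$S, 10L)
  expect_error(morph_config(s_min = 2, s_max = 10, delta_s = 3), "multiple")
  expect_error(mbi(matrix(1, 4, 4), morph_config(s_min = 2, s_max = 2,
                                                 delta_s = 1)),
               "at least two scales")

  small <- morph_config(s_min = 2, s_max = 8, delta_s = 3)
  z <- matrix(42, 16, 16)
  expect_equal(mbi(z, small)$values, matrix(0, 16, 16))
  expect_equal(msi(z, small)$values, matrix(0, 16, 16))

  set.seed(8)
  b <- matrix(runif(256, 0, 255), 16, 16)
  m1 <- mbi(b, small)$values
  expect_true(all(m1 >= 0))
  # additive brightness invariance
  expect_equal(mbi(b + 30, small)$values, m1)
  # duality: MSI(b) = MBI(max - b)
  expect_equal(msi(b, small)$values, mbi(max(b) - b, small)$values)
})

test_that("compact bright blobs give positive MBI, flats give zero", {
  cfg <- morph_config(s_min = 2, s_max = 14, delta_s = 4)
  img <- matrix(50, 30, 30)
  img[10:13, 10:13] <- 220   # 4x4 blob smaller than s_max in every direction
  m <- mbi(img, cfg)$values
  expect_gt(m[11, 11], 0)
  expect_equal(m[25, 25], 0)
  s <- msi(img, cfg)$values
  expect_equal(s[11, 11], 0)  # bright blob is invisible to the shadow index
  img2 <- matrix(50, 30, 30); img2[20:22, 20:22] <- 5
  expect_gt(msi(img2, cfg)$values[21, 21], 0)
})
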