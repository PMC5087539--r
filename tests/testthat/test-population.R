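test_that("zone parameters are ratios of totals, not means of ratios", {
  expect_equal(estimate_la(data.frame(A = c(100, 50), P = c(4, 2))), 25)
  expect_equal(estimate_la(data.frame(A = 30, P = 1)), 30)
  set.seed(3)
  s <- data.frame(A = runif(50, 20, 200), P = sample(1:6, 50, TRUE))
  expect_equal(estimate_la(s), sum(s$A) / sum(s$P))
  expect_error(estimate_la(data.frame(A = 1, P = 0)), "positive")

  expect_equal(estimate_ah(data.frame(H = c(33, 18), RH = c(3, 3),
                                      F = c(10, 5))), 3)
  expect_equal(estimate_ah(data.frame(H = 33, RH = 3, F = 10)), 3)
  set.seed(4)
  s <- data.frame(F = sample(2:20, 30, TRUE))
  s$RH <- runif(30, 1, 4); s$H <- s$RH + s$F * runif(30, 2.5, 3.5)
  expect_equal(estimate_ah(s), sum(s$H - s$RH) / sum(s$F))
  expect_error(estimate_ah(data.frame(H = 2, RH = 3, F = 1)), "RH")
})

test_that("raw population is floor-space times real-valued floors", {
  expect_equal(raw_population(1000, 30, 25, 3), 400)
  expect_equal(raw_population(25, 3, 25, 3), 1)
  expect_equal(raw_population(500, 0, 25, 3), 0)
  # linearity in building volume: doubling BH doubles the estimate
  set.seed(6)
  FS <- runif(20, 100, 2000); BH <- runif(20, 3, 60)
  expect_equal(raw_population(FS, 2 * BH, 30, 3),
               2 * raw_population(FS, BH, 30, 3))
  expect_equal(raw_population(1000, 31, 25, 3, round_floors = TRUE),
               (1000 / 25) * 10)
})

test_that("volume constraint preserves the census total exactly", {
  r <- apply_volume_constraint(c(100, 100), 220)
  expect_equal(r$C, 10)
  expect_equal(r$population, c(110, 110))

  r0 <- apply_volume_constraint(c(60, 40), 100)
  expect_equal(r0$C, 0)
  expect_equal(r0$population, c(60, 40))

  # clamp path: the uniform constant would push the small building negative
  r2 <- apply_volume_constraint(c(1, 500), 400)
  expect_true(all(r2$population >= 0))
  expect_equal(sum(r2$population), 400)
  # iterative-clamp oracle
  oracle <- local({
    pop <- c(1, 500) + (400 - 501) / 2
    for (i in 1:10) {
      if (all(pop >= 0)) break
      pop[pop < 0] <- 0
      pos <- pop > 0
      pop[pos] <- pop[pos] + (400 - sum(pop)) / sum(pos)
    }
    pop * 400 / sum(pop)
  })
  expect_equal(r2$population, oracle)

  set.seed(12)
  for (rep in 1:5) {
    raw <- runif(sample(3:40, 1), 0, 50)
    total <- runif(1, 0, 2 * sum(raw))
    res <- apply_volume_constraint(raw, total)
    expect_true(all(res$population >= 0))
    expect_lt(abs(sum(res$population) - total), 1e-6 * max(total, 1))
  }
  expect_error(apply_volume_constraint(c(1, 2), -5), "non-negative")
})

test_that("epsilon is the per-zone least-squares (mean) residual", {
  expect_equal(unname(fit_epsilon(numeric(0), numeric(0), character(0),
                                  zones = c("a", "b"))), c(0, 0))
  eps <- fit_epsilon(c(12, 22), c(10, 20), c("a", "a"), zones = c("a", "b"))
  expect_equal(unname(eps), c(2, 0))
  set.seed(8)
  obs <- rnorm(30, 100, 5); mod <- rnorm(30, 98, 5)
  z <- sample(c("a", "b", "c"), 30, TRUE)
  eps <- fit_epsilon(obs, mod, z)
  for (zz in unique(z))
    expect_equal(unname(eps[zz]), mean((obs - mod)[z == zz]))
})

test_that("unit aggregation partitions the total", {
  set.seed(10)
  pop <- runif(100, 0, 20)
  unit <- sample(1:7, 100, TRUE)
  agg <- aggregate_to_units(pop, unit)
  expect_equal(sum(agg), sum(pop))
  expect_equal(unname(agg["3"]), sum(pop[unit == 3]))
  one <- aggregate_to_units(pop, rep(1, 100))
  expect_equal(unname(one), sum(pop))
})

test_that("the full population model satisfies the pycnophylactic property", {
  set.seed(20)
  b <- data.frame(FS_m2 = runif(60, 200, 1500), BH_m = runif(60, 6, 45),
                  zone = sample(c("high", "low"), 60, TRUE),
                  unit = sample(1:5, 60, TRUE))
  zones <- data.frame(zone = c("high", "low"), LA = c(20, 40), AH = c(2.8, 3.2))
  est <- estimate_population(b, zones, census_total = 5000)
  expect_lt(abs(sum(est$buildings$population) - 5000), 1e-6 * 5000)
  expect_true(all(est$buildings$population >= 0))
  expect_equal(sum(est$unit_totals), 5000)

  # survey-driven epsilon shifts zone members before the constraint
  survey <- data.frame(building = 1:10, observed = est$buildings$population[1:10] + 3)
  est2 <- estimate_population(b, zones, 5000, survey = survey)
  expect_lt(abs(sum(est2$buildings$population) - 5000), 1e-6 * 5000)
  out <- capture.output(print(est2))
  expect_true(any(grepl("volume-preserving constant", out)))
})
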