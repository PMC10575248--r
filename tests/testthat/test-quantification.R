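vd100 <- dropletVolumeUl(100)

test_that("droplet volume follows the sphere formula", {
  expect_equal(vd100, pi / 6 * 1e6 * 1e-9)
  expect_equal(vd100, 5.236e-4, tolerance = 1e-4)
  expect_equal(dropletVolumeUl(200) / vd100, 8)
})

test_that("the threshold is twice the negative-control signal", {
  expect_equal(negativeThreshold(rep(0.1, 5)), 0.2)
  expect_equal(negativeThreshold(c(0.05, 0.15)), 0.2)
  # the factor is exactly 2 at any scale
  set.seed(40)
  neg <- runif(50, 0.01, 0.2)
  for (c in c(0.5, 2, 7))
    expect_equal(negativeThreshold(c * neg), c * negativeThreshold(neg))
  expect_equal(negativeThreshold(c(0.05, 0.5), statistic = "median"),
               2 * median(c(0.05, 0.5)))
  expect_error(negativeThreshold(numeric(0)), "empty")
})

test_that("classification is strict and counts are consistent", {
  ds <- new("DropletSet", droplets = data.frame(
    droplet_id = 1:6, diameter_um = 100,
    luminance = c(0.05, 0.1, 0.100001, 0.3, 0.5, 0.09),
    label = "unclassified"), umPerPx = 0.5)
  cl <- classifyDroplets(ds, 0.1)
  expect_equal(cl@nTotal, 6L)
  expect_equal(cl@nPositive, 3L)  # 0.1 itself is negative (ties negative)
  expect_equal(cl@fractionPositive, 0.5)
  expect_equal(droplets(cl@droplets)$label,
               c("negative", "negative", "positive", "positive",
                 "positive", "negative"))
  all_lo <- classifyDroplets(ds, 1)
  expect_equal(all_lo@nPositive, 0L)
  expect_equal(all_lo@fractionPositive, 0)
  all_hi <- classifyDroplets(ds, 0.01)
  expect_equal(all_hi@fractionPositive, 1)
})

test_that("the Poisson pmf matches the closed form and normalises", {
  expect_equal(poissonPmf(0, 3), exp(-3))
  expect_equal(poissonPmf(1, 1), exp(-1))
  expect_equal(poissonPmf(1, 1), 0.3679, tolerance = 1e-4)
  expect_equal(poissonPmf(0, 0), 1)
  expect_equal(sum(poissonPmf(0:50, 3)), 1, tolerance = 1e-12)
  # independent cross-check against the stats implementation
  set.seed(41)
  for (lam in c(0.005, 0.5, 5)) {
    k <- 0:20
    expect_equal(poissonPmf(k, lam), dpois(k, lam), tolerance = 1e-12)
  }
  expect_error(poissonPmf(-1, 1), "non-negative")
  expect_error(poissonPmf(2, -1), ">= 0")
})

test_that("the expected positive fraction follows 1 - exp(-C V)", {
  expect_equal(expectedFraction(0, vd100), 0)
  # the low end of the assay's measured range: ~0.005 at 10 copies/uL
  expect_equal(expectedFraction(10, vd100), 0.0052, tolerance = 2e-2)
  expect_lt(abs(expectedFraction(10, vd100) - 0.005), 5e-4)
  # monotone saturation towards 1
  cs <- 10^(0:6)
  fp <- expectedFraction(cs, vd100)
  expect_true(all(diff(fp) >= 0))
  expect_true(all(diff(fp[1:5]) > 0))   # strictly rising below saturation
  expect_gt(fp[7], 0.999999)
  expect_error(expectedFraction(-1, vd100), ">= 0")
})

test_that("concentration estimation inverts the Poisson relation", {
  expect_equal(concentration(estimateConcentration(0, 1000, vd100)), 0)
  est <- estimateConcentration(52, 10000, vd100)
  expect_equal(concentration(est), -log(1 - 0.0052) / vd100)
  expect_equal(concentration(est), 9.96, tolerance = 1e-3)
  # round trip with the forward model
  expect_equal(expectedFraction(concentration(est), vd100), 0.0052)
  expect_error(estimateConcentration(10, 10, vd100), "aturat")
  expect_error(estimateConcentration(1, 0, vd100), "nTotal")
  # monotone in N_P; halving V_d doubles the estimate
  cs <- vapply(c(10, 50, 100, 400), function(np)
    concentration(estimateConcentration(np, 1000, vd100)), 0)
  expect_true(all(diff(cs) > 0))
  expect_equal(concentration(estimateConcentration(100, 1000, vd100 / 2)),
               2 * concentration(estimateConcentration(100, 1000, vd100)))
})

test_that("round trip holds across the assay's dynamic range", {
  nT <- 20000
  for (co in 10^(0:4)) {
    np <- round(expectedFraction(co, vd100) * nT)
    if (np == 0 || np == nT) next
    rec <- concentration(estimateConcentration(np, nT, vd100))
    # one-count discretisation bound: dC = 1 / ((1 - f_p) N_T V_d)
    expect_lt(abs(rec - co), 1 / ((1 - np / nT) * nT * vd100))
  }
})

test_that("Clopper-Pearson intervals are exact, monotone and cover", {
  ci <- concentrationInterval(0, 1000, vd100)
  expect_equal(unname(ci["low"]), 0)
  # cross-check the f_p bounds against binom.test
  for (np in c(1, 17, 430)) {
    bt <- as.numeric(binom.test(np, 1000)$conf.int)
    ci <- concentrationInterval(np, 1000, vd100)
    expect_equal(unname(ci), -log(1 - bt) / vd100, tolerance = 1e-9)
  }
  # bounds monotone in N_P
  lows <- highs <- numeric(0)
  for (np in c(5, 20, 80, 320)) {
    ci <- concentrationInterval(np, 1000, vd100)
    lows <- c(lows, ci["low"]); highs <- c(highs, ci["high"])
  }
  expect_true(all(diff(lows) > 0) && all(diff(highs) > 0))
  # saturated upper bound is infinite
  expect_equal(unname(concentrationInterval(10, 10, vd100)["high"]), Inf)
  # empirical coverage at the assay's low end (lambda = 0.005)
  set.seed(42)
  lam <- 0.005; co <- lam / vd100; nT <- 2000
  fp <- expectedFraction(co, vd100)
  cover <- 0; nrep <- 1000
  for (r in seq_len(nrep)) {
    np <- rbinom(1, nT, fp)
    ci <- concentrationInterval(np, nT, vd100)
    cover <- cover + (ci["low"] <= co && co <= ci["high"])
  }
  expect_gte(cover / nrep, 0.95)
})
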