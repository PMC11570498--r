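frap_trace <- function(A = 0.8, k = log(2) / 131, n_pre = 10, n_post = 30,
                       t_max = 600, bleach_depth = 0.7, drift = 0,
                       background = 50, noise = 0) {
  t_pre <- seq(-n_pre, -1)
  t_post <- seq(0, t_max, length.out = n_post)
  t <- c(t_pre, t_post)
  truth <- c(rep(1, n_pre), (1 - bleach_depth) + A * (1 - exp(-k * t_post)))
  ref <- 1000 * (1 - drift * (seq_along(t) - 1) / length(t))
  bleached <- background + truth * ref +
    if (noise > 0) stats::rnorm(length(t), 0, noise) else 0
  data.frame(t = t, bleached = bleached, unbleached = background + ref,
             background = background)
}

test_that("FRAP normalization yields unit pre-bleach mean and removes drift", {
  # constant trace, no bleach: flat 1.0
  flat <- data.frame(t = -5:20, bleached = 600, unbleached = 600,
                     background = 100)
  norm <- normalizeFrap(flat)
  expect_equal(norm$intensity, rep(1, 26))

  # 20% photobleach drift in the reference divides out; k recovered within 1%
  k_true <- log(2) / 131
  tr <- frap_trace(drift = 0.2)
  norm <- normalizeFrap(tr)
  expect_equal(mean(norm$intensity[norm$t < 0]), 1, tolerance = 1e-9)
  post <- norm[norm$t >= 0, ]
  fit <- fitFrap(post$t, post$intensity - min(post$intensity), nBoot = 0)
  expect_equal(fitParams(fit)[["k"]], k_true, tolerance = 0.01)

  # zero background, constant reference: output proportional to bleached
  tr0 <- frap_trace(background = 0)
  norm0 <- normalizeFrap(tr0)
  expect_equal(norm0$intensity / norm0$intensity[1],
               tr0$bleached / tr0$bleached[1])

  expect_error(normalizeFrap(data.frame(t = 0:5, bleached = 1,
                                        unbleached = 1, background = 0)),
               "pre-bleach")
  suppressWarnings(
    expect_error(normalizeFrap(data.frame(t = -2:2, bleached = 5,
                                          unbleached = 1, background = 2)),
                 "reference")
  )
  expect_warning(normalizeFrap(data.frame(t = -2:10, bleached = 500,
                                          unbleached = 600,
                                          background = 10)),
                 "fewer than 5")
})

test_that("the exponential recovery fit recovers its generating parameters", {
  A <- 0.8; k <- log(2) / 131
  t <- seq(0, 600, length.out = 30)
  fit <- fitFrap(t, A * (1 - exp(-k * t)), nBoot = 0)
  # half-maximal recovery time to 4 significant digits
  expect_equal(fitDerived(fit)[["T0.5"]], 131, tolerance = 1e-4)
  expect_equal(fitParams(fit)[["A"]], A, tolerance = 1e-6)
  # y(T0.5) = A/2 on the fitted curve, by definition of T0.5
  p <- fitParams(fit)
  t_half <- fitDerived(fit)[["T0.5"]]
  expect_equal(p[["A"]] * (1 - exp(-p[["k"]] * t_half)), p[["A"]] / 2)
  expect_error(fitFrap(t, rep(0.5, 30), nBoot = 0), "flat")
  expect_error(fitFrap(t[1:3], c(1, 2, 3), nBoot = 0))
})

test_that("noisy FRAP replicates recover k with small median error", {
  set.seed(99)
  k <- log(2) / 131
  t <- seq(0, 600, length.out = 30)
  err <- vapply(1:200, function(r) {
    y <- 0.8 * (1 - exp(-k * t)) + stats::rnorm(30, 0, 0.02 * 0.8)
    abs(fitParams(fitFrap(t, y, nBoot = 0))[["k"]] - k) / k
  }, 0)
  expect_lt(stats::median(err), 0.05)
})

test_that("the occupancy fit recovers KD and honours the Hill form", {
  x <- c(0.05, 0.1, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 128)
  y <- 100 * x / (1.21 + x)
  fit <- fitHill(x, y, nBoot = 0)
  expect_equal(fitParams(fit)[["KD"]], 1.21, tolerance = 1e-6)
  expect_equal(fitParams(fit)[["Bmax"]], 100, tolerance = 1e-6)
  expect_equal(fitDerived(fit)[["K0.5"]], fitParams(fit)[["KD"]])
  # y at x = KD equals Bmax/2 on the fitted curve
  p <- fitParams(fit)
  expect_equal(p[["Bmax"]] * p[["KD"]] / (p[["KD"]] + p[["KD"]]),
               p[["Bmax"]] / 2)
  # normalized output as plotted for SPR
  fitn <- fitHill(x, y, nBoot = 0, normalize = TRUE)
  expect_equal(max(attr(fitn, "normalized")), max(y) / p[["Bmax"]])
  expect_error(fitHill(x, rep(0, 12), nBoot = 0), "all-zero")
  expect_error(fitHill(c(-1, 1, 2), c(1, 2, 3), nBoot = 0), "concentration")
  xa <- c(2, 4, 8, 16)  # all above the apparent midpoint
  expect_warning(fitHill(xa, 100 * xa / (1.21 + xa), nBoot = 0), "midpoint")
})

test_that("noisy binding replicates give small bias and calibrated bootstrap CIs", {
  set.seed(99)
  x <- c(0.05, 0.1, 0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 128)
  kd <- 1.21
  rel <- numeric(200); cov <- logical(200)
  for (r in 1:200) {
    y <- 100 * x / (kd + x) * (1 + stats::rnorm(length(x), 0, 0.03))
    f <- fitHill(x, y, nBoot = 199, seed = r)
    rel[r] <- (fitParams(f)[["KD"]] - kd) / kd
    ci <- f@ci["KD", ]
    cov[r] <- kd >= ci[1] && kd <= ci[2]
  }
  expect_lt(abs(mean(rel)), 0.02)          # bias < 2%
  expect_lt(stats::median(abs(rel)), 0.10) # median relative error < 10%
  expect_gte(mean(cov), 0.90)              # percentile CI coverage
})

test_that("fits are scale-equivariant and never worse than their initialization", {
  x <- c(0.1, 0.3, 1, 3, 10, 30)
  set.seed(13)
  y <- 50 * x / (2 + x) * (1 + stats::rnorm(6, 0, 0.02))
  f1 <- fitHill(x, y, nBoot = 0)
  f2 <- fitHill(x, 3 * y, nBoot = 0)
  expect_equal(fitParams(f2)[["KD"]], fitParams(f1)[["KD"]],
               tolerance = 1e-6)
  expect_equal(fitParams(f2)[["Bmax"]], 3 * fitParams(f1)[["Bmax"]],
               tolerance = 1e-6)
  # RSS at the solution <= RSS at the initialization (Bmax0 = max y, KD0
  # = x nearest half-max)
  B0 <- max(y); K0 <- x[which.min(abs(y - B0 / 2))]
  rss0 <- sum((y - B0 * x / (K0 + x))^2)
  expect_lte(f1@rss, rss0)

  t <- seq(0, 300, length.out = 20)
  yf <- 0.6 * (1 - exp(-0.02 * t)) + stats::rnorm(20, 0, 0.005)
  g1 <- fitFrap(t, yf, nBoot = 0)
  g2 <- fitFrap(t, 5 * yf, nBoot = 0)
  expect_equal(fitParams(g2)[["k"]], fitParams(g1)[["k"]], tolerance = 1e-6)
  expect_equal(fitParams(g2)[["A"]], 5 * fitParams(g1)[["A"]],
               tolerance = 1e-6)
})

test_that("bootstrap uncertainties are reproducible and vanish with the noise", {
  x <- c(0.1, 0.3, 1, 3, 10, 30, 100)
  set.seed(17)
  y_hi <- 80 * x / (1.5 + x) * (1 + stats::rnorm(7, 0, 0.05))
  y_lo <- 80 * x / (1.5 + x) * (1 + stats::rnorm(7, 0, 0.002))
  f_a <- fitHill(x, y_hi, nBoot = 99, seed = 42)
  f_b <- fitHill(x, y_hi, nBoot = 99, seed = 42)
  expect_identical(f_a@se, f_b@se)
  expect_identical(f_a@ci, f_b@ci)
  f_lo <- fitHill(x, y_lo, nBoot = 99, seed = 42)
  expect_lt(f_lo@se[["KD"]], f_a@se[["KD"]])
})

test_that("pellet fractions behave like proportions", {
  expect_equal(pelletFraction(5, 5), 0.5)
  expect_equal(pelletFraction(1, 0), 1)
  expect_equal(pelletFraction(30, 70), 0.3)
  expect_equal(pelletFraction(30, 70) + pelletFraction(70, 30), 1)
  expect_error(pelletFraction(0, 0), "both zero")
  expect_error(pelletFraction(-1, 2))
})

test_that("titration series locate the saturation point of a demixing curve", {
  kd <- 1.5
  conc <- c(0.2, 0.5, 1, 2, 4, 8, 16, 32, 64)
  frac <- 0.95 * conc / (kd + conc)
  ts <- titrationSeries(conc, frac)
  expect_equal(fitParams(ts$fit)[["KD"]], kd, tolerance = 1e-6)
  expect_equal(ts$saturation, 19 * kd, tolerance = 0.05 * 19 * kd)
  expect_error(titrationSeries(conc, rep(0.5, 9)), "flat")
  expect_error(titrationSeries(c(1, 2), c(0.1, 0.9)), "4 titration points")
  w <- testthat::capture_warnings(
    titrationSeries(c(1, 2, 4, 8, 16), c(0.8, 0.1, 0.9, 0.95, 0.97)))
  expect_match(w, "non-monotone", all = FALSE)
})

test_that("calibration-curve quantification inverts the forward simulation", {
  # standards exactly on a line; sample at the midpoint interpolates exactly
  std <- data.frame(amount = c(1, 2, 4, 8), intensity = 100 * c(1, 2, 4, 8))
  q <- calibrationQuantify(std, 300, cellsPerSample = 1e6,
                           compartmentVolumeFl = 20,
                           molecularWeightDa = 5e4)
  expect_equal(q$amountNg, 3)

  # forward-simulated holoenzyme quantification: planted 2.95 uM recovered
  cells <- 6e6; vol_fl <- 20; mw <- 5.5e5
  conc_true <- 2.95
  copies <- conc_true * 1e-6 * vol_fl * 1e-15 * 6.02214076e23
  amount_ng <- copies * cells * mw / 6.02214076e23 * 1e9
  std <- data.frame(amount = amount_ng * c(0.25, 0.5, 1.5, 2),
                    intensity = 7 * amount_ng * c(0.25, 0.5, 1.5, 2))
  q <- calibrationQuantify(std, 7 * amount_ng, cells, vol_fl, mw)
  expect_equal(q$concentrationUM, 2.95, tolerance = 1e-9)
  expect_false(q$extrapolated)

  # molar ratio of two planted species: 2:1 recovered as 2.0
  conc2 <- 2 * conc_true
  copies2 <- conc2 * 1e-6 * vol_fl * 1e-15 * 6.02214076e23
  amount2 <- copies2 * cells * (mw / 10) / 6.02214076e23 * 1e9
  std2 <- data.frame(amount = amount2 * c(0.25, 0.5, 1.5, 2),
                     intensity = 3 * amount2 * c(0.25, 0.5, 1.5, 2))
  q2 <- calibrationQuantify(std2, 3 * amount2, cells, vol_fl, mw / 10)
  expect_equal(q2$concentrationUM / q$concentrationUM, 2, tolerance = 1e-9)

  # guard rails
  expect_error(calibrationQuantify(std[1:2, ], 1, 1, 1, 1), "3 standards")
  expect_error(calibrationQuantify(
    data.frame(amount = c(1, 1, 1), intensity = c(1, 2, 3)), 1, 1, 1, 1),
    "singular")
  expect_error(calibrationQuantify(std, max(std$intensity) * 10,
                                   cells, vol_fl, mw), "outside")
  q3 <- calibrationQuantify(std, max(std$intensity) * 10, cells, vol_fl,
                            mw, extrapolate = TRUE)
  expect_true(q3$extrapolated)
})
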