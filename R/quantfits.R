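# Quantitative curve analyses: hyperbolic (Hill, coefficient 1) binding
# occupancy fits, FRAP recovery normalization and single-exponential fits,
# droplet sedimentation pellet fractions, and absolute quantification from
# an external calibration line.  Nonlinear least squares go through
# minpack.lm; uncertainties come from a seeded residual-resampling
# bootstrap with percentile intervals.

#' @importFrom minpack.lm nlsLM
#' @importFrom stats coef lm predict quantile resid rnorm runif sd setNames
NULL

.boot_fit <- function(x, y, fitted_y, refit, params, nBoot, seed) {
  if (nBoot <= 0L)
    return(list(se = setNames(numeric(0), character(0)),
                ci = matrix(numeric(0), 0, 2)))
  res <- y - fitted_y
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- matrix(NA_real_, nBoot, length(params),
                  dimnames = list(NULL, names(params)))
  for (b in seq_len(nBoot)) {
    yb <- fitted_y + sample(res, length(res), replace = TRUE)
    pb <- tryCatch(refit(x, yb), error = function(e) NULL)
    if (!is.null(pb)) draws[b, ] <- pb
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  ci <- t(apply(draws, 2L, quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("2.5%", "97.5%")
  list(se = apply(draws, 2L, sd), ci = ci)
}

#' Normalize a FRAP trace
#'
#' Standard double normalization of a fluorescence-recovery trace: the
#' background is subtracted from the bleached and unbleached series, the
#' bleached series is divided by the unbleached reference (photobleach
#' correction), and the result is divided by its mean pre-bleach value
#' (full-scale normalization), so the pre-bleach mean of the output is
#' exactly 1.
#'
#' @param trace a data frame with columns `t` (seconds, negative =
#'   pre-bleach), `bleached`, `unbleached`, `background`.
#' @return A data frame with columns `t` and `intensity` (normalized).
#' @export
normalizeFrap <- function(trace) {
  trace <- as.data.frame(trace)
  stopifnot(all(c("t", "bleached", "unbleached", "background")
                %in% names(trace)))
  pre <- trace$t < 0
  if (!any(pre)) stop("no pre-bleach points (t < 0)")
  if (sum(pre) < 5L) warning("fewer than 5 pre-bleach points")
  corr_b <- trace$bleached - trace$background
  corr_u <- trace$unbleached - trace$background
  if (any(corr_u <= 0))
    stop("non-positive background-corrected reference intensity")
  ratio <- corr_b / corr_u
  scale <- mean(ratio[pre])
  if (scale <= 0) stop("non-positive pre-bleach mean")
  data.frame(t = trace$t, intensity = ratio / scale)
}

.fit_frap_params <- function(t, y) {
  A0 <- y[length(y)]
  if (A0 <= 0) A0 <- max(y)
  ihalf <- which(y >= A0 / 2)[1L]
  k0 <- if (!is.na(ihalf) && t[ihalf] > 0) 1 / t[ihalf] else 1 / max(t[t > 0])
  fit <- nlsLM(y ~ A * (1 - exp(-k * t)),
               start = list(A = A0, k = k0),
               lower = c(A = 1e-12, k = 1e-12),
               control = minpack.lm::nls.lm.control(ftol = 1e-8,
                                                    maxiter = 200))
  coef(fit)
}

#' Fit an exponential FRAP recovery
#'
#' Least-squares fit of `y(t) = A * (1 - exp(-k t))` to post-bleach data,
#' with `t = 0` at the first post-bleach frame.  The derived half-maximal
#' recovery time is `T0.5 = ln(2) / k`.  Initial values are `A0` = last
#' observed intensity and `k0 = 1 / t_half` (time at half of `A0`).
#'
#' @param t postbleach times (seconds, ascending, `>= 0`), at least 4
#'   points.
#' @param y normalized post-bleach intensities (see [normalizeFrap()]).
#' @param nBoot residual-resampling bootstrap replicates (0 disables).
#' @param seed bootstrap RNG seed.
#' @return A [FitResult-class] with params `A`, `k` and derived `T0.5`.
#' @examples
#' t <- seq(0, 600, by = 20)
#' y <- 0.8 * (1 - exp(-log(2) / 131 * t))
#' fitDerived(fitFrap(t, y, nBoot = 0))[["T0.5"]]  # 131
#' @export
fitFrap <- function(t, y, nBoot = 1000L, seed = 1L) {
  stopifnot(length(t) == length(y), length(t) >= 4L)
  if (any(!is.finite(t)) || any(!is.finite(y))) stop("non-finite values")
  if (any(t < 0) || is.unsorted(t)) stop("t must be >= 0 and ascending")
  if (sd(y) < 1e-12 * max(abs(y), 1))
    stop("flat trace: recovery rate k is unidentifiable")
  p <- .fit_frap_params(t, y)
  fitted_y <- p[["A"]] * (1 - exp(-p[["k"]] * t))
  bt <- .boot_fit(t, y, fitted_y, .fit_frap_params, p, as.integer(nBoot),
                  as.integer(seed))
  new("FitResult",
    model = "frap", params = p,
    derived = c(T0.5 = log(2) / p[["k"]]),
    se = bt$se, ci = bt$ci, nBoot = as.integer(nBoot),
    seed = as.integer(seed), rss = sum((y - fitted_y)^2)
  )
}

.fit_hill_params <- function(x, y) {
  B0 <- max(y)
  K0 <- x[which.min(abs(y - B0 / 2))]
  if (K0 <= 0) K0 <- stats::median(x[x > 0])
  fit <- nlsLM(y ~ Bmax * x / (KD + x),
               start = list(Bmax = B0, KD = K0),
               lower = c(Bmax = 1e-12, KD = 1e-12),
               control = minpack.lm::nls.lm.control(ftol = 1e-8,
                                                    maxiter = 200))
  coef(fit)
}

#' Fit a binding occupancy curve (Hill equation, coefficient 1)
#'
#' Least-squares fit of `y(x) = Bmax * x / (KD + x)` -- the Hill form with
#' unit coefficient -- to a titration, as used for SPR responses and native
#' PAGE complex occupancy.  The half-occupancy concentration `K0.5` equals
#' `KD` for this hyperbolic form.  Initial values are `Bmax0 = max(y)` and
#' `KD0` = the concentration nearest half-maximal response.
#'
#' @param x analyte concentrations (non-negative, at least 3 distinct).
#' @param y responses (same length as `x`).
#' @param nBoot,seed residual-resampling bootstrap settings.
#' @param normalize if `TRUE`, also return the normalized responses
#'   `y / Bmax` in the `normalized` attribute (as plotted for SPR).
#' @return A [FitResult-class] with params `Bmax`, `KD` and derived `K0.5`.
#' @examples
#' x <- c(0.05, 0.1, 0.25, 0.5, 1, 2, 4, 8, 16, 32)
#' y <- 100 * x / (1.21 + x)
#' fitParams(fitHill(x, y, nBoot = 0))[["KD"]]  # 1.21
#' @export
fitHill <- function(x, y, nBoot = 1000L, seed = 1L, normalize = FALSE) {
  stopifnot(length(x) == length(y))
  if (any(x < 0)) stop("non-positive concentrations not allowed")
  if (length(unique(x)) < 3L) stop("need at least 3 distinct concentrations")
  if (all(y == 0)) stop("all-zero responses")
  mid_guess <- x[which.min(abs(y - max(y) / 2))]
  if (!any(x > mid_guess) || !any(x < mid_guess))
    warning("no concentrations on both sides of the apparent midpoint")
  p <- .fit_hill_params(x, y)
  fitted_y <- p[["Bmax"]] * x / (p[["KD"]] + x)
  bt <- .boot_fit(x, y, fitted_y, .fit_hill_params, p, as.integer(nBoot),
                  as.integer(seed))
  out <- new("FitResult",
    model = "hill", params = p,
    derived = c(K0.5 = p[["KD"]]),
    se = bt$se, ci = bt$ci, nBoot = as.integer(nBoot),
    seed = as.integer(seed), rss = sum((y - fitted_y)^2)
  )
  if (normalize) attr(out, "normalized") <- y / p[["Bmax"]]
  out
}

#' Pellet fraction of a sedimentation assay
#'
#' Fraction of material in the pellet relative to pellet plus supernatant,
#' `P / (P + S)`, from band intensities.
#'
#' @param pellet,supernatant non-negative band intensities, not both zero.
#' @return Value in \[0, 1\].
#' @examples
#' pelletFraction(30, 70)  # 0.3
#' @export
pelletFraction <- function(pellet, supernatant) {
  stopifnot(all(pellet >= 0), all(supernatant >= 0))
  if (any(pellet + supernatant == 0)) stop("pellet and supernatant both zero")
  pellet / (pellet + supernatant)
}

#' Titration series of pellet fractions
#'
#' Fits the same hyperbolic occupancy form to pellet fraction versus
#' titrant concentration and reports the concentration at 95% of the fitted
#' plateau as the estimated saturation point (for the hyperbolic form this
#' is `19 * KD`).  Used to locate the titrant excess needed to fully demix
#' the fixed component.
#'
#' @param concentration titrant concentrations (at least 4 points).
#' @param fraction pellet fractions in \[0, 1\].
#' @param nBoot,seed bootstrap settings passed to [fitHill()].
#' @return A list with `fit` (a [FitResult-class]), `saturation` (the 95%
#'   of-plateau concentration) and `table` (the input points plus fitted
#'   values).
#' @export
titrationSeries <- function(concentration, fraction, nBoot = 0L, seed = 1L) {
  stopifnot(length(concentration) == length(fraction))
  if (length(concentration) < 4L) stop("need at least 4 titration points")
  if (sd(fraction) < 1e-12) stop("flat series: no titration response")
  o <- order(concentration)
  fr_o <- fraction[o]
  runmax <- cummax(fr_o)
  if (any(runmax - fr_o > 0.25))
    warning("series non-monotone beyond noise tolerance")
  fit <- fitHill(concentration, fraction, nBoot = nBoot, seed = seed)
  kd <- fitParams(fit)[["KD"]]
  list(
    fit = fit,
    saturation = 19 * kd,
    table = data.frame(
      concentration = concentration, fraction = fraction,
      fitted = fitParams(fit)[["Bmax"]] * concentration / (kd + concentration)
    )
  )
}

#' Absolute quantification from an external calibration curve
#'
#' Interpolates sample intensities on an ordinary least-squares calibration
#' line (intensity versus standard amount), converts the interpolated
#' amounts to copies per cell and to molar concentration within a
#' compartment of known volume:
#' `copies = amount * N_A / (MW * cells)` and
#' `concentration = copies / (N_A * volume)`.
#'
#' @param standards data frame with columns `amount` (nanograms) and
#'   `intensity`; at least 3 standards spanning the sample intensities.
#' @param sampleIntensities numeric intensities to quantify.
#' @param cellsPerSample number of cells each sample derives from.
#' @param compartmentVolumeFl compartment (for example chloroplast) volume
#'   in femtolitres.
#' @param molecularWeightDa protein molecular weight (g/mol).
#' @param extrapolate allow samples outside the standard intensity range
#'   (flagged in the output either way).
#' @return A data frame with one row per sample: `intensity`, `amountNg`,
#'   `copiesPerCell`, `concentrationUM`, `extrapolated`.
#' @export
calibrationQuantify <- function(standards, sampleIntensities, cellsPerSample,
                                compartmentVolumeFl, molecularWeightDa,
                                extrapolate = FALSE) {
  standards <- as.data.frame(standards)
  stopifnot(all(c("amount", "intensity") %in% names(standards)),
            compartmentVolumeFl > 0, cellsPerSample > 0,
            molecularWeightDa > 0)
  if (nrow(standards) < 3L) stop("need at least 3 standards")
  if (length(unique(standards$amount)) < 2L)
    stop("singular standards: all at one amount")
  line <- lm(intensity ~ amount, data = standards)
  slope <- coef(line)[["amount"]]
  if (abs(slope) < 1e-12) stop("singular calibration line")
  amount <- (sampleIntensities - coef(line)[["(Intercept)"]]) / slope
  rng <- range(standards$intensity)
  outside <- sampleIntensities < rng[1L] | sampleIntensities > rng[2L]
  if (any(outside) && !extrapolate)
    stop("sample intensity outside the standard range; ",
         "set extrapolate = TRUE to allow")
  NA_CONST <- 6.02214076e23
  copies <- amount * 1e-9 * NA_CONST / (molecularWeightDa * cellsPerSample)
  conc_um <- copies / (NA_CONST * compartmentVolumeFl * 1e-15) * 1e6
  data.frame(
    intensity = sampleIntensities, amountNg = amount,
    copiesPerCell = copies, concentrationUM = conc_um,
    extrapolated = outside
  )
}
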