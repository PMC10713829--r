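#' Combined methyl chemical-shift perturbation
#'
#' `CSP = sqrt((dH^2 + dC^2/4) / 2)` where `dH` and `dC` are the proton and
#' carbon shift changes in ppm (carbon scaled by 2 inside the square, the
#' standard methyl-group weighting).
#'
#' @param free,bound lists/rows with `probe`, `delta_H`, `delta_C` (ppm);
#'   probes must match.
#' @return CSP in ppm (non-negative, zero iff shifts identical).
#' @export
methyl_csp <- function(free, bound) {
  if (!identical(free$probe, bound$probe))
    stop("mismatched probes: ", free$probe, " vs ", bound$probe)
  d_h <- bound$delta_H - free$delta_H
  d_c <- bound$delta_C - free$delta_C
  sqrt((d_h^2 + d_c^2 / 4) / 2)
}

#' Flag perturbed and broadened methyl probes
#'
#' CSP outliers exceed `mean(csp) + n_sd * sd(csp)`; broadened probes fall
#' below `mean(ratio) - n_sd * sd(ratio)` (intensity ratio = empty/bound).
#' Records marked `excluded` (e.g. fully line-broadened peaks) are omitted
#' from the mean/SD and never flagged. Flags are invariant to record order.
#'
#' @param records data.frame with `probe`, `csp`, `intensity_ratio` and
#'   optionally logical `excluded` (plus `exclude_reason`).
#' @param n_sd number of standard deviations (default 1).
#' @return the records with added logical columns `csp_outlier` and
#'   `broadened`, plus the thresholds as attributes `csp_threshold` and
#'   `ratio_threshold`.
#' @export
flag_perturbed <- function(records, n_sd = 1) {
  records <- as.data.frame(records)
  if (is.null(records$excluded)) records$excluded <- FALSE
  use <- !records$excluded
  if (sum(use) < 2L) stop("need at least 2 non-excluded records")
  csp_thr <- mean(records$csp[use]) + n_sd * stats::sd(records$csp[use])
  ratio_thr <- mean(records$intensity_ratio[use]) -
    n_sd * stats::sd(records$intensity_ratio[use])
  records$csp_outlier <- use & records$csp > csp_thr
  records$broadened <- use & records$intensity_ratio < ratio_thr
  attr(records, "csp_threshold") <- csp_thr
  attr(records, "ratio_threshold") <- ratio_thr
  records
}

#' Fit a single-phase exponential decay
#'
#' `I(t) = plateau + (I0 - plateau) * exp(-k t)`; half-life `t_half =
#' ln(2)/k`. The fit is deterministic least squares (`nls`, port algorithm)
#' from analytic initial guesses (endpoint amplitudes, log-linear rate).
#' Non-decaying data pin `k` at 0 with a warning and an infinite half-life.
#'
#' @param times numeric, strictly increasing (hours).
#' @param intensities numeric, same length, >= 4 points.
#' @param probe optional label carried through to the result.
#' @return object of class `DecayFit`: list with `I0`, `plateau`, `k`
#'   (1/h), `t_half` (h), `rss`, `se` (named standard errors or `NA`) and
#'   `fitted`.
#' @export
fit_decay <- function(times, intensities, probe = NA_character_) {
  stopifnot(length(times) == length(intensities), length(times) >= 4L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  i0_g <- intensities[1L]
  pl_g <- min(intensities)
  amp <- i0_g - pl_g
  rng <- diff(range(intensities))
  if (rng < 1e-12 * max(abs(intensities), 1) || amp <= 0) {
    warning("non-decaying data; k pinned at 0")
    return(structure(list(probe = probe, I0 = mean(intensities),
                          plateau = mean(intensities), k = 0, t_half = Inf,
                          rss = sum((intensities - mean(intensities))^2),
                          se = c(I0 = NA, plateau = NA, k = NA),
                          fitted = rep(mean(intensities), length(times))),
                     class = "DecayFit"))
  }
  # log-linear initial rate from points above the plateau guess
  y <- intensities - (pl_g - 0.05 * amp)
  ok <- y > 0
  k_g <- max(-stats::coef(stats::lm(log(y[ok]) ~ times[ok]))[[2L]], 1e-3)
  df <- data.frame(t = times, I = intensities)
  fit <- stats::nls(I ~ plateau + (I0 - plateau) * exp(-k * t), data = df,
                    start = list(I0 = i0_g, plateau = pl_g, k = k_g),
                    lower = c(-Inf, -Inf, 0), algorithm = "port",
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(I0 = NA, plateau = NA, k = NA))
  structure(list(probe = probe, I0 = cf[["I0"]], plateau = cf[["plateau"]],
                 k = cf[["k"]],
                 t_half = if (cf[["k"]] > 0) log(2) / cf[["k"]] else Inf,
                 rss = sum(stats::resid(fit)^2), se = se,
                 fitted = stats::fitted(fit)),
            class = "DecayFit")
}

#' Percent empty receptor from thermal-melt fluorescence
#'
#' `100 * F_sample(T_eval) / max(F_reference_empty)`: the sample's
#' fluorescence at the evaluation temperature relative to the maximum
#' fluorescence of the empty-receptor reference curve.
#'
#' @param sample,reference_empty data.frames with `temperature` (deg C) and
#'   `fluorescence`.
#' @param t_eval evaluation temperature (default 25 deg C); the nearest
#'   scanned temperature within 0.51 deg C is used.
#' @return percentage.
#' @export
percent_empty <- function(sample, reference_empty, t_eval = 25) {
  f_max <- max(reference_empty$fluorescence)
  if (f_max <= 0) stop("reference maximum fluorescence is not positive")
  i <- which.min(abs(sample$temperature - t_eval))
  if (abs(sample$temperature[i] - t_eval) > 0.51)
    stop("sample curve does not include the evaluation temperature ", t_eval)
  100 * sample$fluorescence[i] / f_max
}

#' Fit a Boltzmann sigmoid to a thermal melt curve
#'
#' `F(T) = F_min + (F_max - F_min) / (1 + exp((T_m - T)/slope))`; at
#' `T = T_m` the curve equals the midpoint `(F_min + F_max)/2`. Deterministic
#' least squares from analytic starts (range endpoints; midpoint-crossing
#' temperature; slope from the 25-75% width).
#'
#' @param temperatures deg C (increasing scan).
#' @param fluorescence same length.
#' @return object of class `MeltCurveFit`: list with `F_min`, `F_max`,
#'   `T_m` (deg C), `slope` (deg C), `rss`, `fitted`.
#' @export
fit_tm <- function(temperatures, fluorescence) {
  stopifnot(length(temperatures) == length(fluorescence),
            length(temperatures) >= 5L)
  f_min_g <- min(fluorescence)
  f_max_g <- max(fluorescence)
  if (f_max_g - f_min_g < 1e-12 * max(abs(fluorescence), 1))
    stop("flat melt curve; no transition to fit")
  frac <- (fluorescence - f_min_g) / (f_max_g - f_min_g)
  cross <- function(level) {
    i <- which(frac >= level)[1L]
    if (is.na(i) || i == 1L) return(temperatures[which.min(abs(frac - level))])
    # linear interpolation across the crossing
    t0 <- temperatures[i - 1L]; t1 <- temperatures[i]
    f0 <- frac[i - 1L]; f1 <- frac[i]
    t0 + (level - f0) * (t1 - t0) / (f1 - f0)
  }
  tm_g <- cross(0.5)
  slope_g <- max((cross(0.75) - cross(0.25)) / (2 * log(3)), 0.1)
  df <- data.frame(T = temperatures, F = fluorescence)
  fit <- stats::nls(F ~ F_min + (F_max - F_min) / (1 + exp((T_m - T) / slope)),
                    data = df,
                    start = list(F_min = f_min_g, F_max = f_max_g,
                                 T_m = tm_g, slope = slope_g),
                    algorithm = "port",
                    lower = c(-Inf, -Inf, min(temperatures), 1e-3),
                    upper = c(Inf, Inf, max(temperatures), Inf),
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE))
  cf <- stats::coef(fit)
  structure(list(F_min = cf[["F_min"]], F_max = cf[["F_max"]],
                 T_m = cf[["T_m"]], slope = cf[["slope"]],
                 rss = sum(stats::resid(fit)^2),
                 fitted = stats::fitted(fit)),
            class = "MeltCurveFit")
}
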