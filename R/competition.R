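#' Two-ligand one-site competitive binding equilibrium
#'
#' A receptor R binds a labeled tracer L (dissociation constant `Kd_L`) and
#' an unlabeled competitor C (`Kd_C`), one site, no cooperativity. The free
#' receptor concentration solves the mass balance
#' `Rf + Rf*Lt/(Kd_L + Rf) + Rf*Ct/(Kd_C + Rf) = Rt`
#' (monotone in Rf; solved by bisection/uniroot to 1e-12 relative). Mass is
#' conserved to better than 1e-9 relative.
#'
#' @param R_tot,L_tot,C_tot total concentrations (> 0 except `C_tot >= 0`),
#'   any consistent unit.
#' @param Kd_L,Kd_C dissociation constants, same unit.
#' @return list with `free_R`, `bound_L`, `bound_C`, `free_L`, `free_C`,
#'   and `fraction_L_bound`.
#' @export
competition_model <- function(R_tot, L_tot, C_tot, Kd_L, Kd_C) {
  if (R_tot <= 0 || L_tot <= 0 || C_tot < 0 || Kd_L <= 0 || Kd_C <= 0)
    stop("non-physical input concentrations or dissociation constants")
  balance <- function(rf)
    rf * (1 + L_tot / (Kd_L + rf) + C_tot / (Kd_C + rf)) - R_tot
  rf <- stats::uniroot(balance, c(0, R_tot), tol = 1e-14 * max(R_tot, 1))$root
  bound_l <- L_tot * rf / (Kd_L + rf)
  bound_c <- C_tot * rf / (Kd_C + rf)
  list(free_R = rf, bound_L = bound_l, bound_C = bound_c,
       free_L = L_tot - bound_l, free_C = C_tot - bound_c,
       fraction_L_bound = bound_l / L_tot)
}

# anisotropy of the tracer at competitor concentration cc
aniso_at <- function(cc, R_tot, L_tot, Kd_L, Kd_C, r_min, r_max) {
  fb0 <- competition_model(R_tot, L_tot, 0, Kd_L, Kd_C)$fraction_L_bound
  fb <- competition_model(R_tot, L_tot, max(cc, 0), Kd_L, Kd_C)$fraction_L_bound
  r_min + (r_max - r_min) * fb / fb0
}

#' IC50 of a fitted competition model
#'
#' The competitor concentration at half-maximal signal displacement (the
#' operational IC50, not a Kd), found numerically on the fitted curve. The
#' asymptotic displacement at infinite competitor is evaluated at 1e6 times
#' `Kd_C`.
#'
#' @param R_tot,L_tot,Kd_L,Kd_C model parameters (consistent unit).
#' @return IC50 in the same unit.
#' @export
ic50_from_model <- function(R_tot, L_tot, Kd_L, Kd_C) {
  fb <- function(cc) competition_model(R_tot, L_tot, cc, Kd_L,
                                       Kd_C)$fraction_L_bound
  fb0 <- fb(0)
  fb_inf <- fb(1e6 * Kd_C)
  target <- (fb0 + fb_inf) / 2
  stats::uniroot(function(cc) fb(cc) - target,
                 c(1e-9 * Kd_C, 1e6 * Kd_C), tol = 1e-12)$root
}

#' Kd of the competitor implied by a target IC50 (model inversion)
#'
#' Inverse of [ic50_from_model()] in `Kd_C`, used by the synthetic
#' generator to produce data at a stated IC50.
#'
#' @param ic50 target IC50.
#' @param R_tot,L_tot,Kd_L assay constants.
#' @return `Kd_C`.
#' @export
kd_from_ic50 <- function(ic50, R_tot, L_tot, Kd_L) {
  stats::uniroot(function(lkd)
    log(ic50_from_model(R_tot, L_tot, Kd_L, exp(lkd))) - log(ic50),
    c(log(ic50) - 12, log(ic50) + 6), tol = 1e-12)$root |> exp()
}

#' Fit a competitive-anisotropy displacement series
#'
#' Fits observed anisotropy versus competitor concentration to the
#' one-site competition equilibrium mapped linearly between `r_max` (no
#' competitor) and `r_min` (full displacement): free parameters are
#' `r_max`, `r_min` and `Kd_C`; `R_tot`, `L_tot` and `Kd_L` are assay
#' constants. Deterministic Nelder-Mead from analytic starts (endpoint
#' anisotropies; Kd at the mid-signal concentration). The reported IC50 is
#' the half-maximal-displacement concentration of the fitted curve.
#'
#' @param concentrations competitor concentrations (>= 4 values including
#'   0), in the unit the result should carry.
#' @param anisotropy observed anisotropy, same length (replicate means or
#'   raw replicates with repeated concentrations).
#' @param R_tot,L_tot,Kd_L assay constants in the same unit.
#' @return object of class `CompetitionFit`: list with `IC50`, `Kd_C`,
#'   `r_max`, `r_min`, `rss`, `fitted`.
#' @export
fit_ic50 <- function(concentrations, anisotropy, R_tot, L_tot, Kd_L) {
  stopifnot(length(concentrations) == length(anisotropy))
  if (length(unique(concentrations)) < 4L || !any(concentrations == 0))
    stop("need >= 4 competitor concentrations including 0")
  r_max_g <- mean(anisotropy[concentrations == 0])
  r_min_g <- min(tapply(anisotropy, concentrations, mean))
  mid_r <- (r_max_g + r_min_g) / 2
  means <- tapply(anisotropy, concentrations, mean)
  concs <- as.numeric(names(means))
  kd_g <- concs[which.min(abs(means - mid_r))]
  if (kd_g <= 0) kd_g <- stats::median(concs[concs > 0])
  obj <- function(p) {
    r_max <- p[1L]; r_min <- p[2L]; kd_c <- exp(p[3L])
    pred <- vapply(concentrations, aniso_at, numeric(1),
                   R_tot = R_tot, L_tot = L_tot, Kd_L = Kd_L, Kd_C = kd_c,
                   r_min = r_min, r_max = r_max)
    sum((anisotropy - pred)^2)
  }
  opt <- stats::optim(c(r_max_g, r_min_g, log(kd_g)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  # polish with a second deterministic restart from the optimum
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  kd_c <- exp(opt$par[3L])
  structure(list(
    IC50 = ic50_from_model(R_tot, L_tot, Kd_L, kd_c),
    Kd_C = kd_c, r_max = opt$par[1L], r_min = opt$par[2L],
    rss = opt$value,
    fitted = vapply(concentrations, aniso_at, numeric(1),
                    R_tot = R_tot, L_tot = L_tot, Kd_L = Kd_L, Kd_C = kd_c,
                    r_min = opt$par[2L], r_max = opt$par[1L])),
    class = "CompetitionFit")
}

#' Cheng-Prusoff conversion of an IC50 to an apparent Ki
#'
#' `Ki = IC50 / (1 + L_tot/Kd_L)`. A derived quantity, reported for
#' convenience only: the operational IC50 is the primary readout.
#'
#' @param ic50 measured IC50.
#' @param L_tot tracer concentration.
#' @param Kd_L tracer dissociation constant.
#' @return apparent Ki.
#' @export
cheng_prusoff_ki <- function(ic50, L_tot, Kd_L) ic50 / (1 + L_tot / Kd_L)
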