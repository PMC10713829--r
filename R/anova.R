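#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch (1951) F statistic: with group weights `w_i = n_i/s_i^2`,
#' `F = sum(w_i (xbar_i - xtilde)^2) / (k-1) / (1 + 2(k-2)/(k^2-1) * L)`
#' where `xtilde = sum(w_i xbar_i)/sum(w_i)` and
#' `L = sum((1 - w_i/W)^2/(n_i - 1))`; df1 = k-1,
#' df2 = (k^2-1)/(3 L).
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with `statistic`, `df1`, `df2`, `p_value`.
#' @export
welch_anova <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  n <- lengths(groups)
  xb <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  if (all(v == 0)) {
    eq <- length(unique(xb)) == 1L
    return(list(statistic = if (eq) 0 else Inf, df1 = k - 1, df2 = Inf,
                p_value = if (eq) 1 else 0))
  }
  w <- n / v
  ww <- sum(w)
  xt <- sum(w * xb) / ww
  lam <- sum((1 - w / ww)^2 / (n - 1))
  f <- sum(w * (xb - xt)^2) / (k - 1) / (1 + 2 * (k - 2) / (k^2 - 1) * lam)
  df2 <- (k^2 - 1) / (3 * lam)
  list(statistic = f, df1 = k - 1, df2 = df2,
       p_value = stats::pf(f, k - 1, df2, lower.tail = FALSE))
}

#' Brown-Forsythe test for equality of means
#'
#' The means version (as in the Brown-Forsythe/Welch one-way ANOVA pair):
#' `F* = sum(n_i (xbar_i - xbar)^2) / sum((1 - n_i/N) s_i^2)` with
#' numerator df `k-1` and Satterthwaite denominator df
#' `1/sum(c_i^2/(n_i-1))` where
#' `c_i = (1 - n_i/N) s_i^2 / sum((1 - n_j/N) s_j^2)`.
#'
#' @inheritParams welch_anova
#' @return list with `statistic`, `df1`, `df2`, `p_value`.
#' @export
brown_forsythe <- function(groups) {
  check_groups(groups)
  k <- length(groups)
  n <- lengths(groups)
  big_n <- sum(n)
  xb <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  xg <- sum(n * xb) / big_n
  denom_terms <- (1 - n / big_n) * v
  denom <- sum(denom_terms)
  if (denom == 0) {
    eq <- length(unique(xb)) == 1L
    return(list(statistic = if (eq) 0 else Inf, df1 = k - 1, df2 = Inf,
                p_value = if (eq) 1 else 0))
  }
  f <- sum(n * (xb - xg)^2) / denom
  ci <- denom_terms / denom
  df2 <- 1 / sum(ci^2 / (n - 1))
  list(statistic = f, df1 = k - 1, df2 = df2,
       p_value = stats::pf(f, k - 1, df2, lower.tail = FALSE))
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need >= 2 groups")
  if (any(lengths(groups) < 2L))
    stop("every group needs >= 2 replicates")
  invisible(TRUE)
}

#' Between-state comparison of replicate uptake values
#'
#' Runs both heteroscedastic one-way tests on per-state replicate values
#' for one fragment/timepoint, the standard pairing for biological
#' triplicate HDX comparisons. When every group has zero within-group
#' variance the exact-equality shortcut applies (p = 1 if all means equal,
#' p = 0 otherwise).
#'
#' @param groups named list of numeric replicate vectors, one per state.
#' @return data.frame with one row per test (`test`, `statistic`, `df1`,
#'   `df2`, `p_value`).
#' @export
compare_states <- function(groups) {
  w <- welch_anova(groups)
  b <- brown_forsythe(groups)
  data.frame(test = c("welch", "brown-forsythe"),
             statistic = c(w$statistic, b$statistic),
             df1 = c(w$df1, b$df1), df2 = c(w$df2, b$df2),
             p_value = c(w$p_value, b$p_value),
             stringsAsFactors = FALSE)
}
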