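#' Case carrier frequency implied by an odds ratio
#'
#' Given the control carrier frequency `p0` and the odds ratio `OR` of
#' carriage in cases versus controls, the case carrier frequency is
#' `p1 = OR * p0 / (1 - p0 + OR * p0)`, i.e. the frequency whose odds are
#' `OR` times the control odds.
#'
#' @param p0 Control carrier (risk-allele) frequency in (0, 1).
#' @param odds_ratio Odds ratio of carriage, > 0. Both arguments are
#'   vectorized.
#' @return Case carrier frequency `p1`.
#' @examples
#' case_carrier_freq(0.01, 22)   # 0.22 / 1.21
#' @export
case_carrier_freq <- function(p0, odds_ratio) {
  if (any(p0 <= 0) || any(p0 >= 1)) {
    stop_hemiassoc("p0 must be in (0, 1)", "hemiassoc_bad_argument")
  }
  if (any(odds_ratio <= 0)) {
    stop_hemiassoc("odds_ratio must be > 0", "hemiassoc_bad_argument")
  }
  odds_ratio * p0 / (1 - p0 + odds_ratio * p0)
}

#' Monte-Carlo power of the Fisher exact test on carrier counts
#'
#' Each individual contributes exactly one allele (hemizygosity), so one
#' replicate draws case carriers from `Binomial(n_case, p1)` and control
#' carriers from `Binomial(n_control, p0)` with
#' `p1 = case_carrier_freq(p0, odds_ratio)`, applies the two-sided Fisher
#' exact test to the resulting 2x2, and counts rejections at `alpha`.
#'
#' @param p0 Control carrier frequency.
#' @param odds_ratio Odds ratio of carriage in cases vs controls.
#' @param n_case,n_control Group sizes (defaults 40 and 48).
#' @param alpha Per-test significance level (default 0.05).
#' @param reps Monte-Carlo replicates (default 20,000).
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `power_estimate`: list with `power`
#'   (rejection fraction), `mc_se` (binomial standard error
#'   `sqrt(power * (1 - power) / reps)`), `p1`, and the design fields.
#' @examples
#' simulate_power(0.01, 22, reps = 2000, seed = 1)
#' @export
simulate_power <- function(p0, odds_ratio, n_case = 40, n_control = 48,
                           alpha = 0.05, reps = 20000, seed = NULL) {
  stopifnot(is_count(reps), reps >= 1, alpha > 0, alpha < 1,
            is_count(n_case), is_count(n_control), n_case >= 1,
            n_control >= 1)
  p1 <- case_carrier_freq(p0, odds_ratio)
  if (!is.null(seed)) set.seed(seed)
  a <- rbinom(reps, n_case, p1)
  c <- rbinom(reps, n_control, p0)
  p_lut <- fisher_p_table(n_case, n_control)
  rej <- p_lut[cbind(a + 1L, c + 1L)] < alpha
  power <- mean(rej)
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / reps),
                 p0 = p0, p1 = p1, odds_ratio = odds_ratio,
                 n_case = n_case, n_control = n_control,
                 alpha = alpha, reps = reps, seed = seed),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate> power = %.4f (MC s.e. %.4f)\n", x$power, x$mc_se))
  cat(sprintf("  design: p0 = %g, OR = %g (p1 = %.4g), n = %d/%d, alpha = %g, reps = %d\n",
              x$p0, x$odds_ratio, x$p1, x$n_case, x$n_control, x$alpha,
              x$reps))
  invisible(x)
}

#' Exact power of the Fisher exact test on carrier counts
#'
#' Deterministic companion to [simulate_power()]: sums
#' `P(a carriers) * P(c carriers)` over the full binomial grid of carrier
#' counts, restricted to tables rejected at `alpha`. Useful as a
#' noise-free reference for the Monte-Carlo estimate.
#'
#' @inheritParams simulate_power
#' @return The exact rejection probability.
#' @export
exact_power <- function(p0, odds_ratio, n_case = 40, n_control = 48,
                        alpha = 0.05) {
  p1 <- case_carrier_freq(p0, odds_ratio)
  p_lut <- fisher_p_table(n_case, n_control)
  wa <- dbinom(0:n_case, n_case, p1)
  wc <- dbinom(0:n_control, n_control, p0)
  sum(outer(wa, wc) * (p_lut < alpha))
}

#' Power curve over a grid of odds ratios
#'
#' @inheritParams simulate_power
#' @param or_grid Increasing vector of odds ratios.
#' @return A data frame of class `power_curve`: `odds_ratio`, `p1`,
#'   `power`, `mc_se`.
#' @seealso [plot_power_curve()]
#' @export
power_curve <- function(p0, or_grid, n_case = 40, n_control = 48,
                        alpha = 0.05, reps = 20000, seed = NULL) {
  stopifnot(length(or_grid) >= 1, !is.unsorted(or_grid))
  rows <- lapply(seq_along(or_grid), function(i) {
    est <- simulate_power(p0, or_grid[i], n_case, n_control, alpha, reps,
                          seed = if (is.null(seed)) NULL else seed + i - 1)
    data.frame(odds_ratio = or_grid[i], p1 = est$p1, power = est$power,
               mc_se = est$mc_se)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_curve", class(out))
  attr(out, "design") <- list(p0 = p0, n_case = n_case,
                              n_control = n_control, alpha = alpha,
                              reps = reps)
  out
}

#' Plot a power curve
#'
#' Power against odds ratio with a horizontal reference line at the target
#' power.
#'
#' @param curve A [power_curve()] result.
#' @param target_power Reference line (default 0.8).
#' @return A ggplot object.
#' @export
plot_power_curve <- function(curve, target_power = 0.8) {
  ggplot2::ggplot(curve, ggplot2::aes(x = odds_ratio, y = power)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = target_power, linetype = "dashed") +
    ggplot2::labs(x = "odds ratio", y = "power") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Minimum detectable odds ratio at a target power
#'
#' Bisects the odds-ratio axis for the smallest OR whose estimated power
#' reaches `target_power`. Common random numbers are used across all
#' evaluations — one fixed set of per-individual uniform draws is
#' thresholded at each candidate `p1` — making estimated power exactly
#' monotone in OR, so the bisection is well defined despite Monte-Carlo
#' noise.
#'
#' @inheritParams simulate_power
#' @param target_power Target power in (0, 1), default 0.8.
#' @param or_max Upper search bound; if power at `or_max` is still below
#'   target, a typed error (`hemiassoc_power_unreachable`) is raised.
#' @param tol Width of the final OR bracket (default 0.1).
#' @return List of class `min_detectable_or`: `or_star` (smallest bracketed
#'   OR reaching the target), `bracket` (c(below, at-or-above)), `power_at_or_star`,
#'   and the design fields.
#' @export
min_detectable_or <- function(p0, n_case = 40, n_control = 48, alpha = 0.05,
                              target_power = 0.8, reps = 20000, seed = 1,
                              or_max = 1000, tol = 0.1) {
  stopifnot(target_power > 0, target_power < 1, is_count(reps), reps >= 1)
  set.seed(seed)
  u_case <- matrix(runif(reps * n_case), nrow = reps)
  c_carriers <- rbinom(reps, n_control, p0)
  p_lut <- fisher_p_table(n_case, n_control)
  power_at <- function(or) {
    p1 <- case_carrier_freq(p0, or)
    a <- rowSums(u_case < p1)
    mean(p_lut[cbind(a + 1L, c_carriers + 1L)] < alpha)
  }
  lo <- 1
  hi <- or_max
  if (power_at(hi) < target_power) {
    stop_hemiassoc(sprintf("target power %.2f unreachable at OR <= %g",
                           target_power, or_max),
                   "hemiassoc_power_unreachable")
  }
  if (power_at(lo) >= target_power) {
    hi <- lo
  } else {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (power_at(mid) >= target_power) hi <- mid else lo <- mid
    }
  }
  structure(list(or_star = hi, bracket = c(lo, hi),
                 power_at_or_star = power_at(hi),
                 p0 = p0, n_case = n_case, n_control = n_control,
                 alpha = alpha, target_power = target_power, reps = reps,
                 seed = seed),
            class = "min_detectable_or")
}

#' @export
print.min_detectable_or <- function(x, ...) {
  cat(sprintf("<min_detectable_or> OR* = %.2f (bracket %.2f-%.2f), power there = %.3f\n",
              x$or_star, x$bracket[1], x$bracket[2], x$power_at_or_star))
  cat(sprintf("  design: p0 = %g, n = %d/%d, alpha = %g, target = %g, reps = %d\n",
              x$p0, x$n_case, x$n_control, x$alpha, x$target_power, x$reps))
  invisible(x)
}
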