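#' Two-sided Fisher exact test on a 2x2 carrier table
#'
#' The association unit throughout this package is a 2x2 table of carrier
#' status by diagnostic group:
#'
#' |            | carrier | non-carrier |
#' |------------|---------|-------------|
#' | case       | a       | b           |
#' | control    | c       | d           |
#'
#' The two-sided p-value sums the hypergeometric probabilities, conditional
#' on both margins, of every table whose probability does not exceed that of
#' the observed table (the classical probability-ordering convention, as in
#' `stats::fisher.test`). The odds ratio is the sample estimate
#' `(a*d)/(b*c)`; when any cell is zero, 0.5 is added to every cell for the
#' odds-ratio estimate only (Haldane-Anscombe), never for the p-value.
#'
#' All four arguments are vectorized and recycled to a common length.
#'
#' @param a,b,c,d Non-negative integer cell counts: case carriers, case
#'   non-carriers, control carriers, control non-carriers.
#' @return A data frame with columns `p_value` and `odds_ratio`.
#' @examples
#' fisher_exact(20, 20, 24, 24)   # identical proportions: p = 1, OR = 1
#' fisher_exact(15, 25, 1, 47)
#' @export
fisher_exact <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  cells <- cbind(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop_hemiassoc("cell counts must be non-negative integers",
                   "hemiassoc_bad_table")
  }
  p <- vapply(seq_len(n), function(i) {
    fisher_p_scalar(a[i], b[i], c[i], d[i])
  }, numeric(1))
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  or <- ifelse(zero,
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)),
               (a * d) / (b * c))
  data.frame(p_value = p, odds_ratio = or)
}

## conditional two-sided p for one table; relative tolerance guards ties in
## the probability ordering against floating-point noise (same convention as
## stats::fisher.test)
fisher_p_scalar <- function(a, b, c, d) {
  m <- a + b          # cases
  k <- a + c          # total carriers
  nn <- a + b + c + d
  lo <- max(0, k - (c + d))
  hi <- min(k, m)
  support <- lo:hi
  pmf <- dhyper(support, m, nn - m, k)
  obs <- pmf[a - lo + 1L]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

## p-value lookup for all tables with fixed group sizes: entry [a+1, c+1]
## is the two-sided p for (a, n_case - a, c, n_control - c).  Association
## scans over thousands of units share these margins, so the full grid is
## computed once.
fisher_p_table <- function(n_case, n_control) {
  grid <- expand.grid(a = 0:n_case, c = 0:n_control)
  p <- vapply(seq_len(nrow(grid)), function(i) {
    fisher_p_scalar(grid$a[i], n_case - grid$a[i],
                    grid$c[i], n_control - grid$c[i])
  }, numeric(1))
  matrix(p, nrow = n_case + 1L, ncol = n_control + 1L)
}

#' Bonferroni family-wise significance threshold
#'
#' Returns both the exact threshold `alpha / m` and its order of magnitude
#' (the nearest power of ten), the form in which such thresholds are
#' conventionally quoted: for m = 4176 variants at alpha = 0.05 the exact
#' threshold is 1.2e-5 and the order-of-magnitude threshold is 1e-5; for
#' m = 73 genes it is 6.8e-4 and 1e-3.
#'
#' @param m Number of tests in the family (positive integer).
#' @param alpha Family-wise error rate, default 0.05.
#' @return A list with elements `exact` and `order_of_magnitude`.
#' @examples
#' bonferroni_threshold(4176)
#' bonferroni_threshold(73)
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (!is_count(m) || m < 1) {
    stop_hemiassoc("m must be a positive integer", "hemiassoc_bad_argument")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_hemiassoc("alpha must be in (0, 1)", "hemiassoc_bad_argument")
  }
  exact <- alpha / m
  list(exact = exact, order_of_magnitude = 10^round(log10(exact)))
}

#' Risk ratio and odds ratio between two prevalences
#'
#' Small helpers for translating between the two effect-size scales used in
#' case-control power reasoning. `risk_ratio(0.30, 0.01)` is 30;
#' `odds_ratio_from_props(0.30, 0.01)` is (0.30/0.70)/(0.01/0.99), about
#' 42.4 — the two scales diverge once the risks are not small, which is why
#' a 30-fold prevalence ratio does not correspond to an odds ratio of 30.
#'
#' @param p1,p0 Proportions in (0, 1): exposed/affected vs reference.
#' @return A single number.
#' @export
risk_ratio <- function(p1, p0) {
  stopifnot(p1 > 0, p1 < 1, p0 > 0, p0 < 1)
  p1 / p0
}

#' @rdname risk_ratio
#' @export
odds_ratio_from_props <- function(p1, p0) {
  stopifnot(p1 > 0, p1 < 1, p0 > 0, p0 < 1)
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}
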