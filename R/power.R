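# Closed-form two-proportion sample-size and power calculations
# (normal approximation, no continuity correction). With the continuity
# correction the same inputs would give n ~ 474; without it the benchmark
# inputs (5% vs 10%, 80% power, two-sided 5%, 1:1) give 434.4 -> 435.

#' Required sample size per drug group for a two-proportion test
#'
#' Smallest integer `n` per drug group giving the target power for the
#' Pearson chi-squared test (normal approximation, no continuity
#' correction) of `p1` vs `p2` at two-sided level `alpha`, with the control
#' group `ratio` times the drug group:
#' \deqn{n = \frac{\left(z_{\alpha/2}\sqrt{(1+1/r)\,\bar p \bar q} +
#'   z_\beta\sqrt{p_1 q_1 + p_2 q_2 / r}\right)^2}{(p_1-p_2)^2}}
#' with the pooled rate \eqn{\bar p = (p_1 + r\,p_2)/(1+r)}.
#'
#' @param p1 True event rate in the drug group.
#' @param p2 True event rate in the control group.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param ratio Control-to-drug size ratio `n2/n1` (default 1).
#' @return Integer sample size per drug group (ceiling applied). The control
#'   group needs `ceiling(ratio * n)` patients.
#' @examples
#' required_n_per_group(0.05, 0.10)   # 435
#' @export
required_n_per_group <- function(p1, p2, alpha = 0.05, power = 0.80, ratio = 1) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, alpha > 0, alpha < 1,
            power > 0, power < 1, ratio > 0)
  if (p1 == p2) stop("`p1` and `p2` must differ (no finite sample size).",
                     call. = FALSE)
  r <- ratio
  pbar <- (p1 + r * p2) / (1 + r)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- (za * sqrt((1 + 1 / r) * pbar * (1 - pbar)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2) / r))^2 / (p1 - p2)^2
  as.integer(ceiling(n - 1e-9))
}

#' Approximate power of the two-proportion chi-squared test
#'
#' Normal-approximation power of the two-sided test,
#' \deqn{\Phi\!\left(\frac{\delta - z_{\alpha/2}\,SE_0}{SE_1}\right) +
#'       \Phi\!\left(\frac{-\delta - z_{\alpha/2}\,SE_0}{SE_1}\right)}
#' with \eqn{\delta = |p_1-p_2|}, where
#' \eqn{SE_0 = \sqrt{\bar p \bar q (1/n_1 + 1/n_2)}} uses the pooled
#' rate \eqn{\bar p = (n_1 p_1 + n_2 p_2)/(n_1+n_2)} and
#' \eqn{SE_1 = \sqrt{p_1 q_1/n_1 + p_2 q_2/n_2}} the unpooled rates. The
#' second (wrong-direction) term is negligible at practical effect sizes but
#' makes the power equal the size `alpha` at `p1 == p2`.
#'
#' Serves as the analytic cross-check on the simulated rejection rates:
#' increasing `n2` for fixed `n1` strictly increases power, which is the
#' mechanism by which unequal allocation to the shared placebo helps.
#'
#' @inheritParams required_n_per_group
#' @param n1,n2 Drug and control group sizes.
#' @return Power (vectorized over the inputs).
#' @examples
#' approx_power(0.075, 0.125, 435, 870)  # ~0.80
#' approx_power(0.10, 0.15, 435, 435)    # ~0.61
#' @export
approx_power <- function(p1, p2, n1, n2, alpha = 0.05) {
  stopifnot(all(n1 >= 1), all(n2 >= 1), alpha > 0, alpha < 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  za <- stats::qnorm(1 - alpha / 2)
  d <- abs(p1 - p2)
  ifelse(se1 == 0,
         as.numeric(d > za * se0),
         stats::pnorm((d - za * se0) / se1) + stats::pnorm((-d - za * se0) / se1))
}
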