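# Independent oracles used across the suite.

# Textbook Pearson chi-squared p-value for a 2x2 table (no continuity
# correction): X2 = N (ad - bc)^2 / (r1 r2 c1 c2).
pearson_p_oracle <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  x2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

# Two-sided Fisher exact p-value by full hypergeometric enumeration with
# the point-probability rule: sum the probabilities of all tables with the
# same margins whose probability does not exceed that of the observed table.
fisher_p_oracle <- function(a, b, c, d) {
  n1 <- a + b
  n2 <- c + d
  c1 <- a + c
  xs <- max(0, c1 - n2):min(c1, n1)
  probs <- stats::dhyper(xs, n1, n2, c1)
  obs <- stats::dhyper(a, n1, n2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact rejection probability of the implemented 2x2 test for two
# independent Binomial(n, .) arms, by full enumeration over the outcome
# lattice — the gold-standard oracle for simulated power.
exact_reject_oracle <- function(p1, p2, n = 435, alpha = 0.05) {
  pr1 <- stats::dbinom(0:n, n, p1)
  pr2 <- stats::dbinom(0:n, n, p2)
  tot <- 0
  for (d1 in 0:n) {
    if (pr1[d1 + 1] < 1e-14) next
    res <- platformsim:::two_prop_p(rep(d1, n + 1), n, 0:n, n)
    tot <- tot + pr1[d1 + 1] * sum(pr2[res$p < alpha])
  }
  tot
}

# Closed-form simple linear regression (y on x) coefficients.
ols_oracle <- function(x, y) {
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  c(intercept = alpha, slope = beta)
}

# Minimum expected cell count of a 2x2 table (Cochran's rule threshold).
min_expected <- function(a, b, c, d) {
  n <- a + b + c + d
  min(outer(c(a + b, c + d), c(a + c, b + d)) / n)
}

# A tiny hand-built platform-trial ledger used by concurrent-control tests:
# placebo enrolls months 0..6, drug D only months 3..6.
toy_pt_ledger <- function() {
  tibble::tibble(
    patient_id = 1:22,
    arm = c(rep("placebo", 14), rep("A", 4), rep("D", 4)),
    month = c(0:6, 0:6, 0:3, 3:6)
  )
}
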