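# helper: the five arm names of a four-drug trial
arm_names_for_test <- function() c("A", "B", "C", "D", "placebo")

test_that("outcome generation follows the per-arm Bernoulli rates", {
  led <- simulate_enrollment(build_design("MAT(1:1:1:1:1)"), 500, seed = 1)

  none <- assign_outcomes(led, rates = stats::setNames(rep(0, 5), arm_names_for_test()))
  expect_true(all(none$outcome == 0))
  all_die <- assign_outcomes(led, rates = stats::setNames(rep(1, 5), arm_names_for_test()))
  expect_true(all(all_die$outcome == 1))

  # placebo deaths ~ Binomial(435, 0.10): mean 43.5, checked within 3 SD
  out <- assign_outcomes(led, scenario_rates(4, 1, rp = 0.10), seed = 2)
  deaths <- sum(out$outcome[out$arm == "placebo"])
  expect_lt(abs(deaths - 43.5), 3 * sqrt(435 * 0.10 * 0.90))

  expect_error(assign_outcomes(led, c(A = 0.1)), "No mortality rate")
})

test_that("concurrent controls are the placebo patients inside the drug's enrollment window", {
  led <- toy_pt_ledger()
  # drug D enrolled months 3..6: placebo months 0..2 are excluded
  cc <- concurrent_controls(led, "D")
  expect_true(all(cc$arm == "placebo"))
  expect_true(all(cc$month >= 3 & cc$month <= 6))
  expect_equal(nrow(cc), 8)
  # drug A's window (months 0..3) covers part of the placebo accrual
  expect_equal(nrow(concurrent_controls(led, "A")), 8)
  # a window covering the whole placebo accrual returns everyone
  led2 <- dplyr::mutate(led, month = ifelse(arm == "D", c(rep(0, 18), 0, 2, 4, 6), month))
  expect_equal(nrow(concurrent_controls(led2, "D")), 14)
  expect_error(concurrent_controls(led, "Z"), "never enrolled")
})

test_that("the chi-squared branch reproduces the textbook Pearson formula", {
  # identical proportions: statistic 0, p = 1
  flat <- test_2x2(20, 435, 40, 870)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_false(flat$rejected)

  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(100:600, 1)
    n2 <- sample(100:900, 1)
    a <- stats::rbinom(1, n1, stats::runif(1, 0.05, 0.3))
    c_ <- stats::rbinom(1, n2, stats::runif(1, 0.05, 0.3))
    if (min_expected(a, n1 - a, c_, n2 - c_) < 5) next
    got <- test_2x2(a, n1, c_, n2)
    expect_equal(got$method, "chisq")
    expect_equal(got$p_value, pearson_p_oracle(a, n1 - a, c_, n2 - c_),
                 tolerance = 1e-10)
  }
})

test_that("the Fisher fallback matches exhaustive hypergeometric enumeration", {
  # sparse tables trigger Cochran's rule; enumerate all tables on a grid of
  # small margins plus the corner case with an empty cell
  for (n1 in c(4, 7, 10, 12)) {
    for (n2 in c(5, 8, 11)) {
      for (a in 0:min(n1, 4)) {
        for (c_ in 0:min(n2, 4)) {
          if (min_expected(a, n1 - a, c_, n2 - c_) >= 5) next
          got <- test_2x2(a, n1, c_, n2)
          expect_equal(got$method, "fisher")
          expect_equal(got$p_value, fisher_p_oracle(a, n1 - a, c_, n2 - c_),
                       tolerance = 1e-10)
        }
      }
    }
  }
  ex <- test_2x2(0, 10, 5, 10)
  expect_equal(ex$p_value, fisher_p_oracle(0, 10, 5, 5), tolerance = 1e-10)
  # zero death margin: no evidence either way
  expect_equal(test_2x2(0, 20, 0, 30)$p_value, 1)
})

test_that("swapping the two rows leaves the p-value unchanged", {
  cases <- list(c(22, 435, 60, 870), c(3, 12, 1, 9), c(50, 400, 30, 500))
  for (x in cases) {
    p1 <- test_2x2(x[1], x[2], x[3], x[4])$p_value
    p2 <- test_2x2(x[3], x[4], x[1], x[2])$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("analyze_trial tests each drug against its own concurrent controls", {
  led <- toy_pt_ledger()
  led$outcome <- c(1, 0, 0, 1, 0, 0, 0,  0, 0, 1, 0, 0, 0, 0,  # placebo
                   1, 0, 0, 0,  1, 1, 0, 1)                    # A, D
  dec <- analyze_trial(led, alpha = 0.05)
  expect_equal(dec$drug, c("A", "D"))
  # drug D: 3/4 deaths vs concurrent placebo months 3..6: 1/8
  d_manual <- test_2x2(3, 4, 1, 8)
  expect_equal(dec$p_value[dec$drug == "D"], d_manual$p_value)
  expect_equal(dec$n_control[dec$drug == "D"], 8)

  # a single-drug platform ledger reduces to the stand-alone analysis
  solo <- dplyr::filter(led, arm %in% c("A", "placebo"))
  dec_solo <- analyze_trial(solo)
  a_cc <- concurrent_controls(led, "A")
  expect_equal(dec_solo$p_value,
               test_2x2(1, 4, sum(a_cc$outcome), nrow(a_cc))$p_value)
})
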