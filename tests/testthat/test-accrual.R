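test_that("multi-arm trials hit their planned totals exactly", {
  for (s in 1:3) {
    led <- simulate_enrollment(build_design("MAT(1:1:1:1:2)"), 300, seed = s)
    counts <- dplyr::count(led, arm)
    expect_equal(counts$n[counts$arm == "placebo"], 870)
    expect_true(all(counts$n[counts$arm != "placebo"] == 435))
    expect_equal(nrow(led), 2610)
  }
  led_eq <- simulate_enrollment(build_design("MAT(1:1:1:1:1)"), 250, seed = 4)
  expect_equal(nrow(led_eq), 2175)
  expect_true(all(dplyr::count(led_eq, arm)$n == 435))
})

test_that("platform-trial drug arms end at exactly their cap and the placebo stops with them", {
  for (lab in c("PT(1:1:1:1:k)", "PT(1:1:1:1:1)", "PT-irr(1:1:1:1:k)")) {
    led <- simulate_enrollment(build_design(lab), 200, seed = 7)
    smry <- arm_summary(led)
    drugs <- dplyr::filter(smry, arm != "placebo")
    expect_true(all(drugs$enrolled == 435))
    # placebo enrollment cannot outlive the last drug arm
    expect_lte(smry$last_enroll_month[smry$arm == "placebo"],
               max(drugs$last_enroll_month))
    # staggered entry: first enrollment no earlier than the entry month
    entry <- attr(led, "entry_month")
    expect_true(all(drugs$first_enroll_month >= entry[drugs$arm]))
  }
})

test_that("a stand-alone set decomposes into independent 870-patient trials", {
  led <- simulate_enrollment(build_design("stand-alone"), 200, seed = 2)
  per_trial <- dplyr::count(led, trial)
  expect_equal(nrow(per_trial), 4)
  expect_true(all(per_trial$n == 870))
  a <- dplyr::filter(led, trial == "A")
  expect_equal(sort(unique(a$arm)), c("A", "placebo"))
  expect_equal(sum(a$arm == "A"), 435)
  expect_equal(sum(a$arm == "placebo"), 435)
})

test_that("identical seeds give identical ledgers", {
  d <- build_design("PT-irr(1:1:1:1:k)")
  expect_identical(
    as.data.frame(simulate_enrollment(d, 150, seed = 11)),
    as.data.frame(simulate_enrollment(d, 150, seed = 11))
  )
})

test_that("open_arms applies entry times, caps, and the placebo stop rule", {
  pt <- build_design("PT(1:1:1:1:k)")
  entry <- c(A = 0L, B = 1L, C = 2L, D = 3L)
  expect_equal(open_arms(pt, entry, month = 0), c("A", "placebo"))
  expect_equal(open_arms(pt, entry, month = 3), c("A", "B", "C", "D", "placebo"))
  # all drugs at cap: everything closed, including the placebo
  expect_equal(open_arms(pt, entry, month = 10, enrolled = c(rep(435L, 4), 50L)),
               character(0))
  # one drug still open keeps the placebo open
  expect_equal(open_arms(pt, entry, month = 10, enrolled = c(435L, 435L, 435L, 100L, 50L)),
               c("D", "placebo"))
})

test_that("allocation fractions track the weights (goodness of fit on 1e5 patients)", {
  big <- 100000L
  # one drug + placebo under the dynamic rule: 1:1
  d1 <- trial_design("pt", n_drugs = 4, allocation = "dynamic_k",
                     per_drug_cap = big)
  x <- allocate_month(d1, 1000L, open_drugs = "A", seed = 1)
  expect_equal(sum(x), 1000)
  expect_gt(stats::chisq.test(c(x[["A"]], x[["placebo"]]))$p.value, 0.001)

  # four open drugs: equal weights 1/5 each...
  deq <- trial_design("mat", n_drugs = 4, allocation = "equal",
                      per_drug_cap = big)
  xeq <- allocate_month(deq, big, seed = 2)
  expect_gt(stats::chisq.test(xeq, p = rep(1 / 5, 5))$p.value, 0.001)

  # ...fixed unequal 1:1:1:1:2...
  dun <- trial_design("mat", n_drugs = 4, allocation = "fixed_unequal",
                      per_drug_cap = big, placebo_weight = 2)
  xun <- allocate_month(dun, big, seed = 3)
  expect_gt(stats::chisq.test(xun, p = c(rep(1, 4), 2) / 6)$p.value, 0.001)

  # ...and dynamic square root with k = 4: placebo weight 2
  ddy <- trial_design("mat", n_drugs = 4, allocation = "dynamic_k",
                      per_drug_cap = big)
  xdy <- allocate_month(ddy, big, seed = 4)
  expect_gt(stats::chisq.test(xdy, p = c(rep(1, 4), 2) / 6)$p.value, 0.001)
})

test_that("the compiled engine matches the weight fractions too", {
  # month 3 of a slow-filling platform trial has all four drugs open;
  # shares should be 1:1:1:1:sqrt(4) over 6 weight units
  d <- trial_design("pt", n_drugs = 4, allocation = "dynamic_k",
                    per_drug_cap = 50000)
  set.seed(5)
  res <- platformsim:::sim_arm_counts(d, lambda = 20000)
  row <- res$counts[4, ]
  expect_gt(stats::chisq.test(row, p = c(rep(1, 4), 2) / 6)$p.value, 0.001)
})

test_that("capped arms never overshoot even when a month overflows them", {
  # tiny caps with a huge month force mid-month closures and k updates
  d <- trial_design("pt", n_drugs = 4, allocation = "dynamic_k",
                    per_drug_cap = 50)
  for (s in 1:5) {
    led <- simulate_enrollment(d, 5000, seed = s)
    counts <- dplyr::count(led, arm)
    expect_true(all(counts$n[counts$arm != "placebo"] == 50))
  }
  # fixed-unequal placebo cap binds: drugs keep enrolling after placebo closes
  dm <- build_design("MAT(1:1:1:1:2)")
  led <- simulate_enrollment(dm, 2000, seed = 6)
  expect_equal(sum(led$arm == "placebo"), 870)
  expect_equal(nrow(led), 2610)
})
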