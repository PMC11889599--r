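test_that("the slope fit reproduces hand-computed least squares", {
  # three hand-listed points: x = 100, 200, 300 patients; y = 1, 3, 5 points
  pts <- tibble::tibble(delta_placebo = c(100, 200, 300),
                        delta_power = c(1, 3, 5))
  fit <- fit_slope(pts)
  oracle <- ols_oracle(pts$delta_placebo / 100, pts$delta_power)
  expect_equal(fit$slope_per_100, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, -1, tolerance = 1e-12)
  expect_equal(fit$slope_per_100, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-12)
})

test_that("collinear points give the exact slope with a degenerate interval", {
  pts <- tibble::tibble(delta_placebo = c(100, 250, 400, 550),
                        delta_power = 2 * c(1, 2.5, 4, 5.5))
  fit <- fit_slope(pts)
  expect_equal(fit$slope_per_100, 2, tolerance = 1e-10)
  expect_equal(unname(fit$ci95["upper"] - fit$ci95["lower"]), 0,
               tolerance = 1e-8)
})

test_that("least squares matches the closed form on random fixtures", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- stats::runif(n, 50, 1500)
    y <- 0.02 * x + stats::rnorm(n, sd = 2)
    fit <- fit_slope(tibble::tibble(delta_placebo = x, delta_power = y))
    oracle <- ols_oracle(x / 100, y)
    expect_equal(fit$slope_per_100, unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
    # the interval always contains its own point estimate
    expect_gte(fit$slope_per_100, fit$ci95[["lower"]])
    expect_lte(fit$slope_per_100, fit$ci95[["upper"]])
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_slope(tibble::tibble(delta_placebo = c(1, 2),
                                        delta_power = c(1, 2))),
               "at least 3")
  expect_error(fit_slope(tibble::tibble(delta_placebo = rep(100, 5),
                                        delta_power = 1:5)),
               "constant")
})

test_that("a through-origin fit is available and pins the intercept at zero", {
  pts <- tibble::tibble(delta_placebo = c(100, 200, 300, 400),
                        delta_power = c(1.1, 3.0, 4.9, 7.2))
  fit <- fit_slope(pts, origin = TRUE)
  expect_equal(fit$intercept, 0)
  # closed-form through-origin slope: sum(xy)/sum(x^2)
  x <- pts$delta_placebo / 100
  expect_equal(fit$slope_per_100, sum(x * pts$delta_power) / sum(x^2),
               tolerance = 1e-12)
})

test_that("tidy, glance, and autoplot surface the fit", {
  pts <- tibble::tibble(delta_placebo = c(120, 260, 380, 450, 600),
                        delta_power = c(1.5, 3.1, 5.2, 6.8, 9.9))
  fit <- fit_slope(pts)
  td <- tidy(fit)
  expect_setequal(td$term, c("intercept", "slope_per_100"))
  gl <- glance(fit)
  expect_equal(gl$slope_per_100, fit$slope_per_100)
  expect_equal(gl$n_points, 5)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("point construction pairs cells and applies the saturation exclusion", {
  designs <- c("PT(1:1:1:1:k)", "PT(1:1:1:1:1)")
  grid <- run_oc_grid(designs, scenarios = c(1, 5), rps = c(0.05, 0.125),
                      accrual_means = 300, n_reps = 30, seed = 13)
  # rp = 5% cells are excluded by default; scenario 1 has no effective drug
  pts <- build_points(grid, designs[1], designs[2])
  expect_equal(nrow(pts), 1)
  expect_equal(pts$rp, 0.125)
  expect_equal(pts$scenario, 5)

  # an all-saturated grid yields no points
  grid5 <- run_oc_grid(designs, scenarios = 5, rps = 0.05,
                       accrual_means = 300, n_reps = 30, seed = 14)
  expect_equal(nrow(build_points(grid5, designs[1], designs[2])), 0)

  # unpaired runs are an error
  expect_error(build_points(dplyr::filter(grid, design == designs[1]),
                            designs[1], designs[2]),
               "must contain both")
})

test_that("null-scenario paired comparisons show no systematic gain", {
  designs <- c("PT(1:1:1:1:k)", "PT(1:1:1:1:1)")
  grid <- run_oc_grid(designs, scenarios = 1, rps = 0.10,
                      accrual_means = 200, n_reps = 400, seed = 15)
  a <- grid$oc[[which(grid$design == designs[1])]]
  b <- grid$oc[[which(grid$design == designs[2])]]
  cmp <- compare_designs(a, b)
  # average type I error difference within Monte Carlo noise of zero
  expect_lt(abs(cmp$delta_avg_tie), 3 * sqrt(2) * mc_se(0.05, 400))
})
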