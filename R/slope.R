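# Regression of the unequal-minus-equal power gain on the placebo-group
# size increase.

#' Run a grid of operating-characteristic simulations
#'
#' Simulates every combination of design x scenario x placebo rate x accrual
#' mean with an independent, reproducibly seed-derived random stream per
#' cell, and returns one row per cell with the headline operating
#' characteristics (full per-drug tables in a list column).
#'
#' Per-cell seeds are drawn once from `sample.int(2^31 - 2, n_cells)` under
#' `set.seed(seed)`, so a given master seed always maps to the same
#' per-cell streams and cells are mutually independent.
#'
#' @param designs Character vector of design labels ([build_design()]).
#' @param scenarios Integer scenario indices.
#' @param rps Numeric vector of true placebo mortality rates.
#' @param accrual_means Numeric vector of mean monthly accruals.
#' @param n_reps Replicates per cell.
#' @param n_drugs Number of drug arms (default 4).
#' @param alpha Two-sided level per drug.
#' @param seed Master seed (integer).
#' @param verbose Print one line per cell as it completes.
#' @return A tibble with one row per cell: design labels, `avg_power`,
#'   `avg_tie`, `overall_power`, `mean_total_placebo`, `mean_months`,
#'   `n_reps`, `cell_seed`, and the `oc_summary` in list column `oc`.
#' @export
run_oc_grid <- function(designs, scenarios, rps, accrual_means, n_reps,
                        n_drugs = 4, alpha = 0.05, seed = 1, verbose = FALSE) {
  grid <- tidyr::expand_grid(
    design = designs, scenario = scenarios, rp = rps,
    accrual_mean = accrual_means
  )
  set.seed(seed)
  grid$cell_seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- purrr::pmap(grid, function(design, scenario, rp, accrual_mean, cell_seed) {
    oc <- simulate_oc(build_design(design, n_drugs = n_drugs),
                      scenario = scenario, rp = rp,
                      accrual_mean = accrual_mean, n_reps = n_reps,
                      alpha = alpha, seed = cell_seed)
    if (verbose) {
      message(sprintf("%-18s scenario %d  RP %4.1f%%  accrual %3d: avg power %s",
                      design, scenario, 100 * rp, accrual_mean,
                      format(oc$avg_power, digits = 3)))
    }
    dplyr::bind_cols(glance(oc), tibble::tibble(cell_seed = cell_seed,
                                                oc = list(oc)))
  })
  dplyr::bind_rows(rows)
}

#' Build regression points from paired equal/unequal grid runs
#'
#' Pairs the unequal- and equal-allocation rows of a [run_oc_grid()] result
#' cell by cell and computes, per (scenario, rp, accrual mean), the power
#' difference (average group-specific power over effective drugs, unequal
#' minus equal, in percentage points) and the placebo-size difference (mean
#' total placebo patients, unequal minus equal). Cells whose scenario has no
#' effective drug are dropped, as are cells with `rp` in `exclude_rp`:
#' at a placebo mortality of 5% both designs sit at 100% power, so those
#' cells carry no information about the power gain.
#'
#' @param grid A [run_oc_grid()] result containing both designs.
#' @param unequal,equal Design labels of the unequal and equal runs.
#' @param exclude_rp Placebo rates to drop (default 0.05).
#' @return A tibble of regression points: `scenario`, `rp`, `accrual_mean`,
#'   `delta_placebo` (patients), `delta_power` (percentage points).
#' @export
build_points <- function(grid, unequal, equal, exclude_rp = 0.05) {
  need <- c(unequal, equal)
  if (!all(need %in% grid$design)) {
    stop("Grid must contain both designs: ", paste(need, collapse = " and "),
         call. = FALSE)
  }
  keyed <- grid |>
    dplyr::filter(.data$design %in% need, !is.na(.data$avg_power)) |>
    dplyr::select(dplyr::all_of(c("design", "scenario", "rp", "accrual_mean",
                                  "avg_power", "mean_total_placebo")))
  u <- dplyr::filter(keyed, .data$design == unequal)
  e <- dplyr::filter(keyed, .data$design == equal)
  pts <- dplyr::inner_join(u, e, by = c("scenario", "rp", "accrual_mean"),
                           suffix = c("_u", "_e"))
  if (nrow(pts) < max(nrow(u), nrow(e))) {
    stop("Unpaired cells: the two designs were not run on the same grid.",
         call. = FALSE)
  }
  pts |>
    dplyr::filter(!purrr::map_lgl(.data$rp, ~ any(abs(.x - exclude_rp) < 1e-12))) |>
    dplyr::transmute(
      scenario = .data$scenario, rp = .data$rp,
      accrual_mean = .data$accrual_mean,
      delta_placebo = .data$mean_total_placebo_u - .data$mean_total_placebo_e,
      delta_power = 100 * (.data$avg_power_u - .data$avg_power_e)
    )
}

#' Fit the power-gain-per-placebo-patient regression
#'
#' Ordinary least squares of the power difference (percentage points) on the
#' placebo-size difference divided by 100, so the slope reads as percentage
#' points of average power gained per 100 additional placebo patients. An
#' intercept is included by default; `origin = TRUE` forces the fit through
#' the origin.
#'
#' @param points A tibble from [build_points()] (columns `delta_placebo`,
#'   `delta_power`).
#' @param origin Fit through the origin instead of estimating an intercept.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return A `slope_fit` object: slope per 100 patients with its confidence
#'   interval, intercept, point count, and the underlying `lm` fit.
#' @examples
#' pts <- tibble::tibble(delta_placebo = c(100, 200, 300),
#'                       delta_power = c(1, 3, 5))
#' fit_slope(pts)   # slope 2, intercept -1
#' @export
fit_slope <- function(points, origin = FALSE, conf_level = 0.95) {
  stopifnot(is.data.frame(points),
            all(c("delta_placebo", "delta_power") %in% names(points)))
  if (nrow(points) < 3) stop("Need at least 3 points.", call. = FALSE)
  if (stats::sd(points$delta_placebo) == 0) {
    stop("`delta_placebo` is constant; the slope is not identifiable.",
         call. = FALSE)
  }
  dat <- data.frame(x = points$delta_placebo / 100, y = points$delta_power)
  fit <- if (origin) stats::lm(y ~ x + 0, data = dat) else stats::lm(y ~ x, data = dat)
  co <- stats::coef(fit)
  ci <- suppressWarnings(stats::confint(fit, "x", level = conf_level))
  ci[is.na(ci)] <- co[["x"]]  # zero-residual fits: degenerate interval
  structure(
    list(
      slope_per_100 = unname(co[["x"]]),
      ci95 = c(lower = ci[1], upper = ci[2]),
      intercept = if (origin) 0 else unname(co[["(Intercept)"]]),
      n_points = nrow(points),
      conf_level = conf_level,
      fit = fit,
      points = tibble::as_tibble(points)
    ),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> %.2f %%-points average power per 100 placebo patients (%d%% CI %.2f to %.2f), intercept %.2f, %d points\n",
    x$slope_per_100, round(100 * x$conf_level), x$ci95[["lower"]],
    x$ci95[["upper"]], x$intercept, x$n_points
  ))
  invisible(x)
}

#' Tidy a slope fit
#'
#' @param x A `slope_fit`.
#' @param ... Unused.
#' @return A tibble of coefficients on the per-100-patient scale with
#'   standard errors and confidence bounds.
#' @method tidy slope_fit
#' @export
tidy.slope_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  ci <- suppressWarnings(stats::confint(x$fit, level = x$conf_level))
  tibble::tibble(
    term = ifelse(rownames(s) == "x", "slope_per_100", "intercept"),
    estimate = s[, 1],
    std_error = s[, 2],
    statistic = s[, 3],
    p_value = s[, 4],
    conf_low = ci[, 1],
    conf_high = ci[, 2]
  )
}

#' One-row summary of a slope fit
#'
#' @param x A `slope_fit`.
#' @param ... Unused.
#' @return A one-row tibble: slope per 100 placebo patients, its confidence
#'   interval, intercept, R-squared, and point count.
#' @method glance slope_fit
#' @export
glance.slope_fit <- function(x, ...) {
  tibble::tibble(
    slope_per_100 = x$slope_per_100,
    conf_low = x$ci95[["lower"]],
    conf_high = x$ci95[["upper"]],
    intercept = x$intercept,
    r_squared = summary(x$fit)$r.squared,
    n_points = x$n_points
  )
}

#' Plot the power-gain regression
#'
#' Scatter of the per-cell power difference against the placebo-size
#' difference with the fitted line.
#'
#' @param object A `slope_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot slope_fit
#' @export
autoplot.slope_fit <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$delta_placebo, y = .data$delta_power)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope_per_100 / 100,
                         color = "steelblue") +
    ggplot2::labs(
      x = "increase in total placebo patients (unequal - equal)",
      y = "average power difference (percentage points)",
      title = sprintf("%.2f %%-points per 100 placebo patients (CI %.2f to %.2f)",
                      object$slope_per_100, object$ci95[["lower"]],
                      object$ci95[["upper"]])
    ) +
    ggplot2::theme_minimal()
}
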