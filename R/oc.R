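# Replicated simulation and aggregation into operating characteristics.

#' Monte Carlo standard error of a simulated proportion
#'
#' @param p Estimated proportion(s).
#' @param n_reps Number of simulation replicates.
#' @return `sqrt(p * (1 - p) / n_reps)`.
#' @export
mc_se <- function(p, n_reps) sqrt(p * (1 - p) / n_reps)

# One replicate, fast path: simulate enrollment counts, draw deaths per
# (arm, month) cell, and return the per-drug 2x2 ingredients plus trial-level
# placebo totals. Binomial draws per cell are distributionally identical to
# per-patient Bernoulli outcomes.
sim_replicate <- function(design, rates, lambda) {
  m <- design$n_drugs
  if (design$design == "standalone") {
    sub <- standalone_unit(design)
    per_drug <- matrix(0, m, 4)
    tot_pl <- 0
    months <- 0
    for (d in seq_len(m)) {
      res <- sim_arm_counts(sub, lambda, rates = c(rates[d], rates[m + 1]),
                            keep_counts = FALSE)
      per_drug[d, ] <- res$per_drug
      tot_pl <- tot_pl + res$per_drug[1, 3]
      months <- max(months, res$months)
    }
    return(list(per_drug = per_drug, total_placebo = tot_pl, months = months))
  }
  res <- sim_arm_counts(design, lambda, rates = rates, keep_counts = FALSE)
  list(per_drug = res$per_drug, total_placebo = res$enrolled[m + 1],
       months = res$months)
}

#' Simulate operating characteristics of a design under one scenario
#'
#' Runs `n_reps` independent trial replicates of `design` under the true
#' mortality rates of `scenario` (see [scenario_rates()]), tests every drug
#' against its concurrent controls, and aggregates rejection proportions and
#' sample-size statistics.
#'
#' @param design A [trial_design()] or a label accepted by [build_design()].
#' @param scenario Scenario index in `1..(n_drugs + 1)` (scenario `s` has
#'   `s - 1` effective drugs).
#' @param rp True placebo mortality rate.
#' @param accrual_mean Mean total arrivals per month (Poisson).
#' @param n_reps Number of replicates (10,000 for full-precision runs).
#' @param alpha Two-sided significance level per drug (default 0.05).
#' @param seed Optional integer seed.
#' @param rd True mortality of an effective drug (default `rp - 0.05`).
#' @param keep_decisions Retain the per-replicate decision table (for
#'   debugging; off by default so long runs need no replicate storage).
#' @return An `oc_summary` object; see [summarize_decisions()] for its
#'   contents, and [tidy.oc_summary()] / [glance.oc_summary()] for tabular
#'   views.
#' @examples
#' oc <- simulate_oc("MAT(1:1:1:1:2)", scenario = 5, rp = 0.125,
#'                   accrual_mean = 200, n_reps = 200, seed = 1)
#' glance(oc)
#' @export
simulate_oc <- function(design, scenario, rp, accrual_mean, n_reps,
                        alpha = 0.05, seed = NULL, rd = rp - 0.05,
                        keep_decisions = FALSE) {
  if (is.character(design)) design <- build_design(design)
  stopifnot(inherits(design, "trial_design"))
  if (n_reps < 1) stop("`n_reps` must be at least 1.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- design$n_drugs
  rates <- scenario_rates(m, scenario, rp, rd)
  effective <- attr(rates, "effective")

  n_d <- d_d <- n_c <- d_c <- matrix(0, n_reps, m)
  total_pl <- months <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    rep <- sim_replicate(design, rates, accrual_mean)
    n_d[r, ] <- rep$per_drug[, 1]
    d_d[r, ] <- rep$per_drug[, 2]
    n_c[r, ] <- rep$per_drug[, 3]
    d_c[r, ] <- rep$per_drug[, 4]
    total_pl[r] <- rep$total_placebo
    months[r] <- rep$months
  }
  p <- two_prop_p(as.vector(d_d), as.vector(n_d), as.vector(d_c), as.vector(n_c))
  decisions <- tibble::tibble(
    replicate = rep(seq_len(n_reps), m),
    drug = rep(LETTERS[seq_len(m)], each = n_reps),
    effective = rep(effective, each = n_reps),
    n_drug = as.vector(n_d),
    deaths_drug = as.vector(d_d),
    n_concurrent = as.vector(n_c),
    deaths_control = as.vector(d_c),
    p_value = p$p,
    rejected = p$p < alpha,
    total_placebo = rep(total_pl, m),
    months = rep(months, m)
  )
  out <- summarize_decisions(decisions, n_reps = n_reps)
  out$design <- format(design)
  out$n_drugs <- m
  out$scenario <- scenario
  out$rp <- rp
  out$rd <- rd
  out$accrual_mean <- accrual_mean
  out$alpha <- alpha
  if (keep_decisions) out$decisions <- decisions
  out
}

#' Aggregate per-replicate decisions into operating characteristics
#'
#' Computes the per-drug rejection proportion (group-specific power for
#' effective drugs, type I error rate for ineffective drugs), the overall
#' power (probability that at least one effective drug is declared
#' efficacious; absent when the scenario has no effective drug), mean
#' concurrent-control sizes, placebo totals and trial duration, all with
#' Monte Carlo standard errors `sqrt(p(1-p)/n_reps)` for proportions.
#'
#' @param decisions A tibble of per-replicate, per-drug decisions with
#'   columns `replicate`, `drug`, `effective`, `rejected`, `n_concurrent`,
#'   and optionally `total_placebo` and `months`.
#' @param n_reps Number of replicates (defaults to the number of distinct
#'   `replicate` values).
#' @return An `oc_summary` object: a list with elements `per_drug` (tibble),
#'   `overall_power`, `avg_power`, `avg_tie`, `placebo` (tibble), `n_reps`.
#' @export
summarize_decisions <- function(decisions, n_reps = dplyr::n_distinct(decisions$replicate)) {
  per_drug <- decisions |>
    dplyr::group_by(.data$drug, .data$effective) |>
    dplyr::summarise(
      reject_rate = mean(.data$rejected),
      mean_concurrent = mean(.data$n_concurrent),
      .groups = "drop"
    ) |>
    dplyr::mutate(mc_se = mc_se(.data$reject_rate, n_reps)) |>
    dplyr::arrange(.data$drug)

  any_eff <- any(per_drug$effective)
  overall <- if (any_eff) {
    decisions |>
      dplyr::filter(.data$effective) |>
      dplyr::group_by(.data$replicate) |>
      dplyr::summarise(any_reject = any(.data$rejected), .groups = "drop") |>
      dplyr::pull(.data$any_reject) |>
      mean()
  } else {
    NA_real_
  }

  placebo <- if ("total_placebo" %in% names(decisions)) {
    decisions |>
      dplyr::distinct(.data$replicate, .data$total_placebo, .data$months) |>
      dplyr::summarise(
        mean_total_placebo = mean(.data$total_placebo),
        sd_total_placebo = stats::sd(.data$total_placebo),
        mean_months = mean(.data$months)
      )
  } else {
    tibble::tibble(mean_total_placebo = NA_real_, sd_total_placebo = NA_real_,
                   mean_months = NA_real_)
  }

  structure(
    list(
      per_drug = per_drug,
      overall_power = overall,
      avg_power = if (any_eff) mean(per_drug$reject_rate[per_drug$effective]) else NA_real_,
      avg_tie = if (any(!per_drug$effective)) mean(per_drug$reject_rate[!per_drug$effective]) else NA_real_,
      placebo = placebo,
      n_reps = n_reps
    ),
    class = "oc_summary"
  )
}

#' @export
print.oc_summary <- function(x, ...) {
  cat("<oc_summary>", if (!is.null(x$design)) x$design else "", "\n")
  if (!is.null(x$scenario)) {
    cat("  scenario ", x$scenario, ", RP = ", 100 * x$rp, "%, RD = ",
        100 * x$rd, "%, accrual ", x$accrual_mean, "/month, ",
        x$n_reps, " replicates\n", sep = "")
  }
  print(x$per_drug)
  cat("  overall power: ", format(x$overall_power), "\n", sep = "")
  cat("  mean total placebo: ", format(x$placebo$mean_total_placebo),
      " over ", format(x$placebo$mean_months), " months\n", sep = "")
  invisible(x)
}

#' Tidy an operating-characteristic summary
#'
#' @param x An `oc_summary`.
#' @param ... Unused.
#' @return A long tibble: one row per (metric, drug) with `estimate` and
#'   `mc_se` (NA for non-proportion metrics), carrying the run labels.
#' @method tidy oc_summary
#' @export
tidy.oc_summary <- function(x, ...) {
  base <- tibble::tibble(
    design = x$design %||% NA_character_,
    scenario = x$scenario %||% NA_integer_,
    rp = x$rp %||% NA_real_,
    accrual_mean = x$accrual_mean %||% NA_real_,
    n_reps = x$n_reps
  )
  per <- x$per_drug |>
    dplyr::transmute(
      metric = ifelse(.data$effective, "group_specific_power", "type_I_error"),
      drug = .data$drug,
      estimate = .data$reject_rate,
      mc_se = .data$mc_se
    )
  conc <- x$per_drug |>
    dplyr::transmute(metric = "mean_concurrent_control", drug = .data$drug,
                     estimate = .data$mean_concurrent, mc_se = NA_real_)
  glob <- tibble::tibble(
    metric = c("overall_power", "mean_total_placebo", "mean_months"),
    drug = NA_character_,
    estimate = c(x$overall_power, x$placebo$mean_total_placebo, x$placebo$mean_months),
    mc_se = c(if (is.na(x$overall_power)) NA_real_ else mc_se(x$overall_power, x$n_reps),
              NA_real_, NA_real_)
  )
  dplyr::cross_join(base, dplyr::bind_rows(per, conc, glob))
}

#' One-row summary of an operating-characteristic run
#'
#' @param x An `oc_summary`.
#' @param ... Unused.
#' @return A one-row tibble: average group-specific power over effective
#'   drugs, average type I error over ineffective drugs, overall power,
#'   mean total placebo count, mean duration, and replicate count.
#' @method glance oc_summary
#' @export
glance.oc_summary <- function(x, ...) {
  tibble::tibble(
    design = x$design %||% NA_character_,
    scenario = x$scenario %||% NA_integer_,
    rp = x$rp %||% NA_real_,
    rd = x$rd %||% NA_real_,
    accrual_mean = x$accrual_mean %||% NA_real_,
    avg_power = x$avg_power,
    avg_tie = x$avg_tie,
    overall_power = x$overall_power,
    mean_total_placebo = x$placebo$mean_total_placebo,
    mean_months = x$placebo$mean_months,
    n_reps = x$n_reps
  )
}

#' Paired differences between two design runs
#'
#' Signed differences (A minus B; call with the unequal-allocation run
#' first) of the average group-specific power over effective drugs, the
#' average type I error rate over ineffective drugs, and the mean total
#' placebo count, for two runs under the same scenario and settings.
#'
#' @param oc_a,oc_b `oc_summary` objects from [simulate_oc()] under
#'   identical scenario, rates, and accrual settings.
#' @return A one-row tibble with `delta_avg_power`, `delta_avg_tie`,
#'   `delta_total_placebo` and the shared run labels.
#' @export
compare_designs <- function(oc_a, oc_b) {
  stopifnot(inherits(oc_a, "oc_summary"), inherits(oc_b, "oc_summary"))
  same <- function(f) identical(oc_a[[f]], oc_b[[f]])
  if (!all(vapply(c("scenario", "rp", "rd", "accrual_mean"), same, logical(1)))) {
    stop("The two runs were not simulated under the same scenario/settings.",
         call. = FALSE)
  }
  tibble::tibble(
    design_a = oc_a$design %||% NA_character_,
    design_b = oc_b$design %||% NA_character_,
    scenario = oc_a$scenario,
    rp = oc_a$rp,
    accrual_mean = oc_a$accrual_mean,
    delta_avg_power = oc_a$avg_power - oc_b$avg_power,
    delta_avg_tie = oc_a$avg_tie - oc_b$avg_tie,
    delta_total_placebo = oc_a$placebo$mean_total_placebo - oc_b$placebo$mean_total_placebo
  )
}

#' Plot per-drug rejection proportions of an OC run
#'
#' Bar chart of the per-drug rejection proportion with 95% Monte Carlo
#' error bars; effective and ineffective drugs are colored separately.
#'
#' @param object An `oc_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oc_summary
#' @export
autoplot.oc_summary <- function(object, ...) {
  dat <- object$per_drug |>
    dplyr::mutate(role = ifelse(.data$effective, "effective (power)",
                                "ineffective (type I error)"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$drug, y = .data$reject_rate,
                                    fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$reject_rate - 1.96 * .data$mc_se,
                   ymax = .data$reject_rate + 1.96 * .data$mc_se),
      width = 0.2
    ) +
    ggplot2::labs(
      x = "drug arm", y = "rejection proportion",
      title = object$design %||% NULL,
      subtitle = if (!is.null(object$scenario)) {
        sprintf("scenario %d, RP = %g%%, accrual %g/month, %d replicates",
                object$scenario, 100 * object$rp, object$accrual_mean,
                object$n_reps)
      },
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}
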