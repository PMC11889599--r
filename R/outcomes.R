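# Outcome generation, concurrent-control extraction, and the per-drug
# two-by-two test.

#' Assign Bernoulli mortality outcomes to an enrollment ledger
#'
#' Each patient independently dies with the true mortality rate of their arm
#' (`outcome` 1 = death, 0 = survival).
#'
#' @param ledger An enrollment ledger from [simulate_enrollment()].
#' @param rates Named true mortality rates covering every arm in the ledger,
#'   e.g. from [scenario_rates()].
#' @param seed Optional seed.
#' @return The ledger with an `outcome` column added.
#' @export
assign_outcomes <- function(ledger, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  missing <- setdiff(unique(ledger$arm), names(rates))
  if (length(missing)) {
    stop("No mortality rate supplied for arm(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- unname(rates[ledger$arm])
  if (any(p < 0 | p > 1)) stop("Mortality rates must lie in [0, 1].", call. = FALSE)
  ledger$outcome <- stats::rbinom(nrow(ledger), 1L, p)
  ledger
}

#' Concurrent controls for one drug arm
#'
#' The only placebo patients used in a drug's analysis are those enrolled
#' while that drug was actively enrolling: placebo patients whose enrollment
#' month `m` satisfies `first_enroll_month(drug) <= m <= last_enroll_month(drug)`
#' (inclusive bounds on actual, not nominal, enrollment months).
#'
#' This month-window rule is what makes staggered (platform) designs
#' different from simultaneous ones. In a stand-alone or multi-arm trial all
#' arms share a single enrollment period by design, so every placebo
#' patient is concurrent with every drug; [analyze_trial()] and
#' [simulate_oc()] therefore use the full placebo group for
#' simultaneous-entry designs rather than the realized month window (whose
#' month-resolution tail could otherwise drop a handful of placebo patients
#' enrolled after a drug arm happened to fill first).
#'
#' @param ledger An enrollment ledger (outcomes optional).
#' @param drug Drug arm name, e.g. `"A"`.
#' @return The subset of placebo rows concurrent with `drug`.
#' @export
concurrent_controls <- function(ledger, drug) {
  if ("trial" %in% names(ledger)) {
    ledger <- dplyr::filter(ledger, .data$trial == drug)
  }
  dm <- ledger$month[ledger$arm == drug]
  if (!length(dm)) stop("Drug ", sQuote(drug), " never enrolled.", call. = FALSE)
  win <- range(dm)
  dplyr::filter(ledger, .data$arm == "placebo",
                .data$month >= win[1], .data$month <= win[2])
}

# Vectorized two-proportion p-value: Pearson chi-squared without continuity
# correction; Fisher's exact test (two-sided, point-probability method) when
# any expected cell count is below 5 (Cochran's rule). Zero margins fall
# through to Fisher, where the p-value is 1.
two_prop_p <- function(deaths_drug, n_drug, deaths_control, n_control) {
  a <- as.numeric(deaths_drug)           # doubles: (ad - bc)^2 overflows
  b <- as.numeric(n_drug) - a            # 32-bit integers at these n
  c_ <- as.numeric(deaths_control)
  d <- as.numeric(n_control) - c_
  n_drug <- a + b
  n_control <- c_ + d
  n <- n_drug + n_control
  stat <- n * (a * d - b * c_)^2 / (n_drug * n_control * (a + c_) * (b + d))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  min_exp <- pmin(n_drug * (a + c_), n_drug * (b + d),
                  n_control * (a + c_), n_control * (b + d)) / n
  fisher <- is.na(min_exp) | min_exp < 5
  method <- ifelse(fisher, "fisher", "chisq")
  if (any(fisher)) {
    for (i in which(fisher)) {
      tab <- matrix(c(a[i], b[i], c_[i], d[i]), nrow = 2, byrow = TRUE)
      p[i] <- stats::fisher.test(tab)$p.value
      stat[i] <- NA_real_
    }
  }
  list(p = p, statistic = stat, method = method)
}

#' Two-by-two test of a drug against its concurrent controls
#'
#' Pearson chi-squared test without continuity correction on the 2x2
#' death/survival table; when any expected cell count is below 5 (Cochran's
#' rule) Fisher's exact test (two-sided) is used instead. Efficacy is
#' declared when `p < alpha` in either direction.
#'
#' @param deaths_drug,n_drug Deaths and total patients in the drug arm.
#' @param deaths_control,n_control Deaths and total concurrent controls.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A one-row tibble: `p_value`, `statistic` (NA on the Fisher path),
#'   `method`, `rejected`, observed rates, and group sizes.
#' @examples
#' test_2x2(20, 435, 40, 870)
#' @export
test_2x2 <- function(deaths_drug, n_drug, deaths_control, n_control,
                     alpha = 0.05) {
  stopifnot(length(deaths_drug) == 1)
  if (n_drug <= 0 || n_control <= 0) {
    stop("Both group sizes must be positive.", call. = FALSE)
  }
  if (deaths_drug < 0 || deaths_drug > n_drug ||
      deaths_control < 0 || deaths_control > n_control) {
    stop("Death counts must lie between 0 and the group size.", call. = FALSE)
  }
  res <- two_prop_p(deaths_drug, n_drug, deaths_control, n_control)
  tibble::tibble(
    p_value = res$p,
    statistic = res$statistic,
    method = res$method,
    rejected = res$p < alpha,
    rate_drug = deaths_drug / n_drug,
    rate_control = deaths_control / n_control,
    n_drug = n_drug,
    n_control = n_control
  )
}

#' Analyze one trial replicate: per-drug efficacy decisions
#'
#' For each drug arm, builds the 2x2 table of deaths/survivors against its
#' own concurrent-control placebo patients and applies [test_2x2()]. Each
#' drug is tested at the unadjusted two-sided level `alpha` (no multiplicity
#' adjustment across drugs).
#'
#' @param ledger An enrollment ledger with outcomes ([assign_outcomes()]).
#' @param alpha Two-sided significance level.
#' @param full_overlap Use the whole placebo group as every drug's
#'   concurrent control, as appropriate for simultaneous-entry designs
#'   (stand-alone, multi-arm) whose arms share one enrollment period; the
#'   default applies the per-drug month window of [concurrent_controls()].
#' @return A tibble with one row per drug: `drug`, group sizes, death
#'   counts, `p_value`, `method`, `rejected`.
#' @export
analyze_trial <- function(ledger, alpha = 0.05, full_overlap = FALSE) {
  if (!"outcome" %in% names(ledger)) {
    stop("Ledger has no outcomes; call assign_outcomes() first.", call. = FALSE)
  }
  drugs <- sort(setdiff(unique(ledger$arm), "placebo"))
  purrr::map_dfr(drugs, function(d) {
    rows <- if ("trial" %in% names(ledger)) {
      dplyr::filter(ledger, .data$trial == d, .data$arm == d)
    } else {
      dplyr::filter(ledger, .data$arm == d)
    }
    cc <- if (full_overlap) {
      sub <- if ("trial" %in% names(ledger)) {
        dplyr::filter(ledger, .data$trial == d)
      } else {
        ledger
      }
      dplyr::filter(sub, .data$arm == "placebo")
    } else {
      concurrent_controls(ledger, d)
    }
    dec <- test_2x2(sum(rows$outcome), nrow(rows), sum(cc$outcome), nrow(cc),
                    alpha = alpha)
    tibble::add_column(dec, drug = d, .before = 1)
  })
}
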