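# Accrual and randomization engine.
#
# Time is discrete months 0, 1, 2, ... Each month a Poisson(lambda) number of
# patients arrives and is randomized one at a time among the currently open
# arms with probability proportional to the allocation weights. An arm leaves
# the open set the moment it reaches its cap, and under dynamic k:1 the
# placebo weight is re-evaluated before the next patient, so drug arms never
# overshoot their planned size. The sequential scheme is implemented in
# batches: a whole month is drawn at once, the draw is truncated at the first
# patient that would overflow an arm, and the remainder is re-drawn under the
# updated open set — exactly equivalent to patient-by-patient assignment.

# Draw per-replicate arm entry months for a design (in months, floored).
draw_entry_months <- function(design) {
  m <- design$n_drugs
  switch(design$entry$kind,
    simultaneous = integer(m),
    fixed_monthly = seq_len(m) - 1L,
    uniform_irregular = as.integer(floor(c(0, stats::runif(m - 1, 0, design$entry$uniform_upper))))
  )
}

alloc_mode_code <- function(mode) {
  match(mode, c("equal", "fixed_unequal", "dynamic_k")) - 1L
}

# Core single-trial engine (compiled). Returns a months x (n_drugs + 1)
# count matrix (drugs in columns 1..n_drugs, placebo last), plus entry
# months used. `rates` (drugs then placebo) additionally draws outcomes and
# returns the per-drug 2x2 ingredients against concurrent controls.
sim_arm_counts <- function(design, lambda, entry_month = NULL,
                           rates = numeric(0), keep_counts = TRUE) {
  m <- design$n_drugs
  if (is.null(entry_month)) entry_month <- draw_entry_months(design)
  stopifnot(length(entry_month) == m, entry_month[1] == 0L)
  res <- .engine_replicate(
    m, as.integer(entry_month), design$per_drug_cap, design$placebo_cap,
    alloc_mode_code(design$allocation$mode), design$allocation$placebo_weight,
    lambda, as.numeric(rates), keep_counts,
    design$entry$kind == "simultaneous"
  )
  res$entry_month <- entry_month
  res
}

# Expand a count matrix into a per-patient ledger tibble.
counts_to_ledger <- function(counts, n_drugs, trial = NULL) {
  arms <- arm_names(n_drugs)
  n_months <- nrow(counts)
  arm_idx <- rep(rep(seq_len(ncol(counts)), n_months), as.vector(t(counts)))
  month <- rep(rep(seq_len(n_months) - 1L, each = ncol(counts)), as.vector(t(counts)))
  out <- tibble::tibble(
    patient_id = seq_along(arm_idx),
    arm = arms[arm_idx],
    month = month
  )
  if (!is.null(trial)) out <- tibble::add_column(out, trial = trial, .before = 1)
  out
}

#' Simulate patient enrollment for one trial replicate
#'
#' Runs the monthly accrual/randomization engine once and returns the
#' enrollment ledger: one row per enrolled patient with the arm and the
#' (0-based) month of enrollment. Arrivals follow a Poisson distribution
#' each month with mean `accrual_mean`; each patient is randomized among the
#' arms open that month with probability proportional to the design's
#' allocation weights, arms close the instant they reach their cap, and the
#' placebo closes with the last drug arm. A stand-alone design is simulated
#' as `n_drugs` independent two-arm trials, each with its own accrual stream
#' at the same mean, distinguished by a `trial` column.
#'
#' @param design A [trial_design()].
#' @param accrual_mean Mean total arrivals per month (Poisson), e.g. 100-400.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble (class `enrollment_ledger`) with columns `patient_id`,
#'   `arm`, `month` (plus `trial` for stand-alone sets). Per-replicate arm
#'   entry months are attached as attribute `entry_month`.
#' @examples
#' led <- simulate_enrollment(build_design("MAT(1:1:1:1:2)"), 300, seed = 1)
#' dplyr::count(led, arm)   # 435 per drug, 870 placebo
#' @export
simulate_enrollment <- function(design, accrual_mean, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (accrual_mean <= 0) stop("`accrual_mean` must be positive.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (design$design == "standalone") {
    sub <- standalone_unit(design)
    pieces <- purrr::map(seq_len(design$n_drugs), function(i) {
      res <- sim_arm_counts(sub, accrual_mean)
      led <- counts_to_ledger(res$counts, 1L, trial = LETTERS[i])
      led$arm[led$arm == "A"] <- LETTERS[i]
      led
    })
    out <- dplyr::bind_rows(pieces)
    attr(out, "entry_month") <- stats::setNames(integer(design$n_drugs),
                                                LETTERS[seq_len(design$n_drugs)])
  } else {
    res <- sim_arm_counts(design, accrual_mean)
    out <- counts_to_ledger(res$counts, design$n_drugs)
    attr(out, "entry_month") <- stats::setNames(res$entry_month,
                                                LETTERS[seq_len(design$n_drugs)])
  }
  class(out) <- c("enrollment_ledger", class(out))
  out
}

# A single two-arm 1:1 trial used as the stand-alone building block.
standalone_unit <- function(design) {
  trial_design("standalone", n_drugs = 1, allocation = "equal",
               per_drug_cap = design$per_drug_cap)
}

#' Summarize arm states from an enrollment ledger
#'
#' @param ledger An enrollment ledger from [simulate_enrollment()].
#' @return A tibble with one row per arm (per trial for stand-alone sets):
#'   enrolled count and first/last enrollment month.
#' @export
arm_summary <- function(ledger) {
  grp <- intersect(c("trial", "arm"), names(ledger))
  ledger |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      enrolled = dplyr::n(),
      first_enroll_month = min(.data$month),
      last_enroll_month = max(.data$month),
      .groups = "drop"
    )
}

#' Arms open for enrollment at a given month
#'
#' A drug arm is open at month `m` when it has entered
#' (`floor(entry time) <= m`) and has not reached its cap. A placebo with a
#' planned size (finite cap, as in stand-alone and multi-arm designs) is
#' open until that size is reached; the uncapped platform-trial placebo is
#' open only while at least one drug arm is open.
#'
#' @param design A [trial_design()].
#' @param entry_month Integer entry month per drug arm.
#' @param month Month to evaluate (0-based).
#' @param enrolled Named or positional counts enrolled so far, drugs then
#'   placebo (default all zero).
#' @return Character vector of open arm names.
#' @export
open_arms <- function(design, entry_month, month,
                      enrolled = integer(design$n_drugs + 1)) {
  m <- design$n_drugs
  stopifnot(length(entry_month) == m, length(enrolled) == m + 1)
  open <- entry_month <= month & enrolled[seq_len(m)] < design$per_drug_cap
  arms <- LETTERS[seq_len(m)][open]
  pl_open <- enrolled[m + 1] < design$placebo_cap &&
    (any(open) || is.finite(design$placebo_cap))
  if (pl_open) arms <- c(arms, "placebo")
  arms
}

#' Allocate one month of arrivals among open arms
#'
#' Sequentially randomizes `n_arrivals` patients among the open arms with
#' probability proportional to the allocation weights, closing arms at their
#' caps and (for dynamic k:1) re-evaluating the placebo weight after every
#' closure. Exposed mainly for inspection and testing; [simulate_enrollment()]
#' uses the same engine internally.
#'
#' @param design A [trial_design()].
#' @param n_arrivals Number of arriving patients (>= 0).
#' @param open_drugs Character vector of open drug arms (default all).
#' @param enrolled Current enrollment, drugs then placebo.
#' @param seed Optional seed.
#' @return Named integer vector of patients assigned per arm this month.
#' @export
allocate_month <- function(design, n_arrivals, open_drugs = LETTERS[seq_len(design$n_drugs)],
                           enrolled = integer(design$n_drugs + 1), seed = NULL) {
  if (n_arrivals < 0) stop("`n_arrivals` must be non-negative.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- design$n_drugs
  entered <- LETTERS[seq_len(m)] %in% open_drugs
  counts <- month_allocation(design, entered, n_arrivals, enrolled)
  stats::setNames(counts, arm_names(m))
}

# One month of the batched-sequential allocation among the entered arms.
month_allocation <- function(design, entered, n_arr, enrolled) {
  m <- design$n_drugs
  n_arms <- m + 1L
  drug_cap <- design$per_drug_cap
  placebo_cap <- design$placebo_cap
  mode <- design$allocation$mode
  pw_fixed <- design$allocation$placebo_weight
  drugs <- seq_len(m)
  assigned <- integer(n_arms)
  enrolled <- as.integer(enrolled)
  while (n_arr > 0L) {
    open <- drugs[entered & enrolled[drugs] < drug_cap]
    k <- length(open)
    pl_open <- enrolled[n_arms] < placebo_cap
    if (k == 0L) {
      if (pl_open && is.finite(placebo_cap)) { # placebo finishes its group
        take <- min(n_arr, placebo_cap - enrolled[n_arms])
        enrolled[n_arms] <- enrolled[n_arms] + take
        assigned[n_arms] <- assigned[n_arms] + take
      }
      break
    }
    if (pl_open) {
      arms <- c(open, n_arms)
      pw <- switch(mode, equal = 1, fixed_unequal = pw_fixed, dynamic_k = sqrt(k))
      w <- c(rep.int(1, k), pw)
    } else {
      arms <- open
      w <- rep.int(1, k)
    }
    draw <- arms[sample.int(length(arms), n_arr, replace = TRUE, prob = w)]
    cut <- n_arr + 1L
    for (a in arms) {
      rem <- (if (a == n_arms) placebo_cap else drug_cap) - enrolled[a]
      if (is.finite(rem)) {
        cs <- cumsum(draw == a)
        if (cs[n_arr] > rem) cut <- min(cut, which(cs > rem)[1L])
      }
    }
    take <- if (cut > n_arr) draw else draw[seq_len(cut - 1L)]
    tb <- tabulate(take, nbins = n_arms)
    enrolled <- enrolled + tb
    assigned <- assigned + tb
    n_arr <- n_arr - length(take)
  }
  assigned
}
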