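#' Construct a trial design
#'
#' A `trial_design` bundles everything needed to simulate one trial family:
#' the design type (stand-alone set, multi-arm trial, platform trial with
#' fixed-monthly or irregular arm additions), the number of drug arms, the
#' per-arm enrollment caps, the randomization rule for the shared placebo,
#' and the arm-entry schedule.
#'
#' `trial_design()` is the low-level constructor with every field exposed;
#' [build_design()] parses the conventional design labels (e.g.
#' `"PT(1:1:1:1:k)"`) and is what most code should use.
#'
#' Allocation modes:
#' \describe{
#'   \item{`"equal"`}{placebo weight 1 at all times; with `m` open drug arms
#'     the placebo receives an expected fraction `1/(m+1)` of accrual.}
#'   \item{`"fixed_unequal"`}{placebo weight constant at `placebo_weight`
#'     (2 for the usual unequal multi-arm trial, giving a 870-patient
#'     placebo group against 435 per drug).}
#'   \item{`"dynamic_k"`}{the square-root allocation rule: with `k` drug
#'     arms currently open for enrollment the placebo weight is `sqrt(k)`
#'     (so 2 when four drugs enroll simultaneously), giving the placebo an
#'     expected accrual fraction `1/(1 + sqrt(k))`. The weight is
#'     re-evaluated whenever an arm opens or closes. Square-root weighting
#'     maximizes the per-comparison power of a shared control for a given
#'     total sample size.}
#' }
#'
#' Entry schedules: `"simultaneous"` (all arms at month 0),
#' `"fixed_monthly"` (arm `i`, 0-indexed, opens at month `i`), and
#' `"uniform_irregular"` (arm 0 at time 0; the others at i.i.d.
#' Uniform(0, `uniform_upper`) times, re-drawn every replicate). The default
#' `uniform_upper` is `n_drugs - 1` months (2, 3, 4 months for 3, 4, 5
#' drugs). An arm with continuous entry time `t` first takes part in the
#' allocation of month `floor(t)`.
#'
#' Placebo caps: each stand-alone trial and the equal multi-arm trial cap the
#' placebo at `per_drug_cap`; the unequal multi-arm trial at
#' `placebo_weight * per_drug_cap`; platform trials leave the placebo
#' uncapped — placebo patients are enrolled as long as at least one drug arm
#' is still enrolling.
#'
#' @param design One of `"standalone"`, `"mat"`, `"pt"`, `"pt_irr"`.
#' @param n_drugs Number of drug arms (3, 4, or 5; default 4).
#' @param allocation Allocation mode, see Details.
#' @param per_drug_cap Planned patients per drug arm (default 435, the
#'   two-proportion sample size for 80% power against 5% vs 10% mortality at
#'   two-sided 5%; see [required_n_per_group()]).
#' @param placebo_weight Placebo randomization weight for
#'   `allocation = "fixed_unequal"` (default 2).
#' @param uniform_upper Upper bound (months) of the uniform entry-time
#'   distribution for `design = "pt_irr"`; default `n_drugs - 1`.
#' @return An object of class `trial_design`.
#' @seealso [build_design()], [planned_total()], [simulate_enrollment()]
#' @export
trial_design <- function(design = c("standalone", "mat", "pt", "pt_irr"),
                         n_drugs = 4,
                         allocation = c("equal", "fixed_unequal", "dynamic_k"),
                         per_drug_cap = 435,
                         placebo_weight = 2,
                         uniform_upper = n_drugs - 1) {
  design <- match.arg(design)
  allocation <- match.arg(allocation)
  if (!is.numeric(n_drugs) || length(n_drugs) != 1 || n_drugs != round(n_drugs) ||
      n_drugs < 1) {
    stop("`n_drugs` must be a single positive integer.", call. = FALSE)
  }
  n_drugs <- as.integer(n_drugs)
  if (per_drug_cap < 1) stop("`per_drug_cap` must be positive.", call. = FALSE)
  if (placebo_weight <= 0) stop("`placebo_weight` must be positive.", call. = FALSE)
  if (design == "standalone" && allocation != "equal") {
    stop("Stand-alone trials are 1:1 by definition.", call. = FALSE)
  }

  entry_kind <- switch(design,
    standalone = "simultaneous",
    mat = "simultaneous",
    pt = "fixed_monthly",
    pt_irr = "uniform_irregular"
  )
  placebo_cap <- switch(design,
    standalone = per_drug_cap,
    mat = if (allocation == "fixed_unequal") placebo_weight * per_drug_cap else per_drug_cap,
    pt = ,
    pt_irr = Inf
  )

  structure(
    list(
      design = design,
      n_drugs = n_drugs,
      per_drug_cap = as.integer(per_drug_cap),
      placebo_cap = placebo_cap,
      allocation = list(
        mode = allocation,
        placebo_weight = if (allocation == "fixed_unequal") placebo_weight else 1
      ),
      entry = list(
        kind = entry_kind,
        uniform_upper = if (entry_kind == "uniform_irregular") uniform_upper else 0
      )
    ),
    class = "trial_design"
  )
}

#' Build a trial design from its conventional label
#'
#' Parses labels such as `"stand-alone"`, `"MAT(1:1:1:1:1)"`,
#' `"MAT(1:1:1:1:2)"`, `"PT(1:1:1:1:k)"`, or `"PT-irr(1:1:1:1:1)"` into a
#' fully populated [trial_design()]. The ratio string encodes one weight per
#' drug arm followed by the placebo weight: a final `"k"` selects the
#' dynamic square-root rule (placebo weight `sqrt(k)` for `k` open drug
#' arms), a final `"1"` equal allocation, and any other integer a
#' fixed unequal placebo weight. Annotations such as `"(=4)"` after the
#' placebo weight are ignored (they restate the number of drug arms).
#' Shorthand names (`"mat_equal"`, `"mat_unequal"`, `"pt_equal"`, `"pt_k"`,
#' `"pt_irr_equal"`, `"pt_irr_k"`) are also accepted.
#'
#' @param name Design label (see Details).
#' @param n_drugs Number of drug arms; when the label carries a ratio string
#'   the arm count is inferred from it and `n_drugs` must agree if supplied.
#' @param per_drug_cap Planned patients per drug arm (default 435).
#' @return A `trial_design`.
#' @examples
#' build_design("MAT(1:1:1:1:2)")      # unequal multi-arm, placebo cap 870
#' build_design("PT(1:1:1:1:k)")       # dynamic k:1 platform trial
#' build_design("pt_irr_k", n_drugs = 3)
#' @export
build_design <- function(name, n_drugs = NULL, per_drug_cap = 435) {
  stopifnot(is.character(name), length(name) == 1)
  raw <- name
  nm <- tolower(gsub("\\s+", "", name))

  shorthand <- c(
    standalone = "standalone", `stand-alone` = "standalone",
    mat_equal = "mat:equal", mat_unequal = "mat:fixed_unequal",
    pt_equal = "pt:equal", pt_k = "pt:dynamic_k",
    pt_irr_equal = "pt_irr:equal", pt_irr_k = "pt_irr:dynamic_k",
    ptirr_equal = "pt_irr:equal", ptirr_k = "pt_irr:dynamic_k"
  )

  placebo_weight <- NULL
  if (nm %in% names(shorthand)) {
    parts <- strsplit(shorthand[[nm]], ":")[[1]]
    design <- parts[1]
    allocation <- if (length(parts) > 1) parts[2] else "equal"
    m <- if (is.null(n_drugs)) 4L else as.integer(n_drugs)
    # unequal MAT follows the square-root rule with all arms open: sqrt(m)
    if (allocation == "fixed_unequal") placebo_weight <- sqrt(m)
  } else if (grepl("^(mat|pt|pt-irr|ptirr)\\(", nm)) {
    design <- sub("\\(.*$", "", nm)
    design <- c(mat = "mat", pt = "pt", `pt-irr` = "pt_irr", ptirr = "pt_irr")[[design]]
    ratio <- sub("^[^(]*\\(", "", sub("\\)$", "", nm))
    ratio <- gsub("\\(=[0-9]+\\)", "", ratio)  # "(=4)" annotation, not a weight
    toks <- strsplit(ratio, ":")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) < 2 || !all(toks[-length(toks)] == "1")) {
      stop("Cannot parse design ratio in ", sQuote(raw), call. = FALSE)
    }
    m <- length(toks) - 1L
    if (!is.null(n_drugs) && as.integer(n_drugs) != m) {
      stop("Label ", sQuote(raw), " implies ", m, " drug arms but `n_drugs` = ",
           n_drugs, ".", call. = FALSE)
    }
    last <- toks[length(toks)]
    if (last == "k") {
      allocation <- "dynamic_k"
    } else if (last == "1") {
      allocation <- "equal"
    } else if (grepl("^[0-9]+$", last)) {
      allocation <- "fixed_unequal"
      placebo_weight <- as.numeric(last)
    } else {
      stop("Unrecognized placebo weight ", sQuote(last), " in ", sQuote(raw),
           call. = FALSE)
    }
    if (design %in% c("pt", "pt_irr") && allocation == "fixed_unequal") {
      stop("Platform-trial unequal allocation is the dynamic k:1 rule; use ",
           sQuote("k"), " as the placebo weight.", call. = FALSE)
    }
  } else {
    stop("Unknown design name ", sQuote(raw), call. = FALSE)
  }

  if (!m %in% c(1L, 3L, 4L, 5L)) {
    stop("`n_drugs` must be 3, 4, or 5 (or 1 for a single stand-alone trial).",
         call. = FALSE)
  }
  trial_design(
    design = design, n_drugs = m,
    allocation = if (design == "standalone") "equal" else allocation,
    per_drug_cap = per_drug_cap,
    placebo_weight = placebo_weight %||% 2
  )
}

#' @export
format.trial_design <- function(x, ...) {
  if (x$design == "standalone") return("stand-alone")
  ones <- paste(rep("1", x$n_drugs), collapse = ":")
  last <- switch(x$allocation$mode,
    equal = "1",
    fixed_unequal = format(x$allocation$placebo_weight),
    dynamic_k = "k"
  )
  prefix <- switch(x$design, mat = "MAT", pt = "PT", pt_irr = "PT-irr")
  paste0(prefix, "(", ones, ":", last, ")")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design> ", format(x), "\n", sep = "")
  cat("  drug arms: ", x$n_drugs, " x ", x$per_drug_cap, " patients\n", sep = "")
  cat("  placebo cap: ",
      if (is.finite(x$placebo_cap)) x$placebo_cap else "none (open while any drug enrolls)",
      "\n", sep = "")
  cat("  allocation: ", x$allocation$mode,
      if (x$allocation$mode == "fixed_unequal")
        paste0(" (placebo weight ", x$allocation$placebo_weight, ")") else "",
      "\n", sep = "")
  cat("  entry: ", x$entry$kind,
      if (x$entry$kind == "uniform_irregular")
        paste0(" on [0, ", x$entry$uniform_upper, "] months") else "",
      "\n", sep = "")
  invisible(x)
}

#' Planned total enrollment of a design
#'
#' The deterministic planned total: stand-alone set `2 * cap * n_drugs`
#' (3480 for four drugs at 435 each), equal multi-arm `(n_drugs + 1) * cap`
#' (2175), unequal multi-arm `n_drugs * cap + placebo_cap` (2610). Platform
#' trials have no fixed total (the placebo group is uncapped and its size
#' depends on accrual speed), so `NA` is returned.
#'
#' @param design A [trial_design()].
#' @return A single number, or `NA` for platform trials.
#' @export
planned_total <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  switch(design$design,
    standalone = design$n_drugs * 2 * design$per_drug_cap,
    mat = design$n_drugs * design$per_drug_cap + design$placebo_cap,
    NA_real_
  )
}

#' The seven benchmark designs
#'
#' Labels of the seven designs compared throughout: four stand-alone trials,
#' equal and unequal multi-arm trials, and platform trials (fixed-monthly or
#' irregular arm additions) under equal and dynamic k:1 allocation.
#'
#' @param n_drugs Number of drug arms (default 4).
#' @return Character vector of design labels accepted by [build_design()].
#' @export
design_labels <- function(n_drugs = 4) {
  ones <- paste(rep("1", n_drugs), collapse = ":")
  c(
    "stand-alone",
    paste0("MAT(", ones, ":1)"),
    paste0("MAT(", ones, ":2)"),
    paste0("PT(", ones, ":1)"),
    paste0("PT(", ones, ":k)"),
    paste0("PT-irr(", ones, ":1)"),
    paste0("PT-irr(", ones, ":k)")
  )
}

# Arm names: drugs "A".."E" then "placebo".
arm_names <- function(n_drugs) c(LETTERS[seq_len(n_drugs)], "placebo")

#' Scenario table of true mortality rates
#'
#' Builds the `n_drugs + 1` effectiveness scenarios for a given true placebo
#' mortality rate `rp`. Scenario `s` has exactly `s - 1` effective drugs,
#' with effectiveness assigned from the last-indexed drug backwards
#' (scenario 2 makes only the last drug effective, scenario 3 the last two,
#' and so on). An effective drug has true mortality `rd` (default
#' `rp - 0.05`, so 5 percentage points below placebo, and 0 when
#' `rp = 0.05`); an ineffective drug has the placebo's rate.
#'
#' @param n_drugs Number of drug arms (3, 4, or 5).
#' @param rp True placebo mortality rate; the studied grid is
#'   `c(0.05, 0.075, 0.10, 0.125, 0.15)` and other values trigger a warning.
#' @param rd True mortality rate of an effective drug.
#' @return A tibble with one row per (scenario, arm): columns `scenario`,
#'   `arm`, `effective`, `true_rate`, `rp`, `rd`.
#' @examples
#' scenario_table(4, rp = 0.10)
#' @export
scenario_table <- function(n_drugs, rp, rd = rp - 0.05) {
  check_scenario_rates(rp, rd)
  arms <- arm_names(n_drugs)
  purrr::map_dfr(seq_len(n_drugs + 1L), function(s) {
    eff <- scenario_flags(n_drugs, s)
    tibble::tibble(
      scenario = s,
      arm = arms,
      effective = c(eff, NA),
      true_rate = c(ifelse(eff, rd, rp), rp),
      rp = rp,
      rd = rd
    )
  })
}

check_scenario_rates <- function(rp, rd) {
  stopifnot(is.numeric(rp), length(rp) == 1, is.numeric(rd), length(rd) == 1)
  if (rp < 0 || rp > 1 || rd < 0 || rd > 1) {
    stop("Mortality rates must lie in [0, 1].", call. = FALSE)
  }
  if (rd > rp) stop("`rd` must not exceed `rp`.", call. = FALSE)
  grid <- c(0.05, 0.075, 0.10, 0.125, 0.15)
  if (!any(abs(rp - grid) < 1e-12)) {
    warning("`rp` = ", rp, " is outside the studied grid ",
            "{0.05, 0.075, 0.10, 0.125, 0.15}.", call. = FALSE)
  }
  invisible(TRUE)
}

# Effectiveness flags for scenario s: the last s-1 drugs are effective.
scenario_flags <- function(n_drugs, scenario) {
  if (scenario < 1 || scenario > n_drugs + 1) {
    stop("`scenario` must lie in 1..", n_drugs + 1, ".", call. = FALSE)
  }
  seq_len(n_drugs) > n_drugs - (scenario - 1L)
}

#' True per-arm mortality rates for one scenario
#'
#' @inheritParams scenario_table
#' @param scenario Scenario index in `1..(n_drugs + 1)`; scenario `s` has
#'   `s - 1` effective drugs (assigned from the last drug backwards).
#' @return Named numeric vector of length `n_drugs + 1` (drugs then
#'   `placebo`), with an `effective` logical attribute for the drug arms.
#' @export
scenario_rates <- function(n_drugs, scenario, rp, rd = rp - 0.05) {
  check_scenario_rates(rp, rd)
  eff <- scenario_flags(n_drugs, scenario)
  rates <- c(ifelse(eff, rd, rp), rp)
  names(rates) <- arm_names(n_drugs)
  attr(rates, "effective") <- eff
  rates
}
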