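MEDICAID_CATEGORIES <- c("mother_opioid_treatment", "nas_treatment", "intervention")
SYSTEM_EXTRA_CATEGORIES <- c("overdose_death", "living_with_oud", "special_education")
COST_CATEGORIES <- c(MEDICAID_CATEGORIES, SYSTEM_EXTRA_CATEGORIES)

#' Present value of lifetime productivity lost to an overdose death
#'
#' Values a death at age `a` as the discounted sum of annual earnings over the
#' remaining working life: `sum_{t=0}^{R-a-1} earnings(a+t) / (1+r)^t`, where
#' `R` is the retirement age. The first year is undiscounted (annuity-due
#' convention: the year of death is a lost year of earnings). A death at
#' retirement age costs zero.
#'
#' @param age integer age(s) at death, in years
#' @param earnings_by_age named numeric vector, names = ages, values = annual
#'   earnings
#' @param retirement_age retirement age in years
#' @param rate annual discount rate in \[0, 1)
#' @return numeric vector of productivity losses, same length as `age`
#' @export
productivity_loss <- function(age, earnings_by_age, retirement_age, rate) {
  if (any(age > retirement_age))
    stop_nassim("age %s exceeds retirement age %s",
                max(age), retirement_age)
  vapply(age, function(a) {
    if (a == retirement_age) return(0)
    yrs <- seq.int(a, retirement_age - 1)
    key <- as.character(yrs)
    if (!all(key %in% names(earnings_by_age)))
      stop_nassim("earnings_by_age has no entry for age(s): %s",
                  paste(setdiff(key, names(earnings_by_age)), collapse = ", "))
    sum(earnings_by_age[key] / (1 + rate)^(seq_along(yrs) - 1))
  }, numeric(1))
}

productivity_loss_table <- function(costs, ages) {
  setNames(productivity_loss(ages, costs$earnings_by_age,
                             costs$retirement_age,
                             costs$productivity_discount_rate),
           as.character(ages))
}

# modality sampled on the path, NA if the woman never started treatment
outcome_modality <- function(outcomes, costs) {
  ms <- costs$modality_states
  modality <- rep(NA_character_, nrow(outcomes))
  for (m in names(ms)) {
    pat <- paste0("(^|>)", ms[[m]], "(>|$)")
    hit <- grepl(pat, outcomes$path)
    modality[hit] <- m
  }
  modality
}

#' Per-woman category-tagged costs
#'
#' Attaches the six cost categories to each sampled outcome:
#' * `mother_opioid_treatment`: episode cost of the sampled treatment modality;
#' * `nas_treatment`: NAS flag x treatment days x (daily hospital + daily NAS
#'   treatment cost);
#' * `intervention`: eligibility-gated per-woman intervention costs;
#' * `overdose_death`: death flag x productivity loss at the woman's age;
#' * `living_with_oud`: flag x annual incremental healthcare cost (one-year
#'   horizon, undiscounted);
#' * `special_education`: NAS flag x special-education cost.
#'
#' The two reporting perspectives are definitional sums: `medicaid` is the
#' first three categories, `system` adds the remaining three.
#'
#' @param outcomes data.frame from [sample_paths()] with an added integer
#'   `age` column
#' @param costs cost schedule (from a `parameter_set`)
#' @param active named list of active intervention specs (empty for baseline)
#' @return data.frame of per-woman costs: one column per category plus
#'   `medicaid` and `system`
#' @export
cost_outcomes <- function(outcomes, costs, active = list()) {
  n <- nrow(outcomes)
  if (is.null(outcomes$age))
    stop_nassim("outcomes must carry an integer 'age' column")
  modality <- outcome_modality(outcomes, costs)
  mot_cost <- numeric(n)
  started <- !is.na(modality)
  if (any(started)) {
    known <- modality[started] %in% names(costs$mother_treatment_costs)
    if (!all(known))
      stop_nassim("no mother_treatment_costs entry for modality '%s'",
                  unique(modality[started][!known])[1])
    mot_cost[started] <- costs$mother_treatment_costs[modality[started]]
  }
  nas <- as.numeric(outcomes$nas_case)
  dead <- which(outcomes$overdose_death)
  od_cost <- numeric(n)
  if (length(dead))
    od_cost[dead] <- productivity_loss(outcomes$age[dead],
                                       costs$earnings_by_age,
                                       costs$retirement_age,
                                       costs$productivity_discount_rate)
  out <- data.frame(
    mother_opioid_treatment = mot_cost,
    nas_treatment = nas * costs$nas_treatment_days *
      (costs$daily_hospital_cost + costs$daily_nas_treatment_cost),
    intervention = intervention_cost(active, outcomes),
    overdose_death = od_cost,
    living_with_oud = as.numeric(outcomes$living_with_oud) *
      costs$annual_oud_incremental_cost,
    special_education = nas * costs$special_education_cost
  )
  out$medicaid <- out$mother_opioid_treatment + out$nas_treatment +
    out$intervention
  out$system <- out$medicaid + out$overdose_death + out$living_with_oud +
    out$special_education
  out
}

#' @rdname cost_outcomes
#' @param outcome a single outcome (one-row data.frame or the list returned by
#'   [sample_path()] with an `age` element)
#' @export
cost_outcome <- function(outcome, costs, active = list()) {
  if (!is.data.frame(outcome)) {
    row <- data.frame(path = paste(outcome$path, collapse = ">"),
                      terminal = outcome$terminal,
                      age = outcome$age, stringsAsFactors = FALSE)
    for (f in names(outcome$flags)) row[[f]] <- isTRUE(outcome$flags[[f]])
    outcome <- row
  }
  as.list(cost_outcomes(outcome, costs, active)[1, ])
}

#' Aggregate per-woman costs and outcome counts
#'
#' Category-wise totals over a costed cohort, with both perspective totals and
#' the outcome flag counts. The perspective identities (`medicaid` = mother
#' treatment + NAS treatment + intervention; `system` = medicaid + overdose
#' death + living with OUD + special education) hold exactly at the aggregate
#' because they hold per woman.
#'
#' @param outcomes data.frame of sampled outcomes (with flag columns)
#' @param woman_costs data.frame from [cost_outcomes()] aligned with
#'   `outcomes`
#' @return object of class `cost_breakdown`: list with `categories` (named
#'   totals), `medicaid`, `system` and `counts`
#' @export
aggregate_costs <- function(outcomes, woman_costs) {
  categories <- if (nrow(woman_costs)) {
    vapply(COST_CATEGORIES, function(k) sum(woman_costs[[k]]), numeric(1))
  } else {
    setNames(numeric(length(COST_CATEGORIES)), COST_CATEGORIES)
  }
  flags <- intersect(c("pregnant", "started_treatment", "completed_treatment",
                       "nas_case", "overdose_death", "living_with_oud"),
                     names(outcomes))
  counts <- vapply(flags, function(f) sum(outcomes[[f]]), numeric(1))
  structure(
    list(categories = categories,
         medicaid = sum(categories[MEDICAID_CATEGORIES]),
         system = sum(categories),
         counts = counts),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown>\n")
  for (k in names(x$categories))
    cat(sprintf("  %-24s %15.2f\n", k, x$categories[k]))
  cat(sprintf("  %-24s %15.2f\n", "medicaid total", x$medicaid))
  cat(sprintf("  %-24s %15.2f\n", "system total", x$system))
  if (length(x$counts)) {
    cat("  counts:\n")
    for (k in names(x$counts))
      cat(sprintf("    %-22s %10d\n", k, as.integer(x$counts[k])))
  }
  invisible(x)
}

#' Read an earnings table from CSV
#'
#' @param path CSV with columns `age` and `annual_earnings`
#' @return named numeric vector suitable for the `earnings_by_age` cost field
#' @export
read_earnings_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "annual_earnings") %in% names(df)))
    stop_nassim("earnings CSV must have columns 'age' and 'annual_earnings'")
  setNames(as.numeric(df$annual_earnings), as.integer(df$age))
}
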