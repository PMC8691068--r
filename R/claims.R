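# Shipped code lists are placeholders, not authoritative coding guidance:
# OUD is matched by the ICD-10 F11.* family prefix; treatment codes are a
# small configurable stand-in for detoxification/MAT procedure coding.
DEFAULT_OUD_CODES <- c("F11")
DEFAULT_TREATMENT_CODES <- c("HZ81ZZZ", "HZ91ZZZ", "HZ96ZZZ", "H0020", "J0592")

#' Read claims-style records from CSV
#'
#' @param path CSV with columns `member_id`, `event_date` (ISO-8601),
#'   `code`, `event_kind` (one of `delivery`, `diagnosis`, `treatment`)
#' @return data.frame of claim records with `event_date` parsed to `Date`
#' @export
read_claims <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("member_id", "event_date", "code", "event_kind")
  if (!all(need %in% names(df)))
    stop_nassim("claims CSV must have columns: %s", paste(need, collapse = ", "))
  dates <- as.Date(df$event_date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) | !nzchar(df$code))
  if (length(bad))
    stop_nassim("malformed claim record at line %d (bad date or empty code)",
                bad[1] + 1L)
  df$event_date <- dates
  df
}

matches_any_prefix <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

#' Extract the delivering-with-OUD cohort from claims records
#'
#' Implements the claims-based validation rule: a member counts as delivered
#' if she has at least one delivery event in the target year (her first such
#' delivery anchors the lookback window); as delivered-with-OUD if any OUD
#' diagnosis code falls within the inclusive 365-day window
#' `[delivery - 365, delivery]`; and as treated if additionally any treatment
#' code falls in that window. Each member is counted once. Record order never
#' matters.
#'
#' @param claims data.frame of claim records (see [read_claims()])
#' @param oud_codes character vector of OUD code prefixes (default `F11`)
#' @param treatment_codes character vector of treatment code prefixes
#' @param year target delivery year
#' @return object of class `cohort_counts`: `deliveries`,
#'   `delivered_with_oud`, `delivered_with_oud_treated`, `treated_ratio`
#'   (treated / identified; 0 with `ratio_defined = FALSE` when no member has
#'   OUD) and `treated_to_untreated_ratio`.
#' @export
extract_cohort <- function(claims, oud_codes = DEFAULT_OUD_CODES,
                           treatment_codes = DEFAULT_TREATMENT_CODES,
                           year) {
  if (!length(oud_codes) || !length(treatment_codes))
    stop_nassim("code sets must be non-empty")
  if (nrow(claims) == 0)
    return(cohort_counts(0L, 0L, 0L))
  if (!inherits(claims$event_date, "Date"))
    claims$event_date <- as.Date(claims$event_date)

  is_delivery <- claims$event_kind == "delivery" &
    as.integer(format(claims$event_date, "%Y")) == year
  deliveries <- claims[is_delivery, c("member_id", "event_date")]
  if (nrow(deliveries) == 0) return(cohort_counts(0L, 0L, 0L))
  # first delivery of the year anchors each member's window
  deliveries <- deliveries[order(deliveries$member_id, deliveries$event_date), ]
  anchor <- deliveries[!duplicated(deliveries$member_id), ]
  anchor_date <- setNames(anchor$event_date, anchor$member_id)

  in_window <- function(kind, prefixes) {
    rows <- claims$event_kind == kind &
      claims$member_id %in% names(anchor_date) &
      matches_any_prefix(claims$code, prefixes)
    sub <- claims[rows, c("member_id", "event_date")]
    if (!nrow(sub)) return(character(0))
    a <- anchor_date[sub$member_id]
    gap <- as.numeric(a - sub$event_date)
    unique(sub$member_id[gap >= 0 & gap <= 365])
  }
  oud_members <- in_window("diagnosis", oud_codes)
  treated_members <- intersect(oud_members, in_window("treatment", treatment_codes))
  cohort_counts(nrow(anchor), length(oud_members), length(treated_members))
}

cohort_counts <- function(deliveries, with_oud, treated) {
  defined <- with_oud > 0
  structure(
    list(deliveries = as.integer(deliveries),
         delivered_with_oud = as.integer(with_oud),
         delivered_with_oud_treated = as.integer(treated),
         treated_ratio = if (defined) treated / with_oud else 0,
         ratio_defined = defined,
         treated_to_untreated_ratio =
           if (with_oud > treated) treated / (with_oud - treated)
           else if (treated > 0) Inf else 0),
    class = "cohort_counts"
  )
}

#' @export
print.cohort_counts <- function(x, ...) {
  cat("<cohort_counts>\n")
  cat(sprintf("  deliveries:                 %d\n", x$deliveries))
  cat(sprintf("  delivered with OUD:         %d\n", x$delivered_with_oud))
  cat(sprintf("  delivered with OUD treated: %d\n", x$delivered_with_oud_treated))
  cat(sprintf("  treated/identified ratio:   %.4f%s\n", x$treated_ratio,
              if (!x$ratio_defined) " (undefined: no OUD members)" else ""))
  invisible(x)
}

#' Validate a baseline simulation against claims-derived estimates
#'
#' Compares the simulated treated fraction among pregnant women with OUD to
#' the claims-extracted ratio (relative gap in percent) and the simulated NAS
#' rate per 1000 births — computed from mean NAS cases over the reference
#' population with [nas_rate_per_1000()] — to the claims NAS rate (absolute
#' gap per 1000). Both the treated/identified and treated/untreated ratio
#' conventions are computed and reported; `ratio_type` selects which one the
#' pass/fail tolerance applies to. Claims-derived ratios are biased relative
#' to simulation truth whenever OUD goes unrecognized in claims; both numbers
#' are surfaced without correction.
#'
#' @param sim a baseline `scenario_result`
#' @param claims_counts a `cohort_counts`
#' @param claims_nas_rate claims-derived NAS cases per 1000 births
#' @param reference_population births denominator for the simulated NAS rate
#' @param ratio_type `"treated_over_identified"` (default) or
#'   `"treated_over_untreated"`
#' @param ratio_tolerance_pct maximum relative ratio gap, percent (default 4.8)
#' @param rate_tolerance maximum absolute NAS-rate gap per 1000 (default 0.5)
#' @return object of class `nas_validation` with the gaps and pass flags
#' @export
validate_against_baseline <- function(sim, claims_counts, claims_nas_rate,
                                      reference_population,
                                      ratio_type = c("treated_over_identified",
                                                     "treated_over_untreated"),
                                      ratio_tolerance_pct = 4.8,
                                      rate_tolerance = 0.5) {
  ratio_type <- match.arg(ratio_type)
  if (claims_counts$delivered_with_oud == 0)
    stop_nassim("claims cohort has no delivered-with-OUD members")

  preg <- scenario_mean(sim, "count_pregnant")
  started <- scenario_mean(sim, "count_started_treatment")
  sim_ratios <- c(
    treated_over_identified = started / preg,
    treated_over_untreated = started / (preg - started))
  claims_ratios <- c(
    treated_over_identified = claims_counts$treated_ratio,
    treated_over_untreated = claims_counts$treated_to_untreated_ratio)
  if (claims_ratios[ratio_type] == 0)
    stop_nassim("claims ratio '%s' is zero; relative gap undefined", ratio_type)
  ratio_gap_pct <- 100 * abs(sim_ratios[[ratio_type]] - claims_ratios[[ratio_type]]) /
    claims_ratios[[ratio_type]]

  sim_rate <- nas_rate_per_1000(scenario_mean(sim, "count_nas_cases"),
                                reference_population)
  rate_gap <- abs(sim_rate - claims_nas_rate)

  structure(
    list(sim_ratios = sim_ratios, claims_ratios = claims_ratios,
         ratio_type = ratio_type, ratio_gap_pct = ratio_gap_pct,
         ratio_pass = ratio_gap_pct <= ratio_tolerance_pct,
         sim_nas_rate = sim_rate, claims_nas_rate = claims_nas_rate,
         rate_gap = rate_gap, rate_pass = rate_gap <= rate_tolerance,
         ratio_tolerance_pct = ratio_tolerance_pct,
         rate_tolerance = rate_tolerance),
    class = "nas_validation"
  )
}

#' @export
print.nas_validation <- function(x, ...) {
  cat("<nas_validation>\n")
  cat(sprintf("  treated/identified: sim %.4f vs claims %.4f\n",
              x$sim_ratios["treated_over_identified"],
              x$claims_ratios["treated_over_identified"]))
  cat(sprintf("  treated/untreated:  sim %.4f vs claims %.4f\n",
              x$sim_ratios["treated_over_untreated"],
              x$claims_ratios["treated_over_untreated"]))
  cat(sprintf("  ratio gap (%s): %.2f%% [tolerance %.1f%%] -> %s\n",
              x$ratio_type, x$ratio_gap_pct, x$ratio_tolerance_pct,
              if (x$ratio_pass) "pass" else "FAIL"))
  cat(sprintf("  NAS rate per 1000: sim %.1f vs claims %.1f (gap %.1f, tolerance %.1f) -> %s\n",
              x$sim_nas_rate, x$claims_nas_rate, x$rate_gap, x$rate_tolerance,
              if (x$rate_pass) "pass" else "FAIL"))
  invisible(x)
}
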