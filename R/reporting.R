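#' Integer percent difference from baseline
#'
#' `100 * (scenario - baseline) / baseline`, rounded half away from zero to
#' the nearest integer — the convention under which every printed
#' percent-difference cell of the results tables reproduces (e.g. -0.54%
#' prints as -1%, -3.48% as -3%).
#'
#' @param scenario_mean,baseline_mean scenario and baseline means (vectorized)
#' @return signed integer percent(s)
#' @export
percent_difference <- function(scenario_mean, baseline_mean) {
  if (any(baseline_mean == 0))
    stop_nassim("percent difference undefined for zero baseline mean")
  round_half_away(100 * (scenario_mean - baseline_mean) / baseline_mean)
}

#' NAS cases per 1000 births
#'
#' One-decimal rate, truncated (not rounded): `floor(10000 * cases / births)
#' / 10`. Truncation is deliberate — it is the convention under which
#' 3697/239,200 prints as 15.4 (the arithmetic value is 15.456).
#'
#' @param nas_cases number of NAS cases (vectorized)
#' @param births number of births in the reference population
#' @return rate(s) per 1000 births with one decimal
#' @export
nas_rate_per_1000 <- function(nas_cases, births) {
  if (any(births <= 0)) stop_nassim("births must be positive")
  floor(10000 * nas_cases / births + 1e-9) / 10
}

TABLE_ROW_ORDER <- names(canonical_scenarios())

# Coerce either a scenario_results object or a plain fixture data.frame into
# the long mean/CI frame the table builders consume.
results_frame <- function(results) {
  if (is.data.frame(results)) return(results)
  rows <- lapply(names(results), function(nm) {
    s <- results[[nm]]$summary
    data.frame(scenario = nm, output = s$output, mean = s$mean,
               ci_lo = s$ci_lo, ci_hi = s$ci_hi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

pick <- function(df, scenario, output, col = "mean") {
  v <- df[[col]][df$scenario == scenario & df$output == output]
  if (length(v) != 1L)
    stop_nassim("results missing output '%s' for scenario '%s'", output, scenario)
  v
}

sig_lookup <- function(results, scenario, output) {
  cmp <- attr(results, "comparisons")
  if (is.null(cmp)) return(NA)
  v <- cmp$significant[cmp$scenario == scenario & cmp$output == output]
  if (length(v) == 1L) v else NA
}

#' Build a results table
#'
#' Assembles one of the model's three results tables from scenario results
#' (or from a fixture data.frame of means in the same long format:
#' columns `scenario`, `output`, `mean`, optionally `ci_lo`/`ci_hi`):
#' * table 1 — Medicaid incremental costs: mother opioid treatment, NAS
#'   treatment, total (with CI) and integer percent difference from baseline;
#' * table 2 — total-system costs by category (Medicaid, overdose death,
#'   living with OUD, special education), overall total (with CI) and percent
#'   difference;
#' * table 3 — effect sizes: started treatment, completed treatment and NAS
#'   cases, each with CI and per-output percent difference.
#'
#' Component columns sum to the total columns exactly, because the totals are
#' computed as those sums. Percent differences use [percent_difference()];
#' the unrounded value is kept in a `*_pct_raw` companion column. Baseline
#' rows carry `NA` percent differences. Row order follows the canonical
#' scenario order for the scenarios present; baseline must be present.
#'
#' @param results a `scenario_results` object or a long-format data.frame of
#'   means
#' @param table 1, 2 or 3
#' @param scenarios optional character vector of scenario display names to
#'   require; an error lists any that are missing
#' @return data.frame, one row per scenario, with a `scaling_factor`
#'   attribute when effect sizes are rescaled
#' @export
build_table <- function(results, table, scenarios = NULL) {
  df <- results_frame(results)
  present <- unique(df$scenario)
  if (!is.null(scenarios)) {
    missing <- setdiff(scenarios, present)
    if (length(missing))
      stop_nassim("results missing scenario(s): %s",
                  paste(missing, collapse = ", "))
  }
  if (!"Baseline" %in% present)
    stop_nassim("results missing scenario(s): Baseline")
  order <- c(intersect(TABLE_ROW_ORDER, present),
             setdiff(present, TABLE_ROW_ORDER))
  has_ci <- all(c("ci_lo", "ci_hi") %in% names(df))

  if (table == 1) {
    rows <- lapply(order, function(sc) {
      mother <- pick(df, sc, "cost_mother_opioid_treatment")
      nas <- pick(df, sc, "cost_nas_treatment")
      iv <- tryCatch(pick(df, sc, "cost_intervention"), error = function(e) 0)
      data.frame(scenario = sc,
                 mother_opioid_treatment = mother + iv,
                 nas_treatment = nas,
                 total = mother + iv + nas,
                 ci_lo = if (has_ci) tryCatch(pick(df, sc, "cost_medicaid", "ci_lo"),
                                              error = function(e) NA_real_) else NA_real_,
                 ci_hi = if (has_ci) tryCatch(pick(df, sc, "cost_medicaid", "ci_hi"),
                                              error = function(e) NA_real_) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    base <- out$total[out$scenario == "Baseline"]
    out$percent_diff_raw <- ifelse(out$scenario == "Baseline", NA_real_,
                                   100 * (out$total - base) / base)
    out$percent_diff <- ifelse(out$scenario == "Baseline", NA_real_,
                               percent_difference(out$total, base))
    out$significant <- vapply(out$scenario, function(sc)
      if (sc == "Baseline") NA else sig_lookup(results, sc, "cost_medicaid"),
      logical(1))
    return(out)
  }

  if (table == 2) {
    rows <- lapply(order, function(sc) {
      med <- pick(df, sc, "cost_medicaid")
      od <- pick(df, sc, "cost_overdose_death")
      oud <- pick(df, sc, "cost_living_with_oud")
      sped <- pick(df, sc, "cost_special_education")
      data.frame(scenario = sc, medicaid = med, overdose_death = od,
                 living_with_oud = oud, special_education = sped,
                 total = med + od + oud + sped,
                 ci_lo = if (has_ci) tryCatch(pick(df, sc, "cost_system", "ci_lo"),
                                              error = function(e) NA_real_) else NA_real_,
                 ci_hi = if (has_ci) tryCatch(pick(df, sc, "cost_system", "ci_hi"),
                                              error = function(e) NA_real_) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    base <- out$total[out$scenario == "Baseline"]
    out$percent_diff_raw <- ifelse(out$scenario == "Baseline", NA_real_,
                                   100 * (out$total - base) / base)
    out$percent_diff <- ifelse(out$scenario == "Baseline", NA_real_,
                               percent_difference(out$total, base))
    out$significant <- vapply(out$scenario, function(sc)
      if (sc == "Baseline") NA else sig_lookup(results, sc, "cost_system"),
      logical(1))
    return(out)
  }

  if (table == 3) {
    spec <- c(started = "count_started_treatment",
              completed = "count_completed_treatment",
              nas_cases = "count_nas_cases")
    out <- data.frame(scenario = order, stringsAsFactors = FALSE)
    for (j in names(spec)) {
      out[[paste0(j, "_mean")]] <- vapply(order, function(sc)
        pick(df, sc, spec[[j]]), numeric(1))
      if (has_ci) {
        out[[paste0(j, "_ci_lo")]] <- vapply(order, function(sc)
          tryCatch(pick(df, sc, spec[[j]], "ci_lo"),
                   error = function(e) NA_real_), numeric(1))
        out[[paste0(j, "_ci_hi")]] <- vapply(order, function(sc)
          tryCatch(pick(df, sc, spec[[j]], "ci_hi"),
                   error = function(e) NA_real_), numeric(1))
      }
      base <- out[[paste0(j, "_mean")]][out$scenario == "Baseline"]
      is_base <- out$scenario == "Baseline"
      out[[paste0(j, "_pct_raw")]] <- ifelse(is_base, NA_real_,
        100 * (out[[paste0(j, "_mean")]] - base) / base)
      out[[paste0(j, "_pct")]] <- ifelse(is_base, NA_real_,
        percent_difference(out[[paste0(j, "_mean")]], base))
      out[[paste0(j, "_significant")]] <- vapply(out$scenario, function(sc)
        if (sc == "Baseline") NA else sig_lookup(results, sc, spec[[j]]),
        logical(1))
    }
    return(out)
  }
  stop_nassim("table must be 1, 2 or 3")
}

#' Scale simulated counts to the reference population
#'
#' Effect sizes are reported for a reference population (by default the
#' 239,200 Medicaid-enrolled pregnant women) proportionally to the simulated
#' counts; the factor applied is recorded in the `scaling_factor` attribute.
#'
#' @param counts numeric vector of simulated counts
#' @param n_simulated simulated denominator the counts came from
#' @param reference_population target population
#' @return rescaled counts with attribute `scaling_factor`
#' @export
scale_to_reference <- function(counts, n_simulated, reference_population) {
  f <- reference_population / n_simulated
  structure(counts * f, scaling_factor = f)
}

#' Render a built table as Markdown
#'
#' Formats a [build_table()] result the way the tables are printed: totals
#' with comma separators, `(lo, hi)` confidence intervals, and percent cells
#' like `-8%` with `(NS)` appended when the difference is not significant at
#' the 95% level.
#'
#' @param tbl data.frame from [build_table()]
#' @return character vector of Markdown lines
#' @export
render_table_markdown <- function(tbl) {
  fmt_n <- function(x) ifelse(is.na(x), "", formatC(x, format = "f",
                                                    digits = 2, big.mark = ","))
  pct_cols <- grep("_pct$|^percent_diff$", names(tbl), value = TRUE)
  out <- tbl
  for (pc in pct_cols) {
    sig_col <- sub("_pct$", "_significant", sub("^percent_diff$", "significant", pc))
    cell <- ifelse(is.na(tbl[[pc]]), "",
                   paste0(tbl[[pc]], "%",
                          ifelse(!is.na(tbl[[sig_col]]) & !tbl[[sig_col]],
                                 " (NS)", "")))
    out[[pc]] <- cell
  }
  keep <- !grepl("_raw$|significant$", names(out))
  out <- out[, keep, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  for (j in names(out)[num]) out[[j]] <- fmt_n(out[[j]])
  header <- paste0("| ", paste(names(out), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(out)), collapse = "|"), "|")
  body <- apply(out, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, unname(body))
}

#' Shipped reference results tables
#'
#' The three incremental-cost/effect-size results tables that the default
#' configuration emulates, as printed: Medicaid costs (1), total-system costs
#' by category (2) and effect sizes (3), each with confidence intervals,
#' integer percent differences and significance flags (`FALSE` marks the
#' not-significant cells).
#'
#' @param which 1, 2 or 3
#' @return data.frame of the reference table
#' @export
reference_table <- function(which) {
  if (!which %in% 1:3) stop_nassim("which must be 1, 2 or 3")
  path <- system.file("extdata", sprintf("reference_table%d.csv", which),
                      package = "nassim")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Compare a built table against reference values
#'
#' Cell-by-cell residuals between a simulated table and a reference table with
#' the same columns (e.g. the shipped reference results the default
#' configuration emulates). Nothing is hidden or harmonized: every shared
#' numeric cell is reported with its difference.
#'
#' @param tbl data.frame from [build_table()]
#' @param reference data.frame with a `scenario` column and a subset of
#'   `tbl`'s numeric columns
#' @return long data.frame: `scenario`, `column`, `value`, `reference`, `diff`
#' @export
compare_to_reference <- function(tbl, reference) {
  shared <- setdiff(intersect(names(tbl), names(reference)), "scenario")
  shared <- shared[vapply(reference[shared], is.numeric, logical(1))]
  rows <- list()
  for (sc in intersect(tbl$scenario, reference$scenario)) {
    for (cl in shared) {
      v <- tbl[[cl]][tbl$scenario == sc]
      r <- reference[[cl]][reference$scenario == sc]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, column = cl, value = v, reference = r, diff = v - r,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a built table (rounded and unrounded) to CSV
#'
#' @param tbl data.frame from [build_table()]
#' @param path output CSV path; the unrounded companion (all `_raw` columns
#'   retained) goes to `<path>` while the display columns go through as-is
#' @return `path`, invisibly
#' @export
write_table_csv <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}
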