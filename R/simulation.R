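#' Derive per-replication substream seeds from one root seed
#'
#' One root seed governs a whole experiment; each replication re-seeds the
#' generator with a child seed derived by a fixed multiplicative mixing scheme
#' modulo the Mersenne prime 2^31 - 1:
#' `s = root mod m; s = 48271 s mod m; s = (s + 16807 i) mod m; s = 48271 s mod m`
#' for replication index `i`. Replications are therefore individually
#' reproducible, and two scenarios sharing the same indices share streams
#' (the common-random-numbers pairing).
#'
#' @param root_seed integer root seed
#' @param n number of substreams
#' @param offset index offset (used to decouple scenarios when common random
#'   numbers are disabled)
#' @return integer vector of `n` seeds in \[1, 2^31 - 2\]
#' @export
substream_seeds <- function(root_seed, n, offset = 0) {
  m <- 2147483647
  base <- (as.numeric(root_seed) %% m) * 48271 %% m
  idx <- offset + seq_len(n)
  s <- (base + idx * 16807) %% m
  s <- (s * 48271) %% m
  s[s == 0] <- 1
  as.integer(s)
}

#' Precompute the constant parts of a scenario simulation
#'
#' Everything about a scenario tree that does not change across replications:
#' the exact path distribution, per-path flag membership, the per-path
#' treatment-episode cost, per-path intervention cost, and the
#' productivity-loss lookup by age. [run_replication()] consumes this object.
#'
#' @param tree a scenario `nas_tree` (after [apply_interventions()])
#' @param costs cost schedule
#' @param active named list of active intervention specs
#' @param age_distribution `list(ages, probs)` from the cohort configuration
#' @return an opaque engine list
#' @export
scenario_engine <- function(tree, costs, active, age_distribution) {
  dist <- enumerate_paths(tree)
  modality <- outcome_modality(dist, costs)
  episode <- numeric(nrow(dist))
  started <- !is.na(modality)
  episode[started] <- costs$mother_treatment_costs[modality[started]]
  iv <- numeric(nrow(dist))
  for (id in names(active)) {
    sp <- active[[id]]
    iv <- iv + sp$per_woman_cost * as.numeric(dist[[sp$eligibility]])
  }
  list(
    dist = dist,
    episode_cost = episode,
    intervention_cost = iv,
    age_distribution = age_distribution,
    pl_by_age = productivity_loss_table(costs, age_distribution$ages),
    nas_unit_cost = costs$nas_treatment_days *
      (costs$daily_hospital_cost + costs$daily_nas_treatment_cost),
    oud_annual = costs$annual_oud_incremental_cost,
    sped_cost = costs$special_education_cost
  )
}

REPLICATION_OUTPUTS <- c(
  "count_pregnant", "count_started_treatment", "count_completed_treatment",
  "count_nas_cases", "count_overdose_deaths", "count_living_with_oud",
  "cost_mother_opioid_treatment", "cost_nas_treatment", "cost_intervention",
  "cost_overdose_death", "cost_living_with_oud", "cost_special_education",
  "cost_medicaid", "cost_system")

#' Simulate one replication of a cohort
#'
#' Draws `n_women` independent paths through the scenario tree and returns the
#' replication's outcome counts and category-tagged cost totals. Because every
#' woman's path is an independent categorical draw over the same enumerated
#' path set, the engine samples one uniform per woman and classifies it
#' against the cumulative path probabilities (in canonical path order). This
#' inverse-CDF form is what makes common random numbers effective: two
#' scenarios sharing a substream classify the same uniforms against slightly
#' different cutpoints, so paired differences isolate the intervention effect.
#' Ages, which only enter through the productivity-loss valuation of overdose
#' deaths, are drawn for the women who die. The result is deterministic given
#' `seed`.
#'
#' @param engine precomputed scenario engine (internal; built by
#'   [run_scenario()] from the tree, cost schedule and active interventions)
#' @param n_women cohort size
#' @param seed substream seed for this replication
#' @return one-row data.frame of replication outputs
#' @export
run_replication <- function(engine, n_women, seed) {
  set.seed(seed)
  dist <- engine$dist
  u <- stats::runif(n_women)
  bin <- findInterval(u, cumsum(dist$prob)) + 1L
  counts <- tabulate(pmin(bin, nrow(dist)), nbins = nrow(dist))
  flag_count <- function(f) sum(counts[dist[[f]]])

  n_dead <- flag_count("overdose_death")
  od_cost <- if (n_dead > 0) {
    ages <- sample(engine$age_distribution$ages, n_dead, replace = TRUE,
                   prob = engine$age_distribution$probs)
    sum(engine$pl_by_age[as.character(ages)])
  } else 0

  n_nas <- flag_count("nas_case")
  out <- data.frame(
    count_pregnant = flag_count("pregnant"),
    count_started_treatment = flag_count("started_treatment"),
    count_completed_treatment = flag_count("completed_treatment"),
    count_nas_cases = n_nas,
    count_overdose_deaths = n_dead,
    count_living_with_oud = flag_count("living_with_oud"),
    cost_mother_opioid_treatment = sum(counts * engine$episode_cost),
    cost_nas_treatment = n_nas * engine$nas_unit_cost,
    cost_intervention = sum(counts * engine$intervention_cost),
    cost_overdose_death = od_cost,
    cost_living_with_oud = flag_count("living_with_oud") * engine$oud_annual,
    cost_special_education = n_nas * engine$sped_cost
  )
  out$cost_medicaid <- out$cost_mother_opioid_treatment +
    out$cost_nas_treatment + out$cost_intervention
  out$cost_system <- out$cost_medicaid + out$cost_overdose_death +
    out$cost_living_with_oud + out$cost_special_education
  out
}

#' Run a replicated scenario
#'
#' Applies the scenario's interventions, enumerates the resulting tree once,
#' then simulates `n_replications` cohorts of `n_women` women, each on its own
#' reproducible substream of `root_seed`. Outputs are summarized across
#' replications as mean, SD, SE = SD/sqrt(R) and a normal-approximation 95%
#' interval (mean +/- 1.96 SE).
#'
#' @param params a validated `parameter_set`
#' @param scenario scenario string, e.g. `"baseline"` or `"mot+coaches"`
#' @param n_women,n_replications cohort size and replication count; default to
#'   the parameter set's cohort configuration
#' @param root_seed root seed; defaults to the cohort configuration's seed
#' @param stream_offset substream index offset (see [substream_seeds()])
#' @return object of class `scenario_result`: list with `scenario`, `summary`
#'   (one row per output), `replications` (one row per replication), the run
#'   sizes and the root seed.
#' @export
run_scenario <- function(params, scenario = "baseline",
                         n_women = NULL, n_replications = NULL,
                         root_seed = NULL, stream_offset = 0) {
  n_women <- n_women %||% params$cohort$n_women
  n_replications <- n_replications %||% params$cohort$n_replications
  root_seed <- root_seed %||% params$cohort$seed

  app <- apply_interventions(params, scenario)
  engine <- scenario_engine(app$tree, params$costs, app$active,
                            params$cohort$age_distribution)
  seeds <- substream_seeds(root_seed, n_replications, offset = stream_offset)
  reps <- do.call(rbind, lapply(seeds, function(s)
    run_replication(engine, n_women, s)))
  reps <- cbind(replication = seq_len(n_replications), seed = seeds, reps)

  mu <- vapply(REPLICATION_OUTPUTS, function(k) mean(reps[[k]]), numeric(1))
  sdv <- vapply(REPLICATION_OUTPUTS, function(k) stats::sd(reps[[k]]), numeric(1))
  se <- sdv / sqrt(n_replications)
  summary <- data.frame(
    output = REPLICATION_OUTPUTS, mean = unname(mu), sd = unname(sdv),
    se = unname(se),
    ci_lo = unname(mu - 1.96 * se), ci_hi = unname(mu + 1.96 * se),
    stringsAsFactors = FALSE
  )
  structure(
    list(scenario = app$scenario, summary = summary, replications = reps,
         n_women = n_women, n_replications = n_replications,
         root_seed = root_seed, stream_offset = stream_offset,
         expected = vapply(
           c(pregnant = "pregnant", started_treatment = "started_treatment",
             completed_treatment = "completed_treatment",
             nas_case = "nas_case", overdose_death = "overdose_death",
             living_with_oud = "living_with_oud"),
           function(f) n_women * expected_flag_rate(engine$dist, f),
           numeric(1))),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s': %s replications x %s women (root seed %s)\n",
              x$scenario, x$n_replications,
              format(x$n_women, big.mark = ","), x$root_seed))
  print(x$summary, row.names = FALSE, digits = 8)
  invisible(x)
}

#' Extract a summarized mean from a scenario result
#'
#' @param result a `scenario_result`
#' @param output one of the replication outputs, e.g. `"count_nas_cases"` or
#'   `"cost_medicaid"`
#' @return the across-replication mean
#' @export
scenario_mean <- function(result, output) {
  result$summary$mean[result$summary$output == output]
}

#' Run every scenario of an experiment
#'
#' Runs each scenario with the same root seed. With common random numbers
#' (the default) every scenario reuses the same per-replication substream
#' indices, so paired differences against baseline are low-variance and a
#' cost-only intervention shifts totals by exactly its billed amount. With
#' `crn = FALSE` each scenario gets disjoint substream indices. A Welch
#' two-sample t-test per output flags significance of each scenario against
#' baseline at the 95% level.
#'
#' @param params a validated `parameter_set`
#' @param scenarios named character vector of scenario strings (default: the
#'   13 canonical scenarios)
#' @param n_women,n_replications,root_seed as in [run_scenario()]
#' @param crn share substreams across scenarios (common random numbers)
#' @return object of class `scenario_results`: named list of
#'   `scenario_result`s with a `comparisons` attribute (data.frame of
#'   scenario x output mean differences, percent differences and Welch
#'   p-values against baseline).
#' @export
run_all_scenarios <- function(params, scenarios = canonical_scenarios(),
                              n_women = NULL, n_replications = NULL,
                              root_seed = NULL, crn = TRUE) {
  n_replications <- n_replications %||% params$cohort$n_replications
  if (is.null(names(scenarios))) names(scenarios) <- scenarios
  results <- vector("list", length(scenarios))
  names(results) <- names(scenarios)
  for (i in seq_along(scenarios)) {
    results[[i]] <- run_scenario(
      params, scenarios[[i]], n_women = n_women,
      n_replications = n_replications, root_seed = root_seed,
      stream_offset = if (crn) 0 else (i - 1) * n_replications)
  }

  base_idx <- which(vapply(results, function(r) r$scenario == "baseline",
                           logical(1)))
  comparisons <- NULL
  if (length(base_idx)) {
    base <- results[[base_idx[1]]]
    rows <- list()
    for (nm in names(results)) {
      r <- results[[nm]]
      if (identical(r$scenario, "baseline")) next
      for (k in REPLICATION_OUTPUTS) {
        x <- r$replications[[k]]; y <- base$replications[[k]]
        p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
          if (mean(x) == mean(y)) 1 else 0
        } else {
          stats::t.test(x, y)$p.value
        }
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = nm, output = k,
          mean = mean(x), baseline_mean = mean(y),
          diff = mean(x) - mean(y),
          percent_diff = if (mean(y) != 0)
            100 * (mean(x) - mean(y)) / mean(y) else NA_real_,
          p_value = p, significant = p < 0.05,
          stringsAsFactors = FALSE)
      }
    }
    comparisons <- do.call(rbind, rows)
  }
  structure(results, class = "scenario_results",
            comparisons = comparisons, crn = crn,
            ci_mode = if (crn) "common-random-numbers paired substreams"
                      else "independent substreams")
}

#' @export
print.scenario_results <- function(x, ...) {
  cat(sprintf("<scenario_results> %d scenarios (%s)\n", length(x),
              attr(x, "ci_mode")))
  for (nm in names(x))
    cat(sprintf("  %-32s nas=%10.2f medicaid=%14.2f\n", nm,
                scenario_mean(x[[nm]], "count_nas_cases"),
                scenario_mean(x[[nm]], "cost_medicaid")))
  invisible(x)
}
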