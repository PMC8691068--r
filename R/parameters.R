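#' Assemble a parameter set
#'
#' A parameter set bundles everything the simulation needs: the baseline
#' probability tree, the cost schedule, the cohort settings and the
#' intervention definitions. All of it is data read from one YAML (or JSON)
#' file, so alternative transition tables, cost schedules or intervention
#' effects are configuration, not code changes.
#'
#' @param tree a `nas_tree`
#' @param costs cost schedule list (see [load_parameters()] for the schema)
#' @param cohort cohort configuration list
#' @param interventions named list of intervention specifications
#' @param metadata list; `currency` (default `"USD"`) and `money_scale` are
#'   recorded but never applied to values.
#' @return object of class `parameter_set`
#' @export
parameter_set <- function(tree, costs, cohort, interventions = list(),
                          metadata = list()) {
  metadata$currency <- metadata$currency %||% "USD"
  metadata$money_scale <- metadata$money_scale %||% "as_printed"
  structure(
    list(tree = tree, costs = costs, cohort = cohort,
         interventions = interventions, metadata = metadata),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  print(x$tree)
  cat(sprintf("  cohort: %s women x %s replications (reference population %s)\n",
              format(x$cohort$n_women, big.mark = ","),
              x$cohort$n_replications,
              format(x$cohort$reference_population, big.mark = ",")))
  cat(sprintf("  interventions: %s\n",
              if (length(x$interventions))
                paste(names(x$interventions), collapse = ", ") else "none"))
  cat(sprintf("  currency: %s\n", x$metadata$currency))
  invisible(x)
}

PARAM_TOP_KEYS <- c("metadata", "states", "transitions", "flags", "costs",
                    "cohort", "interventions")
COST_KEYS <- c("daily_hospital_cost", "daily_nas_treatment_cost",
               "nas_treatment_days", "mother_treatment_costs",
               "modality_states", "annual_oud_incremental_cost",
               "special_education_cost", "productivity_discount_rate",
               "retirement_age", "earnings_by_age")
COHORT_KEYS <- c("n_women", "n_replications", "reference_population",
                 "time_horizon_years", "seed", "age_distribution")
MODIFIER_MODES <- c("set", "multiply_prob", "multiply_odds")

#' Load a parameter set from file
#'
#' Reads the canonical YAML schema (JSON with the same structure is accepted,
#' chosen by file extension). The file must contain `states`, `transitions`,
#' `costs` and `cohort` sections; `flags`, `interventions` and `metadata` are
#' optional. Unknown top-level keys are rejected by name. Sibling-probability
#' groups that miss one by more than `1e-9` but lie within \[0.99, 1.01\] are
#' renormalized with a warning (published transition tables are rounded);
#' anything worse is a validation error naming the state. The returned set
#' always passes [validate_parameters()].
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`
#' @return a validated `parameter_set`
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop_nassim("parameter file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  params_from_list(raw, origin = path)
}

params_from_list <- function(raw, origin = "parameter list") {
  unknown <- setdiff(names(raw), PARAM_TOP_KEYS)
  if (length(unknown))
    stop_nassim("unknown top-level key(s) in %s: %s", origin,
                paste(unknown, collapse = ", "))
  for (k in c("states", "transitions", "costs", "cohort"))
    if (is.null(raw[[k]]))
      stop_nassim("missing required section '%s' in %s", k, origin)

  states <- do.call(rbind, lapply(raw$states, function(s) {
    for (k in c("id", "label", "stage", "is_terminal"))
      if (is.null(s[[k]]))
        stop_nassim("state entry missing required field '%s'", k)
    data.frame(id = s$id, label = s$label, stage = s$stage,
               is_terminal = isTRUE(s$is_terminal), stringsAsFactors = FALSE)
  }))
  transitions <- do.call(rbind, lapply(raw$transitions, function(t) {
    for (k in c("name", "from", "to", "prob"))
      if (is.null(t[[k]]))
        stop_nassim("transition entry missing required field '%s'", k)
    data.frame(name = t$name, from = t$from, to = t$to,
               prob = as.numeric(t$prob), stringsAsFactors = FALSE)
  }))
  flags <- lapply(raw$flags %||% list(), function(x) as.character(unlist(x)))

  costs <- raw$costs
  unknown <- setdiff(names(costs), COST_KEYS)
  if (length(unknown))
    stop_nassim("unknown cost key(s): %s", paste(unknown, collapse = ", "))
  for (k in setdiff(COST_KEYS, "modality_states"))
    if (is.null(costs[[k]]))
      stop_nassim("missing required cost field '%s'", k)
  costs$mother_treatment_costs <-
    unlist(costs$mother_treatment_costs)
  costs$modality_states <-
    vapply(costs$modality_states %||% list(), as.character, "")
  eb <- costs$earnings_by_age
  costs$earnings_by_age <- setNames(as.numeric(unlist(eb)), names(unlist(eb)))

  cohort <- raw$cohort
  unknown <- setdiff(names(cohort), COHORT_KEYS)
  if (length(unknown))
    stop_nassim("unknown cohort key(s): %s", paste(unknown, collapse = ", "))
  for (k in COHORT_KEYS)
    if (is.null(cohort[[k]]))
      stop_nassim("missing required cohort field '%s'", k)
  cohort$age_distribution <- normalize_age_distribution(cohort$age_distribution)

  interventions <- lapply(raw$interventions %||% list(), function(sp) {
    for (k in c("per_woman_cost", "eligibility"))
      if (is.null(sp[[k]]))
        stop_nassim("intervention entry missing required field '%s'", k)
    list(label = sp$label %||% NA_character_,
         per_woman_cost = as.numeric(sp$per_woman_cost),
         eligibility = sp$eligibility,
         modifiers = lapply(sp$modifiers %||% list(), function(m) {
           for (k in c("target", "mode", "value"))
             if (is.null(m[[k]]))
               stop_nassim("modifier entry missing required field '%s'", k)
           list(target = m$target, mode = m$mode, value = as.numeric(m$value))
         }))
  })

  tree <- nas_tree(states, transitions, flags)
  tree <- renormalize_near_misses(tree)
  params <- parameter_set(tree, costs, cohort, interventions,
                          raw$metadata %||% list())
  v <- validate_parameters(params)
  if (length(v))
    stop_nassim("invalid parameter set (%s): %s", origin,
                paste(v, collapse = "; "))
  params
}

# uniform {min, max} shorthand or explicit {ages, probs}
normalize_age_distribution <- function(ad) {
  if (!is.null(ad$min) && !is.null(ad$max)) {
    ages <- seq.int(as.integer(ad$min), as.integer(ad$max))
    list(ages = ages, probs = rep(1 / length(ages), length(ages)))
  } else if (!is.null(ad$ages) && !is.null(ad$probs)) {
    list(ages = as.integer(unlist(ad$ages)), probs = as.numeric(unlist(ad$probs)))
  } else {
    stop_nassim("age_distribution must give either {min, max} or {ages, probs}")
  }
}

renormalize_near_misses <- function(tree, tol = PROB_TOL) {
  tr <- tree$transitions
  terminal <- setNames(tree$states$is_terminal, tree$states$id)
  for (s in tree$states$id) {
    if (isTRUE(terminal[s])) next
    idx <- which(tr$from == s)
    if (!length(idx)) next
    tot <- sum(tr$prob[idx])
    if (is.finite(tot) && abs(tot - 1) > tol && tot >= 0.99 && tot <= 1.01) {
      warning(sprintf(
        "renormalizing outgoing probabilities of state '%s' (sum %.6f)",
        s, tot), call. = FALSE)
      tr$prob[idx] <- tr$prob[idx] / tot
    }
  }
  tree$transitions <- tr
  tree
}

#' Validate a parameter set
#'
#' Runs every invariant over every component — the tree (see
#' [validate_tree()]), the cost schedule (non-negative money, earnings
#' coverage of the working-age range, discount rate in \[0, 1)), the cohort
#' configuration (positive counts, age distribution summing to one, one-year
#' undiscounted horizon) and the intervention definitions (existing modifier
#' targets, known eligibility flags, valid modes). Deterministic, and never
#' throws: violations are returned as messages.
#'
#' @param params a `parameter_set`
#' @return character vector of violations; empty if the set is valid.
#' @export
validate_parameters <- function(params) {
  v <- validate_tree(params$tree)
  co <- params$costs
  ch <- params$cohort

  money_scalar <- c("daily_hospital_cost", "daily_nas_treatment_cost",
                    "annual_oud_incremental_cost", "special_education_cost")
  for (k in money_scalar) {
    x <- co[[k]]
    if (!is_scalar_number(x) || x < 0)
      v <- c(v, sprintf("cost '%s' must be a nonnegative number", k))
  }
  if (!is_scalar_number(co$nas_treatment_days) || co$nas_treatment_days < 0)
    v <- c(v, "nas_treatment_days must be a nonnegative number")
  if (any(co$mother_treatment_costs < 0))
    v <- c(v, "mother_treatment_costs must all be nonnegative")
  r <- co$productivity_discount_rate
  if (!is_scalar_number(r) || r < 0 || r >= 1)
    v <- c(v, "productivity_discount_rate must lie in [0, 1)")
  if (any(co$earnings_by_age < 0))
    v <- c(v, "earnings_by_age must all be nonnegative")

  ad <- ch$age_distribution
  if (length(ad$ages) != length(ad$probs) ||
      abs(sum(ad$probs) - 1) > PROB_TOL || any(ad$probs < 0))
    v <- c(v, "age_distribution probabilities must be nonnegative and sum to 1")
  # earnings must cover every simulated age up to retirement
  need_ages <- seq.int(min(ad$ages), co$retirement_age - 1)
  have_ages <- as.integer(names(co$earnings_by_age))
  missing_ages <- setdiff(need_ages, have_ages)
  if (length(missing_ages))
    v <- c(v, sprintf("earnings_by_age missing age(s): %s",
                      paste(missing_ages, collapse = ", ")))

  if (!is_count(ch$n_women)) v <- c(v, "n_women must be a positive integer")
  if (!is_count(ch$n_replications))
    v <- c(v, "n_replications must be a positive integer")
  if (!is_count(ch$reference_population))
    v <- c(v, "reference_population must be a positive integer")
  if (!identical(as.numeric(ch$time_horizon_years), 1))
    v <- c(v, "time_horizon_years must be 1 (single-pass, undiscounted model)")

  # modality -> state mapping must name costed modalities and real states
  ms <- co$modality_states
  bad <- setdiff(names(ms), names(co$mother_treatment_costs))
  if (length(bad))
    v <- c(v, sprintf("modality_states names modality without a cost: %s",
                      paste(bad, collapse = ", ")))
  bad <- setdiff(unname(ms), params$tree$states$id)
  if (length(bad))
    v <- c(v, sprintf("modality_states references unknown state(s): %s",
                      paste(bad, collapse = ", ")))

  for (id in names(params$interventions)) {
    sp <- params$interventions[[id]]
    if (!is_scalar_number(sp$per_woman_cost) || sp$per_woman_cost < 0)
      v <- c(v, sprintf("intervention '%s': per_woman_cost must be >= 0", id))
    if (!sp$eligibility %in% names(params$tree$flags))
      v <- c(v, sprintf("intervention '%s': unknown eligibility flag '%s'",
                        id, sp$eligibility))
    for (m in sp$modifiers) {
      if (!m$target %in% params$tree$transitions$name)
        v <- c(v, sprintf("intervention '%s': modifier targets unknown transition '%s'",
                          id, m$target))
      if (!m$mode %in% MODIFIER_MODES)
        v <- c(v, sprintf("intervention '%s': unknown modifier mode '%s'",
                          id, m$mode))
      if (!is_scalar_number(m$value) || m$value < 0)
        v <- c(v, sprintf("intervention '%s': modifier value must be >= 0", id))
      if (identical(m$mode, "set") && (m$value < 0 || m$value > 1))
        v <- c(v, sprintf("intervention '%s': set-mode value must lie in [0, 1]", id))
    }
  }
  v
}

#' Write a parameter set to file
#'
#' Serializes back to the same YAML (or JSON) schema that [load_parameters()]
#' reads, at full double precision so that a write/load round trip reproduces
#' every value to better than `1e-12`.
#'
#' @param params a `parameter_set`
#' @param path output path; `.json` selects JSON, anything else YAML
#' @return `path`, invisibly
#' @export
write_parameters <- function(params, path) {
  st <- params$tree$states
  tr <- params$tree$transitions
  raw <- list(
    metadata = params$metadata,
    states = lapply(seq_len(nrow(st)), function(i)
      list(id = st$id[i], label = st$label[i], stage = st$stage[i],
           is_terminal = st$is_terminal[i])),
    transitions = lapply(seq_len(nrow(tr)), function(i)
      list(name = tr$name[i], from = tr$from[i], to = tr$to[i],
           prob = tr$prob[i])),
    flags = params$tree$flags,
    costs = {
      co <- params$costs
      co$mother_treatment_costs <- as.list(co$mother_treatment_costs)
      co$modality_states <- as.list(co$modality_states)
      co$earnings_by_age <- as.list(co$earnings_by_age)
      co
    },
    cohort = {
      ch <- params$cohort
      ch$age_distribution <- list(ages = ch$age_distribution$ages,
                                  probs = ch$age_distribution$probs)
      ch
    },
    interventions = params$interventions
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(raw, path, precision = 17)
  }
  invisible(path)
}

.nassim_env <- new.env(parent = emptyenv())

#' Default parameter set
#'
#' Loads (and caches) the parameter file shipped with the package:
#' the baseline community-care probability tree, the cost schedule, the
#' four intervention definitions and the canonical cohort settings
#' (200,000 women with OUD per replication, 500 replications, reference
#' population of 239,200 Medicaid-enrolled pregnant women).
#'
#' @param fresh reload from disk instead of the cached copy
#' @return a validated `parameter_set`
#' @export
default_parameters <- function(fresh = FALSE) {
  if (fresh || is.null(.nassim_env$default_params)) {
    path <- system.file("extdata", "default_parameters.yaml", package = "nassim")
    if (!nzchar(path))
      stop_nassim("shipped default parameter file not found; is nassim installed?")
    .nassim_env$default_params <- load_parameters(path)
  }
  .nassim_env$default_params
}
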