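# Canonical application order. Modifiers compose sequentially in this order,
# each application renormalizing the untouched siblings, so a combined
# scenario's effect is generally not the sum of its single-intervention
# effects.
INTERVENTION_ORDER <- c("mot", "navigators", "capacity", "coaches")

#' Parse a scenario string
#'
#' Scenario names are `+`-separated intervention ids, order-insensitive:
#' `"baseline"`, `"mot"`, `"mot+navigators+coaches"`, `"coaches+mot"` and so
#' on. The result is the subset of intervention ids in canonical application
#' order (mandatory testing, navigators, capacity, coaches).
#'
#' @param name scenario string
#' @param known character vector of defined intervention ids
#' @return character vector of intervention ids (empty for baseline)
#' @export
parse_scenario <- function(name, known = INTERVENTION_ORDER) {
  parts <- trimws(strsplit(tolower(name), "+", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (identical(parts, "baseline") || length(parts) == 0L) return(character(0))
  bad <- setdiff(parts, known)
  if (length(bad))
    stop_nassim("unknown intervention(s): %s", paste(bad, collapse = ", "))
  ordered <- intersect(INTERVENTION_ORDER, parts)
  c(ordered, setdiff(parts, INTERVENTION_ORDER))
}

#' The thirteen canonical scenarios
#'
#' Baseline plus the twelve intervention combinations reported by the model,
#' in table row order.
#'
#' @return named character vector: display label -> scenario string
#' @export
canonical_scenarios <- function() {
  c("Baseline" = "baseline",
    "MOT" = "mot",
    "Patient Navigators" = "navigators",
    "Capacity Increase" = "capacity",
    "Peer Recovery Coaches" = "coaches",
    "Navigators + Coaches" = "navigators+coaches",
    "MOT + Navigators" = "mot+navigators",
    "MOT + Capacity" = "mot+capacity",
    "MOT + Coaches" = "mot+coaches",
    "MOT + Navigators + Coaches" = "mot+navigators+coaches",
    "Navigators + Capacity" = "navigators+capacity",
    "Coaches + Capacity" = "coaches+capacity",
    "Capacity + Navigators + Coaches" = "capacity+navigators+coaches")
}

# Apply one transition modifier to a tree. The target's new probability is
# computed from its current value; the untouched siblings are then rescaled
# proportionally so the group still sums to one. Driving the touched mass to
# one or beyond while positive mass remains on untouched siblings is an
# error, never a silent clamp.
apply_modifier <- function(tree, target, mode, value) {
  tr <- tree$transitions
  i <- which(tr$name == target)
  if (length(i) != 1L)
    stop_nassim("modifier targets unknown transition '%s'", target)
  p_old <- tr$prob[i]
  p_new <- switch(mode,
    set = value,
    multiply_prob = p_old * value,
    multiply_odds = {
      if (p_old >= 1) 1 else (value * p_old) / (1 - p_old + value * p_old)
    },
    stop_nassim("unknown modifier mode '%s'", mode))
  if (p_new < 0 || p_new > 1 + PROB_TOL)
    stop_nassim(
      "modifier on transition '%s' yields probability %.6f outside [0, 1]",
      target, p_new)
  p_new <- min(p_new, 1)

  sib <- which(tr$from == tr$from[i])
  others <- setdiff(sib, i)
  residual <- 1 - p_new
  other_mass <- sum(tr$prob[others])
  if (residual < -PROB_TOL)
    stop_nassim("modifier on transition '%s' drives sibling mass above 1", target)
  if (other_mass > 0) {
    tr$prob[others] <- tr$prob[others] * (residual / other_mass)
  } else if (residual > PROB_TOL) {
    stop_nassim(
      "modifier on transition '%s' leaves mass %.6f with no sibling to absorb it",
      target, residual)
  }
  tr$prob[i] <- p_new
  tree$transitions <- tr
  tree
}

#' Compose interventions into a scenario tree
#'
#' Applies the scenario's intervention modifiers to the baseline tree in the
#' canonical order (mot, navigators, capacity, coaches). Each modifier sets
#' its target transition's new probability and proportionally renormalizes the
#' untouched siblings, so single-intervention trees match their definitions
#' exactly while combinations interact rather than add. The baseline scenario
#' returns the tree unchanged.
#'
#' @param params a validated `parameter_set`
#' @param scenario scenario string (see [parse_scenario()]) or character
#'   vector of intervention ids
#' @return list with `tree` (the modified, revalidated `nas_tree`), `active`
#'   (named list of active intervention specs) and `scenario` (the canonical
#'   scenario string).
#' @export
apply_interventions <- function(params, scenario) {
  ids <- if (length(scenario) <= 1L) {
    parse_scenario(if (length(scenario)) scenario else "baseline",
                   known = names(params$interventions))
  } else {
    bad <- setdiff(scenario, names(params$interventions))
    if (length(bad))
      stop_nassim("unknown intervention(s): %s", paste(bad, collapse = ", "))
    c(intersect(INTERVENTION_ORDER, scenario),
      setdiff(scenario, INTERVENTION_ORDER))
  }
  tree <- params$tree
  for (id in ids) {
    for (m in params$interventions[[id]]$modifiers)
      tree <- apply_modifier(tree, m$target, m$mode, m$value)
  }
  v <- validate_tree(tree)
  if (length(v))
    stop_nassim("scenario '%s' produced an invalid tree: %s",
                paste(ids, collapse = "+"), paste(v, collapse = "; "))
  list(tree = tree,
       active = params$interventions[ids],
       scenario = if (length(ids)) paste(ids, collapse = "+") else "baseline")
}

#' Per-woman intervention cost
#'
#' Each active intervention bills its `per_woman_cost` once for every woman
#' whose outcome raises the intervention's eligibility flag (e.g. every
#' pregnant woman for mandatory testing, every treatment entrant for peer
#' coaches). Baseline (no active interventions) costs zero for everyone.
#'
#' @param active named list of active intervention specs (from
#'   [apply_interventions()])
#' @param outcomes data.frame of sampled outcomes with logical flag columns
#'   (as returned by [sample_paths()])
#' @return numeric vector of per-woman intervention cost
#' @export
intervention_cost <- function(active, outcomes) {
  cost <- numeric(nrow(outcomes))
  for (id in names(active)) {
    sp <- active[[id]]
    flag <- outcomes[[sp$eligibility]]
    if (is.null(flag))
      stop_nassim("outcomes lack eligibility flag '%s' for intervention '%s'",
                  sp$eligibility, id)
    cost <- cost + sp$per_woman_cost * as.numeric(flag)
  }
  cost
}
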