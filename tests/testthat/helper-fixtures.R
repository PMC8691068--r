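# Fixtures built in code: toy trees and a miniature parameter set that
# exercise every stage, flag and cost category at hand-checkable sizes.

toy_tree_3leaf <- function(p = c(0.2, 0.3, 0.5)) {
  nas_tree(
    states = data.frame(
      id = c("r", "a", "b", "c"),
      label = c("root", "leaf a", "leaf b", "leaf c"),
      stage = c("pregnancy", "terminal", "terminal", "terminal"),
      is_terminal = c(FALSE, TRUE, TRUE, TRUE)),
    transitions = data.frame(
      name = c("ta", "tb", "tc"), from = "r", to = c("a", "b", "c"),
      prob = p),
    flags = list(hit = c("a", "b"))
  )
}

toy_tree_2level <- function() {
  nas_tree(
    states = data.frame(
      id = c("r", "L", "R", "LL", "LR", "RL", "RR"),
      label = c("root", "L", "R", "LL", "LR", "RL", "RR"),
      stage = c("pregnancy", "treatment_entry", "treatment_entry",
                "terminal", "terminal", "terminal", "terminal"),
      is_terminal = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)),
    transitions = data.frame(
      name = c("l", "r", "ll", "lr", "rl", "rr"),
      from = c("r", "r", "L", "L", "R", "R"),
      to = c("L", "R", "LL", "LR", "RL", "RR"),
      prob = c(0.3, 0.7, 0.5, 0.5, 0.5, 0.5)),
    flags = list(nas_case = c("LL", "RL"))
  )
}

# chain with certain transitions: pregnant, treated, completed, healthy birth
degenerate_params <- function(n_women = 50, n_replications = 2) {
  tree <- nas_tree(
    states = data.frame(
      id = c("root", "pregnant", "tx", "done", "ok"),
      label = c("root", "pregnant", "in treatment", "completed", "healthy birth"),
      stage = c("pregnancy", "treatment_entry", "treatment_modality",
                "treatment_outcome", "terminal"),
      is_terminal = c(FALSE, FALSE, FALSE, FALSE, TRUE)),
    transitions = data.frame(
      name = c("preg", "start", "complete", "birth"),
      from = c("root", "pregnant", "tx", "done"),
      to = c("pregnant", "tx", "done", "ok"),
      prob = 1),
    flags = list(pregnant = "pregnant", started_treatment = "tx",
                 completed_treatment = "done", nas_case = character(0),
                 overdose_death = character(0), living_with_oud = character(0))
  )
  parameter_set(tree, toy_costs(modality_states = c(methadone = "tx")),
                toy_cohort(n_women, n_replications))
}

toy_costs <- function(modality_states = c(methadone = "tx")) {
  list(daily_hospital_cost = 100, daily_nas_treatment_cost = 40,
       nas_treatment_days = 10,
       mother_treatment_costs = c(methadone = 1000, buprenorphine = 800,
                                  detoxification = 300,
                                  psychological_support = 200),
       modality_states = modality_states,
       annual_oud_incremental_cost = 500, special_education_cost = 250,
       productivity_discount_rate = 0.03, retirement_age = 32,
       earnings_by_age = setNames(rep(100, 4), 28:31))
}

toy_cohort <- function(n_women = 100, n_replications = 3) {
  list(n_women = n_women, n_replications = n_replications,
       reference_population = 1000, time_horizon_years = 1, seed = 7,
       age_distribution = list(ages = 28:31, probs = rep(0.25, 4)))
}

# small full-featured model: every flag and cost category reachable
toy_full_params <- function(n_women = 200, n_replications = 3,
                            interventions = list()) {
  tree <- nas_tree(
    states = data.frame(
      id = c("root", "preg", "nopreg", "np_live",
             "np_dead", "tx", "notx", "done", "drop",
             "dn_nas", "dn_ok", "dr_nas", "dr_ok",
             "nt_dead", "nt_nas", "nt_ok"),
      label = c("root", "pregnant", "not pregnant", "living with OUD",
                "overdose death", "starts treatment", "untreated",
                "completed", "dropped out",
                "NAS birth", "healthy birth", "NAS birth", "healthy birth",
                "overdose death", "NAS birth", "healthy birth"),
      stage = c("pregnancy", "treatment_entry", "pregnancy", "terminal",
                "terminal", "treatment_modality", "treatment_entry",
                "treatment_outcome", "treatment_outcome",
                rep("terminal", 7)),
      is_terminal = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                      FALSE, FALSE, rep(TRUE, 7))),
    transitions = data.frame(
      name = c("is_preg", "no_preg", "np_live_t", "np_dead_t",
               "start", "no_start", "complete", "drop_out",
               "dn_nas_t", "dn_ok_t", "dr_nas_t", "dr_ok_t",
               "nt_dead_t", "nt_nas_t", "nt_ok_t"),
      from = c("root", "root", "nopreg", "nopreg",
               "preg", "preg", "tx", "tx",
               "done", "done", "drop", "drop",
               "notx", "notx", "notx"),
      to = c("preg", "nopreg", "np_live", "np_dead",
             "tx", "notx", "done", "drop",
             "dn_nas", "dn_ok", "dr_nas", "dr_ok",
             "nt_dead", "nt_nas", "nt_ok"),
      prob = c(0.5, 0.5, 0.9, 0.1,
               0.6, 0.4, 0.7, 0.3,
               0.2, 0.8, 0.5, 0.5,
               0.1, 0.45, 0.45)),
    flags = list(
      pregnant = "preg", started_treatment = "tx",
      completed_treatment = "done",
      nas_case = c("dn_nas", "dr_nas", "nt_nas"),
      overdose_death = c("np_dead", "nt_dead"),
      living_with_oud = c("np_live", "dr_nas", "dr_ok", "nt_nas", "nt_ok"))
  )
  parameter_set(tree, toy_costs(), toy_cohort(n_women, n_replications),
                interventions)
}

# random outcomes with ages for costing tests
sampled_outcomes <- function(params, n, seed = 1) {
  set.seed(seed)
  out <- sample_paths(params$tree, n)
  ad <- params$cohort$age_distribution
  out$age <- sample(ad$ages, n, replace = TRUE, prob = ad$probs)
  out
}

expect_no_violations <- function(v) {
  expect_identical(v, character(0))
}
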