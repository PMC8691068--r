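test_that("substreams repeat exactly for one index and differ across indices", {
  s1 <- substream_seeds(42, 5)
  s2 <- substream_seeds(42, 5)
  expect_identical(s1, s2)
  expect_false(any(duplicated(s1)))
  expect_false(identical(substream_seeds(43, 5), s1))

  params <- toy_full_params()
  app <- apply_interventions(params, "baseline")
  engine <- scenario_engine(app$tree, params$costs, app$active,
                            params$cohort$age_distribution)
  r1 <- run_replication(engine, 500, s1[1])
  r2 <- run_replication(engine, 500, s1[1])
  r3 <- run_replication(engine, 500, s1[2])
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
})

test_that("a certain path gives deterministic counts (n, n, n, 0, 0)", {
  params <- degenerate_params(n_women = 50, n_replications = 2)
  res <- run_scenario(params, "baseline", root_seed = 1)
  reps <- res$replications
  expect_true(all(reps$count_pregnant == 50))
  expect_true(all(reps$count_started_treatment == 50))
  expect_true(all(reps$count_completed_treatment == 50))
  expect_true(all(reps$count_nas_cases == 0))
  expect_true(all(reps$count_overdose_deaths == 0))
})

test_that("replication counts track enumeration expectations within binomial error", {
  params <- toy_full_params()
  n <- 5000
  dist <- enumerate_paths(params$tree)
  for (seed in 1:10) {
    res <- run_scenario(params, "baseline", n_women = n, n_replications = 1,
                        root_seed = seed)
    for (pair in list(c("count_pregnant", "pregnant"),
                      c("count_nas_cases", "nas_case"),
                      c("count_started_treatment", "started_treatment"))) {
      p <- expected_flag_rate(dist, pair[2])
      got <- res$replications[[pair[1]]]
      expect_lt(abs(got - n * p), 4 * sqrt(n * p * (1 - p)) + 1e-9)
    }
  }
})

test_that("summary statistics satisfy their definitions", {
  params <- toy_full_params(n_replications = 8)
  res <- run_scenario(params, "baseline", n_women = 1000, root_seed = 3)
  s <- res$summary
  i <- which(s$output == "count_nas_cases")
  expect_equal(s$mean[i], mean(res$replications$count_nas_cases))
  expect_equal(s$se[i], s$sd[i] / sqrt(8))
  expect_equal(s$ci_lo[i], s$mean[i] - 1.96 * s$se[i])
  expect_equal(s$ci_hi[i], s$mean[i] + 1.96 * s$se[i])
  expect_true(all(s$ci_lo <= s$mean & s$mean <= s$ci_hi))
  # single replication: mean equals that replication's count
  res1 <- run_scenario(params, "baseline", n_women = 1000,
                       n_replications = 1, root_seed = 3)
  expect_equal(scenario_mean(res1, "count_nas_cases"),
               res1$replications$count_nas_cases[1])
})

test_that("a no-op intervention under common random numbers equals baseline exactly", {
  params <- toy_full_params(interventions = list(
    noop = list(label = "nothing", per_woman_cost = 0,
                eligibility = "pregnant", modifiers = list())))
  res <- run_all_scenarios(params, scenarios = c(Baseline = "baseline",
                                                 Noop = "noop"),
                           n_women = 2000, n_replications = 5,
                           root_seed = 11, crn = TRUE)
  expect_identical(res$Noop$replications, res$Baseline$replications)
})

test_that("a costed, effect-less intervention shifts Medicaid by eligible x cost", {
  params <- toy_full_params(interventions = list(
    tax = list(label = "cost only", per_woman_cost = 25,
               eligibility = "pregnant", modifiers = list())))
  res <- run_all_scenarios(params, scenarios = c(Baseline = "baseline",
                                                 Tax = "tax"),
                           n_women = 3000, n_replications = 4,
                           root_seed = 5, crn = TRUE)
  shift <- res$Tax$replications$cost_medicaid -
    res$Baseline$replications$cost_medicaid
  expect_equal(shift, 25 * res$Baseline$replications$count_pregnant)
})

test_that("completed never exceeds started in any replication of any scenario", {
  params <- default_parameters()
  res <- run_all_scenarios(params, n_women = 5000, n_replications = 4,
                           root_seed = 17)
  for (r in res) {
    expect_true(all(r$replications$count_completed_treatment <=
                      r$replications$count_started_treatment))
    expect_true(all(r$replications$count_started_treatment <= r$n_women))
    expect_true(all(r$replications$count_nas_cases <=
                      r$replications$count_pregnant))
  }
})

test_that("no single intervention increases mean NAS cases under CRN", {
  params <- default_parameters()
  res <- run_all_scenarios(
    params,
    scenarios = c(Baseline = "baseline", MOT = "mot",
                  `Patient Navigators` = "navigators",
                  `Capacity Increase` = "capacity",
                  `Peer Recovery Coaches` = "coaches"),
    n_women = 50000, n_replications = 30, root_seed = 23, crn = TRUE)
  base <- scenario_mean(res$Baseline, "count_nas_cases")
  for (nm in setdiff(names(res), "Baseline"))
    expect_lte(scenario_mean(res[[nm]], "count_nas_cases"), base)
})

test_that("doubling the cohort roughly halves the variance of per-woman means", {
  params <- toy_full_params()
  var_of_mean <- function(n_women) {
    rates <- vapply(1:20, function(seed) {
      r <- run_scenario(params, "baseline", n_women = n_women,
                        n_replications = 1, root_seed = seed)
      r$replications$count_nas_cases / n_women
    }, numeric(1))
    stats::var(rates)
  }
  ratio <- var_of_mean(2000) / var_of_mean(4000)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})

test_that("common random numbers reduce the paired-difference variability", {
  params <- default_parameters()
  paired_se <- function(crn, seed) {
    res <- run_all_scenarios(params,
                             scenarios = c(Baseline = "baseline", MOT = "mot"),
                             n_women = 20000, n_replications = 10,
                             root_seed = seed, crn = crn)
    d <- res$MOT$replications$count_nas_cases -
      res$Baseline$replications$count_nas_cases
    stats::sd(d) / sqrt(length(d))
  }
  ses <- vapply(1:10, function(s) c(paired_se(TRUE, s), paired_se(FALSE, s)),
                numeric(2))
  expect_lt(mean(ses[1, ]), mean(ses[2, ]))
})

test_that("scenario results record their seed and run sizes", {
  params <- toy_full_params()
  res <- run_scenario(params, "baseline", n_women = 100, n_replications = 2,
                      root_seed = 99)
  expect_equal(res$root_seed, 99)
  expect_equal(res$n_women, 100)
  expect_equal(res$n_replications, 2)
})
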