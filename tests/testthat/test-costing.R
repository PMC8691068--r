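test_that("productivity loss reduces to the undiscounted sum and empty sum", {
  eb <- setNames(rep(100, 10), 25:34)
  expect_equal(productivity_loss(25, eb, 35, 0), 10 * 100)
  expect_equal(productivity_loss(30, eb, 35, 0), 5 * 100)
  expect_equal(productivity_loss(35, eb, 35, 0.03), 0)
  expect_error(productivity_loss(10, eb, 35, 0.03), "age")
  expect_error(productivity_loss(40, eb, 35, 0.03), "retirement")
})

test_that("discounted productivity loss matches the annuity-due closed form", {
  E <- 50000; r <- 0.03; N <- 40; age <- 25
  eb <- setNames(rep(E, N), age + 0:(N - 1))
  closed_form <- E * (1 - (1 + r)^(-N)) / r * (1 + r)
  loop <- sum(E / (1 + r)^(0:(N - 1)))
  expect_equal(loop, closed_form, tolerance = 1e-12)
  expect_equal(productivity_loss(age, eb, age + N, r), closed_form,
               tolerance = 1e-9)
  # non-increasing in age for flat earnings
  losses <- productivity_loss(age + 0:(N - 1), eb, age + N, r)
  expect_true(all(diff(losses) < 0))
})

test_that("cost categories are gated by outcome flags", {
  params <- toy_full_params()
  out <- sampled_outcomes(params, 2000)
  costs <- cost_outcomes(out, params$costs)

  # a not-pregnant woman alive with OUD accrues only the living-with-OUD cost
  w <- which(out$terminal == "np_live")[1]
  expect_equal(costs$living_with_oud[w], 500)
  expect_equal(costs$mother_opioid_treatment[w], 0)
  expect_equal(costs$nas_treatment[w], 0)
  expect_equal(costs$overdose_death[w], 0)
  expect_equal(costs$special_education[w], 0)

  # NAS birth: treatment days x (hospital + NAS daily), plus special education
  w <- which(out$nas_case)[1]
  expect_equal(costs$nas_treatment[w], 10 * (100 + 40))
  expect_equal(costs$special_education[w], 250)

  # treated woman carries her modality's episode cost
  w <- which(out$started_treatment)[1]
  expect_equal(costs$mother_opioid_treatment[w], 1000)

  # overdose death costs the discounted remaining career at her age
  w <- which(out$overdose_death)[1]
  expect_equal(costs$overdose_death[w],
               productivity_loss(out$age[w], params$costs$earnings_by_age,
                                 32, 0.03))
})

test_that("a missing modality cost errors naming the modality", {
  params <- toy_full_params()
  params$costs$mother_treatment_costs <-
    params$costs$mother_treatment_costs[c("buprenorphine", "detoxification")]
  out <- sampled_outcomes(params, 200)
  expect_error(cost_outcomes(out, params$costs), "methadone")
})

test_that("perspective identities hold exactly for every sampled woman", {
  params <- toy_full_params()
  out <- sampled_outcomes(params, 1000)
  active <- list(mot = list(per_woman_cost = 30, eligibility = "pregnant"))
  costs <- cost_outcomes(out, params$costs, active)
  expect_identical(costs$medicaid,
                   costs$mother_opioid_treatment + costs$nas_treatment +
                     costs$intervention)
  expect_identical(costs$system,
                   costs$medicaid + costs$overdose_death +
                     costs$living_with_oud + costs$special_education)
})

test_that("aggregation equals the brute-force per-woman loop", {
  params <- toy_full_params()
  out <- sampled_outcomes(params, 1000)
  costs <- cost_outcomes(out, params$costs)
  agg <- aggregate_costs(out, costs)
  # independent loop oracle
  loop_tot <- setNames(numeric(ncol(costs)), names(costs))
  for (i in seq_len(nrow(costs)))
    loop_tot <- loop_tot + unlist(costs[i, ])
  for (k in names(agg$categories))
    expect_equal(agg$categories[[k]], loop_tot[[k]])
  expect_equal(agg$medicaid, loop_tot[["medicaid"]])
  expect_equal(agg$system, loop_tot[["system"]])
  expect_equal(unname(agg$counts["nas_case"]), sum(out$nas_case))

  empty <- aggregate_costs(out[0, ], costs[0, ])
  expect_true(all(empty$categories == 0))
  expect_equal(empty$system, 0)
})

test_that("single-outcome costing agrees with the vectorized route", {
  params <- toy_full_params()
  out <- sampled_outcomes(params, 20)
  costs <- cost_outcomes(out, params$costs)
  one <- cost_outcome(out[3, ], params$costs)
  expect_equal(one$system, costs$system[3])
  expect_equal(one$medicaid, costs$medicaid[3])
})

test_that("expected Monte Carlo cost matches enumeration-based expectation", {
  params <- toy_full_params()
  dist <- enumerate_paths(params$tree)
  # exact expected per-woman system cost: per-path cost x path probability,
  # with death cost replaced by its expectation over the age distribution
  ad <- params$cohort$age_distribution
  mean_pl <- sum(productivity_loss(ad$ages, params$costs$earnings_by_age,
                                   params$costs$retirement_age,
                                   params$costs$productivity_discount_rate) *
                   ad$probs)
  dist$age <- ad$ages[1]
  path_costs <- cost_outcomes(dist, params$costs)
  pl_at_first_age <- productivity_loss(ad$ages[1],
                                       params$costs$earnings_by_age,
                                       params$costs$retirement_age,
                                       params$costs$productivity_discount_rate)
  exact_system <- sum(dist$prob * (path_costs$system -
    as.numeric(dist$overdose_death) * (pl_at_first_age - mean_pl)))

  n <- 20000
  out <- sampled_outcomes(params, n, seed = 5)
  emp <- mean(cost_outcomes(out, params$costs)$system)
  # per-woman system cost is bounded; 4 standard errors of the sample mean
  se <- stats::sd(cost_outcomes(out, params$costs)$system) / sqrt(n)
  expect_lt(abs(emp - exact_system), 4 * se)
})
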