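#' Generate a perturbed-but-valid parameter set
#'
#' Resamples every sibling-probability group of the base tree from a
#' Dirichlet distribution centred on the base probabilities
#' (`alpha = concentration * p`), and jitters monetary values by an
#' independent multiplicative factor uniform on
#' `[1 - cost_jitter, 1 + cost_jitter]`. Large concentrations shrink the
#' perturbation: as `concentration -> Inf` the output converges to the base
#' set. Topology, flags, cohort settings and interventions are preserved, and
#' the result always passes [validate_parameters()].
#'
#' @param base a validated `parameter_set` to perturb
#' @param seed integer seed
#' @param concentration Dirichlet concentration parameter (default 200;
#'   larger = closer to base)
#' @param cost_jitter half-width of the multiplicative cost jitter (default
#'   0.1)
#' @return list with `params` (the perturbed, validated `parameter_set`) and
#'   `truth` (exact perturbed transition probabilities and costs)
#' @export
generate_parameter_set <- function(base, seed, concentration = 200,
                                   cost_jitter = 0.1) {
  set.seed(seed)
  tree <- base$tree
  tr <- tree$transitions
  for (s in unique(tr$from)) {
    idx <- which(tr$from == s)
    p <- tr$prob[idx]
    pos <- p > 0
    if (sum(pos) <= 1L) next  # degenerate group: nothing to resample
    g <- stats::rgamma(sum(pos), shape = concentration * p[pos], rate = 1)
    if (sum(g) <= 0) next     # numerically degenerate draw: keep base probs
    p[pos] <- g / sum(g)
    tr$prob[idx] <- p
  }
  tree$transitions <- tr

  costs <- base$costs
  jitter1 <- function(x) x * stats::runif(length(x), 1 - cost_jitter, 1 + cost_jitter)
  for (k in c("daily_hospital_cost", "daily_nas_treatment_cost",
              "annual_oud_incremental_cost", "special_education_cost"))
    costs[[k]] <- jitter1(costs[[k]])
  costs$mother_treatment_costs <- jitter1(costs$mother_treatment_costs)

  params <- parameter_set(tree, costs, base$cohort, base$interventions,
                          base$metadata)
  v <- validate_parameters(params)
  if (length(v))
    stop_nassim("perturbed parameter set failed validation: %s",
                paste(v, collapse = "; "))
  list(params = params,
       truth = list(transition_probs = setNames(tr$prob, tr$name),
                    costs = costs, seed = seed,
                    concentration = concentration, cost_jitter = cost_jitter))
}

SYNTH_OUD_CODES <- c("F11.10", "F11.20", "F11.23", "F11.90")
SYNTH_TREATMENT_CODES <- c("HZ81ZZZ", "HZ91ZZZ", "H0020", "J0592")
SYNTH_DECOY_DIAGNOSES <- c("Z34.90", "O80", "E11.9", "J06.9")

#' Generate synthetic claims with known ground truth
#'
#' Builds a claims-style dataset whose member-level truth labels (delivered /
#' delivered-with-OUD / treated) are known exactly and recoverable by
#' [extract_cohort()]: OUD and treatment codes for true positives are placed
#' strictly inside the 365-day lookback window from the member's delivery
#' date, while decoy codes — irrelevant diagnoses inside the window, and real
#' OUD/treatment codes strictly outside it — are injected at `decoy_rate` to
#' exercise the window and code matching. Truth labels are returned in a
#' separate sidecar table, never encoded in the claims themselves.
#'
#' @param seed integer seed
#' @param n_members number of members
#' @param delivery_rate probability a member delivers in `year`
#' @param oud_rate probability a deliverer has OUD (codes in-window)
#' @param treated_rate probability an OUD deliverer is treated
#' @param year delivery calendar year (default 2018)
#' @param decoy_rate probability of injecting each kind of decoy record
#' @param claims_path,truth_path optional CSV output paths
#' @return list with `claims` (data.frame of records, shuffled) and `truth`
#'   (data.frame member_id / delivered / oud / treated)
#' @export
generate_claims <- function(seed, n_members, delivery_rate = 0.8,
                            oud_rate = 0.2, treated_rate = 0.15,
                            year = 2018, decoy_rate = 0.1,
                            claims_path = NULL, truth_path = NULL) {
  for (r in c(delivery_rate, oud_rate, treated_rate, decoy_rate))
    if (r < 0 || r > 1) stop_nassim("rates must lie in [0, 1]")
  set.seed(seed)
  member_id <- sprintf("M%06d", seq_len(n_members))
  delivered <- stats::runif(n_members) < delivery_rate
  oud <- delivered & stats::runif(n_members) < oud_rate
  treated <- oud & stats::runif(n_members) < treated_rate

  year_start <- as.Date(sprintf("%d-01-01", year))
  ndays <- as.integer(as.Date(sprintf("%d-12-31", year)) - year_start) + 1L
  delivery_date <- rep(as.Date(NA), n_members)
  delivery_date[delivered] <- year_start +
    sample.int(ndays, sum(delivered), replace = TRUE) - 1L

  rec <- list()
  add <- function(ids, dates, codes, kind) {
    if (!length(ids)) return(invisible(NULL))
    rec[[length(rec) + 1L]] <<- data.frame(
      member_id = ids, event_date = as.Date(dates, origin = "1970-01-01"),
      code = codes, event_kind = kind, stringsAsFactors = FALSE)
  }

  d_idx <- which(delivered)
  add(member_id[d_idx], delivery_date[d_idx],
      rep("O80", length(d_idx)), "delivery")

  # true in-window codes: offsets 0..365 inclusive are all inside
  o_idx <- which(oud)
  add(member_id[o_idx],
      delivery_date[o_idx] - sample(0:365, length(o_idx), replace = TRUE),
      sample(SYNTH_OUD_CODES, length(o_idx), replace = TRUE), "diagnosis")
  t_idx <- which(treated)
  add(member_id[t_idx],
      delivery_date[t_idx] - sample(0:365, length(t_idx), replace = TRUE),
      sample(SYNTH_TREATMENT_CODES, length(t_idx), replace = TRUE), "treatment")

  # decoys: irrelevant diagnoses in-window for any deliverer
  dec1 <- d_idx[stats::runif(length(d_idx)) < decoy_rate]
  add(member_id[dec1],
      delivery_date[dec1] - sample(0:365, length(dec1), replace = TRUE),
      sample(SYNTH_DECOY_DIAGNOSES, length(dec1), replace = TRUE), "diagnosis")
  # decoys: real OUD codes strictly outside the window for non-OUD deliverers
  dec2 <- setdiff(d_idx, o_idx)
  dec2 <- dec2[stats::runif(length(dec2)) < decoy_rate]
  out_offset <- function(k) ifelse(stats::runif(k) < 0.5,
                                   -sample(366:500, k, replace = TRUE),
                                   sample(1:120, k, replace = TRUE))
  add(member_id[dec2], delivery_date[dec2] + out_offset(length(dec2)),
      sample(SYNTH_OUD_CODES, length(dec2), replace = TRUE), "diagnosis")
  # decoys: treatment codes strictly outside the window for untreated OUD members
  dec3 <- setdiff(o_idx, t_idx)
  dec3 <- dec3[stats::runif(length(dec3)) < decoy_rate]
  add(member_id[dec3], delivery_date[dec3] + out_offset(length(dec3)),
      sample(SYNTH_TREATMENT_CODES, length(dec3), replace = TRUE), "treatment")

  claims <- do.call(rbind, rec)
  claims <- claims[sample.int(nrow(claims)), , drop = FALSE]
  rownames(claims) <- NULL
  truth <- data.frame(member_id = member_id, delivered = delivered,
                      oud = oud, treated = treated, stringsAsFactors = FALSE)
  if (!is.null(claims_path)) {
    out <- claims
    out$event_date <- format(out$event_date, "%Y-%m-%d")
    utils::write.csv(out, claims_path, row.names = FALSE)
  }
  if (!is.null(truth_path)) utils::write.csv(truth, truth_path, row.names = FALSE)
  list(claims = claims, truth = truth)
}
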