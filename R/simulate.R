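#' Define a Monte Carlo exposure scenario
#'
#' Bundles one contaminant x age-group simulation: marginal distributions
#' for concentration `C` (mg/L), ingestion rate `IR` (L/day) and body
#' weight `BW` (kg); fixed exposure frequency `ef` (days/year), duration
#' `ed` (years) and averaging time `at` (days); the trial count and the
#' root seed. Per trial,
#' `HQ = C * IR * ef * ed / (BW * at * RfD)`.
#'
#' Sub-stream seeds for C, IR and BW are derived deterministically from the
#' root seed; the IR and BW streams depend only on the group, so scenarios
#' for different contaminants in the same group share ingestion-rate and
#' body-weight draws trial-for-trial (one simulated person per trial),
#' which [simulate_hi()] relies on.
#'
#' @param contaminant A [contaminant_spec()].
#' @param group Age-group identifier.
#' @param c_dist,ir_dist,bw_dist [dist_spec()] marginals.
#' @param ef,ed,at Fixed exposure frequency, duration and averaging time.
#' @param n_trials Number of Monte Carlo trials (default 10000).
#' @param seed Integer root seed.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(contaminant, group, c_dist, ir_dist, bw_dist,
                          ef, ed, at, n_trials = 10000, seed = 1L) {
  if (!inherits(contaminant, "contaminant_spec")) {
    stop_validation("`contaminant` must be a contaminant_spec.")
  }
  for (d in list(c_dist, ir_dist, bw_dist)) {
    if (!inherits(d, "dist_spec")) stop_validation("Distributions must be dist_spec objects.")
  }
  fixed <- c(ef = ef, ed = ed, at = at)
  if (any(!is.finite(fixed)) || any(fixed <= 0)) {
    stop_validation("ef, ed and at must be strictly positive.")
  }
  if (!is.numeric(n_trials) || length(n_trials) != 1 || is.na(n_trials) || n_trials < 1) {
    stop_validation("`n_trials` must be a count >= 1.")
  }
  structure(
    list(contaminant = contaminant, group = as.character(group),
         c_dist = c_dist, ir_dist = ir_dist, bw_dist = bw_dist,
         ef = as.double(ef), ed = as.double(ed), at = as.double(at),
         n_trials = as.integer(n_trials), seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Build the default scenario for a panel and profile
#'
#' The package's default uncertainty model: the concentration is lognormal,
#' fitted to the panel's measured values by [fit_lognormal()]; the
#' ingestion rate is lognormal with median equal to the profile's `ir` and
#' log-SD `ir_sdlog`; body weight is normal with mean `bw`, coefficient of
#' variation `bw_cv`, truncated below at `0.2 * bw` to keep the divisor
#' physical. Exposure frequency, duration and averaging time stay at their
#' point values.
#'
#' @param panel A `brand_panel` supplying the concentration fit.
#' @param profile One exposure-profile row.
#' @param floor Detection floor passed to [fit_lognormal()].
#' @param ir_sdlog Log-SD of the ingestion-rate lognormal (default 0.25).
#' @param bw_cv Coefficient of variation of body weight (default 0.15).
#' @param n_trials,seed Passed to [scenario_spec()].
#' @return A `scenario_spec`.
#' @export
#' @examples
#' sc <- default_scenario(
#'   load_fixture("fluoride_table2"),
#'   dplyr::filter(load_fixture("exposure_table1"), group == "infants"),
#'   seed = 7
#' )
default_scenario <- function(panel, profile, floor = 0.005,
                             ir_sdlog = 0.25, bw_cv = 0.15,
                             n_trials = 10000, seed = 1L) {
  spec <- panel_contaminant(panel)
  p <- as.list(profile)
  scenario_spec(
    contaminant = spec,
    group = p$group[[1]],
    c_dist = fit_lognormal(panel$measured, floor = floor),
    ir_dist = dist_lognormal(log(p$ir[[1]]), ir_sdlog),
    bw_dist = dist_normal(p$bw[[1]], bw_cv * p$bw[[1]], lower = 0.2 * p$bw[[1]]),
    ef = p$ef[[1]], ed = p$ed[[1]], at = p$at[[1]],
    n_trials = n_trials, seed = seed
  )
}

scenario_draws <- function(scenario) {
  tibble(
    C = sample_dist(scenario$c_dist, scenario$n_trials,
                    seed = derive_seed(scenario$seed, "C", scenario$contaminant$name,
                                       scenario$group)),
    IR = sample_dist(scenario$ir_dist, scenario$n_trials,
                     seed = derive_seed(scenario$seed, "IR", scenario$group)),
    BW = sample_dist(scenario$bw_dist, scenario$n_trials,
                     seed = derive_seed(scenario$seed, "BW", scenario$group))
  )
}

new_sim_result <- function(trials, inputs, scenario, kind, probs) {
  structure(
    list(
      kind = kind,
      trials = trials,
      inputs = inputs,
      scenario = scenario,
      mean = mean(trials),
      sd = if (length(trials) > 1) sd(trials) else 0,
      percentiles = setNames(quantile(trials, probs, type = 7, names = FALSE),
                             paste0("p", format(100 * probs, trim = TRUE))),
      probs = probs
    ),
    class = "hq_sim"
  )
}

#' Simulate the hazard quotient distribution
#'
#' Runs the scenario's Monte Carlo: per trial draws C, IR and BW
#' independently from their marginals and computes
#' `HQ = C * IR * ef * ed / (BW * at * RfD)`. Identical scenarios
#' (including seed) reproduce identical trial vectors.
#'
#' @param scenario A [scenario_spec()].
#' @param probs Percentile probabilities to summarise (default 5, 50, 95).
#' @return An `hq_sim` object: trial vector, per-input draw table, mean,
#'   SD and percentiles.
#' @export
simulate_hq <- function(scenario, probs = c(0.05, 0.5, 0.95)) {
  if (!inherits(scenario, "scenario_spec")) stop_validation("`scenario` must be a scenario_spec.")
  draws <- scenario_draws(scenario)
  # Same op order as edi() then hazard_quotient(), so an all-point scenario
  # collapses to the deterministic value bit for bit.
  edi_t <- draws$C * draws$IR * scenario$ef * scenario$ed /
    (draws$BW * scenario$at)
  hq <- edi_t / scenario$contaminant$rfd
  new_sim_result(hq, draws, scenario, kind = "HQ", probs = probs)
}

#' Simulate the hazard index distribution
#'
#' Joint simulation over contaminants for one receptor group: ingestion
#' rate and body weight draws are shared across contaminants within a
#' trial (one simulated person per trial), concentration draws are
#' independent per contaminant, and `HI` is the trialwise sum of the
#' per-contaminant HQs.
#'
#' @param scenarios List of [scenario_spec()]s, one per contaminant, all
#'   sharing group, trial count, seed and IR/BW marginals.
#' @param probs Percentile probabilities to summarise.
#' @return An `hq_sim` object of kind `"HI"`; its `components` field keeps
#'   the per-contaminant `hq_sim` results.
#' @export
simulate_hi <- function(scenarios, probs = c(0.05, 0.5, 0.95)) {
  if (!is.list(scenarios) || length(scenarios) == 0) {
    stop_validation("`scenarios` must be a non-empty list of scenario_spec objects.")
  }
  for (field in c("group", "n_trials", "seed")) {
    vals <- unique(map_chr(scenarios, function(s) paste(s[[field]])))
    if (length(vals) > 1) {
      stop_validation(sprintf("Scenarios disagree on %s: %s.", field,
                              paste(vals, collapse = " vs ")))
    }
  }
  for (field in c("ir_dist", "bw_dist")) {
    if (length(unique(map_chr(scenarios, function(s) paste(deparse(s[[field]]), collapse = "")))) > 1) {
      stop_validation(sprintf("Scenarios must share the same %s for shared draws.", field))
    }
  }
  sims <- map(scenarios, simulate_hq, probs = probs)
  hi <- Reduce(`+`, map(sims, "trials"))
  out <- new_sim_result(hi, inputs = map(sims, "inputs"),
                        scenario = scenarios, kind = "HI", probs = probs)
  out$components <- sims
  out
}

#' @export
print.hq_sim <- function(x, ...) {
  cat(sprintf("<hq_sim> %s, %d trials\n  mean %.4g, sd %.4g\n",
              x$kind, length(x$trials), x$mean, x$sd))
  cat("  percentiles:", paste(sprintf("%s = %.4g", names(x$percentiles), x$percentiles),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Percentile of simulated trials
#'
#' Linear interpolation between adjacent order statistics at rank
#' `1 + (n - 1) * q` (the type-7 convention of [stats::quantile()]).
#'
#' @param result An `hq_sim` object or a numeric trial vector.
#' @param q Probability strictly inside (0, 1).
#' @return The interpolated percentile value.
#' @export
#' @examples
#' percentile(c(1, 2, 3, 4), 0.95)  # 3.85
percentile <- function(result, q) {
  trials <- if (inherits(result, "hq_sim")) result$trials else result
  if (length(trials) == 0) stop_empty("No trials to take a percentile of.")
  if (!is.numeric(q) || any(is.na(q)) || any(q <= 0) || any(q >= 1)) {
    stop_domain("`q` must lie strictly inside (0, 1).")
  }
  quantile(trials, q, type = 7, names = FALSE)
}
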