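# One-at-a-time sensitivity coefficients of the 2 h white-matter/lesion and
# gray-matter/lesion concentration ratios, a Monte-Carlo sweep of binding
# affinity x lesion target concentration, and the lipophilicity sweep.

#' Sensitivity coefficient of an output to an input perturbation
#'
#' `SC = ((perturbed - baseline) / baseline) / delta_x`, the relative
#' output change per relative input change.
#'
#' @param baseline_output baseline output value (non-zero).
#' @param perturbed_output output under the perturbed input.
#' @param delta_x relative input change (non-zero), e.g. 1.0 for a
#'   doubling.
#' @return scalar sensitivity coefficient.
#' @export
sensitivity_coefficient <- function(baseline_output, perturbed_output,
                                    delta_x) {
  if (!is.finite(baseline_output) || baseline_output == 0)
    stop("baseline_output must be finite and non-zero")
  if (!is.finite(delta_x) || delta_x == 0) stop("delta_x must be non-zero")
  ((perturbed_output - baseline_output) / baseline_output) / delta_x
}

# baseline parameter set of the sensitivity analysis
sensitivity_baseline <- function() {
  list(plasma_protein_bound = 0.10, liver_microsomal_cl = 8e-3, logp = 4,
       lesion_target_M = 3.61e-4, kd = 1e-6, kon = 5.5e5)
}

sensitivity_ratios <- function(par, t = 7200, dose_moles = 1e-9) {
  phys <- physiology_model(lesion_target_M = par$lesion_target_M)
  agent <- agent_properties(
    logp = par$logp, plasma_protein_bound = par$plasma_protein_bound,
    liver_microsomal_cl = par$liver_microsomal_cl,
    binding = binding_params(par$kd, par$kon), dose_moles = dose_moles)
  tac <- simulate_biodistribution(phys, agent, t_end = max(10800, t))
  c(wm_lesion = concentration_ratio(tac, "white_matter", "lesion", t),
    gm_lesion = concentration_ratio(tac, "gray_matter", "lesion", t))
}

#' One-at-a-time sensitivity table
#'
#' Reproduces the layout of the published sensitivity analysis: a baseline
#' run plus six runs each perturbing a single input (plasma protein
#' binding 10 to 20%, liver microsomal clearance 8 to 8.8e-3 mL/min/mg,
#' logP 4 to 5, lesion target concentration 3.61e-4 to 5.42e-4 M, Kd 1e-6
#' to 2e-6 M, kon 5.5e5 to 1e6 /M/s). The monitored outputs are the white-
#' and gray-matter to lesion concentration ratios 2 h after administration.
#' The relative input change is computed from the printed parameter values
#' (e.g. 1.0 for the doubled plasma protein binding, 0.25 for logP 4 to 5
#' on the raw value).
#'
#' @param baseline named list of baseline values (see defaults).
#' @param t evaluation time, s (default 7200).
#' @return data.frame with one row per perturbation run: input name,
#'   baseline and perturbed values, relative change `delta_x`, both
#'   baseline and perturbed outputs and the two sensitivity coefficients.
#' @export
run_sensitivity_table <- function(baseline = sensitivity_baseline(),
                                  t = 7200) {
  perturb <- list(
    plasma_protein_bound = 0.20,
    liver_microsomal_cl = 8.8e-3,
    logp = 5,
    lesion_target_M = 5.42e-4,
    kd = 2e-6,
    kon = 1e6)
  base_out <- sensitivity_ratios(baseline, t)
  rows <- lapply(names(perturb), function(nm) {
    par <- baseline
    par[[nm]] <- perturb[[nm]]
    dx <- (perturb[[nm]] - baseline[[nm]]) / baseline[[nm]]
    out <- sensitivity_ratios(par, t)
    data.frame(
      input = nm, baseline_value = baseline[[nm]],
      perturbed_value = perturb[[nm]], delta_x = dx,
      baseline_wm_lesion = base_out[["wm_lesion"]],
      perturbed_wm_lesion = out[["wm_lesion"]],
      baseline_gm_lesion = base_out[["gm_lesion"]],
      perturbed_gm_lesion = out[["gm_lesion"]],
      sc_wm_lesion = sensitivity_coefficient(
        base_out[["wm_lesion"]], out[["wm_lesion"]], dx),
      sc_gm_lesion = sensitivity_coefficient(
        base_out[["gm_lesion"]], out[["gm_lesion"]], dx))
  })
  do.call(rbind, rows)
}

#' Monte-Carlo sweep of binding affinity and lesion target concentration
#'
#' Samples Kd log-uniformly and the lesion MBP concentration uniformly over
#' the given ranges, simulates each draw, and records the white-matter to
#' lesion concentration ratio at 2 h - the heatmap-ready imageability
#' landscape.
#'
#' @param kd_range range of Kd, mol/L (default 1e-9 to 1e-6).
#' @param lesion_conc_range range of lesion target concentration, mol/L
#'   (default 1e-4 to 9e-4).
#' @param n number of simulation runs (default 500).
#' @param seed integer seed.
#' @param t evaluation time, s.
#' @return data.frame with `kd`, `lesion_conc`, `wm_lesion_ratio`.
#' @export
monte_carlo_sweep <- function(kd_range = c(1e-9, 1e-6),
                              lesion_conc_range = c(1e-4, 9e-4),
                              n = 500, seed = 1, t = 7200) {
  stopifnot(n >= 1, all(kd_range > 0), all(lesion_conc_range > 0))
  draws <- withr::with_seed(seed, list(
    kd = exp(stats::runif(n, log(kd_range[1]), log(kd_range[2]))),
    conc = stats::runif(n, lesion_conc_range[1], lesion_conc_range[2])))
  ratio <- vapply(seq_len(n), function(i) {
    par <- sensitivity_baseline()
    par$kd <- draws$kd[i]
    par$lesion_target_M <- draws$conc[i]
    sensitivity_ratios(par, t)[["wm_lesion"]]
  }, 0)
  data.frame(kd = draws$kd, lesion_conc = draws$conc,
             wm_lesion_ratio = ratio)
}

#' Lipophilicity sweep of the white-matter/lesion activity ratio
#'
#' Simulates the biodistribution for several logP values (other parameters
#' at the sensitivity baseline) and returns the white-matter to lesion
#' total-activity ratio as a function of time after administration.
#'
#' @param logp_values logP grid within 2-5.
#' @param t_end simulation end, s.
#' @return data.frame with `logp`, `time_s`, `wm_lesion_ratio` (NA where
#'   the lesion activity is still zero at t = 0).
#' @export
logp_sweep <- function(logp_values = c(2, 3, 4, 5), t_end = 10800) {
  if (any(logp_values < 2 | logp_values > 5))
    stop("logp values outside the supported 2-5 range")
  base <- sensitivity_baseline()
  out <- lapply(logp_values, function(lp) {
    par <- base
    par$logp <- lp
    phys <- physiology_model(lesion_target_M = par$lesion_target_M)
    agent <- agent_properties(
      logp = lp, plasma_protein_bound = par$plasma_protein_bound,
      liver_microsomal_cl = par$liver_microsomal_cl,
      binding = binding_params(par$kd, par$kon))
    tac <- simulate_biodistribution(phys, agent, t_end = t_end)
    tac <- activity_weight(tac)
    les <- tac$activity[, "lesion"]
    ratio <- ifelse(les > 0, tac$activity[, "white_matter"] / les, NA)
    data.frame(logp = lp, time_s = tac$times, wm_lesion_ratio = ratio)
  })
  do.call(rbind, out)
}
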