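#' Imaging agent properties
#'
#' Physicochemical and binding parameters of the (BMB-like) myelin imaging
#' agent: a small, lipophilic molecule administered intravenously in tracer
#' amounts.
#'
#' @param mw agent molecular weight, g/mol.
#' @param logp octanol-water partition descriptor (log10 scale). The
#'   published sensitivity table labels the same column Log P and Log D;
#'   a single lipophilicity parameter named `logp` is used here.
#' @param plasma_protein_bound fraction of plasma agent bound to plasma
#'   proteins (0 <= x < 1); only the free fraction exchanges with tissue and
#'   is cleared.
#' @param liver_microsomal_cl liver microsomal intrinsic clearance,
#'   mL/min per mg microsomal protein.
#' @param binding specific target binding, a [binding_params()].
#' @param nonspecific_kd dissociation constant of nonspecific binding to
#'   bulk tissue protein, mol/L (default 1e-3 M).
#' @param dose_moles administered amount, mol (tracer dose, default 1e-9).
#' @return object of class `agent_properties`.
#' @export
agent_properties <- function(mw = 342, logp = 4,
                             plasma_protein_bound = 0.10,
                             liver_microsomal_cl = 8e-3,
                             binding = binding_params(),
                             nonspecific_kd = 1e-3,
                             dose_moles = 1e-9) {
  if (!is.finite(mw) || mw <= 0) stop("mw must be > 0")
  if (!is.finite(plasma_protein_bound) || plasma_protein_bound < 0 ||
      plasma_protein_bound >= 1)
    stop("plasma_protein_bound must lie in [0, 1)")
  if (!is.finite(dose_moles) || dose_moles < 0)
    stop("dose_moles must be >= 0")
  if (!is.finite(nonspecific_kd) || nonspecific_kd <= 0)
    stop("nonspecific_kd must be > 0")
  if (!inherits(binding, "binding_params"))
    stop("binding must be a binding_params object")
  structure(list(mw = mw, logp = logp,
                 plasma_protein_bound = plasma_protein_bound,
                 liver_microsomal_cl = liver_microsomal_cl,
                 binding = binding, nonspecific_kd = nonspecific_kd,
                 dose_moles = dose_moles),
            class = "agent_properties")
}

#' Tissue-plasma partition coefficient from lipophilicity
#'
#' Simple lipophilicity-driven partition model for flow-limited peripheral
#' tissues: `Kp = 1 + (1 - water_fraction) * 10^logp * scale`, with a single
#' calibration constant `scale`.
#'
#' @param logp agent lipophilicity.
#' @param water_fraction tissue water fraction of wet weight.
#' @param scale calibration constant (default 2e-3, chosen so that a
#'   logP 4 compound partitions strongly, Kp of order 5-10, into typical
#'   soft tissue).
#' @return partition coefficient (>= 1).
#' @export
kp_from_logp <- function(logp, water_fraction, scale = 2e-3) {
  1 + (1 - water_fraction) * 10^logp * scale
}

# lipophilicity scaling of brain membrane permeability, relative to logP 4
lipo_permeability_factor <- function(logp, exponent = 0.35) {
  10^(exponent * (logp - 4))
}

#' Whole-body physiology for the PBPK model
#'
#' A reduced whole-body model: plasma, liver, kidney and rest-of-body as
#' flow-limited compartments, plus a permeability-limited brain block
#' (plasma <-> brain extracellular fluid <-> white matter / gray matter /
#' lesion cellular spaces). Brain sub-compartment volumes follow the
#' 42/56/2 % mass split; the lesion is perfused like white matter, as the
#' maintained vascular component of MS plaques supports agent delivery.
#'
#' @param compositions brain compartment compositions,
#'   see [brain_compositions()].
#' @param lesion_target_M lesion MBP concentration in mol/L. Defaults to
#'   the composition-derived lesion value; feasibility scenarios override it
#'   via [scaled_lesion_concentration()].
#' @param brain_mass_g total brain mass in g (volume at density 1 g/mL).
#' @param plasma_volume_L plasma volume, L.
#' @param cardiac_output_L_min cardiac output, L/min.
#' @param brain_flow_L_min total brain blood (plasma) flow, L/min.
#' @param ps_bbb_L_s blood-brain-barrier permeability-surface product at
#'   logP 4, L/s (combined in series with brain flow).
#' @param k_cell_per_s brain cellular membrane exchange rate constant at
#'   logP 4, 1/s per unit tissue volume (PS_j = k_cell * V_j).
#' @param kp_scale calibration constant of [kp_from_logp()].
#' @param gfr_L_min glomerular filtration rate, L/min (renal clearance of
#'   the free plasma fraction).
#' @param liver_mass_g,microsomal_mg_per_g hepatic scale-up constants:
#'   microsomal clearance (mL/min/mg) x mg microsomal protein per g liver x
#'   liver mass g gives whole-liver intrinsic clearance.
#' @param ref_protein_mw molecular weight (g/mol) of the reference protein
#'   used to express bulk tissue protein in molar units for nonspecific
#'   binding.
#' @return object of class `physiology_model`.
#' @export
physiology_model <- function(compositions = brain_compositions(),
                             lesion_target_M = NULL,
                             brain_mass_g = 1400,
                             plasma_volume_L = 3,
                             cardiac_output_L_min = 5.6,
                             brain_flow_L_min = 0.75,
                             ps_bbb_L_s = 3e-3,
                             k_cell_per_s = 0.05,
                             kp_scale = 2e-3,
                             gfr_L_min = 0.12,
                             liver_mass_g = 1800,
                             microsomal_mg_per_g = 45,
                             ref_protein_mw = 5e4) {
  mf <- attr(compositions, "mass_fraction")
  if (is.null(mf)) mf <- c(white_matter = 0.42, gray_matter = 0.56,
                           lesion = 0.02)
  if (abs(sum(mf) - 1) > 1e-8)
    stop("brain mass fractions must sum to 1")
  brain_vol_L <- brain_mass_g / 1000
  ecf_frac <- 0.15
  vols <- (1 - ecf_frac) * brain_vol_L * mf
  # molar target and bulk protein concentrations from composition
  target_M <- vapply(compositions, molar_target_concentration, 0)
  protein_g_L <- vapply(compositions, function(c)
    1000 * protein_wet_fraction(c) * c$tissue_density, 0)
  if (!is.null(lesion_target_M)) {
    if (!is.finite(lesion_target_M) || lesion_target_M < 0)
      stop("lesion_target_M must be >= 0")
    target_M[["lesion"]] <- lesion_target_M
  }
  co <- cardiac_output_L_min / 60
  q_brain <- brain_flow_L_min / 60
  q_liver <- 1.45 / 60
  q_kidney <- 1.2 / 60
  q_rest <- co - q_brain - q_liver - q_kidney
  if (q_rest <= 0) stop("cardiac output too small for organ flows")
  structure(list(
    compositions = compositions,
    mass_fraction = mf,
    volumes = list(plasma = plasma_volume_L, liver = 1.8, kidney = 0.31,
                   rest = 36,
                   ecf = ecf_frac * brain_vol_L,
                   white_matter = vols[["white_matter"]],
                   gray_matter = vols[["gray_matter"]],
                   lesion = vols[["lesion"]]),
    flows = list(liver = q_liver, kidney = q_kidney, rest = q_rest,
                 brain = q_brain),
    water_fraction_periph = c(liver = 0.71, kidney = 0.81, rest = 0.65),
    protein_g_L_periph = c(liver = 100, kidney = 90, rest = 80),
    target_M = target_M,
    protein_g_L = protein_g_L,
    ps_bbb_L_s = ps_bbb_L_s,
    k_cell_per_s = k_cell_per_s,
    kp_scale = kp_scale,
    gfr_L_s = gfr_L_min / 60,
    cl_liver_scaleup = liver_mass_g * microsomal_mg_per_g,  # mg protein
    ref_protein_mw = ref_protein_mw),
    class = "physiology_model")
}

# assemble the numeric parameter vector consumed by the ODE right-hand side
pbpk_parameters <- function(phys, agent) {
  fu_p <- 1 - agent$plasma_protein_bound
  lipo <- lipo_permeability_factor(agent$logp)
  kp <- vapply(names(phys$water_fraction_periph), function(t)
    kp_from_logp(agent$logp, phys$water_fraction_periph[[t]],
                 phys$kp_scale), 0)
  # whole-liver intrinsic clearance, mL/min -> L/s
  cl_h <- agent$liver_microsomal_cl * phys$cl_liver_scaleup / 1000 / 60
  ps_bbb <- phys$ps_bbb_L_s * lipo
  q_br <- phys$flows$brain
  g_bbb <- q_br * ps_bbb / (q_br + ps_bbb)  # flow and permeability in series
  ns <- phys$protein_g_L / phys$ref_protein_mw / agent$nonspecific_kd
  r_ns <- 1 + ns  # free fraction in brain tissue water+protein space
  list(fu_p = fu_p,
       v = phys$volumes, q = phys$flows,
       kp = kp, cl_h = cl_h, cl_r = phys$gfr_L_s,
       g_bbb = g_bbb,
       ps_cell = phys$k_cell_per_s * lipo *
         unlist(phys$volumes[c("white_matter", "gray_matter", "lesion")]),
       r_ns = r_ns[c("white_matter", "gray_matter", "lesion")],
       target = phys$target_M[c("white_matter", "gray_matter", "lesion")],
       kon = agent$binding$kon, koff = agent$binding$koff)
}

pbpk_rhs <- function(t, y, p) {
  v <- p$v
  c_pl <- y[1] / v$plasma
  cf_pl <- p$fu_p * c_pl
  cf_li <- y[2] / (v$liver * p$kp[["liver"]])
  cf_ki <- y[3] / (v$kidney * p$kp[["kidney"]])
  cf_rb <- y[4] / (v$rest * p$kp[["rest"]])
  c_ecf <- y[5] / v$ecf

  j_li <- p$q$liver * (cf_pl - cf_li)
  j_ki <- p$q$kidney * (cf_pl - cf_ki)
  j_rb <- p$q$rest * (cf_pl - cf_rb)
  j_ecf <- p$g_bbb * (cf_pl - c_ecf)
  e_li <- p$cl_h * cf_li
  e_ki <- p$cl_r * cf_pl

  vb <- c(v$white_matter, v$gray_matter, v$lesion)
  a_t <- y[c(6, 8, 10)]
  b_t <- y[c(7, 9, 11)]
  cf_t <- a_t / (vb * p$r_ns)
  cb_t <- b_t / vb
  j_t <- p$ps_cell * (c_ecf - cf_t)
  bind_t <- p$kon * cf_t * (p$target - cb_t) - p$koff * cb_t

  dy <- numeric(12)
  dy[1] <- -(j_li + j_ki + j_rb + j_ecf) - e_ki
  dy[2] <- j_li - e_li
  dy[3] <- j_ki
  dy[4] <- j_rb
  dy[5] <- j_ecf - sum(j_t)
  dy[c(6, 8, 10)] <- j_t - vb * bind_t
  dy[c(7, 9, 11)] <- vb * bind_t
  dy[12] <- e_li + e_ki
  list(dy)
}

pbpk_state_names <- c("plasma", "liver", "kidney", "rest", "brain_ecf",
                      "white_matter_free", "white_matter_bound",
                      "gray_matter_free", "gray_matter_bound",
                      "lesion_free", "lesion_bound", "cleared")

#' Simulate whole-body biodistribution of the imaging agent
#'
#' Integrates the compartmental PBPK system: an intravenous bolus into
#' plasma, flow-limited exchange with peripheral tissues using a
#' lipophilicity-derived partition coefficient, permeability-limited brain
#' uptake (blood-brain barrier in series with brain plasma flow), mass-action
#' specific binding to the target in white matter / gray matter / lesion,
#' instantaneous-equilibrium nonspecific binding to bulk tissue protein,
#' hepatic clearance scaled up from microsomal intrinsic clearance, and
#' renal clearance of the free plasma fraction. The integrator is an
#' adaptive stiff solver (deSolve's lsoda) since specific binding rates
#' exceed transport rates by orders of magnitude.
#'
#' @param phys a [physiology_model()].
#' @param agent an [agent_properties()].
#' @param t_end end of the simulated window, s (default 3 h, covering the
#'   2 h uptake period plus a 20 min scan with margin).
#' @param dt_out output sampling interval, s (default 120, the
#'   time-activity measurement interval).
#' @param rtol,atol solver tolerances. `atol` is interpreted in mol on
#'   compartment amounts and defaults to 1e-12 times the dose scale.
#' @return object of class `tac` (time-activity curve): `times` (s), `conc`
#'   (matrix, one column per compartment, total mol/L, free + specific +
#'   nonspecific), `amounts` (mol, including cumulative `cleared`),
#'   `activity` (NULL until [activity_weight()] is applied).
#' @export
simulate_biodistribution <- function(phys, agent, t_end = 10800,
                                     dt_out = 120, rtol = 1e-8,
                                     atol = NULL) {
  stopifnot(inherits(phys, "physiology_model"),
            inherits(agent, "agent_properties"))
  if (t_end <= 0 || dt_out <= 0) stop("t_end and dt_out must be > 0")
  p <- pbpk_parameters(phys, agent)
  y0 <- numeric(12)
  y0[1] <- agent$dose_moles
  names(y0) <- pbpk_state_names
  times <- seq(0, t_end, by = dt_out)
  if (is.null(atol)) atol <- 1e-12 * max(agent$dose_moles, 1e-12)
  sol <- deSolve::lsoda(y0, times, pbpk_rhs, p, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("PBPK integration failed")
  amounts <- sol[, -1, drop = FALSE]
  # formulation keeps states non-negative; clamp solver-level jitter
  if (min(amounts) < -1e-6 * max(agent$dose_moles, .Machine$double.eps))
    stop("negative compartment amount: integration inaccurate")
  amounts[amounts < 0] <- 0
  v <- p$v
  conc <- cbind(
    plasma = amounts[, "plasma"] / v$plasma,
    liver = amounts[, "liver"] / v$liver,
    kidney = amounts[, "kidney"] / v$kidney,
    rest = amounts[, "rest"] / v$rest,
    brain_ecf = amounts[, "brain_ecf"] / v$ecf,
    white_matter = (amounts[, "white_matter_free"] +
                      amounts[, "white_matter_bound"]) / v$white_matter,
    gray_matter = (amounts[, "gray_matter_free"] +
                     amounts[, "gray_matter_bound"]) / v$gray_matter,
    lesion = (amounts[, "lesion_free"] +
                amounts[, "lesion_bound"]) / v$lesion)
  structure(list(times = times, conc = conc, amounts = amounts,
                 activity = NULL, dose_moles = agent$dose_moles,
                 phys = phys, agent = agent),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d time points over %.0f s, %d compartments\n",
              length(x$times), max(x$times), ncol(x$conc)))
  cat("  compartments:", paste(colnames(x$conc), collapse = ", "), "\n")
  invisible(x)
}

#' Concentration ratio between two compartments at a time point
#'
#' Linear interpolation of the total-concentration curves, then the ratio.
#' The 2 h white-matter/lesion and gray-matter/lesion ratios are the
#' primary pharmacokinetic readouts of the feasibility study.
#'
#' @param curve a `tac` from [simulate_biodistribution()].
#' @param num,den compartment names (columns of `curve$conc`).
#' @param t time, s, within the simulated range.
#' @return scalar ratio.
#' @export
concentration_ratio <- function(curve, num, den, t = 7200) {
  stopifnot(inherits(curve, "tac"))
  if (t < min(curve$times) || t > max(curve$times))
    stop("t outside simulated range")
  if (!num %in% colnames(curve$conc) || !den %in% colnames(curve$conc))
    stop("unknown compartment name")
  cn <- stats::approx(curve$times, curve$conc[, num], xout = t)$y
  cd <- stats::approx(curve$times, curve$conc[, den], xout = t)$y
  if (cd <= 0) stop("denominator concentration is zero")
  cn / cd
}

#' Convert concentrations into decay-weighted activity
#'
#' Fills the activity channel of a time-activity curve:
#' `activity(t) = conc(t) * (injected_dose * positron_yield / dose_moles) *
#' 2^(-t / half_life)`. Units are mCi-equivalents per litre per mole of
#' administered agent; only relative activity matters downstream.
#'
#' @param curve a `tac`.
#' @param injected_dose injected activity, mCi (default 10).
#' @param half_life radioisotope half-life, s (default 6588).
#' @param positron_yield positron branching fraction (default 0.97).
#' @return the `tac` with `activity` set (same shape as `conc`).
#' @export
activity_weight <- function(curve, injected_dose = 10, half_life = 6588,
                            positron_yield = 0.97) {
  stopifnot(inherits(curve, "tac"))
  if (!is.finite(half_life) || half_life <= 0) stop("half_life must be > 0")
  if (!is.finite(positron_yield) || positron_yield < 0 ||
      positron_yield > 1)
    stop("positron_yield must lie in [0, 1]")
  scale <- if (curve$dose_moles > 0)
    injected_dose * positron_yield / curve$dose_moles else 0
  decay <- 2^(-curve$times / half_life)
  curve$activity <- curve$conc * scale * decay
  curve
}

#' Export a time-activity curve as a data frame
#'
#' @param x a `tac`.
#' @param row.names,optional,... passed through for S3 consistency.
#' @return data.frame with `time_s`, one `conc_*` column per compartment
#'   and, if present, one `activity_*` column per compartment.
#' @export
as.data.frame.tac <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- data.frame(time_s = x$times)
  conc <- as.data.frame(x$conc)
  names(conc) <- paste0("conc_", names(conc))
  out <- cbind(out, conc)
  if (!is.null(x$activity)) {
    act <- as.data.frame(x$activity)
    names(act) <- paste0("activity_", names(act))
    out <- cbind(out, act)
  }
  out
}
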