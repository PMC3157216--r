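test_that("zero dose gives identically zero concentrations", {
  phys <- physiology_model()
  agent <- agent_properties(dose_moles = 0)
  tac <- simulate_biodistribution(phys, agent, t_end = 3600)
  expect_true(all(tac$conc == 0))
})

test_that("mass is conserved to 1e-6 relative at every output time", {
  phys <- physiology_model()
  for (kd in c(1e-9, 1e-6)) {
    agent <- agent_properties(binding = binding_params(kd, 5.5e5))
    tac <- simulate_biodistribution(phys, agent)
    total <- rowSums(tac$amounts)
    expect_lt(max(abs(total - agent$dose_moles)) / agent$dose_moles, 1e-6)
    expect_true(all(tac$conc >= 0))
  }
})

test_that("without binding and partitioning, free levels equilibrate", {
  # kon effectively zero, Kp = 1, negligible nonspecific binding and
  # clearance: all well-perfused compartments approach a common free
  # concentration
  phys <- physiology_model(kp_scale = 0, gfr_L_min = 0)
  agent <- agent_properties(plasma_protein_bound = 0,
                            liver_microsomal_cl = 0,
                            binding = binding_params(1e-6, 1e-10),
                            nonspecific_kd = 1e9)
  tac <- simulate_biodistribution(phys, agent, t_end = 4e5, dt_out = 2000)
  last <- tac$conc[nrow(tac$conc), c("plasma", "liver", "kidney", "rest",
                                     "brain_ecf", "white_matter",
                                     "gray_matter", "lesion")]
  expect_lt(diff(range(last)) / mean(last), 0.01)
})

test_that("concentration ratios behave at reference points", {
  phys <- physiology_model()
  agent <- agent_properties()
  tac <- simulate_biodistribution(phys, agent)
  expect_equal(concentration_ratio(tac, "white_matter", "white_matter"), 1)
  expect_error(concentration_ratio(tac, "white_matter", "lesion", t = 0),
               "zero")
  expect_error(concentration_ratio(tac, "white_matter", "lesion",
                                   t = 1e9), "range")
  # lesion parameterized exactly like white matter behaves like it
  phys_sym <- physiology_model(
    lesion_target_M = molar_target_concentration(
      brain_compositions()$white_matter))
  phys_sym$protein_g_L[["lesion"]] <- phys_sym$protein_g_L[["white_matter"]]
  tac_sym <- simulate_biodistribution(phys_sym, agent)
  expect_equal(concentration_ratio(tac_sym, "white_matter", "lesion"), 1,
               tolerance = 1e-4)
})

test_that("weak binding separates lesion from white matter", {
  # with a 100-fold demyelinated lesion, micromolar affinity yields a
  # higher 2 h ratio than nanomolar affinity
  r_weak <- wm_lesion_ratio(kd = 1e-6, lesion_M = 1.015e-5)
  r_strong <- wm_lesion_ratio(kd = 1e-9, lesion_M = 1.015e-5)
  expect_gt(r_weak, r_strong)
  expect_lt(abs(r_strong - 1), 0.1)
})

test_that("time-activity curves coincide at high affinity and separate at low", {
  run <- function(kd, lesion_M) {
    phys <- physiology_model(lesion_target_M = lesion_M)
    agent <- agent_properties(binding = binding_params(kd, 5.5e5))
    activity_weight(simulate_biodistribution(phys, agent))
  }
  sep <- function(tac) {
    sel <- tac$times >= 1800
    wm <- tac$activity[sel, "white_matter"]
    les <- tac$activity[sel, "lesion"]
    max(abs(wm - les) / pmax(wm, 1e-300))
  }
  # nanomolar: curves nearly coincide for both lesion target levels
  expect_lt(sep(run(1e-9, 3.61e-4)), 0.05)
  expect_lt(sep(run(1e-9, 1.015e-5)), 0.10)
  # micromolar: visible separation, growing with demyelination
  s_base <- sep(run(1e-6, 3.61e-4))
  s_demyel <- sep(run(1e-6, 1.015e-5))
  expect_gt(s_base, 0.10)
  expect_gt(s_demyel, s_base)
})

test_that("decay weighting follows the closed-form decay factor", {
  phys <- physiology_model()
  agent <- agent_properties()
  tac <- simulate_biodistribution(phys, agent, t_end = 7200)
  tac <- activity_weight(tac, injected_dose = 10, half_life = 6588,
                         positron_yield = 0.97)
  scale <- 10 * 0.97 / agent$dose_moles
  i <- which(tac$times == 7200)
  expect_equal(tac$activity[i, "plasma"],
               tac$conc[i, "plasma"] * scale * 2^(-7200 / 6588))
  expect_equal(2^(-7200 / 6588), 0.4688, tolerance = 1e-3)
  # at one half-life the decay factor is exactly one half
  j <- which.min(abs(tac$times - 6588))
  tac2 <- activity_weight(tac, half_life = tac$times[j])
  expect_equal(unname(tac2$activity[j, "plasma"] /
                        tac2$conc[j, "plasma"] / scale), 0.5)
  tac0 <- activity_weight(tac, positron_yield = 0)
  expect_true(all(tac0$activity == 0))
})

test_that("physiology and agent validation rejects bad inputs", {
  expect_error(agent_properties(plasma_protein_bound = 1), "plasma")
  expect_error(agent_properties(nonspecific_kd = 0), "nonspecific")
  expect_error(agent_properties(binding = list(kd = 1)), "binding_params")
  expect_error(physiology_model(lesion_target_M = -1), "lesion_target_M")
  expect_error(physiology_model(cardiac_output_L_min = 0.1),
               "cardiac output")
})
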