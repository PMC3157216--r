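# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# lesion-free phantom at half reference resolution (2.2 mm voxels)
phantom_128 <- function() {
  fixture("phantom_128", function()
    generate_head_phantom(dim = c(128, 128, 64), seed = 1))
}

# phantom used for imaging experiments (1.76 mm voxels)
phantom_160 <- function() {
  fixture("phantom_160", function()
    generate_head_phantom(dim = c(160, 160, 80), seed = 1))
}

# 2 h compartment concentrations for a pharmacological scenario, cached
scenario_conc <- function(kd = 1e-6, fold = 100, kon = 5.5e5) {
  key <- sprintf("conc_%g_%g_%g", kd, fold, kon)
  fixture(key, function() {
    comps <- brain_compositions()
    wm <- molar_target_concentration(comps$white_matter)
    phys <- physiology_model(comps,
      lesion_target_M = scaled_lesion_concentration(wm, fold))
    agent <- agent_properties(binding = binding_params(kd, kon))
    tac <- simulate_biodistribution(phys, agent)
    at <- function(cmp) stats::approx(tac$times, tac$conc[, cmp],
                                      xout = 7200)$y
    c(white_matter = at("white_matter"), gray_matter = at("gray_matter"),
      lesion = at("lesion"), other = at("rest"))
  })
}

# 2 h white-matter/lesion concentration ratio for arbitrary parameters
wm_lesion_ratio <- function(kd = 1e-6, lesion_M = 3.61e-4, logp = 4,
                            ppb = 0.1, cl = 8e-3, kon = 5.5e5,
                            num = "white_matter") {
  phys <- physiology_model(lesion_target_M = lesion_M)
  agent <- agent_properties(logp = logp, plasma_protein_bound = ppb,
                            liver_microsomal_cl = cl,
                            binding = binding_params(kd, kon))
  tac <- simulate_biodistribution(phys, agent)
  concentration_ratio(tac, num, "lesion", 7200)
}

# synthetic disk image on an n x n grid with given pixel size
disk_image <- function(n, pixel_mm, radius_mm, value = 1,
                       background = 0, center_mm = c(0, 0)) {
  ctr <- (n + 1) / 2
  xs <- (1:n - ctr) * pixel_mm
  r2 <- outer((xs - center_mm[1])^2, (xs - center_mm[2])^2, "+")
  ifelse(r2 <= radius_mm^2, value, background)
}

# independent oracle for equilibrium binding: bisection on the mass-action
# balance g(x) = (T - x)(L - x) - kd * x over [0, min(T, L)]
bound_fraction_bisect <- function(t_tot, l_tot, kd, iter = 200) {
  if (l_tot == 0) return(0)
  lo <- 0
  hi <- min(t_tot, l_tot)
  g <- function(x) (t_tot - x) * (l_tot - x) - kd * x
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / l_tot
}
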