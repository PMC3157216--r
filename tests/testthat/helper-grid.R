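# Shared imaging-grid experiments for the feasibility trend checks:
# paired-seed SNR measurements over lesion diameter, placement and
# demyelination, with the 50%-inflated ROI scored alongside.

snr_grid_experiments <- function() {
  fixture("snr_grid", function() {
    vol <- phantom_160()
    lt <- reference_lesion_table(dim(vol$labels))
    acq <- acquisition_params()
    seeds <- 101:108
    conds <- rbind(
      expand.grid(diameter = c(4, 6, 8, 10),
                  placement = c("interior_wm", "wm_gm_border"),
                  fold = 100, stringsAsFactors = FALSE),
      expand.grid(diameter = c(4, 6, 8, 10), placement = "interior_wm",
                  fold = 10, stringsAsFactors = FALSE))
    out <- vector("list", nrow(conds))
    for (i in seq_len(nrow(conds))) {
      cd <- conds[i, ]
      row <- lt[lt$diameter_mm == cd$diameter &
                  lt$placement_class == cd$placement, ]
      spec <- lesion_spec(c(row$x, row$y, row$z), cd$diameter,
                          cd$placement)
      conc <- scenario_conc(kd = 1e-6, fold = cd$fold)
      out[[i]] <- lesion_snr_experiment(
        vol, spec, conc, acq, seeds = seeds, calibrate_counts = 1e6,
        area_factor = 1.5)
    }
    conds$mean_snr <- vapply(out, function(e) mean(e$snr), 0)
    conds$mean_snr_inflated <- vapply(out,
                                      function(e) mean(e$snr_inflated), 0)
    list(conditions = conds, experiments = out, seeds = seeds)
  })
}

grid_snr <- function(grid, diameter, placement, fold, inflated = FALSE) {
  i <- which(grid$conditions$diameter == diameter &
               grid$conditions$placement == placement &
               grid$conditions$fold == fold)
  stopifnot(length(i) == 1)
  if (inflated) grid$experiments[[i]]$snr_inflated
  else grid$experiments[[i]]$snr
}

# paired one-sided check: mean difference must be non-negative within
# two standard errors of the paired Monte-Carlo differences
expect_paired_nondecreasing <- function(lo, hi) {
  d <- hi - lo
  se <- stats::sd(d) / sqrt(length(d))
  expect_gte(mean(d), -2 * se)
}
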