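#' Tissue composition of a brain compartment
#'
#' Bundles the wet-weight water fraction, the dry-weight protein fraction and
#' the myelin-basic-protein (MBP) content of a brain compartment, from which
#' the protein wet fraction and the molar target concentration are derived.
#' The defaults for the three modeled compartments (white matter, gray
#' matter, MS lesion) are available from [brain_compositions()].
#'
#' @param name compartment label, e.g. `"white_matter"`.
#' @param water_fraction water content as a fraction of wet weight (0-1).
#' @param protein_dry_fraction total protein as a fraction of dry weight
#'   (0-1).
#' @param target_mg_per_g_protein mg of target protein (MBP) per g of total
#'   protein.
#' @param tissue_density tissue density in g/mL used to convert mg per g wet
#'   weight into mg/mL. The published composition table is only internally
#'   consistent for a density of 1 g/mL, the default.
#' @param target_mw molecular weight of the target in g/mol. Defaults to
#'   18500 (major human MBP isoform); other isoforms span roughly
#'   17200-21000.
#' @return an object of class `tissue_composition`.
#' @export
tissue_composition <- function(name, water_fraction, protein_dry_fraction,
                               target_mg_per_g_protein,
                               tissue_density = 1.0, target_mw = 18500) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(water_fraction) || water_fraction < 0 || water_fraction > 1)
    stop("water_fraction must lie in [0, 1]")
  if (!is.finite(protein_dry_fraction) || protein_dry_fraction < 0 ||
      protein_dry_fraction > 1)
    stop("protein_dry_fraction must lie in [0, 1]")
  if (!is.finite(target_mg_per_g_protein) || target_mg_per_g_protein < 0)
    stop("target_mg_per_g_protein must be >= 0")
  if (!is.finite(target_mw) || target_mw <= 0)
    stop("target_mw must be > 0")
  if (!is.finite(tissue_density) || tissue_density <= 0)
    stop("tissue_density must be > 0")
  structure(
    list(name = name,
         water_fraction = water_fraction,
         protein_dry_fraction = protein_dry_fraction,
         target_mg_per_g_protein = target_mg_per_g_protein,
         tissue_density = tissue_density,
         target_mw = target_mw),
    class = "tissue_composition")
}

#' @export
print.tissue_composition <- function(x, ...) {
  cat(sprintf(
    "<tissue_composition> %s\n  water %.3f | protein (dry) %.3f | target %.4g mg/g protein\n  protein (wet) %.4f | target %.4g mg/g wet | target %.4g M\n",
    x$name, x$water_fraction, x$protein_dry_fraction,
    x$target_mg_per_g_protein, protein_wet_fraction(x),
    target_mg_per_g_wet(x), molar_target_concentration(x)))
  invisible(x)
}

#' Default compositions of the modeled brain compartments
#'
#' White matter, gray matter and MS-lesion composition (water fraction,
#' protein dry-weight fraction, MBP per g protein) as used throughout the
#' feasibility study, together with the mass fraction each compartment
#' contributes to total brain mass (42/56/2 %).
#'
#' @param target_mw MBP molecular weight in g/mol passed to each
#'   [tissue_composition()].
#' @return named list of `tissue_composition` objects with an attribute
#'   `mass_fraction` (named numeric, sums to 1).
#' @export
brain_compositions <- function(target_mw = 18500) {
  comps <- list(
    white_matter = tissue_composition("white_matter", 0.72, 0.39, 172,
                                      target_mw = target_mw),
    gray_matter = tissue_composition("gray_matter", 0.82, 0.553, 25,
                                     target_mw = target_mw),
    lesion = tissue_composition("lesion", 0.76, 0.317, 87.8,
                                target_mw = target_mw))
  attr(comps, "mass_fraction") <-
    c(white_matter = 0.42, gray_matter = 0.56, lesion = 0.02)
  comps
}

#' Protein content as a fraction of wet weight
#'
#' @param c a [tissue_composition()].
#' @return protein wet-weight fraction, `protein_dry_fraction *
#'   (1 - water_fraction)`. Multiply by 100 for the percent form.
#' @export
protein_wet_fraction <- function(c) {
  stopifnot(inherits(c, "tissue_composition"))
  c$protein_dry_fraction * (1 - c$water_fraction)
}

#' Target content in mg per g wet tissue
#'
#' @param c a [tissue_composition()].
#' @return `target_mg_per_g_protein * protein_wet_fraction(c)`.
#' @export
target_mg_per_g_wet <- function(c) {
  c$target_mg_per_g_protein * protein_wet_fraction(c)
}

#' Molar target concentration of a compartment
#'
#' Converts the target content per g wet tissue into mol/L using the tissue
#' density: mg/g wet times density (g/mL) is mg/mL, numerically equal to
#' g/L, which divided by the molecular weight (g/mol) gives mol/L.
#'
#' @param c a [tissue_composition()].
#' @return molar concentration in mol/L.
#' @export
molar_target_concentration <- function(c) {
  # mg/g wet * g/mL = mg/mL = g/L; divide by MW (g/mol) for mol/L
  target_mg_per_g_wet(c) * c$tissue_density / c$target_mw
}

#' Reduce a target concentration by a demyelination factor
#'
#' Lesion scenarios are expressed as fold reductions of a base (white-matter
#' or lesion) MBP concentration, e.g. 10- or 100-fold demyelination.
#'
#' @param base base molar concentration (mol/L), must be >= 0.
#' @param fold_reduction fold reduction, must be >= 1.
#' @return `base / fold_reduction`.
#' @export
scaled_lesion_concentration <- function(base, fold_reduction) {
  stopifnot(is.numeric(base), all(base >= 0))
  if (any(!is.finite(fold_reduction)) || any(fold_reduction < 1))
    stop("fold_reduction must be >= 1")
  base / fold_reduction
}

#' Read compartment compositions from a YAML file
#'
#' The file holds one entry per compartment with the fields of
#' [tissue_composition()] (snake_case), plus an optional top-level
#' `mass_fraction` map. See
#' `system.file("extdata", "brain_composition.yaml", package = "myelinpet")`
#' for the default brain definition.
#'
#' @param path YAML file path.
#' @return named list of `tissue_composition` objects with a
#'   `mass_fraction` attribute when present in the file.
#' @export
read_compositions <- function(path) {
  cfg <- yaml::read_yaml(path)
  mf <- cfg$mass_fraction
  cfg$mass_fraction <- NULL
  comps <- lapply(names(cfg), function(nm) {
    x <- cfg[[nm]]
    tissue_composition(
      name = nm, water_fraction = x$water_fraction,
      protein_dry_fraction = x$protein_dry_fraction,
      target_mg_per_g_protein = x$target_mg_per_g_protein,
      tissue_density = if (is.null(x$tissue_density)) 1 else
        x$tissue_density,
      target_mw = if (is.null(x$target_mw)) 18500 else x$target_mw)
  })
  names(comps) <- names(cfg)
  if (!is.null(mf)) attr(comps, "mass_fraction") <- unlist(mf)
  comps
}

#' Derived composition table for a set of compartments
#'
#' Mirrors the layout of the published composition table: inputs (water %,
#' protein % dry weight, MBP mg/g protein) followed by the derived rows
#' (protein % wet weight, MBP mg/g wet weight, molar MBP concentration).
#'
#' @param comps list of `tissue_composition` objects (default
#'   [brain_compositions()]).
#' @return data.frame with one column per compartment and one row per
#'   quantity.
#' @export
composition_table <- function(comps = brain_compositions()) {
  cols <- lapply(comps, function(c) {
    c(water_pct = 100 * c$water_fraction,
      protein_pct_dry = 100 * c$protein_dry_fraction,
      protein_pct_wet = 100 * protein_wet_fraction(c),
      target_mg_per_g_protein = c$target_mg_per_g_protein,
      target_mg_per_g_wet = target_mg_per_g_wet(c),
      target_molar = molar_target_concentration(c))
  })
  out <- as.data.frame(cols)
  names(out) <- vapply(comps, `[[`, "", "name")
  cbind(quantity = rownames(out), out, row.names = NULL)
}
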