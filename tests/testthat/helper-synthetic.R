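# Shared fixtures, all built in code.

# A deterministic noise-free curve from known parameters.
toy_curve <- function(vcmax25 = 60, jmax25 = 110, rd25 = 1.2,
                      tp25 = NA_real_, tleaf = 31, noise_sd = 0,
                      seed = 101) {
  gen_aci_curve(vcmax25, jmax25, rd25, tp25 = tp25, tleaf = tleaf,
                noise_sd = noise_sd, seed = seed)
}

# Export-limb parameter that caps the gross plateau at `frac` of the
# leaf's attainable maximum (a genuinely binding plateau).
binding_tp <- function(vcmax25, jmax25, rd25, frac = 0.6, tleaf = 31) {
  fw <- fvcb_forward(0.8 * aci_co2_sequence(), tleaf, 1800,
                     vcmax25 = vcmax25, jmax25 = jmax25, rd25 = rd25)
  frac * max(pmin(fw$ac, fw$aj)) / (3 * temp_scaler("tp", tleaf))
}

# A small trait table reused by several files.
small_traits <- function(seed = 11, n_species = 30) {
  gen_traits(trait_gen_config(n_species = n_species,
                              leaves_per_species = c(3L, 6L)),
             seed = seed)
}

# Per-leaf dataset expanded from the packaged species-composition counts,
# with a dummy trait so every leaf is split-eligible.
composition_leaves <- function() {
  comp <- readr::read_csv(
    system.file("extdata", "species_composition.csv",
                package = "spectraphys"),
    show_col_types = FALSE)
  long <- tidyr::pivot_longer(comp, cols = -1, names_to = "campaign",
                              values_to = "n")
  long <- long[!is.na(long$n), ]
  leaves <- tidyr::uncount(long, weights = long$n)
  leaves$leaf_id <- sprintf("leaf_%03d", seq_len(nrow(leaves)))
  leaves$site <- ifelse(leaves$campaign == "Brazil_2012_2013",
                        "Brazil_Tapajos", "Panama_SanLorenzo")
  leaves$trait <- 1
  leaves[, c("leaf_id", "species", "campaign", "site", "trait")]
}
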