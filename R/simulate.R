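#' Configuration for the synthetic trait generator
#'
#' Defaults emulate the joint structure of photosynthetic traits in a
#' diverse tropical canopy dataset: log-normal marginals with medians near
#' 40 / 75 / 5.5 / 0.65 umol m-2 s-1 for Vcmax25 / Jmax25 / Tp25 /
#' Rdark25, a strong Vcmax-Jmax correlation (0.9 on the log scale) and
#' weaker correlations with Tp and Rdark, a species-level/leaf-level
#' variance split, a low-mean "Brazil-like" site with no dark-respiration
#' measurements and almost no export-limited curves, and a 68% missing
#' fraction for Tp25 (only about a third of curves show an export
#' limitation).
#'
#' @param n_species Number of species.
#' @param leaves_per_species Integer range (min, max) of leaves per species.
#' @param meanlog,sdlog Named length-4 vectors of log-scale means and sds
#'   for `vcmax25`, `jmax25`, `tp25`, `rdark25`.
#' @param correlation 4x4 log-scale correlation matrix (must be positive
#'   definite).
#' @param species_variance_frac Share of total log-scale variance at the
#'   species level (the rest is leaf-level).
#' @param site_probs Named probabilities of assigning a species to each
#'   site; names starting with `"Brazil"` get the low-trait shift.
#' @param brazil_shift Log-scale mean shift applied to Brazil species.
#' @param tp_missing_frac Fraction of non-Brazil leaves whose Tp25 is
#'   masked (no export limitation evident).
#' @return A list of class `trait_gen_config`.
#' @export
trait_gen_config <- function(
    n_species = 40,
    leaves_per_species = c(1L, 12L),
    meanlog = c(vcmax25 = log(40), jmax25 = log(75),
                tp25 = log(5.5), rdark25 = log(0.65)),
    sdlog = c(vcmax25 = 0.55, jmax25 = 0.5, tp25 = 0.45, rdark25 = 0.55),
    correlation = matrix(c(1.00, 0.90, 0.80, 0.60,
                           0.90, 1.00, 0.75, 0.55,
                           0.80, 0.75, 1.00, 0.50,
                           0.60, 0.55, 0.50, 1.00), 4, 4),
    species_variance_frac = 0.6,
    site_probs = c(Panama_SanLorenzo = 0.6, Panama_PNM = 0.2,
                   Brazil_Tapajos = 0.2),
    brazil_shift = -0.45,
    tp_missing_frac = 0.68) {
  traits <- c("vcmax25", "jmax25", "tp25", "rdark25")
  stopifnot(identical(names(meanlog), traits),
            identical(names(sdlog), traits),
            all(dim(correlation) == c(4, 4)),
            species_variance_frac >= 0, species_variance_frac <= 1)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) stop("correlation matrix is not positive definite",
                             call. = FALSE)
  structure(
    list(n_species = n_species, leaves_per_species = leaves_per_species,
         meanlog = meanlog, sdlog = sdlog, correlation = correlation,
         species_variance_frac = species_variance_frac,
         site_probs = site_probs, brazil_shift = brazil_shift,
         tp_missing_frac = tp_missing_frac),
    class = "trait_gen_config"
  )
}

#' Generate a hierarchical multi-species trait table
#'
#' Species mean log-traits are drawn from a multivariate normal carrying
#' the configured share of the total variance; leaf values are drawn
#' around their species mean with the remainder. Brazil-like species get a
#' downward mean shift and no Rdark25 (their curves also almost never show
#' an export limitation); Tp25 is masked for the configured fraction of
#' the remaining leaves. Latent (unmasked) values are kept in
#' `tp25_latent` / `rdark25_latent` so the spectra generator can couple
#' reflectance to the full trait vector.
#'
#' @param config A [trait_gen_config()].
#' @param seed Integer seed.
#' @return A tibble: `leaf_id`, `species`, `site`, `campaign`,
#'   `canopy_height_class`, `leaf_age_class`, `vcmax25`, `jmax25`, `tp25`,
#'   `rdark25`, `tp25_latent`, `rdark25_latent`.
#' @export
gen_traits <- function(config = trait_gen_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  sigma_full <- diag(cfg$sdlog) %*% cfg$correlation %*% diag(cfg$sdlog)
  sigma_sp <- cfg$species_variance_frac * sigma_full
  sigma_leaf <- (1 - cfg$species_variance_frac) * sigma_full

  sites <- sample(names(cfg$site_probs), cfg$n_species, replace = TRUE,
                  prob = cfg$site_probs)
  rows <- vector("list", cfg$n_species)
  for (s in seq_len(cfg$n_species)) {
    mu <- cfg$meanlog
    is_brazil <- grepl("^Brazil", sites[s])
    if (is_brazil) mu <- mu + cfg$brazil_shift
    sp_mean <- MASS::mvrnorm(1, mu, sigma_sp)
    n_leaf <- sample(seq(cfg$leaves_per_species[1],
                         cfg$leaves_per_species[2]), 1)
    leaf_log <- MASS::mvrnorm(n_leaf, sp_mean, sigma_leaf)
    leaf_log <- matrix(leaf_log, nrow = n_leaf)
    vals <- exp(leaf_log)
    campaign <- if (is_brazil) {
      "2012_2013"
    } else if (sites[s] == "Panama_PNM") {
      "2016_2017"
    } else {
      # San Lorenzo species: most are newly sampled in the latest campaign
      sample(c("2020", "2016_2017", "both"), 1, prob = c(0.6, 0.2, 0.2))
    }
    camp_leaf <- if (identical(campaign, "both")) {
      sample(c("2016_2017", "2020"), n_leaf, replace = TRUE)
    } else rep(campaign, n_leaf)
    rows[[s]] <- tibble::tibble(
      species = sprintf("species_%02d", s),
      site = sites[s],
      campaign = camp_leaf,
      canopy_height_class = sample(1:5, n_leaf, replace = TRUE),
      leaf_age_class = sample(c("young", "mature", "old"), n_leaf,
                              replace = TRUE),
      vcmax25 = vals[, 1], jmax25 = vals[, 2],
      tp25_latent = vals[, 3], rdark25_latent = vals[, 4]
    )
  }
  out <- dplyr::bind_rows(rows)
  out$leaf_id <- sprintf("leaf_%03d", seq_len(nrow(out)))

  is_brazil <- grepl("^Brazil", out$site)
  tp_present <- ifelse(is_brazil,
                       stats::runif(nrow(out)) < 0.02,
                       stats::runif(nrow(out)) >= cfg$tp_missing_frac)
  out$tp25 <- ifelse(tp_present, out$tp25_latent, NA_real_)
  out$rdark25 <- ifelse(is_brazil, NA_real_, out$rdark25_latent)
  dplyr::select(out, "leaf_id", "species", "site", "campaign",
                "canopy_height_class", "leaf_age_class",
                "vcmax25", "jmax25", "tp25", "rdark25",
                "tp25_latent", "rdark25_latent")
}

#' Default chamber CO2 setpoint sequence
#'
#' The 15-step sequence used for the A-Ci protocol: down from ambient,
#' back to ambient, then up to 1800 umol mol-1.
#'
#' @return Integer vector of 15 CO2 setpoints (umol mol-1).
#' @export
aci_co2_sequence <- function() {
  c(400, 300, 225, 150, 100, 75, 50, 400, 475, 575, 675, 800, 1000, 1400, 1800)
}

#' Simulate one A-Ci curve from a leaf's traits
#'
#' Chamber CO2 follows the measurement sequence; intercellular CO2 is a
#' fixed stomatal drawdown fraction of the setpoint (the pipeline needs
#' realistic Ci ranges, not stomatal realism); leaf temperature is one of
#' 30, 31 or 32 C; assimilation is the forward FvCB prediction plus iid
#' Gaussian noise.
#'
#' @param vcmax25,jmax25,rd25 Leaf parameters at 25 C (umol m-2 s-1).
#' @param tp25 Export-limb parameter, `NA` for none.
#' @param leaf_id Identifier carried into the output.
#' @param co2_sequence Chamber CO2 setpoints (umol mol-1).
#' @param tleaf Leaf temperature; default drawn from {30, 31, 32} C.
#' @param q Irradiance (umol m-2 s-1), saturating by default.
#' @param noise_sd Gaussian noise sd on A (umol m-2 s-1).
#' @param drawdown Ci/chamber-CO2 ratio.
#' @param seed Integer seed.
#' @param constants An `fvcb_constants` object.
#' @return A gas-exchange tibble: `leaf_id`, `a`, `ci`, `tleaf`, `q`.
#' @export
gen_aci_curve <- function(vcmax25, jmax25, rd25, tp25 = NA_real_,
                          leaf_id = "leaf_1",
                          co2_sequence = aci_co2_sequence(),
                          tleaf = NULL, q = 1800, noise_sd = 0.5,
                          drawdown = 0.8, seed = 1,
                          constants = fvcb_constants()) {
  if (any(!is.finite(c(vcmax25, jmax25, rd25)))) {
    stop("leaf is missing traits needed to simulate a curve", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(tleaf)) tleaf <- sample(c(30, 31, 32), 1)
  ci <- drawdown * co2_sequence
  mu <- fvcb_forward(ci, tleaf, q, vcmax25 = vcmax25, jmax25 = jmax25,
                     rd25 = rd25, tp25 = tp25, constants = constants)$a_net
  tibble::tibble(
    leaf_id = leaf_id,
    a = mu + stats::rnorm(length(ci), 0, noise_sd),
    ci = ci, tleaf = tleaf, q = q
  )
}

#' Simulate a dark-respiration efflux time series
#'
#' One reading per second for a minute, centred on the leaf's respiration
#' at measurement temperature (its 25 C value times the Arrhenius scaler)
#' with instrument noise.
#'
#' @param rdark25 Dark respiration at 25 C (umol m-2 s-1).
#' @param tleaf Measurement temperature (degrees C).
#' @param n_samples Number of 1 Hz readings.
#' @param noise_sd Instrument noise sd (umol m-2 s-1).
#' @param leaf_id Identifier.
#' @param seed Integer seed.
#' @param constants An `fvcb_constants` object.
#' @return A tibble `leaf_id`, `time_s`, `efflux`, `tleaf`.
#' @export
gen_rdark_series <- function(rdark25, tleaf = 30, n_samples = 60,
                             noise_sd = 0.05, leaf_id = "leaf_1", seed = 1,
                             constants = fvcb_constants()) {
  set.seed(seed)
  mu <- rdark25 * temp_scaler("rdark", tleaf, constants)
  tibble::tibble(
    leaf_id = leaf_id,
    time_s = seq_len(n_samples),
    efflux = mu + stats::rnorm(n_samples, 0, noise_sd),
    tleaf = tleaf
  )
}

#' Configuration for the synthetic reflectance generator
#'
#' Spectra are a smooth vegetation-like baseline minus Gaussian absorption
#' features whose depths are linear in the standardized log traits (so a
#' linear method can recover them), plus smooth correlated noise and white
#' noise. Default feature centers sit in the visible (680 nm), the two
#' water-absorption regions (1450, 1940 nm) and the SWIR (2100 nm).
#'
#' @param grid_start,grid_end,step Wavelength grid in nm.
#' @param centers,widths Feature centers and Gaussian widths (nm).
#' @param base_depth Trait-independent depth per feature.
#' @param loadings Feature x trait matrix of depth loadings per standard
#'   deviation of each log trait (`vcmax25`, `jmax25`, `tp25`, `rdark25`).
#' @param smooth_noise_sd,smooth_length Correlated-noise amplitude and
#'   Gaussian kernel length-scale (nm).
#' @param white_noise_sd Per-wavelength white-noise sd.
#' @return A list of class `spectra_gen_config`.
#' @export
spectra_gen_config <- function(
    grid_start = 500, grid_end = 2400, step = 1,
    centers = c(680, 1450, 1940, 2100),
    widths = c(45, 60, 70, 60),
    base_depth = c(0.035, 0.04, 0.03, 0.03),
    loadings = rbind(
      c(0.030, 0.012, 0.000, 0.004),
      c(0.008, 0.022, 0.010, 0.000),
      c(0.010, 0.000, 0.006, 0.020),
      c(0.014, -0.008, 0.016, 0.006)
    ),
    smooth_noise_sd = 0.006, smooth_length = 50,
    white_noise_sd = 0.004) {
  grid <- seq(grid_start, grid_end, by = step)
  stopifnot(all(centers >= grid_start & centers <= grid_end),
            length(widths) == length(centers),
            length(base_depth) == length(centers),
            nrow(loadings) == length(centers), ncol(loadings) == 4)
  structure(
    list(grid = grid, centers = centers, widths = widths,
         base_depth = base_depth, loadings = loadings,
         smooth_noise_sd = smooth_noise_sd, smooth_length = smooth_length,
         white_noise_sd = white_noise_sd),
    class = "spectra_gen_config"
  )
}

# Smooth vegetation-like baseline reflectance over the grid (green peak,
# red absorption, NIR plateau, water dips, SWIR decline).
baseline_reflectance <- function(grid) {
  anchors_wl <- c(500, 550, 620, 680, 710, 760, 900, 1100, 1300, 1450,
                  1650, 1850, 1940, 2050, 2200, 2400)
  anchors_r <- c(0.07, 0.13, 0.09, 0.06, 0.18, 0.44, 0.46, 0.45, 0.40,
                 0.28, 0.34, 0.25, 0.17, 0.24, 0.22, 0.11)
  stats::spline(anchors_wl, anchors_r, xout = grid, method = "natural")$y
}

#' Generate reflectance spectra coupled to a trait table
#'
#' @param traits A trait table from [gen_traits()] (uses the latent
#'   columns when present so masked traits still shape the spectrum).
#' @param config A [spectra_gen_config()].
#' @param seed Integer seed.
#' @param n_replicates Replicate scans per leaf (replicates differ by
#'   white noise only, mimicking re-clipping the same leaf).
#' @return A long tibble `leaf_id`, `replicate`, `wavelength`,
#'   `reflectance` (values clipped to [0, 1]).
#' @export
gen_spectra <- function(traits, config = spectra_gen_config(), seed = 1,
                        n_replicates = 1) {
  set.seed(seed)
  cfg <- config
  grid <- cfg$grid
  n <- nrow(traits)

  lat <- cbind(
    vcmax25 = traits$vcmax25,
    jmax25 = traits$jmax25,
    tp25 = if ("tp25_latent" %in% names(traits)) traits$tp25_latent
           else traits$tp25,
    rdark25 = if ("rdark25_latent" %in% names(traits)) traits$rdark25_latent
              else traits$rdark25
  )
  z <- scale(log(lat))
  z[!is.finite(z)] <- 0

  gauss <- vapply(seq_along(cfg$centers), function(k) {
    exp(-0.5 * ((grid - cfg$centers[k]) / cfg$widths[k])^2)
  }, numeric(length(grid))) # grid x features
  depths <- matrix(cfg$base_depth, n, length(cfg$centers), byrow = TRUE) +
    z %*% t(cfg$loadings) # leaves x features
  base <- baseline_reflectance(grid)

  refl_clean <- matrix(base, n, length(grid), byrow = TRUE) -
    depths %*% t(gauss)

  # correlated noise: white noise convolved with a Gaussian kernel
  kern_half <- ceiling(3 * cfg$smooth_length / (grid[2] - grid[1]))
  kern <- stats::dnorm(seq(-kern_half, kern_half),
                       sd = cfg$smooth_length / (grid[2] - grid[1]))
  kern <- kern / sqrt(sum(kern^2)) # preserve noise sd
  smooth_noise <- t(vapply(seq_len(n), function(i) {
    e <- stats::rnorm(length(grid) + 2 * kern_half, 0, cfg$smooth_noise_sd)
    stats::convolve(e, kern, type = "filter")
  }, numeric(length(grid))))
  refl_leaf <- refl_clean + smooth_noise

  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    refl <- refl_leaf +
      matrix(stats::rnorm(n * length(grid), 0, cfg$white_noise_sd),
             n, length(grid))
    refl <- pmin(pmax(refl, 0), 1)
    out[[r]] <- tibble::tibble(
      leaf_id = rep(traits$leaf_id, each = length(grid)),
      replicate = r,
      wavelength = rep(grid, n),
      reflectance = as.vector(t(refl))
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$leaf_id, .data$replicate,
                 .data$wavelength)
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes every CSV interface the pipeline ingests: per-observation
#' gas-exchange curves, 1 Hz dark-respiration series, wide replicate
#' spectra, leaf metadata, the true trait table, and a species-by-campaign
#' composition report. Byte-identical given the seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param trait_config A [trait_gen_config()].
#' @param spectra_config A [spectra_gen_config()].
#' @param seed Integer master seed.
#' @param aci_noise_sd Gaussian noise sd on assimilation (umol m-2 s-1).
#' @param rdark_noise_sd Instrument noise sd on the efflux series.
#' @param n_replicates Replicate spectra per leaf.
#' @return Invisibly, a list with the file paths and the in-memory
#'   `traits` table.
#' @export
gen_dataset <- function(out_dir, trait_config = trait_gen_config(),
                        spectra_config = spectra_gen_config(), seed = 1,
                        aci_noise_sd = 0.5, rdark_noise_sd = 0.05,
                        n_replicates = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 4)
  traits <- gen_traits(trait_config, seed = seeds[1])
  n <- nrow(traits)

  curve_seeds <- derive_seeds(seeds[2], n)
  gas <- purrr::map_dfr(seq_len(n), function(i) {
    gen_aci_curve(traits$vcmax25[i], traits$jmax25[i],
                  rd25 = traits$rdark25_latent[i], tp25 = traits$tp25[i],
                  leaf_id = traits$leaf_id[i], noise_sd = aci_noise_sd,
                  seed = curve_seeds[i])
  })
  rdark_seeds <- derive_seeds(seeds[3], n)
  has_rdark <- !is.na(traits$rdark25)
  rdark <- purrr::map_dfr(which(has_rdark), function(i) {
    gen_rdark_series(traits$rdark25[i], tleaf = gas$tleaf[match(
      traits$leaf_id[i], gas$leaf_id)], noise_sd = rdark_noise_sd,
      leaf_id = traits$leaf_id[i], seed = rdark_seeds[i])
  })
  spectra <- gen_spectra(traits, spectra_config, seed = seeds[4],
                         n_replicates = n_replicates)

  meta <- dplyr::select(traits, "leaf_id", "species", "site", "campaign",
                        "canopy_height_class", "leaf_age_class")
  comp <- dplyr::count(meta, .data$species, .data$campaign, name = "n_leaves")

  paths <- list(
    gas_exchange = file.path(out_dir, "gas_exchange.csv"),
    dark_respiration = file.path(out_dir, "dark_respiration.csv"),
    spectra = file.path(out_dir, "spectra.csv"),
    metadata = file.path(out_dir, "metadata.csv"),
    traits = file.path(out_dir, "traits_true.csv"),
    composition = file.path(out_dir, "species_composition.csv")
  )
  readr::write_csv(
    dplyr::rename(gas, A = "a", Ci = "ci", Tleaf = "tleaf", Qin = "q"),
    paths$gas_exchange, progress = FALSE)
  readr::write_csv(rdark, paths$dark_respiration, progress = FALSE)
  write_spectra(spectra, paths$spectra)
  readr::write_csv(meta, paths$metadata, progress = FALSE)
  readr::write_csv(
    dplyr::select(traits, -"tp25_latent", -"rdark25_latent"),
    paths$traits, progress = FALSE)
  readr::write_csv(comp, paths$composition, progress = FALSE)
  invisible(c(paths, list(traits = traits)))
}
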