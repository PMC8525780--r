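#' Load FvCB temperature-response and kinetic constants
#'
#' Reads the constants file that parameterizes the temperature normalization
#' (activation energy `ha`, deactivation energy `hd` and entropy term `ds`
#' per parameter kind) and the Rubisco kinetics at 25 degrees C (`kc25`,
#' `ko25`, `gammastar25`, chamber oxygen). The packaged defaults are the
#' in-vivo tobacco kinetics of Bernacchi and colleagues (expressed as mole
#' fractions) together with widely used peaked-Arrhenius parameters for
#' Vcmax, Jmax and Tp; they are configuration, not hard-coded science, and a
#' user file with the same YAML layout can be substituted.
#'
#' @param path Path to a YAML constants file. `NULL` (default) loads the file
#'   shipped with the package.
#' @return A list of class `fvcb_constants` with elements `tref_c`,
#'   `gas_constant`, `kinetics` (named numeric vector) and
#'   `temperature_response` (named list of `ha`/`hd`/`ds` lists).
#' @examples
#' cst <- fvcb_constants()
#' cst$kinetics[["kc25"]]
#' @export
fvcb_constants <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.spectraphys_env$constants)) {
      return(.spectraphys_env$constants)
    }
    path <- system.file("extdata", "photosynthesis_constants.yml",
                        package = "spectraphys", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  cst <- structure(
    list(
      tref_c = as.numeric(raw$reference$tref_c),
      gas_constant = as.numeric(raw$reference$gas_constant),
      kinetics = vapply(raw$kinetics, as.numeric, numeric(1)),
      temperature_response = raw$temperature_response
    ),
    class = "fvcb_constants"
  )
  validate_fvcb_constants(cst)
  if (is.null(.spectraphys_env$constants) &&
      identical(path, system.file("extdata", "photosynthesis_constants.yml",
                                  package = "spectraphys"))) {
    .spectraphys_env$constants <- cst
  }
  cst
}

.spectraphys_env <- new.env(parent = emptyenv())

validate_fvcb_constants <- function(cst) {
  kin <- cst$kinetics
  needed <- c("kc25", "ko25", "gammastar25", "oxygen")
  if (!all(needed %in% names(kin))) {
    stop("constants file is missing kinetic entries: ",
         paste(setdiff(needed, names(kin)), collapse = ", "), call. = FALSE)
  }
  if (any(kin[needed] <= 0)) {
    stop("kinetic constants must be strictly positive", call. = FALSE)
  }
  if (kin[["gammastar25"]] >= kin[["kc25"]]) {
    stop("gammastar25 must be smaller than kc25", call. = FALSE)
  }
  for (kind in names(cst$temperature_response)) {
    tr <- cst$temperature_response[[kind]]
    if (is.null(tr$ha) || tr$ha <= 0) {
      stop("temperature response for '", kind, "' needs ha > 0", call. = FALSE)
    }
    if (!is.null(tr$hd)) {
      if (is.null(tr$ds)) {
        stop("peaked form for '", kind, "' needs both hd and ds", call. = FALSE)
      }
      if (tr$hd <= tr$ha) {
        stop("peaked form for '", kind, "' needs hd > ha", call. = FALSE)
      }
    }
  }
  invisible(cst)
}

#' Temperature scaling factor for a photosynthetic parameter
#'
#' Computes the dimensionless factor `f` such that a parameter value at leaf
#' temperature equals its 25 C value times `f`, using the modified (peaked)
#' Arrhenius function when deactivation energy `hd` and entropy `ds` are
#' present for that parameter kind, and the pure Arrhenius function
#' otherwise. The factor is exactly 1 at the reference temperature.
#'
#' @param param_kind One of the parameter tags in the constants file
#'   (`"vcmax"`, `"jmax"`, `"tp"`, `"rdark"`, `"kc"`, `"ko"`, `"gammastar"`).
#' @param tleaf Leaf temperature(s) in degrees C; must be finite and within
#'   0-50 C.
#' @param constants An `fvcb_constants` object.
#' @return Numeric vector of scaling factors, same length as `tleaf`.
#' @examples
#' temp_scaler("vcmax", 25) # exactly 1
#' temp_scaler("vcmax", 30) # > 1 below the thermal optimum
#' @export
temp_scaler <- function(param_kind, tleaf, constants = fvcb_constants()) {
  stopifnot(is.character(param_kind), length(param_kind) == 1L)
  tr <- constants$temperature_response[[tolower(param_kind)]]
  if (is.null(tr)) {
    stop("unknown parameter kind '", param_kind, "'; known kinds: ",
         paste(names(constants$temperature_response), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(tleaf))) stop("tleaf must be finite", call. = FALSE)
  if (any(tleaf < 0 | tleaf > 50)) {
    stop("tleaf outside the plausible 0-50 C range", call. = FALSE)
  }
  arrhenius_factor(tleaf, ha = tr$ha, hd = tr$hd, ds = tr$ds,
                   tref_c = constants$tref_c, r = constants$gas_constant)
}

# Peaked (modified) Arrhenius scaler; reduces to pure Arrhenius when hd is
# NULL. Normalized so f(tref) == 1 to machine precision.
arrhenius_factor <- function(tleaf, ha, hd = NULL, ds = NULL,
                             tref_c = 25, r = 8.314) {
  tk <- tleaf + 273.15
  tref <- tref_c + 273.15
  f <- exp(ha * (tk - tref) / (tref * r * tk))
  if (!is.null(hd) && !is.null(ds)) {
    f <- f * (1 + exp((tref * ds - hd) / (tref * r))) /
      (1 + exp((tk * ds - hd) / (tk * r)))
  }
  f
}

#' Rubisco kinetics at leaf temperature
#'
#' Scales the Michaelis constants for CO2 and O2 and the CO2 compensation
#' point from 25 C to leaf temperature, each with its own Arrhenius
#' activation energy.
#'
#' @inheritParams temp_scaler
#' @return A tibble with columns `tleaf`, `kc` (umol mol-1), `ko`
#'   (mmol mol-1), `gammastar` (umol mol-1).
#' @examples
#' kinetics_at_t(c(25, 30))
#' @export
kinetics_at_t <- function(tleaf, constants = fvcb_constants()) {
  kin <- constants$kinetics
  tibble::tibble(
    tleaf = tleaf,
    kc = kin[["kc25"]] * temp_scaler("kc", tleaf, constants),
    ko = kin[["ko25"]] * temp_scaler("ko", tleaf, constants),
    gammastar = kin[["gammastar25"]] * temp_scaler("gammastar", tleaf, constants)
  )
}
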