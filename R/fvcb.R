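#' Electron transport rate at a given irradiance
#'
#' Solves the non-rectangular hyperbola
#' \eqn{\theta J^2 - (\alpha Q + J_{max}) J + \alpha Q J_{max} = 0}
#' for its smaller root, the standard light response of whole-chain electron
#' transport. `J` saturates at `jmax` for large `Q` and rises with initial
#' slope `alpha`.
#'
#' @param q Incident photosynthetically active irradiance
#'   (umol photons m-2 s-1), `>= 0`. `NA` is treated as saturating light
#'   (`J = jmax`), matching protocols that measure A-Ci curves at per-leaf
#'   saturating irradiance.
#' @param jmax Maximum electron transport rate (umol m-2 s-1) at the same
#'   temperature as the requested `J`.
#' @param theta Curvature of the light response, in (0, 1).
#' @param alpha Apparent quantum yield (mol electrons per mol photons).
#' @return Electron transport rate(s) `J` (umol m-2 s-1).
#' @examples
#' electron_transport_rate(1800, jmax = 100)
#' @export
electron_transport_rate <- function(q, jmax, theta = 0.7, alpha = 0.425) {
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)", call. = FALSE)
  if (any(q < 0, na.rm = TRUE)) stop("irradiance q must be >= 0", call. = FALSE)
  iq <- alpha * q
  disc <- (iq + jmax)^2 - 4 * theta * iq * jmax
  j <- (iq + jmax - sqrt(pmax(disc, 0))) / (2 * theta)
  ifelse(is.na(q), jmax, j)
}

#' Forward FvCB model of net CO2 assimilation
#'
#' Net assimilation is the minimum of three potentially limiting gross
#' rates minus respiration in the light, all evaluated at leaf temperature:
#' \itemize{
#'   \item Rubisco-limited: \eqn{A_c = V_{cmax}(C_i - \Gamma^*)/(C_i + K_c(1 + O/K_o))}
#'   \item electron-transport-limited: \eqn{A_j = J(C_i - \Gamma^*)/(4C_i + 8\Gamma^*)}
#'   \item triose-phosphate-export-limited: \eqn{A_p = 3 T_p}
#' }
#' Parameters are supplied at 25 C and scaled to each observation's leaf
#' temperature with [temp_scaler()]; kinetics come from [kinetics_at_t()].
#' When `tp25` is `NA` the export limb is disabled (equivalent to
#' `tp25 = Inf`). Mesophyll conductance is assumed infinite, so parameters
#' are apparent.
#'
#' @param ci Intercellular CO2 mole fraction (umol mol-1), `>= 0`. Vectorized.
#' @param tleaf Leaf temperature (degrees C); scalar or same length as `ci`.
#' @param q Irradiance (umol m-2 s-1); scalar, same length as `ci`, or `NA`
#'   for saturating light.
#' @param vcmax25,jmax25,rd25 FvCB parameters at 25 C (umol m-2 s-1).
#' @param tp25 Triose phosphate utilization rate at 25 C, or `NA` to disable
#'   the export limb.
#' @param theta,alpha Light-response curvature and apparent quantum yield
#'   passed to [electron_transport_rate()].
#' @param constants An `fvcb_constants` object.
#' @return A tibble with one row per observation: `ci`, `tleaf`, `q`,
#'   the three gross limbs `ac`, `aj`, `ap`, the net rate `a_net`
#'   (umol m-2 s-1) and the limitation `state` (`"Ac"`, `"Aj"` or `"Ap"`,
#'   the argmin of the gross rates).
#' @examples
#' fvcb_forward(ci = c(100, 300, 1200), tleaf = 25, vcmax25 = 50,
#'              jmax25 = 100, rd25 = 1)
#' @export
fvcb_forward <- function(ci, tleaf, q = NA_real_,
                         vcmax25, jmax25, rd25, tp25 = NA_real_,
                         theta = 0.7, alpha = 0.425,
                         constants = fvcb_constants()) {
  if (any(ci < 0)) stop("ci must be >= 0", call. = FALSE)
  pars <- c(vcmax25 = vcmax25, jmax25 = jmax25, rd25 = rd25,
            theta = theta, alpha = alpha)
  if (any(!is.finite(pars))) stop("non-finite FvCB parameters", call. = FALSE)
  n <- length(ci)
  tleaf <- rep_len(tleaf, n)
  q <- rep_len(q, n)

  kin <- kinetics_at_t(tleaf, constants)
  vcmax <- vcmax25 * temp_scaler("vcmax", tleaf, constants)
  jm <- jmax25 * temp_scaler("jmax", tleaf, constants)
  rd <- rd25 * temp_scaler("rdark", tleaf, constants)
  o <- constants$kinetics[["oxygen"]]

  ac <- vcmax * (ci - kin$gammastar) / (ci + kin$kc * (1 + o / kin$ko))
  j <- electron_transport_rate(q, jm, theta = theta, alpha = alpha)
  aj <- j * (ci - kin$gammastar) / (4 * ci + 8 * kin$gammastar)
  if (is.na(tp25)) {
    ap <- rep(Inf, n)
  } else {
    ap <- 3 * tp25 * temp_scaler("tp", tleaf, constants)
  }

  gross <- cbind(Ac = ac, Aj = aj, Ap = ap)
  idx <- max.col(-gross, ties.method = "first")
  a_gross <- gross[cbind(seq_len(n), idx)]

  tibble::tibble(
    ci = ci, tleaf = tleaf, q = q,
    ac = ac, aj = aj, ap = ap,
    a_net = a_gross - rd,
    state = colnames(gross)[idx]
  )
}
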