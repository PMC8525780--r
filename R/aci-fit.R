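#' Standardize a gas-exchange curve table
#'
#' Accepts the instrument-style column names (`A`, `Ci`, `Tleaf`, `Qin`) or
#' lower-case equivalents and returns a validated tibble with columns
#' `leaf_id`, `a`, `ci`, `tleaf`, `q`. Fitting requires at least 6
#' observations spanning sub- and supra-ambient CO2.
#'
#' @param data A data frame with one row per A-Ci observation.
#' @return A tibble with standardized columns.
#' @export
as_gas_exchange <- function(data) {
  nm <- tolower(names(data))
  pick <- function(cands, required = TRUE) {
    hit <- which(nm %in% cands)
    if (length(hit) == 0L) {
      if (required) {
        stop("gas-exchange table needs a column named one of: ",
             paste(cands, collapse = ", "), call. = FALSE)
      }
      return(NULL)
    }
    data[[hit[1L]]]
  }
  out <- tibble::tibble(
    leaf_id = {
      id <- pick(c("leaf_id", "leaf", "id"), required = FALSE)
      if (is.null(id)) "leaf_1" else as.character(id)
    },
    a = as.numeric(pick(c("a", "anet", "photo"))),
    ci = as.numeric(pick(c("ci"))),
    tleaf = as.numeric(pick(c("tleaf", "tleaf_c"))),
    q = {
      qv <- pick(c("qin", "q", "par", "qabs"), required = FALSE)
      if (is.null(qv)) NA_real_ else as.numeric(qv)
    }
  )
  if (any(!is.finite(out$a)) || any(!is.finite(out$ci))) {
    stop("A and Ci must be finite", call. = FALSE)
  }
  if (any(out$ci < 0)) stop("Ci must be >= 0", call. = FALSE)
  out
}

#' Gaussian negative log-likelihood of an A-Ci curve
#'
#' The likelihood the fitter maximizes: observed net assimilation is the
#' FvCB forward prediction plus iid Gaussian noise with standard deviation
#' `sigma`.
#'
#' @param data A gas-exchange table (see [as_gas_exchange()]).
#' @param vcmax25,jmax25,rd25,tp25 FvCB parameters at 25 C; `tp25 = NA`
#'   disables the export limb.
#' @param sigma Residual standard deviation (umol m-2 s-1), `> 0`.
#' @param theta,alpha,constants Passed to [fvcb_forward()].
#' @return The scalar negative log-likelihood.
#' @export
negloglik_aci <- function(data, vcmax25, jmax25, rd25, tp25 = NA_real_,
                          sigma, theta = 0.7, alpha = 0.425,
                          constants = fvcb_constants()) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  cur <- as_gas_exchange(data)
  pred <- fvcb_forward(cur$ci, cur$tleaf, cur$q,
                       vcmax25 = vcmax25, jmax25 = jmax25, rd25 = rd25,
                       tp25 = tp25, theta = theta, alpha = alpha,
                       constants = constants)$a_net
  if (any(!is.finite(pred))) stop("non-finite model prediction", call. = FALSE)
  n <- nrow(cur)
  rss <- sum((cur$a - pred)^2)
  n / 2 * log(2 * pi * sigma^2) + rss / (2 * sigma^2)
}

# Precompute everything in the likelihood that depends only on the curve
# (temperature scalers, kinetics), so the optimizer's objective is a lean
# vectorized evaluation without per-call scaling work.
aci_precompute <- function(cur, theta, alpha, constants) {
  kin <- kinetics_at_t(cur$tleaf, constants)
  list(
    a = cur$a, ci = cur$ci, q = cur$q,
    sv = temp_scaler("vcmax", cur$tleaf, constants),
    sj = temp_scaler("jmax", cur$tleaf, constants),
    sr = temp_scaler("rdark", cur$tleaf, constants),
    st = temp_scaler("tp", cur$tleaf, constants),
    gammastar = kin$gammastar,
    km = kin$kc * (1 + constants$kinetics[["oxygen"]] / kin$ko),
    theta = theta, alpha = alpha
  )
}

# Fast residual sum of squares on a precomputed curve.
aci_rss_pre <- function(par, pre, include_tp) {
  vc <- par[[1L]] * pre$sv
  jm <- par[[2L]] * pre$sj
  rd <- par[[3L]] * pre$sr
  ac <- vc * (pre$ci - pre$gammastar) / (pre$ci + pre$km)
  iq <- pre$alpha * pre$q
  disc <- (iq + jm)^2 - 4 * pre$theta * iq * jm
  j <- ifelse(is.na(pre$q), jm,
              (iq + jm - sqrt(pmax(disc, 0))) / (2 * pre$theta))
  aj <- j * (pre$ci - pre$gammastar) / (4 * pre$ci + 8 * pre$gammastar)
  gross <- pmin(ac, aj)
  if (include_tp) gross <- pmin(gross, 3 * par[[4L]] * pre$st)
  pred <- gross - rd
  if (any(!is.finite(pred))) return(Inf)
  sum((pre$a - pred)^2)
}

# Slow-path RSS retained for the public likelihood and cross-checks.
aci_rss <- function(par, cur, include_tp, theta, alpha, constants) {
  pred <- fvcb_forward(cur$ci, cur$tleaf, cur$q,
                       vcmax25 = par[["vcmax25"]], jmax25 = par[["jmax25"]],
                       rd25 = par[["rd25"]],
                       tp25 = if (include_tp) par[["tp25"]] else NA_real_,
                       theta = theta, alpha = alpha,
                       constants = constants)$a_net
  if (any(!is.finite(pred))) return(Inf)
  sum((cur$a - pred)^2)
}

# Heuristic initial values: Vcmax from inverting the Rubisco limb at the
# lowest-Ci points, Jmax from the high-Ci plateau, Tp from plateau/3.
aci_init <- function(cur, include_tp, constants) {
  kin <- kinetics_at_t(stats::median(cur$tleaf), constants)
  km <- kin$kc * (1 + constants$kinetics[["oxygen"]] / kin$ko)
  rd0 <- 1
  low <- cur[order(cur$ci), ][seq_len(min(3L, nrow(cur))), ]
  vc <- stats::median((low$a + rd0) * (low$ci + km) /
                        pmax(low$ci - kin$gammastar, 5))
  vc <- min(max(vc, 5), 400)
  amax <- max(cur$a)
  jm <- min(max(4.5 * (amax + rd0), 10), 600)
  init <- c(vcmax25 = vc, jmax25 = jm, rd25 = rd0)
  if (include_tp) init <- c(init, tp25 = max((amax + rd0) / 3, 1))
  init
}

#' Fit the FvCB model to one A-Ci curve by maximum likelihood
#'
#' Estimates `vcmax25`, `jmax25`, `rd25` (and optionally `tp25`) at the 25 C
#' reference, using each observation's own leaf temperature for the
#' Arrhenius scaling. The Gaussian likelihood is concentrated over the
#' residual standard deviation and minimized by bounded quasi-Newton
#' optimization from multiple jittered starts; the limb limiting each
#' observation is assigned automatically by the fit, never by hand.
#' Standard errors come from the inverse observed information (Hessian) at
#' the optimum and 95% intervals are Wald intervals.
#'
#' @param data A gas-exchange table for a single leaf (>= 6 observations).
#' @param include_tp Fit the triose-phosphate-utilization limb (`tp25`)?
#' @param init Optional named vector of starting values
#'   (`vcmax25`, `jmax25`, `rd25`, and `tp25` when `include_tp`).
#' @param n_starts Number of optimization starts (first is the heuristic
#'   start, the rest are jittered around it).
#' @param seed Integer seed controlling the start jitter.
#' @param theta,alpha,constants Passed to [fvcb_forward()].
#' @return An object of class `fvcb_fit`: a list with the point estimates
#'   (`params`), `sigma`, `se`, the covariance matrix `vcov`, `logLik`,
#'   `AIC`, `n_params` (counting sigma), per-observation limitation
#'   `states`, `tp_included`, a `reliable` flag (FALSE when the Hessian is
#'   singular so Wald intervals are untrustworthy), and the standardized
#'   curve in `$data`. Use [tidy()][generics::tidy] and
#'   [glance()][generics::glance] for tabular summaries.
#' @seealso [select_tp_model()], [curve_intervals()]
#' @export
fit_aci <- function(data, include_tp = FALSE, init = NULL, n_starts = 5,
                    seed = 1, theta = 0.7, alpha = 0.425,
                    constants = fvcb_constants()) {
  cur <- as_gas_exchange(data)
  if (nrow(cur) < 6L) stop("need at least 6 observations to fit", call. = FALSE)
  if (length(unique(cur$leaf_id)) > 1L) {
    stop("fit_aci fits one leaf at a time; got multiple leaf_id values",
         call. = FALSE)
  }
  n <- nrow(cur)

  par0 <- if (is.null(init)) aci_init(cur, include_tp, constants) else {
    init[c("vcmax25", "jmax25", "rd25", if (include_tp) "tp25")]
  }
  lower <- c(vcmax25 = 1, jmax25 = 1, rd25 = 1e-3,
             if (include_tp) c(tp25 = 0.1))
  upper <- c(vcmax25 = 1000, jmax25 = 1500, rd25 = 50,
             if (include_tp) c(tp25 = 200))

  pre <- aci_precompute(cur, theta, alpha, constants)
  obj <- function(p) {
    rss <- aci_rss_pre(p, pre, include_tp)
    n / 2 * log(max(rss, 1e-12) / n)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  jitters <- matrix(stats::rnorm((n_starts - 1) * length(par0), 0, 0.25),
                    nrow = max(n_starts - 1, 0))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  starts <- list(par0)
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1L]] <- pmin(pmax(par0 * exp(jitters[i, ]), lower), upper)
    }
  }
  if (include_tp) {
    # the plateau can be explained by either limb (Aj saturation or a flat
    # Ap cap); seed both basins explicitly
    s_ap <- par0; s_ap[["jmax25"]] <- min(par0[["jmax25"]] * 2, upper[["jmax25"]])
    s_ap[["tp25"]] <- max(par0[["tp25"]] * 0.8, lower[["tp25"]])
    s_aj <- par0; s_aj[["tp25"]] <- min(par0[["tp25"]] * 4, upper[["tp25"]])
    starts <- c(starts, list(s_ap, s_aj))
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, parscale = pmax(st, 0.5))),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("FvCB fit failed to converge from any start",
                          call. = FALSE)

  # simplex polish: the min() kinks between limbs can stall L-BFGS-B short
  # of the optimum, which Nelder-Mead handles well
  polish <- tryCatch(
    stats::optim(best$par, function(p) {
      if (any(p < lower) || any(p > upper)) return(Inf)
      obj(p)
    }, method = "Nelder-Mead",
    control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL
  )
  if (!is.null(polish) && polish$value < best$value) best <- polish

  par_hat <- best$par
  names(par_hat) <- names(par0)
  rss <- aci_rss(par_hat, cur, include_tp, theta, alpha, constants)
  sigma <- sqrt(max(rss, 1e-12) / n)
  loglik <- -n / 2 * (log(2 * pi * sigma^2) + 1)
  k <- length(par_hat) + 1L # + sigma
  aic <- 2 * k - 2 * loglik

  hess <- tryCatch(
    stats::optimHess(par_hat, obj, control = list(parscale = pmax(par_hat, 0.5))),
    error = function(e) NULL
  )
  vcov <- NULL
  se <- rep(NA_real_, length(par_hat))
  reliable <- FALSE
  if (!is.null(hess)) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov)) {
      # concentrated likelihood uses sigma^2 = RSS/n, which is biased low in
      # short curves; rescale to the df-corrected residual variance so Wald
      # intervals hold their nominal level
      vcov <- vcov * n / max(n - length(par_hat), 1L)
    }
    if (!is.null(vcov)) {
      dv <- diag(vcov)
      if (all(is.finite(dv)) && all(dv > 0)) {
        se <- sqrt(dv)
        reliable <- TRUE
      }
    }
  }
  names(se) <- names(par_hat)
  if (!is.null(vcov)) dimnames(vcov) <- list(names(par_hat), names(par_hat))

  pred <- fvcb_forward(cur$ci, cur$tleaf, cur$q,
                       vcmax25 = par_hat[["vcmax25"]],
                       jmax25 = par_hat[["jmax25"]],
                       rd25 = par_hat[["rd25"]],
                       tp25 = if (include_tp) par_hat[["tp25"]] else NA_real_,
                       theta = theta, alpha = alpha, constants = constants)

  structure(
    list(
      leaf_id = cur$leaf_id[1L],
      params = par_hat,
      sigma = sigma,
      se = se,
      se_sigma = sigma / sqrt(2 * n),
      vcov = vcov,
      logLik = loglik,
      AIC = aic,
      n_params = k,
      n_obs = n,
      states = pred$state,
      fitted = pred$a_net,
      tp_included = include_tp,
      convergence = best$convergence,
      reliable = reliable,
      data = cur,
      theta = theta,
      alpha = alpha,
      constants = constants
    ),
    class = "fvcb_fit"
  )
}

#' @export
print.fvcb_fit <- function(x, ...) {
  cat("FvCB fit for leaf", x$leaf_id,
      if (x$tp_included) "(with Ap limb)" else "(without Ap limb)", "\n")
  est <- format(round(x$params, 2))
  cat(paste0("  ", names(x$params), " = ", est,
             " (se ", format(round(x$se, 2)), ")", collapse = "\n"), "\n")
  cat("  sigma =", round(x$sigma, 3), " AIC =", round(x$AIC, 2),
      " n =", x$n_obs, "\n")
  if (!x$reliable) cat("  WARNING: singular Hessian; intervals unreliable\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an FvCB fit into one row per parameter
#'
#' @param x An `fvcb_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high` (95% Wald).
#' @method tidy fvcb_fit
#' @export
tidy.fvcb_fit <- function(x, ...) {
  # Wald interval with the t critical value at the residual df (short curves)
  z <- stats::qt(0.975, df = max(x$n_obs - (x$n_params - 1L), 1L))
  tibble::tibble(
    term = names(x$params),
    estimate = unname(x$params),
    std.error = unname(x$se),
    conf.low = unname(x$params - z * x$se),
    conf.high = unname(x$params + z * x$se)
  )
}

#' One-row model summary of an FvCB fit
#'
#' @param x An `fvcb_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `leaf_id`, `sigma`, `logLik`, `AIC`,
#'   `n_params`, `n_obs`, `tp_included`, `reliable`.
#' @method glance fvcb_fit
#' @export
glance.fvcb_fit <- function(x, ...) {
  tibble::tibble(
    leaf_id = x$leaf_id, sigma = x$sigma, logLik = x$logLik, AIC = x$AIC,
    n_params = x$n_params, n_obs = x$n_obs, tp_included = x$tp_included,
    reliable = x$reliable
  )
}

#' Choose between the fits with and without the export limb by AIC
#'
#' Compares the fit that includes the triose-phosphate-utilization limb
#' with the fit that omits it, on the same curve, and returns the fit with
#' the lower AIC. Ties (|dAIC| < 1e-6) resolve to the model without the
#' limb (parsimony), so a `tp25` value is only reported where the extra
#' limb genuinely improves the fit.
#'
#' @param fit_with An `fvcb_fit` with `tp_included = TRUE`.
#' @param fit_without An `fvcb_fit` with `tp_included = FALSE`.
#' @return The selected `fvcb_fit`.
#' @export
select_tp_model <- function(fit_with, fit_without) {
  stopifnot(inherits(fit_with, "fvcb_fit"), inherits(fit_without, "fvcb_fit"))
  if (!fit_with$tp_included || fit_without$tp_included) {
    stop("expected one fit with and one without the Ap limb", call. = FALSE)
  }
  same <- identical(fit_with$leaf_id, fit_without$leaf_id) &&
    nrow(fit_with$data) == nrow(fit_without$data) &&
    isTRUE(all.equal(fit_with$data$a, fit_without$data$a))
  if (!same) stop("fits come from different curves", call. = FALSE)
  if (fit_with$AIC < fit_without$AIC - 1e-6) fit_with else fit_without
}

#' Fit one curve with and without the export limb and select by AIC
#'
#' Runs [fit_aci()] for both candidate models with mutual warm starts —
#' each model is also refit from the other's optimum (the models are
#' nested, so the full model's solution is a legitimate start for the
#' restricted one and vice versa), keeping the better likelihood — then
#' applies [select_tp_model()]. This guards the AIC comparison against
#' one of the two optimizations stalling in a poor basin.
#'
#' @inheritParams fit_aci
#' @return The selected `fvcb_fit`.
#' @export
fit_aci_selected <- function(data, n_starts = 5, seed = 1, theta = 0.7,
                             alpha = 0.425, constants = fvcb_constants()) {
  f0 <- fit_aci(data, include_tp = FALSE, n_starts = n_starts, seed = seed,
                theta = theta, alpha = alpha, constants = constants)
  f1 <- fit_aci(data, include_tp = TRUE, n_starts = n_starts, seed = seed,
                theta = theta, alpha = alpha, constants = constants)
  # warm-start each model from the other's optimum
  f1b <- tryCatch(
    fit_aci(data, include_tp = TRUE,
            init = c(f0$params, tp25 = max(max(f0$fitted) / 3, 0.5)),
            n_starts = 1, seed = seed, theta = theta, alpha = alpha,
            constants = constants),
    error = function(e) NULL)
  if (!is.null(f1b) && f1b$logLik > f1$logLik) f1 <- f1b
  f0b <- tryCatch(
    fit_aci(data, include_tp = FALSE, init = f1$params[c("vcmax25", "jmax25", "rd25")],
            n_starts = 1, seed = seed, theta = theta, alpha = alpha,
            constants = constants),
    error = function(e) NULL)
  if (!is.null(f0b) && f0b$logLik > f0$logLik) f0 <- f0b
  select_tp_model(f1, f0)
}

#' Fit a whole table of A-Ci curves with AIC limb selection
#'
#' Convenience wrapper: splits a multi-leaf gas-exchange table by
#' `leaf_id`, fits each curve with and without the export limb, keeps the
#' lower-AIC model per leaf, and returns a tidy per-leaf table. Leaves
#' whose fit fails are reported with `converged = FALSE` rather than
#' dropped silently.
#'
#' @param data Gas-exchange table with a `leaf_id` column.
#' @param n_starts,seed,theta,alpha,constants Passed to [fit_aci()].
#' @return A tibble with one row per leaf: estimates and standard errors
#'   for `vcmax25`, `jmax25`, `rd25`, `tp25` (`NA` where the limb was not
#'   selected), `sigma`, `AIC`, `tp_included`, `reliable`, `converged`.
#' @export
fit_aci_curves <- function(data, n_starts = 5, seed = 1, theta = 0.7,
                           alpha = 0.425, constants = fvcb_constants()) {
  cur <- as_gas_exchange(data)
  purrr::map_dfr(split(cur, cur$leaf_id), function(one) {
    res <- tryCatch(
      fit_aci_selected(one, n_starts = n_starts, seed = seed, theta = theta,
                       alpha = alpha, constants = constants),
      error = function(e) NULL)
    if (is.null(res)) {
      return(tibble::tibble(
        leaf_id = one$leaf_id[1L], vcmax25 = NA_real_, jmax25 = NA_real_,
        rd25 = NA_real_, tp25 = NA_real_, vcmax25_se = NA_real_,
        jmax25_se = NA_real_, rd25_se = NA_real_, tp25_se = NA_real_,
        sigma = NA_real_, AIC = NA_real_, tp_included = NA,
        reliable = NA, converged = FALSE
      ))
    }
    p <- res$params
    s <- res$se
    tibble::tibble(
      leaf_id = res$leaf_id,
      vcmax25 = p[["vcmax25"]], jmax25 = p[["jmax25"]], rd25 = p[["rd25"]],
      tp25 = if (res$tp_included) p[["tp25"]] else NA_real_,
      vcmax25_se = s[["vcmax25"]], jmax25_se = s[["jmax25"]],
      rd25_se = s[["rd25"]],
      tp25_se = if (res$tp_included) s[["tp25"]] else NA_real_,
      sigma = res$sigma, AIC = res$AIC, tp_included = res$tp_included,
      reliable = res$reliable, converged = TRUE
    )
  })
}

#' Confidence and prediction bands for a fitted A-Ci curve
#'
#' Parametric bootstrap: parameter vectors are drawn from the multivariate
#' normal implied by the Wald covariance, propagated through the forward
#' model on a Ci grid for the band of the mean assimilation rate; the
#' prediction band additionally adds Gaussian residual noise with the
#' fitted sigma. Bands are percentile-based and always enclose the
#' point-estimate prediction.
#'
#' @param fit An `fvcb_fit` with a valid covariance.
#' @param ci_grid Ci values (umol mol-1) at which to evaluate the bands.
#' @param level Interval level (default 0.95).
#' @param n_draws Number of parameter draws.
#' @param seed Integer seed.
#' @return A tibble: `ci`, `estimate`, `mean_low`, `mean_high`,
#'   `pred_low`, `pred_high`.
#' @export
curve_intervals <- function(fit, ci_grid = seq(40, 1600, by = 20),
                            level = 0.95, n_draws = 1000, seed = 1) {
  stopifnot(inherits(fit, "fvcb_fit"))
  if (is.null(fit$vcov) || any(!is.finite(fit$vcov))) {
    stop("fit has no valid covariance; cannot build bands", call. = FALSE)
  }
  vc <- fit$vcov
  pd <- tryCatch({ chol(vc); TRUE }, error = function(e) FALSE)
  if (!pd) {
    warning("covariance not positive definite; using diagonal approximation")
    vc <- diag(pmax(diag(vc), 0), nrow = nrow(vc))
    dimnames(vc) <- dimnames(fit$vcov)
  }
  tl <- stats::median(fit$data$tleaf)
  qsat <- NA_real_

  forward_one <- function(p) {
    fvcb_forward(ci_grid, tl, qsat,
                 vcmax25 = p[["vcmax25"]], jmax25 = p[["jmax25"]],
                 rd25 = p[["rd25"]],
                 tp25 = if (fit$tp_included) p[["tp25"]] else NA_real_,
                 theta = fit$theta, alpha = fit$alpha,
                 constants = fit$constants)$a_net
  }
  point <- forward_one(fit$params)

  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = fit$params, Sigma = vc)
  draws <- pmax(draws, rep(c(vcmax25 = 1e-3, jmax25 = 1e-3, rd25 = 0,
                             tp25 = 1e-3)[colnames(draws)],
                           each = n_draws))
  mean_mat <- apply(draws, 1, forward_one) # grid x draws
  noise <- matrix(stats::rnorm(length(mean_mat), 0, fit$sigma),
                  nrow = nrow(mean_mat))
  pred_mat <- mean_mat + noise

  alpha2 <- (1 - level) / 2
  qs <- function(m) t(apply(m, 1, stats::quantile, probs = c(alpha2, 1 - alpha2)))
  mb <- qs(mean_mat)
  pb <- qs(pred_mat)
  tibble::tibble(
    ci = ci_grid,
    estimate = point,
    mean_low = pmin(mb[, 1], point),
    mean_high = pmax(mb[, 2], point),
    pred_low = pmin(pb[, 1], mb[, 1], point),
    pred_high = pmax(pb[, 2], mb[, 2], point)
  )
}

#' Dark respiration from a 1 Hz efflux time series
#'
#' Implements the dark-adapted protocol: CO2 efflux sampled once per second
#' for about a minute is averaged to give `rdark` at measurement
#' temperature, then normalized to 25 C by dividing by the Arrhenius
#' scaler for respiration. The standard error is the sample standard
#' deviation over sqrt(n) — an instrument-noise summary, since the samples
#' are repeated readings of one leaf.
#'
#' @param samples Numeric vector of CO2 efflux readings
#'   (umol m-2 s-1, efflux-positive sign convention); at least 30.
#' @param tleaf Leaf temperature (degrees C) during the measurement.
#' @param leaf_id Optional leaf identifier.
#' @param constants An `fvcb_constants` object.
#' @return A one-row tibble: `leaf_id`, `n`, `tleaf`, `rdark`, `se`,
#'   `rdark25`, `rdark25_se`.
#' @export
rdark_from_timeseries <- function(samples, tleaf, leaf_id = "leaf_1",
                                  constants = fvcb_constants()) {
  samples <- as.numeric(samples)
  if (length(samples) < 30L) {
    stop("need at least 30 efflux samples (got ", length(samples), ")",
         call. = FALSE)
  }
  rdark <- mean(samples)
  if (rdark < 0) {
    warning("negative mean efflux for leaf ", leaf_id,
            "; kept under the efflux-positive convention")
  }
  se <- stats::sd(samples) / sqrt(length(samples))
  sc <- temp_scaler("rdark", tleaf, constants)
  tibble::tibble(
    leaf_id = leaf_id, n = length(samples), tleaf = tleaf,
    rdark = rdark, se = se,
    rdark25 = rdark / sc, rdark25_se = se / sc
  )
}
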