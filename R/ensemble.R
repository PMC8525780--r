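# Per-iteration seeds derived from one master seed so resampling iterations
# are reproducible and order-independent.
derive_seeds <- function(seed, n) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  s
}

#' Resampled PRESS profile over component counts
#'
#' The component-selection engine of the spectra-trait workflow: the
#' training set is resampled `n_iter` times into a random 70/30 split, a
#' PLS model with `max_ncomp` components is fit on the 70% part, and the
#' prediction residual sum of squares (PRESS) of every component count
#' 1..`max_ncomp` is evaluated on the held-out 30% (internal validation).
#'
#' @param x Predictor matrix (training set).
#' @param y Response vector (already transformed if applicable).
#' @param max_ncomp Largest component count to evaluate.
#' @param n_iter Number of random subsets (1000 in the full workflow;
#'   reduce for quick checks).
#' @param train_frac Fraction of rows in each fitting subset.
#' @param seed Integer master seed; the profile is deterministic given it.
#' @return A numeric matrix `n_iter` x `max_ncomp` of PRESS values, class
#'   `press_profile`.
#' @export
press_profile <- function(x, y, max_ncomp, n_iter = 1000, train_frac = 0.7,
                          seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  n_fit <- floor(train_frac * n)
  if (n_fit >= n) stop("train_frac leaves an empty internal-validation part",
                       call. = FALSE)
  if (max_ncomp > n_fit - 2) {
    stop("max_ncomp too large for the ", n_fit, "-row fitting subset",
         call. = FALSE)
  }
  seeds <- derive_seeds(seed, n_iter)
  out <- matrix(NA_real_, n_iter, max_ncomp,
                dimnames = list(NULL, paste0("ncomp", seq_len(max_ncomp))))
  for (i in seq_len(n_iter)) {
    set.seed(seeds[i])
    idx <- sample.int(n, n_fit)
    fit <- fit_pls(x[idx, , drop = FALSE], y[idx], max_ncomp)
    hold_x <- x[-idx, , drop = FALSE]
    hold_y <- y[-idx]
    pred <- hold_x %*% fit$coef_path +
      matrix(fit$intercept_path, nrow(hold_x), max_ncomp, byrow = TRUE)
    out[i, ] <- colSums((pred - hold_y)^2)
  }
  class(out) <- c("press_profile", class(out))
  out
}

#' One-standard-error component selection from a PRESS profile
#'
#' Let m(k) be the mean PRESS over iterations and k* its argmin. The
#' selected count is the smallest k whose mean PRESS is within one standard
#' error of m(k*), the standard error being taken across iterations at k*.
#' This deliberately prefers fewer components than the raw minimum, the
#' usual guard against PLSR overfitting.
#'
#' @param press A matrix of PRESS values (iterations x component counts),
#'   e.g. from [press_profile()].
#' @param se_rule `"se"` (standard error of the mean, sd/sqrt(n_iter),
#'   default) or `"sd"` (one full standard deviation) — the guide texts are
#'   ambiguous, so both are available.
#' @return The selected component count (integer).
#' @export
select_ncomp <- function(press, se_rule = c("se", "sd")) {
  se_rule <- match.arg(se_rule)
  press <- as.matrix(press)
  if (ncol(press) < 2) stop("need at least 2 component counts", call. = FALSE)
  m <- colMeans(press)
  if (any(!is.finite(m))) stop("non-finite mean PRESS column", call. = FALSE)
  k_star <- which.min(m) # which.min takes the first (smallest k) on ties
  s <- if (nrow(press) > 1) stats::sd(press[, k_star]) else 0
  if (se_rule == "se") s <- s / sqrt(nrow(press))
  as.integer(which(m <= m[k_star] + s)[1L])
}

#' Fit an ensemble of resampled PLSR sub-models for one trait
#'
#' The prediction machinery of the spectra-trait workflow: `n_iter`
#' sub-models are each fit on a fresh random 70% subset of the training
#' data (response transformed per `transformation`), all with the same,
#' externally chosen component count. Each sub-model keeps its coefficient
#' vector, intercept, and the residual standard deviation measured on its
#' own 30% holdout; the spread across sub-models yields confidence
#' intervals and, with the residual noise added back, prediction intervals.
#'
#' @param x Training predictor matrix (leaves x wavelengths).
#' @param y Training response on the original trait scale.
#' @param ncomp Component count, chosen beforehand with [select_ncomp()]
#'   (kept fixed when the same trait is re-validated on other splits).
#' @param transformation `"sqrt"` or `"none"`; applied to `y` before
#'   fitting, inverted at prediction time.
#' @param trait Optional trait label carried in the object.
#' @param n_iter Number of sub-models (1000 in the full workflow).
#' @param train_frac Fraction of training rows per sub-model; `1.0` makes
#'   all sub-models identical (degenerate but allowed; the residual sd then
#'   comes from the training residuals).
#' @param seed Integer master seed.
#' @return An object of class `plsr_ensemble`: coefficient matrix
#'   (p x n_iter) and intercepts on the transformed scale, per-sub-model
#'   residual sds, the ensemble-mean VIP vector, wavelength grid,
#'   `ncomp`, `transformation`, `trait`, `seed`.
#' @export
fit_ensemble <- function(x, y, ncomp, transformation = c("none", "sqrt"),
                         trait = NA_character_, n_iter = 1000,
                         train_frac = 0.7, seed = 1) {
  transformation <- match.arg(transformation)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  yt <- transform_response(y, transformation)
  n_fit <- floor(train_frac * n)
  if (n_fit < ncomp + 2) stop("fitting subset too small for ncomp",
                              call. = FALSE)
  seeds <- derive_seeds(seed, n_iter)

  coefs <- matrix(NA_real_, p, n_iter)
  intercepts <- numeric(n_iter)
  resid_sd <- numeric(n_iter)
  vip_sum <- numeric(p)
  for (i in seq_len(n_iter)) {
    set.seed(seeds[i])
    idx <- if (n_fit == n) seq_len(n) else sample.int(n, n_fit)
    fit <- tryCatch(
      fit_pls(x[idx, , drop = FALSE], yt[idx], ncomp),
      error = function(e) {
        stop("sub-model ", i, " failed: ", conditionMessage(e), call. = FALSE)
      }
    )
    coefs[, i] <- fit$coef
    intercepts[i] <- fit$intercept
    hold <- if (n_fit == n) idx else setdiff(seq_len(n), idx)
    res <- yt[hold] -
      (x[hold, , drop = FALSE] %*% fit$coef + fit$intercept)
    resid_sd[i] <- sqrt(mean(res^2))
    vip_sum <- vip_sum + vip_scores(fit)
  }

  structure(
    list(
      coefficients = coefs, intercepts = intercepts, resid_sd = resid_sd,
      vip = vip_sum / n_iter,
      wavelengths = as.numeric(colnames(x)),
      ncomp = as.integer(ncomp), transformation = transformation,
      trait = trait, n_iter = as.integer(n_iter),
      train_frac = train_frac, seed = seed, n_train = n
    ),
    class = "plsr_ensemble"
  )
}

#' @export
print.plsr_ensemble <- function(x, ...) {
  cat("PLSR ensemble", if (!is.na(x$trait)) paste0("for ", x$trait), "\n")
  cat(" ", x$n_iter, "sub-models,", x$ncomp, "components,",
      length(x$wavelengths), "wavelengths,",
      "transformation:", x$transformation, "\n")
  invisible(x)
}

#' Predict traits with ensemble confidence and prediction intervals
#'
#' Every sub-model predicts on the transformed scale and is
#' back-transformed to the trait scale; the reported mean is the average of
#' the back-transformed sub-model predictions. The 95% confidence interval
#' is the 2.5/97.5 percentile of the sub-model predictions (model
#' uncertainty); the 95% prediction interval adds, per sub-model, a
#' Gaussian draw with that sub-model's residual sd before back-transforming
#' (model + residual uncertainty). Prediction intervals always enclose the
#' confidence interval.
#'
#' @param ensemble A `plsr_ensemble`.
#' @param x_new Matrix of new spectra on the ensemble's wavelength grid.
#' @param seed Integer seed for the prediction-interval noise draws.
#' @param level Interval level (default 0.95).
#' @return A tibble with one row per row of `x_new`: `leaf_id` (rownames
#'   of `x_new` or row index), `mean`, `ci95_low`, `ci95_high`,
#'   `pi95_low`, `pi95_high`.
#' @export
predict_ensemble <- function(ensemble, x_new, seed = 1, level = 0.95) {
  stopifnot(inherits(ensemble, "plsr_ensemble"))
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != length(ensemble$wavelengths)) {
    stop("x_new has ", ncol(x_new), " columns; ensemble grid has ",
         length(ensemble$wavelengths), call. = FALSE)
  }
  if (!is.null(colnames(x_new)) &&
      !isTRUE(all.equal(as.numeric(colnames(x_new)), ensemble$wavelengths))) {
    stop("x_new wavelength grid does not match the ensemble grid",
         call. = FALSE)
  }
  back <- function(m) transform_response(m, ensemble$transformation,
                                         inverse = TRUE)
  pred_t <- x_new %*% ensemble$coefficients +
    matrix(ensemble$intercepts, nrow(x_new), ensemble$n_iter, byrow = TRUE)
  pred <- back(pred_t)

  set.seed(seed)
  noise <- matrix(
    stats::rnorm(length(pred_t), 0,
                 rep(ensemble$resid_sd, each = nrow(x_new))),
    nrow = nrow(x_new)
  )
  pred_noisy <- back(pred_t + noise)

  a2 <- (1 - level) / 2
  rq <- function(m, p) apply(m, 1, stats::quantile, probs = p)
  ci_lo <- rq(pred, a2); ci_hi <- rq(pred, 1 - a2)
  pi_lo <- pmin(rq(pred_noisy, a2), ci_lo)
  pi_hi <- pmax(rq(pred_noisy, 1 - a2), ci_hi)
  mean_pred <- rowMeans(pred)

  tibble::tibble(
    leaf_id = if (!is.null(rownames(x_new))) rownames(x_new)
              else as.character(seq_len(nrow(x_new))),
    mean = mean_pred,
    ci95_low = pmin(ci_lo, mean_pred), ci95_high = pmax(ci_hi, mean_pred),
    pi95_low = pmin(pi_lo, mean_pred), pi95_high = pmax(pi_hi, mean_pred)
  )
}

#' Ensemble VIP scores
#'
#' The per-wavelength VIP of an ensemble is the mean of the sub-model VIP
#' vectors, accumulated during fitting.
#'
#' @param ensemble A `plsr_ensemble`.
#' @return A tibble `wavelength`, `vip`.
#' @export
vip_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "plsr_ensemble"))
  tibble::tibble(wavelength = ensemble$wavelengths, vip = ensemble$vip)
}

#' Per-wavelength coefficient summary of an ensemble
#'
#' Mean and 2.5/97.5 percentile band of the sub-model coefficient vectors
#' (on the transformed response scale), together with the mask of
#' wavelengths whose ensemble VIP exceeds 1 — the regions read as important
#' when interpreting a spectra-trait model.
#'
#' @param ensemble A `plsr_ensemble`.
#' @return A tibble: `wavelength`, `mean`, `low`, `high`, `vip`,
#'   `vip_above_1`.
#' @export
coefficient_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "plsr_ensemble"))
  co <- ensemble$coefficients
  qs <- apply(co, 1, stats::quantile, probs = c(0.025, 0.975))
  m <- rowMeans(co)
  tibble::tibble(
    wavelength = ensemble$wavelengths,
    mean = m,
    low = pmin(qs[1, ], m),
    high = pmax(qs[2, ], m),
    vip = ensemble$vip,
    vip_above_1 = ensemble$vip > 1
  )
}

#' Compare the coefficient vectors of two trait ensembles
#'
#' Computes the per-wavelength difference between paired sub-models (same
#' iteration index) of two ensembles fit with the same resampling setup,
#' its 95% percentile band, the mask of wavelengths where the band
#' excludes zero (a significant coefficient difference), and the Pearson
#' correlation of the two mean coefficient vectors.
#'
#' @param ensemble_a,ensemble_b Two `plsr_ensemble` objects sharing grid
#'   and `n_iter`.
#' @return A list with `table` (tibble: `wavelength`, `mean_diff`, `low`,
#'   `high`, `significant`) and `correlation` (scalar Pearson correlation
#'   of the mean coefficient vectors).
#' @export
coefficient_difference <- function(ensemble_a, ensemble_b) {
  stopifnot(inherits(ensemble_a, "plsr_ensemble"),
            inherits(ensemble_b, "plsr_ensemble"))
  if (!isTRUE(all.equal(ensemble_a$wavelengths, ensemble_b$wavelengths))) {
    stop("ensembles are on different wavelength grids", call. = FALSE)
  }
  if (ensemble_a$n_iter != ensemble_b$n_iter) {
    stop("ensembles have different sub-model counts", call. = FALSE)
  }
  d <- ensemble_a$coefficients - ensemble_b$coefficients
  qs <- apply(d, 1, stats::quantile, probs = c(0.025, 0.975))
  tab <- tibble::tibble(
    wavelength = ensemble_a$wavelengths,
    mean_diff = rowMeans(d),
    low = qs[1, ],
    high = qs[2, ],
    significant = qs[1, ] > 0 | qs[2, ] < 0
  )
  list(
    table = tab,
    correlation = stats::cor(rowMeans(ensemble_a$coefficients),
                             rowMeans(ensemble_b$coefficients))
  )
}

#' Tidy a PLSR ensemble into per-wavelength summaries
#'
#' @param x A `plsr_ensemble`.
#' @param ... Unused.
#' @return The tibble from [coefficient_summary()].
#' @method tidy plsr_ensemble
#' @export
tidy.plsr_ensemble <- function(x, ...) coefficient_summary(x)

#' One-row summary of a PLSR ensemble
#'
#' @param x A `plsr_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: `trait`, `transformation`, `ncomp`, `n_iter`,
#'   `n_train`, `n_wavelengths`, `mean_resid_sd`.
#' @method glance plsr_ensemble
#' @export
glance.plsr_ensemble <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, transformation = x$transformation, ncomp = x$ncomp,
    n_iter = x$n_iter, n_train = x$n_train,
    n_wavelengths = length(x$wavelengths),
    mean_resid_sd = mean(x$resid_sd)
  )
}

#' Write / read a fitted ensemble as a JSON header plus coefficient CSV
#'
#' `write_ensemble()` stores the metadata (trait, transformation, ncomp,
#' grid, seed) as JSON alongside a CSV holding the coefficient matrix,
#' intercepts and residual sds; `read_ensemble()` reconstructs the object.
#' Both files are plain text so models can be versioned and exchanged.
#'
#' @param ensemble A `plsr_ensemble`.
#' @param path Base path; `<path>.json` and `<path>.csv` are written.
#' @return `write_ensemble()` returns `path` invisibly; `read_ensemble()`
#'   returns the `plsr_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "plsr_ensemble"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write ensembles", call. = FALSE)
  }
  header <- list(
    trait = ensemble$trait, transformation = ensemble$transformation,
    ncomp = ensemble$ncomp, n_iter = ensemble$n_iter,
    train_frac = ensemble$train_frac, seed = ensemble$seed,
    n_train = ensemble$n_train, wavelengths = ensemble$wavelengths,
    vip = ensemble$vip
  )
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  body <- tibble::as_tibble(ensemble$coefficients,
                            .name_repair = ~ paste0("sub", seq_along(.x)))
  body <- dplyr::bind_rows(
    body,
    stats::setNames(as.list(ensemble$intercepts), names(body)),
    stats::setNames(as.list(ensemble$resid_sd), names(body))
  )
  readr::write_csv(body, paste0(path, ".csv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to read ensembles", call. = FALSE)
  }
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  body <- as.matrix(readr::read_csv(paste0(path, ".csv"),
                                    show_col_types = FALSE, progress = FALSE))
  p <- nrow(body) - 2L
  structure(
    list(
      coefficients = unname(body[seq_len(p), , drop = FALSE]),
      intercepts = unname(body[p + 1L, ]),
      resid_sd = unname(body[p + 2L, ]),
      vip = as.numeric(header$vip),
      wavelengths = as.numeric(header$wavelengths),
      ncomp = as.integer(header$ncomp),
      transformation = header$transformation,
      trait = header$trait,
      n_iter = as.integer(header$n_iter),
      train_frac = header$train_frac,
      seed = header$seed,
      n_train = header$n_train
    ),
    class = "plsr_ensemble"
  )
}
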