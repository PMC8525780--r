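#' Response transformation for the spectra-trait models
#'
#' Vcmax25 and Jmax25 are square-root transformed before PLSR to make their
#' distributions more symmetric; Tp25 and Rdark25 are modeled untransformed.
#'
#' @param values Numeric vector.
#' @param tag `"sqrt"` or `"none"`.
#' @param inverse Apply the inverse transformation (square for `"sqrt"`)?
#' @return Transformed numeric vector.
#' @export
transform_response <- function(values, tag = c("none", "sqrt"),
                               inverse = FALSE) {
  tag <- match.arg(tag)
  if (tag == "none") return(values)
  if (inverse) return(values^2)
  if (any(values < 0, na.rm = TRUE)) {
    stop("sqrt transformation needs non-negative values", call. = FALSE)
  }
  sqrt(values)
}

# Default transformation tag per trait.
trait_transformation <- function(trait) {
  switch(trait,
         vcmax25 = , jmax25 = "sqrt",
         tp25 = , rdark25 = "none",
         "none")
}

#' Fit a single PLS1 model by NIPALS
#'
#' Classic NIPALS partial least squares for a univariate response:
#' predictors and response are mean-centered (no unit-variance scaling, so
#' spectral shape is preserved), weights are the covariance direction of
#' the deflated predictor matrix with the response, and only X is deflated.
#' Coefficients on the original predictor scale reproduce fitted values as
#' `X %*% coef + intercept`.
#'
#' @param x Numeric predictor matrix (n x p), e.g. from [spectra_matrix()].
#' @param y Numeric response vector of length n (already transformed if
#'   applicable).
#' @param ncomp Number of latent components; must satisfy
#'   `ncomp <= min(n - 2, p)`.
#' @return An object of class `pls_fit`: weights `w` (p x ncomp,
#'   unit-norm columns), loadings `p`, y-loadings `q`, scores `t`,
#'   per-component explained response variance `ssy`, centers, and the
#'   coefficient path `coef_path` (p x ncomp; column k gives coefficients
#'   of the k-component model) with `intercept_path`.
#' @export
fit_pls <- function(x, y, ncomp) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)", call. = FALSE)
  if (ncomp > p) stop("ncomp exceeds predictor count", call. = FALSE)
  if (n < ncomp + 2) stop("need at least ncomp + 2 rows", call. = FALSE)
  if (stats::sd(y) == 0) stop("constant response", call. = FALSE)

  x_center <- colMeans(x)
  y_center <- mean(y)
  xc <- sweep(x, 2, x_center)
  yc <- y - y_center

  w_mat <- matrix(0, p, ncomp)
  p_mat <- matrix(0, p, ncomp)
  t_mat <- matrix(0, n, ncomp)
  q_vec <- numeric(ncomp)
  ssy <- numeric(ncomp)

  xk <- xc
  yscale <- sum(yc^2)
  ncomp_eff <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(xk, yc)
    wn <- sqrt(sum(w^2))
    # response exhausted (noiseless low-rank data): stop early; later
    # components cannot change the fit
    if (wn < 1e-10 * max(yscale, 1)) break
    w <- w / wn
    tt <- xk %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pl <- crossprod(xk, tt) / tt2
    q <- sum(yc * tt) / tt2
    xk <- xk - tcrossprod(tt, pl)
    w_mat[, k] <- w
    p_mat[, k] <- pl
    t_mat[, k] <- tt
    q_vec[k] <- q
    ssy[k] <- q^2 * tt2
    ncomp_eff <- k
  }
  if (ncomp_eff == 0L) stop("response orthogonal to predictors", call. = FALSE)

  # Coefficient path: B_k = W_k (P_k' W_k)^{-1} q_{1:k}; beyond the
  # effective rank the path is constant
  pw <- crossprod(p_mat[, seq_len(ncomp_eff), drop = FALSE],
                  w_mat[, seq_len(ncomp_eff), drop = FALSE])
  coef_path <- matrix(0, p, ncomp)
  for (k in seq_len(ncomp_eff)) {
    r <- solve(pw[seq_len(k), seq_len(k), drop = FALSE],
               q_vec[seq_len(k)])
    coef_path[, k] <- w_mat[, seq_len(k), drop = FALSE] %*% r
  }
  if (ncomp_eff < ncomp) {
    coef_path[, (ncomp_eff + 1L):ncomp] <- coef_path[, ncomp_eff]
  }
  intercept_path <- y_center - as.numeric(crossprod(x_center, coef_path))

  structure(
    list(w = w_mat, p = p_mat, q = q_vec, t = t_mat, ssy = ssy,
         x_center = x_center, y_center = y_center,
         coef_path = coef_path, intercept_path = intercept_path,
         coef = coef_path[, ncomp], intercept = intercept_path[ncomp],
         ncomp = ncomp, ncomp_eff = ncomp_eff, wavelengths = colnames(x)),
    class = "pls_fit"
  )
}

#' Predict from a single PLS fit
#'
#' @param object A `pls_fit`.
#' @param newdata Matrix on the same predictor grid.
#' @param ncomp Component count to predict with (default: the fit's).
#' @param ... Unused.
#' @return Numeric vector of predictions on the (transformed) response
#'   scale.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$coef_path[, ncomp] + object$intercept_path[ncomp])
}

#' Variable importance in projection (VIP) scores
#'
#' The standard PLS1 VIP: for predictor j,
#' \eqn{VIP_j = \sqrt{p \sum_k SS_k w_{jk}^2 / \sum_k SS_k}}
#' with unit-norm weight vectors and \eqn{SS_k} the response variance
#' explained by component k. Squared VIPs average to 1 over predictors, so
#' wavelengths with VIP above 1 carry more than average importance.
#'
#' @param fit A `pls_fit` (for an ensemble, see [vip_ensemble()] or the
#'   `vip` element stored on the ensemble).
#' @return Numeric vector of length p.
#' @export
vip_scores <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  ss <- fit$ssy
  if (sum(ss) <= 0) stop("zero explained variance", call. = FALSE)
  p <- nrow(fit$w)
  # weights are unit-norm, so w^2 needs no renormalization
  sqrt(p * drop(fit$w^2 %*% ss) / sum(ss))
}
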