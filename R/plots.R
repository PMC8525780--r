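#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted A-Ci curve with its limiting rates and bands
#'
#' Shows the observations, the fitted net assimilation curve, the three
#' potentially limiting limbs, and (when the fit has a valid covariance)
#' the percentile confidence band of the mean and the prediction band.
#'
#' @param object An `fvcb_fit`.
#' @param n_draws,seed Passed to [curve_intervals()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fvcb_fit
#' @export
autoplot.fvcb_fit <- function(object, n_draws = 500, seed = 1, ...) {
  cur <- object$data
  grid <- seq(max(min(cur$ci) * 0.5, 5), max(cur$ci) * 1.05, length.out = 120)
  tl <- stats::median(cur$tleaf)
  limbs <- fvcb_forward(
    grid, tl, NA_real_,
    vcmax25 = object$params[["vcmax25"]], jmax25 = object$params[["jmax25"]],
    rd25 = object$params[["rd25"]],
    tp25 = if (object$tp_included) object$params[["tp25"]] else NA_real_,
    theta = object$theta, alpha = object$alpha, constants = object$constants
  )
  rd <- object$params[["rd25"]] * temp_scaler("rdark", tl, object$constants)
  limb_long <- tidyr::pivot_longer(
    dplyr::mutate(limbs,
                  Ac = .data$ac - rd, Aj = .data$aj - rd,
                  Ap = ifelse(is.finite(.data$ap), .data$ap - rd, NA_real_)),
    cols = c("Ac", "Aj", "Ap"), names_to = "limb", values_to = "rate"
  )

  p <- ggplot2::ggplot(limbs, ggplot2::aes(x = .data$ci))
  if (object$reliable) {
    bands <- curve_intervals(object, ci_grid = grid, n_draws = n_draws,
                             seed = seed)
    p <- p +
      ggplot2::geom_ribbon(
        data = bands,
        ggplot2::aes(ymin = .data$pred_low, ymax = .data$pred_high),
        fill = "grey80", alpha = 0.6) +
      ggplot2::geom_ribbon(
        data = bands,
        ggplot2::aes(ymin = .data$mean_low, ymax = .data$mean_high),
        fill = "darkgreen", alpha = 0.3)
  }
  p +
    ggplot2::geom_line(
      data = limb_long[is.finite(limb_long$rate), ],
      ggplot2::aes(y = .data$rate, colour = .data$limb), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$a_net)) +
    ggplot2::geom_point(data = cur, ggplot2::aes(y = .data$a)) +
    ggplot2::labs(
      x = expression(C[i] ~ (mu * mol ~ mol^-1)),
      y = expression(A[net] ~ (mu * mol ~ m^-2 ~ s^-1)),
      colour = "Limiting rate",
      title = paste("FvCB fit:", object$leaf_id)
    ) +
    ggplot2::theme_minimal()
}

#' Plot ensemble PLSR coefficients with VIP > 1 regions shaded
#'
#' The mean coefficient vector with its 95% band; grey background columns
#' mark wavelengths whose ensemble VIP score exceeds one.
#'
#' @param object A `plsr_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plsr_ensemble
#' @export
autoplot.plsr_ensemble <- function(object, ...) {
  cs <- coefficient_summary(object)
  step <- if (length(object$wavelengths) > 1) {
    min(diff(object$wavelengths))
  } else 1
  vip_runs <- cs[cs$vip_above_1, "wavelength"]
  p <- ggplot2::ggplot(cs, ggplot2::aes(x = .data$wavelength))
  if (nrow(vip_runs) > 0) {
    p <- p + ggplot2::geom_tile(
      data = vip_runs,
      ggplot2::aes(y = 0, height = Inf), width = step,
      fill = "grey85")
  }
  p +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$low, ymax = .data$high),
      fill = "darkgreen", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(
      x = "Wavelength (nm)", y = "PLSR coefficient",
      title = if (!is.na(object$trait)) {
        paste("Ensemble coefficients:", object$trait)
      } else "Ensemble coefficients",
      subtitle = "Grey columns: ensemble VIP > 1"
    ) +
    ggplot2::theme_minimal()
}

#' Observed-versus-predicted plot for a validation set
#'
#' Points are ensemble-mean predictions; dark segments the 95% confidence
#' intervals, light segments the 95% prediction intervals; the identity
#' line marks perfect prediction.
#'
#' @param predictions A tibble from [predict_ensemble()].
#' @param observed Observed trait values aligned with `predictions` rows.
#' @param trait Optional axis label.
#' @return A ggplot object.
#' @export
plot_validation <- function(predictions, observed, trait = "trait") {
  df <- dplyr::mutate(predictions, observed = observed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$mean)) +
    ggplot2::geom_segment(
      ggplot2::aes(y = .data$pi95_low, yend = .data$pi95_high,
                   xend = .data$observed),
      colour = "grey75") +
    ggplot2::geom_segment(
      ggplot2::aes(y = .data$ci95_low, yend = .data$ci95_high,
                   xend = .data$observed),
      colour = "grey30") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::labs(x = paste("Observed", trait),
                  y = paste("Predicted", trait)) +
    ggplot2::theme_minimal()
}
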