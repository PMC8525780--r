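test_that("gaussian negative log-likelihood matches closed forms", {
  cur <- toy_curve()
  # residuals all zero, sigma = 1 -> n/2 * log(2*pi)
  p <- fvcb_forward(cur$ci, cur$tleaf, cur$q, vcmax25 = 60, jmax25 = 110,
                    rd25 = 1.2)
  exact <- tibble::tibble(leaf_id = cur$leaf_id, a = p$a_net, ci = cur$ci,
                          tleaf = cur$tleaf, q = cur$q)
  n <- nrow(cur)
  expect_equal(negloglik_aci(exact, 60, 110, 1.2, sigma = 1),
               n / 2 * log(2 * pi), tolerance = 1e-10)
  # doubling sigma with fixed residuals follows the closed form
  nll1 <- negloglik_aci(cur, 55, 100, 1, sigma = 1)
  nll2 <- negloglik_aci(cur, 55, 100, 1, sigma = 2)
  pred <- fvcb_forward(cur$ci, cur$tleaf, cur$q, vcmax25 = 55, jmax25 = 100,
                       rd25 = 1)$a_net
  rss <- sum((cur$a - pred)^2)
  expect_equal(nll2 - nll1, n * log(2) + rss / 8 - rss / 2, tolerance = 1e-9)
  # 3-point toy curve against an independent term-by-term sum
  toy3 <- tibble::tibble(a = c(5, 10, 14), ci = c(150, 400, 900),
                         tleaf = 30, q = 1500)
  mu <- fvcb_forward(toy3$ci, 30, 1500, vcmax25 = 50, jmax25 = 90,
                     rd25 = 1)$a_net
  byhand <- sum(-dnorm(toy3$a, mu, 1.3, log = TRUE))
  expect_equal(negloglik_aci(toy3, 50, 90, 1, sigma = 1.3), byhand,
               tolerance = 1e-10)
  expect_error(negloglik_aci(toy3, 50, 90, 1, sigma = 0), "sigma")
})

test_that("noise-free curves return the generating parameters", {
  cur <- toy_curve()
  f <- fit_aci(cur, include_tp = FALSE, seed = 1)
  expect_equal(unname(f$params), c(60, 110, 1.2), tolerance = 1e-3)
  expect_true(f$tp_included == FALSE)
  expect_equal(f$n_params, 4L)
  # with a strongly binding export limb
  tp <- binding_tp(60, 110, 1.2)
  cur2 <- toy_curve(tp25 = tp)
  f2 <- fit_aci(cur2, include_tp = TRUE, seed = 1)
  expect_equal(unname(f2$params), c(60, 110, 1.2, tp), tolerance = 1e-2)
})

test_that("refitting a fit's own predictions is idempotent", {
  cur <- toy_curve(noise_sd = 0.5, seed = 42)
  f <- fit_aci(cur, include_tp = FALSE, seed = 1)
  refit_data <- tibble::tibble(leaf_id = cur$leaf_id, a = f$fitted,
                               ci = cur$ci, tleaf = cur$tleaf, q = cur$q)
  f2 <- fit_aci(refit_data, include_tp = FALSE, seed = 1)
  expect_equal(f2$params, f$params, tolerance = 1e-3)
})

test_that("AIC bookkeeping and Wald intervals are coherent", {
  cur <- toy_curve(noise_sd = 0.4, seed = 7)
  f <- fit_aci(cur, include_tp = FALSE, seed = 1)
  expect_equal(f$AIC, 2 * f$n_params - 2 * f$logLik, tolerance = 1e-10)
  td <- tidy(f)
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  expect_true(all(td$std.error > 0))
  gl <- glance(f)
  expect_identical(gl$n_obs, nrow(cur))
})

test_that("curves with no Rubisco-limited points are flagged unidentifiable", {
  # only high-Ci observations: everything Aj-limited, Vcmax unconstrained
  ci <- seq(800, 1500, length.out = 8)
  mu <- fvcb_forward(ci, 31, 1200, vcmax25 = 120, jmax25 = 80,
                     rd25 = 1)$a_net
  set.seed(5)
  cur <- tibble::tibble(a = mu + rnorm(8, 0, 0.2), ci = ci, tleaf = 31,
                        q = 1200)
  f <- fit_aci(cur, include_tp = FALSE, seed = 1)
  # Vcmax cannot be pinned by these data: a fit forced to a much larger
  # Vcmax reaches essentially the same likelihood (flat ridge), or the
  # fit is already flagged / reports an enormous relative standard error
  f_hi <- fit_aci(cur, include_tp = FALSE,
                  init = c(vcmax25 = 300, jmax25 = 80, rd25 = 1),
                  n_starts = 1, seed = 1)
  ridge_flat <- abs(f_hi$logLik - f$logLik) < 2 &&
    abs(f_hi$params[["vcmax25"]] - f$params[["vcmax25"]]) >
      0.5 * f$params[["vcmax25"]]
  expect_true(ridge_flat || !f$reliable ||
                f$se[["vcmax25"]] / f$params[["vcmax25"]] > 0.25)
})

test_that("AIC model choice keeps the parsimonious model on ties", {
  cur <- toy_curve(noise_sd = 0.3, seed = 9)
  f0 <- fit_aci(cur, include_tp = FALSE, seed = 1)
  f1 <- fit_aci(cur, include_tp = TRUE, seed = 1)
  forced_tie <- f1
  forced_tie$AIC <- f0$AIC
  expect_false(select_tp_model(forced_tie, f0)$tp_included)
  # mismatched curves are rejected
  other <- toy_curve(vcmax25 = 40, noise_sd = 0.3, seed = 10)
  fo <- fit_aci(other, include_tp = FALSE, seed = 1)
  expect_error(select_tp_model(f1, fo), "different curves")
  # and the lower-AIC fit wins otherwise
  sel <- select_tp_model(f1, f0)
  expect_equal(sel$AIC, min(f1$AIC, f0$AIC))
})

test_that("limitation states move forward along the limb order with Ci", {
  tp <- binding_tp(60, 110, 1.2, frac = 0.6)
  cur <- toy_curve(tp25 = tp, noise_sd = 0.4, seed = 21)
  f <- fit_aci(cur, include_tp = TRUE, seed = 1)
  # the canonical limb ordering holds above the compensation point (below
  # it both carboxylation-driven limbs are negative and their argmin is
  # not physiologically meaningful)
  g <- kinetics_at_t(31)$gammastar
  keep <- f$data$ci > g
  ord <- order(f$data$ci[keep])
  codes <- match(f$states[keep][ord], c("Ac", "Aj", "Ap"))
  expect_true(all(diff(codes) >= 0))
})

test_that("parametric-bootstrap bands behave like intervals", {
  cur <- toy_curve(noise_sd = 0.4, seed = 13)
  f <- fit_aci(cur, include_tp = FALSE, seed = 1)
  grid <- seq(100, 1400, by = 100)
  b <- curve_intervals(f, ci_grid = grid, n_draws = 400, seed = 2)
  expect_true(all(b$mean_low <= b$estimate & b$estimate <= b$mean_high))
  expect_true(all(b$pred_low <= b$mean_low & b$mean_high <= b$pred_high))
  # sigma -> 0 collapses the prediction band onto the mean band
  f0 <- f; f0$sigma <- 1e-9
  b0 <- curve_intervals(f0, ci_grid = grid, n_draws = 400, seed = 2)
  expect_equal(b0$pred_low, b0$mean_low, tolerance = 1e-5)
  expect_equal(b0$pred_high, b0$mean_high, tolerance = 1e-5)
  # band widths stable against a larger-draw reference (within 15%)
  bref <- curve_intervals(f, ci_grid = grid, n_draws = 4000, seed = 3)
  w <- b$mean_high - b$mean_low
  wref <- bref$mean_high - bref$mean_low
  expect_lt(max(abs(w - wref) / wref), 0.15)
})

test_that("dark respiration averaging and normalization follow the protocol", {
  r <- rdark_from_timeseries(rep(0.8, 60), tleaf = 25)
  expect_equal(r$rdark25, 0.8)
  expect_equal(r$se, 0)
  # se matches the closed form sd/sqrt(n)
  set.seed(3)
  s <- rnorm(60, 0.9, 0.05)
  r2 <- rdark_from_timeseries(s, tleaf = 25)
  expect_equal(r2$rdark, mean(s))
  expect_equal(r2$se, sd(s) / sqrt(60))
  # warmer leaf -> smaller 25 C value, by exactly the Arrhenius factor
  r3 <- rdark_from_timeseries(rep(0.8, 60), tleaf = 30)
  expect_equal(r3$rdark25, 0.8 / temp_scaler("rdark", 30), tolerance = 1e-12)
  expect_lt(r3$rdark25, r3$rdark)
  expect_error(rdark_from_timeseries(rep(0.8, 10), 25), "at least 30")
  expect_warning(rdark_from_timeseries(rnorm(60, -0.5, 0.01), 25),
                 "negative")
})

test_that("multi-leaf tables fit leaf by leaf with limb selection", {
  tr <- small_traits(seed = 31, n_species = 4)
  tr <- tr[1:4, ]
  gas <- purrr::map_dfr(1:4, function(i) {
    gen_aci_curve(tr$vcmax25[i], tr$jmax25[i], tr$rdark25_latent[i],
                  leaf_id = tr$leaf_id[i], noise_sd = 0.3, seed = 50 + i)
  })
  fits <- fit_aci_curves(gas, seed = 1)
  expect_identical(nrow(fits), 4L)
  expect_true(all(fits$converged))
  expect_equal(fits$vcmax25, tr$vcmax25[match(fits$leaf_id, tr$leaf_id)],
               tolerance = 0.15)
})
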