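test_that("temperature scaler is exactly 1 at the reference temperature", {
  for (kind in c("vcmax", "jmax", "tp", "rdark", "kc", "ko", "gammastar")) {
    expect_identical(temp_scaler(kind, 25), 1)
  }
})

test_that("temperature scaler matches direct exponential evaluation", {
  # pure Arrhenius with Ha = 65330 J/mol at 30 C, evaluated by hand
  tk <- 303.15
  expected <- exp(65330 * (tk - 298.15) / (298.15 * 8.314 * tk))
  expect_equal(arrhenius_factor <- spectraphys:::arrhenius_factor(30, 65330),
               expected, tolerance = 1e-12)
  # rdark ships as pure Arrhenius, so the public path hits the same form
  expect_equal(temp_scaler("rdark", 30),
               exp(46390 * (tk - 298.15) / (298.15 * 8.314 * tk)),
               tolerance = 1e-12)
  # monotone below the optimum
  expect_gt(temp_scaler("vcmax", 30), temp_scaler("vcmax", 25))
})

test_that("temperature scaler validates inputs", {
  expect_error(temp_scaler("nonsense", 25), "unknown parameter kind")
  expect_error(temp_scaler("vcmax", NaN), "finite")
  expect_error(temp_scaler("vcmax", 80), "0-50")
})

test_that("kinetics scale with their own activation energies", {
  k25 <- kinetics_at_t(25)
  cst <- fvcb_constants()
  expect_equal(k25$kc, cst$kinetics[["kc25"]])
  expect_equal(k25$ko, cst$kinetics[["ko25"]])
  expect_equal(k25$gammastar, cst$kinetics[["gammastar25"]])
  k30 <- kinetics_at_t(30)
  expect_true(all(unlist(k30[, -1]) > unlist(k25[, -1])))
  # one-step vs chained scaling agree: f(35) == f(30->35 via ratio)
  k35 <- kinetics_at_t(35)
  chained <- k30$kc * (k35$kc / k30$kc)
  expect_equal(k35$kc, chained, tolerance = 1e-10)
})

test_that("electron transport follows the non-rectangular hyperbola", {
  expect_equal(electron_transport_rate(0, 100), 0)
  # saturation within 1%
  expect_equal(electron_transport_rate(1e6, 100), 100, tolerance = 0.01)
  # quadratic-root oracle
  theta <- 0.7; alpha <- 0.425; q <- 1800; jmax <- 100
  roots <- Re(polyroot(c(alpha * q * jmax, -(alpha * q + jmax), theta)))
  expect_equal(electron_transport_rate(q, jmax, theta, alpha), min(roots),
               tolerance = 1e-9)
  j <- electron_transport_rate(q, jmax, theta, alpha)
  expect_lte(j, min(alpha * q, jmax))
  expect_error(electron_transport_rate(100, 100, theta = 1.2), "theta")
})

test_that("forward model reproduces the hand-computed Rubisco limb", {
  # Vcmax 50, Ci 300, default Bernacchi kinetics at 25 C
  fw <- fvcb_forward(300, 25, NA, vcmax25 = 50, jmax25 = 500, rd25 = 0)
  expect_equal(fw$ac, 50 * (300 - 42.75) / (300 + 404.9 * (1 + 210 / 278.4)),
               tolerance = 1e-12)
  expect_equal(round(fw$ac, 2), 12.73)
})

test_that("gross limbs vanish at the compensation point", {
  g <- kinetics_at_t(25)$gammastar
  fw <- fvcb_forward(g, 25, NA, vcmax25 = 50, jmax25 = 100, rd25 = 0.9)
  expect_equal(fw$ac, 0, tolerance = 1e-10)
  expect_equal(fw$aj, 0, tolerance = 1e-10)
  expect_equal(fw$a_net, -0.9, tolerance = 1e-10)
})

test_that("export limb caps the gross rate at 3 Tp", {
  fw <- fvcb_forward(5000, 25, NA, vcmax25 = 200, jmax25 = 400, rd25 = 0,
                     tp25 = 10)
  expect_equal(fw$a_net, 30, tolerance = 1e-9)
  expect_identical(fw$state, "Ap")
})

test_that("absent Tp equals infinite Tp and states index the minimum", {
  ci <- c(50, 150, 300, 600, 1200)
  a <- fvcb_forward(ci, 30, 1500, vcmax25 = 60, jmax25 = 110, rd25 = 1)
  b <- fvcb_forward(ci, 30, 1500, vcmax25 = 60, jmax25 = 110, rd25 = 1,
                    tp25 = Inf)
  expect_equal(a$a_net, b$a_net)
  # explicit three-way argmin check
  c3 <- fvcb_forward(ci, 31, 1800, vcmax25 = 80, jmax25 = 130, rd25 = 1,
                     tp25 = 6)
  manual <- apply(cbind(c3$ac, c3$aj, c3$ap), 1,
                  function(r) c("Ac", "Aj", "Ap")[which.min(r)])
  expect_identical(c3$state, manual)
})

test_that("net assimilation is non-decreasing in Ci above the compensation point", {
  g <- kinetics_at_t(30)$gammastar
  ci <- seq(ceiling(g) + 1, 1500, by = 25)
  fw <- fvcb_forward(ci, 30, 1800, vcmax25 = 70, jmax25 = 120, rd25 = 1)
  expect_true(all(diff(fw$a_net) > -1e-9))
})

test_that("forward model rejects invalid inputs", {
  expect_error(fvcb_forward(-5, 25, NA, vcmax25 = 50, jmax25 = 100, rd25 = 1),
               "ci")
  expect_error(fvcb_forward(300, 25, NA, vcmax25 = NaN, jmax25 = 100,
                            rd25 = 1), "non-finite")
})

test_that("constants file is validated on load", {
  bad <- tempfile(fileext = ".yml")
  writeLines(c("reference: {tref_c: 25, gas_constant: 8.314}",
               "kinetics: {kc25: 10, ko25: 278.4, gammastar25: 42.75, oxygen: 210}",
               "temperature_response:",
               "  vcmax: {ha: 65330}"), bad)
  expect_error(fvcb_constants(bad), "gammastar25")
  bad2 <- tempfile(fileext = ".yml")
  writeLines(c("reference: {tref_c: 25, gas_constant: 8.314}",
               "kinetics: {kc25: 404.9, ko25: 278.4, gammastar25: 42.75, oxygen: 210}",
               "temperature_response:",
               "  vcmax: {ha: 65330, hd: 100, ds: 485}"), bad2)
  expect_error(fvcb_constants(bad2), "hd > ha")
})
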