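test_that("volume ratio reproduces Table-derived values", {
  expect_equal(fh_volume_ratio(ibu, va64), 286.69, tolerance = 1e-4)
  expect_equal(fh_volume_ratio(ibu, pf17), 48.13, tolerance = 1e-3)
  expect_equal(fh_volume_ratio(ibu, ibu), 1)
})

test_that("per-point chi inverts the SLE relation exactly", {
  model <- fh_model(ibu, va64, A = 0.65, B = 0)
  # zero-depression limit: T_end = Tm
  d0 <- mpd_dataset(0.6, ibu$tm_K)
  cp0 <- fh_chi_points(d0, ibu, va64)
  phi <- cp0$phi_api
  m <- fh_volume_ratio(ibu, va64)
  expect_equal(cp0$chi,
               -(log(phi) + (1 - 1 / m) * (1 - phi)) / (1 - phi)^2)
  # round trip through the generating relation at chi* = 0.65
  sle <- fh_sle(model, w_api = seq(0.3, 0.9, 0.1))
  d <- mpd_dataset(sle$w_api, sle$T_K)
  cp <- fh_chi_points(d, ibu, va64)
  expect_equal(cp$chi, rep(0.65, nrow(cp)), tolerance = 1e-10)
  expect_error(fh_chi_points(mpd_dataset(1, ibu$tm_K), ibu, va64), "w_api = 1")
})

test_that("slope-method chi recovers a constant generating chi", {
  model <- fh_model(ibu, va64, A = 0.96, B = 0)
  sle <- suppressWarnings(fh_sle(model, w_api = seq(0.3, 0.95, 0.05)))
  d <- mpd_dataset(sle$w_api, sle$T_K)
  fit <- fh_chi_slope(d, ibu, va64)
  expect_equal(fit$params$chi, 0.96, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # chi* = 0 data give slope 0
  model0 <- fh_model(ibu, va64, A = 0, B = 0)
  sle0 <- fh_sle(model0, w_api = seq(0.3, 0.9, 0.1))
  fit0 <- fh_chi_slope(mpd_dataset(sle0$w_api, sle0$T_K), ibu, va64)
  expect_equal(fit0$params$chi, 0, tolerance = 1e-10)
  expect_error(fh_chi_slope(mpd_dataset(rep(0.5, 4), rep(340, 4)), ibu, va64),
               "degenerate")
})

test_that("chi(T) fit interpolates exact linear data and flags UCST", {
  # chi = -2 + 1000/T exactly
  spec <- synth_spec("fh", list(A = -2, B = 1000), noise_sd = 0, seed = 1)
  mpd <- gen_mpd_quiet(spec, ibu, va64)
  fit <- fh_chi_temperature(mpd, ibu, va64)
  expect_equal(fit$A, -2, tolerance = 1e-8)
  expect_equal(fit$B, 1000, tolerance = 1e-5)
  expect_true(asdkit:::is_ucst(fit))
  expect_error(fh_chi_temperature(mpd_dataset(c(0.5, 0.6), c(340, 340)),
                                  ibu, va64), "distinct")
})

test_that("SLE solver hits the pure-API limit and agrees with an ideal-limit oracle", {
  model <- fh_model(ibu, va64, A = -2, B = 800)
  expect_identical(fh_sle(model, w_api = 1)$T_K, ibu$tm_K)
  # chi = 0, 1/m -> 0: ln(phi) + phi_p = -dH/R (1/T - 1/Tm), brute bisection
  big <- ibu
  big$name <- "bigpoly"
  big$mw <- 1e9
  model2 <- fh_model(ibu, big, A = 0, B = 0)
  for (phi in c(0.4, 0.7, 0.9)) {
    Ts <- asdkit:::fh_sle_T(model2, phi)
    f <- function(T) {
      log(phi) + (1 - phi) + ibu$dhfus / asdkit:::.R * (1 / T - 1 / ibu$tm_K)
    }
    lo <- 200
    hi <- ibu$tm_K
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    expect_equal(Ts, (lo + hi) / 2, tolerance = 1e-7)
  }
  # UCST parameters with moderate chi: solubility temperature rises with
  # drug load
  sle <- fh_sle(model, w_api = seq(0.2, 1, 0.1))
  expect_true(all(diff(sle$T_K) > 0))
})

test_that("Gibbs mixing curve has the symmetric ideal value and double wells", {
  sym <- ibu
  sym$name <- "sym"
  model <- fh_model(ibu, sym, A = 0, B = 0) # m = 1, chi = 0
  g <- fh_gibbs(model, 300, phi_api = c(0, 0.5, 1))
  expect_equal(g$g, c(0, log(0.5), 0))
  # exchange symmetry at m = 1
  model2 <- fh_model(ibu, sym, A = 1.5, B = 0)
  gg <- fh_gibbs(model2, 300, phi_api = seq(0.05, 0.95, 0.05))
  expect_equal(gg$g, rev(gg$g), tolerance = 1e-12)
  # large chi: double well (two interior minima of g)
  model5 <- fh_model(ibu, sym, A = 5, B = 0)
  gv <- fh_gibbs(model5, 300, phi_api = seq(0.001, 0.999, length.out = 999))$g
  d <- diff(gv)
  n_min <- sum(diff(sign(d)) > 0)
  expect_equal(n_min, 2)
})

test_that("spinodal quadratic matches the closed-form critical point", {
  for (m in c(1, 48.13, 286.69)) {
    crit <- fh_critical(m = m)
    expect_equal(crit$chi_c, 0.5 * (1 + 1 / sqrt(m))^2)
    expect_equal(crit$phi_c_poly, 1 / (1 + sqrt(m)))
    # just above critical: two roots straddling phi_c; just below: none
    r <- asdkit:::fh_spinodal_phi(m, crit$chi_c * (1 + 1e-6))
    expect_length(r, 2)
    expect_true(r[1] < crit$phi_c && r[2] > crit$phi_c)
    expect_length(asdkit:::fh_spinodal_phi(m, crit$chi_c * 0.999), 0)
  }
  # m = 1: symmetric roots coincide at 0.5 when chi = 2
  r <- asdkit:::fh_spinodal_phi(1, 2 + 1e-10)
  expect_equal(r, c(0.5, 0.5), tolerance = 1e-4)
})

test_that("binodal encloses spinodal and matches the grid-search oracle", {
  # symmetric case against the brute-force common tangent
  bn <- asdkit:::fh_binodal_phi(1, 2.5)
  g <- function(p) p * log(p) + (1 - p) * log(1 - p) + 2.5 * p * (1 - p)
  oracle <- hull_tangent_oracle(g, step = 1e-4)
  expect_equal(bn, oracle, tolerance = 1e-3)
  expect_equal(bn[1], 1 - bn[2], tolerance = 1e-10)
  # nesting across asymmetric systems and quench depths
  for (m in c(1, 48.13, 286.69)) {
    for (f in c(1.05, 1.3, 2, 4)) {
      chi <- fh_critical(m = m)$chi_c * f
      bn <- asdkit:::fh_binodal_phi(m, chi)
      sp <- asdkit:::fh_spinodal_phi(m, chi)
      expect_false(is.null(bn))
      expect_lte(bn[1], sp[1])
      expect_gte(bn[2], sp[2])
    }
  }
})

test_that("slope chi fed back into the SLE reproduces generating temperatures", {
  model <- fh_model(ibu, pf17, A = 0.4, B = 0)
  sle <- fh_sle(model, w_api = seq(0.35, 0.9, 0.05))
  d <- mpd_dataset(sle$w_api, sle$T_K)
  chi_hat <- fh_chi_slope(d, ibu, pf17)$params$chi
  back <- fh_sle(fh_model(ibu, pf17, A = chi_hat, B = 0),
                 w_api = sle$w_api)
  expect_equal(back$T_K, sle$T_K, tolerance = 1e-6)
})
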