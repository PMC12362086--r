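nm_va <- c("IBU", "KOL VA64")

test_that("ideal-gas and association-off limits are exact", {
  st <- pcsaft_state(pp, "IBU", 298.15, eta = 1e-12, x = 1)
  expect_equal(st$a_res, 0, tolerance = 1e-8)
  expect_equal(st$Z, 1, tolerance = 1e-8)
  # kappa = 0 switches association off exactly
  p0 <- pp
  p0$kappa_assoc <- 0
  st0 <- pcsaft_state(p0, nm_va, 330, eta = 0.4, x = c(0.9, 0.1))
  expect_identical(st0$a_assoc, 0)
  st1 <- pcsaft_state(pp, nm_va, 330, eta = 0.4, x = c(0.9, 0.1))
  expect_lt(st1$a_assoc, 0)
  expect_true(st1$assoc_converged)
})

test_that("analytic Z matches central-difference d(a_res)/d(eta) at random states", {
  set.seed(42)
  for (i in 1:10) {
    T <- runif(1, 280, 420)
    eta <- runif(1, 0.1, 0.55)
    x1 <- runif(1, 0.05, 0.999)
    nm <- c("IBU", sample(polymers, 1))
    h <- 1e-6
    ap <- pcsaft_state(pp, nm, T, eta + h, c(x1, 1 - x1))$a_res
    am <- pcsaft_state(pp, nm, T, eta - h, c(x1, 1 - x1))$a_res
    Zana <- pcsaft_state(pp, nm, T, eta, c(x1, 1 - x1))$Z - 1
    Znum <- eta * (ap - am) / (2 * h)
    expect_equal(Zana, Znum, tolerance = 1e-6)
  }
})

test_that("analytic composition derivatives match a numeric oracle", {
  pr <- asdkit:::saft_pars(pp, nm_va)
  T <- 330
  d <- pr$sigma * (1 - 0.12 * exp(-3 * pr$epsk / T))
  x0 <- c(0.97, 0.03)
  st0 <- pcsaft_state(pp, nm_va, T, 0.45, x0)
  rho <- st0$rho
  ares_at <- function(x) {
    eta <- rho * pi / 6 * sum(x * pr$m * d^3)
    pcsaft_state(pp, nm_va, T, eta, x)$a_res
  }
  for (k in 1:2) {
    h <- 1e-6
    xp <- x0
    xm <- x0
    xp[k] <- xp[k] + h
    xm[k] <- xm[k] - h
    num <- (ares_at(xp) - ares_at(xm)) / (2 * h)
    expect_equal(st0$dadx[k], num, tolerance = 1e-5)
  }
})

test_that("liquid density root is deterministic, dense and pressure-monotone", {
  eta1 <- pcsaft_density(pp, "IBU", 298.15, x = 1, P = 1e5)
  eta2 <- pcsaft_density(pp, "IBU", 298.15, x = 1, P = 1e5)
  expect_identical(eta1, eta2)
  expect_gt(eta1, 0.3)
  expect_lt(eta1, 0.6)
  etas <- vapply(c(1e5, 1e6, 1e7, 1e8), function(P) {
    pcsaft_density(pp, "IBU", 298.15, x = 1, P = P)
  }, numeric(1))
  expect_true(all(diff(etas) > 0))
})

test_that("activity coefficients normalize at pure limits and for twins", {
  lg <- pcsaft_lngamma(pp, nm_va, 330, c(1, 0))
  expect_identical(lg[[1]], 0)
  # two identical components: gamma = 1 at any composition
  twin <- pp[c(1, 1), ]
  twin$name <- c("IBU", "IBU2")
  lg2 <- pcsaft_lngamma(twin, c("IBU", "IBU2"), 330, c(0.3, 0.7))
  expect_equal(unname(lg2), c(0, 0), tolerance = 1e-9)
})

test_that("Gibbs-Duhem consistency holds along a composition path", {
  # sum_i x_i dln(gamma_i)/dx = 0; normalized residual with Richardson
  gd <- function(xa, h) {
    lp <- function(x1) pcsaft_lngamma(pp, nm_va, 330, c(x1, 1 - x1))
    dp <- (lp(xa + h) - lp(xa - h)) / (2 * h)
    c(res = xa * dp[[1]] + (1 - xa) * dp[[2]],
      scale = abs(xa * dp[[1]]) + abs((1 - xa) * dp[[2]]))
  }
  for (xa in c(0.999, 0.99, 0.95, 0.8)) {
    r1 <- gd(xa, 1e-5)
    r2 <- gd(xa, 5e-6)
    rich <- (4 * r2[["res"]] - r1[["res"]]) / 3
    expect_lt(abs(rich) / max(1, r1[["scale"]]), 1e-5)
  }
})

test_that("SLE passes through (x = 1, Tm) and matches the ideal hand value", {
  for (p in polymers) {
    sol <- pcsaft_sle_x(ibu, pp, c("IBU", p), ibu$tm_K)
    expect_identical(sol$x, 1)
  }
  expect_equal(sle_ideal_x(ibu, 298.15), 0.266, tolerance = 1e-3)
  expect_error(pcsaft_sle_x(ibu, pp, nm_va, 360), "Tm")
})

test_that("fixed-point SLE equals the bisection oracle", {
  for (T in c(298.15, 320, 340)) {
    a <- pcsaft_sle_x(ibu, pp, c("IBU", "HPMCAS"), T)$x
    b <- pcsaft_sle_x(ibu, pp, c("IBU", "HPMCAS"), T, method = "bisection")$x
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("k_ij recovery is exact on noise-free synthetic MPD", {
  spec <- synth_spec("pcsaft", list(kij = 0.05), noise_sd = 0, seed = 2)
  mpd <- gen_mpd_quiet(spec, ibu, va64, pp)
  fit <- fit_kij(mpd, ibu, va64, pp)
  expect_lt(abs(fit$params$k_int - 0.05), 0.005)
  expect_lt(fit$aard_pct, 1e-4)
})

test_that("LLE satisfies isoactivity, rejects twins, and brackets the spinodal", {
  r <- pcsaft_lle(pp, nm_va, 320, kij = 0.05)
  expect_true(r$converged)
  expect_lt(r$residual, 1e-8)
  expect_lt(r$x_L1, r$x_L2)
  sp <- r$spinodal
  expect_gte(length(sp), 2)
  expect_lte(r$x_L1, sp[1])
  expect_gte(r$x_L2, sp[length(sp)])
  # identical components never demix
  twin <- pp[c(1, 1), ]
  twin$name <- c("IBU", "IBU2")
  r2 <- pcsaft_lle(twin, c("IBU", "IBU2"), 320)
  expect_false(r2$converged)
})
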