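make_table <- function(method, rows) {
  df <- tibble::as_tibble(rows)
  attr(df, "method") <- method
  df
}

test_that("Fedors delta_t follows sqrt(sum E / sum V)", {
  tab <- make_table("Fedors", list(group = "G", E = 40000, V = 100))
  inv <- tibble::tibble(group = "G", count = 1)
  sp <- solubility_params(inv, tab)
  expect_equal(sp$delta_t, 20)
  # ratio invariance under uniform count scaling
  inv2 <- tibble::tibble(group = "G", count = 7)
  expect_equal(solubility_params(inv2, tab)$delta_t, 20)
  # additivity: two half-groups equal one whole
  tab2 <- make_table("Fedors", list(group = c("a", "b", "c"),
                                    E = c(10000, 10000, 20000),
                                    V = c(50, 50, 100)))
  two <- solubility_params(tibble::tibble(group = c("a", "b"), count = c(1, 1)), tab2)
  one <- solubility_params(tibble::tibble(group = "c", count = 1), tab2)
  expect_equal(two$delta_t, one$delta_t)
})

test_that("HVK components combine per the three-term rule", {
  tab <- make_table("HVK", list(group = c("g1", "g2"),
                                Fd = c(300, 300), Fp = c(500, 500),
                                Eh = c(0, 0), V = c(50, 50)))
  inv <- tibble::tibble(group = c("g1", "g2"), count = c(1, 1))
  sp <- solubility_params(inv, tab)
  expect_equal(sp$delta_d, 600 / 100)
  # delta_p uses sqrt of the sum of squares, not the squared sum
  expect_equal(sp$delta_p, sqrt(2 * 500^2) / 100)
  expect_equal(sp$delta_p, 7.071, tolerance = 1e-3)
  expect_equal(sp$delta_t, sqrt(sp$delta_d^2 + sp$delta_p^2 + sp$delta_h^2))
  # single group, no polar/hbond: delta_t collapses to delta_d
  tab1 <- make_table("HVK", list(group = "g", Fd = 420, Fp = 0, Eh = 0, V = 33.5))
  sp1 <- solubility_params(tibble::tibble(group = "g", count = 2), tab1)
  expect_equal(sp1$delta_d, 420 / 33.5)
  expect_equal(sp1$delta_t, sp1$delta_d)
  expect_error(solubility_params(tibble::tibble(group = "zz", count = 1), tab),
               "absent")
})

test_that("scaling invariance holds for every term except the polar one", {
  # delta_d and delta_h are ratios of count-linear sums; delta_p's
  # root-sum-of-squares numerator makes it covariant with the repeat-unit
  # choice (a known quirk of the combination rule), scaling as 1/sqrt(c)
  for (method in c("HVK", "JB")) {
    tab <- default_group_table(method)
    inv <- default_inventory("IBU")
    sp1 <- solubility_params(inv, tab)
    inv$count <- inv$count * 4
    sp2 <- solubility_params(inv, tab)
    expect_equal(sp1$delta_d, sp2$delta_d, tolerance = 1e-12)
    expect_equal(sp1$delta_h, sp2$delta_h, tolerance = 1e-12)
    expect_equal(sp2$delta_p, sp1$delta_p / 2, tolerance = 1e-12)
    expect_true(sp1$delta_t >= max(sp1$delta_d, sp1$delta_p, sp1$delta_h))
  }
  # Fedors' single-term parameter is fully intensive
  fed <- default_group_table("Fedors")
  inv <- default_inventory("IBU")
  a <- solubility_params(inv, fed)$delta_t
  inv$count <- inv$count * 4
  expect_equal(solubility_params(inv, fed)$delta_t, a, tolerance = 1e-12)
})

test_that("Bagley distance is a symmetric metric with factor-4 weighting", {
  mk <- function(dv, dh) tibble::tibble(method = "HVK", delta_d = dv,
                                        delta_p = 0, delta_h = dh,
                                        delta_t = sqrt(dv^2 + dh^2),
                                        delta_v = dv, V_molar = 100)
  a <- mk(10, 5)
  b <- mk(13, 9)
  expect_equal(bagley_distance(a, b), sqrt(4 * 9 + 16))
  expect_equal(bagley_distance(a, b), 7.2111, tolerance = 1e-4)
  expect_equal(bagley_distance(a, a), 0)
  expect_equal(bagley_distance(a, b), bagley_distance(b, a))
  # triangle inequality over packaged parameter sets
  tab <- default_group_table("JB")
  sps <- lapply(c("IBU", "KOL VA64", "HPMCAS"),
                function(nm) solubility_params(default_inventory(nm), tab))
  d12 <- bagley_distance(sps[[1]], sps[[2]])
  d13 <- bagley_distance(sps[[1]], sps[[3]])
  d23 <- bagley_distance(sps[[2]], sps[[3]])
  expect_lte(d13, d12 + d23 + 1e-12)
  fed <- solubility_params(default_inventory("IBU"), default_group_table("Fedors"))
  expect_error(bagley_distance(fed, fed), "Fedors")
})

test_that("delta-derived chi matches hand arithmetic and scalings", {
  mk <- function(dt) tibble::tibble(method = "Fedors", delta_d = NA_real_,
                                    delta_p = NA_real_, delta_h = NA_real_,
                                    delta_t = dt, delta_v = NA_real_,
                                    V_molar = NA_real_)
  expect_equal(chi_from_delta(mk(18), mk(18), 298.15, 185.84), 0)
  # V0 (delta)^2 / RT with unit bookkeeping: 1 MPa^(1/2) difference
  chi1 <- chi_from_delta(mk(19), mk(18), 298.15, 185.84)
  expect_equal(chi1, 0.0750, tolerance = 1e-3)
  expect_equal(chi_from_delta(mk(19), mk(18), 298.15, 2 * 185.84), 2 * chi1)
  expect_equal(chi_from_delta(mk(20), mk(18), 298.15, 185.84), 4 * chi1,
               tolerance = 1e-12)
})

test_that("screening verdicts follow the 7 / 10 MPa^1/2 rule of thumb", {
  expect_identical(asdkit:::gc_verdict(5), "soluble")
  expect_identical(asdkit:::gc_verdict(-5), "soluble")
  expect_identical(asdkit:::gc_verdict(8.5), "borderline")
  expect_identical(asdkit:::gc_verdict(12), "immiscible")
  scr <- gc_screen("IBU", "KOL VA64", method = "JB")
  expect_true(scr$verdict %in% c("soluble", "borderline", "immiscible"))
  expect_gte(scr$r_av, 0)
  expect_true(is.na(gc_screen("IBU", "EPO", method = "Fedors")$r_av))
})
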