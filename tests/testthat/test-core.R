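test_that("composition conversions match hand arithmetic and round-trip", {
  expect_equal(convert_composition(1, "w", "phi", ibu, va64), 1)
  expect_equal(convert_composition(0, "w", "x", ibu, va64), 0)
  # (0.5/1.11) / ((0.5/1.11) + (0.5/1.22))
  expect_equal(convert_composition(0.5, "w", "phi", ibu, va64), 0.5236,
               tolerance = 1e-4)
  expect_identical(convert_composition(0.37, "w", "w", ibu, va64), 0.37)
  w <- seq(0.01, 0.99, by = 0.07)
  for (to in c("x", "phi")) {
    back <- convert_composition(
      convert_composition(w, "w", to, ibu, va64), to, "w", ibu, va64)
    expect_equal(back, w, tolerance = 1e-12)
  }
  expect_error(convert_composition(1.2, "w", "x", ibu, va64), "fraction")
  expect_error(convert_composition(NaN, "w", "x", ibu, va64), "fraction")
})

test_that("composition conversions are monotone bijections on (0,1)", {
  w <- seq(0.001, 0.999, length.out = 200)
  for (to in c("x", "phi")) {
    out <- convert_composition(w, "w", to, ibu, hpmcas)
    expect_true(all(diff(out) > 0))
    expect_true(all(out > 0 & out < 1))
  }
})

test_that("AARD and ARD follow their definitions and invariances", {
  expect_identical(aard(c(350, 340), c(350, 340)), 0)
  expect_equal(aard(c(350, 340), c(343, 340)), 100 / 2 * 7 / 350)
  expect_equal(ard(100, 105), -5)
  expect_equal(aard(100, 105), 5)
  m <- c(310, 325, 340)
  p <- c(312, 321, 345)
  expect_gte(aard(m, p), abs(ard(m, p)))
  perm <- c(3, 1, 2)
  expect_equal(aard(m[perm], p[perm]), aard(m, p))
  expect_equal(aard(3 * m, 3 * p), aard(m, p))
  expect_error(aard(1:3, 1:2), "length")
  expect_error(aard(c(0, 1), c(1, 1)), "nonzero")
})

test_that("compound registry loads Table-style records with unit conversion", {
  expect_equal(nrow(cmp), 5)
  expect_equal(ibu$tm_K, 75.08 + 273.15)
  expect_equal(ibu$tg_K, -44.68 + 273.15)
  expect_equal(ibu$dhfus, 24680)
  expect_true(all(is.na(cmp$tm_K[cmp$role == "polymer"])))
  expect_equal(molar_volume(ibu), 206.28 / 1.11)
})

test_that("registry round-trips through JSON serialization", {
  path <- withr::local_tempfile(fileext = ".json")
  out <- cmp
  out$tg <- out$tg_K
  out$tm <- out$tm_K
  out$temp_unit <- "K"
  jsonlite::write_json(out[, c("name", "role", "mw", "rho", "tg", "tm",
                               "dhfus", "dcp", "temp_unit")],
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  back <- read_compounds(path)
  expect_equal(back$mw, cmp$mw)
  expect_equal(back$tg_K, cmp$tg_K)
  expect_equal(back$dhfus, cmp$dhfus)
})

test_that("invalid compound records are rejected with context", {
  expect_error(compound("bad", "API", mw = 100, rho = 1, tg = 300, tm = 250,
                        dhfus = 1000), "Tm must exceed Tg")
  expect_error(compound("bad", "API", mw = -1, rho = 1, tg = 300), "Mw")
  expect_error(compound("bad", "API", mw = 100, rho = 1, tg = 300, tm = 350),
               "dHfus")
})

test_that("MPD datasets validate composition range and fit preconditions", {
  expect_error(mpd_dataset(c(0, 0.5), c(340, 345)), "0, 1")
  d <- mpd_dataset(c(0.4, 0.6), c(340, 345))
  expect_error(fh_chi_slope(d, ibu, va64), "at least 3")
  d2 <- mpd_dataset(seq(0.3, 0.9, 0.1), 340 + seq(0.3, 0.9, 0.1),
                    excluded = 1:5)
  expect_error(fh_chi_slope(d2, ibu, va64), "at least 3")
})
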