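# a light FH-only diagram shared across tests
fhm_pd <- fh_model(ibu, va64, A = -2, B = 800)
tg_sb <- fit_tg(tg_dataset(c(0, 1), c(va64$tg_K, ibu$tg_K)), ibu, va64,
                "gt_simha_boyer")
pd_fh <- assemble_phase_diagram(ibu, va64, fh = fhm_pd, tg_fit = tg_sb,
                                w_pct = seq(2, 100, by = 2), n_T = 41)

test_that("FH-only assembly carries SLE, binodal, spinodal and Tg curves", {
  kinds <- unique(pd_fh$curves[, c("curve", "model")])
  expect_setequal(kinds$curve, c("SLE", "binodal", "spinodal", "Tg"))
  expect_equal(nrow(kinds), 4)
})

test_that("every SLE curve passes through the pure-API melting point", {
  d <- mpd_dataset(seq(0.3, 0.95, 0.05),
                   -50 * exp(-0.05 * seq(30, 95, 5)) + ibu$tm_K - 1)
  ky <- ky_fit(d, ibu, mode = "two_step")
  pd <- assemble_phase_diagram(ibu, va64, fh = fhm_pd, ky = ky,
                               w_pct = seq(10, 100, 10), n_T = 5)
  sle <- pd$curves[pd$curves$curve == "SLE", ]
  at100 <- sle[sle$w_pct == 100, ]
  expect_equal(nrow(at100), 2)
  expect_equal(at100$T_K, rep(ibu$tm_K, 2))
})

test_that("grid refinement does not move interpolated curves", {
  pd_a <- assemble_phase_diagram(ibu, va64, fh = fhm_pd,
                                 w_pct = seq(0.5, 100, length.out = 201), n_T = 5)
  pd_b <- assemble_phase_diagram(ibu, va64, fh = fhm_pd,
                                 w_pct = seq(0.5, 100, length.out = 2001), n_T = 5)
  sa <- pd_a$curves[pd_a$curves$curve == "SLE", ]
  sb <- pd_b$curves[pd_b$curves$curve == "SLE", ]
  Ta <- approx(sa$w_pct, sa$T_K, xout = c(20, 50, 80))$y
  Tb <- approx(sb$w_pct, sb$T_K, xout = c(20, 50, 80))$y
  expect_lt(max(abs(Ta - Tb)), 0.05)
})

test_that("region classification is total, consistent and label-ordered", {
  w <- seq(1, 100, length.out = 41)
  Tg <- seq(pd_fh$T_range[1], pd_fh$T_range[2], length.out = 41)
  grid <- expand.grid(w = w, T = Tg)
  labs <- classify_region(pd_fh, grid$w, grid$T, engine = "fh")
  base <- sub(" \\(glassy\\)$", "", labs)
  expect_true(all(base %in% c("stable solution", "supersaturated",
                              "LLE metastable", "LLE unstable")))
  # stable region is a left-contiguous band in w at every temperature
  for (Tv in Tg) {
    lab_T <- base[grid$T == Tv]
    stable <- lab_T == "stable solution"
    if (any(stable)) expect_true(all(stable[seq_len(max(which(stable)))]))
  }
})

test_that("classification respects curve definitions point by point", {
  # just below the SLE curve at a mid load: stable; inside spinodal: unstable
  b <- asdkit:::pd_boundaries(pd_fh, 300, "fh")
  expect_identical(classify_region(pd_fh, b$w_sle - 0.5, 300, "fh"),
                   classify_region(pd_fh, b$w_sle - 0.5, 300, "fh"))
  lab_stable <- classify_region(pd_fh, max(0.5, b$w_sle - 0.5), 300, "fh")
  expect_match(lab_stable, "^stable")
  expect_match(classify_region(pd_fh, mean(b$spin), 300, "fh"), "LLE unstable")
  mid_meta <- (b$bin[2] + b$spin[2]) / 2
  expect_match(classify_region(pd_fh, mid_meta, 300, "fh"), "LLE metastable")
  # glassy flag below the Tg curve
  wlow <- 5
  Tlow <- pd_fh$tg_fun(wlow / 100) - 10
  expect_match(classify_region(pd_fh, wlow, Tlow, "fh"), "glassy")
})

test_that("maximum stable loading behaves like an inverse solubility", {
  expect_equal(max_stable_loading(pd_fh, ibu$tm_K + 1), 100)
  loads <- vapply(c(300, 320, 340), function(T) {
    max_stable_loading(pd_fh, T, "fh")
  }, numeric(1))
  expect_true(all(diff(loads) >= 0)) # UCST: more soluble when hotter
  # agreement with direct SLE inversion to grid tolerance
  b <- asdkit:::pd_boundaries(pd_fh, 320, "fh")
  expect_lt(abs(max_stable_loading(pd_fh, 320, "fh") - min(b$w_sle, b$bin[1])),
            0.5)
  expect_error(max_stable_loading(pd_fh, 1000), "range")
})

test_that("autoplot renders without evaluation errors", {
  p <- autoplot(pd_fh)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)
})
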