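#' Assemble a temperature-composition phase diagram
#'
#' Collects solubility (SLE) curves from any combination of fitted models
#' (Flory-Huggins, Kyeremateng, PC-SAFT), demixing boundaries (binodal and
#' spinodal) from the FH and/or PC-SAFT engines, and a blend-Tg curve, onto
#' a shared drug-load (% w/w) vs temperature canvas. Every SLE curve is
#' anchored at the pure-API melting point (100 % w/w, Tm): the
#' thermodynamic models satisfy this identically and the empirical curve is
#' pinned there, since the melting end-set of the pure drug is a fixed
#' point of the canvas.
#'
#' @param api,poly One-row compound tibbles.
#' @param fh An [fh_model()] with fitted chi(T), or NULL.
#' @param ky A [ky_fit()] result, or NULL.
#' @param pcsaft `list(params =, kij =)` for the PC-SAFT engine, or NULL.
#' @param tg_fit A [fit_tg()] result, or NULL for the Simha-Boyer GT curve.
#' @param w_pct Composition grid, % w/w drug.
#' @param T_range Temperature span of the canvas, K (default 250 K to
#'   Tm + 20 K).
#' @param n_T Temperatures at which demixing boundaries are traced.
#' @return A `phase_diagram` object: elements `pair`, `curves` (tibble:
#'   `curve`, `model`, `w_pct`, `T_K`), `tg_fun`, and region classifiers
#'   used by [classify_region()] / [max_stable_loading()].
#' @export
assemble_phase_diagram <- function(api, poly, fh = NULL, ky = NULL,
                                   pcsaft = NULL, tg_fit = NULL,
                                   w_pct = seq(1, 100, by = 0.5),
                                   T_range = NULL, n_T = 61) {
  if (is.null(fh) && is.null(ky) && is.null(pcsaft)) {
    abort("at least one SLE model is required")
  }
  if (is.null(T_range)) T_range <- c(250, api$tm_K + 20)
  w_pct <- sort(unique(c(w_pct, 100)))
  w <- w_pct / 100
  curves <- list()
  anchor <- function(df) {
    df$T_K[df$w_pct == 100] <- api$tm_K
    df
  }

  if (!is.null(fh)) {
    sle <- fh_sle(fh, w_api = w)
    curves$fh_sle <- anchor(tibble::tibble(curve = "SLE", model = "fh",
                                           w_pct = w_pct, T_K = sle$T_K))
    Tgrid <- seq(T_range[1], T_range[2], length.out = n_T)
    bin <- fh_binodal(fh, Tgrid)
    spin <- fh_spinodal(fh, Tgrid)
    if (nrow(bin)) {
      curves$fh_binodal <- tibble::tibble(
        curve = "binodal", model = "fh",
        w_pct = 100 * phi_to_w(c(bin$phi_lo, rev(bin$phi_hi)), api, poly),
        T_K = c(bin$T_K, rev(bin$T_K)))
    }
    if (nrow(spin)) {
      curves$fh_spinodal <- tibble::tibble(
        curve = "spinodal", model = "fh",
        w_pct = 100 * phi_to_w(c(spin$phi_lo, rev(spin$phi_hi)), api, poly),
        T_K = c(spin$T_K, rev(spin$T_K)))
    }
  }
  if (!is.null(ky)) {
    crv <- ky_curve(ky, x_pct = w_pct)
    curves$ky_sle <- anchor(tibble::tibble(curve = "SLE", model = "kyeremateng",
                                           w_pct = w_pct, T_K = crv$T_K))
  }
  if (!is.null(pcsaft)) {
    params <- pcsaft$params %||% default_pcsaft_params()
    kij <- pcsaft$kij %||% 0
    sle <- pcsaft_sle_curve(api, poly, params, w_api = w, kij = kij,
                            t_lo = max(150, T_range[1] - 50))
    curves$pcsaft_sle <- anchor(tibble::tibble(curve = "SLE", model = "pcsaft",
                                               w_pct = w_pct, T_K = sle$T_K))
    Tgrid <- seq(T_range[2], T_range[1], length.out = n_T)
    lle <- pcsaft_lle_curve(params, c(api$name, poly$name), Tgrid, kij = kij)
    conv <- lle[lle$converged, , drop = FALSE]
    if (nrow(conv)) {
      curves$pcsaft_binodal <- tibble::tibble(
        curve = "binodal", model = "pcsaft",
        w_pct = 100 * x_to_w(c(conv$x_L1, rev(conv$x_L2)), api, poly),
        T_K = c(conv$T_K, rev(conv$T_K)))
    }
    spin_ok <- lle[is.finite(lle$x_sp_lo), , drop = FALSE]
    if (nrow(spin_ok)) {
      curves$pcsaft_spinodal <- tibble::tibble(
        curve = "spinodal", model = "pcsaft",
        w_pct = 100 * x_to_w(c(spin_ok$x_sp_lo, rev(spin_ok$x_sp_hi)), api, poly),
        T_K = c(spin_ok$T_K, rev(spin_ok$T_K)))
    }
  }

  tg_fun <- if (!is.null(tg_fit)) {
    p <- tg_fit$params
    if (!is.null(p$q)) {
      function(wv) tg_kwei(wv, api, poly, k = p$K, q = p$q)
    } else {
      function(wv) tg_gt(wv, api, poly, K = p$K)
    }
  } else {
    function(wv) tg_gt(wv, api, poly)
  }
  curves$tg <- tibble::tibble(curve = "Tg", model = "tg", w_pct = w_pct,
                              T_K = tg_fun(w))

  pd <- list(pair = c(api = api$name, polymer = poly$name), api = api,
             poly = poly, fh = fh, ky = ky, pcsaft = pcsaft,
             tg_fun = tg_fun, curves = dplyr::bind_rows(curves),
             T_range = T_range, cache = new.env(parent = emptyenv()))
  class(pd) <- "phase_diagram"
  pd
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase diagram %s / %s>\n", x$pair["api"], x$pair["polymer"]))
  print(dplyr::count(x$curves, .data$curve, .data$model))
  invisible(x)
}

# SLE solubility limit (w %, possibly > 100 meaning unbounded) at T for an
# engine; binodal/spinodal pair in w % (NULL if none). Cached per (engine, T).
pd_boundaries <- function(pd, T_K, engine) {
  key <- sprintf("%s_%.8f", engine, T_K)
  if (!is.null(pd$cache[[key]])) return(pd$cache[[key]])
  api <- pd$api
  poly <- pd$poly
  out <- list(w_sle = 100, bin = NULL, spin = NULL)
  if (engine == "fh") {
    model <- pd$fh
    if (T_K < api$tm_K) {
      f <- function(p) fh_sle_T(model, p) - T_K
      root <- tryCatch(uniroot(f, c(1e-10, 1), tol = 1e-10)$root,
                       error = function(e) NA_real_)
      out$w_sle <- if (is.na(root)) 0 else 100 * phi_to_w(root, api, poly)
    }
    chi <- fh_chi_of_T(model, T_K)
    sp <- fh_spinodal_phi(model$m, chi)
    if (length(sp) == 2) {
      out$spin <- 100 * phi_to_w(sp, api, poly)
      bn <- fh_binodal_phi(model$m, chi)
      if (!is.null(bn)) out$bin <- 100 * phi_to_w(bn, api, poly)
    }
  } else if (engine == "pcsaft") {
    params <- pd$pcsaft$params %||% default_pcsaft_params()
    kij <- pd$pcsaft$kij %||% 0
    names <- c(api$name, poly$name)
    if (T_K < api$tm_K) {
      sol <- tryCatch(pcsaft_sle_x(api, params, names, T_K, kij),
                      error = function(e) NULL)
      out$w_sle <- if (is.null(sol)) 0 else 100 * x_to_w(sol$x, api, poly)
    }
    lle <- pcsaft_lle(params, names, T_K, kij)
    if (length(lle$spinodal) >= 2) {
      sp <- range(lle$spinodal)
      out$spin <- 100 * x_to_w(sp, api, poly)
    }
    if (lle$converged) {
      out$bin <- 100 * x_to_w(c(lle$x_L1, lle$x_L2), api, poly)
    }
  } else if (engine == "kyeremateng") {
    # numeric inversion of the (monotone) empirical curve
    wg <- seq(0, 100, by = 0.1)
    Ts <- ky_curve(pd$ky, x_pct = wg)$T_K
    below <- which(Ts <= T_K)
    out$w_sle <- if (length(below)) wg[max(below)] else 0
  }
  pd$cache[[key]] <- out
  out
}

#' Classify a point of the phase diagram
#'
#' Region labels follow the standard reading of the diagram: inside the
#' spinodal demixing is spontaneous ("LLE unstable"); between binodal and
#' spinodal phase separation is thermodynamically favored but kinetically
#' hindered ("LLE metastable"); otherwise the blend is a stable solution
#' up to the SLE solubility and supersaturated against the crystal beyond
#' it. A "(glassy)" flag is appended below the blend Tg curve.
#'
#' @param pd A [assemble_phase_diagram()] result.
#' @param w_pct Drug load(s), % w/w.
#' @param T_K Temperature(s), K (recycled against `w_pct`).
#' @param engine `"fh"`, `"pcsaft"` or `"kyeremateng"` (defaults to the
#'   first available thermodynamic engine).
#' @return Character vector of region labels.
#' @export
classify_region <- function(pd, w_pct, T_K, engine = NULL) {
  if (is.null(engine)) {
    engine <- if (!is.null(pd$fh)) "fh"
    else if (!is.null(pd$pcsaft)) "pcsaft" else "kyeremateng"
  }
  n <- max(length(w_pct), length(T_K))
  w_pct <- rep_len(w_pct, n)
  T_K <- rep_len(T_K, n)
  vapply(seq_len(n), function(i) {
    b <- pd_boundaries(pd, T_K[i], engine)
    w <- w_pct[i]
    lab <- if (!is.null(b$spin) && w > b$spin[1] && w < b$spin[2]) {
      "LLE unstable"
    } else if (!is.null(b$bin) && w > b$bin[1] && w < b$bin[2]) {
      "LLE metastable"
    } else if (w <= b$w_sle) {
      "stable solution"
    } else {
      "supersaturated"
    }
    if (T_K[i] < pd$tg_fun(w / 100)) lab <- paste0(lab, " (glassy)")
    lab
  }, character(1))
}

#' Maximum thermodynamically stable drug load at a temperature
#'
#' The largest drug load classified "stable solution" at the given
#' temperature (scanning the canvas composition grid), per engine.
#'
#' @inheritParams classify_region
#' @param T_K Temperature, K.
#' @param w_step Scan resolution, % w/w.
#' @return Drug load, % w/w.
#' @export
max_stable_loading <- function(pd, T_K, engine = NULL, w_step = 0.25) {
  if (T_K < pd$T_range[1] || T_K > pd$T_range[2]) {
    abort("T outside the diagram's temperature range")
  }
  if (T_K >= pd$api$tm_K) return(100)
  w <- seq(w_step, 100, by = w_step)
  lab <- classify_region(pd, w, rep(T_K, length(w)), engine)
  stable <- startsWith(lab, "stable")
  if (!any(stable)) return(0)
  if (all(stable)) return(100)
  w[max(which(cumsum(!stable) == 0))]
}

#' Plot a phase diagram
#'
#' @param object A `phase_diagram`.
#' @param mpd Optional MPD tibble overlaid as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_diagram <- function(object, mpd = NULL, ...) {
  cur <- object$curves[is.finite(object$curves$T_K), ]
  p <- ggplot2::ggplot(cur, ggplot2::aes(x = .data$w_pct, y = .data$T_K - 273.15,
                                         colour = .data$model,
                                         linetype = .data$curve,
                                         group = interaction(.data$model,
                                                             .data$curve))) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "drug load (% w/w)", y = "temperature (°C)",
                  title = sprintf("%s / %s phase diagram", object$pair["api"],
                                  object$pair["polymer"]),
                  colour = "model", linetype = "curve") +
    ggplot2::theme_minimal()
  if (!is.null(mpd)) {
    p <- p + ggplot2::geom_point(
      data = data.frame(w_pct = 100 * mpd$w_api, T_K = mpd$T_K),
      ggplot2::aes(x = .data$w_pct, y = .data$T_K - 273.15),
      inherit.aes = FALSE, shape = 1)
  }
  p
}

#' Plot measured vs fitted values of any fit
#'
#' @param object An `asdkit_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.asdkit_fit <- function(object, ...) {
  df <- data.frame(measured = object$measured, predicted = object$predicted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measured, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(title = sprintf("%s fit (AARD %.3g %%)", object$model,
                                  object$aard_pct),
                  x = "measured", y = "predicted") +
    ggplot2::theme_minimal()
}
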