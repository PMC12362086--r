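#' Lattice volume ratio of a drug-polymer pair
#'
#' m = (Mw_poly / rho_poly) / (Mw_API / rho_API): the molar volume of the
#' polymer relative to the lattice site occupied by the API.
#'
#' @param api,poly One-row compound tibbles.
#' @return Dimensionless volume ratio.
#' @export
#' @examples
#' cmp <- default_compounds()
#' fh_volume_ratio(get_compound(cmp, "IBU"), get_compound(cmp, "KOL VA64"))
fh_volume_ratio <- function(api, poly) {
  molar_volume(poly) / molar_volume(api)
}

#' Flory-Huggins model of a drug-polymer pair
#'
#' Bundles the pure-component records, the lattice volume ratio m and the
#' temperature law of the interaction parameter, chi(T) = A + B/T (A the
#' entropic constant, B the enthalpic coefficient in K). Upper critical
#' solution temperature (UCST) behavior corresponds to A < 0, B > 0:
#' demixing on cooling.
#'
#' @param api,poly One-row compound tibbles; the API needs `tm_K`, `dhfus`.
#' @param A,B chi(T) coefficients.
#' @return An `fh_model` object.
#' @export
fh_model <- function(api, poly, A, B) {
  if (!is.finite(api$tm_K) || !is.finite(api$dhfus)) {
    abort("API needs melting temperature and enthalpy of fusion")
  }
  structure(list(api = api, poly = poly, m = fh_volume_ratio(api, poly),
                 A = A, B = B),
            class = "fh_model")
}

#' @export
print.fh_model <- function(x, ...) {
  cat(sprintf("<FH model %s / %s>  m = %.4g, chi(T) = %.4g + %.4g/T  [%s]\n",
              x$api$name, x$poly$name, x$m, x$A, x$B,
              if (is_ucst(x)) "UCST" else "non-UCST"))
  invisible(x)
}

#' @export
tidy.fh_model <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "m"), estimate = c(x$A, x$B, x$m))
}

is_ucst <- function(model) model$A < 0 && model$B > 0

fh_chi_of_T <- function(model, T_K) model$A + model$B / T_K

#' Per-point interaction parameters from melting-point depression
#'
#' Inverts the Flory-Huggins solid-liquid equilibrium relation at each
#' non-excluded observation:
#' chi = [(-dHfus/R)(1/T - 1/Tm) - ln(phi_API) - (1 - 1/m) phi_poly] /
#' phi_poly^2.
#'
#' @param mpd MPD tibble (see [mpd_dataset()]); `w_api` must be < 1.
#' @param api,poly One-row compound tibbles.
#' @return Tibble: `w_api`, `phi_api`, `phi_poly`, `T_K`, `chi`.
#' @export
fh_chi_points <- function(mpd, api, poly) {
  pts <- mpd[!mpd$excluded, , drop = FALSE]
  if (any(pts$w_api >= 1)) abort("chi is undefined at w_api = 1 (phi_poly = 0)")
  phi <- w_to_phi(pts$w_api, api, poly)
  phi_p <- 1 - phi
  m <- fh_volume_ratio(api, poly)
  chi <- ((-api$dhfus / .R) * (1 / pts$T_K - 1 / api$tm_K) -
            log(phi) - (1 - 1 / m) * phi_p) / phi_p^2
  tibble::tibble(w_api = pts$w_api, phi_api = phi, phi_poly = phi_p,
                 T_K = pts$T_K, chi = chi)
}

#' Single interaction parameter from the depression slope
#'
#' Rearranges the FH melting-point-depression relation so that
#' Y = (-dHfus/R)(1/T - 1/Tm) - ln(phi_API) - (1 - 1/m) phi_poly is linear
#' through the origin in phi_poly^2, and estimates chi as the least-squares
#' slope.
#'
#' @inheritParams fh_chi_points
#' @return An `asdkit_fit` with parameter `chi` and an `r_squared` element.
#' @export
fh_chi_slope <- function(mpd, api, poly) {
  pts <- mpd_active(mpd)
  if (length(unique(pts$w_api)) < 2) abort("degenerate design: one composition")
  phi <- w_to_phi(pts$w_api, api, poly)
  phi_p <- 1 - phi
  m <- fh_volume_ratio(api, poly)
  y <- (-api$dhfus / .R) * (1 / pts$T_K - 1 / api$tm_K) -
    log(phi) - (1 - 1 / m) * phi_p
  xx <- phi_p^2
  chi <- sum(y * xx) / sum(xx^2)
  fitted <- chi * xx
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum(y^2) # through-origin R^2
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  # report deviations on the temperature scale for comparability
  Tm_pred <- fh_sle_T(chi_const_model(api, poly, chi), phi)
  new_fit_report("fh_slope", list(chi = chi), pts$T_K, Tm_pred,
                 extra = list(r_squared = r2, phi_poly_sq = xx, y = y))
}

chi_const_model <- function(api, poly, chi) fh_model(api, poly, A = chi, B = 0)

#' Fit the temperature law chi(T) = A + B/T
#'
#' Ordinary least squares of per-point chi values on 1/T. High-drug-loading
#' points that deviate from linearity can be excluded through the dataset's
#' `excluded` flags (exclusion is explicit and user-driven).
#'
#' @inheritParams fh_chi_points
#' @param min_points Minimum number of usable points (distinct T), default 2.
#' @return An `fh_model` with fitted `A`, `B` plus elements `chi_points`
#'   (the per-point values) and `r_squared`.
#' @export
fh_chi_temperature <- function(mpd, api, poly, min_points = 2) {
  cp <- fh_chi_points(mpd, api, poly)
  if (nrow(cp) < min_points || length(unique(cp$T_K)) < 2) {
    abort("need at least two points with distinct temperatures")
  }
  fit <- lm(chi ~ I(1 / T_K), data = cp)
  A <- unname(coef(fit)[1])
  B <- unname(coef(fit)[2])
  out <- fh_model(api, poly, A = A, B = B)
  out$chi_points <- cp
  out$r_squared <- summary(fit)$r.squared
  out
}

# solve the FH SLE relation for T at given API volume fraction(s)
fh_sle_T <- function(model, phi_api, t_lo = 100) {
  api <- model$api
  vapply(phi_api, function(p) {
    if (p >= 1) return(api$tm_K)
    if (p <= 0) abort("phi_api must be in (0, 1]")
    pp <- 1 - p
    f <- function(T) {
      1 / T - 1 / api$tm_K + (.R / api$dhfus) *
        (log(p) + (1 - 1 / model$m) * pp + fh_chi_of_T(model, T) * pp^2)
    }
    lo <- t_lo
    # bracket extends above Tm: strongly positive chi can elevate the
    # liquidus slightly at high drug load
    hi <- api$tm_K + 60
    flo <- f(lo)
    fhi <- f(hi)
    if (is.nan(flo) || is.nan(fhi) || flo * fhi > 0) {
      abort(sprintf("no SLE root in (%g, %g) K at phi_api = %g", lo, hi, p))
    }
    uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

#' Flory-Huggins solubility (SLE) curve
#'
#' Solves the melting-point-depression relation self-consistently for the
#' solubility temperature at each composition:
#' 1/T = 1/Tm - (R/dHfus) [ln(phi) + (1 - 1/m) phi_p + chi(T) phi_p^2].
#' The pure-API limit returns Tm exactly.
#'
#' @param model An [fh_model()].
#' @param w_api Mass-fraction grid (converted to volume fractions
#'   internally); alternatively give `phi_api`.
#' @param phi_api Optional volume-fraction grid.
#' @return Tibble: `w_api`, `phi_api`, `T_K`.
#' @export
fh_sle <- function(model, w_api = seq(0.05, 1, by = 0.05), phi_api = NULL) {
  if (is.null(phi_api)) {
    phi_api <- w_to_phi(w_api, model$api, model$poly)
  } else {
    w_api <- phi_to_w(phi_api, model$api, model$poly)
  }
  T_K <- fh_sle_T(model, phi_api)
  tibble::tibble(w_api = w_api, phi_api = phi_api, T_K = T_K)
}

#' Gibbs free energy of mixing (FH)
#'
#' g(phi) = Delta_mix G / (RT) = phi ln(phi) + (phi_p / m) ln(phi_p) +
#' chi(T) phi phi_p, with the pure-component limits g(0) = g(1) = 0.
#'
#' @param model An [fh_model()].
#' @param T_K Temperature, K.
#' @param phi_api Composition grid in [0, 1].
#' @return Tibble: `phi_api`, `g`.
#' @export
fh_gibbs <- function(model, T_K, phi_api = seq(0, 1, length.out = 201)) {
  if (T_K <= 0) abort("T must be > 0")
  chi <- fh_chi_of_T(model, T_K)
  g <- vapply(phi_api, function(p) {
    if (p <= 0 || p >= 1) return(0)
    p * log(p) + ((1 - p) / model$m) * log(1 - p) + chi * p * (1 - p)
  }, numeric(1))
  tibble::tibble(phi_api = phi_api, g = g)
}

#' Critical point of the FH model
#'
#' Closed forms: chi_c = (1 + 1/sqrt(m))^2 / 2 and a critical polymer
#' volume fraction of 1 / (1 + sqrt(m)), i.e. phi_c = sqrt(m) / (1 +
#' sqrt(m)) on the API axis used throughout this package. For a UCST
#' chi(T) law the critical temperature solves chi(T_c) = chi_c.
#'
#' @param model An [fh_model()] (or a bare volume ratio via `m`).
#' @param m Optional volume ratio overriding the model.
#' @return List with `phi_c` (API volume fraction), `phi_c_poly`, `chi_c`
#'   and (when resolvable) `T_c`.
#' @export
fh_critical <- function(model = NULL, m = NULL) {
  if (is.null(m)) m <- model$m
  phi_c <- sqrt(m) / (1 + sqrt(m))
  chi_c <- 0.5 * (1 + 1 / sqrt(m))^2
  T_c <- NA_real_
  if (!is.null(model) && model$B != 0) {
    T_c <- model$B / (chi_c - model$A)
    if (!is.finite(T_c) || T_c <= 0) T_c <- NA_real_
  }
  list(phi_c = phi_c, phi_c_poly = 1 - phi_c, chi_c = chi_c, T_c = T_c)
}

# spinodal compositions at a single chi: roots of 1/phi + 1/(m phi_p) = 2 chi
# (a quadratic in phi); empty below the critical point, where the real roots
# either vanish or fall outside (0, 1)
fh_spinodal_phi <- function(m, chi) {
  if (!is.finite(chi) || chi <= 0) return(numeric(0))
  a <- 2 * chi
  b <- -(2 * chi + 1 - 1 / m)
  disc <- b^2 - 4 * a
  if (disc < 0) return(numeric(0))
  r <- sort(c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a)))
  r <- r[r > 0 & r < 1]
  if (length(r) < 2) return(numeric(0))
  r
}

#' Spinodal boundary of the FH model
#'
#' Solves d2 g / d phi^2 = 0, i.e. 1/phi + 1/(m phi_p) - 2 chi(T) = 0 (a
#' quadratic in phi), at each requested temperature. Above the critical
#' point the spinodal is empty.
#'
#' @param model An [fh_model()] with UCST-type chi(T).
#' @param T_K Temperature grid, K.
#' @return Tibble: `T_K`, `phi_lo`, `phi_hi` (rows only where a spinodal
#'   exists).
#' @export
fh_spinodal <- function(model, T_K) {
  rows <- lapply(T_K, function(Tv) {
    r <- fh_spinodal_phi(model$m, fh_chi_of_T(model, Tv))
    if (!length(r)) return(NULL)
    tibble::tibble(T_K = Tv, phi_lo = r[1], phi_hi = r[2])
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- tibble::tibble(T_K = numeric(), phi_lo = numeric(),
                                        phi_hi = numeric())
  out
}

# two-variable Newton for the common tangent, in (log phi_a, log phi_p,b)
# coordinates (phi_p,b = polymer fraction of the API-rich phase, which can
# underflow in direct phi space at deep quenches)
fh_binodal_phi <- function(m, chi, tol = 1e-12, max_iter = 200) {
  sp <- fh_spinodal_phi(m, chi)
  if (!length(sp)) return(NULL)
  crit <- fh_critical(m = m)
  g <- function(p) p * log(p) + ((1 - p) / m) * log(1 - p) + chi * p * (1 - p)
  dg <- function(p) log(p) + 1 - (log(1 - p) + 1) / m + chi * (1 - 2 * p)
  d2g <- function(p) 1 / p + 1 / (m * (1 - p)) - 2 * chi
  # stable right-branch expressions in q = phi_polymer = 1 - phi
  g_b <- function(q, lq) (1 - q) * log1p(-q) + (q / m) * lq + chi * (1 - q) * q
  dg_b <- function(q, lq) log1p(-q) + 1 - (lq + 1) / m + chi * (2 * q - 1)
  # initial guesses: common tangent on the lower convex hull of a coarse
  # grid (log-refined near both axes), bracketing the spinodal
  grid <- sort(unique(c(exp(seq(log(1e-8), log(0.5), length.out = 400)),
                        seq(0.002, 0.998, by = 0.002),
                        1 - exp(seq(log(1e-8), log(0.5), length.out = 400)))))
  gv <- g(grid)
  hull <- grDevices::chull(c(grid, 0, 1), c(gv, max(gv) + 1, max(gv) + 1))
  hx <- sort(grid[hull[hull <= length(grid)]])
  gaps <- diff(hx)
  cand <- which(hx[-length(hx)] < sp[1] & hx[-1] > sp[2])
  if (!length(cand)) return(NULL)
  i <- cand[which.max(gaps[cand])]
  u <- log(hx[i])
  v <- log1p(-hx[i + 1])
  # if the hull end-point saturated at the grid edge, refine the start of v
  # with a 1-D solve of dg(b) = dg(a) in log polymer fraction
  for (it in seq_len(max_iter)) {
    a <- exp(u)
    q <- exp(v) # polymer fraction in the API-rich phase
    F1 <- dg(a) - dg_b(q, v)
    F2 <- (g_b(q, v) - g(a)) - dg(a) * ((1 - q) - a)
    if (max(abs(F1), abs(F2)) < 1e-12) return(c(a, 1 - q))
    # Jacobian in (u, v): da/du = a, db/dv = -q
    d2g_bq <- q / (1 - q) + 1 / m - 2 * chi * q   # d2g(b) * q
    J11 <- d2g(a) * a
    J12 <- d2g_bq
    J21 <- (-d2g(a) * ((1 - q) - a)) * a
    J22 <- (dg_b(q, v) - dg(a)) * (-q)
    det <- J11 * J22 - J12 * J21
    if (!is.finite(det) || det == 0) break
    du <- (F1 * J22 - F2 * J12) / det
    dv <- (J11 * F2 - J21 * F1) / det
    step <- 1
    repeat {
      u2 <- u - step * du
      v2 <- v - step * dv
      ok <- is.finite(u2) && is.finite(v2) && exp(u2) < crit$phi_c &&
        exp(v2) < 1 - crit$phi_c
      if (ok || step < 1e-4) break
      step <- step / 2
    }
    if (!ok) return(NULL)
    conv <- max(abs(u2 - u), abs(v2 - v))
    u <- u2
    v <- v2
    if (conv < tol) return(c(exp(u), 1 - exp(v)))
  }
  NULL
}

#' Binodal (coexistence) boundary of the FH model
#'
#' Common-tangent construction on the mixing free energy: phi_a < phi_c <
#' phi_b with g'(phi_a) = g'(phi_b) and g(phi_b) - g(phi_a) =
#' g'(phi_a)(phi_b - phi_a), solved by a damped two-variable Newton method
#' in logit-type coordinates with spinodal-bracketed initial guesses. The
#' binodal always encloses the spinodal. With `mode = "extremum"` the
#' literal stationary points of g (g' = 0) are returned instead, for
#' comparison.
#'
#' @param model An [fh_model()].
#' @param T_K Temperature grid, K.
#' @param mode `"common_tangent"` (default) or `"extremum"`.
#' @return Tibble: `T_K`, `phi_lo`, `phi_hi`.
#' @export
fh_binodal <- function(model, T_K, mode = c("common_tangent", "extremum")) {
  mode <- match.arg(mode)
  rows <- lapply(T_K, function(Tv) {
    chi <- fh_chi_of_T(model, Tv)
    if (mode == "extremum") {
      r <- fh_extremum_phi(model$m, chi)
    } else {
      r <- fh_binodal_phi(model$m, chi)
    }
    if (is.null(r)) return(NULL)
    tibble::tibble(T_K = Tv, phi_lo = r[1], phi_hi = r[2])
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- tibble::tibble(T_K = numeric(), phi_lo = numeric(),
                                        phi_hi = numeric())
  out
}

# stationary points of g (the printed "first derivative = 0" reading)
fh_extremum_phi <- function(m, chi) {
  sp <- fh_spinodal_phi(m, chi)
  if (!length(sp)) return(NULL)
  dg <- function(p) log(p) + 1 - (log(1 - p) + 1) / m + chi * (1 - 2 * p)
  lo <- tryCatch(uniroot(dg, c(1e-12, sp[1]), tol = 1e-12)$root,
                 error = function(e) NA_real_)
  hi <- tryCatch(uniroot(dg, c(sp[2], 1 - 1e-12), tol = 1e-12)$root,
                 error = function(e) NA_real_)
  if (is.na(lo) || is.na(hi)) return(NULL)
  c(lo, hi)
}
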