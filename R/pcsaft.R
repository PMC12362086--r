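#' Read a PC-SAFT pure-component parameter registry
#'
#' JSON/CSV with fields `name`, `m_seg` (segment number), `sigma` (segment
#' diameter, Angstrom), `eps_k` (dispersion energy / k, K), `eps_assoc_k`
#' (association energy / k, K), `kappa_assoc` (association volume),
#' `n_assoc` (total association-site count; split equally into donors and
#' acceptors, fractional values allowed).
#'
#' @param path `.json` or `.csv` file.
#' @return Parameter tibble.
#' @export
read_pcsaft_params <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- tibble::as_tibble(jsonlite::fromJSON(path, simplifyDataFrame = TRUE))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  need <- c("name", "m_seg", "sigma", "eps_k", "eps_assoc_k", "kappa_assoc",
            "n_assoc")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (any(df$m_seg <= 0 | df$sigma <= 0 | df$eps_k <= 0)) {
    abort("m_seg, sigma, eps_k must be positive")
  }
  if (any(df$kappa_assoc < 0 | df$kappa_assoc >= 1)) {
    abort("kappa_assoc must lie in [0, 1)")
  }
  if (any(df$n_assoc < 0)) abort("n_assoc must be non-negative")
  df
}

#' Built-in PC-SAFT parameters for the ibuprofen case-study compounds
#'
#' @return Parameter tibble (see [read_pcsaft_params()]).
#' @export
default_pcsaft_params <- function() {
  read_pcsaft_params(system.file("extdata", "pcsaft.json", package = "asdkit"))
}

# select rows by name (order preserved) and unpack to the kernel's layout
saft_pars <- function(params, names) {
  idx <- match(names, params$name)
  if (anyNA(idx)) abort(paste0("PC-SAFT parameters missing for: ",
                               paste(names[is.na(idx)], collapse = ", ")))
  p <- params[idx, ]
  list(m = p$m_seg, sigma = p$sigma, epsk = p$eps_k, epsab = p$eps_assoc_k,
       kappa = p$kappa_assoc, nsite = p$n_assoc)
}

# binary interaction parameter: constant or linear in T
kij_value <- function(kij, T_K) {
  if (is.list(kij)) kij$k_int + kij$k_slope * T_K else kij
}

kij_mat <- function(kij, T_K, n) {
  k <- kij_value(kij, T_K)
  mat <- matrix(0, n, n)
  if (n >= 2) mat[1, 2] <- mat[2, 1] <- k
  mat
}

#' Evaluate the PC-SAFT residual Helmholtz energy and compressibility
#'
#' Returns the hard-chain, dispersion and association contributions to the
#' residual Helmholtz energy per molecule (units of kT), the analytic
#' compressibility factor Z = 1 + eta d(a_res)/d(eta), the pressure and the
#' association site fractions, at given temperature, packing fraction and
#' composition.
#'
#' @param params Parameter tibble ([default_pcsaft_params()]).
#' @param names Component names (rows of `params`), API first by convention.
#' @param T_K Temperature, K.
#' @param eta Packing fraction in (0, 0.74).
#' @param x Mole fractions (whole-molecule basis), summing to 1.
#' @param kij Binary interaction parameter: a number, or
#'   `list(k_int =, k_slope =)` for a linear-in-T law.
#' @return List with `a_hc`, `a_disp`, `a_assoc`, `a_res`, `Z`, `P` (Pa),
#'   `rho` (molecules/Angstrom^3), `XA`, `XB`, `dadx`.
#' @export
pcsaft_state <- function(params, names, T_K, eta, x, kij = 0) {
  p <- saft_pars(params, names)
  if (abs(sum(x) - 1) > 0.01) abort("mole fractions must sum to 1")
  pcsaft_state_cpp(T_K, eta, x, p$m, p$sigma, p$epsk, p$epsab, p$kappa,
                   p$nsite, kij_mat(kij, T_K, length(x)))
}

#' Solve the liquid density
#'
#' Deterministic bracketed search for the largest packing-fraction root of
#' P(eta) = P (the liquid branch).
#'
#' @inheritParams pcsaft_state
#' @param P Pressure, Pa (default 1 bar; the condensed-phase results are
#'   insensitive to it).
#' @return Packing fraction eta.
#' @export
pcsaft_density <- function(params, names, T_K, x, P = 1e5, kij = 0) {
  p <- saft_pars(params, names)
  pcsaft_density_cpp(T_K, P, x, p$m, p$sigma, p$epsk, p$epsab, p$kappa,
                     p$nsite, kij_mat(kij, T_K, length(x)))
}

#' Fugacity coefficients at (T, P, x)
#'
#' ln(phi_i) = mu_i^res/kT - ln Z at the solved liquid density, with
#' analytic composition derivatives of the residual Helmholtz energy.
#'
#' @inheritParams pcsaft_density
#' @return List with `lnphi` (per component), `eta`, `rho`, `Z`.
#' @export
pcsaft_lnphi <- function(params, names, T_K, x, P = 1e5, kij = 0) {
  p <- saft_pars(params, names)
  pcsaft_lnphi_cpp(T_K, P, x, p$m, p$sigma, p$epsk, p$epsab, p$kappa,
                   p$nsite, kij_mat(kij, T_K, length(x)))
}

#' Activity coefficients from PC-SAFT
#'
#' gamma_i = phi_i^L(T, P, x) / phi_i^L(T, P, pure i), the symmetric
#' (pure-liquid reference) activity coefficient; gamma_i = 1 at the pure
#' limit by construction.
#'
#' @inheritParams pcsaft_density
#' @return Named numeric vector of ln(gamma_i).
#' @export
pcsaft_lngamma <- function(params, names, T_K, x, P = 1e5, kij = 0) {
  n <- length(x)
  out <- numeric(n)
  mix <- NULL
  for (i in seq_len(n)) {
    if (x[i] == 1) {
      out[i] <- 0
      next
    }
    if (is.null(mix)) mix <- pcsaft_lnphi(params, names, T_K, x, P, kij)
    pure <- pcsaft_lnphi(params, names[i], T_K, 1, P, kij = 0)
    out[i] <- mix$lnphi[i] - pure$lnphi[1]
  }
  setNames(out, names)
}

# ln of the ideal crystalline-solubility right-hand side (gamma = 1)
sle_rhs_ln <- function(api, T_K) {
  if (!is.finite(api$tm_K) || !is.finite(api$dhfus) || !is.finite(api$dcp)) {
    abort("API needs tm_K, dhfus and dcp for SLE")
  }
  -api$dhfus / (.R * T_K) * (1 - T_K / api$tm_K) -
    api$dcp / .R * (1 - api$tm_K / T_K + log(api$tm_K / T_K))
}

#' Ideal crystalline solubility (gamma = 1)
#'
#' @param api One-row compound tibble with `tm_K`, `dhfus`, `dcp`.
#' @param T_K Temperature(s), K.
#' @return Ideal mole-fraction solubility.
#' @export
sle_ideal_x <- function(api, T_K) exp(sle_rhs_ln(api, T_K))

#' PC-SAFT solid-liquid equilibrium: API solubility at a temperature
#'
#' Solves x = (1/gamma_API(x)) exp\[-dHfus/(RT)(1 - T/Tm) - dCp/R (1 - Tm/T
#' + ln(Tm/T))\] by damped fixed-point iteration on ln x, with a bracketed
#' bisection fallback (`method = "bisection"` forces the oracle route).
#'
#' @param api One-row compound tibble (thermo constants).
#' @param params PC-SAFT parameter tibble.
#' @param names Component names, API first.
#' @param T_K Temperature, K (at T = Tm the solution is x = 1 exactly).
#' @param kij Binary interaction parameter (number or linear-in-T list).
#' @param P Pressure, Pa.
#' @param method `"fixed_point"` or `"bisection"`.
#' @return List: `x` (converged mole fraction), `x_ideal`, `converged`,
#'   `iterations`.
#' @export
pcsaft_sle_x <- function(api, params, names, T_K, kij = 0, P = 1e5,
                         method = c("fixed_point", "bisection")) {
  method <- match.arg(method)
  if (T_K > api$tm_K + 1e-9) abort("SLE defined for T <= Tm")
  rhs <- sle_rhs_ln(api, T_K)
  x_ideal <- exp(rhs)
  if (abs(T_K - api$tm_K) < 1e-12) {
    return(list(x = 1, x_ideal = 1, converged = TRUE, iterations = 0L))
  }
  lng <- function(lx) {
    x1 <- exp(lx)
    pcsaft_lngamma(params, names, T_K, c(x1, 1 - x1), P, kij)[1]
  }
  if (method == "fixed_point") {
    lx <- min(rhs, -1e-8)
    ok <- FALSE
    for (it in 1:300) {
      target <- rhs - lng(lx)
      target <- min(target, -1e-12)
      new_lx <- lx + 0.5 * (target - lx)
      if (abs(new_lx - lx) < 1e-12) {
        lx <- new_lx
        ok <- TRUE
        break
      }
      lx <- new_lx
    }
    if (ok) {
      return(list(x = exp(lx), x_ideal = x_ideal, converged = TRUE,
                  iterations = it))
    }
  }
  # bracketed bisection on f(lx) = lx + ln gamma(x) - rhs
  f <- function(lx) lx + lng(lx) - rhs
  lo <- log(1e-8)
  hi <- -1e-12
  flo <- f(lo)
  fhi <- f(hi)
  if (flo * fhi > 0) abort("no SLE solution in (1e-8, 1)")
  for (i in 1:120) {
    mid <- 0.5 * (lo + hi)
    fm <- f(mid)
    if ((flo <= 0) == (fm <= 0)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
    if (hi - lo < 1e-13) break
  }
  list(x = exp(0.5 * (lo + hi)), x_ideal = x_ideal, converged = TRUE,
       iterations = i)
}

# SLE temperature at fixed composition: root of ln(x gamma(x; T)) = rhs(T)
pcsaft_sle_T <- function(api, params, names, x_api, kij = 0, P = 1e5,
                         t_lo = 200) {
  if (x_api >= 1) return(api$tm_K)
  f <- function(T) {
    log(x_api) + pcsaft_lngamma(params, names, T, c(x_api, 1 - x_api), P, kij)[1] -
      sle_rhs_ln(api, T)
  }
  # activity-elevated mixtures (e.g. inside a demixing region) can carry the
  # homogeneous-liquid solubility line slightly above Tm
  hi <- api$tm_K + 30
  fhi <- f(hi)
  flo <- f(t_lo)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
  uniroot(f, c(t_lo, hi), f.lower = flo, f.upper = fhi, tol = 1e-8)$root
}

#' PC-SAFT solubility (SLE) curve
#'
#' Solubility temperature for each drug load on a mass-fraction grid
#' (internally converted to whole-molecule mole fractions). The pure-API
#' point returns Tm exactly.
#'
#' @param api,poly One-row compound tibbles.
#' @param params PC-SAFT parameter tibble.
#' @param w_api Drug mass-fraction grid.
#' @param kij Binary interaction parameter.
#' @param P Pressure, Pa.
#' @param t_lo Lower temperature bound for the root search, K.
#' @return Tibble: `w_api`, `x_api`, `T_K` (NA where no solution above
#'   `t_lo`).
#' @export
pcsaft_sle_curve <- function(api, poly, params, w_api = seq(0.05, 1, 0.05),
                             kij = 0, P = 1e5, t_lo = 200) {
  names <- c(api$name, poly$name)
  x <- w_to_x(w_api, api, poly)
  T_K <- vapply(x, function(xi) {
    pcsaft_sle_T(api, params, names, xi, kij, P, t_lo)
  }, numeric(1))
  tibble::tibble(w_api = w_api, x_api = x, T_K = T_K)
}

#' Molar Gibbs energy of mixing from PC-SAFT
#'
#' g(x)/RT = sum_i x_i (ln x_i + ln gamma_i); used for spinodal detection
#' and as the common-tangent oracle for the LLE solver.
#'
#' @inheritParams pcsaft_lngamma
#' @param x_api Grid of API mole fractions in (0, 1).
#' @return Tibble: `x_api`, `g`.
#' @export
pcsaft_gibbs_mix <- function(params, names, T_K, x_api, P = 1e5, kij = 0) {
  g <- vapply(x_api, function(x1) {
    if (x1 <= 0 || x1 >= 1) return(0)
    lg <- pcsaft_lngamma(params, names, T_K, c(x1, 1 - x1), P, kij)
    x1 * (log(x1) + lg[1]) + (1 - x1) * (log(1 - x1) + lg[2])
  }, numeric(1))
  tibble::tibble(x_api = x_api, g = g)
}

# default composition grid for LLE scans: dense near the pure-API side,
# log-spaced in polymer mole fraction
lle_grid <- function(n = 101) {
  xp <- exp(seq(log(1e-12), log(0.9), length.out = n))
  sort(unique(1 - xp))
}

# spinodal in x: zeros of d(ln a_polymer)/d(x_polymer), located in log
# polymer-fraction coordinates (the demixing region can sit entirely within
# a sliver of mole-fraction space next to pure API)
pcsaft_spinodal_x <- function(params, names, T_K, kij = 0, P = 1e5,
                              n_grid = 121) {
  vp <- seq(log(1e-12), log(0.9), length.out = n_grid)
  lna2 <- vapply(vp, function(v) {
    xp <- exp(v)
    v + pcsaft_lngamma(params, names, T_K, c(1 - xp, xp), P, kij)[2]
  }, numeric(1))
  # d(ln a2)/d(vp); same sign as d(ln a2)/d(xp)
  slope <- diff(lna2) / diff(vp)
  idx <- which(diff(sign(slope)) != 0)
  if (!length(idx)) return(numeric(0))
  h <- 0.25 * (vp[2] - vp[1])
  dfun <- function(v) {
    xs <- exp(c(v - h, v + h))
    ln2 <- vapply(xs, function(xp) {
      log(xp) + pcsaft_lngamma(params, names, T_K, c(1 - xp, xp), P, kij)[2]
    }, numeric(1))
    (ln2[2] - ln2[1]) / (2 * h)
  }
  roots <- vapply(idx, function(i) {
    tryCatch(uniroot(dfun, c(vp[i], vp[i + 2]), tol = 1e-9)$root,
             error = function(e) NA_real_)
  }, numeric(1))
  roots <- roots[is.finite(roots)]
  if (!length(roots)) return(numeric(0))
  sort(1 - exp(roots)) # return as x_API
}

#' PC-SAFT liquid-liquid equilibrium at one temperature
#'
#' Solves the isoactivity conditions x_i^L1 gamma_i^L1 = x_i^L2 gamma_i^L2
#' for both components (L1 = API-poor, L2 = API-rich phase) with a damped
#' Newton method in log polymer-fraction coordinates. Initial guesses come
#' from a common-tangent grid construction bracketing the spinodal; the
#' trivial root is rejected.
#'
#' @inheritParams pcsaft_lngamma
#' @param guess Optional starting pair `c(x_api_L1, x_api_L2)` (used for
#'   continuation in temperature).
#' @param tol Convergence tolerance on the ln-activity residuals.
#' @return List: `T_K`, `x_L1`, `x_L2`, `w_L1`, `w_L2` (needs compound
#'   records for mass conversion: NA here), `residual`, `converged`,
#'   `spinodal` (the x pair, possibly empty).
#' @export
pcsaft_lle <- function(params, names, T_K, kij = 0, P = 1e5, guess = NULL,
                       tol = 1e-10) {
  sp <- pcsaft_spinodal_x(params, names, T_K, kij, P)
  fail <- list(T_K = T_K, x_L1 = NA_real_, x_L2 = NA_real_,
               residual = NA_real_, converged = FALSE, spinodal = sp)
  act <- function(v) { # v = log(x_poly) per phase -> ln-activities
    xp <- exp(v)
    x1 <- 1 - xp
    lg <- pcsaft_lngamma(params, names, T_K, c(x1, xp), P, kij)
    c(log1p(-xp) + lg[1], v + lg[2])
  }
  res_fun <- function(v) act(v[1]) - act(v[2])
  newton <- function(v) {
    r <- tryCatch(res_fun(v), error = function(e) NULL)
    if (is.null(r) || !all(is.finite(r))) return(NULL)
    for (it in 1:80) {
      if (max(abs(r)) < tol) return(list(v = v, r = r))
      J <- matrix(0, 2, 2)
      h <- 1e-6
      for (k in 1:2) {
        vp <- v
        vp[k] <- vp[k] + h
        rp <- tryCatch(res_fun(vp), error = function(e) NULL)
        if (is.null(rp)) return(NULL)
        J[, k] <- (rp - r) / h
      }
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      repeat {
        v2 <- v - lam * step
        ok <- all(is.finite(v2)) && all(v2 < log(0.99)) &&
          v2[1] > v2[2] + 1e-10 # L1 (API-poor) holds more polymer
        if (ok) {
          r2 <- tryCatch(res_fun(v2), error = function(e) NULL)
          ok <- !is.null(r2) && all(is.finite(r2))
        }
        if (ok || lam < 1e-6) break
        lam <- lam / 2
      }
      if (!ok) return(NULL)
      v <- v2
      r <- r2
    }
    if (max(abs(r)) < tol * 100) list(v = v, r = r) else NULL
  }
  sol <- NULL
  if (!is.null(guess)) {
    sol <- newton(log(1 - guess))
  }
  if (is.null(sol)) {
    if (length(sp) < 2) return(fail)
    vp_lo <- log1p(-sp[1])                 # polymer-rich spinodal edge
    vp_hi <- log1p(-sp[length(sp)])        # API-rich spinodal edge
    for (push in c(1, 2, 4, 8)) {          # multi-start straddling the spinodal
      v0 <- c(min(vp_lo + push, log(0.9)), vp_hi - push)
      sol <- newton(v0)
      if (!is.null(sol)) break
    }
  }
  if (is.null(sol)) return(fail)
  x_L1 <- 1 - exp(sol$v[1])
  x_L2 <- 1 - exp(sol$v[2])
  if (abs(sol$v[1] - sol$v[2]) < 1e-4) return(fail) # trivial root
  list(T_K = T_K, x_L1 = min(x_L1, x_L2), x_L2 = max(x_L1, x_L2),
       residual = max(abs(sol$r)), converged = TRUE, spinodal = sp)
}

#' PC-SAFT demixing (binodal + spinodal) curve over a temperature grid
#'
#' Continuation in temperature: each converged binodal pair seeds the next
#' temperature. Non-convergence at a grid temperature is reported, not
#' fatal.
#'
#' @inheritParams pcsaft_lle
#' @param T_grid Temperatures, K (solved in the given order).
#' @return Tibble: `T_K`, `x_L1`, `x_L2`, `x_sp_lo`, `x_sp_hi`,
#'   `converged`.
#' @export
pcsaft_lle_curve <- function(params, names, T_grid, kij = 0, P = 1e5) {
  guess <- NULL
  rows <- lapply(T_grid, function(Tv) {
    r <- pcsaft_lle(params, names, Tv, kij, P, guess = guess)
    if (r$converged) guess <<- c(r$x_L1, r$x_L2)
    sp <- r$spinodal
    tibble::tibble(T_K = Tv, x_L1 = r$x_L1, x_L2 = r$x_L2,
                   x_sp_lo = if (length(sp) >= 2) sp[1] else NA_real_,
                   x_sp_hi = if (length(sp) >= 2) sp[length(sp)] else NA_real_,
                   converged = r$converged)
  })
  dplyr::bind_rows(rows)
}

#' Fit the PC-SAFT binary interaction parameter to MPD data
#'
#' Minimizes the AARD between measured end-set temperatures and the model's
#' SLE temperature at each composition, over k_ij (constant mode) or
#' (k_int, k_slope) (linear-in-T mode). A deterministic coarse grid (step
#' 0.005) is scanned first, then refined locally.
#'
#' @param mpd MPD tibble.
#' @param api,poly One-row compound tibbles.
#' @param params PC-SAFT parameter tibble.
#' @param mode `"constant"` or `"linear"`.
#' @param grid Coarse k_ij grid.
#' @param P Pressure, Pa.
#' @param t_lo Lower temperature bound for SLE roots, K.
#' @return An `asdkit_fit` with parameters `k_int` (and `k_slope`), element
#'   `kij` ready to pass to the curve functions.
#' @export
fit_kij <- function(mpd, api, poly, params, mode = c("constant", "linear"),
                    grid = seq(-0.02, 0.10, by = 0.005), P = 1e5, t_lo = 200) {
  mode <- match.arg(mode)
  pts <- mpd_active(mpd)
  names <- c(api$name, poly$name)
  x <- w_to_x(pts$w_api, api, poly)
  pred_T <- function(kij) {
    vapply(x, function(xi) pcsaft_sle_T(api, params, names, xi, kij, P, t_lo),
           numeric(1))
  }
  obj_k <- function(k) {
    Tp <- pred_T(k)
    if (anyNA(Tp)) return(1e6)
    aard(pts$T_K, Tp)
  }
  vals <- vapply(grid, obj_k, numeric(1))
  if (diff(range(vals)) < 1e-10) {
    warn("flat k_ij objective; data may not constrain k_ij")
  }
  i0 <- which.min(vals)
  lo <- grid[max(1, i0 - 1)]
  hi <- grid[min(length(grid), i0 + 1)]
  ref <- optimize(obj_k, c(lo, hi), tol = 1e-6)
  k_int <- ref$minimum
  if (obj_k(grid[i0]) < ref$objective) k_int <- grid[i0]
  if (mode == "constant") {
    kij <- k_int
    pars <- list(k_int = k_int, k_slope = 0)
  } else {
    obj2 <- function(p) {
      Tp <- pred_T(list(k_int = p[1], k_slope = p[2] * 1e-4))
      if (anyNA(Tp)) return(1e6)
      aard(pts$T_K, Tp)
    }
    opt <- optim(c(k_int, 0), obj2, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-12))
    pars <- list(k_int = opt$par[1], k_slope = opt$par[2] * 1e-4)
    kij <- list(k_int = pars$k_int, k_slope = pars$k_slope)
  }
  Tp <- pred_T(kij)
  new_fit_report("pcsaft_kij", pars, pts$T_K, Tp,
                 extra = list(kij = kij, mode = mode, pair = names))
}
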