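#' Fit the Kyeremateng empirical solubility equation
#'
#' T_s = -A exp(b x) + T_m + C, with x the drug content in % w/w (0-100).
#' Two strategies are supported:
#'
#' * `"one_step"`: C fixed at 0 and b fixed at `b_fixed` (default -0.05, the
#'   value reported as transferable across API-polymer blends); A is the
#'   closed-form least-squares amplitude. With `free_b = TRUE`, A and b are
#'   both fitted with C = 0 (the alternative reading of a one-step fit).
#' * `"two_step"`: stage 1 fits (A, b) with C = 0; stage 2 fits C holding
#'   (A, b). The two stages are then alternated to convergence (coordinate
#'   descent), so a dataset generated by the model itself is recovered
#'   exactly; the residuals after the first pass are recorded in
#'   `stage_residuals`.
#'
#' @param mpd MPD tibble (see [mpd_dataset()]); `w_api` in (0, 1] is
#'   converted to % w/w internally.
#' @param api One-row compound tibble providing T_m.
#' @param mode `"one_step"` or `"two_step"`.
#' @param b_fixed Fixed decay constant for one-step fitting, per % w/w.
#' @param free_b Let b float in one-step mode (C stays 0).
#' @return An `asdkit_fit` with parameters `A` (K), `b` (1/%), `C` (K),
#'   elements `mode`, `frozen`, `tm_K`, `stage_residuals`.
#' @export
#' @examples
#' cmp <- default_compounds()
#' ibu <- get_compound(cmp, "IBU")
#' mpd <- mpd_dataset(seq(0.3, 0.95, 0.05),
#'                    348.23 - 50 * exp(-0.05 * seq(30, 95, 5)))
#' ky_fit(mpd, ibu, mode = "one_step")
ky_fit <- function(mpd, api, mode = c("one_step", "two_step"),
                   b_fixed = -0.05, free_b = FALSE) {
  mode <- match.arg(mode)
  pts <- mpd_active(mpd, min_points = if (mode == "one_step") 2 else 3)
  x <- 100 * pts$w_api
  Ts <- pts$T_K
  tm <- api$tm_K
  if (!is.finite(tm)) abort("API needs a melting temperature")
  if (length(unique(x)) < 2) abort("degenerate data: one composition")

  fit_A <- function(b, C) {
    e <- exp(b * x)
    -sum((Ts - tm - C) * e) / sum(e^2)
  }
  sse <- function(A, b, C) sum((Ts - (-A * exp(b * x) + tm + C))^2)

  if (mode == "one_step" && !free_b) {
    A <- fit_A(b_fixed, 0)
    pars <- list(A = A, b = b_fixed, C = 0)
    frozen <- c("b", "C")
    stage_res <- NULL
  } else {
    # stage 1: (A, b) with C = 0, deterministic start
    fit_Ab <- function(C) {
      start_A <- max(tm - min(Ts), 1e-3)
      obj <- function(p) sse(p[1], p[2], C)
      opt <- optim(c(start_A, -0.05), obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-15))
      # Gauss-Newton polish on (A, b)
      A <- opt$par[1]
      b <- opt$par[2]
      for (i in 1:200) {
        e <- exp(b * x)
        r <- Ts - (-A * e + tm + C)
        Jm <- cbind(-e, -A * x * e)
        step <- tryCatch(solve(crossprod(Jm), crossprod(Jm, r)),
                         error = function(err) NULL)
        if (is.null(step)) break
        A2 <- A + step[1]
        b2 <- b + step[2]
        if (!is.finite(sse(A2, b2, C)) || sse(A2, b2, C) > sse(A, b, C) + 1e-12) break
        conv <- max(abs(step))
        A <- A2
        b <- b2
        if (conv < 1e-13) break
      }
      c(A, b)
    }
    if (mode == "one_step") {  # free_b reading: C stays 0
      ab <- fit_Ab(0)
      pars <- list(A = ab[1], b = ab[2], C = 0)
      frozen <- "C"
      stage_res <- NULL
    } else {
      C <- 0
      ab <- fit_Ab(0)
      stage_res <- list(
        stage1 = Ts - (-ab[1] * exp(ab[2] * x) + tm),
        stage2 = NULL)
      C <- mean(Ts - (-ab[1] * exp(ab[2] * x) + tm))
      stage_res$stage2 <- Ts - (-ab[1] * exp(ab[2] * x) + tm + C)
      # alternate the two stages to convergence
      for (i in 1:500) {
        ab2 <- fit_Ab(C)
        C2 <- mean(Ts - (-ab2[1] * exp(ab2[2] * x) + tm))
        conv <- max(abs(ab2 - ab), abs(C2 - C))
        ab <- ab2
        C <- C2
        if (conv < 1e-12) break
      }
      pars <- list(A = ab[1], b = ab[2], C = C)
      frozen <- character()
    }
  }
  pred <- -pars$A * exp(pars$b * x) + tm + pars$C
  out <- new_fit_report("kyeremateng", pars, Ts, pred,
                        extra = list(mode = mode, frozen = frozen,
                                     tm_K = tm, free_b = free_b,
                                     stage_residuals = stage_res,
                                     x_pct = x))
  out
}

#' Evaluate a Kyeremateng solubility curve
#'
#' @param fit Result of [ky_fit()].
#' @param x_pct Drug content grid, % w/w (0-100).
#' @return Tibble: `x_pct`, `T_K`, `extrapolated` (TRUE below the smallest
#'   observed drug content).
#' @export
ky_curve <- function(fit, x_pct = seq(0, 100, by = 1)) {
  p <- fit$params
  tibble::tibble(
    x_pct = x_pct,
    T_K = -p$A * exp(p$b * x_pct) + fit$tm_K + p$C,
    extrapolated = x_pct < min(fit$x_pct))
}
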