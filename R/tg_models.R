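#' Simha-Boyer estimate of the Gordon-Taylor constant
#'
#' K = (rho_API Tg_API) / (rho_poly Tg_poly), temperatures in Kelvin.
#'
#' @param api,poly One-row compound tibbles.
#' @return Dimensionless K.
#' @export
simha_boyer_K <- function(api, poly) {
  (api$rho * api$tg_K) / (poly$rho * poly$tg_K)
}

#' Gordon-Taylor glass transition of a blend
#'
#' Tg(w) = (w Tg_API + K (1-w) Tg_poly) / (w + K (1-w)); endpoints are the
#' pure-component glass transitions exactly, and Tg is monotone in w for
#' any K > 0.
#'
#' @param w_api Drug mass fraction(s) in [0, 1].
#' @param api,poly One-row compound tibbles.
#' @param K Gordon-Taylor constant (default: Simha-Boyer rule).
#' @return Blend Tg, K.
#' @export
tg_gt <- function(w_api, api, poly, K = simha_boyer_K(api, poly)) {
  if (any(w_api < 0 | w_api > 1)) abort("w_api must be in [0, 1]")
  if (K <= 0) abort("K must be positive")
  wp <- 1 - w_api
  (w_api * api$tg_K + K * wp * poly$tg_K) / (w_api + K * wp)
}

#' Kwei glass transition of a blend
#'
#' Gordon-Taylor term plus the interaction term q w (1-w); q < 0 produces a
#' negative deviation from the GT curve (hydrogen-bond-driven
#' plasticization), q > 0 a positive one. Endpoints are unaffected by q.
#'
#' @inheritParams tg_gt
#' @param k Kwei constant (role of K).
#' @param q Interaction parameter, K.
#' @return Blend Tg, K.
#' @export
tg_kwei <- function(w_api, api, poly, k, q) {
  tg_gt(w_api, api, poly, K = k) + q * w_api * (1 - w_api)
}

#' Fit a glass-transition mixing model
#'
#' `"gt_simha_boyer"` evaluates the parameter-free Gordon-Taylor model with
#' the Simha-Boyer K. `"gt_fitted"` fits K, `"kwei"` fits (k, q). Fits are
#' least squares followed by a direct AARD polish (Nelder-Mead started from
#' the least-squares solution, and for Kwei also from the fitted-GT
#' solution with q = 0), so the nested-model AARD ordering
#' Kwei <= fitted GT <= Simha-Boyer holds by construction.
#'
#' @param tg Tg tibble (see [tg_dataset()]).
#' @param api,poly One-row compound tibbles.
#' @param model `"gt_simha_boyer"`, `"gt_fitted"` or `"kwei"`.
#' @return An `asdkit_fit` with parameters `K` (and `q` for Kwei).
#' @export
fit_tg <- function(tg, api, poly,
                   model = c("gt_simha_boyer", "gt_fitted", "kwei")) {
  model <- match.arg(model)
  w <- tg$w_api
  y <- tg$tg_K
  interior <- sum(w > 0 & w < 1)
  K_sb <- simha_boyer_K(api, poly)
  pred_gt <- function(K) tg_gt(w, api, poly, K)
  pred_kwei <- function(k, q) tg_kwei(w, api, poly, k, q)

  polish <- function(obj, start) {
    # never returns a point worse than `start`
    opt <- if (length(start) == 1) {
      optim(start, obj, method = "Brent", lower = start - 3, upper = start + 3)
    } else {
      optim(start, obj, method = "Nelder-Mead",
            control = list(maxit = 1000, reltol = 1e-14))
    }
    if (opt$value <= obj(start)) opt$par else start
  }

  if (model == "gt_simha_boyer") {
    params <- list(K = K_sb)
    pred <- pred_gt(K_sb)
  } else if (model == "gt_fitted") {
    if (interior < 2) abort("fitting K needs at least 2 interior points")
    sse <- function(lK) sum((y - pred_gt(exp(lK)))^2)
    ls <- optimize(sse, log(c(K_sb * 0.05, K_sb * 20)))$minimum
    ob <- function(lK) aard(y, pred_gt(exp(lK)))
    start <- if (ob(ls) <= ob(log(K_sb))) ls else log(K_sb)
    lK <- polish(ob, start)
    params <- list(K = exp(lK))
    pred <- pred_gt(params$K)
  } else {
    if (interior < 3) abort("fitting (k, q) needs at least 3 interior points")
    gt <- fit_tg(tg, api, poly, "gt_fitted")
    sse <- function(p) sum((y - pred_kwei(exp(p[1]), p[2]))^2)
    ls <- optim(c(log(gt$params$K), 0), sse, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-15))$par
    ob <- function(p) aard(y, pred_kwei(exp(p[1]), p[2]))
    start <- if (ob(ls) <= ob(c(log(gt$params$K), 0))) {
      ls
    } else {
      c(log(gt$params$K), 0)
    }
    p <- polish(ob, start)
    params <- list(K = exp(p[1]), q = p[2])
    pred <- pred_kwei(params$K, params$q)
  }
  out <- new_fit_report(paste0("tg_", model), params, y, pred,
                        extra = list(tg_model = model, w_api = w,
                                     K_simha_boyer = K_sb))
  out
}
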