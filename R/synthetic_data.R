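#' Specification for synthetic DSC-style datasets
#'
#' The raw melting-point-depression and blend-Tg tables behind this kind of
#' study are rarely published, so the package generates stand-ins with a
#' known ground truth: end-set temperatures from a chosen generating model
#' over the usual experimental design (drug loads 30-95 % w/w in 5 % steps)
#' plus additive Gaussian noise. Every fitting stage then has a
#' parameter-recovery test with no external data.
#'
#' @param generator `"fh"` (chi(T) = A + B/T), `"kyeremateng"` (A, b, C) or
#'   `"pcsaft"` (kij); `params` carries the matching named list.
#' @param params Named list of generator parameters: FH `list(A, B)`,
#'   Kyeremateng `list(A, b, C)`, PC-SAFT `list(kij)`.
#' @param compositions Drug mass fractions (default `seq(0.30, 0.95, 0.05)`).
#' @param noise_sd Gaussian noise on end-set temperatures, K (default 0.5,
#'   a typical DSC end-set repeatability).
#' @param seed Integer RNG seed; seeded runs are bit-reproducible.
#' @param tg_params Kwei ground truth for Tg generation, `list(k, q)`.
#' @param noise_sd_tg Noise on Tg values, K.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(generator = c("fh", "kyeremateng", "pcsaft"),
                       params = list(), compositions = seq(0.30, 0.95, 0.05),
                       noise_sd = 0.5, seed = 1L,
                       tg_params = list(k = 0.6, q = -30), noise_sd_tg = 1) {
  generator <- match.arg(generator)
  if (noise_sd < 0 || noise_sd_tg < 0) abort("noise sd must be >= 0")
  if (any(compositions <= 0 | compositions > 1)) {
    abort("compositions must be in (0, 1]")
  }
  structure(list(generator = generator, params = params,
                 compositions = compositions, noise_sd = noise_sd,
                 seed = as.integer(seed), tg_params = tg_params,
                 noise_sd_tg = noise_sd_tg),
            class = "synth_spec")
}

#' Generate a synthetic melting-point-depression dataset
#'
#' Noise-free end-set temperatures come from the exact generating model
#' (FH SLE, Kyeremateng curve, or PC-SAFT SLE); Gaussian noise is added on
#' top. The noise-free curve is checked for monotone depression.
#'
#' @param spec A [synth_spec()].
#' @param api,poly One-row compound tibbles.
#' @param params PC-SAFT parameter tibble (PC-SAFT generator only).
#' @return An MPD tibble with attributes `truth` (the generator parameters)
#'   and `T_true` (noise-free temperatures).
#' @export
generate_mpd <- function(spec, api, poly, params = NULL) {
  w <- spec$compositions
  T_true <- switch(spec$generator,
    fh = {
      gp <- spec$params
      model <- fh_model(api, poly, A = gp$A, B = gp$B)
      fh_sle(model, w_api = w)$T_K
    },
    kyeremateng = {
      gp <- spec$params
      -gp$A * exp(gp$b * 100 * w) + api$tm_K + (gp$C %||% 0)
    },
    pcsaft = {
      if (is.null(params)) params <- default_pcsaft_params()
      gp <- spec$params
      crv <- pcsaft_sle_curve(api, poly, params, w_api = w,
                              kij = gp$kij %||% 0)
      if (anyNA(crv$T_K)) {
        abort("generating model has no SLE solution at some composition")
      }
      crv$T_K
    })
  ord <- order(w)
  if (!all(diff(T_true[ord]) >= -1e-9)) {
    warn("noise-free generating curve is not monotonically depressed in drug load")
  }
  T_obs <- with_seed_(spec$seed, T_true + rnorm(length(w), 0, spec$noise_sd))
  out <- mpd_dataset(w, T_obs, api = api$name, polymer = poly$name)
  attr(out, "truth") <- spec$params
  attr(out, "T_true") <- T_true
  out
}

#' Generate a synthetic glass-transition dataset
#'
#' Kwei-generated Tg values with additive noise at the spec compositions
#' plus the two pure endpoints, which are anchored at the pure-component
#' Tg exactly (no noise at w = 0 or 1).
#'
#' @inheritParams generate_mpd
#' @return A Tg tibble with attribute `truth`.
#' @export
generate_tg <- function(spec, api, poly) {
  w <- sort(unique(c(0, spec$compositions, 1)))
  kq <- spec$tg_params
  tg_true <- tg_kwei(w, api, poly, k = kq$k, q = kq$q)
  noise <- with_seed_(spec$seed + 1L, rnorm(length(w), 0, spec$noise_sd_tg))
  noise[w == 0 | w == 1] <- 0
  out <- tg_dataset(w, tg_true + noise, api = api$name, polymer = poly$name)
  attr(out, "truth") <- kq
  out
}
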