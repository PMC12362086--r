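#' Convert a binary drug-polymer composition between bases
#'
#' Converts between mass fraction (`"w"`), mole fraction (`"x"`) and volume
#' fraction (`"phi"`) of the API in a binary API-polymer blend. Mass/volume
#' conversion uses the true densities, mass/mole conversion the molar
#' masses; all conversions refer to the API component and round-trip to
#' better than 1e-12.
#'
#' @param value Fraction in [0, 1] on the `from` basis.
#' @param from,to One of `"w"`, `"x"`, `"phi"`.
#' @param api,poly One-row compound tibbles (see [compound()]).
#' @return The equivalent fraction on the `to` basis.
#' @export
#' @examples
#' cmp <- default_compounds()
#' ibu <- get_compound(cmp, "IBU")
#' va64 <- get_compound(cmp, "KOL VA64")
#' convert_composition(0.5, "w", "phi", ibu, va64)
convert_composition <- function(value, from = c("w", "x", "phi"),
                                to = c("w", "x", "phi"), api, poly) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (any(!is.finite(value)) || any(value < 0) || any(value > 1)) {
    abort("composition must be a finite fraction in [0, 1]")
  }
  if (from == to) return(value)
  w <- switch(from,
    w = value,
    x = x_to_w(value, api, poly),
    phi = phi_to_w(value, api, poly))
  switch(to,
    w = w,
    x = w_to_x(w, api, poly),
    phi = w_to_phi(w, api, poly))
}

w_to_phi <- function(w, api, poly) {
  (w / api$rho) / (w / api$rho + (1 - w) / poly$rho)
}

phi_to_w <- function(phi, api, poly) {
  (phi * api$rho) / (phi * api$rho + (1 - phi) * poly$rho)
}

w_to_x <- function(w, api, poly) {
  (w / api$mw) / (w / api$mw + (1 - w) / poly$mw)
}

x_to_w <- function(x, api, poly) {
  (x * api$mw) / (x * api$mw + (1 - x) * poly$mw)
}
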