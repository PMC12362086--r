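#' Create a compound thermodynamic record
#'
#' A compound record holds the pure-component properties that drive every
#' model in the package: molar mass, true density, glass transition and (for
#' crystalline drugs) melting end-set, enthalpy of fusion and the
#' liquid-solid heat-capacity step. All temperatures are stored in Kelvin
#' and all energies in J/mol regardless of the input unit.
#'
#' @param name Compound identifier.
#' @param role `"API"` or `"polymer"`.
#' @param mw Molar mass, g/mol.
#' @param rho True density, g/cm^3.
#' @param tg Glass transition temperature.
#' @param tm Melting end-set temperature (APIs only), or `NA`.
#' @param dhfus Molar enthalpy of fusion, J/mol (or kJ/mol with
#'   `energy_unit = "kJ/mol"`), or `NA`.
#' @param dcp Liquid-minus-solid molar heat capacity, J/(mol K), or `NA`.
#' @param temp_unit Unit of `tg`/`tm`: `"K"` or `"C"`.
#' @param energy_unit Unit of `dhfus`: `"J/mol"` or `"kJ/mol"`.
#' @return A one-row tibble with columns `name`, `role`, `mw`, `rho`,
#'   `tg_K`, `tm_K`, `dhfus`, `dcp`.
#' @export
#' @examples
#' compound("IBU", "API", mw = 206.28, rho = 1.11, tg = -44.68, tm = 75.08,
#'          dhfus = 24.68, dcp = 70.91, temp_unit = "C", energy_unit = "kJ/mol")
compound <- function(name, role = c("API", "polymer"), mw, rho, tg,
                     tm = NA_real_, dhfus = NA_real_, dcp = NA_real_,
                     temp_unit = c("K", "C"), energy_unit = c("J/mol", "kJ/mol")) {
  role <- match.arg(role)
  temp_unit <- match.arg(temp_unit)
  energy_unit <- match.arg(energy_unit)
  to_K <- function(x) if (temp_unit == "C") x + 273.15 else x
  tg_K <- to_K(tg)
  tm_K <- to_K(tm)
  if (energy_unit == "kJ/mol" && is.finite(dhfus)) dhfus <- dhfus * 1000
  rec <- tibble::tibble(name = as.character(name), role = role,
                        mw = as.numeric(mw), rho = as.numeric(rho),
                        tg_K = as.numeric(tg_K), tm_K = as.numeric(tm_K),
                        dhfus = as.numeric(dhfus), dcp = as.numeric(dcp))
  validate_compounds(rec)
  rec
}

validate_compounds <- function(df) {
  need <- c("name", "role", "mw", "rho", "tg_K", "tm_K", "dhfus", "dcp")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("missing compound column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df$name)) abort("duplicate compound names")
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    ctx <- paste0(" (row ", i, ", '", r$name, "')")
    if (!is.finite(r$mw) || r$mw <= 0) abort(paste0("Mw must be > 0", ctx))
    if (!is.finite(r$rho) || r$rho <= 0) abort(paste0("density must be > 0", ctx))
    if (!is.finite(r$tg_K) || r$tg_K <= 0) abort(paste0("Tg must be > 0 K", ctx))
    if (is.finite(r$tm_K)) {
      if (r$tm_K <= r$tg_K) abort(paste0("Tm must exceed Tg", ctx))
      if (!is.finite(r$dhfus) || r$dhfus <= 0) {
        abort(paste0("a melting compound needs dHfus > 0", ctx))
      }
    }
  }
  invisible(df)
}

#' Molar volume of a compound
#'
#' @param cmpd One-row compound tibble.
#' @return Molar volume Mw/rho in cm^3/mol.
#' @export
molar_volume <- function(cmpd) cmpd$mw / cmpd$rho

#' Look up one compound in a registry
#'
#' @param compounds Compound tibble (several rows).
#' @param name Compound name.
#' @return The matching one-row tibble.
#' @export
get_compound <- function(compounds, name) {
  hit <- compounds[compounds$name == name, ]
  if (nrow(hit) != 1) abort(paste0("compound '", name, "' not found in registry"))
  hit
}

#' Built-in registry of the ibuprofen case-study compounds
#'
#' Pure-component true density and thermodynamic properties for ibuprofen and
#' the four carrier polymers (Kollidon VA64, Kollidon 17PF, HPMCAS AS-LMP,
#' Eudragit EPO), read from the packaged `compounds.json`.
#'
#' @return A five-row compound tibble (see [compound()]).
#' @export
#' @examples
#' default_compounds()
default_compounds <- function() {
  read_compounds(system.file("extdata", "compounds.json", package = "asdkit"))
}

#' Read a compound registry from JSON or CSV
#'
#' JSON: a list of records with fields `name`, `role`, `mw`, `rho`, `tg`,
#' and optionally `tm`, `dhfus`, `dcp`, `temp_unit` ("K"/"C"), `energy_unit`
#' ("J/mol"/"kJ/mol"). CSV: the same columns. Temperatures are converted to
#' Kelvin and energies to J/mol on ingest.
#'
#' @param path File path (`.json` or `.csv`).
#' @return Compound tibble.
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- tibble::as_tibble(raw)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, ])
    tryCatch(
      compound(r$name, r$role, r$mw, r$rho, r$tg,
               tm = r$tm %||% NA_real_, dhfus = r$dhfus %||% NA_real_,
               dcp = r$dcp %||% NA_real_,
               temp_unit = r$temp_unit %||% "K",
               energy_unit = r$energy_unit %||% "J/mol"),
      error = function(e) abort(paste0("row ", i, ": ", conditionMessage(e)))
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_compounds(out)
  out
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a
}

#' Read a melting-point-depression dataset
#'
#' Expects CSV columns `w_api` (drug mass fraction, in (0, 1]), `T_end`
#' (melting end-set temperature) and optionally `unit` ("K" or "C", default
#' K). Temperatures are converted to Kelvin.
#'
#' @param path CSV path.
#' @param api,polymer Optional identifiers stored as attributes.
#' @param heating_rate Optional heating-rate metadata, K/min.
#' @return An MPD tibble with columns `w_api`, `T_K` and attributes
#'   `api`, `polymer`, `heating_rate`.
#' @export
read_mpd <- function(path, api = NULL, polymer = NULL, heating_rate = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("w_api", "T_end") %in% names(df))) {
    abort("mpd csv needs columns w_api, T_end")
  }
  unit <- if ("unit" %in% names(df)) df$unit else rep("K", nrow(df))
  T_K <- ifelse(toupper(unit) == "C", df$T_end + 273.15, df$T_end)
  mpd_dataset(df$w_api, T_K, api = api, polymer = polymer,
              heating_rate = heating_rate)
}

#' Build a melting-point-depression dataset
#'
#' @param w_api Drug mass fractions, strictly in (0, 1].
#' @param T_K End-set melting temperatures, K.
#' @param api,polymer,heating_rate Metadata.
#' @param excluded Integer indices of points to leave out of fits.
#' @return Tibble with columns `w_api`, `T_K`, `excluded` (logical).
#' @export
mpd_dataset <- function(w_api, T_K, api = NULL, polymer = NULL,
                        heating_rate = NULL, excluded = integer()) {
  if (length(w_api) != length(T_K)) abort("w_api and T_K lengths differ")
  if (any(!is.finite(w_api)) || any(w_api <= 0) || any(w_api > 1)) {
    abort("w_api must be in (0, 1]")
  }
  if (any(!is.finite(T_K)) || any(T_K <= 0)) abort("temperatures must be positive")
  out <- tibble::tibble(w_api = as.numeric(w_api), T_K = as.numeric(T_K),
                        excluded = seq_along(w_api) %in% excluded)
  attr(out, "api") <- api
  attr(out, "polymer") <- polymer
  attr(out, "heating_rate") <- heating_rate
  out
}

mpd_active <- function(mpd, min_points = 3) {
  keep <- mpd[!mpd$excluded, , drop = FALSE]
  if (nrow(keep) < min_points) {
    abort(paste0("at least ", min_points, " non-excluded points required"))
  }
  keep
}

#' Read a glass-transition dataset
#'
#' CSV columns `w_api`, `Tg` and optionally `unit` ("K"/"C").
#'
#' @inheritParams read_mpd
#' @return Tibble with columns `w_api`, `tg_K`.
#' @export
read_tg <- function(path, api = NULL, polymer = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("w_api", "Tg") %in% names(df))) abort("tg csv needs columns w_api, Tg")
  unit <- if ("unit" %in% names(df)) df$unit else rep("K", nrow(df))
  tg_K <- ifelse(toupper(unit) == "C", df$Tg + 273.15, df$Tg)
  tg_dataset(df$w_api, tg_K, api = api, polymer = polymer)
}

#' Build a glass-transition dataset
#'
#' @param w_api Drug mass fractions in [0, 1].
#' @param tg_K Measured glass transitions, K.
#' @param api,polymer Metadata.
#' @return Tibble with columns `w_api`, `tg_K`.
#' @export
tg_dataset <- function(w_api, tg_K, api = NULL, polymer = NULL) {
  if (length(w_api) != length(tg_K)) abort("w_api and tg_K lengths differ")
  if (any(w_api < 0 | w_api > 1)) abort("w_api must be in [0, 1]")
  if (any(!is.finite(tg_K)) || any(tg_K <= 0)) abort("Tg values must be positive")
  out <- tibble::tibble(w_api = as.numeric(w_api), tg_K = as.numeric(tg_K))
  attr(out, "api") <- api
  attr(out, "polymer") <- polymer
  out
}
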