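#' Read a group-contribution coefficient table
#'
#' CSV columns: `group`, `E` (cohesive energy, J/mol; Fedors), `Fd`, `Fp`
#' ((J cm^3)^1/2 / mol), `Eh` (J/mol) and `V` (cm^3/mol). Fedors tables carry
#' `E` and `V`; Hoftyzer-van Krevelen (HVK) and Just-Breitkreutz (JB) tables
#' carry `Fd`, `Fp`, `Eh` and `V`. The packaged tables are illustrative
#' subsets of the published databases; the package defines the schema and
#' the math, not a canonical chemistry.
#'
#' @param path CSV path.
#' @param method `"Fedors"`, `"HVK"` or `"JB"`.
#' @return Tibble with a `method` attribute.
#' @export
read_group_table <- function(path, method = c("Fedors", "HVK", "JB")) {
  method <- match.arg(method)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  if (!all(c("group", "V") %in% names(df))) abort("group table needs group, V")
  if (any(!is.finite(df$V) | df$V == 0)) abort("every group needs nonzero V")
  need <- if (method == "Fedors") "E" else c("Fd", "Fp", "Eh")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("missing column(s) for ", method, ": ",
                                 paste(miss, collapse = ", ")))
  attr(df, "method") <- method
  df
}

#' Packaged group-contribution table
#'
#' @param method `"Fedors"`, `"HVK"` or `"JB"`.
#' @return Group table tibble (see [read_group_table()]).
#' @export
default_group_table <- function(method = c("Fedors", "HVK", "JB")) {
  method <- match.arg(method)
  path <- system.file("extdata",
                      paste0("groups_", tolower(method), ".csv"),
                      package = "asdkit")
  read_group_table(path, method)
}

#' Read a functional-group inventory for one compound
#'
#' CSV columns `group`, `count`. Fractional counts are allowed (copolymer
#' repeat units weighted by monomer ratio). The packaged inventories are
#' illustrative assignments.
#'
#' @param path CSV path.
#' @param compound Identifier stored as attribute.
#' @return Tibble with columns `group`, `count`.
#' @export
read_inventory <- function(path, compound = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  if (!all(c("group", "count") %in% names(df))) {
    abort("inventory needs columns group, count")
  }
  if (any(df$count < 0) || all(df$count == 0)) {
    abort("inventory needs non-negative counts with at least one nonzero")
  }
  attr(df, "compound") <- compound
  df
}

#' Packaged illustrative group inventory
#'
#' @param compound One of `"IBU"`, `"KOL VA64"`, `"KOL 17PF"`, `"HPMCAS"`,
#'   `"EPO"`.
#' @return Inventory tibble.
#' @export
default_inventory <- function(compound) {
  slug <- c("IBU" = "ibu", "KOL VA64" = "kolva64", "KOL 17PF" = "kol17pf",
            "HPMCAS" = "hpmcas", "EPO" = "epo")[[compound]]
  if (is.null(slug)) abort(paste0("no packaged inventory for '", compound, "'"))
  read_inventory(system.file("extdata", paste0("inventory_", slug, ".csv"),
                             package = "asdkit"), compound = compound)
}

match_groups <- function(inv, table) {
  idx <- match(inv$group, table$group)
  if (anyNA(idx)) {
    abort(paste0("group(s) absent from table: ",
                 paste(inv$group[is.na(idx)], collapse = ", ")))
  }
  table[idx, ]
}

#' Solubility parameters from a group inventory
#'
#' Fedors: delta_t = sqrt(sum(n E) / sum(n V)) (MPa^1/2; 1 J/cm^3 = 1 MPa).
#' HVK/JB: delta_d = sum(n Fd)/sum(n V), delta_p = sqrt(sum(n Fp^2))/sum(n V),
#' delta_h = sqrt(sum(n Eh)/sum(n V)), combined as
#' delta_t^2 = delta_d^2 + delta_p^2 + delta_h^2, with the volume-dependent
#' component delta_v^2 = delta_d^2 + delta_p^2 used on Bagley plots.
#'
#' @param inv Inventory tibble (`group`, `count`).
#' @param table Group table from [read_group_table()] /
#'   [default_group_table()].
#' @return One-row tibble: `method`, `delta_d`, `delta_p`, `delta_h`,
#'   `delta_t`, `delta_v` (MPa^1/2; Fedors populates `delta_t` only) and
#'   `V_molar` (cm^3/mol).
#' @export
#' @examples
#' solubility_params(default_inventory("IBU"), default_group_table("HVK"))
solubility_params <- function(inv, table) {
  method <- attr(table, "method")
  if (is.null(method)) abort("table must come from read_group_table()")
  rows <- match_groups(inv, table)
  n <- inv$count
  Vsum <- sum(n * rows$V)
  if (Vsum <= 0) abort("total molar volume must be positive")
  if (method == "Fedors") {
    dt <- sqrt(sum(n * rows$E) / Vsum)
    out <- tibble::tibble(method = method, delta_d = NA_real_,
                          delta_p = NA_real_, delta_h = NA_real_,
                          delta_t = dt, delta_v = NA_real_, V_molar = Vsum)
  } else {
    dd <- sum(n * rows$Fd) / Vsum
    dp <- sqrt(sum(n * rows$Fp^2)) / Vsum
    dh <- sqrt(sum(n * rows$Eh) / Vsum)
    out <- tibble::tibble(method = method, delta_d = dd, delta_p = dp,
                          delta_h = dh, delta_t = sqrt(dd^2 + dp^2 + dh^2),
                          delta_v = sqrt(dd^2 + dp^2), V_molar = Vsum)
  }
  out
}

#' Bagley-plot distance between two parameter sets
#'
#' R_av = sqrt(4 (delta_v,poly - delta_v,API)^2 + (delta_h,poly -
#' delta_h,API)^2), the miscibility distance in the (delta_v, delta_h) plane
#' with the conventional factor-4 weighting.
#'
#' @param api,poly One-row tibbles from [solubility_params()] (HVK or JB;
#'   Fedors has no components and is rejected).
#' @return Distance in MPa^1/2.
#' @export
bagley_distance <- function(api, poly) {
  if (api$method != poly$method) abort("parameter sets from different methods")
  if (api$method == "Fedors") {
    abort("Bagley distance needs component parameters (HVK/JB), not Fedors")
  }
  sqrt(4 * (poly$delta_v - api$delta_v)^2 + (poly$delta_h - api$delta_h)^2)
}

#' Flory-Huggins interaction parameter from solubility parameters
#'
#' chi = V0 (delta_API - delta_poly)^2 / (R T), dimensionless, with delta in
#' MPa^1/2 and the lattice-site volume V0 in cm^3/mol.
#'
#' @param api,poly Parameter sets from [solubility_params()].
#' @param T_K Temperature, K.
#' @param V0 Lattice site volume, cm^3/mol (conventionally the molar volume
#'   of the smaller molecule, i.e. the API).
#' @return chi (dimensionless).
#' @export
chi_from_delta <- function(api, poly, T_K, V0) {
  if (!is.finite(T_K) || T_K <= 0) abort("T must be > 0")
  if (!is.finite(V0) || V0 <= 0) abort("V0 must be > 0")
  ddelta <- api$delta_t - poly$delta_t
  # (MPa^1/2)^2 = 1e6 Pa; V0 cm^3/mol = 1e-6 m^3/mol
  V0 * 1e-6 * (ddelta^2 * 1e6) / (.R * T_K)
}

#' Screen an API-polymer pair by group contribution
#'
#' Computes the signed total-parameter difference (API minus polymer), the
#' Bagley distance (HVK/JB only), a delta-derived chi at a reference
#' temperature, and a verdict from the |d delta_t| rule of thumb: below
#' 7 MPa^1/2 likely soluble, above 10 MPa^1/2 likely immiscible, borderline
#' in between.
#'
#' @param api_name,poly_name Compound identifiers with packaged inventories,
#'   or supply `api_inv`/`poly_inv` directly.
#' @param method `"Fedors"`, `"HVK"` or `"JB"`.
#' @param T_K Reference temperature for chi, K.
#' @param compounds Compound registry (for the default lattice volume
#'   V0 = Mw/rho of the API).
#' @param api_inv,poly_inv Optional explicit inventories.
#' @param table Optional explicit group table.
#' @param V0 Optional lattice site volume, cm^3/mol.
#' @return One-row tibble: `api`, `polymer`, `method`, `delta_t_api`,
#'   `delta_t_poly`, `delta_delta_t`, `r_av`, `chi_gc`, `verdict`.
#' @export
#' @examples
#' gc_screen("IBU", "KOL VA64", method = "JB")
gc_screen <- function(api_name, poly_name, method = c("Fedors", "HVK", "JB"),
                      T_K = 298.15, compounds = default_compounds(),
                      api_inv = NULL, poly_inv = NULL, table = NULL,
                      V0 = NULL) {
  method <- match.arg(method)
  if (is.null(table)) table <- default_group_table(method)
  if (is.null(api_inv)) api_inv <- default_inventory(api_name)
  if (is.null(poly_inv)) poly_inv <- default_inventory(poly_name)
  sp_a <- solubility_params(api_inv, table)
  sp_p <- solubility_params(poly_inv, table)
  dd <- sp_a$delta_t - sp_p$delta_t
  r_av <- if (method == "Fedors") NA_real_ else bagley_distance(sp_a, sp_p)
  if (is.null(V0)) V0 <- molar_volume(get_compound(compounds, api_name))
  chi <- chi_from_delta(sp_a, sp_p, T_K, V0)
  tibble::tibble(api = api_name, polymer = poly_name, method = method,
                 delta_t_api = sp_a$delta_t, delta_t_poly = sp_p$delta_t,
                 delta_delta_t = dd, r_av = r_av, chi_gc = chi,
                 verdict = gc_verdict(dd))
}

gc_verdict <- function(delta_delta_t) {
  a <- abs(delta_delta_t)
  dplyr::case_when(a < 7 ~ "soluble", a <= 10 ~ "borderline",
                   TRUE ~ "immiscible")
}
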