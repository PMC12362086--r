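# shared fixtures: the packaged registries and frequently used records
cmp <- default_compounds()
ibu <- get_compound(cmp, "IBU")
va64 <- get_compound(cmp, "KOL VA64")
pf17 <- get_compound(cmp, "KOL 17PF")
hpmcas <- get_compound(cmp, "HPMCAS")
epo <- get_compound(cmp, "EPO")
pp <- default_pcsaft_params()
polymers <- c("KOL VA64", "KOL 17PF", "HPMCAS", "EPO")

# generators can warn about non-monotone noise-free curves (slight liquidus
# elevation at high drug load is genuine for strongly positive chi)
gen_mpd_quiet <- function(...) suppressWarnings(generate_mpd(...))

# brute-force common-tangent oracle: lower convex hull of g(phi) on a fine
# uniform grid; returns the end-points of the largest non-convex gap
hull_tangent_oracle <- function(g, step = 1e-5) {
  x <- seq(step, 1 - step, by = step)
  y <- g(x)
  h <- grDevices::chull(c(x, 0, 1), c(y, max(y) + 1, max(y) + 1))
  hx <- sort(x[h[h <= length(x)]])
  i <- which.max(diff(hx))
  c(hx[i], hx[i + 1])
}
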