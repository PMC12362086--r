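---
title: "Modeling drug–polymer solubility and miscibility for amorphous solid dispersions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug-polymer solubility and miscibility for amorphous solid dispersions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdkit)
```

## The problem

An amorphous solid dispersion (ASD) keeps a poorly soluble crystalline drug
molecularly dispersed in an amorphous polymer matrix. Its viability hinges on
two thermodynamic questions: how much drug the polymer can *dissolve*
(solid–liquid equilibrium, SLE — the solubility curve) and over what
composition range drug and polymer remain *miscible* as a single amorphous
phase (liquid–liquid equilibrium, LLE — binodal and spinodal). `asdkit`
implements the complementary model families practitioners use to answer
these from differential-scanning-calorimetry (DSC) style data, and assembles
them into annotated temperature–composition phase diagrams. The worked
system is ibuprofen (IBU) with four carrier polymers (Kollidon VA64,
Kollidon 17PF, HPMCAS AS-LMP, Eudragit EPO); the pure-component property and
PC-SAFT parameter registries ship with the package
(`default_compounds()`, `default_pcsaft_params()`).

All temperatures are stored in Kelvin and all energies in J/mol; registry
loaders convert °C and kJ/mol on ingest. Densities are treated as
temperature-independent single pycnometer values.

## Group-contribution screening

Fedors, Hoftyzer–van Krevelen (HVK) and Just–Breitkreutz (JB) tables
estimate solubility parameters from functional-group counts:
$\delta_t = \sqrt{\sum n_iE_i/\sum n_iV_i}$ (Fedors) or the three-component
form $\delta_d=\Sigma F_d/\Sigma V$, $\delta_p=\sqrt{\Sigma F_p^2}/\Sigma V$,
$\delta_h=\sqrt{\Sigma E_h/\Sigma V}$ with
$\delta_t^2=\delta_d^2+\delta_p^2+\delta_h^2$. Screening uses the
$|\Delta\delta_t| < 7\,\mathrm{MPa^{1/2}}$ rule of thumb (immiscible beyond
10), the Bagley distance
$R_{av}=\sqrt{4\Delta\delta_v^2+\Delta\delta_h^2}$, and the
$\delta$-derived interaction parameter
$\chi = V_0(\Delta\delta_t)^2/RT$ with the lattice volume $V_0$ defaulting
to the API molar volume (the conventional choice of sizing the lattice site
by the smaller molecule; it is an explicit argument).

Two caveats are deliberate design choices. First, the packaged group tables
and per-compound inventories are clearly labeled **illustrative**: the
package defines the schema and the arithmetic, not a canonical fragment
chemistry, and users should substitute their own curated tables for
decisions. Second, the polar term $\delta_p$ is *not* invariant under
uniform scaling of group counts (its numerator is a root-sum-of-squares);
this is a property of the published combination rule, so the repeat-unit
basis chosen for a polymer matters and copolymers are evaluated per
averaged repeat unit with fractional counts.

## Flory–Huggins analysis of melting-point depression

The end-set melting temperature of a drug–polymer blend obeys

$$\frac{1}{T}-\frac{1}{T_m} = -\frac{R}{\Delta_{fus}H}\left[\ln\phi +
\left(1-\tfrac1m\right)(1-\phi) + \chi (1-\phi)^2\right],$$

with $\phi$ the drug volume fraction and $m$ the polymer/drug molar-volume
ratio. Three estimators are provided: per-point inversion
(`fh_chi_points()`), the pooled slope of the rearranged relation against
$(1-\phi)^2$ (`fh_chi_slope()`), and the temperature law $\chi = A + B/T$
fitted by OLS on $1/T$ (`fh_chi_temperature()`; $A<0, B>0$ flags UCST
behavior). Outlier exclusion (e.g. the viscosity plateau at high polymer
content) is explicit and user-driven through the dataset's `excluded`
flags — there is no automatic outlier rejection, mirroring how such points
are handled in practice.

The mixing free energy uses the standard combinatorial form
$g = \phi\ln\phi + \frac{1-\phi}{m}\ln(1-\phi) + \chi\phi(1-\phi)$ (one
printed source form duplicates the first term; the standard form is the one
consistent with the pure-component limits and the common-tangent usage).
The spinodal is the quadratic root of $g''=0$; the binodal uses the common
tangent (equal chemical potentials), solved by a damped two-variable Newton
method in $(\log\phi_a, \log\phi_{p,b})$ coordinates, because at deep
quenches the polymer fraction of the drug-rich phase underflows ordinary
$\phi$ coordinates. Initial guesses come from a convex-hull common-tangent
construction on a coarse grid; the literal "$g'=0$" reading is available as
`fh_binodal(mode = "extremum")` for comparison. Closed forms
$\chi_c = \tfrac12(1+1/\sqrt m)^2$ and critical polymer fraction
$1/(1+\sqrt m)$ anchor the tests. Root-finding tolerances are $10^{-10}$ on
$T$ and $\phi$ with deterministic bracketing.

One consequence of the model worth knowing: for strongly positive $\chi$ and
large $m$, the relation predicts a slight melting-point *elevation* near
pure drug (the bracketed sum is $\approx (1-\phi)(\chi(1-\phi) - 1/m) > 0$),
so solubility-temperature roots are bracketed up to $T_m + 60$ K and the
generator's monotone-depression check is a warning, not an error.

## Kyeremateng empirical fitting

$T_s = -A e^{bx} + T_m + C$, with $x$ the drug content in **% w/w (0–100)**
— the transferable decay constant $b \approx -0.05$ is only meaningful on
that scale, so the unit is fixed and documented. "One-step" fixes
$b = -0.05$, $C = 0$ (amplitude $A$ in closed form; `free_b = TRUE` gives
the alternative reading with $b$ floating). "Two-step" fits $(A, b)$ with
$C = 0$, then $C$ holding $(A, b)$; the pair of stages is iterated to
convergence (coordinate descent), which preserves the staged structure while
making the fit exact on data the model itself generated. Initialization is
deterministic ($A_0 = T_m - \min T_s$, $b_0 = -0.05$, $C_0 = 0$). $C$ is
reported as a fitting parameter only — its sign is printed but no physical
interpretation is attached. Points are equally weighted.

## PC-SAFT equation of state

The engine sums hard-chain, dispersion and association contributions to the
residual Helmholtz energy, with the standard universal dispersion constants,
Boublík–Mansoori hard-sphere mixtures, and Wertheim first-order association.
Conventions: $\sigma_{ij}=(\sigma_i+\sigma_j)/2$,
$\epsilon_{ij}=\sqrt{\epsilon_i\epsilon_j}(1-k_{ij}(T))$ with
$k_{ij}(T)=k_{int}+k_{slope}T$ (both constant and linear modes exposed);
cross-association by arithmetic-mean energy and geometric-mean volume with
the Wolbach–Sandler $\sigma$ correction, so induced association is active
when only one partner self-associates. The total site count $N^{assoc}$ is
split equally into donors and acceptors (fractional halves allowed) — the
source parameter sets do not state the split, so it is isolated in one
place and configurable in the parameter table. Polymers are single
pseudo-components at their tabulated $M_w$; mole fractions are
whole-molecule based; the reference pressure is 1 bar everywhere
(condensed-phase results are insensitive); below $T_g$ the subcooled liquid
is the analytic continuation of the EOS, with no glass correction.

The kernel (C++): association site fractions are solved by damped
successive substitution to $10^{-12}$; the compressibility factor is fully
analytic, using the stationarity of the association free energy in the site
fractions (so only the explicit density dependence contributes); fugacity
coefficients use analytic composition derivatives of $a^{res}$ — an early
numeric-derivative version lost four digits of Gibbs–Duhem consistency
exactly where SLE operates (polymer mole fractions of $10^{-3}$ and below),
which motivated the analytic route. The liquid density is the largest
packing-fraction root of $P(\eta)=P$ in $(0, 0.74)$, found by a
deterministic descending scan plus bisection.

Solubility solves $x\gamma(x) = \exp[-\Delta_{fus}H/RT(1-T/T_m) -
\Delta C_p/R(1-T_m/T+\ln(T_m/T))]$ by damped fixed-point iteration on
$\ln x$ with a bisection fallback (and as a test oracle). LLE solves the
two isoactivity equations by damped Newton in log polymer-fraction
coordinates with multi-starts straddling the spinodal; the spinodal itself
is located as the zero of $\partial\ln a_{poly}/\partial x$ in log
composition — in these systems the demixing region can occupy a sliver of
mole-fraction space next to pure drug (mass fractions tell the real story),
and linear-in-$x$ curvature scans cannot see it. $k_{ij}$ fitting minimizes
the AARD between measured end-sets and model SLE temperatures over a
deterministic coarse grid (step 0.005) with local refinement.

## Glass-transition models

Gordon–Taylor $T_g = (wT_{g,1}+K(1-w)T_{g,2})/(w+K(1-w))$ with $K$ either
from the Simha–Boyer rule $K = \rho_1T_{g,1}/\rho_2T_{g,2}$ (Kelvin
mandatory; implemented exactly in the printed drug-in-numerator form) or
fitted; Kwei adds $q\,w(1-w)$. Because the models are nested
(Simha–Boyer GT ⊂ fitted GT ⊂ Kwei) their fit quality should be ordered,
and the package guarantees it: fits are least squares followed by a direct
AARD polish (Nelder–Mead that never accepts a point worse than its start,
with Kwei started from the fitted-GT solution at $q=0$). AARD is the
package's common accuracy metric, $100/N\sum|T_{meas}-T_{pred}|/T_{meas}$;
ARD is its signed companion (the two printed definitions coincide, so the
signed reading is adopted for ARD, else the second metric is redundant).

## Synthetic data: what it emulates and what it does not

The raw melting-point-depression and blend-$T_g$ tables behind studies of
this kind are typically unpublished, so `generate_mpd()` / `generate_tg()`
produce stand-ins with known ground truth: end-set temperatures from an
exact generating model (FH $\chi(T)$, Kyeremateng, or PC-SAFT at a chosen
$k_{ij}$) over the usual experimental design — drug loads 0.30–0.95 w/w in
0.05 steps — plus additive Gaussian noise, 0.5 K by default (typical DSC
end-set repeatability); blend $T_g$ comes from a Kwei ground truth with
1 K noise and exact pure-component endpoints. Seeded runs are
bit-reproducible and leave the caller's RNG state untouched.

These generators emulate the *statistical* structure of DSC data, not its
physics: no heat-flow signals, no heating-rate or viscosity artifacts (the
high-polymer-content plateau must be injected by hand and handled via the
`excluded` mechanism), no composition-dependent $\chi$, and noise is
homoscedastic Gaussian. Passing parameter-recovery tests therefore
demonstrates that the estimators are correct and stable under realistic
noise — not that any particular model is the true data-generating process
for a real formulation.

A practical observation from these tests: the per-point $\chi$-vs-$1/T$
fit is extremely noise-sensitive (0.3 K of end-set noise can destroy the
linear correlation and even flip the apparent UCST signature), while the
pooled slope estimator is robust. This mirrors the point-exclusion
practice in the experimental literature and is why both estimators are
exposed.

## Phase-diagram assembly

`assemble_phase_diagram()` puts every fitted SLE model, the FH and/or
PC-SAFT demixing boundaries, and a blend-$T_g$ curve on a shared
drug-load (% w/w) vs temperature canvas — FH's $\phi$ and PC-SAFT's $x$ are
converted at the boundary. Every SLE curve is anchored at
(100 % w/w, $T_m$): the thermodynamic models satisfy this identically,
and the empirical Kyeremateng curve is pinned there because the pure-drug
melting end-set is a fixed point of the canvas (the raw `ky_curve()` is
not anchored). The region classifier is a total function: inside the
spinodal → "LLE unstable"; between binodal and spinodal → "LLE metastable";
otherwise stable solution up to the SLE solubility and supersaturated
beyond it, with a "(glassy)" flag below the blend $T_g$. The
"$T_g - 50$ K" storage rule is left as an optional annotation only.
`max_stable_loading()` scans the canvas for the largest stable drug load
at a temperature, per engine.

## Problem sizes and numerical defaults

Default canvases use 199 composition points and 41–61 boundary
temperatures; simulation studies in the test suite use 100–200 replicates
for the FH slope estimator and 50 for $k_{ij}$ recovery — sizes chosen so
the full suite exercises every estimator at meaningful replication while
remaining comfortably interactive. Key tolerances: composition round-trips
$10^{-12}$; association fractions $10^{-12}$; FH roots $10^{-10}$; SLE
fixed point $10^{-12}$ on $\ln x$; LLE isoactivity residuals $10^{-10}$
(accepted below $10^{-8}$); EOS consistency (analytic vs numeric volume
derivative) verified to $10^{-6}$ relative.

## Known limitations

No composition dependence of $\chi$; no vapor–liquid equilibrium, moisture
or ternary systems; polymers are homosegment pseudo-components (no
copolymer PC-SAFT); no kinetic or stability-time modeling; no DSC
thermogram parsing (inputs are reduced end-set/$T_g$ tables); no
SMILES-based fragmentation for the group-contribution module. The printed
group-contribution outputs depend on the illustrative tables and are not
regression targets.

## A worked example

```{r, eval = FALSE}
cmp <- default_compounds()
ibu <- get_compound(cmp, "IBU")
va64 <- get_compound(cmp, "KOL VA64")

spec <- synth_spec("fh", list(A = -2, B = 800), noise_sd = 0.05, seed = 7)
mpd <- generate_mpd(spec, ibu, va64)

mpd$excluded[mpd$w_api > 0.8] <- TRUE # high loads destabilize the 1/T fit
fh <- fh_chi_temperature(mpd, ibu, va64)
ky <- ky_fit(mpd, ibu, mode = "two_step")
tg <- fit_tg(generate_tg(spec, ibu, va64), ibu, va64, "kwei")

pd <- assemble_phase_diagram(ibu, va64, fh = fh, ky = ky,
                             pcsaft = list(params = default_pcsaft_params(),
                                           kij = 0.05),
                             tg_fit = tg)
classify_region(pd, w_pct = 30, T_K = 298.15)
max_stable_loading(pd, 298.15, engine = "pcsaft")
autoplot(pd, mpd = mpd)
```
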