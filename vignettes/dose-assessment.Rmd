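---
title: "From gamma peaks to dietary dose and risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gamma peaks to dietary dose and risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seadose)
```

`seadose` models the pathway from radioactivity and trace metals in
marine fish to the committed dose, cancer risk and metal exposure of the
population eating them. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not demonstrate.

## Activity quantification under secular equilibrium

²²⁶Ra and ²³²Th emit no usable gamma lines themselves at environmental
activities; after 6–8 weeks of sealed ingrowth their short-lived progeny
(²¹⁴Pb/²¹⁴Bi for the radium chain; ²¹²Pb/²⁰⁸Tl/²²⁸Ac for the thorium
chain) reach secular equilibrium, so a progeny line activity equals the
parent activity. The bundled decay table carries thirteen lines of which
six strong, interference-free ones carry a `primary_flag` and are used
for quantification by default: 351.9 and 609.3 keV (radium chain), 238.6,
583.2 and 911.2 keV (thorium chain), 1460.8 keV (⁴⁰K).

For each peak, the activity concentration is
$A = N / (t\,\varepsilon(E)\,P_\gamma\,b\,m)$ with $N$ the net peak
area, $t$ the live time (the survey used 86,400 s per sample), $P_\gamma$
the emission intensity, $b$ a chain-branch multiplier and $m$ the dry
mass. Two genuinely open choices:

* **Combining multiple lines of one chain.** The combination rule is not
  dictated by the measurement model; we use the inverse-variance weighted
  mean, the standard spectrometry estimator (minimum-variance unbiased
  under independent Gaussian errors). A plain mean is available when
  uncertainties are absent. The combined value provably lies within the
  range of the inputs and its uncertainty never exceeds the smallest
  input uncertainty — both are enforced by property tests.
* **The 583.2 keV ²⁰⁸Tl line.** Published $P_\gamma$ values for this line
  (85.0%) are per ²⁰⁸Tl decay; only 35.94% of the ²³²Th chain passes
  through ²⁰⁸Tl. Whether a tabulated intensity is already
  branch-corrected varies between compilations, so the default keeps
  $b = 1$ (consistent with treating the tabulated value as
  chain-referenced) and a config toggle `apply_tl208_branch: true`
  applies the 0.3594 branch for users whose decay data are
  nuclide-referenced.

The efficiency curve is fitted as a polynomial of $\ln\varepsilon$
against $\ln E$ — the parameterisation in which HPGe efficiency curves
are closest to low-order polynomials — by unweighted least squares
(`stats::lsfit` on the Vandermonde matrix). Default order 4 for a
multi-nuclide calibration, capped below the number of distinct energies;
evaluation outside the calibration range errors unless extrapolation is
explicitly allowed, and then still warns. Detection capability uses the
Currie 95%-confidence expression
$\mathrm{MDA} = (2.71 + 4.65\sqrt{B})/(t\,\varepsilon\,P_\gamma\,m)$,
the standard reading of an MDA "at 95% confidence level".

### Uncertainty budget

Relative components are treated as independent and added in quadrature:
per-peak counting statistics (0.5–10% in the survey data), detection
efficiency 4%, sample mass 1.5%, emission intensity 1% — giving the
4.4–10.9% combined range the survey reports. Each component is
overridable via the `uncertainty_budget` config key; a few survey rows
carry slightly larger printed uncertainties (up to ~13% relative),
suggesting additional sample-specific components we do not attempt to
reverse-engineer.

## Exposure model

```{r}
p <- default_exposure_params()
unlist(p)
```

The per-capita annual fish intake is production-derived:
$A_{if} = A_P \cdot 907.188 \cdot F_c / M_P$ with annual landings
$A_P = 1{,}472{,}240$ short tons (the registry treats the short-ton
factor as an explicit, overridable constant — it is what reproduces the
national 47.4 kg/y figure), consumed fraction $F_c = 0.68$ (32% wastage
and export) and an adult population $M_P = 19.15$ million, with no age
stratification:

```{r}
derive_per_capita_intake(p)
```

The default bundle carries $A_{if} = 47.4$ kg/y — the registered
national per-capita figure, which the derivation reproduces to printed
precision — and every downstream quantity uses it consistently:
$D_{int} = A_s A_{if}/365$, $D_{eff} = A_s A_{if} D_{cf}$, and
$\mathrm{LCR} = D_{int}\cdot 365\cdot A_{ls}\cdot R_c$ with
$A_{ls} = 70$ y. Using the registered constant rather than the
15-significant-digit derivation keeps the chain self-consistent with the
national statistics it summarises; overriding any component parameter
and calling `derive_per_capita_intake()` switches to a fully derived
intake. Dose coefficients are the standard ingestion values
($2.8\times10^{-7}$, $2.3\times10^{-7}$, $6.2\times10^{-9}$ Sv/Bq for
²²⁶Ra, ²³²Th, ⁴⁰K) and risk coefficients the USEPA mortality values
($9.56\times10^{-9}$, $2.45\times10^{-9}$, $5.89\times10^{-10}$ Bq⁻¹).

Two modelling notes. First, the total committed dose is the **plain sum**
of per-chain doses: a formulation that re-multiplies the summed doses by
$(A_{if} F_c)$ double-counts both factors, since $A_{if}$ already
contains $F_c$ and each per-chain dose already contains $A_{if}$; the
published per-sample totals equal the plain sum, confirming this
reading. Second, the annual intake entering the LCR is
$D_{int}\times365$ — making LCR exactly linear in activity, an identity
the tests verify symbolically on random inputs. Water activities are
carried in reports but never enter the dose pipeline (drinking seawater
is not an exposure pathway); activities are on a dry-weight basis
throughout, with no wet-weight conversion.

## Heavy metals

$\mathrm{EDI} = C_\mathrm{metal}\cdot W/m_\mathrm{bw}$ with
$W = 130$ g/day and $m_\mathrm{bw} = 70$ kg; mg/kg × g/kg resolves to
µg/kg body weight/day. Location means **exclude non-detects** — with two
replicates of which one is censored, the mean is the detected value.
This is the only rule consistent with the published survey averages
(e.g. a chromium pair with one non-detect averaging to the detected
value); zero- and LOD/2-substitution remain available as options for
sensitivity analysis, and a fully censored element/location pair yields
no EDI row at all rather than a zero. EDIs are computed from unrounded
means (rounding the mean first visibly shifts the fourth decimal). The
TDI screen classifies a ratio of exactly 1 as `below_tdi` — the TDI is a
tolerable ceiling, so the boundary is inclusive — and elements without a
registry entry are flagged `no_tdi`, never silently dropped.

## Location statistics

The one-way ANOVA is computed from its defining sums of squares
(between/within, $F = \mathrm{MS}_B/\mathrm{MS}_W$) rather than through
a model-fitting interface, and is cross-checked in the tests against
`stats::aov` to $10^{-9}$ on random datasets. Tukey HSD uses the
studentized-range distribution from base R (`qtukey`/`ptukey`), which is
exact for any group count, error degrees of freedom and level — we
preferred it over an embedded interpolated quantile table, which would
only approximate non-tabulated degrees of freedom. Unbalanced groups use
the Tukey–Kramer per-pair harmonic sample size. Fully degenerate input
(all observations identical) has an undefined $F$: `oneway_anova()`
errors, while `tukey_hsd()` reports every pairwise difference as zero
and non-significant, which is the useful answer for a screening report.

On the bundled survey, ²²⁶Ra and ²³²Th differ significantly across
locations ($p < 0.05$; both in fact far below), ⁴⁰K across locations
only at $p \approx 0.016$, while ⁴⁰K *levels* dominate the other
nuclides at $p < 0.001$ — the across-nuclide contrast is the one that is
overwhelmingly significant, and the package tests assert exactly these
statements.

## Synthetic surveys and what they validate

`scenario_config()` defaults encode the case-study conditions: 3
locations × 3 replicates of fish and water, true activities at the
observed location means, 10% lognormal replicate dispersion (activities
are positive and right-skewed; a normal option exists), 86,400 s counts,
dry masses uniform on 120–218 g, a power-law efficiency curve typical of
a ~28%-relative-efficiency p-type HPGe ($\ln\varepsilon = 0.416 -
0.7\ln E$, i.e. $\varepsilon \approx 0.025$ at 352 keV), ~400 continuum
counts under each peak, and a metal profile whose detection
probabilities match the observed detected fractions. One global seed is
split into fixed per-module child seeds (activity / peaks / metals), so
regenerating one table never perturbs the others.

The validation this supports: peak generation → quantification recovers
true activities within 3 combined standard uncertainties in ≥99% of
seeded trials; zero-dispersion surveys centred on the observed means
reproduce the published mean dose table within printed rounding; and
location means recover truth within sampling error at the expected rate.
What it does **not** show: the generator draws ideal Poisson peaks on a
known efficiency curve with no coincidence summing, self-absorption,
peak-fitting error or matrix effects, and lognormal replicate scatter is
an assumption, not a measured property — so passing tests demonstrate
the correctness of the computation chain, not the field accuracy of any
particular spectrometer.

Problem sizes used in the shipped tests (a thousand single-sample
round-trip trials, a hundred random ANOVA datasets, fifty-to-sixty-seed
recovery sweeps) were chosen so the binomial coverage checks have
negligible false-failure probability at the asserted thresholds while
the whole suite stays interactive.

## Degenerate inputs and numerical conventions

Zero net counts give zero activity with a finite uncertainty from the
systematic budget; empty uncertainty-component lists propagate to 0;
`combine_lines()` refuses empty input and non-positive weights;
efficiency fits refuse efficiencies outside (0, 1) and underdetermined
orders. Printed-table comparisons in the tests use half-up rounding to
the displayed precision (the convention of the published tables — R's
default round-half-even would disagree on exact ties) with a 0.5%
relative fallback for the handful of cells whose last printed digit
differs from exact recomputation. CSV output is written at full
precision (17 significant digits) so write/read round-trips are
lossless.

## Known limitations

* Only the ingestion pathway is modelled: no external, inhalation or
  radon dose; no age-group-specific coefficients.
* The decay registry covers only the nuclides and lines of this
  measurement campaign; it is not a general decay-chain database.
* Metals are screened against TDI only; no target hazard quotients or
  carcinogenic slope factors, and nutritional adequacy of essential
  elements is out of scope.
* Quantification starts from net peak areas: spectrum deconvolution,
  coincidence-summing and self-absorption corrections belong to the
  acquisition software upstream of this package.
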