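---
title: "Host-guest binding analysis: models, designs and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-guest binding analysis: models, designs and their limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdbind)
```

## The system and the questions

A small hydrophobic guest molecule partitions into the cavity of
β-cyclodextrin (β-CD), a cyclic heptasaccharide host, forming a
non-covalent inclusion complex. Characterizing that complex means
answering three questions: the **stoichiometry** of the assembly, the
**association constant** K of `H + G ⇌ HG`, and the **thermodynamic
signature** (ΔG, ΔH, ΔS) that tells hydrophobic release-of-water binding
apart from enthalpy-driven contact formation. This package implements the
standard solution-state route: continuous-variation ¹H NMR for
stoichiometry and K, isothermal titration calorimetry (ITC) for K, n and
ΔH in one experiment, and the linkage identities tying everything
together.

## The exact 1:1 isotherm

Everything rests on the mass-action equilibrium. With total guest A,
total host B and K in L/mol, the complex concentration is the smaller
root of `x² − (A + B + 1/K)x + AB = 0`. `complex_concentration()`
evaluates it as `2AB / (b + √(b² − 4AB))` with `b = A + B + 1/K`. The
conjugate form matters: the textbook subtractive form loses up to half
the significant digits when `4AB ≪ b²`, which is precisely the weak-
binding, millimolar regime of cyclodextrin work. The suite cross-checks
the closed form against blind bisection of the mass-action equation to
below 1e−12 mol/L over 10⁴ random systems spanning K ∈ [1, 10⁶] L/mol and
concentrations of 10 µM–10 mM; `K = 0` returns 0 by continuity so that
null models need no special casing.

## Continuous variation and the global K fit

The NMR experiment holds `C = A + B` fixed at 4 mM and varies the guest
mole ratio r over eleven mixtures, `r = 1/12 … 11/12`; the endpoints are
the pure components whose spectra define `δ_free`. Under fast exchange
(one population-averaged peak per proton, valid for these weakly bound,
rapidly exchanging complexes) the perturbation
`Δδ(i,j) = δ_free(j) − δ_obs(i,j)` obeys
`Δδ = Δδc(j) · [HG]/X`, X being the total concentration of the proton's
own molecule. The sign convention is *free minus observed* throughout;
Δδc is signed and the model assumes nothing about its direction.

**Stoichiometry.** The Job response `y = Δδ·X` is proportional to [HG],
which for a 1:1 complex is symmetric in (A, B) and therefore peaks at
r = 0.5 for every K — the package refines the peak by parabolic
interpolation through the discrete maximum of |y| and its neighbours
(ties resolve to the smallest r; an edge maximum is reported unrefined),
then classifies 1:1 within a ±0.05 window, a tolerance wide enough for
grid effects and narrow enough to exclude the 1/3 and 2/3 signatures of
higher stoichiometries.

**K.** All traced protons share one K while each keeps its own Δδc, so
the least-squares problem is solved by variable projection: at fixed K
each Δδc has a closed-form solution, and the remaining one-dimensional
profile is minimized on log₁₀K ∈ [−2, 8] by a coarse 61-point scan (to
bracket the global minimum) followed by golden-section refinement to a
relative tolerance of 1e−8, with the best objective recorded per
iteration (it is non-increasing by construction). The quoted correlation
R is the Pearson correlation between observed and fitted Δδ pooled over
all (sample, proton) records — the single-scalar convention of
multi-proton fits. Because no analytic uncertainty accompanies a profiled
K, `fit_association_constant(..., bootstrap = 500)` resamples records
nonparametrically for a percentile interval.

## The ITC forward model and fit

The titration design is 25 × 10 µL injections of 3 mM guest into 0.75 mM
host at 25 °C. The cell volume is not part of that design statement;
the package default is V₀ = 1.0 mL, typical of the overfilled
perfusion cells this class of instrument uses, and all simulate/fit round
trips use one V₀ consistently so results are V₀-consistent. Each
injection of volume dV expels cell liquid; the pre-injection contents are
diluted by the symmetric factor `f = (1 − dV/2V₀)/(1 + dV/2V₀)` while the
injected material adds `[syringe]·dV/V₀`. With n identical independent
sites the equilibrium is solved at effective site concentration n·[host],
and the injection heat is

```
q_k = ΔH · V₀ · (bound_k − f_k · bound_{k−1})
```

in calories (exothermic negative). A `displacement = FALSE` variant
exists because without expulsion total heat equals `ΔH·V₀·bound_final`
*exactly*, which the tests exploit as a conservation oracle; the first
injection is likewise checked against a direct hand-solved equilibrium.
Blank (guest-into-solvent) runs subtract elementwise. Discarding the
first injection — common practice against syringe-diffusion artifacts —
is available but off by default.

The fit profiles ΔH out exactly (it enters linearly), scans a coarse
(log₁₀K, n) grid and polishes by Nelder-Mead; with `fix_n` only log₁₀K is
searched (Brent). The Wiseman parameter `c = nK[host]` is always
attached: this study's regime is c ≈ 0.8, and below c ≈ 1 the isotherm
is shallow enough that K, n and ΔH are strongly correlated. The fitter
does not silence that — it returns the warning with the result.

## Thermodynamic linkage

`ΔG = −RT ln K` and `ΔS = (ΔH − ΔG)/T` with R = 1.98720425
cal mol⁻¹ K⁻¹. `check_consistency()` verifies both identities for a
(K, ΔG, ΔH, ΔS, T) set within a tolerance of 0.01 kcal/mol — deliberately
wide enough to absorb the rounding conventions of reported values and the
298 vs 298.15 K ambiguity of software defaults, both of which move ΔG by
a few thousandths of a kcal/mol. For a K near 1.1 × 10³ L/mol this yields
ΔG ≈ −4.14 kcal/mol; with ΔH ≈ −1.0 kcal/mol the balance,
ΔS ≈ +10.5 cal mol⁻¹ K⁻¹, is entropy-dominated — the release of ordered
water from the cavity — even though the interaction is (mildly)
exothermic.

## What the synthetic data emulate, and what they do not

The generators are pure functions of (ground truth, seed) and reproduce
the two experimental designs exactly: the 11-mixture 4 mM
continuous-variation series and the 25-injection titration above. Guest
free-state shifts default to the published D₂O assignments of the study
compound (Ha 6.97, Hb 7.79, Hc 6.88, Hd 6.96, He 6.98, Hf 6.90, Hg 1.24,
Hh 4.00 ppm); the β-CD cavity protons H3/H5 use literature-typical values
(3.94, 3.83 ppm). Limiting shifts Δδc are not experimentally reported
anywhere to draw on, so the defaults are order-of-magnitude-plausible
for β-CD inclusion (|Δδc| 0.02–0.09 ppm, host protons shifted opposite
to guest aromatics) and are explicit configuration, never silently
assumed. Noise is homoscedastic Gaussian — on δ_obs (ppm) and on heats
(cal) — the simplest model consistent with instrument precision.

Not emulated: lineshapes, overlap and baseline artifacts in real spectra;
ITC baseline drift and the first-injection diffusion artifact; any
heteroscedasticity. Passing round-trip tests therefore demonstrates the
*estimators* are correct and efficient, not that real spectra would yield
parameters this clean.

## Identifiability: the honest limits of both designs

Two negative results are part of the package's account and are
documented rather than smoothed over. Both follow from the Fisher
information of the designs, not from the fitters — the replicate studies
in `analysis/06_robustness.R` show the median recovery error scaling
linearly with σ, the signature of an efficient estimator.

* **Continuous variation, K·C ≈ 0.33.** At K ≈ 82 L/mol and 4 mM total,
  bound fractions stay below ~30%, so Δδ is nearly proportional to
  Δδc·K·B and K is identified only through second-order curvature. With
  plausible |Δδc| ≤ 0.1 ppm, the linearized Cramér-Rao bound at
  σ = 0.001 ppm puts the relative standard deviation of K near or above
  100%. Single-realization K estimates at realistic shift noise are
  therefore close to meaningless for this system, and the bootstrap
  intervals say so; precise K recovery needs σ in the 1e−5–1e−4 ppm
  range, more concentrated samples, or protons with larger Δδc.
* **ITC, c ≈ 0.8.** The low-c isotherm is shallow: at σ = 0.5 µcal the
  K–ΔH correlation exceeds 0.99 and the Cramér-Rao relative sd of ΔH is
  ≈ 15% even with n fixed at 1 (≈ 47% with n free). Median ΔH recovery
  below a few percent at this noise level is not achievable by any
  unbiased fit of a single titration at this design; the robustness study
  accordingly conditions on n = 1 (stoichiometry being independently
  established by the Job analysis) and reports the resulting ~10% median
  error together with the wide K spread.

## Numerical and design choices

* Internal units: mol/L, ppm, calories; CSV dialects accept mM and
  µcal/µJ and convert on read. K in L/mol, ΔG/ΔH in kcal/mol, ΔS in
  cal mol⁻¹ K⁻¹ — the units these quantities are conventionally quoted in.
* Outer searches are derivative-free (golden-section / Nelder-Mead):
  robust to the flat, correlated objectives of low-saturation data, and
  fast enough (milliseconds per CV fit, ~0.1 s per ITC fit) that
  derivatives buy nothing.
* Degenerate inputs fail loudly: all-zero perturbation tables and flat
  thermograms raise unidentifiability errors rather than returning a
  boundary K.
* Replicate-study sizes (100–200 CV fits, 50–100 ITC fits; 10⁴ systems in
  the equilibrium cross-check) were chosen so the whole suite runs in
  well under a minute while medians and quantiles are stable across
  seeds.

## Known limitations

1:1 binding only — no 1:2/2:1 isotherms, no slow-exchange or lineshape
analysis, no heat-capacity or multi-temperature van 't Hoff treatment,
no parsing of instrument binary formats. The bootstrap treats records as
exchangeable, which ignores per-proton noise structure; and the
displacement convention, while standard for overfilled perfusion cells,
is one of several in circulation — the no-displacement variant is
provided for comparison against software using a different bookkeeping.
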