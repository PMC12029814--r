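# cdbind

Quantitative analysis of 1:1 host–guest complexation, aimed at the kind of
physico-chemical characterization done for cyclodextrin inclusion
complexes: a hydrophobic guest (here, an ethyl-thiazolylidene
hydroxybenzohydrazide drug candidate) inserting into the cavity of
β-cyclodextrin. The package answers the three standard questions of such a
study — *what is the stoichiometry?* (continuous-variation NMR), *how
strong is the association?* (chemical-shift titration and isothermal
titration calorimetry), and *what drives it?* (binding thermodynamics) —
with tested, reproducible code instead of vendor black boxes.

## The models

**Exact 1:1 equilibrium.** For totals A (guest) and B (host) and
association constant K (L/mol), the complex concentration is the smaller
root of the mass-action quadratic,

    [HG] = ½ [ (A + B + 1/K) − √( (A + B + 1/K)² − 4AB ) ],

evaluated in the numerically stable conjugate form
`[HG] = 2AB / (b + √(b² − 4AB))`, `b = A + B + 1/K`.

**Fast-exchange NMR.** The shift perturbation of proton *j* in sample *i*
is `Δδ(i,j) = δ_free(j) − δ_obs(i,j)` and follows
`Δδ(i,j) = Δδc(j) · [HG]_i / X_i`, with X the total concentration of the
proton's own molecule and Δδc the limiting complexation shift. A
continuous-variation series (constant A + B, mole ratio r spanning (0, 1))
gives the Job response `Δδ·X`, which peaks at r = 0.5 for a 1:1 complex;
the same data fit K globally across all traced protons by variable
projection (exact linear solve for every Δδc, golden-section search on
log₁₀K).

**Independent-sites ITC.** Per-injection heats in an overfilled perfusion
cell follow `q_k = ΔH · V₀ · (bound_k − f_k · bound_{k−1})`, with the
symmetric displacement factor `f = (1 − dV/2V₀)/(1 + dV/2V₀)` and the
equilibrium solved at effective site concentration n·[host]. Fitting
(K, n, ΔH) profiles ΔH out exactly and searches (log₁₀K, n) by
Nelder-Mead; the Wiseman parameter c = nK[host] is always reported, with
an explicit warning in the weakly identified low-c regime.

**Thermodynamic linkage.** `ΔG = −RT ln K` and `ΔS = (ΔH − ΔG)/T`
(R = 1.98720425 cal mol⁻¹ K⁻¹), plus a consistency checker for
independently rounded (K, ΔG, ΔH, ΔS) quadruples.

## Worked example

```r
library(cdbind)

# simulate a continuous-variation NMR series: 11 mixtures, 4 mM total,
# K = 81.97 L/mol ground truth, five traced protons
tab <- generate_cv_table(cv_ground_truth(K = 81.97), build_cv_design(4e-3, 11))
job_curve(tab, "Hd")$r_max          # 0.5  -> 1:1 stoichiometry
fit_association_constant(tab)
#> 1:1 NMR binding fit (variable projection)
#>   K = 81.97 L/mol  (converged: TRUE, 35 outer iterations)
#>   correlation R (obs vs fitted, pooled) = 1.0000
#>   ...

# simulate and refit an ITC titration: 3 mM guest into 0.75 mM host,
# 25 x 10 uL injections at 25 C
des <- itc_design()
fit_independent_model(simulate_thermogram(1096, 1, -1013, des), des)
#> independent-sites ITC fit
#>   K  = 1096 L/mol
#>   n  = 1.000
#>   dH = -1013.0 cal/mol (-1.013 kcal/mol)
#>   dG = -4.147 kcal/mol, dS = +10.51 cal/(mol K) at 298.15 K
#>   Wiseman c = 0.822
#>   note: low-c regime (c = 0.822 < 1): ...
```

The negative ΔG says association is spontaneous; the small exothermic ΔH
together with a positive ΔS is the classic signature of hydrophobic
cavity inclusion (release of ordered water).

## The analysis workflow

The `analysis/` directory holds the numbered drivers of the full study,
each a thin narrative over package functions, writing its tables under
`results/`:

1. `01_simulate_nmr.R` — continuous-variation shift tables (noiseless and noisy)
2. `02_job_plot.R` — Job curves and stoichiometry classification
3. `03_fit_nmr_K.R` — global K fit with bootstrap uncertainty
4. `04_simulate_itc.R` — thermogram plus blank, dilution-corrected
5. `05_fit_itc.R` — independent-sites fit and thermodynamic profile
6. `06_robustness.R` — noise-robustness study of both designs

Run them in order from the repository root: `Rscript analysis/01_simulate_nmr.R`, …

## Scope

Single-site 1:1 binding only: no 1:2/2:1 stoichiometries, slow-exchange
lineshapes, multi-temperature van 't Hoff analysis, or instrument binary
formats. See `vignettes/binding-analysis.Rmd` for the methods account,
including what the weakly saturated designs can and cannot determine.
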