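---
title: "Models, calibrations and design choices in leafphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibrations and design choices in leafphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafphys)
```

leafphys analyses leaf-level ecophysiology experiments of the kind used to
dissect stomatal versus non-stomatal limitation of photosynthesis in crops
under stress — here, cucumber seedlings under short-term waterlogging, in a
two-cultivar × two-treatment randomized complete block design (RCBD). This
vignette explains the models the package implements, the calibrations baked
into the synthetic-experiment generator, and the numerical choices made
where the design was genuinely open.

## Fluorescence calculus

One pulse-amplitude-modulated (PAM) quenching measurement yields five raw
fluorescence levels: dark-adapted minimal and maximal fluorescence (Fo,
Fm), steady-state fluorescence under actinic light (Fs), light-adapted
maximal fluorescence after a saturating pulse (Fm′), and light-adapted
minimal fluorescence after far-red illumination (Fo′). From these the
package computes the conventional parameter set:

* Fv/Fm = (Fm − Fo)/Fm, the maximal PSII photochemical efficiency
  (≈ 0.75–0.83 in healthy leaves);
* ΦPSII = (Fm′ − Fs)/Fm′, ΦNPQ = Fs/Fm′ − Fs/Fm, ΦNO = Fs/Fm — the
  three-way partition of absorbed excitation energy into photochemistry,
  regulated thermal dissipation and non-regulated dissipation, which sums
  to one *algebraically*, not just numerically;
* qP = (Fm′ − Fs)/(Fm′ − Fo′) (puddle model) and qL = qP·Fo′/Fs (lake
  model), with 1 − qL reported directly as the closed-centre / reduced-QA
  fraction;
* Stern–Volmer NPQ = (Fm − Fm′)/Fm′ and Fv′/Fm′ = (Fm′ − Fo′)/Fm′;
* ETR = ΦPSII·Q·α·f with defaults α = 0.84 (broad-leaf absorptance) and
  f = 0.5 (even excitation split between photosystems). Both constants are
  per-record overridable; they are community defaults, not measurements.

When the far-red Fo′ step is missing, `estimate_fo_prime()` applies the
Oxborough–Baker relation Fo′ = Fo/(Fv/Fm + Fo/Fm′), which is exact at
Fm′ = Fm and guarantees qP ≤ 1.

Useful identities enforced by tests: ΦPSII + ΦNPQ + ΦNO = 1 to 1e−12 and
ΦPSII = qP × Fv′/Fm′ (so a decline in ΦPSII can be attributed to qP and/or
Fv′/Fm′ components).

## Stomatal indices and Rubisco velocities

From each steady-state gas-exchange record: intrinsic water-use efficiency
WUE = A/gs, the Ci/Ca ratio, and the stomatal limitation index
Ls = 1 − Ci/Ca (so Ls + Ci/Ca = 1 exactly). Percent changes are reported
decline-positive, 100·(control − treated)/control, matching how treatment
effects are conventionally narrated.

Carboxylation and oxygenation velocities are obtained from the
fluorescence-based partitioning with four electrons per carboxylation and
four per oxygenation:

Vc = (ETR + 8(A + Rd))/12, Vo = 2(ETR − 4(A + Rd))/12,

chosen because it uses exactly the simultaneously collected data streams
(A from the IRGA, ETR from fluorescence). Both stoichiometric identities —
A = Vc − 0.5·Vo − Rd and ETR = 4(Vc + Vo) — hold algebraically and are
asserted to 1e−9 on random inputs. Day respiration Rd is required but
rarely measured; it defaults to the A/Ci-fitted Rd when available and to
1 µmol m⁻² s⁻¹ otherwise. The electron costs are exposed
(`e_c`, `e_o`) for sensitivity analyses. A Ci/Γ*-based estimate would give
the same ordering but different magnitudes; the fluorescence route was
preferred for being invertible and testable. When ETR < 4(A + Rd) the pair
is flagged invalid rather than raising.

## FvCB A/Ci fitting

The Farquhar–von Caemmerer–Berry model partitions net assimilation into
Rubisco-limited, RuBP-regeneration-limited and TPU-limited rates:

* Ac = Vcmax(Cc − Γ*)/(Cc + Kc(1 + O/Ko)) − Rd
* Aj = J(Cc − Γ*)/(4Cc + 8Γ*) − Rd
* Ap = 3·TPU − Rd

with A = min(Ac, Aj, Ap). Kinetic constants default to the Bernacchi 25 °C
values (Kc = 404.9 µmol mol⁻¹, Ko = 278.4 mmol mol⁻¹, Γ* = 42.75
µmol mol⁻¹, O = 210 mmol mol⁻¹) — the constants embedded in the popular
spreadsheet fitting tools — and are all exposed in `fvcb_params()`.
Mesophyll conductance defaults to infinite (Ci-basis fitting, Cc = Ci); a
finite gm applies Cc = Ci − A/gm. Arrhenius temperature normalisation to
25 °C is available (`temperature_adjust()`); with the default activation
energy the Vcmax scale factor is ≈ 9.3% per degree near 25 °C.

`fit_aci()` assigns each Ci-sorted point to a limitation state under the
constraint that labels are monotone in the Rubisco → RuBP → TPU order, as
in the spreadsheet-tool procedure. The key numerical observation is that
*for a fixed label assignment the model is exactly linear* in
(Vcmax, J, 3·TPU, Rd), so each assignment is solved in closed form by QR
least squares — no multi-start nonlinear optimisation, no convergence
tolerance, fully deterministic. All O(n²) assignments are enumerated; the
admissible one (assigned rate equal to the min rule at the fitted
parameters, within 0.5 µmol m⁻² s⁻¹ — commensurate with IRGA noise near
the limitation crossover) with the lowest SSE wins. SSE ties are broken
towards more Rubisco-limited points (conservative Vcmax), then towards
fewer TPU points, because a single-point TPU segment always fits exactly.
Rd is clamped non-negative (refit with Rd = 0 when the unconstrained
solution goes negative); Rd is weakly identified from A/Ci data and its
recovery error is accordingly larger than Vcmax's or J's. A curve with no
RuBP-limited points flags J as unidentifiable instead of reporting a
number. The fitted J is reported as "Jmax", mirroring common usage for
fits without a light-saturation extrapolation.

## Light-response fitting and model selection

Four candidate families are implemented: rectangular hyperbola,
non-rectangular hyperbola (curvature θ), exponential saturation, and the
Ye modified rectangular hyperbola A = φ(1 − βI)/(1 + γI)(I − Ic) — the
only candidate able to represent supra-optimal (photoinhibited) decline.
`select_light_model()` fits all candidates and keeps the lowest-SSE fit,
breaking ties (within 1e−6 relative) towards fewer parameters. Fits use
Levenberg–Marquardt from a small deterministic grid of moment-based
starting values; no randomness enters the fitters.

Cardinal points: Ic is the root of A(I) = 0 (a parameter of the Ye
family, a bracketed root otherwise); the apparent quantum yield Φi is the
analytic derivative dA/dI at I = Ic (the Ye formulation's natural
definition; the slope at I = 0 is also reported since some traditions use
it); Pmax is the maximum net rate over 0–5000 µmol m⁻² s⁻¹; Ik is the
intersection of the initial-slope line with the Pmax plateau,
Ik = Pmax/Φi + Ic (Ik has no universal definition; this one is selectable
behaviour in the sense that all ingredients are returned); and Amax is
reported as the fitted value at I = 1500 µmol m⁻² s⁻¹ — the highest PPFD
of the measurement protocol and therefore the value comparable across
treatments — alongside the model's global maximum. Φi values above the
theoretical quantum-yield ceiling of 0.125 mol CO2 mol⁻¹ photons are
flagged non-physiological.

## RCBD statistics

The experimental design is a 2 × 2 factorial in four complete blocks with
six measured plants per plot. Plants are subsamples, not replicates:
`anova_factorial_rcbd()` averages them to plot means first (df_error = 9
for the 2×2×4 design). The balanced fixed-effects decomposition (sources
cultivar, treatment, interaction, block, error) is computed via
`stats::aov`; a generalized linear mixed model with Gaussian response and
this balance yields identical F tests, so the fixed-effects reduction
loses nothing here. The test suite checks the sums of squares against an
independent projection-based partition and the null distribution of the F
test (type-I error ≈ 0.05 over 2000 simulated null experiments).

Mean separation uses Fisher's protected LSD at α = 0.05:
LSD = t(0.975, df_error)·√(2·MSE/n), letters assigned by the standard
descending-mean sweep, with the protection rule that a non-significant
omnibus F collapses all groups to a single letter. The pooled SEM
reported with each trait is √(MSE/n) — e.g. MSE = 0.0740 with n = 4
blocks gives 0.136. Shapiro–Wilk (Royston's approximation, via base R)
serves as the pre-pooling normality diagnostic, and
`pearson_matrix()` gives the trait-by-trait product-moment correlations
with t-transform p-values and α = 0.05 stars. No multiple-testing
correction is applied across traits, matching standard practice for this
report format.

## The synthetic-experiment generator

No public dataset accompanies studies of this kind, so the package ships
a forward simulator (`simulate_experiment()`) whose defaults encode the
study conditions: two cultivars ("Marketmore" tolerant, "Straight 8"
sensitive) × control/waterlogged × 4 blocks × 6 plants per plot;
A/Ci curves at the CO2 setpoints 300, 200, 100, 50, 200, 400, 600, 800,
1000, 1200, 1500 µmol mol⁻¹ (a decreasing-then-ascending bitonic path
from ambient 415, optionally recorded as a 12th point); light curves at
0–1500 µmol m⁻² s⁻¹ in 12 steps; saturating pulses of 8000 and actinic
light of 1400 µmol m⁻² s⁻¹.

Calibration choices, made once:

* **Effects are the printed percent changes.** Morphology declines
  (LN/LA/FM/DM: Marketmore 8/8/14/8%, Straight 8 14/17/25/25%), gas
  exchange (gs/E/WUE: 22/14/52% and 24/13/40%), Ci increases (+6/+4%),
  Vcmax/Jmax declines (14/15% and 33/14%), ETR declines (23/26%) and
  control Amax values (23.62 and 19.59 µmol m⁻² s⁻¹ with −8%/−20%
  declines) are wired into `default_paper_config()`.
* **Noise is SEM-calibrated.** The only variance information such reports
  print is the pooled SEM per trait; the generator sets the plot-level
  error SD to SEM·√(4 blocks), plant-level SD to half the plot SD, and
  additive block-effect SD to half the plot SD (block effects cancel from
  treatment contrasts but exercise the RCBD machinery).
* **Absolute control means are plausible constants, not data.** Only
  relative changes and noise levels matter for the recovery analyses;
  the chosen means (e.g. FM 12.5 g, gs 0.85 mol m⁻² s⁻¹, WUE 21) are
  declared non-authoritative.
* **Internal consistency is imposed where printed values conflict.**
  A printed Ci increase and Ls decline jointly determine the control
  Ci/Ca ratio under Ls = 1 − Ci/Ca; the generator solves for the control
  Ci (≈ 364 and 371 µmol mol⁻¹ at Ca = 415) so both hold simultaneously.
  Likewise ETR ∝ ΦPSII at fixed actinic light, so the waterlogged ΦPSII
  targets are scaled by the ETR declines (the printed ΦPSII and ETR
  declines differ by one point — they cannot both hold exactly).
  Fluorescence yield targets always satisfy ΦPSII = 1 − ΦNO(1 + NPQ), the
  partition identity; `fluorescence_from_targets()` refuses inconsistent
  triples. A consequence of holding the Fm scale constant is that Fo
  moves opposite to Fv/Fm, so the printed simultaneous declines of Fo
  and Fv/Fm at constant Fm are not reproducible and Fo is not a recovery
  target.
* **A/Ci curves treat the setpoints as the Ci grid** with 2%
  multiplicative observation noise; the chamber-control-to-Ci mapping of
  a real instrument is out of scope. Light curves get a plot-level
  amplitude factor calibrated to the A SEM plus small per-point noise.
* **What the generator does not emulate:** time-course dynamics over the
  waterlogging period (endpoint only), mechanistic hypoxia physiology
  (adventitious roots, hormones, aerenchyma), instrument drift,
  non-Gaussian error, or correlated trait noise beyond the identities
  above. Passing recovery tests therefore demonstrates that the
  *analysis* pipeline is unbiased and internally consistent under
  realistic noise — not that it would be robust to every artefact of
  real field data.

With zero noise every simulated cell mean equals its configured value
exactly, and the whole pipeline reproduces every configured percent
change to numerical precision — the strongest end-to-end identity test.
Identical seeds give bit-identical bundles, and the generator restores
the caller's RNG state.

## Monte-Carlo problem sizes

Recovery checks are stochastic; the suite and the acceptance script
average over repeated independent experiments so that the Monte-Carlo
standard error of each recovered percent change is a fraction of a point:
200 experiments for morphology, 25 repeats of the 4-replicate-per-treatment
A/Ci experiment, 240 light-curve experiments (the fitted-Amax SD of ~2.6
µmol m⁻² s⁻¹ per plot under amplitude noise makes this the binding
precision constraint), and 400 fluorescence / gas-table experiments.
Percent changes over repeated experiments are formed from pooled cell
means (average the treatment means across experiments, then take the
ratio), which avoids the small-sample bias of averaging per-experiment
ratios. Tolerances in tests are expressed as three Monte-Carlo (or
generator) standard errors of the estimator at hand.

## Known limitations

* Rd from A/Ci fits is weakly identified (documented bias up to tens of
  percent); treat fitted Rd as a nuisance parameter.
* The TPU branch has no glycerate re-export term, and no
  chlorophyll-content normalisation is offered.
* The LSD letter display, like all compact letter displays, is not unique
  when mean spacings straddle the threshold; the implementation is
  deterministic and order-invariant.
* `fit_aci` assumes limitation states are monotone in Ci — true for the
  standard model but not for pathological parameter combinations with
  crossing Aj/Ac curves at both ends.
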