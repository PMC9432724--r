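---
title: "Modelling co-translational mRNA localization to mitochondria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling co-translational mRNA localization to mitochondria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoloc)
```

`mitoloc` simulates the localization of nuclear-encoded mitochondrial
mRNAs to the mitochondrial surface in yeast. Localization is
co-translational: a ribosome that has synthesized the amino-terminal
mitochondrial targeting sequence (MTS) of the nascent peptide exposes
it to import receptors on the outer membrane, and an mRNA carrying at
least one such *binding-competent* MTS tethers irreversibly when it
diffuses within binding range. The model asks how translation kinetics
(initiation rate, elongation rate, transcript length, MTS maturation)
and cell geometry (mitochondrial volume fraction, MVF) jointly set the
steady-state localized fraction.

## The four-state skeleton

Before any mechanism, the package exposes an exactly solvable abstraction
(`four_state_rates()`, `steady_state()`): an mRNA is competent or not
(switching rates `k_S`, `k_U`) and near the surface or far (transport
rates `k_R`, `k_L`); competent, near mRNA are bound and can leave only
after losing competence, which breaks detailed balance. The stationary
distribution is closed-form, and `localized_fraction()` interpolates
between two limits:

* *rapid transport* (`k_R, k_L ≫ k_S, k_U`):
  `f_loc = f_s + (1 − f_s) f_d` — even a tiny proximal volume `f_d`
  supports high localization if the competent fraction `f_s` is high;
* *slow transport / fast switching* (`k_R, k_L ≪ k_S, k_U`):
  `f_loc = 1/(1 + (1 − f_s)(1 − f_d)/f_d)` — localization collapses as
  `f_d → 0`.

This is the conceptual backbone of everything below: MVF sensitivity
requires competence switching that is *fast* relative to diffusive
transport. `simulate_ctmc()` is a continuous-time Markov-chain sampler
of the same scheme, used purely as a cross-validation oracle for the
algebra; it starts from the far, non-competent state (an mRNA freshly
exported from the nucleus), which is immaterial for the stationary
quantities tested.

## Translation and MTS competence

`simulate_translation()` runs an exact Gillespie simulation of a single
mRNA (`src/translation.cpp`): initiation at `k_init` (1/s) when codon 1
is free, per-ribosome elongation at `k_elong` (codons/s) into free
codons, termination from codon `L` at `k_elong`, and cytosolic decay at
`k_decay` (default 0.0017 s⁻¹, a 600 s mean lifetime consistent with
measured yeast mRNA decay times). The exclusion footprint is one codon
— real footprints (~10 codons) are a deliberate non-goal, since the
regimes of interest are low-occupancy (`k_init/k_elong ≪ 1` per codon)
where exclusion is negligible; the closed forms below ignore exclusion
for the same reason and are compared to simulation only in that regime.

A ribosome at or past `l_MTS = 100` codons (an MTS of up to ~70 aa plus
~30 aa of ribosome exit tunnel) carries a *translated* MTS. Two
competence models (`competence_model()`):

* **instantaneous** — a translated MTS is immediately competent
  (`k_MTS → ∞`);
* **maturation** — each translated MTS matures at rate `k_MTS`
  (mean `τ_MTS = 1/k_MTS`), an independent exponential clock per
  ribosome drawn inside the Gillespie loop, representing folding of the
  amphipathic helix and/or chaperone engagement. A ribosome that
  terminates before maturing removes its immature MTS with no effect.

Closed-form predictors (`beta()`, `beta_mature()`,
`mature_exposure_time()`, `mean_wait_time()`) give the mean exposed and
mature MTS counts and exposure durations. One genuine ambiguity is the
`k_MTS → ∞` limit of the mature exposure time: the expression as
published, `(1/k_MTS)[1 − e^{−k t_max}(k t_max + 1)]`, tends to zero
there, whereas the exposure per *translated* MTS,
`t_max − (1/k)(1 − e^{−k t_max})`, recovers the instantaneous exposure
time `t_max = (L − l_MTS)/k_elong`. Both bookkeepings are shipped —
`mature_exposure_time()` (the default, as published) and
`mature_exposure_time_alt()`, which also satisfies the exact identity
`beta_mature = beta × alt / t_max`. Conclusions that depend only on the
ordering of exposure versus search times are unaffected at the working
point `τ_MTS ≈ 40 s`.

Nuclear residence is drawn from a normal(60 s, 30 s) with non-positive
values rejected (zero-truncated mean ≈ 61.66 s); no translation and no
decay occur in the nucleus. Lifetime fractions include nuclear time in
the denominator by default — consistent with lifetime-weighted ensemble
averaging over trajectories "from synthesis to decay" — and
`competent_fraction(include_nuclear = FALSE)` exposes the alternative,
since the convention is not otherwise pinned down.

Cycloheximide is modelled as an analysis-time statistic, not modified
dynamics: CHX freezes elongation, so every *translated* (not
necessarily mature) MTS stays exposed indefinitely and the CHX
localization of an ensemble is its lifetime-weighted fraction of life
with ≥ 1 translated MTS (`chx_localizable_fraction()`,
`ensemble_chx_localization()`).

## Geometry and the diffusion propagator

The cytoplasm around one mitochondrial tubule is a set of concentric
cylinders (`cylinder_geometry()`): tubule radius `r_m = 0.350` μm;
binding shell to `r_a = r_m + 25 nm` (ribosome radius 13–14 nm, a
~5 nm MTS helix — 31 aa at 0.54 nm pitch and 3.6 aa/turn — plus
linker); imaging shell to `r_b = r_m + 250 nm` (diffraction limit);
reflecting outer wall at `R = r_m/√(f_m/0.8)` so the enclosed
mitochondrial volume fraction matches the reported `f_m` within the 80%
of cell volume accessible to mitochondria and cytosol
(`geometry_from_mvf()`). The outer wall is *not* the cell boundary but
the typical half-distance to the next tubule of the network; network
topology (junctions, cortical confinement) is deliberately ignored.
Diffusivity is `D = 0.1` μm²/s, independent of gene and ribosome load.

Because region membership depends only on radius, the propagator is 2-D
radial diffusion in the cross-sectional plane. Instead of fixed-step
integration, region-to-region transitions are sampled from exact
first-passage-time (FPT) distributions:

* each region's radial diffusion operator on `[a, b]` with
  reflecting/absorbing ends is expanded in Bessel eigenfunctions
  `φ_n(r) = J₀(k_n r) C_n − Y₀(k_n r) D_n` (`radial_modes()`);
  eigenvalues are bracketed on a wavenumber grid at 1/16 of the
  asymptotic spacing `π/(b − a)` and refined by bisection; 120 modes
  per region are retained and norms/overlaps computed by composite
  Simpson quadrature;
* survival functions are spectral sums `Σ c_n e^{−D k_n² t}`; sampling
  inverts them. For the fixed entry radii the inverse is tabulated once
  per geometry on a ~500-point logarithmic time grid and interpolated
  (monotone, in `log t` vs survival); after an unbinding event the
  start radius is random, and the survival is inverted directly by
  bisection to 10⁻⁹ relative tolerance;
* the truncated series is unreliable only at very short times, so draws
  with survival above the table head (≥ the survival at `5/λ_max`,
  itself ≥ 0.999 in the narrow regions) fall back to the 1-D half-space
  inversion `t = d²/(4D · erfinv(u)²)` with `d` the distance to the
  absorbing boundary, and the deep tail beyond the table extrapolates
  along the slowest mode;
* in the middle annulus (two absorbing boundaries) the exit side is
  drawn from the exact logarithmic splitting probability
  `P(inner | r₀) = ln(r_out/r₀)/ln(r_out/r₀ → r_in)` and the time from
  the side-conditioned flux series.

Boundary buffers `ε = 10 nm` keep successive FPT problems away from
zero-width gaps: a particle absorbed at `r_a + ε` starts region 2 at
that radius and region 1 is re-entered at `r_a − ε`, etc. An mRNA
released from the surface (last competent MTS lost) restarts at a
radius drawn with density ∝ r on `[r_m, r_a]`
(`sample_unbinding_position()`), i.e. uniformly over the annular area.

The numerical method was chosen for the package (the underlying
Green's-function literature does not fix an algorithm), so it is
validated physically: spectral means against the exact annulus
mean-FPT closed forms, full distributions against a fixed-step
Euler–Maruyama integrator of `dr = (D/r) dt + √(2D) dW`
(`sde_first_passage()`, also exposed as a user-facing fallback), the
splitting probabilities against the log formula, and equilibrium
occupancy of a non-binding walker against annular area fractions. The
test suite runs all of these.

## The coupled simulator

`simulate_mrna()` couples the two processes. A realized FPT is a fixed
future event — first-passage times are independent of translation — so
translation is advanced by the Gillespie kernel exactly up to each
spatial transition. Stopping and restarting translation at region
changes is statistically exact because every translation clock
(initiation, per-ribosome elongation, maturation, decay) is
exponential; the implementation exploits the same memorylessness to
batch consecutive far-region segments into one translation window,
which changes nothing statistically but removes most interpreter
overhead. The binding rules are:

* a competent mRNA crossing into the binding shell binds at the
  crossing instant;
* an incompetent mRNA inside the binding shell that gains its first
  competent MTS binds immediately, cancelling its scheduled exit (the
  source model does not state this case; binding-range means
  binding-range);
* a bound mRNA has no radial coordinate; translation continues
  unmodified while bound; when the last competent MTS terminates the
  mRNA unbinds and may re-bind immediately if another MTS matures
  before it leaves the shell;
* decay ends the trajectory anywhere; time spent bound counts as
  binding-shell (region 1) time.

With `k_decay = 0` a horizon `max_time` (default 6000 s, ten mean
lifetimes) applies and is recorded. Each trajectory's RNG stream is a
deterministic hash of `(seed, index)` (`trajectory_seed()`), so
ensembles are reproducible regardless of execution order, and sweeps
(`sweep_localization()`) reuse the base seed across axis values for
variance reduction. Ensemble statistics (`ensemble_localization()`,
with `binding` = region 1, `imaging` = regions 1 + 2) weight
per-trajectory fractions by lifetime, matching how measurements sample
mRNAs. The default ensemble size is 50 trajectories per condition, the
scale at which the ensemble averages are defined; tests and the
acceptance script use 10–50 trajectories and horizons of 1200–4000 s
per condition, sizes at which the Monte-Carlo standard errors quoted in
the tests are computed from the data themselves.

## Rate estimation and the synthetic cohort

`calibrate()` and `estimate_kinit()`/`estimate_kelong()` convert
relative measurements into rates: protein production `k_init N_mRNA`
balances dilution at cell division (effective protein lifetime
`T_div = 90` min — protein degradation is slow compared to division in
growing yeast), giving `k_init = α P/T_div` with `α` fixed by the
reference gene *TIM50* (4095 proteins, 6 mRNAs, `P = 15.12` →
`k_init,ref = 0.1264 s⁻¹`, `α = 45.14`); ribosome occupancy is
proportional to density `k_init/k_elong`, so elongation rates follow
from occupancy ratios anchored at `k_elong,ref = 4 aa/s`. Only ratios
to the reference matter, so occupancy units are arbitrary; by default
the reference occupancy is read off the input table's own reference row.
`build_gene_table()` applies this per gene and appends the closed-form
predictors.

The measured per-gene tables (52 conditional and 70 constitutive genes)
are not bundled with this package.  `generate_synthetic_cohort()`
therefore draws
*synthetic* cohorts: log-normal per-gene kinetics centred on the
published group medians — conditional `(L, k_init, k_elong) =
(393 aa, 0.3253 s⁻¹, 14.5086 aa/s)`, constitutive
`(483 aa, 0.1259 s⁻¹, 7.7468 aa/s)` — with a log-scale standard
deviation of 0.4 for all three parameters. The medians are the
conditions of record; the spread is a fixture choice (the sources
report only medians) picked so that the two groups overlap but remain
distinguishable, roughly the few-fold spread visible in genome-wide
rate estimates, and it is configurable. Draws are inverted through the
calibration into `(P, occ)` columns so the estimation pipeline can be
round-tripped exactly. What passing tests on this cohort shows is that
the *pipeline and the group-median behaviour* are right; it does not
reproduce per-gene tails, covariances between parameters, or the exact
violin shapes of the measured cohort, all of which need the original
tables.

## Degenerate inputs and edge policies

* Four-state: `k_U = 0` or `k_L = 0` make a state absorbing; the
  closed form divides by them, so these raise errors naming the
  absorbing limit rather than returning a limit — the `limit_*`
  functions express the limits explicitly. `f_d = 0` in the
  slow-transport limit returns 0 (1 if `f_s = 1`).
* `L < l_MTS` is legal everywhere and yields identically zero
  competence (β = 0, never binds).
* `geometry_from_mvf()` rejects volume fractions that would eliminate
  the far region (`f_m/0.8 ≥ (r_m/r_b)²`), naming the bound; `ε` must
  be smaller than every inter-radius gap.
* Invalid rows in measurement tables are dropped with a warning naming
  them; an empty table returns an empty result with a warning.
* `k_decay = 0` without a finite horizon is rejected.

## Known limitations

* One-codon ribosome footprint and uniform elongation rates; no codon-
  specific speeds, stalling, or collision-coupled decay.
* A single mRNA at a time — no competition for ribosomes or receptors.
* The geometry is a straight infinite tubule with an effective
  reflecting wall; mitochondrial network topology, cortical confinement
  and anisotropic or state-dependent diffusion are out of scope.
* Binding is all-or-none and irreversible while competent; receptor
  number and occupancy are not modelled.
* Puf3-mediated (MTS-independent) localization is outside the model.
* Localization is obtained by simulation (or the four-state limits);
  no closed-form localization prediction is attempted.
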