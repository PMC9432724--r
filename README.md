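# mitoloc

Stochastic simulation of co-translational mRNA localization to
mitochondria in budding yeast.

## The problem

Many nuclear-encoded mitochondrial mRNAs localize to the mitochondrial
surface while being translated: once a ribosome has synthesized the
amino-terminal mitochondrial targeting sequence (MTS) of the nascent
peptide, the exposed MTS can engage import receptors on the outer
membrane and tether the whole mRNA–ribosome complex. Some of these
mRNAs (*constitutive*, e.g. *TIM50*) are localized under all metabolic
conditions; others (*conditional*, e.g. *ATP3*) lose localization under
fermentative conditions — when the mitochondrial volume fraction (MVF)
is low — and regain it when elongation is frozen with cycloheximide
(CHX). `mitoloc` is a quantitative model of this process for people who
want to ask *which translation parameters make a transcript's
localization switchable*: it couples gene-specific translation kinetics
to diffusive search for the mitochondrial surface and measures the
resulting steady-state localization.

## The model

* **Four-state skeleton.** An mRNA is binding-competent ("sticky") or
  not, and near the mitochondrial surface or far. With switching rates
  `k_S`, `k_U` and transport rates `k_R`, `k_L` (and no escape while
  bound), the stationary localized fraction has a closed form with two
  limits: `f_loc = f_s + (1 − f_s) f_d` when transport is fast, and
  `f_loc = 1 / (1 + (1 − f_s)(1 − f_d)/f_d)` when switching is fast,
  where `f_s = k_S/(k_S + k_U)` and `f_d = k_R/(k_R + k_L)`. Only the
  second regime loses localization as the proximal volume `f_d → 0` —
  sensitivity to MVF requires fast competence switching.
* **Translation.** A Gillespie simulation tracks every ribosome:
  initiation at `k_init` when the first codon is free, elongation at
  `k_elong` with a one-codon exclusion footprint, termination, and mRNA
  decay at `k_decay = 0.0017 s⁻¹`. A ribosome past codon
  `l_MTS = 100` carries a translated MTS; in the maturation model the
  MTS becomes binding-competent only after an exponential delay with
  mean `τ_MTS` (folding/chaperone engagement). The mean numbers of
  exposed and mature MTSs have closed forms,
  `β = k_init (L − l_MTS)/k_elong` and its maturation-corrected
  analogue `β_mature`.
* **Diffusion.** The cytoplasm around a mitochondrial tubule is modelled
  as concentric cylinders: a binding shell (25 nm), an imaging shell
  (250 nm) and an outer reflecting wall set by the MVF
  (`R = r_m/√(f_m/0.8)`). Motion between shells is sampled exactly with
  spectral (Bessel-eigenfunction) first-passage distributions — no time
  discretization. A competent mRNA entering the binding shell binds
  irreversibly until its last competent MTS terminates.
* **Measurement.** Per-trajectory localized fractions are averaged with
  lifetime weights, the way imaging and biochemical assays sample mRNAs.

Gene-specific rates are estimated from protein-per-mRNA (`P`) and
ribosome-occupancy (`occ`) data calibrated on *TIM50*
(`k_init = α P / T_div`, `k_elong ∝ k_init/occ`, `α = 45.14`,
`T_div = 90 min`, `k_elong,TIM50 = 4 aa/s`).

## Worked example

Median conditional and constitutive genes at 4% MVF with a 40 s MTS
maturation time, 50 trajectories each:

```r
library(mitoloc)

geom  <- geometry_from_mvf(0.04)
mat40 <- competence_model("maturation", tau_MTS = 40)
conditional  <- gene_kinetics(0.3253, 14.5086, 393, name = "conditional-median")
constitutive <- gene_kinetics(0.1259,  7.7468, 483, name = "constitutive-median")

for (g in list(conditional, constitutive)) {
  cfg  <- simulation_config(g, mat40, geom, n_trajectories = 50L, seed = 1L)
  recs <- simulate_ensemble(cfg)
  cat(sprintf("%-20s  binding %.3f   imaging %.3f   CHX %.3f\n", g$name,
              ensemble_localization(recs, "binding"),
              ensemble_localization(recs, "imaging"),
              ensemble_chx_localization(recs)))
}
```

```
conditional-median    binding 0.504   imaging 0.541   CHX 0.888
constitutive-median   binding 0.712   imaging 0.726   CHX 0.838
```

The conditional gene is weakly localized at low MVF but would jump to
~0.89 under CHX (every translated MTS stays exposed); the constitutive
gene is already localized and responds little. The closed forms explain
why: at `τ_MTS = 40 s` the conditional median keeps only
`β_mature = 1.41` competent MTSs with a 3.7 s mature exposure time —
shorter than the 9.6 s diffusive search time at 4% MVF — while the
constitutive median keeps `β_mature = 2.65` exposed for 14.0 s:

```r
beta_mature(conditional, 1/40)                       # 1.41
mature_exposure_time(conditional, 1/40)              # 3.67 s
mean_search_time(geom$r_a, geom$R_out, geom$D)       # 9.56 s
mature_exposure_time(constitutive, 1/40)             # 14.01 s
```

A command-line front end (`inst/cli/mitoloc.R`) exposes the same
machinery as `fourstate`, `closedform`, `rates`, `synth`, `simulate`
and `sweep` subcommands, and `run_experiment()` drives YAML-configured
runs with tab-separated outputs and a manifest.

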