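# adti — activity-dependent diffusion tensor model of axonal water flux

`adti` is an R package for neuroimaging physicists and white-matter
modellers who want to ask, quantitatively: *if a fiber tract is conducting
action potentials while a diffusion-weighted MR image is acquired, how much
should its diffusion tensor change, and could we see it?*

During conduction, sodium influx through channels at the nodes of Ranvier
(myelinated axons) and along the membrane (unmyelinated axons) co-transports
water across the axonal membrane, perpendicular to the fiber axis; an equal
water mass leaves with the potassium efflux. The package models the fraction
of voxel water rendered briefly free-diffusing by this exchange and
propagates it through the diffusion tensor:

- fast-water fraction over one diffusion time Δ:
  `f_w* = F_w · Δ / m_water`, where `F_w = 2 (N_MA n_NR S_NR ρ_NR +
  N_nMA S_nMA ρ_nMA) N_w / t` is the bidirectional water flow of the
  channel population;
- perturbed tensor: `λ1* = λ1 = D_∥` (unchanged),
  `λ2* = λ3* = D_⊥* = f_w* D_free + D_⊥`;
- observables: `D_app = (λ1+λ2+λ3)/3`,
  `FA = √(3/2) · √(Σ(λi−λ̄)² / Σλi²)`, and the Stejskal–Tanner echo
  `A = A0 exp(−b D)` with `b = (γgδ)²(Δ−δ/3)`.

The prediction, for a corticospinal-tract–like bundle: mean diffusivity up
~1.8%, FA down ~2.1%, a perpendicular echo drop of ~0.77% at
b = 600 s mm⁻² — just above a 3σ detection threshold at SNR 400. A built-in
synthetic DWI phantom (voxel grid, Rician noise, log-linear tensor refit)
tests whether that FA decrease is recovered under noise.

## Worked example

```r
library(adti)
model <- adti_model()          # default corticospinal-tract bundle
summary(model)
```

```
Activity-dependent diffusion tensor model
  fast-water fraction f_w* = 0.00428 (diffusion time 35 ms)
  eigenvalues inactive: (1e-09, 2e-10, 2e-10) m^2/s
  eigenvalues active:   (1e-09, 2.13e-10, 2.13e-10) m^2/s
  D_app 4.67e-10 -> 4.75e-10 m^2/s (+1.8%)
  FA    0.770 -> 0.754       (-2.1%)
  echo drop at b = 600 s/mm^2: 0.77%
  detection at SNR 400 (z = 3): yes (margin +0.00017)
```

Reading this: 0.43% of the voxel's water is exchanged across axonal
membranes during one 35 ms diffusion time. Mixed in as free water, it
raises both perpendicular eigenvalues from 2.00 to 2.13 ×10⁻¹⁰ m²/s,
which lowers the fractional anisotropy from 0.770 to 0.754. The
perpendicular diffusion-weighted echo at b = 600 s mm⁻² drops by 0.77%,
marginally above the 3σ/SNR = 0.75% detection threshold of an SNR-400
acquisition.

`reproduce_report(model)` prints every intermediate of this chain (channel
counts, water in-flows, `f_w*`, perturbed diffusivities, FA pair, percent
changes) next to its published reference value and flags agreement at the
reported precision. Noisy detectability is a one-liner:

```r
simulate(model, nsim = 20, seed = 7, snr = 400)
```

```
Phantom experiment: 16x16x16 grid, 1280 tract voxels, rician noise (SNR 400), 20 repetition(s)
  tract FA: 0.7698 (inactive) -> 0.7538 (active)
  tract-mean dFA = -0.016 (sd 0.00019), dFA/FA = -2.08%
  detection rate (dFA < 0): 1.00
```

Sensitivity analyses (`param_sweep("diffusion_time", c(20, 35, 70))`) and a
command-line front end (`inst/scripts/adti` with subcommands `reproduce`,
`sweep`, `phantom`) round out the interface. The methods vignette
(`vignettes/activation-model.Rmd`) documents the model assumptions, the
mixing-rule modes, the phantom's scope and the numerical choices.

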