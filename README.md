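# dpdlipid

Dissipative particle dynamics (DPD) for lipid–nanoparticle melts: a
coarse-grained simulation engine plus the analysis pipeline for the
equilibrium structure, chain dynamics, and interfacial mechanics of
lamellar and hexagonal lipid mesophases loaded with nanoparticles.

## Who this is for

Soft-matter and computational-biophysics researchers who want a small,
fully scriptable R implementation of the standard DPD melt model — head
(H) / tail (T) lipid chains with single-bead nanoparticles (N) — with the
observables used to characterise amphiphile self-assembly: density
profiles, orientational order, gyration tensors, and Irving–Kirkwood
stress/tension profiles.

## The model

Beads interact through the three canonical DPD pair forces along
r̂<sub>ij</sub>,

- conservative: F<sup>C</sup> = a<sub>ij</sub> (1 − r/r<sub>c</sub>) r̂ for r < r<sub>c</sub>,
- dissipative: F<sup>D</sup> = −γ w²(r) (r̂·v<sub>ij</sub>) r̂,
- random: F<sup>R</sup> = σ w(r) ζ<sub>ij</sub> Δt<sup>−1/2</sup> r̂, with σ² = 2 γ k<sub>B</sub>T,

plus harmonic bonds F = k<sub>s</sub>(1 − r/r<sub>s</sub>) r̂ and harmonic
angles k<sub>θ</sub>(θ − θ<sub>0</sub>)² along each chain, integrated with
the Groot–Warren modified velocity-Verlet scheme (λ = 0.65) under periodic
boundaries in the NVT ensemble — the dissipative/random pair is the
thermostat.  Defaults: a<sub>ii</sub> = 25, a<sub>ij</sub> = 100
(χ = 0.286 Δa ≈ 21.5), σ = 3, γ = 4.5, k<sub>s</sub> = 120,
r<sub>s</sub> = 0.7 r<sub>c</sub>, k<sub>θ</sub> = 6, θ<sub>0</sub> = π,
Δt = 0.01 τ, ρ = 3 beads/r<sub>c</sub>³.  All quantities are in reduced
units (r<sub>c</sub>, k<sub>B</sub>T, m, τ).

Key analysis quantities:

- order parameter ⟨P₂(cos θ)⟩ = ⟨(3cos²θ − 1)/2⟩ over chain directions
  (1 aligned with z, −0.5 perpendicular, 0 isotropic);
- chain-averaged gyration components R<sub>g,αα</sub> from the per-chain
  bead-averaged second moment about the centre of mass;
- pressure tensor p<sub>αα</sub> = (1/V)[Σ m v<sub>α</sub>² +
  Σ<sub>i&lt;j</sub> F<sub>ij,α</sub> r<sub>ij,α</sub>] and interfacial
  tension σ<sub>z</sub> = p<sub>zz</sub> − (p<sub>xx</sub> + p<sub>yy</sub>)/2,
  both globally and slab-resolved along z via the Irving–Kirkwood
  line-segment partition (the slab average equals the global tension
  identically).

## Worked example

A scaled lamellar melt — one repeat of the natural ~15 r<sub>c</sub> period —
with and without nanoparticles:

```r
library(dpdlipid)

ff  <- dpd_forcefield()              # a_ii = 25, a_ij = 100, sigma = 3, gamma = 4.5
box <- box_spec(15, density = 3)     # 10,125 beads

run_one <- function(phi) {
  top <- lipid_mixture_topology(3, 10, phi, box)       # NH = 3, NT = 10
  fr  <- place_preassembled(top, box, "lamellar", seed = 20)
  fr  <- init_velocities(fr, kT = 1)
  r   <- dpd_run(fr, top, ff, run_config(n_steps = 3000, seed = 21,
                                         sample_every = 250))
  keep <- r$trajectory$frames[7:13]                     # plateau window
  sig  <- sapply(keep, tension_global, top, ff, include = "conservative")
  rg   <- gyration_components(keep, top)
  c(phi = phi, p2 = order_parameter_mean(keep, top),
    tension = mean(sig), rg_zz = mean(rg$rg_zz))
}

rbind(run_one(0), run_one(0.15))
#>       phi        p2   tension    rg_zz
#> [1,] 0.00 0.6860359 0.6834576 2.224777
#> [2,] 0.15 0.7674594 0.2762979 2.282879
```

Read: both melts stay lamellar (order parameter ≈ 0.7, chains aligned with
z); the pure melt carries a positive interfacial tension concentrated at
its two H/T interfaces; loading nanoparticles at φ<sub>NP</sub> = 0.15
lowers the tension and stretches the chains along z (larger
R<sub>g,zz</sub>) — the qualitative signature of nanoparticles relieving
interfacial stress in a lamellar matrix.

The full-scale four-concentration study (D = 30, 300k steps, six seeds) is
driven by a YAML config through `run_experiment()`; see
`?run_experiment` and `inst/scripts/run_experiment.R`.

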