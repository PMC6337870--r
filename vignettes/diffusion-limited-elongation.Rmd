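---
title: "Diffusion-limited translation elongation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-limited translation elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`elongsim` simulates translation elongation in *E. coli* as a
diffusion–collision process. The substrate of elongation is the ternary
complex EFTu·GTP·aminoacyl-tRNA; since EFTu is limiting relative to the tRNA
pool, the number of complexes equals the EFTu copy number (more precisely
`min(EFTu, total tRNA)`, so that extreme perturbation scenarios remain
well-defined). Complexes perform a random walk on a periodic cubic lattice
representing a sub-volume of the cytoplasm; ribosomes sit at fixed lattice
sites, each translating its own copy of the target coding sequence.

Events are generated with the Gillespie direct method. Each complex carries
two channels:

* **travel**, with per-direction rate $d = D/h^2$ (total $6D/h^2$ in 3-D),
  obtained by discretizing the diffusion equation with central differences;
* **dissociation**, first-order with rate $k_\mathrm{diss}$.

The total propensity is $\alpha_0 = N\,(6D/h^2 + k_\mathrm{diss})$ with $N$
the complex count, waiting times are $\tau = \ln(1/r_1)/\alpha_0$, and the
fired channel is the smallest index whose cumulative propensity exceeds
$r_2\alpha_0$. Because all complexes share one travel rate and one
dissociation rate, channel selection factorizes into (travel vs
dissociation) followed by a uniform molecule choice — mathematically
identical to the direct method's cumulative scan, but O(1) per event.

A jump that lands a complex on a site holding a ribosome whose current codon
is served by the complex's tRNA species — and whose catalytic idle time has
expired — is a successful encounter: the ribosome advances one codon
(wrapping to the first codon at the end of the sequence; initiation and
termination are outside the model's scope) and becomes refractory for
$t_\mathrm{cat} = 1/24\,\mathrm{s}$, the reciprocal of the maximum specific
elongation rate of 24 aa/ribosome/s. The delivered tRNA instantly rejoins
the free pool; the freed EFTu immediately re-binds a uniformly chosen free
tRNA *molecule* (species weighted by free counts) and the new complex is
placed at a uniformly random site. Dissociation triggers the same
release/re-bind/relocate sequence without elongation. These rules conserve
every per-species tRNA total, the EFTu count, and the ribosome count exactly
— asserted by tests over $10^7$ events.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `D` | 2.567e-12 | m²/s | ternary-complex diffusion coefficient |
| `h` | 20 | nm | grid spacing = assumed ribosome + complex collision distance |
| `k_diss` | 1 | 1/s | ternary-complex dissociation rate |
| `t_cat` | 1/24 | s | ribosome refractory time after elongation |
| volume | 0.064 | µm³ | reaction sub-volume (20³ lattice at h = 20 nm) |
| ribosomes / EFTu | 1044 / 9122 | molecules | copy numbers at growth rate 1.1 h⁻¹ |
| tRNA | 36 species, 10 827.8 total | molecules | per-species pool at 1.1 h⁻¹ |
| burn-in / stop | 1000 / 5000 | events | analysis window of a run |

The grid spacing deserves emphasis: the lattice collision rule ("same site =
collision") makes the encounter rate proportional to $D\,h/V$, so *h* sets
the absolute scale of the diffusion-limited search time. Physically *h* is
the sum of the ribosome and ternary-complex radii; the published model never
states the radii, so 20 nm (a typical ribosome diameter) is a documented,
configurable default that also yields an even number of grid points (20 per
side) in the 0.064 µm³ volume. Absolute elongation rates, the in vitro/in
vivo ratio, elasticities and the ATP-allocation optimum all shift with *h*;
see "Known limitations" below.

Boundary conditions are periodic (the volume represents bulk cytoplasm, so
walls would be artifacts). Sites can hold any number of molecules (no
excluded volume). If several eligible ribosomes share the destination site,
one is chosen uniformly. The RNG is a seeded Mersenne Twister
(`std::mt19937_64`) private to each run, so traces are bit-reproducible
given the seed on any platform.

## Jump-rate convention

The discretized diffusion equation yields $d = D/\Delta x^2$ as the rate of
jumping to *one* adjacent site; the total per-molecule jump propensity in
3-D is $6D/h^2$. An alternative reading treats $D/h^2$ as the *total* rate
split 1/6 per direction; that convention does not reproduce the continuum
limit. We adopt the per-direction convention and verify it with a tracer
oracle: the mean squared displacement of non-reacting walkers must equal
$6Dt$ (it does, within three standard errors over thousands of tracers).
Note that the two conventions differ by a factor of six in the encounter
rate, which propagates directly into absolute elongation times.

## Sequences and the synthetic generator

Coding sequences are mapped codon-by-codon to tRNA species through a
bundled one-to-one table: wobble reading is collapsed so each of the 61
sense codons is served by exactly one species, following the isoacceptor
naming of the bundled abundance table. The generator
`synth_codon_sequence(length, adaptation, ...)` draws codons independently
from a mixture: with probability `adaptation` proportionally to the cognate
species' abundance (divided evenly among that species' codons, so sampled
species demand matches pool supply exactly at `adaptation = 1`), otherwise
uniformly over the sense codons. `adaptation = 1` emulates a native,
codon-optimized gene (the bundled `tufa_like_synthetic.fasta`, 394 codons,
the length of EFTu); `adaptation = 0` emulates a non-adapted heterologous
gene (`gfp_like_synthetic.fasta`, 238 codons, the length of GFP). The
bundled FASTA fixtures are *synthetic*: the real tufA and GFP coding
sequences are not bundled, so analyses tied to the exact codon order of
those genes (e.g. the codon-optimized GFP* comparison) can only be
approximated by the adaptation parameter. What the generator does not
emulate: codon autocorrelation along real genes, position-dependent codon
bias, repeated-codon runs (His-tags), and mRNA secondary structure.

## Analysis conventions

* **Burn-in.** The initial placement is random and all ribosomes start
  reaction-ready, so early encounter times are not representative; the
  first 1000 of 5000 elongation events are discarded in the default
  full-volume window.
* **Rates.** The ribosome-specific elongation rate is the OLS slope of
  cumulative elongation count over event times, divided by the *total*
  ribosome count of the volume (not the instantaneous non-idle count).
  Replicate errors are standard errors over ten seeds derived
  deterministically from a master seed.
* **Slope comparison.** Two traces are compared by
  $z = (b_1 - b_2)/\sqrt{SE_1^2 + SE_2^2}$ with $df = n_1 + n_2 - 4$; the
  default window (events 1001–3000 from each trace) gives $df = 3996$.
* **Control coefficients.** The substrate elasticity scales EFTu and all
  tRNA species jointly by $1 \pm \delta$ (complexes are EFTu-limited, so the
  ternary-complex pool is perturbed as one unit; an EFTu-only variant is a
  trivial modification of `perturb_scenario`); the flux control coefficient
  scales ribosomes only. Both use central differences of $\ln v$ over
  $\ln c$ with $\delta = 0.1$ — large enough to clear replicate noise at ten
  seeds, small enough for the log-linear approximation. $v$ is the
  translation rate of the whole volume, so when the ribosome pool itself is
  perturbed the per-ribosome normalization is undone. Applied to noise-free
  power laws $v = c^a$ the estimator returns $a$ exactly.
* **ATP allocation.** Budget shares are converted to added molecules by
  `floor(share × budget / cost)` with per-molecule costs (108 461, 700,
  3 565) ATP equivalents for ribosome/tRNA/EFTu; added tRNAs are split over
  species proportionally to the baseline abundances (largest-remainder
  rounding; a uniform-per-species alternative is available because it
  changes which species stop limiting). Normalized rates are
  volume-translation-rate fold-changes against the unaltered scenario run
  with the same seeds. The published per-ribosome total (108 461) differs
  by 2 from the sum of its published components (42 934 + 35 689 + 29 836 =
  108 459); the printed total is shipped.

## Problem sizes and relaxation

Per-ribosome quantities are intensive: a 0.008 µm³ volume with all counts
scaled by 1/8 reproduces the 0.064 µm³ per-ribosome rate within replicate
error (a tested property). Sweep-heavy analyses therefore run in the
reduced volume with burn-in and stop windows scaled by the same 1/8, which
keeps per-ribosome sampling equal. One caveat discovered during
development: near the catalytic cap the relaxation of the free-tRNA pool
composition and of the ribosome idle phases is slow compared with the
default window (5000 events at full volume is only ~5 events per ribosome),
and too-short windows bias *comparisons across ribosome counts* (the raw
FCC estimate moves from ~0.4 to ~0.95 as the window grows). Control
analysis and the allocation sweep therefore default to deeper windows
(burn-in ≈ 4 events per ribosome) in this package; single-scenario rates
use the standard 1000/5000 window, where the residual bias is below a
percent. For the same reason `concentration_sweep()` scales its analysis
window with each point's scaled ribosome count (a fixed event count would
sample 40× less relaxation time at `rel_conc = 2` than at `0.05`); the
scaling has floors of 400 stop / 160 burn-in events and can be disabled.

## Degenerate inputs and numerical choices

Scaling can round a rare species to zero molecules; the species then simply
never reacts, and the event is reported. Scenarios whose ribosome or total
tRNA count rounds to zero fail loudly ("degenerate scenario"), as do runs
with no ternary complexes ("stalled system") and runs that exceed the event
guard (default $10^9$ SSA events) before reaching the stop criterion — the
stall diagnosis names the exhausted species. Fractional published tRNA
counts are rounded half-up at simulation start (the expected error is below
one molecule per species). Ties among eligible ribosomes are broken
uniformly at random. All molecule-count rounding is half-away-from-zero.

## Known limitations

* Absolute rates are set by the product $D\,h/V$; since *h* is not fixed by
  the published parameterization, absolute elongation rates carry a
  systematic uncertainty that does not cancel in concentration ratios. With
  the defaults (per-direction jump rate, h = 20 nm), the in vivo system is
  only mildly diffusion limited — per-ribosome rates sit close to the
  24 aa/s catalytic cap, dilution to in vitro levels halves rather than
  quintuples-down the rate, and the substrate elasticity at in vivo
  concentrations is small. Reproducing strongly diffusion-limited published
  behaviour requires either the total-rate jump convention (which breaks
  the MSD oracle) or a collision distance several-fold below 20 nm.
* No ribosome–ribosome interference, no initiation/termination, no
  aminoacylation kinetics (recharging is instantaneous by construction),
  no mRNA secondary structure.
* Whether the published abundance table already excludes ribosome-bound
  tRNAs is not stated; the model treats the whole pool as
  ternary-complex-eligible.
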