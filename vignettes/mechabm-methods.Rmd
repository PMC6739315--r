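---
title: "The mechabm hybrid simulator: model, assumptions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The mechabm hybrid simulator: model, assumptions and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Osteoblasts sense mechanical load through integrins anchored between the
plasma membrane and the extracellular matrix (ECM). How sensitive an
integrin is — the smallest force that activates it, its mechanosensitivity
threshold (MT) — and how that sensitivity is distributed across the
integrin population together determine how long a cell keeps signalling
under constant load. mechabm simulates this feedback loop: tissue-level
shear is focused onto individual integrins by a closed-form elasticity
solution; activated integrins launch a stochastic, particle-based
FAK–Ras–Raf–MEK–ERK cascade; nuclear pERK drives Runx2-dependent
transcription of four osteogenic matrix genes (ALP, OPN, OCN, BSP); the
translated proteins are secreted and stiffen the ECM, which in turn reduces
the force reaching every integrin (mechanoreciprocity).

## The mechanical model

The cell is a sphere of radius $R$ (10 µm) and shear modulus $\mu_C$
embedded in an ECM of modulus $\mu_M$, joined by a linear-spring interface
of stiffness $\alpha$, loaded by a uniform far-field shear
$\sigma_{xy,\infty}$. With $\eta = \mu_C/\mu_M$ and $k = \alpha R/\mu_M$,
the normal stress at the interface point $(\theta,\phi)$ is

$$\sigma_{rr} \;=\;
\frac{5\eta k}{\,6(2\eta+k) + \dfrac{4\eta k\,(71\eta+16k)}{152\eta+19\eta k+16k}\,}
\;\sigma_{xy,\infty}\,\sin^2\!\theta\,\sin 2\phi .$$

The denominator is implemented exactly as this expression is written; the
mixed term $152\eta + 19\eta k + 16k$ is dimensionally odd but is treated
as authoritative, and `compute_sigma_rr()` exposes it for sensitivity
analysis through the elastic parameters. Each of $N$ equal integrins tiles
an area $4\pi R^2/N$, an equal-area circle of radius $a = 2R/\sqrt{N}$; the
force on an integrin is $F = \pi a^2 \sigma_{rr}$, with the within-patch
stress variation neglected (for $N = 500$ the mean absolute within-patch
deviation of the angular pattern is about 4–5 % of its global maximum;
`patch_variation()` computes it).

None of $\mu_C, \mu_M, \alpha, \sigma_{xy,\infty}$ is published. The
defaults choose the symmetric non-dimensional point $\eta = k = 1$
($\mu_C = \mu_M = 1000$ Pa, $\alpha = \mu_M/R$) and set
$\sigma_{xy,\infty} = 15.8$ Pa so that the *reference force* — the peak
per-integrin force at time zero, at $\theta = \pi/2, \phi = \pi/4$ — is
10 pN, the top of the 2–10 pN range integrins are reported to sense.
Thresholds are fractions of this reference force: 10 % (sensitive class)
or 1 % (ultrasensitive class). Only tension activates; the compressive
hemisphere ($\sin 2\phi < 0$) never does, which is why at most half the
population can be active (the ultrasensitive model peaks near 49 %).

Four population variants are supported: homogeneous sensitive (`SM`),
homogeneous ultrasensitive (`USM`), and heterogeneous mixes with 10 %
(`HM10`) or 1 % (`HM1`) of the population ultrasensitive. The named
percentages are used by default (50 or 5 of 500, rounded); the alternative
reading of the 1:10 / 1:100 mixing ratios as 1/11 and 1/101 is selectable
(`ratio_convention = "odds"`). Ultrasensitive members are drawn uniformly
at random from a dedicated sub-seed, so changing variant does not perturb
any other draw.

## ECM stiffening

Every deposited matrix protein raises ECM elasticity by a nominal
increment of 0.001 whose units are unpublished. Three conventions are
implemented (`update_ecm_modulus()`): linear relative
($\mu_M(n) = \mu_0(1+0.001n)$), per-deposit compounding
($\mu_0 \cdot 1.001^n$), and the calibrated default, a power law
$\mu_M(n) = \mu_0 (1 + 0.001 n)^\beta$ with $\beta = 1.56$. The exponent is
the single parameter that reconciles two published timescales: an
all-sensitive population must fall silent on the order of three hours
(requiring roughly an 11-fold force reduction after a few thousand
deposits), while ultrasensitive integrins must remain active far beyond
eight hours under continued deposition. The linear rule cannot silence the
sensitive model within days; full compounding kills the ultrasensitive
model within hours; $\beta = 1.56$ does both jobs at the deposition rates
the model itself produces.

## The agent world

All 8 892 molecular agents (500 integrins, 1000 FAK, 1000 Ras, 32 Raf,
3400 MEK, 2300 ERK, 24 Runx2, 24 transcription complexes, 600 ribosomes,
2 mRNA and 1 protein per gene) live in a spherical cell of radius 10 µm
with a 4 µm nucleus, at 1 nm spatial and 1 s temporal resolution.
Integrins are static on the membrane, placed on a deterministic equal-area
Fibonacci lattice by default. Mobile agents take independent Gaussian
steps of variance $2D\,\Delta t$ per axis, reflecting at the compartment
boundaries they may not cross; ERK (in all states) crosses the nuclear
envelope freely — which produces the nuclear/cytoplasmic pERK exchange the
pathway needs — and mRNA is exported from the nucleus but not re-imported.

Reactions are encounter-driven: a catalyst reacts with the nearest
receptive partner within the pair's interaction radius (ties to the lower
agent id), each agent participating in at most one reaction per step.
After a reaction both participants receive activation-cycle-switch (ACS)
dormancy timers; active states carry finite lifetimes drawn from a
truncated exponential (memoryless within a hard cap at five times the
mean), and expiry returns an agent to its receptive basal state — the
model's black-box stand-in for dephosphorylation and negative feedback.
The published model gives none of these constants numerically; the
defaults in `kinetics_params()` are this package's calibration (below).

Two activation steps are *distributive*, requiring two successive
catalytic hits through a decaying intermediate: Ras activation (two pFAK
encounters) and ERK activation (two pMEK encounters, the classic
double-phosphorylation). These are what make the cascade's response to the
number of active integrins strongly superlinear at the bottom — so that a
handful of ultrasensitive integrins sustains a pERK baseline two orders of
magnitude below the plateau — while the scarce Raf pool (32 molecules)
saturates at the top, flattening the plateau and sharpening the
downstream response (the fitted Hill steepness orders Raf ≤ MEK ≤ ERK
under a step stimulus, as expected for a kinase cascade).

A small basal channel activates a random ERK at ~0.15 events/s for a
1–4 s transient, giving a mean resting pERK of ~0.25 molecules. This is
required for a finite fold-change of the late pERK baseline over the
pre-stimulus level; its short lifetime keeps the per-replicate basal
estimate stable over the 600 s burn-in.

Gene expression: nuclear pERK activates Runx2; active Runx2 engages a
transcription complex, which emits one mRNA of a uniformly chosen gene
after a 30–90 s delay and then rests. Cytoplasmic mRNA meeting a ribosome
yields a Gaussian number of proteins (mean 2.5, sd 0.5, truncated at
zero); both then rest. Translated proteins are secreted 60 s later:
the agent is removed and the deposited-ECMp counter — the quantity the
mechanical model feels — increments by one. Signalling-produced mRNA decays
with a 1/1800 s per-step hazard; the census baseline pool (2 copies per
gene) is held static, standing for the basal transcript steady state in
which synthesis balances decay, so a world with zero signalling stays
exactly at its census.

## The hybrid loop

Each one-second step executes, in fixed order: (1) coupling exchange — the
current deposit count sets $\mu_M$, forces are evaluated at every integrin
and compared with its threshold — and mechanical priming; (2) Brownian
moves; (3) reaction resolution; (4) expression timers (transcription,
mRNA decay, secretion); (5) ACS/lifetime ticks; (6) sampling every 100th
step (t = 0 included). Priming is stochastic: an unbound integrin whose
force is at or above threshold activates with probability $1/240$ per
second (a geometric delay, mean 4 min, config-exposed including zero).
An instantaneous-priming default would put the peak active-integrin count
at $t=0$; the stochastic delay reproduces the observed activation phase,
with the population peak emerging 20–30 min into loading as priming races
the stiffening-driven loss of eligibility. Deactivation on force loss is
likewise delayed (60 s), so active counts decay on the ACS timescale
rather than instantly.

All randomness flows through four independent xoshiro256++ streams
(placement/thresholds are drawn R-side from derived sub-seeds; motion,
reactions, expression and basal events each have their own compiled
stream), making runs bit-reproducible and mechanisms independently
toggleable. Replicates use deterministically derived per-replicate seeds,
so serial and concurrent execution give identical results.

## Calibration

About ten effective constants (interaction radii per reaction pair, active
lifetimes, ACS durations, the priming delay, the basal rate, transcription
and translation parameters, the mRNA lifetime and the stiffening exponent)
were calibrated once, by stage-wise mean-field design followed by
simulation at the default study conditions, against the published emergent
dynamics: the sensitive model's decline onset, integrin silence near
180 min and pERK extinction near 360 min; the ultrasensitive model's
~49.8 % peak activation and deposition rates (~13 ECMp/min initially,
rising as the transcript pool accumulates); and the 1 % heterogeneous
model's pERK maximum (~669 molecules), 25 min integrin peak, and the
mechanical-memory baseline (~3 % of the maximum, ~80-fold over basal).

Two published values are *not* reproducible in this model family and are
reported as found. First, the combination "pERK maximum at ~7 min" with
"decline onset at ~93 min" requires a peak that stands clear of the
plateau's stochastic envelope while the plateau stays within 10 % of that
peak for 90 minutes; at the published count scale (~650 molecules) the
birth–death shot-noise floor (~4 %) makes these jointly unattainable, and
the calibration favours the decline-onset anchors' flat-then-collapse
shape, so the recorded time of maximum scatters across the early plateau.
Second, a sustained third-phase count of ~12 active integrins in the 1 %
heterogeneous model is incompatible with all-sensitive silence by
180 min: forces are shared, deterministic and monotone in cumulative
deposits, and the heterogeneous model always deposits at least as much as
the sensitive one, so by the time its sensitive majority must be silent
only its ~5 ultrasensitive members (about half of them on the tensile
hemisphere) can remain — the stable phase holds 2–3 active integrins here,
not 12.

## What the simulator does and does not show

The generator's defaults are the study conditions: 500 integrins, constant
unidirectional shear, four variants, 1 s steps, 100-step sampling, 16
replicates by default (8 in the acceptance runs), horizons of 6–10
simulated hours (all cited transitions occur within 8 h; multi-day
horizons run fine but add nothing to the checks). Problem sizes in the
test suite are chosen so the whole suite runs in tens of minutes on one
CPU.

Real osteoblasts are not spheres; cytoskeletal and actomyosin mechanics,
integrin recruitment and turnover, crowding, cell-shape change and
osteocyte signalling are all outside the model, as are explicit
phosphatases (ACS expiry stands in for them). Passing the acceptance
anchors therefore shows that the *mechanistic skeleton* — threshold
mechanosensation, ultrasensitive cascade, expression-coupled
stiffening — reproduces the published dynamics, not that the kinetic
constants are biologically measured quantities.

## Numerical notes

Degenerate inputs are handled explicitly: zero far-field stress gives zero
force everywhere and no activation; a zero-diffusion species never moves;
a zero-mean translation yield still consumes the encounter; all-zero
series segment into a single null phase; a zero basal level flags the
fold-change as infinite rather than dividing. Reflection at spherical
boundaries is radial with a midpoint fallback for pathological double
bounces; the neighbour search uses a 400 nm uniform grid verified against
a linear scan; Gaussian deviates come from a ziggurat sampler checked
against the $\langle r^2\rangle = 6D\,\Delta t$ law. Phase segmentation
defaults (active ≥ 50 % of the maximum, stable = tail within ±50 % of its
own median for ≥ 30 samples) are config-exposed; they are conventions, not
published values.
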