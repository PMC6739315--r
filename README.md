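# mechabm

A hybrid mechanical / agent-based simulator of integrin-initiated ERK
mechanotransduction in an osteoblast, for researchers studying how the
mechanosensitivity of a cell's adhesion receptors shapes the duration of
its response to mechanical load.

A spherical cell (radius *R*) sits in an extracellular matrix (ECM) under
a constant far-field shear stress. The normal stress at the cell-ECM
interface has the closed form

σ<sub>rr</sub> = 5ηk / [ 6(2η+k) + 4ηk(71η+16k)/(152η+19ηk+16k) ] ·
σ<sub>xy,∞</sub> · sin²θ · sin 2φ,

with η = µ<sub>C</sub>/µ<sub>M</sub> the cell/ECM shear-modulus ratio and
k = αR/µ<sub>M</sub> the interface-spring number. Each of N = 500 static
integrins tiles an equal area of the membrane (patch radius a = 2R/√N) and
feels the force F = πa²σ<sub>rr</sub>. An integrin activates when F meets
its mechanosensitivity threshold (MT) — 10 % of the 10 pN reference force
for *sensitive* integrins, 1 % for *ultrasensitive* ones; four population
variants (`SM`, `USM`, `HM10`, `HM1`) mix the two classes.

Active integrins drive a particle-based stochastic cascade of 8 892
molecular agents (FAK → Ras → Raf → MEK → ERK → Runx2 → transcription of
ALP/OPN/OCN/BSP → translation → secretion) at 1 nm / 1 s resolution.
Every deposited matrix protein stiffens the ECM
(µ<sub>M</sub> = µ<sub>0</sub>(1 + 0.001·n)<sup>β</sup>), which lowers the
force on every integrin — the mechanoreciprocity feedback that eventually
silences sensitive populations while ultrasensitive ones persist, and that
lets a 1 % ultrasensitive minority hold an elevated pERK baseline long
after the bulk response has decayed (mechanical memory).

## A worked example

```r
library(mechabm)
cfg <- run_config("HM1", duration = 7200, seed = 42)  # 2 h, 1% mix
sim <- run_sim(cfg)
print(sim)
#> mechabm simulation: variant HM1, 7200 s stimulated, seed 42
#>   73 samples; basal pERK 0.262
#>   pERK peak 692 at 68.3 min; active integrins peak 209; 2252 ECMp deposited
summary(sim)
#> Variant HM1, monitored species pERK
#> E_max = 692 at t = 4100 s; EC50 = 346 first reached at t = 1400 s (73 samples)
#> overall ECMp rate 20.79 /min; final ECM modulus 6.29e+03 Pa
#> phases:
#>   start  end  label
#> 1     0 1300 active
#> 2  1400 7200 stable
```

Reading this: after a 600 s unstimulated burn-in the basal pERK level is
~0.26 molecules. Under load, about 209 of the 500 integrins engage
(the tensile hemisphere minus the stochastic priming lag), the doubly
phosphorylated ERK pool rises to ~690 of 2 300 ERK molecules and holds a
plateau, ~2 200 matrix proteins are secreted in two hours (~21/min), and
the accumulated deposits have already stiffened the ECM six-fold.
`plot(sim)` draws the three panels (active integrins, pERK, per-gene
cumulative deposits); `run_replicates(cfg, n = 16)` gives the replicate
set with median ± IQR aggregation (`aggregate_replicates`) and the usual
group tests (`compare_groups`, `compare_variants`).

There is also a shell interface:

```sh
Rscript inst/exec/mech-abm run --variant USM --duration 3600 --seed 7 --out runs/
Rscript inst/exec/mech-abm replicates --n 16 --variant HM1 --out runs/
Rscript inst/exec/mech-abm analyze --in runs/ --metric perk --out runs/
```

which writes one CSV per run plus a JSON manifest sufficient to reproduce
it bit-for-bit.

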