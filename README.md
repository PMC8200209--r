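# carbsorb

Isomer-dependent physisorption of 4-methylcyclohexane methanol (MCHM) on
carbon surfaces, and the temperature-driven desorption kinetics that follow.

After the 2014 Elk River spill, granulated activated carbon (GAC) at the
Kanawha Valley water treatment plant removed MCHM only partially — and
months later, as the river warmed, MCHM reappeared at the plant *outflow*
while undetectable at the intake. `carbsorb` is a desk-scale implementation
of the proposed mechanism: trans-MCHM physisorbs a few kcal/mol more
strongly than cis-MCHM to amorphous carbon, so the filter preferentially
retains the trans isomer, and Arrhenius/Maxwell–Boltzmann kinetics then
predict a strongly temperature-dependent, isomer-skewed release. It is
aimed at environmental/interfacial chemists who want the whole argument —
structures, binding differences, kinetics, statistics — as reproducible,
tested code.

## The model

Two isomers whose desorption activation energies differ by Δε desorb at a
rate ratio

    r_cis / r_trans = exp(Δε / k_B T),

and the total desorption rate at temperature T is proportional to the
Maxwell–Boltzmann high-energy fraction above the barrier E_a,

    frac_hi(E_a, T) = Q(3/2, E_a / k_B T)
                    = erfc(√x) + (2/√π) √x e^(−x),  x = E_a / k_B T.

The **enhancement factor** EF(T1→T2) = frac_hi(E_a,T2) / frac_hi(E_a,T1)
says how much faster everything desorbs after a warm-up; splitting each
desorbing population 1:1-adsorbed by the rate ratio gives isomer-resolved
counts and per-isomer EFs. The binding difference Δε itself comes from a
pairwise van-der-Waals physisorption engine: synthetic PAH flakes and
hydrogen-capped amorphous-carbon slabs, MCHM chair conformers, rigid-body
pose minimization, a 7 kcal/mol conformer retention window, and 12 Å
hydrogen-capped cluster carving with an electron-parity screen.

## Worked example

The isomer-resolved desorption bookkeeping for Δε = 2.4 kcal/mol, using the
published relative-rate table bundled with the package:

```r
library(carbsorb)
ref <- reference_rate_table()
r0  <- ref$ratio[ref$delta_eps == 2.4 & ref$temp_c == 0]    # 106
r30 <- ref$ratio[ref$delta_eps == 2.4 & ref$temp_c == 30]   #  67
p0  <- partition_desorbed(1000,  r0,  "nearest")
p30 <- partition_desorbed(20000, r30, "nearest")
p0
#> <partition_result> total 1000 -> cis 991 / trans 9 (nearest rounding)
p30
#> <partition_result> total 20000 -> cis 19706 / trans 294 (nearest rounding)
isomer_specific_EF(p0, p30)
#> <ef_result> EF_total = 20.000, EF_cis = 19.885, EF_trans = 32.667
```

Of 1000 molecules desorbing at 0 °C only 9 are the strongly-bound,
strongly-odorous trans isomer; a 30 °C summer releases 20× more MCHM
overall but ~33× more trans — which is why warming filters smell.

The warm-up that mattered in spring 2014 (0 → 10 °C at the MMFF94x-scale
barrier of 7.2 kcal/mol):

```r
co <- constants_profile("codata")
(enhancement_factor(7.2, celsius_to_kelvin(0), celsius_to_kelvin(10), co) - 1) * 100
#> [1] 57.10193   # percent increase in the total desorption rate
```

## Analysis workflow

The full analysis is a sequence of thin scripts over the package functions,
writing tables under `results/`:

| script | what it does |
|---|---|
| `analysis/01_build_structures.R` | PAH flake, MCHM conformer sets, 5×5×3 nm amorphous slab |
| `analysis/02_physisorption.R` | 40 poses/isomer, rigid minimization, Δε extraction, cluster carving |
| `analysis/03_kinetics.R` | constant calibration, rate-table replica, EF curves, partition examples |
| `analysis/04_ensemble_stats.R` | t-test/Cohen's d on binding ensembles, seasonal temperature windows |

Run them in order with `Rscript`. Stage 2 takes tens of minutes on one
core; everything else is seconds. `run_pipeline()` / `replica_mode()` drive
the same chain from a single seeded `run_config()`.

On the surrogate surface the chain reproduces the qualitative headline
(seeded output of stages 2 and 4):

```
cis:   M = 16.99, SD = 1.74, n = 39
trans: M = 19.23, SD = 1.47, n = 40
delta_eps (trans - cis) = 2.24 kcal/mol
surrogate ensemble: t(78) = 6.27, p = 1.9e-08, d = 1.40
```

The trans isomer binds more strongly on the amorphous surface, with a
clearly significant separation — but the magnitudes are qualitative: the
engine uses generic UFF pair parameters, not the original force fields, so
only the kinetics downstream of a *given* Δε is quantitative.

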