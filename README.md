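# frrfit

Single-turnover chlorophyll fluorescence analysis for fast repetition
rate fluorometry (FRRf), aimed at algal photophysiologists who measure
rapid light curves and induction–recovery experiments and want the full
chain — raw flashlet transients to quantum-yield partitions and absolute
electron transport rates — as tested, scriptable code.

FRRf excites photosystem II (PSII) with a train of 40 microsecond
flashlets that cumulatively drive a single photochemical turnover. frrfit
models the induction rise with the connectivity-corrected closure mapping

    F(C) = F0 + (FM − F0) · C(1 − ρ) / (1 − ρC),

advancing the closed fraction C per flashlet by the exact flow of
dC/dE = σ(1 − C)/(1 − ρC) over the flashlet dose E, and the relaxation
decay with the biexponential reopening C(t) = C0(α1·e^(−t/τ1) +
α2·e^(−t/τ2)). Bounded least-squares fits of the two curves estimate
(F0, FM, σ_PSII, ρ) and (τ1, τ2, α1). Paired in-light / 1-s-dark
measurements at each light step then yield

    qP      = (FM′ − FS)/(FM′ − F0′)       F0′ = F0′₁ₛ · FM′/FM′₁ₛ
    Y(PSII) = (FM′ − FS)/FM′
    Y(NPQ)  = FS/FM′ − FS/FM               Y(PSII) + Y(NPQ) + Y(NO) ≡ 1
    Y(NO)   = FS/FM
    ETR     = E_Å · σ_PSII′ · Y(PSII) / ((FM − F0)/FM)   [e⁻ PSII⁻¹ s⁻¹]

A seeded generator synthesizes complete experiments with realistic
photoacclimation dynamics — thresholded, time-dependent Y(NPQ) induction
with incomplete dark reversal, σ_PSII′ declining linearly with Y(NPQ)
(slope −0.65), τ1 rising with excitation pressure and halving after
sustained high-light exposure, and a DTT mode with regulated quenching
disabled — so the whole pipeline runs and is tested without instrument
data. See `vignettes/frrfit-methods.Rmd` for the model details and design
choices.

## Worked example

Simulate the canonical non-sequential rapid light curve (nine 30 s steps:
34, 74, 114, 300, 470, 300, 470, 540, 74 µmol photons m⁻² s⁻¹ after a
dark-adapted reference), fit every transient, and assemble the per-step
table:

```r
library(frrfit)
exp <- simulate_experiment(generator_config(seed = 42))
tab <- pair_measurements(exp$transients, exp$train)
round(tab$records[, c("par","Y_PSII","Y_NPQ","Y_NO","ETR","sigma_p","tau1_light")], 3)
#>  par Y_PSII  Y_NPQ  Y_NO     ETR sigma_p tau1_light
#>   34  0.575  0.000 0.425  78.530 400.601    589.082
#>   74  0.539 -0.002 0.463 159.860 399.868    686.325
#>  114  0.490 -0.001 0.511 217.325 388.252    832.447
#>  300  0.337 -0.001 0.664 418.263 412.920   1168.812
#>  470  0.263  0.084 0.653 445.205 359.493   1110.712
#>  300  0.350  0.082 0.568 400.032 379.932   1382.093
#>  470  0.405  0.161 0.434 720.382 378.128    551.997
#>  540  0.379  0.236 0.385 696.677 339.579    549.793
#>   74  0.548  0.232 0.220 136.842 336.786    610.423
```

Read the table top to bottom: Y(NO) rises from its dark value 0.4 with
increasing PAR until, above the ~305 µmol m⁻² s⁻¹ threshold, regulated
quenching Y(NPQ) switches on and keeps growing with *time* rather than
light level; σ_PSII′ shrinks as Y(NPQ) grows; and τ1 climbs with
excitation pressure until the high-light history halves it (551 µs at the
470 revisit against 1110 µs at the first visit). That acceleration is
what upregulates electron transport at revisited light levels:

```r
upregulation_index(tab)
#>   par first_visit_ETR revisit_ETR     ratio n_visits
#> 1  74        159.8605    136.8422 0.8560100        2
#> 2 300        418.2634    400.0321 0.9564117        2
#> 3 470        445.2055    720.3825 1.6180899        2
```

ETR at the 470 revisit is 1.62× its first visit (upregulation), while the
final return to the growth irradiance of 74 sits *below* its first visit
(ratio 0.86) because Y(NPQ) is still engaged. The cross-measurement
regression recovers the generator's σ′–Y(NPQ) coupling:

```r
acclimation_regressions(tab)$sigma_vs_npq
#> <regression_result> slope=-0.5966 intercept=0.9724 R^2=0.819 p=0.000788 n=9
```

(the generator's true slope is −0.65; pooling the two induction–recovery
treatments as `scripts/acceptance.R` does tightens the estimate).

The same pipeline is scriptable from the command line:

```sh
Rscript -e 'frrfit::frrf_cli()' simulate --seed 42 --out out/
Rscript -e 'frrfit::frrf_cli()' pipeline --transients out/transients.csv --out out/
Rscript -e 'frrfit::frrf_cli()' regress --records out/records.csv --out out/
```

All outputs are plain CSV/JSON with provenance headers (package version,
seed, config hash) and are byte-identical across reruns at the same seed.

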