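# rldesign

Evolutionary QSPR tools for designing rhamnolipid (RL) biosurfactants from
harmonized literature and laboratory data.

## The problem

Rhamnolipids are microbial glycolipid surfactants whose properties — the
hydrophobicity of the product (logP_RL, driven by the mono-/di-rhamnolipid
balance) and its ability to solubilize a compound of interest (the molar
solubilization ratio, MSR) — depend on many entangled cultivation and
formulation variables. Published data are fragmented and reported under
heterogeneous conventions, so choosing a feedstock and cultivation recipe for
a *target* application is mostly trial and error.

`rldesign` implements a complete computational workflow for this problem:

1. **Databases** — validated tabular schemas for cultivation experiments
   (feedstock descriptors, conditions, product logP_RL) and solubilization
   experiments (solubilizate/biosurfactant descriptors, conditions, MSR),
   with CSV round-tripping and per-row provenance.
2. **Harmonization** — literature-reduction rules: mass-fraction weighted
   logP/MV descriptors for mixtures, resolution of partially reported
   mono/di congener compositions (default 35/65 split), C:N ratio derivation
   and cross-checking.
3. **Imputation** — chained-equations regression imputation of missing
   descriptor cells, refused above a 10% missingness gate.
4. **GEP engine** — gene expression programming symbolic regression:
   fixed-length Karva chromosomes, protected operators, random numerical
   constants, elitist evolution against RMSE, i.e.
   `logP_RL = f(feedstock, conditions)` and
   `logMSR = f(solubilizate, biosurfactant, conditions)`.
5. **Protocol** — repeated random 80:20 train/validation splits (3 splits x
   10 runs by default), selection by validation RMSE, R-squared reporting,
   producer-group submodels (general / *Pseudomonas* / *Burkholderia*).
6. **Sensitivity** — permutation importance and derivative-sign contribution
   percentages per descriptor.
7. **Applicability domain** — per-descriptor training ranges; forward
   calculators warn outside them, inverse design refuses to leave them.
8. **Lab reduction** — CMC from surface-tension isotherms (two-line
   intersection in log-concentration space) and MSR from the slope of
   solubility curves above the CMC.
9. **Synthetic data** — generators emulating both databases (descriptor
   ranges, nonlinear truths with known sign structure, noise, missingness)
   so the whole pipeline is testable offline.
10. **Calculators** — forward prediction, inverse design of cultivation
    recipes, and a scriptable CLI.

## Worked example

```r
library(rldesign)

# emulate the cultivation database, fill the missing cells, fit a model
g   <- gen_production_dataset(160, seed = 101, noise_sd = 0.05)
imp <- mice_impute(g$data)
cfg <- gep_config(terminals = rl_schema("production")$model_descriptors,
                  generations = 1200, pop_size = 60,
                  rates = list(rnc_mutation = 0.1), seed = 202)
ens <- fit_protocol(imp, cfg = cfg, n_splits = 2, n_runs = 3)
ens$selected$metrics$r2_validation
#> [1] 0.9772482
```

The selected model explains ~98% of held-out variance of the synthetic
truth. Its sensitivity report recovers the generating sign structure —
feedstock hydrophobicity pushes logP_RL up, shaking pushes it down:

```r
head(sensitivity_report(ens$selected, imp, seed = 99), 2)
#>   descriptor importance rank positive_pct negative_pct zero_pct
#> 2     logP_C  1.0000000    1          100            0        0
#> 7    shaking  0.5764067    2            0          100        0
```

Reduce raw lab measurements and use the calculators:

```r
lc <- seq(0.2, 2.8, length.out = 14)                      # log10 mg/L
iso <- data.frame(conc = 10^lc,
                  tension = ifelse(lc <= 1.5, 70 - 20 * lc, 40))
cmc_from_isotherm(iso$conc, iso$tension)$cmc
#> [1] 31.62278    # mg/L, the constructed breakpoint

m <- ens$selected                  # or read_model("model_general.json")
predict_logp_rl(m, as.list(as.data.frame(imp)[1, m$descriptors]))$logP_RL
#> [1] 6.550207
```

Inverse design — which cultivation conditions give a product with logP_RL in
a target window:

```r
invert_production_model(m, target = c(5.5, 6.0), seed = 1)[1:3, ]
#>     conc_C   logP_C   conc_N CN_ratio       pH temperature  shaking     time
#> 1 67674.72 5.018763 6731.036 627.7269 6.547706    34.76425 191.0498 158.6963
#> 2 64288.91 4.993961 8341.371 325.3935 6.442947    29.13870 147.3270 184.7384
#> 3 97155.58 4.443426 7632.871 278.0134 5.479701    26.63505  32.6192 161.3175
#>   predicted
#> 1  5.749284
#> 2  5.750773
#> 3  5.751845
# candidate cultivation conditions inside the applicability domain, ranked
# by closeness of the predicted logP_RL to the 5.75 range midpoint
```

## Command line

```sh
Rscript inst/cli/rldesign synth --schema production --n 213 --seed 1 --out rl.csv
Rscript inst/cli/rldesign pipeline --config config.yaml
Rscript inst/cli/rldesign labcalc-cmc --in isotherm.csv
```

Exit codes: 0 success, 2 validation error, 3 no solution (inverse design),
4 out-of-domain refusal.

## Documentation

The methods vignette (`vignettes/rldesign-methods.Rmd`) documents the model,
its assumptions, every tunable parameter, the synthetic world, and known
limitations.
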