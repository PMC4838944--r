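# ivoryxrf

Species assignment of elephant tusks from handheld X-ray fluorescence (XRF)
elemental panels. Wildlife-forensics labs and customs officers need a
non-destructive way to tell Asian (*Elephas maximus*) from African
(*Loxodonta africana*) ivory; DNA typing is the gold standard but is slow,
destructive and fails on some material. A handheld XRF unit reports the
relative abundance of ~24 elements (Mg–Pb, plus a pooled light-element
remainder) from a five-minute surface scan, and the two species differ
systematically in that panel.

`ivoryxrf` implements the complete statistical chain — the *Bayesian hybrid
classification model* — that turns scan tables into origin calls:

1. percent → ppm conversion (× 10,000) and replicate averaging into
   per-specimen panels;
2. element screening: site ANOVA (E0–E3 longitudinal, four transverse
   planes), Welch species/sex/layer contrasts, CVs, Pearson correlations,
   Ward clustering;
3. ratio features over a reference denominator chosen by three criteria
   (detected with CV < 1 in both species; at most slightly heterogeneous;
   species-different) — Zr in the canonical model, with the valid-data
   fraction tracked for specimens whose denominator is undetected;
4. stepwise linear discriminant analysis (Wilks' lambda, F-to-enter /
   F-to-remove) giving the canonical discriminant value
   `DV = w'x + b`, `w ∝ Sw⁻¹(μ_African − μ_Asian)`, validated by
   leave-one-out classification;
5. Bayesian binary regression `y ~ Bernoulli(F(β₀ + β₁·DV))` under logit,
   probit and cloglog links with N(0, 1/0.001) priors, adaptive Metropolis
   MCMC, Gelman–Rubin/Geweke diagnostics, and DIC link selection;
6. a probability cut-off chosen by Cohen's kappa (> 0.8) plus the highest
   accuracy/precision, with `p ≥ cutoff → African`.

A seeded synthetic-cohort generator (log-normal abundances, Gaussian-copula
inter-element correlation, within-species heterogeneity, detection-limit
censoring) stands in for real scan archives, so the whole chain is testable
end to end.

## Worked example

```r
library(ivoryxrf)

train <- generate_scans(synthetic_config(seed = 1))                      # 72 Asian + 85 African
test  <- generate_scans(synthetic_config(n_asian = 30, n_african = 41,
                                         seed = 501))
res <- run_pipeline(train, test, denominator = "Zr", link = "auto",
                    chains = 3, burnin = 2000, iter = 8000, seed = 1)
res$bundle$discriminant
```

```
Two-class discriminant function
  8 ratio(s): Mg/Zr, Si/Zr, P/Zr, Ti/Zr, Ag/Zr, Cd/Zr, Sn/Zr, Sb/Zr
  eigenvalue 1.985; centroids Asian -1.58 / African 1.24
  leave-one-out accuracy 96.7% (n = 152)
```

Eight element ratios over Zr separate the species with eigenvalue ≈ 2 (the
between/within variance ratio of the DV); 152 of 157 training tusks had a
detectable Zr denominator (valid data ≈ 97%). The independent cohort then
validates the assembled classifier:

```r
res$independent$confusion
res$independent$metrics$accuracy
```

```
         prediction
truth     Asian African
  Asian      22       7
  African     1      38
[1] 88.24
```

and the posterior probability clouds sit where a working classifier should:
true Africans average ~0.96 probability of African origin, true Asians
~0.05, with the kappa-selected cut-off at 0.45–0.55 depending on the
cohort draw.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_simulate_cohorts.R` … `05_validate_independent.R`); each writes its
summary tables under `results/` and prints what it found. Reference metric
arithmetic is exact: confusion counts (64, 8, 6, 79) give kappa 0.82,
accuracy 91.08%, mean-PPV precision 91.12%; counts (29, 1, 3, 38) give
accuracy 94.37%.

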