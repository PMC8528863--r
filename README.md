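# mitorestore

Pathway-wise penalized linear models for targeted-proteomics panels, with
protein-grouped **composite Minimax Concave Penalty (cMCP)** bi-level
selection, post-selection refitting, and treatment-restoration summaries —
plus the frozen-tissue respiratory-complex activity arithmetic
(oxygen-consumption traces, citrate-synthase normalization, enzyme
kinetics) that accompanies such studies.

## Who this is for

Groups analyzing selected-reaction-monitoring (SRM) proteomics of disease
and rescue: a panel of ~10²  proteins quantified across a few dozen
animals spanning genotype (wild type; a hypomorphic *PKD1* mutation over a
hypomorphic or a null second allele) and treatment
(mitochondria-targeted catalase, mCAT, vs. vector). The same machinery
applies to any samples × proteins table with a protein→pathway panel and
group/treatment metadata.

## The model

For sample *i* and protein *j*, on the relative-abundance scale
(wild-type baseline ≈ 1):

    y_ij = α_j + β_j·x_pkd + γ_j·x_dose + δ_j·x_mcat + η_j·x_mcat·x_dose + ε_ij

where `x_pkd` marks disease genotypes, `x_dose` the severe (null-allele)
genotype, `x_mcat` treatment, and ε_ij ~ N(0, σ_j²). Per pathway, proteins
are stacked into one regression; each protein's four effect columns form a
penalty group under the composite MCP

    P(β) = Σ_g MCP( s_g/λ ; K_g·λ, γ_out ),   s_g = Σ_k MCP(|β_gk|; λ, γ_in)

solved by coordinate descent with firm thresholding along a decreasing λ
grid, with BIC model choice, and ordinary-least-squares refitting on the
selected support for the reported estimates, standard errors and p
values. Per protein the pipeline emits the mutation, gene-dosage and
treatment effects, the restoration percentage `100·δ/(−β)`, and
significance flags; per pathway, full-membership averages (unselected
effects count as exact zeros) and flag counts.

## Worked example

```r
library(mitorestore)

res <- run_pipeline(run_config(simulate = sim_config(seed = 7)))
res$summary[1:4, c("pathway", "mean_pkd_effect", "restored_of_means")]
#>       pathway mean_pkd_effect restored_of_means
#> 1         TCA      -0.3247839          48.15679
#> 2         FAO      -0.3046753          79.57049
#> 3 Respiratory      -0.2662289          44.43837
#> 4 Antioxidant      -0.2159418          65.79515
res$counts
#>        altered     suppressed dose_prominent    ameliorated  reversed_gt10
#>             92             88             67             52             52
```

Read: on this simulated 27-sample, 137-protein study, the TCA-cycle
pathway is suppressed by ~32% on average under the *PKD1* mutation, and
treatment restores ~48% of that suppression; 92 of 137 proteins are
significantly altered. The generator's defaults encode study-scale
conditions (TCA −0.31, FAO −0.29, respiratory complexes −0.28; FAO
restoration ~80.7%; catalase overexpressed ~64% under treatment), so a
run recovers values of this order with seed-to-seed variation.

Flux assays:

```r
tr <- simulate_ocr_trace(c(substrate = 100, inhibitor = 20),
                         n_cycles = 20, noise_sd = 2, seed = 1)
act <- complex_activity_from_trace(tr, cs_activity = 10)
unlist(act[c("raw", "cs_normalized")])
#>           raw cs_normalized
#>     20.092512      2.009251   # pmol O2/min/ug, and the CS ratio
```

A thin command-line wrapper lives at `inst/cli/run_pipeline.R`
(`--config cfg.json --out DIR --seed N`).

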