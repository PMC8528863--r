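---
title: "Pathway-wise bi-level selection for targeted proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-wise bi-level selection for targeted proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Targeted (selected-reaction-monitoring) proteomics panels quantify on the
order of a hundred pre-selected proteins across a modest number of animals.
In the polycystic-kidney-disease setting this package addresses, kidneys
from mice carrying a hypomorphic *PKD1* mutation — either over a second
hypomorphic allele (RC/RC, slowly progressive disease) or over a null
allele (RC/null, rapidly progressive disease) — are profiled with and
without treatment by mitochondria-targeted catalase (mCAT), alongside
wild-type controls. Four scientific questions attach to every protein *j*
in every metabolic pathway:

* is the protein suppressed by the mutation (a *PKD1 effect*,
  $\beta_j$)?
* is the suppression stronger in the more severe genotype (a *gene-dosage
  effect*, $\gamma_j$)?
* does treatment push abundance back toward normal (an *mCAT effect*,
  $\delta_j$)?
* does the treatment effect differ between genotypes (an interaction,
  $\eta_j$)?

With 27 samples and five free parameters per protein, protein-by-protein
regression is saturated and noisy, and the interesting statements are
pathway-level. The package therefore fits **one penalized regression per
pathway**, stacking all of the pathway's proteins, and uses a grouped
nonconvex penalty to decide simultaneously *which proteins* respond at all
and *which of their effects* are needed — bi-level selection.

## The model

Abundances are relative to an internal standard and normalized so the
untreated wild-type baseline sits near 1; effects are therefore read as
fractions (an effect of $-0.31$ is a 31% decrease). For sample $i$ and
protein $j$:

$$ y_{ij} = \alpha_j + \beta_j x_{pkd}(i) + \gamma_j x_{dose}(i) +
\delta_j x_{mcat}(i) + \eta_j\, x_{mcat}(i)\,x_{dose}(i) +
\varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma_j^2) $$

with indicator covariates: $x_{pkd} = 1$ for disease genotypes (RC/RC or
RC/null), $x_{dose} = 1$ for RC/null only, $x_{mcat} = 1$ under treatment.
Heterozygous RC/+ animals are phenotypically normal and encode as
$x_{pkd} = 0$. The five design cells (WT, RC/RC, RC/RC+mCAT, RC/null,
RC/null+mCAT) exactly identify the five per-protein parameters, so with
zero noise unpenalized least squares reproduces the generating values —
one of the test suite's oracle checks.

Within a pathway the stacked design is block-diagonal: each protein
contributes an unpenalized baseline indicator and four penalized effect
columns, and the four effect columns form that protein's penalty group.

## The composite MCP penalty and its construction

The minimax concave penalty (MCP) is
$\rho(\theta; \lambda, \gamma) = \lambda\theta - \theta^2/(2\gamma)$ for
$\theta \le \gamma\lambda$ and constant $\gamma\lambda^2/2$ beyond; unlike
the lasso it applies no shrinkage to sufficiently large effects. Bi-level
selection composes two MCPs: an inner one over member magnitudes and an
outer one over each group's inner sum. This package uses

$$ P(\beta) \;=\; \sum_g \rho\!\left( \frac{s_g}{\lambda};\;
K_g \lambda,\; \gamma_{out} \right), \qquad
s_g = \sum_{k \in g} \rho(|\beta_{gk}|; \lambda, \gamma_{in}), $$

where $K_g$ is the group size (4 effects per protein). Two choices here
are deliberate:

* **Group-size scaling.** The outer regularization level is $K_g\lambda$,
  so larger groups face a proportionally larger budget before the group
  enters — the standard group-penalty convention.
* **The $s_g/\lambda$ argument.** Applying the outer MCP to the inner sum
  *divided by* $\lambda$ makes the composite penalty homogeneous:
  $P(c\beta; c\lambda) = c^2 P(\beta;\lambda)$. Consequently (i) rescaling
  all abundances by $c$ and the tuning grid by $c$ rescales every
  coefficient by exactly $c$, so effects, restoration percentages and all
  significance flags are invariant to the units of the abundance table, and
  (ii) the smallest $\lambda$ at which the penalized solution is entirely
  zero has the closed form $\lambda_{max} = \max_k |x_k'r_0/n| / K_{g(k)}$
  (with $r_0$ the residual from the baseline-only fit), linear in the data
  scale. Applying the outer MCP to the raw inner sum — the other natural
  reading of the composite construction — loses both properties, which is
  why this form was chosen.

Defaults: $\gamma_{in} = \gamma_{out} = 3$ (the conventional MCP
concavity), a 100-point log-spaced grid from $\lambda_{max}$ down to
$10^{-3}\lambda_{max}$, convergence tolerance $10^{-8}$ on the maximum
coefficient change per sweep, and at most $10^4$ sweeps per grid point.

## The algorithm

The solver is cyclic coordinate descent with warm starts along the
decreasing grid. For a penalized coordinate the outer penalty is locally
linearized at the current inner sum: with multiplier
$w_g = \partial \rho_{out}/\partial s_g$, the coordinate update minimizes
$\tfrac12(b - z)^2 + w_g\,\rho(|b|; \lambda, \gamma_{in})$ exactly. Because
$w\,\rho(|b|;\lambda,\gamma) = \rho(|b|; w\lambda, \gamma/w)$, this is the
**firm-threshold** operator when $\gamma_{in}/w_g > 1$; when the multiplier
is so large that the surrogate becomes concave, the minimizer lies at one
of three candidate points (zero, the plateau edge, or the unpenalized
solution) and is found by direct comparison. Since the outer MCP is
concave in $s_g$, the linearization majorizes the true objective, so every
exact coordinate update descends — the per-sweep objective is
non-increasing by construction, and the suite asserts it.

Unpenalized baseline columns are refit exactly each sweep. Penalized
columns are centered and scaled to $x'x/n = 1$ once, at design
construction; the recorded transform is inverted when coefficients are
reported, with the centering constants folded into the baseline
coefficients (the baseline indicators partition every stacked row, so the
constant is exactly representable). An active-set refinement — cycling
only nonzero coordinates until stable, then verifying with a full sweep —
accelerates the path without changing fixed points.

Nonconvexity caveat: coordinate descent certifies only a stationary
point. The test suite therefore checks coordinate-wise stationarity
(`kkt_check`) on every selected model and compares path solutions with
brute-force lattice enumeration on problems small enough to enumerate;
global optimality is not claimed in general.

## Model choice, refitting and summaries

The tuning value is chosen by BIC, $n\log(RSS/n) + df\,\log n$ with $df$
the number of nonzero coefficients, ties resolved toward the sparser
(larger-$\lambda$) model. BIC rather than cross-validation keeps the whole
pipeline deterministic for a given seed. Because MCP-type penalties leave
large coefficients essentially unshrunken, the selected support is then
**refit by ordinary least squares**, protein by protein (the stacked
design is block-diagonal, so the joint refit decomposes exactly), with the
residual variance re-estimated per protein; reported estimates, standard
errors and two-sided t tests come from this refit. Effects outside the
support are exact zeros and carry no p value.

Per-protein significance flags (at $\alpha = 0.05$ by default, no
multiplicity correction — the selection step already sparsifies, and a
Benjamini–Hochberg option is exposed but off by default):

* *altered*: mutation or dosage effect selected and significant;
* *suppressed*: altered with a negative mutation effect;
* *dose-prominent*: dosage effect selected, significant, same sign as the
  mutation effect;
* *ameliorated*: treatment effect selected, significant, opposing the
  mutation effect;
* *reversed by >10%*: ameliorated with restoration strictly above 10%.

The restoration percentage is $100\,\delta_j/(-\beta_j)$, undefined (and
reported as missing, never as zero) when $\beta_j = 0$. The treatment
effect feeding it is the RC/RC-scale main effect $\delta_j$ by default;
the RC/null-scale variant $\delta_j + \eta_j$ is always emitted alongside,
since either convention is defensible. Pathway summaries average over the
*full* membership with unselected effects contributing exact zeros — the
meaning of non-selection — and report both the mean of per-protein
restoration ratios and the ratio of pathway means.

## What the synthetic generator emulates

The generator reproduces the statistical structure the models assume, at
the study's dimensions: 27 samples (4 WT, 9 RC/RC, 7 RC/RC+mCAT, 4
RC/null, 3 RC/null+mCAT) and 137 proteins in 8 pathways, with the
fatty-acid-oxidation (FAO) and TCA-cycle panels at their study sizes of 22
and 26. Its defaults encode, as generating truth, the study-scale
conditions: full-membership mean PKD1 effects of $-0.31$ (TCA), $-0.29$
(FAO) and $-0.28$ (respiratory complexes); pathway restoration ratios
sized so the pathway-level restoration percentages sit at 47.8%, 80.7%,
53.7% and 62.1% (TCA, FAO, respiratory complexes, antioxidants); a
catalase protein with no suppression and a $+0.64$ treatment effect; and a
sparse "affected-protein" structure in which only a subset of each
pathway's proteins carries effects, so that roughly 98 of 137 proteins are
truly altered and roughly 65 truly treatment-responsive. Gene-dosage
effects are tied to the mutation effect ($\gamma_j = 0.5\beta_j$ plus
noise). Residual noise is Gaussian and homoscedastic per protein
($\sigma = 0.1$ on the relative scale, giving signal-to-noise above 3 for
the strongly suppressed pathways), and baselines are drawn around 1 (SD
0.1). The antioxidant restoration ratio (0.45) accounts for catalase's
contribution to that pathway's mean treatment effect.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: peak-integration artifacts, missingness,
heteroscedastic or correlated residuals across proteins, batch structure,
or any nonlinearity in the abundance scale. Ground-truth effects are
returned alongside the table for recovery tests but are never written
into the abundance file.

## Flux assays

A second, independent tool set implements the respiratory-complex
arithmetic for frozen-tissue extracellular-flux assays. Oxygen-consumption
traces are piecewise-constant per injection phase (substrate first, then
inhibitor, e.g. NADH then rotenone for complex I); the phase level is the
mean of the last 3 measurement cycles before the next injection,
discarding post-injection equilibration (a standard flux-assay practice;
the cycle count averaged is configurable). Raw complex activity is the
substrate-phase minus inhibitor-phase mean divided by protein loaded
(default 4 µg per well), in pmol O₂/min/µg; negative values are returned
unclipped with a warning flag. Activities are optionally normalized to
citrate synthase activity as a mitochondrial-mass proxy. Enzyme activities
come from the least-squares slope of absorbance kinetics via Beer–Lambert:
$|dA/dt|/(\varepsilon \ell)$ (mM/min) scaled by reaction volume and
normalized to protein mass (nmol/min/mg), reported as a positive magnitude
so product-accumulation (DTNB/TNB, $\varepsilon = 13.6$ mM⁻¹cm⁻¹ at
412 nm) and substrate-consumption (NADH, 6.22 mM⁻¹cm⁻¹ at 340 nm) assays
read the same way. Extinction coefficients and the 1 cm path length are
overridable defaults. The companion power computation for two-group
comparisons uses the noncentral t distribution with noncentrality
$d\sqrt{n/2}$ and $2n-2$ degrees of freedom.

## Worked example

```{r, eval = FALSE}
library(mitorestore)

res <- run_pipeline(run_config(simulate = sim_config(seed = 7)))
res$summary[, c("pathway", "mean_pkd_effect", "restored_of_means")]
res$counts

tr <- simulate_ocr_trace(c(substrate = 100, inhibitor = 20),
                         n_cycles = 20, noise_sd = 2, seed = 1)
complex_activity_from_trace(tr, cs_activity = 10)
```

## Numerical choices and degenerate inputs

* $\lambda_{max}$ is inflated by a relative $10^{-6}$ so the first grid
  point is strictly inside the all-zero region (at exact equality,
  floating-point noise can admit a phantom coefficient of order
  $10^{-17}$, which would corrupt the BIC's degrees of freedom).
* Constant penalized columns (e.g. a dosage covariate when no RC/null
  samples are present) standardize to all-zero columns that can never be
  selected, rather than erroring.
* A singular unpenalized baseline block is an error; so is a
  rank-deficient refit, reported with the offending protein and terms.
* Missing abundances abort design construction with the sample and
  protein named; nothing is imputed.
* Ties in the BIC resolve toward larger $\lambda$; non-converged grid
  points are flagged and excluded from selection, and selection fails
  only if no grid point converged.

## Problem sizes used in the checks

The test suite runs the full study-scale configuration (27 samples, 137
proteins, 8 pathways) for parameter-recovery and null-calibration checks
at 100 simulation seeds each, brute-force lattice enumeration on 2–3
coefficient problems, and a $10^5$-replicate Monte-Carlo oracle for the
power computation; these sizes keep each property estimable with
comfortable margins while the whole suite runs in minutes.

## Known limitations

* Exact reproduction of a specific study's printed tables depends on that
  study's tuning choices (grid, concavities, selection criterion), which
  are not fully determined by a methods section; the package exposes all
  of them as parameters.
* Only a stationary point of the nonconvex objective is guaranteed.
* The pooled-variance penalized fit assumes comparable residual scales
  across a pathway's proteins; grossly heteroscedastic panels would need
  per-protein pre-scaling.
* Post-selection p values from the refit are not corrected for the
  selection event itself; they match the reporting convention the
  pipeline emulates, and the restoration-percentage denominators inherit
  the refit's sampling noise.
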