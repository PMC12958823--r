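---
title: "Causal trait networks in genomic evaluation: models and methods"
author: "bnsem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal trait networks in genomic evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multitrait genomic evaluation treats every relationship between traits as a
symmetric covariance. Real traits, however, can act on one another: a tree's
height influences its wood density and its carbon isotope ratio, not the other
way around. `bnsem` implements an evaluation pipeline that (i) fits a standard
multitrait individual-tree mixed model (MTM), (ii) learns a directed acyclic
network among the traits from the predicted breeding values, and (iii) refits
the evaluation as a recursive structural equation model (SEM) on that network,
so that genetic parameters, breeding values and predictive ability can be
compared between the two views. The package is written around a nine-trait
open-pollinated lodgepole pine breeding population (productivity: HT, WD;
defense: WGR, LIMO, T_MONO; climate adaptation: RES, DECL, C13, CAR), but all
components are generic in the number of traits.

## Models

**Multitrait mixed model.** For tree $i$ and traits $j = 1,\dots,t$:
$$ y = X\beta + a + e,\qquad a \sim N(0,\ \Sigma_a \otimes K),\qquad
   e \sim N(0,\ R_0 \otimes I), $$
with unstructured genetic ($\Sigma_a$) and residual ($R_0$) covariance
matrices. $K$ is the pedigree numerator relationship matrix $A$ (ABLUP),
built by the tabular method, or the VanRaden genomic relationship matrix
$G = WW'/2\sum_k p_k(1-p_k)$ (GBLUP), built from filtered (missingness
$\le$ 30%, MAF $\ge$ 1%), mean-imputed SNP dosages. Because $W$ is centered
on the sample allele frequencies, $G\mathbf{1} = 0$ exactly; a ridge of
$10^{-6}$ is added to the diagonal and recorded whenever the smallest
eigenvalue is numerically zero.

**Recursive SEM.** The structural form
$$ y_i = \Lambda y_i + X_i'\beta^* + a_i^* + e_i^* $$
adds a strictly lower-triangular (in causal order) coefficient matrix
$\Lambda$ whose sparsity pattern comes from the learned network; solving gives
the reduced form $y_i = (I-\Lambda)^{-1}(X_i'\beta^* + a_i^* + e_i^*)$. With
$\Lambda = 0$ the SEM coincides with the MTM exactly.

**Network learning.** Predicted breeding values inherit the kinship
covariance, violating the exchangeability assumed by network scores. With
$K = LL'$ (Cholesky), the transformed values $a^* = L^{-1}\hat a$ are
independent across trees while keeping the trait covariance. On $a^*$ the
package runs score-based search — Hill-Climbing (with optional restarts from
random DAGs: plain greedy search can stall in local optima even on four
variables) and Tabu — under the Gaussian
BIC (per-node log-likelihood minus $\frac{|pa|+2}{2}\log n$) or the BGe
marginal likelihood (normal-Wishart prior: mean 0, $\alpha_\mu = 1$,
$\alpha_w = d + 2$, scale $I$; exactly score-equivalent across
Markov-equivalent DAGs). Uncertainty is quantified by bootstrap model
averaging: edge strength is the fraction of row-resamples whose learned
network contains the edge in either direction, direction confidence the
fraction of the majority orientation among those. The consensus keeps edges
with strength at or above the threshold (default 0.95, as in the reference
analysis with 5,000 replicates; desk analyses use a few hundred); if majority
orientations ever close a cycle, the arc with the weakest direction
confidence is dropped iteratively — a case the averaging literature leaves
open, resolved here deterministically.

## Gibbs sampler

Both models are fitted by a single compiled Gibbs sampler. The kinship is
eigendecomposed once, $K = U\,\mathrm{diag}(d)\,U'$; rotating rows by $U'$
leaves $R_0 \otimes I$ intact and makes the rotated breeding values
row-independent with covariance $d_i\Sigma_a$, so each sweep updates: the
genetic-group means (matrix normal, flat prior), each tree's $t$-vector of
breeding values (conditional normal), $\Sigma_a$ and $R_0$ (inverse-Wishart,
prior df $t+2$, scale $0.5I$ — proper but weak on standardized traits), the
free entries of $\Lambda$, and any missing phenotypes (drawn from their
reduced-form conditional given the observed traits — the data-augmentation
treatment of the unequal record counts per trait).

Two numerical choices deserve emphasis.

* **Collapsed $\Lambda$ update.** $\lambda$ trades off against the genetic
  covariances along a near-ridge of the posterior. Conditioning the
  $\lambda$ draw on the sampled breeding values makes the chain random-walk
  along that ridge (effective sample sizes below 1% of retained draws in our
  experiments). The sampler therefore draws all free $\lambda$ jointly with
  the breeding values integrated out: in the rotated basis the rows of
  $(I-\Lambda)\tilde Y$ are independent $N(\tilde X\beta,\ d_i\Sigma_a + R_0)$,
  which is linear in $\lambda$, giving a closed-form joint normal conditional.
  The subsequent breeding-value draw conditions on the new $\Lambda$, so the
  pair is a valid blocked update.

* **Identifiability of the recursive system.** With unstructured $\Sigma_a$
  *and* unstructured $R_0^*$, the structural parameters outnumber the
  reduced-form moments by the number of free $\lambda$; the coefficients are
  then informed mainly through the prior ($N(0,1)$ per free entry on
  standardized traits) and their posteriors are wide. This is the package
  default because it preserves the exact MTM equivalence at $\Lambda = 0$.
  When sharp structural coefficients are the goal, `mtm_spec(residual =
  "diagonal")` restricts $R_0^*$ to a diagonal matrix, under which the sparse
  recursive system is fully identified through the residual covariances —
  the standard identification condition for recursive systems in quantitative
  genetics. The package's own study-scale recovery analyses use this option.

**Chains.** The desk default is 60,000 iterations, 10,000 burn-in, thinning 5
(10,000 retained); `chain_preset("full")` selects the production-scale
510,000 / 10,000 / 2 chain (250,000 retained). Convergence is monitored with
trace/density plots, an AR-spectral effective sample size and a split-chain
shrink factor, all computed in-package.

**DIC.** The deviance focus is the observed-data multivariate normal
likelihood conditional on the breeding values;
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$
(the standard form; some published accounts print the formula with a minus
sign, which contradicts the additive penalty their comparisons imply). Under
a hierarchical focus $p_D$ is not guaranteed positive: when the posterior of
the variance components is broad, the concavity of the log-determinant can
make the plug-in deviance exceed the posterior-mean deviance. We have
verified (single-retained-sample check) that trace and plug-in use the same
likelihood; DIC *differences* between MTM and SEM, the quantity used for
model choice, behaved consistently in our simulations.

## The synthetic-data generator

The generator emulates the study design the package targets, and its defaults
are the reference analysis's own estimates:

* **Pedigree** — 52 founders in five provenance groups (round-robin), 47
  open-pollinated families of 5–11 offspring (dam known, sire unknown,
  modelled as distinct unrelated males, matching the half-sib assumption of
  the A matrix), plus six small full-sib families; about 390 phenotyped
  offspring.
* **Genotypes** — 25,000 biallelic SNPs by Mendelian gene drop from founder
  haplotypes with allele frequencies uniform on [0.05, 0.5]; 10% of calls
  masked missing at random. No linkage map or LD is simulated.
* **Traits** — nine standardized traits generated through the reduced form of
  the recursive system, with $\Lambda$ fixed to the 12-edge GBLUP network
  ([lodgepole_network()]), $\Sigma_a$ the unstructured direct-effect genetic
  covariance assembled from the reference SEM variances and correlations, and
  $R_0$ diagonal ([lodgepole_sem_covariances()]; direct-effect residual
  correlations are not reported, so independence is assumed).
* **Field design** — a sets-in-reps layout (5 replications × 21 sets) with
  i.i.d. normal replication (SD 0.3) and set-within-replication (SD 0.2)
  effects on the latent scale; values chosen once as typical of midsized
  design effects relative to unit trait variance. The original spatial
  adjustment is deliberately replaced by this fixed-effects mechanism.
* **Observation scales** — latent values are mapped to realistic field
  scales (ordinal 4-category gall-rust scores; log-normal monoterpene
  concentrations and decline index; Gaussian height, density, isotope ratio)
  so the preprocessing pipeline — log transform, normal scoring,
  least-squares design adjustment with sum-to-zero constraints,
  standardization, in that enforced order — has real work to do.
  Per-trait missing-record rates reproduce the reference record counts
  (328–392 of 392).

What the generator does **not** emulate: spatial autocorrelation, genotyping
error and allelic dropout of real GBS data, linkage disequilibrium, selection
history of the breeding population, and pedigree errors. Passing tests on
synthetic data therefore demonstrate internal correctness of the estimators
under the stated model, not robustness to those field realities.

## Problem sizes and what the checks show

The package's study-scale analyses (tests and the acceptance script) run the
full pipeline at the reference design size — about 390 phenotyped trees,
25,000 SNPs, nine traits — with the desk chain, a choice that keeps a
complete run in the tens of minutes on a laptop while leaving Monte Carlo
error well below the posterior spread of every quantity examined. Smaller
unit-test fixtures (30–80 families, 2–5 traits) isolate single properties.
Structure learning on decorrelated *estimated* breeding values recovers the
strong edges of the generating network with bootstrap strength near 1;
support for the weakest coefficients (|λ| ≈ 0.09 on standardized traits) is
intrinsically limited at n ≈ 400, and multitrait BLUP shrinkage itself
reshapes weak partial correlations — an honest caveat that applies equally to
analyses of real data at this scale.

## Known limitations

* Score-based learners only (Hill-Climbing, Tabu); hybrid learners are out of
  scope, so comparisons between learner families are not reproduced.
* No REML/EM alternative to the Gibbs sampler; no multi-chain diagnostics
  beyond split-chain shrink factors.
* Mean imputation and no LD pruning for the genomic matrix; no single-step
  (H-matrix) blending.
* The normal-score transform uses the expected-order-statistic band formula;
  other published variants differ in how ties and extreme bands are handled.
* Breeding values entering network learning are posterior means; propagating
  their full posterior into structure learning is not attempted.
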