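# bnsem — Bayesian networks and structural equation models for multitrait genomic evaluation

`bnsem` is an R package for breeders and quantitative geneticists who want to
go beyond symmetric genetic correlations and ask *which traits drive which*.
It implements an integrated evaluation pipeline for multitrait breeding
populations — developed around a nine-trait open-pollinated lodgepole pine
progeny trial (height HT, wood density WD, gall-rust resistance WGR,
limonene LIMO, total monoterpenes T_MONO, drought resistance RES, growth
decline DECL, carbon isotope ratio C13, carbon assimilation CAR):

1. **Relationship matrices** — pedigree numerator matrix A (tabular method)
   and VanRaden genomic matrix `G = WW' / 2Σ p_k(1 − p_k)` from filtered
   (≤ 30% missing, MAF ≥ 1%), mean-imputed SNP dosages.
2. **Multitrait mixed model (MTM)** — `y = Xβ + a + e`,
   `a ~ N(0, Σa ⊗ K)`, `e ~ N(0, R0 ⊗ I)`, unstructured Σa and R0, fitted by
   a compiled Gibbs sampler (ABLUP with K = A, GBLUP with K = G), with
   missing-record augmentation, heritabilities
   `h² = σ²a / (σ²a + σ²e)`, genetic correlations, HPD intervals and DIC.
3. **Causal structure learning** — predicted breeding values are decorrelated
   through the Cholesky factor of K (`a* = L⁻¹â`), then a directed acyclic
   trait network is learned by score-based search (Hill-Climbing, Tabu;
   Gaussian BIC and BGe scores) with bootstrap model averaging (edge strength
   and direction confidence, consensus at a strength threshold).
4. **Recursive structural equation model (SEM)** —
   `y_i = Λy_i + X_i'β* + a_i* + e_i*` with the sparsity of Λ fixed to the
   learned network; structural coefficients λ are sampled jointly with the
   breeding values integrated out.
5. **Model comparison** — variance components, heritabilities, direct and
   reduced-form genetic correlations, DIC differences, breeding-value
   agreement and elite-ranking stability, and k-fold cross-validated
   predictive ability.

A synthetic-data generator (`simulate_study()`) reproduces the statistical
structure of the reference trial — 47 open-pollinated families, ~390 trees,
25,000 SNPs, a 12-edge causal network with published coefficient values
(`lodgepole_network()`) — so the entire pipeline is testable without any
external download.

## Worked example

```r
library(bnsem)

## a synthetic progeny trial emulating the reference study
study  <- simulate_study(simulation_config(seed = 1))
traits <- preprocess_traits(study$traits)     # log -> normal score -> design adjust -> standardize
G      <- build_G(impute_mean(filter_snps(study$genotypes)))

## GBLUP multitrait fit (here a short 20k-iteration exploratory chain;
## the desk default is 60k/10k/5 and chain_preset("full") the production chain)
chm <- fit_mtm(traits, G, mtm_spec(n_iter = 20000, burn = 5000, seed = 2))
posterior_summary(chm)$varcomp[1:3, c("trait", "additive.mean", "residual.mean", "h2.mean")]
#>   trait additive.mean residual.mean   h2.mean
#> 1   WGR     0.5152258     0.5472703 0.4803745
#> 2  LIMO     0.7990425     0.2717286 0.7445745
#> 3    HT     0.5354762     0.5277998 0.4998592

## learn the trait network from decorrelated breeding values
bvd <- decorrelate_bvs(breeding_values(chm, trees = traits$tree),
                       G[traits$tree, traits$tree])
net <- bootstrap_average(bvd, learner = function(d) hill_climb(d, "bic"),
                         n_boot = 200, threshold = 0.95, seed = 3)
head(net$arcs, 3)
#>   from     to strength direction
#> 1 DECL    CAR        1     0.610
#> 2 LIMO T_MONO        1     0.710
#> 3  RES     HT        1     0.575

## recursive SEM on the learned structure
## (mtm_spec(residual = "diagonal") gives sharply identified lambdas instead)
chs <- fit_sem(traits, G, mtm_spec(n_iter = 20000, burn = 5000, seed = 4),
               mask = net$consensus)
structural_summary(chs)$lambda[1:3, c("from", "to", "mean", "sd")]
#>   from     to       mean        sd
#> 1  C13 T_MONO  0.1725011 0.4233600
#> 2  C13    WGR -0.0127925 0.6003293
#> 3  CAR   LIMO  0.2997927 0.4870564

## compare the two evaluations
compare_dic(chm, chs)           # positive difference favours the SEM
#>   model     Dbar         pD      DIC difference
#> 1   MTM 4386.096   56.67481 4442.771   595.6392
#> 2   SEM 4363.558 -516.42646 3847.131         NA
head(compare_bvs(chm, chs)[, c("trait", "pearson", "spearman_top")], 3)
#>   trait   pearson spearman_top
#> 1   WGR 0.9720213    0.7390516
#> 2  LIMO 0.9883969    0.8612202
#> 3    HT 0.9847770    0.8967079
```

The variance-component table reports, per trait, the posterior mean/SD and
95% HPD interval of the additive and residual variances and of the
narrow-sense heritability h2 = sigma2_a / (sigma2_a + sigma2_e); here the two
models agree closely on breeding values (Pearson 0.97-0.99) while elite
rankings shift more (Spearman 0.74-0.90 over the top 10%), and the DIC
difference of +596 favours the structural model. `net$arcs` lists each
learned edge with its bootstrap strength (fraction of replicates containing
the edge) and direction confidence; the lambda table gives the posterior mean
and SD of each structural coefficient, i.e. the expected change in the child
trait per unit change of the parent trait at the genetic-model level (under
the default unstructured residual covariance these posteriors are wide; see
the methods vignette on identifiability and the diagonal-residual option).

## Package layout

- `R/` — simulation, relationship matrices, preprocessing, samplers,
  structure learning, evaluation, pipeline orchestration (`run_pipeline()`).
- `src/gibbs.cpp` — the MTM/SEM Gibbs sampler core (RcppArmadillo).
- `vignettes/bnsem-methods.Rmd` — models, priors, identifiability, the
  synthetic-data generator's assumptions, and known limitations.
- `tests/testthat/` — unit, property and study-scale acceptance tests.
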