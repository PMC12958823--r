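mk_geno <- function(M) {
  rownames(M) <- paste0("t", seq_len(nrow(M)))
  colnames(M) <- paste0("s", seq_len(ncol(M)))
  M
}

test_that("SNP filtering applies the missingness and MAF rules", {
  set.seed(1)
  n <- 20
  M <- mk_geno(matrix(rbinom(n * 10, 2, 0.4), n, 10))
  # SNP 1: 35% missing -> dropped; SNP 2: monomorphic -> dropped;
  # SNP 3: MAF below 1% (one het in 100 alleles would be 0.5%; here force 0)
  M[1:7, 1] <- NA
  M[, 2] <- 2
  M[, 3] <- 0; M[1, 3] <- 1        # MAF = 1/40 = 2.5% -> kept at default
  out <- filter_snps(M)
  rep <- attr(out, "filter_report")
  expect_false("s1" %in% colnames(out))
  expect_false("s2" %in% colnames(out))
  expect_true("s3" %in% colnames(out))
  expect_equal(rep$n_dropped_missing, 1)
  expect_equal(rep$n_dropped_maf, 1)
  expect_equal(rep$n_retained, 8)
  expect_equal(ncol(out), 8)

  # crafted 10-SNP toy with 3 violators -> 7 retained
  M2 <- mk_geno(matrix(1, 10, 10))
  M2[, 4] <- c(0, 2, rep(c(0, 2), 4))      # polymorphic, kept
  M2[1:4, 5] <- NA                          # 40% missing
  M2[, 6] <- 0                              # monomorphic
  M2[, 7] <- c(2, rep(0, 9))                # MAF 10%, kept
  M2[5:10, 8] <- NA                         # 60% missing
  out2 <- filter_snps(M2)
  expect_equal(ncol(out2), 7)
  expect_error(filter_snps(mk_geno(matrix(0, 5, 2))), "empty panel")
})

test_that("mean imputation fills 2p and preserves column means", {
  M <- mk_geno(matrix(c(0, 2, NA, 1, 1, 1), 3, 2))
  out <- impute_mean(M)
  expect_equal(out[3, 1], 1.0)  # p = 0.5 -> 2p = 1
  expect_false(anyNA(out))
  # identity on complete data
  Mc <- mk_geno(matrix(rbinom(40, 2, 0.3), 8, 5))
  expect_identical(impute_mean(Mc), bnsem:::check_genotypes(Mc))
  # column means unchanged by imputation (algebraic identity)
  set.seed(2)
  Mm <- mk_geno(matrix(rbinom(600, 2, 0.35), 30, 20))
  Mm[sample(length(Mm), 90)] <- NA
  pre <- colMeans(Mm, na.rm = TRUE)
  expect_equal(colMeans(impute_mean(Mm)), pre, tolerance = 1e-12)
  Mall <- mk_geno(matrix(NA_real_, 4, 2))
  expect_error(impute_mean(Mall), "no observed")
})

test_that("G matrix matches its closed form on single-SNP toys", {
  # one SNP, p = 0.5: heterozygote w = 0 -> G entries 0 for that tree
  M <- mk_geno(matrix(c(0, 1, 2), 3, 1))
  G <- build_G(M)   # rank-1, so the recorded 1e-6 ridge is applied
  expect_equal(attr(G, "epsilon"), 1e-6)
  expect_equal(G["t2", "t2"], 0, tolerance = 1e-5)
  # homozygote-alt self relationship: w = 1, denom = 2 * 0.25 -> 2.0
  expect_equal(G["t3", "t3"], 2, tolerance = 1e-5)
  expect_equal(attr(G, "kind"), "G")
  expect_error(build_G(mk_geno(matrix(2, 4, 3))), "monomorphic")
})

test_that("gene-dropped genotypes behave Mendelianly and match HW", {
  cfg <- tiny_config(n_families = 40, offspring = 5, seed = 3)
  cfg$n_snps <- 300
  cfg$maf_range <- c(0.5, 0.5)
  cfg$missing_genotype_rate <- 0
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  founders <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  # p = 0.5 loci: founder dosage mean 1.0 over many loci
  expect_equal(mean(g$M[founders, ]), 1.0, tolerance = 0.03)
  # empirical founder allele frequency tracks the drawn p_k
  cfg2 <- tiny_config(n_families = 200, offspring = 1, seed = 4)
  cfg2$n_snps <- 5000
  cfg2$missing_genotype_rate <- 0
  ped2 <- simulate_pedigree(cfg2)
  g2 <- simulate_genotypes(ped2, cfg2)
  founders2 <- ped2$id[is.na(ped2$sire) & is.na(ped2$dam)]
  emp <- colMeans(g2$M[founders2, ]) / 2
  # binomial SE at n = 200 founders is <= sqrt(.25/400) = 0.025 per locus;
  # the mean absolute deviation across loci stays within 0.02
  expect_lt(mean(abs(emp - g2$p)), 0.02)

  # offspring of two dosage-0 parents is dosage 0
  ped3 <- pedigree(c("p1", "p2", "k"), sire = c(NA, NA, "p1"),
                   dam = c(NA, NA, "p2"))
  cfg3 <- tiny_config(seed = 5)
  cfg3$n_snps <- 50
  cfg3$maf_range <- c(0.05, 0.5)
  cfg3$missing_genotype_rate <- 0
  g3 <- simulate_genotypes(ped3, cfg3)
  zero <- g3$M["p1", ] == 0 & g3$M["p2", ] == 0
  expect_true(all(g3$M["k", zero] == 0))
})

test_that("G of half sibs concentrates near the pedigree expectation", {
  cfg <- tiny_config(n_families = 30, offspring = 4, seed = 6)
  cfg$n_snps <- 4000
  cfg$missing_genotype_rate <- 0
  ped <- simulate_pedigree(cfg)
  g <- simulate_genotypes(ped, cfg)
  G <- build_G(g$M)
  A <- build_A(ped)
  hs <- which(unclass(A) == 0.25 & upper.tri(A), arr.ind = TRUE)
  expect_gt(nrow(hs), 100)
  expect_equal(mean(G[hs]), 0.25, tolerance = 0.05)
  # unrelated founders: off-diagonal mean near zero
  founders <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  Gf <- G[founders, founders]
  # sample-frequency centering biases pairwise entries by about -1/n
  expect_equal(mean(Gf[upper.tri(Gf)]), 0, tolerance = 0.04)
})
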