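test_that("reference trait network carries the published 12-edge structure", {
  net <- lodgepole_network()
  expect_equal(dag_n_edges(net$dag), 12)
  expect_equal(net$lambda["DECL", "RES"], -0.509)
  expect_equal(net$lambda["WD", "HT"], 0.413)
  expect_equal(net$lambda["C13", "HT"], 0.565)
  expect_equal(lodgepole_network("ABLUP")$lambda["C13", "HT"], 0.422)
  # strictly lower triangular in the causal ordering -> acyclic
  expect_true(all(net$lambda[upper.tri(net$lambda, diag = TRUE)] == 0))
  expect_false(is.null(net$dag$topo))
})

test_that("pedigree simulation reproduces the configured family structure", {
  ped <- pedigree(id = c("m", "a", "b", "c"), dam = c(NA, "m", "m", "m"))
  expect_equal(sum(ped$dam == "m", na.rm = TRUE), 3)

  cfg <- simulation_config(seed = 1)
  ped <- simulate_pedigree(cfg)
  founders <- is.na(ped$sire) & is.na(ped$dam)
  expect_equal(sum(founders), 52)          # 47 mothers + 5 extra founders
  op <- !founders & is.na(ped$sire)
  expect_equal(length(unique(ped$dam[op])), 47)
  n_off <- sum(!founders)
  expect_gt(n_off, 350); expect_lt(n_off, 450)
  # full-sib offspring have both parents recorded
  fs <- !founders & !is.na(ped$sire)
  expect_gt(sum(fs), 0)
  # every founder lineage carries a genetic-group label
  expect_false(anyNA(ped$group))
  expect_equal(sort(unique(ped$group)),
               sort(rownames(cfg$group_means)))

  # determinism
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))
  cfg2 <- simulation_config(seed = 1); cfg2$seed <- 99L
  expect_false(identical(simulate_pedigree(cfg), simulate_pedigree(cfg2)))
  expect_error(simulation_config(n_founders = 10, n_families = 20), "n_founders")
  expect_error(simulation_config(maf_range = c(0, 0.7)), "maf_range")
})

test_that("degenerate trait model yields i.i.d. standard normal phenotypes", {
  traits <- c("u", "v")
  cfg <- tiny_config(n_families = 400, offspring = 1, traits = traits,
                     Sigma_a = diag(0, 2), R0 = diag(2),
                     Lambda = matrix(0, 2, 2), seed = 10)
  K <- diag(400)
  dimnames(K) <- list(paste0("i", 1:400), paste0("i", 1:400))
  study <- simulate_traits(K, cfg)
  Y <- trait_matrix(study$traits)
  expect_equal(colMeans(Y), c(u = 0, v = 0), tolerance = 0.15)
  expect_equal(apply(Y, 2, var), c(u = 1, v = 1), tolerance = 0.15)
  expect_equal(cor(Y)[1, 2], 0, tolerance = 0.12)
  expect_true(all(abs(study$true_bvs) < 1e-12))
})

test_that("a single causal edge propagates variance by its closed form", {
  # lambda 1->2 = 0.5, var_1 = 1: marginal var_2 = var2_direct + 0.25 * var_1
  lam <- matrix(c(0, 0, 0.5, 0), 2, 2, byrow = TRUE)
  cfg <- tiny_config(n_families = 4000, offspring = 1, traits = c("x", "y"),
                     Sigma_a = diag(0, 2), R0 = diag(c(1, 0.8)),
                     Lambda = lam, seed = 11)
  K <- diag(4000)
  dimnames(K) <- list(paste0("i", 1:4000), paste0("i", 1:4000))
  Y <- trait_matrix(simulate_traits(K, cfg)$traits)
  expect_equal(var(Y[, "y"]), 0.8 + 0.25 * 1, tolerance = 3 * 0.03)
  expect_equal(unname(coef(lm(Y[, "y"] ~ Y[, "x"]))[2]), 0.5, tolerance = 0.05)
})

test_that("reduced-form covariance matches theory within Monte Carlo error", {
  net <- lodgepole_network()
  n <- 4000
  K <- diag(n); dimnames(K) <- list(paste0("i", 1:n), paste0("i", 1:n))
  cfg <- simulation_config(
    n_snps = 10, observation_scale = FALSE, seed = 12,
    design = list(n_reps = 1, n_sets = 1, rep_sd = 0, set_sd = 0),
    trait_missing_rates = stats::setNames(rep(0, 9), net$trait_order))
  study <- simulate_traits(K, cfg)
  emp <- cov(trait_matrix(study$traits))
  Iml <- solve(diag(9) - cfg$Lambda_true)
  theo <- Iml %*% (cfg$Sigma_a_true + cfg$R0_true) %*% t(Iml)
  # entrywise MC standard error of a sample covariance of normals:
  # sqrt((s_ii s_jj + s_ij^2) / n); allow 3 SE
  se <- sqrt((outer(diag(theo), diag(theo)) + theo^2) / n)
  z <- abs(emp - theo) / se
  zu <- z[upper.tri(z, diag = TRUE)]
  # 45 simultaneous entries: allow the occasional 3-SE excursion but no
  # entry beyond 5 SE
  expect_gte(mean(zu < 3), 42 / 45)
  expect_lt(max(zu), 5)
})

test_that("half-sib breeding values correlate at the pedigree expectation", {
  cfg <- tiny_config(n_families = 150, offspring = 2, traits = c("z", "w"),
                     Sigma_a = diag(c(1, 1)), R0 = diag(2) * 0.5, seed = 13)
  ped <- simulate_pedigree(cfg)
  study <- simulate_traits(ped, cfg)
  a <- study$true_direct_bvs
  fam <- split(ped$id[!is.na(ped$dam)], ped$dam[!is.na(ped$dam)])
  pairs <- do.call(rbind, lapply(fam[lengths(fam) == 2], function(x) x))
  r <- cor(a[pairs[, 1], "z"], a[pairs[, 2], "z"])
  expect_equal(r, 0.25, tolerance = 3 * sqrt(1 / nrow(pairs)))
})

test_that("study-level generator is reproducible and internally consistent", {
  cfg <- tiny_config(seed = 14)
  cfg$n_snps <- 50
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$traits, s2$traits)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_true(all(s1$traits$tree %in% s1$pedigree$id))
  expect_equal(nrow(s1$true_bvs), nrow(s1$pedigree))
  # observation-scale mapping: categorical trait is 1..4, log traits positive
  full <- simulate_study(simulation_config(n_snps = 10, seed = 15),
                         genotypes = FALSE)
  expect_true(all(full$traits$WGR %in% c(NA, 1:4)))
  expect_true(all(full$traits$LIMO > 0, na.rm = TRUE))
  expect_true(all(full$traits$DECL > 0, na.rm = TRUE))
  # per-trait missingness follows the configured rates
  expect_gt(sum(is.na(full$traits$DECL)), 20)
  expect_equal(sum(is.na(full$traits$HT)), 0)
})
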