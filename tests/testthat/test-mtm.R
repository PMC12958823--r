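# Short chains keep these tests fast; tolerances are Monte Carlo aware.

fit_tiny <- function(Y, K, ..., model = "mtm", mask = NULL) {
  spec <- mtm_spec(n_iter = 4000, burn = 1000, thin = 3, ...)
  if (model == "mtm") fit_mtm(Y, K, spec) else fit_sem(Y, K, spec, mask = mask)
}

id_K <- function(n, prefix = "i") {
  K <- diag(n)
  dimnames(K) <- list(paste0(prefix, 1:n), paste0(prefix, 1:n))
  K
}

test_that("chain bookkeeping follows floor((total - burn) / thin)", {
  set.seed(1)
  Y <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("i", 1:30), c("P", "Q")))
  ch <- fit_mtm(Y, id_K(30), mtm_spec(n_iter = 1100, burn = 100, thin = 7,
                                      seed = 1))
  expect_equal(ch$n_keep, floor((1100 - 100) / 7))
  expect_equal(dim(ch$Sigma_a), c(2, 2, ch$n_keep))
  expect_error(mtm_spec(n_iter = 100, burn = 200), "burn")
})

test_that("degenerate no-genetics model recovers the sample variance", {
  set.seed(2)
  y <- rnorm(150, sd = 1.3)
  Y <- matrix(y, dimnames = list(paste0("i", 1:150), "T1"))
  # pin Sigma_a at ~0 through an overwhelming prior
  ch <- fit_tiny(Y, id_K(150), nu_a = 1e8, S_a_scale = 1e-6, seed = 2)
  s <- posterior_summary(ch)
  expect_lt(s$varcomp$additive.mean, 0.01)
  expect_equal(s$varcomp$residual.mean, var(y), tolerance = 0.1)
  # flat-prior beta matches the conjugate posterior mean (the GLS mean)
  b <- mean(ch$beta[1, 1, ])
  mcse <- sd(ch$beta[1, 1, ]) / sqrt(bnsem:::ess(ch$beta[1, 1, ]))
  expect_lt(abs(b - mean(y)), 3 * mcse + 0.02)
})

test_that("posterior draws stay positive definite and summaries stay in range", {
  cfg <- tiny_config(n_families = 40, offspring = 4, seed = 3)
  ped <- simulate_pedigree(cfg)
  study <- simulate_traits(ped, cfg)
  ch <- fit_tiny(trait_matrix(study$traits), build_A(ped), seed = 3)
  for (k in unique(round(seq(1, ch$n_keep, length.out = 25)))) {
    expect_gt(min(eigen(ch$Sigma_a[, , k], symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    expect_gt(min(eigen(ch$R0[, , k], symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  s <- posterior_summary(ch)
  expect_true(all(s$varcomp$h2.mean >= 0 & s$varcomp$h2.mean <= 1))
  gc <- s$genetic_correlations[lower.tri(s$genetic_correlations)]
  expect_true(all(abs(gc) <= 1))
  expect_true(all(s$varcomp$`h2.lower` <= s$varcomp$h2.mean &
                    s$varcomp$h2.mean <= s$varcomp$`h2.upper`))
})

test_that("heritability is recovered within posterior uncertainty", {
  cfg <- tiny_config(n_families = 60, offspring = 5,
                     Sigma_a = diag(c(0.6, 0.3)), R0 = diag(c(0.4, 0.7)),
                     seed = 4)
  ped <- simulate_pedigree(cfg)
  study <- simulate_traits(ped, cfg)
  ch <- fit_mtm(trait_matrix(study$traits), build_A(ped),
                mtm_spec(n_iter = 8000, burn = 2000, thin = 3, seed = 4))
  s <- posterior_summary(ch)
  truth <- c(0.6 / (0.6 + 0.4), 0.3 / (0.3 + 0.7))
  expect_true(all(abs(s$varcomp$h2.mean - truth) < 3 * s$varcomp$h2.sd))
})

test_that("missing phenotypes are augmented and unphenotyped trees predicted", {
  cfg <- tiny_config(n_families = 40, offspring = 4,
                     Sigma_a = matrix(c(.6, .3, .3, .6), 2), seed = 5)
  ped <- simulate_pedigree(cfg)
  study <- simulate_traits(ped, cfg)
  Y <- trait_matrix(study$traits)
  Y[sample(length(Y), length(Y) %/% 5)] <- NA
  ch <- fit_tiny(Y, build_A(ped), seed = 5)
  expect_false(anyNA(breeding_values(ch)))
  # founders carry no records yet receive BVs through the pedigree
  founders <- ped$id[is.na(ped$dam)]
  expect_true(all(founders %in% rownames(breeding_values(ch))))
  off_of <- ped$id[!is.na(ped$dam) & ped$dam == founders[1]]
  fam_mean <- colMeans(breeding_values(ch, off_of))
  # dam BV should correlate with its family's mean BV in sign at least
  expect_gt(cor(breeding_values(ch, founders[1])[1, ], fam_mean), 0)
})

test_that("the kinship argument is the only ABLUP/GBLUP difference", {
  cfg <- tiny_config(n_families = 25, offspring = 4, seed = 6)
  ped <- simulate_pedigree(cfg)
  study <- simulate_traits(ped, cfg)
  A <- build_A(ped)
  G_like <- structure(unclass(A), kind = "G",
                      class = c("kinship_matrix", "matrix", "array"))
  ch_a <- fit_tiny(trait_matrix(study$traits), A, seed = 7)
  ch_g <- fit_tiny(trait_matrix(study$traits), G_like, seed = 7)
  expect_equal(ch_a$Sigma_a, ch_g$Sigma_a, tolerance = 1e-12)
  expect_equal(ch_a$kinship_kind, "A")
  expect_equal(ch_g$kinship_kind, "G")
  # non-PD kinship is rejected with advice
  bad <- matrix(1, 4, 4, dimnames = list(paste0("i", 1:4), paste0("i", 1:4)))
  expect_error(fit_mtm(matrix(rnorm(8), 4, 2,
                              dimnames = list(paste0("i", 1:4), c("P", "Q"))),
                       bad, mtm_spec(n_iter = 200, burn = 50)),
               "regularize")
})

test_that("HPD intervals are shortest and match equal tails for normals", {
  set.seed(8)
  x <- rnorm(50000, 3, 2)
  h <- hpd_interval(x, 0.95)
  q <- quantile(x, c(0.025, 0.975))
  expect_equal(unname(h), unname(q), tolerance = 0.05)
  # on a skewed sample the HPD is shorter than the equal-tailed interval
  y <- rexp(50000)
  hy <- hpd_interval(y, 0.9)
  qy <- quantile(y, c(0.05, 0.95))
  expect_lt(diff(hy), diff(qy))
})

test_that("DIC components follow the Spiegelhalter definitions", {
  # constant deviance: pD = 0, DIC = Dbar
  ch0 <- list(deviance = rep(12.5, 100), deviance_at_mean = 12.5)
  d0 <- dic(ch0)
  expect_equal(d0$pD, 0)
  expect_equal(d0$DIC, 12.5)

  # iid normal means, known variance: pD ~ number of mean parameters
  set.seed(9)
  p <- 5; n <- 80
  y <- matrix(rnorm(p * n, rep(1:p, each = n)), n, p)
  ybar <- colMeans(y)
  draws <- t(replicate(4000, rnorm(p, ybar, 1 / sqrt(n))))
  devs <- apply(draws, 1, function(th) sum(sweep(y, 2, th)^2))
  d <- dic(list(deviance = devs,
                deviance_at_mean = sum(sweep(y, 2, colMeans(draws))^2)))
  expect_equal(d$pD, p, tolerance = 0.5)
  expect_error(dic(list(deviance = NULL)), "deviance")
})

test_that("convergence report computes ESS, shrink factors and plots", {
  cfg <- tiny_config(n_families = 20, offspring = 4, seed = 10)
  ped <- simulate_pedigree(cfg)
  study <- simulate_traits(ped, cfg)
  ch <- fit_tiny(trait_matrix(study$traits), build_A(ped), seed = 10)
  dir <- withr::local_tempdir()
  rep <- convergence_report(ch, dir = dir)
  expect_true(all(c("parameter", "mean", "ess", "rhat") %in% names(rep)))
  expect_true(all(rep$ess > 1 & rep$ess <= ch$n_keep))
  expect_true(all(is.finite(rep$rhat)))
  expect_true(all(file.exists(attr(rep, "plots"))))
  # white-noise series: shrink factor near 1, ESS near full length
  wn <- rnorm(4000)
  expect_equal(bnsem:::split_rhat(wn), 1, tolerance = 0.02)
  expect_gt(bnsem:::ess(wn), 2500)
  # a near-random-walk series is flagged with low ESS
  rw <- cumsum(rnorm(4000, sd = 0.05)) + rnorm(4000, sd = 0.01)
  expect_lt(bnsem:::ess(rw), 500)
})
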