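#' Reference causal network among the nine lodgepole pine traits
#'
#' Returns the 12-edge directed acyclic network among the nine standardized
#' traits (WGR, LIMO, HT, CAR, RES, WD, T_MONO, DECL, C13) together with the
#' posterior-mean structural coefficients estimated for an interior lodgepole
#' pine progeny trial under the pedigree-based (ABLUP) or genomic-based
#' (GBLUP) recursive structural equation model. The node order is the causal
#' ordering of the network, so the coefficient matrix is strictly lower
#' triangular. This network is also the default generative structure of the
#' synthetic-data module.
#'
#' @param approach which published coefficient set to attach, `"GBLUP"`
#'   (default) or `"ABLUP"`.
#' @return list with `dag` (a `trait_dag`), `lambda` (9 x 9 strictly
#'   lower-triangular coefficient matrix, `lambda[to, from]`), and
#'   `trait_order` (the causal ordering of the nine traits).
#' @examples
#' net <- lodgepole_network()
#' dag_n_edges(net$dag)        # 12
#' net$lambda["DECL", "RES"]   # -0.509
#' @export
lodgepole_network <- function(approach = c("GBLUP", "ABLUP")) {
  approach <- match.arg(approach)
  trait_order <- c("WGR", "LIMO", "HT", "CAR", "RES", "WD", "T_MONO", "DECL", "C13")
  edges <- data.frame(
    from = c("HT", "HT", "HT", "WGR", "WGR", "WD", "WD", "RES", "LIMO",
             "LIMO", "LIMO", "T_MONO"),
    to = c("WD", "C13", "CAR", "C13", "CAR", "DECL", "T_MONO", "DECL", "RES",
           "T_MONO", "CAR", "C13"),
    ABLUP = c(0.263, 0.422, -0.110, 0.011, -0.048, 0.117, 0.069, -0.359,
              0.111, 0.252, 0.194, 0.159),
    GBLUP = c(0.413, 0.565, -0.254, 0.097, -0.195, 0.096, 0.086, -0.509,
              0.205, 0.119, 0.368, 0.140),
    stringsAsFactors = FALSE)
  dag <- dag_from_edges(trait_order, edges$from, edges$to)
  lambda <- matrix(0, 9, 9, dimnames = list(trait_order, trait_order))
  lambda[cbind(edges$to, edges$from)] <- edges[[approach]]
  list(dag = dag, lambda = lambda, trait_order = trait_order)
}

#' Direct-effect genetic and residual covariances of the reference analysis
#'
#' The structural (direct-effect) genetic covariance among the nine traits,
#' assembled from the GBLUP structural-equation estimates for the lodgepole
#' pine trial: per-trait additive variances on the standardized scale combined
#' with the direct-effect genetic correlations. Residual covariance is
#' diagonal, holding the corresponding residual variances (residual
#' correlations are not reported for that analysis). These are the generative
#' defaults of [simulation_config()].
#'
#' @return list with matrices `Sigma_a` and `R0` (9 x 9, causal trait order).
#' @export
lodgepole_sem_covariances <- function() {
  tn <- lodgepole_network()$trait_order
  va <- c(WGR = 0.74, LIMO = 0.38, HT = 0.51, CAR = 0.49, RES = 0.44,
          WD = 0.80, T_MONO = 0.39, DECL = 0.48, C13 = 0.72)
  ve <- c(WGR = 0.36, LIMO = 0.67, HT = 0.44, CAR = 0.63, RES = 0.62,
          WD = 0.28, T_MONO = 0.65, DECL = 0.62, C13 = 0.34)
  R <- diag(9)
  dimnames(R) <- list(tn, tn)
  cors <- rbind(
    c("WD", "HT", 0.32), c("DECL", "HT", 0.03), c("C13", "HT", 0.46),
    c("T_MONO", "HT", 0.04), c("CAR", "HT", -0.25), c("C13", "WGR", 0.09),
    c("CAR", "WGR", -0.22), c("DECL", "WD", 0.12), c("C13", "WD", 0.15),
    c("T_MONO", "WD", 0.11), c("CAR", "WD", -0.08), c("DECL", "RES", -0.49),
    c("LIMO", "RES", 0.17), c("T_MONO", "RES", 0.03), c("CAR", "RES", 0.06),
    c("C13", "DECL", 0.01), c("LIMO", "DECL", -0.08), c("CAR", "DECL", -0.03),
    c("LIMO", "C13", 0.02), c("T_MONO", "C13", 0.13), c("CAR", "C13", -0.13),
    c("T_MONO", "LIMO", 0.20), c("CAR", "LIMO", 0.31), c("CAR", "T_MONO", 0.05))
  R[cbind(cors[, 1], cors[, 2])] <- as.numeric(cors[, 3])
  R[cbind(cors[, 2], cors[, 1])] <- as.numeric(cors[, 3])
  D <- diag(sqrt(va[tn]))
  Sigma_a <- D %*% R %*% D
  dimnames(Sigma_a) <- list(tn, tn)
  R0 <- diag(ve[tn])
  dimnames(R0) <- list(tn, tn)
  list(Sigma_a = Sigma_a, R0 = R0)
}

# Observation-scale models per trait (location/scale of the field data the
# generator emulates): latent standardized values are mapped to a raw scale so
# the preprocessing stages (log, normal score, design adjustment,
# standardization) have real work to do.
lodgepole_trait_scales <- function() {
  list(
    WGR    = list(type = "ordinal", probs = c(0.50, 0.25, 0.15, 0.10)),
    LIMO   = list(type = "lognormal", mean = 223.71, sd = 360.93),
    HT     = list(type = "gaussian", mean = 1051.92, sd = 102.61),
    CAR    = list(type = "gaussian", mean = 577.34, sd = 204.49),
    RES    = list(type = "gaussian", mean = 0.76, sd = 0.19),
    WD     = list(type = "gaussian", mean = 402.08, sd = 28.07),
    T_MONO = list(type = "lognormal", mean = 4374.70, sd = 2581.77),
    DECL   = list(type = "lognormal", mean = 2.00, sd = 1.00),
    C13    = list(type = "gaussian", mean = -26.06, sd = 0.54))
}

#' Configuration of the synthetic progeny-trial generator
#'
#' Bundles every knob of the synthetic-data module. The defaults emulate the
#' open-pollinated interior lodgepole pine trial the package's analyses are
#' designed for: 52 founders (47 mothers plus 5 identified fathers), 47
#' open-pollinated families with 5-11 offspring each plus six small full-sib
#' families (about 390 phenotyped trees), 25,000 biallelic SNPs, five
#' provenance genetic groups, a sets-in-reps field layout with five
#' replications of 21 sets, and nine standardized traits generated under the
#' 12-edge recursive network of [lodgepole_network()] with the GBLUP
#' structural coefficients. Genetic and residual covariances default to the
#' trial's structural (direct-effect) estimates ([lodgepole_sem_covariances()]):
#' an unstructured genetic covariance and a diagonal residual covariance, with
#' further trait correlation arising through the network.
#'
#' @param n_founders total founders; must be at least `n_families`.
#' @param n_families number of open-pollinated (known dam, unknown sire)
#'   families.
#' @param offspring_per_family integer count or length-2 range per OP family.
#' @param n_fullsib_families,fullsib_per_family optional full-sib families
#'   (both parents known) and their size (count or range).
#' @param n_snps number of simulated SNP loci.
#' @param maf_range interval in (0, 0.5] for founder allele frequencies.
#' @param missing_genotype_rate proportion of genotype calls masked missing.
#' @param trait_names ordered trait labels (causal order).
#' @param Sigma_a_true,R0_true 9 x 9 genetic and residual covariance matrices
#'   of the structural (direct) effects; symmetric positive semi-definite.
#' @param Lambda_true strictly lower-triangular (in `trait_names` order)
#'   structural coefficient matrix, `Lambda_true[to, from]`.
#' @param group_means genetic-group fixed effects: groups x traits matrix.
#' @param design list with `n_reps`, `n_sets`, `rep_sd`, `set_sd` (SDs of the
#'   i.i.d. normal replication and set-within-replication effects on the
#'   latent standardized scale).
#' @param trait_missing_rates per-trait missing-record proportions; defaults
#'   reproduce the record counts of the emulated trial (328-392 of 392).
#' @param observation_scale if `TRUE`, phenotypes are mapped to realistic raw
#'   scales (ordinal categories, log-normal concentrations, field units) so
#'   the preprocessing pipeline is exercised; if `FALSE`, latent standardized
#'   phenotypes are returned directly.
#' @param seed integer seed making every generator call reproducible.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_founders = 52,
                              n_families = 47,
                              offspring_per_family = c(5, 11),
                              n_fullsib_families = 6,
                              fullsib_per_family = c(1, 2),
                              n_snps = 25000,
                              maf_range = c(0.05, 0.5),
                              missing_genotype_rate = 0.10,
                              trait_names = lodgepole_network()$trait_order,
                              Sigma_a_true = NULL,
                              R0_true = NULL,
                              Lambda_true = NULL,
                              group_means = NULL,
                              design = list(n_reps = 5, n_sets = 21,
                                            rep_sd = 0.3, set_sd = 0.2),
                              trait_missing_rates = NULL,
                              observation_scale = TRUE,
                              seed = 1L) {
  nt <- length(trait_names)
  if (is.null(Sigma_a_true) || is.null(R0_true)) {
    stopifnot(nt == 9L)
    ref <- lodgepole_sem_covariances()
    if (is.null(Sigma_a_true)) Sigma_a_true <- ref$Sigma_a[trait_names, trait_names]
    if (is.null(R0_true)) R0_true <- ref$R0[trait_names, trait_names]
  }
  if (is.null(Lambda_true)) {
    Lambda_true <- if (nt == 9L && all(trait_names == lodgepole_network()$trait_order))
      lodgepole_network()$lambda else matrix(0, nt, nt)
  }
  dimnames(Sigma_a_true) <- dimnames(R0_true) <- dimnames(Lambda_true) <-
    list(trait_names, trait_names)
  if (is.null(group_means)) {
    groups <- c("DeerMountain", "InvernessRiver", "JudyCreek", "SwanHills",
                "VirginiaHills")
    group_means <- matrix(rep(c(-0.3, -0.15, 0, 0.15, 0.3), nt), 5, nt,
                          dimnames = list(groups, trait_names))
  }
  group_means <- as.matrix(group_means)
  if (is.null(rownames(group_means))) {
    rownames(group_means) <- paste0("G", seq_len(nrow(group_means)))
  }
  colnames(group_means) <- trait_names
  if (is.null(trait_missing_rates)) {
    counts <- c(WGR = 392, LIMO = 391, HT = 392, CAR = 378, RES = 368,
                WD = 367, T_MONO = 391, DECL = 328, C13 = 392)
    trait_missing_rates <- if (nt == 9L && all(trait_names %in% names(counts)))
      1 - counts[trait_names] / 392 else stats::setNames(rep(0, nt), trait_names)
  }
  cfg <- list(n_founders = n_founders, n_families = n_families,
              offspring_per_family = offspring_per_family,
              n_fullsib_families = n_fullsib_families,
              fullsib_per_family = fullsib_per_family,
              n_snps = n_snps, maf_range = maf_range,
              missing_genotype_rate = missing_genotype_rate,
              trait_names = trait_names, Sigma_a_true = Sigma_a_true,
              R0_true = R0_true, Lambda_true = Lambda_true,
              group_means = group_means, design = design,
              trait_missing_rates = trait_missing_rates,
              observation_scale = observation_scale, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_founders < 1 || n_families < 1) stop("counts must be positive")
    if (n_founders < n_families) stop("n_founders must be >= n_families")
    if (any(offspring_per_family < 1)) stop("family sizes must be >= 1")
    if (n_snps < 1) stop("n_snps must be positive")
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || diff(maf_range) < 0)
      stop("maf_range must be an interval in (0, 0.5]")
    rates <- c(missing_genotype_rate, trait_missing_rates)
    if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
    check_psd(Sigma_a_true, "Sigma_a_true")
    check_psd(R0_true, "R0_true")
    lt <- Lambda_true
    if (any(lt[upper.tri(lt, diag = TRUE)] != 0))
      stop("Lambda_true must be strictly lower triangular in trait order")
  })
  invisible(cfg)
}

check_psd <- function(S, name, tol = 1e-8) {
  if (!isSymmetric(unname(S), tol = 1e-10)) stop(name, " must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) stop(name, " is not positive semi-definite")
  invisible(S)
}

# Symmetric PSD square root (tolerates rank deficiency, e.g. Sigma_a = 0).
psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

draw_size <- function(spec, n) {
  if (length(spec) == 1L) rep.int(as.integer(spec), n)
  else sample(seq.int(spec[1L], spec[2L]), n, replace = TRUE)
}

#' Simulate an open-pollinated progeny-trial pedigree
#'
#' Founders are unrelated and assigned round-robin to the genetic groups.
#' The first `n_families` founders act as mothers of open-pollinated families
#' (offspring with known dam, unknown sire, modelled as distinct unrelated
#' unsampled males); remaining founders serve as identified fathers for the
#' optional full-sib families. Offspring inherit their dam's group.
#'
#' @param config a [simulation_config()].
#' @return a [pedigree()].
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- rownames(config$group_means)
  nf <- config$n_founders
  founder_id <- sprintf("F%03d", seq_len(nf))
  founder_group <- groups[(seq_len(nf) - 1L) %% length(groups) + 1L]
  dams <- founder_id[seq_len(config$n_families)]
  sizes <- draw_size(config$offspring_per_family, config$n_families)
  off_dam <- rep(dams, sizes)
  off_group <- rep(founder_group[seq_len(config$n_families)], sizes)
  off_sire <- rep(NA_character_, length(off_dam))
  nfs <- config$n_fullsib_families
  if (nfs > 0) {
    sires_pool <- setdiff(founder_id, dams)
    if (!length(sires_pool)) stop("no founders left to act as full-sib sires")
    fs_dam <- sample(dams, nfs, replace = nfs > length(dams))
    fs_sire <- sample(sires_pool, nfs, replace = nfs > length(sires_pool))
    fs_sizes <- draw_size(config$fullsib_per_family, nfs)
    off_dam <- c(off_dam, rep(fs_dam, fs_sizes))
    off_sire <- c(off_sire, rep(fs_sire, fs_sizes))
    off_group <- c(off_group,
                   rep(founder_group[match(fs_dam, founder_id)], fs_sizes))
  }
  off_id <- sprintf("T%04d", seq_along(off_dam))
  pedigree(id = c(founder_id, off_id),
           sire = c(rep(NA_character_, nf), off_sire),
           dam = c(rep(NA_character_, nf), off_dam),
           group = c(founder_group, off_group))
}

#' Gene-drop simulation of SNP genotypes along a pedigree
#'
#' Founder haplotypes are drawn per locus from Bernoulli(p_k) with p_k uniform
#' on `maf_range`; each offspring receives one allele from each parent chosen
#' at random per locus (Mendelian gene drop). An unknown parent transmits a
#' fresh population allele. Calls are then masked missing completely at
#' random at `missing_genotype_rate`.
#'
#' @param ped a [pedigree()].
#' @param config a [simulation_config()].
#' @return list with `M` (trees x SNPs dosage matrix, `NA` = missing) and `p`
#'   (the founder allele frequencies drawn).
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(ped, "bnsem_pedigree"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(ped); m <- config$n_snps
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  idx <- seq_len(n); names(idx) <- ped$id
  H1 <- H2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    H1[i, ] <- if (is.na(s)) as.integer(stats::runif(m) < p) else {
      si <- idx[[s]]; pick <- stats::runif(m) < 0.5
      ifelse(pick, H1[si, ], H2[si, ])
    }
    H2[i, ] <- if (is.na(d)) as.integer(stats::runif(m) < p) else {
      di <- idx[[d]]; pick <- stats::runif(m) < 0.5
      ifelse(pick, H1[di, ], H2[di, ])
    }
  }
  M <- H1 + H2
  storage.mode(M) <- "double"
  dimnames(M) <- list(ped$id, sprintf("snp%05d", seq_len(m)))
  if (config$missing_genotype_rate > 0) {
    M[stats::runif(length(M)) < config$missing_genotype_rate] <- NA_real_
  }
  list(M = M, p = p)
}

#' Simulate trait phenotypes under the recursive structural model
#'
#' Draws breeding values `a ~ N(0, Sigma_a kron K)` (K from the pedigree's A
#' matrix, or a kinship matrix supplied directly) and residuals
#' `e ~ N(0, R0 kron I)`, then produces phenotypes through the reduced form
#' `y_i = (I - Lambda)^{-1} (x_i' beta + a_i + e_i)` of the recursive system.
#' Replication and set-within-replication effects are added on the latent
#' scale (and recorded), phenotypes are optionally mapped to realistic
#' observation scales, and per-trait records are masked missing completely at
#' random. Founders carry breeding values but no phenotypes.
#'
#' @param pedigree_or_K a [pedigree()] (kinship = its A matrix) or a kinship
#'   matrix with ids as dimnames (then all individuals are phenotyped).
#' @param config a [simulation_config()].
#' @return list of class `sim_study`: `pedigree` (or `NULL`), `traits` (a
#'   [trait_table()] of phenotyped trees with `rep`/`set` columns),
#'   `true_bvs` (reduced-form total genetic effects, all trees x traits),
#'   `true_direct_bvs` (the structural draws `a`), `latent` (phenotypes on the
#'   latent standardized scale, before observation-scale mapping and
#'   missingness), `design_effects`, and `params` (generative parameters).
#' @export
simulate_traits <- function(pedigree_or_K, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (inherits(pedigree_or_K, "bnsem_pedigree")) {
    ped <- pedigree_or_K
    K <- build_A(ped)
    ids <- ped$id
    pheno_ids <- ped$id[!(is.na(ped$sire) & is.na(ped$dam))]
    if (!length(pheno_ids)) pheno_ids <- ids
    group <- stats::setNames(ped$group, ped$id)
  } else {
    ped <- NULL
    K <- as_kinship(pedigree_or_K)
    ids <- rownames(K)
    pheno_ids <- ids
    group <- stats::setNames(rep(rownames(config$group_means)[1L], length(ids)), ids)
  }
  nt <- length(config$trait_names)
  n <- length(ids)
  Lk <- t(chol_psd(K))  # lower factor, L L' = K
  a <- Lk %*% matrix(stats::rnorm(n * nt), n, nt) %*% chol_psd(config$Sigma_a_true)
  dimnames(a) <- list(ids, config$trait_names)
  Iml_inv <- solve(diag(nt) - config$Lambda_true)
  a_reduced <- a %*% t(Iml_inv)
  dimnames(a_reduced) <- dimnames(a)

  q <- length(pheno_ids)
  e <- matrix(stats::rnorm(q * nt), q, nt) %*% chol_psd(config$R0_true)
  gm <- config$group_means[match(group[pheno_ids], rownames(config$group_means)), ,
                           drop = FALSE]
  u <- gm + a[pheno_ids, , drop = FALSE] + e
  Y <- u %*% t(Iml_inv)
  dimnames(Y) <- list(pheno_ids, config$trait_names)

  # sets-in-reps layout with i.i.d. normal design effects per trait
  d <- config$design
  rep_id <- sample(seq_len(d$n_reps), q, replace = TRUE)
  set_id <- sample(seq_len(d$n_sets), q, replace = TRUE)
  rep_eff <- matrix(stats::rnorm(d$n_reps * nt, sd = d$rep_sd), d$n_reps, nt)
  set_eff <- matrix(stats::rnorm(d$n_reps * d$n_sets * nt, sd = d$set_sd),
                    d$n_reps * d$n_sets, nt)
  cell <- (rep_id - 1L) * d$n_sets + set_id
  Ylat <- Y + rep_eff[rep_id, , drop = FALSE] + set_eff[cell, , drop = FALSE]

  Yobs <- Ylat
  if (config$observation_scale && nt == 9L &&
      all(config$trait_names %in% names(lodgepole_trait_scales()))) {
    scales <- lodgepole_trait_scales()
    for (tr in config$trait_names) {
      sc <- scales[[tr]]
      z <- Ylat[, tr]
      Yobs[, tr] <- switch(sc$type,
        gaussian = sc$mean + sc$sd * z,
        lognormal = {
          s2 <- log(1 + (sc$sd / sc$mean)^2)
          exp(log(sc$mean) - s2 / 2 + sqrt(s2) * z)
        },
        ordinal = {
          br <- stats::qnorm(cumsum(sc$probs))[-length(sc$probs)]
          findInterval(z / stats::sd(z), br) + 1
        })
    }
  }
  for (tr in config$trait_names) {
    r <- config$trait_missing_rates[[tr]]
    if (r > 0) Yobs[stats::runif(q) < r, tr] <- NA_real_
  }
  traits <- trait_table(
    data.frame(tree = pheno_ids, rep = rep_id, set = set_id,
               as.data.frame(Yobs), stringsAsFactors = FALSE),
    traits = config$trait_names)
  structure(list(pedigree = ped, traits = traits, true_bvs = a_reduced,
                 true_direct_bvs = a,
                 latent = Ylat, design_effects = list(rep = rep_eff, set = set_eff),
                 params = config),
            class = "sim_study")
}

# Upper Cholesky factor tolerating PSD input (falls back to the eigen root).
chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) out <- t(psd_sqrt(S))
  out
}

#' Simulate a complete study: pedigree, genotypes and traits
#'
#' @param config a [simulation_config()].
#' @param genotypes set `FALSE` to skip the (comparatively slow) gene drop.
#' @return `sim_study` list with `genotypes` (and `snp_freq`) filled in.
#' @export
simulate_study <- function(config = simulation_config(), genotypes = TRUE) {
  ped <- simulate_pedigree(config)
  study <- simulate_traits(ped, config)
  if (genotypes) {
    g <- simulate_genotypes(ped, config)
    study$genotypes <- g$M
    study$snp_freq <- g$p
  }
  study
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic progeny trial:",
      if (!is.null(x$pedigree)) nrow(x$pedigree) else nrow(x$true_bvs),
      "pedigree records,", nrow(x$traits), "phenotyped trees,",
      length(trait_cols(x$traits)), "traits",
      if (!is.null(x$genotypes)) sprintf(", %d SNPs", ncol(x$genotypes)) else "",
      "\n")
  invisible(x)
}
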