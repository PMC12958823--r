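#' Chain settings and priors for the multitrait Gibbs sampler
#'
#' Priors follow the weakly-informative defaults used throughout the package:
#' inverse-Wishart with degrees of freedom `traits + 2` and scale `0.5 * I`
#' for both the genetic (`Sigma_a`) and residual (`R0`) covariance matrices
#' (proper but vague on standardized traits), a flat prior on the
#' genetic-group means, and independent N(0, `v_lambda`) priors on free
#' structural coefficients. The default desk-scale chain is 60,000 iterations
#' with 10,000 burn-in and thinning 5; `chain_preset("full")` switches to the
#' long 510,000 / 10,000 / 2 chain used for production analyses.
#'
#' @param n_iter,burn,thin total Gibbs iterations, burn-in discarded, and
#'   thinning interval; `floor((n_iter - burn) / thin)` samples are retained.
#' @param nu_a,nu_r inverse-Wishart degrees of freedom (default traits + 2,
#'   resolved at fit time when `NULL`).
#' @param S_a_scale,S_r_scale inverse-Wishart scale matrices are
#'   `scale * diag(traits)`.
#' @param v_lambda prior variance of each free structural coefficient.
#' @param residual residual-covariance structure: `"unstructured"` (default;
#'   at `Lambda = 0` the structural model then coincides with the MTM) or
#'   `"diagonal"` (independent residuals, under which a sparse recursive
#'   system is fully identified and the structural coefficients are estimated
#'   sharply).
#' @param groups optional named character vector (tree id -> genetic group)
#'   defining the fixed-effect design; default a single intercept.
#' @param trace_deviance record the observed-data deviance on retained
#'   iterations (needed for [dic()]).
#' @param seed integer seed for the sampler.
#' @return list of class `mtm_spec`.
#' @export
mtm_spec <- function(n_iter = 60000, burn = 10000, thin = 5,
                     nu_a = NULL, nu_r = NULL,
                     S_a_scale = 0.5, S_r_scale = 0.5,
                     v_lambda = 1, residual = c("unstructured", "diagonal"),
                     groups = NULL,
                     trace_deviance = TRUE, seed = 1L) {
  stopifnot(burn < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn = as.integer(burn),
                 thin = as.integer(thin), nu_a = nu_a, nu_r = nu_r,
                 S_a_scale = S_a_scale, S_r_scale = S_r_scale,
                 v_lambda = v_lambda, residual = match.arg(residual),
                 groups = groups,
                 trace_deviance = isTRUE(trace_deviance),
                 seed = as.integer(seed)),
            class = "mtm_spec")
}

#' @rdname mtm_spec
#' @param preset `"desk"` (default short chain) or `"full"` (the long
#'   production chain: 510,000 iterations, 10,000 burn-in, thin 2).
#' @param ... further arguments passed to [mtm_spec()].
#' @export
chain_preset <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  if (preset == "desk") mtm_spec(...)
  else mtm_spec(n_iter = 510000, burn = 10000, thin = 2, ...)
}

#' Fit the multitrait individual-tree mixed model by Gibbs sampling
#'
#' Fits `y = X beta + a + e` jointly over all traits, with unstructured
#' genetic and residual covariance matrices, `a ~ N(0, Sigma_a kron K)` and
#' `e ~ N(0, R0 kron I)`. `K` is the pedigree numerator relationship matrix
#' (ABLUP) or the genomic relationship matrix (GBLUP). Trees present in `K`
#' but without phenotype records (founders, validation trees) are carried as
#' fully missing and receive breeding values through their relationships.
#' Missing phenotypes are imputed by Gibbs data augmentation every sweep.
#'
#' @param traits a [trait_table()] (ideally preprocessed) or a numeric matrix
#'   (trees x traits, rownames = ids, `NA` = missing).
#' @param kinship a [build_A()] / [build_G()] matrix (positive definite after
#'   any recorded regularization) covering every phenotyped tree.
#' @param spec an [mtm_spec()].
#' @return object of class `mtm_chain`; see [posterior_summary()], [dic()],
#'   [convergence_report()].
#' @export
fit_mtm <- function(traits, kinship, spec = mtm_spec()) {
  fit_gibbs(traits, kinship, spec, mask = NULL, model = "MTM")
}

# Shared fitting core for MTM (mask = NULL) and SEM (mask = lambda_mask).
fit_gibbs <- function(traits, kinship, spec, mask, model) {
  stopifnot(inherits(spec, "mtm_spec"))
  Y0 <- if (inherits(traits, "trait_table")) trait_matrix(traits) else traits
  stopifnot(is.matrix(Y0), !is.null(rownames(Y0)))
  trait_names <- colnames(Y0)
  K <- as_kinship(kinship)
  missing_ids <- setdiff(rownames(Y0), rownames(K))
  if (length(missing_ids)) {
    stop("phenotyped trees absent from kinship: ",
         paste(utils::head(missing_ids, 10L), collapse = ", "))
  }
  ids <- rownames(K)
  nt <- length(trait_names)
  Y <- matrix(NA_real_, length(ids), nt, dimnames = list(ids, trait_names))
  Y[rownames(Y0), ] <- Y0

  # fixed-effect design: genetic-group cell means (or a single intercept)
  if (is.null(spec$groups)) {
    X <- matrix(1, length(ids), 1, dimnames = list(ids, "(mean)"))
  } else {
    g <- spec$groups[ids]
    if (anyNA(g)) stop("spec$groups must cover every tree in the kinship matrix")
    X <- stats::model.matrix(~ 0 + factor(g))
    colnames(X) <- levels(factor(g))
    rownames(X) <- ids
  }
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")

  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) <= 1e-10) {
    stop("kinship matrix is not positive definite (min eigenvalue ",
         format(min(eg$values)), "); regularize it, e.g. build_G(epsilon = 1e-6)")
  }

  if (is.null(mask)) {
    lam_idx <- matrix(0L, 0, 2)
    lam_edges <- data.frame(from = character(0), to = character(0))
  } else {
    stopifnot(inherits(mask, "lambda_mask"))
    if (!identical(mask$trait_order, trait_names)) {
      stop("lambda mask trait order does not match the trait columns")
    }
    w <- which(mask$mask, arr.ind = TRUE)  # [to, from]
    lam_idx <- cbind(w[, 1L], w[, 2L]) - 1L
    lam_edges <- data.frame(from = trait_names[w[, 2L]],
                            to = trait_names[w[, 1L]],
                            stringsAsFactors = FALSE)
    if (nrow(lam_edges) > 1L) {
      o <- order(lam_edges$from, lam_edges$to)
      lam_edges <- lam_edges[o, , drop = FALSE]
      lam_idx <- lam_idx[o, , drop = FALSE]
    }
  }

  nu_a <- if (is.null(spec$nu_a)) nt + 2 else spec$nu_a
  nu_r <- if (is.null(spec$nu_r)) nt + 2 else spec$nu_r
  if (nu_a <= nt - 1 || nu_r <= nt - 1) stop("prior df must exceed traits - 1")

  set.seed(spec$seed)
  res <- .gibbs_core(Y, X, eg$vectors, eg$values, lam_idx,
                     nu_a, diag(spec$S_a_scale, nt),
                     nu_r, diag(spec$S_r_scale, nt),
                     spec$v_lambda,
                     spec$n_iter, spec$burn, spec$thin, spec$trace_deviance,
                     identical(spec$residual, "diagonal"))

  n_keep <- res$n_keep
  chain <- structure(list(
    model = model,
    kinship_kind = attr(kinship, "kind") %||% "K",
    trait_names = trait_names, tree_ids = ids,
    Sigma_a = array(t(res$Sigma_a), c(nt, nt, n_keep),
                    dimnames = list(trait_names, trait_names, NULL)),
    R0 = array(t(res$R0), c(nt, nt, n_keep),
               dimnames = list(trait_names, trait_names, NULL)),
    beta = array(t(res$beta), c(ncol(X), nt, n_keep),
                 dimnames = list(colnames(X), trait_names, NULL)),
    lambda = if (nrow(lam_edges)) {
      lm <- res$lambda
      colnames(lm) <- paste0(lam_edges$from, "->", lam_edges$to)
      lm
    } else NULL,
    lambda_edges = lam_edges,
    deviance = if (spec$trace_deviance) as.numeric(res$deviance) else NULL,
    a_mean = structure(res$a_mean, dimnames = list(ids, trait_names)),
    a_sd = structure(res$a_sd, dimnames = list(ids, trait_names)),
    n_keep = n_keep, spec = spec, Y = Y, X = X),
    class = "mtm_chain")
  if (spec$trace_deviance) {
    chain$deviance_at_mean <- deviance_at_point(
      Y, X,
      beta = apply(chain$beta, c(1, 2), mean),
      a = chain$a_mean,
      Lambda = lambda_point_matrix(chain),
      R0 = apply(chain$R0, c(1, 2), mean))
  }
  chain
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Posterior-mean Lambda as a traits x traits matrix ([to, from]).
lambda_point_matrix <- function(chain) {
  nt <- length(chain$trait_names)
  L <- matrix(0, nt, nt, dimnames = list(chain$trait_names, chain$trait_names))
  if (!is.null(chain$lambda)) {
    L[cbind(chain$lambda_edges$to, chain$lambda_edges$from)] <-
      colMeans(chain$lambda)
  }
  L
}

# Observed-data deviance -2 log p(y_obs | beta, a, Lambda, R0) at a parameter
# point; same likelihood focus as the per-iteration trace in the sampler.
deviance_at_point <- function(Y, X, beta, a, Lambda, R0) {
  nt <- ncol(Y)
  ImL_inv <- solve(diag(nt) - Lambda)
  Mu <- (X %*% beta + a) %*% t(ImL_inv)
  V <- ImL_inv %*% R0 %*% t(ImL_inv)
  dev <- 0
  for (i in seq_len(nrow(Y))) {
    obs <- which(!is.na(Y[i, ]))
    if (!length(obs)) next
    Vo <- V[obs, obs, drop = FALSE]
    L <- chol(Vo)
    z <- backsolve(L, Y[i, obs] - Mu[i, obs], transpose = TRUE)
    dev <- dev + length(obs) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2)
  }
  dev
}

#' @export
print.mtm_chain <- function(x, ...) {
  cat(sprintf("%s chain (%s): %d traits, %d trees, %d retained samples\n",
              x$model, x$kinship_kind, length(x$trait_names),
              length(x$tree_ids), x$n_keep))
  if (!is.null(x$lambda)) {
    cat("  free structural coefficients:", ncol(x$lambda), "\n")
  }
  invisible(x)
}

#' Posterior-mean breeding values from a fitted chain
#' @param chain an `mtm_chain`.
#' @param trees optional subset of tree ids.
#' @return trees x traits matrix of posterior-mean breeding values.
#' @export
breeding_values <- function(chain, trees = NULL) {
  bv <- chain$a_mean
  if (!is.null(trees)) bv <- bv[trees, , drop = FALSE]
  bv
}
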