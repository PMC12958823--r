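#' Structural-coefficient sparsity mask from a learned DAG
#'
#' Converts a trait-level causal network into the sparsity pattern of the
#' structural coefficient matrix Lambda: entry `(r, j)` is free exactly when
#' the network has the edge `j -> r`; the diagonal is zero and entries outside
#' the mask stay exactly zero during sampling. `trait_order` fixes the row and
#' column ordering; it need not be a topological order of the DAG (the matrix
#' is lower triangular under any topological reordering).
#'
#' @param dag a `trait_dag` over the traits.
#' @param trait_order trait ordering of the phenotype columns the SEM will be
#'   fitted to; defaults to a topological order of `dag`.
#' @return object of class `lambda_mask`: list with `trait_order`, logical
#'   matrix `mask` (`mask[to, from]`), and `edges`.
#' @export
build_lambda_mask <- function(dag, trait_order = NULL) {
  stopifnot(inherits(dag, "trait_dag"))
  if (is.null(dag$topo)) stop("network must be acyclic")
  if (is.null(trait_order)) trait_order <- dag$topo
  stopifnot(setequal(trait_order, dag$nodes))
  mask <- t(dag$amat[trait_order, trait_order, drop = FALSE]) == 1L
  structure(list(trait_order = trait_order, mask = mask,
                 edges = dag_edges(dag)),
            class = "lambda_mask")
}

#' @export
print.lambda_mask <- function(x, ...) {
  cat("Lambda mask:", sum(x$mask), "free coefficients over",
      length(x$trait_order), "traits\n")
  invisible(x)
}

#' Fit the recursive structural equation model by Gibbs sampling
#'
#' Extends [fit_mtm()] with the structural layer
#' `y_i = Lambda y_i + X beta + a_i + e_i`: each sweep additionally samples
#' the free entries of Lambda jointly from their conditional normal, treating
#' the parent-trait phenotypes as regressors of the child equations, while
#' `beta`, the breeding values and the (unstructured by default) covariance
#' matrices are updated on the structural residuals `y - Lambda y`. With an
#' empty mask the model — and its posterior — coincides with the MTM.
#'
#' @param traits,kinship,spec as in [fit_mtm()] (`spec$v_lambda` is the prior
#'   variance of each free coefficient).
#' @param mask a [build_lambda_mask()] whose `trait_order` matches the trait
#'   columns, or a `trait_dag` (converted with the trait columns as order).
#' @return `mtm_chain` with `lambda` samples; see [structural_summary()].
#' @export
fit_sem <- function(traits, kinship, spec = mtm_spec(), mask) {
  if (inherits(mask, "trait_dag")) {
    tn <- if (inherits(traits, "trait_table")) trait_cols(traits) else colnames(traits)
    mask <- build_lambda_mask(mask, trait_order = tn)
  }
  fit_gibbs(traits, kinship, spec, mask = mask, model = "SEM")
}

#' Coefficient and parameter tables of a structural chain
#'
#' Posterior means and SDs of every free structural coefficient, the per-trait
#' variance components and heritabilities, and the genetic correlation
#' matrices. Because the structural genetic effects are direct effects, two
#' correlation matrices are reported: `direct` (correlations of the structural
#' genetic covariance `Sigma_a`) and `reduced_form` (correlations of the total
#' genetic covariance `(I - Lambda)^{-1} Sigma_a (I - Lambda)^{-T}`, the scale
#' on which the MTM estimates its genetic correlations).
#'
#' @param chain an `mtm_chain` from [fit_sem()].
#' @param hpd HPD interval mass.
#' @return list of class `sem_summary`: `lambda`, `varcomp`,
#'   `genetic_correlations` (list `direct` / `reduced_form`),
#'   `residual_correlations`, `dic`.
#' @export
structural_summary <- function(chain, hpd = 0.95) {
  stopifnot(inherits(chain, "mtm_chain"))
  if (chain$model != "SEM") stop("structural_summary() expects a SEM chain")
  base <- posterior_summary(chain, hpd = hpd)
  tn <- chain$trait_names
  nt <- length(tn)
  ed <- chain$lambda_edges
  rf <- matrix(0, nt, nt)
  for (s in seq_len(chain$n_keep)) {
    L <- matrix(0, nt, nt)
    if (!is.null(chain$lambda)) L[cbind(match(ed$to, tn), match(ed$from, tn))] <-
        chain$lambda[s, ]
    M <- solve(diag(nt) - L)
    rf <- rf + stats::cov2cor(M %*% chain$Sigma_a[, , s] %*% t(M))
  }
  rf <- rf / chain$n_keep
  dimnames(rf) <- list(tn, tn)
  structure(list(model = "SEM", kinship_kind = chain$kinship_kind,
                 lambda = base$lambda, varcomp = base$varcomp,
                 genetic_correlations = list(
                   direct = base$genetic_correlations, reduced_form = rf),
                 residual_correlations = base$residual_correlations,
                 dic = base$dic, n_keep = chain$n_keep),
            class = "sem_summary")
}

#' @export
print.sem_summary <- function(x, digits = 3, ...) {
  cat(sprintf("SEM (%s) structural summary, %d samples\n",
              x$kinship_kind, x$n_keep))
  if (!is.null(x$lambda)) print(format(x$lambda, digits = digits), row.names = FALSE)
  print(format(x$varcomp, digits = digits), row.names = FALSE)
  if (!is.null(x$dic)) {
    cat(sprintf("DIC = %.1f (Dbar = %.1f, pD = %.1f)\n",
                x$dic$DIC, x$dic$Dbar, x$dic$pD))
  }
  invisible(x)
}

#' Export posterior structural coefficients as CSV
#' @param summary a `sem_summary` (or `mtm_summary` with lambda).
#' @param path output CSV path (`from,to,mean,sd,lower,upper`).
#' @export
write_lambda_csv <- function(summary, path) {
  stopifnot(!is.null(summary$lambda))
  utils::write.csv(summary$lambda, path, row.names = FALSE)
  invisible(path)
}
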