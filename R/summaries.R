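#' Shortest (highest posterior density) interval of a Monte Carlo sample
#' @param x numeric sample.
#' @param prob interval mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) stop("need at least two finite samples")
  k <- max(1L, floor(prob * n))
  widths <- x[(k + 1L):n] - x[1L:(n - k)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k])
}

#' Posterior summaries of a fitted multitrait chain
#'
#' Computes, per retained Gibbs sample, the narrow-sense heritability
#' `h2_j = sigma2_a_j / (sigma2_a_j + sigma2_e_j)` and the genetic correlation
#' `r_jr = sigma_a_jr / sqrt(sigma2_a_j * sigma2_a_r)`, then reports posterior
#' means, SDs and shortest 95% HPD intervals of variance components,
#' heritabilities and correlations (point estimates are posterior means of the
#' per-sample quantities). For a structural chain the free coefficients are
#' summarized as well.
#'
#' @param chain an `mtm_chain` from [fit_mtm()] or [fit_sem()].
#' @param hpd HPD interval mass.
#' @return list of class `mtm_summary` with data.frames `varcomp` (additive
#'   and residual variances and heritability per trait), `genetic_correlations`
#'   (posterior-mean matrix), `residual_correlations`, optional `lambda`, and
#'   the `dic` components when a deviance trace is present.
#' @export
posterior_summary <- function(chain, hpd = 0.95) {
  stopifnot(inherits(chain, "mtm_chain"))
  if (chain$n_keep < 2L) stop("chain is empty or too short to summarize")
  tn <- chain$trait_names
  nt <- length(tn)
  sa <- chain$Sigma_a; r0 <- chain$R0

  va <- t(vapply(seq_len(nt), function(j) sa[j, j, ], numeric(chain$n_keep)))
  ve <- t(vapply(seq_len(nt), function(j) r0[j, j, ], numeric(chain$n_keep)))
  h2 <- va / (va + ve)

  s_row <- function(x) {
    ci <- hpd_interval(x, hpd)
    c(mean = mean(x), sd = stats::sd(x), ci)
  }
  varcomp <- data.frame(trait = tn,
                        do.call(rbind, lapply(seq_len(nt), function(j) {
                          c(additive = s_row(va[j, ]), residual = s_row(ve[j, ]),
                            h2 = s_row(h2[j, ]))
                        })), row.names = NULL, check.names = FALSE)

  cor_mean <- function(arr) {
    if (nt == 1L) return(matrix(1, 1, 1, dimnames = list(tn, tn)))
    m <- apply(arr, 3L, stats::cov2cor)
    matrix(rowMeans(m), nt, nt, dimnames = list(tn, tn))
  }
  out <- list(model = chain$model, kinship_kind = chain$kinship_kind,
              varcomp = varcomp,
              genetic_correlations = cor_mean(sa),
              residual_correlations = cor_mean(r0),
              beta = data.frame(
                effect = rep(rownames(chain$beta), nt),
                trait = rep(tn, each = nrow(chain$beta)),
                mean = as.vector(apply(chain$beta, c(1, 2), mean)),
                sd = as.vector(apply(chain$beta, c(1, 2), stats::sd))),
              n_keep = chain$n_keep)
  if (!is.null(chain$lambda)) {
    out$lambda <- data.frame(
      chain$lambda_edges,
      mean = colMeans(chain$lambda),
      sd = apply(chain$lambda, 2L, stats::sd),
      t(apply(chain$lambda, 2L, hpd_interval, prob = hpd)),
      row.names = NULL)
  }
  if (!is.null(chain$deviance)) out$dic <- dic(chain)
  structure(out, class = "mtm_summary")
}

#' @export
print.mtm_summary <- function(x, digits = 3, ...) {
  cat(sprintf("%s (%s) posterior summary, %d samples\n", x$model,
              x$kinship_kind, x$n_keep))
  print(format(x$varcomp, digits = digits), row.names = FALSE)
  if (!is.null(x$lambda)) {
    cat("\nStructural coefficients:\n")
    print(format(x$lambda, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$dic)) {
    cat(sprintf("\nDIC = %.1f (Dbar = %.1f, pD = %.1f)\n",
                x$dic$DIC, x$dic$Dbar, x$dic$pD))
  }
  invisible(x)
}

#' @describeIn posterior_summary `summary` method alias for fitted chains.
#' @param object an `mtm_chain`.
#' @param ... passed on (`hpd`).
#' @export
summary.mtm_chain <- function(object, ...) posterior_summary(object, ...)

#' Deviance information criterion of a fitted chain
#'
#' Standard Spiegelhalter form: `Dbar` is the posterior mean of the deviance
#' trace, `pD = Dbar - D(theta_bar)` the effective number of parameters
#' (deviance at the posterior-mean parameters), and `DIC = Dbar + pD`. The
#' deviance focus is the observed-data multivariate normal likelihood
#' conditional on the breeding values. Lower DIC is better.
#'
#' @param chain an `mtm_chain` fitted with `trace_deviance = TRUE`, or any
#'   list carrying a `deviance` trace and `deviance_at_mean` scalar.
#' @return list with `Dbar`, `pD`, `DIC`.
#' @export
dic <- function(chain) {
  if (is.null(chain$deviance)) {
    stop("no deviance trace; refit with trace_deviance = TRUE")
  }
  if (is.null(chain$deviance_at_mean)) stop("deviance at posterior mean missing")
  Dbar <- mean(chain$deviance)
  pD <- Dbar - chain$deviance_at_mean
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)
}

# Effective sample size from the spectral density at frequency zero of an AR
# fit (the classical time-series estimator).
ess <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10L || stats::var(x) == 0) return(n)
  fit <- try(stats::ar(x, aic = TRUE, order.max = min(50L, n %/% 4L)), silent = TRUE)
  if (inherits(fit, "try-error") || !length(fit$ar)) return(n)
  spec0 <- fit$var.pred / (1 - sum(fit$ar))^2
  max(1, min(n, n * stats::var(x) / spec0))
}

# Split-chain potential scale reduction factor.
split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 4L) return(NA_real_)
  halves <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  m <- 2L
  mu <- colMeans(halves)
  B <- n * stats::var(mu)
  Wv <- mean(apply(halves, 2L, stats::var))
  if (Wv == 0) return(1)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

#' Convergence diagnostics for a fitted chain
#'
#' Writes trace and posterior-density plots for every variance parameter and
#' reports effective sample sizes and split-chain shrink factors.
#'
#' @param chain an `mtm_chain`.
#' @param dir directory for plot files (created if needed); `NULL` disables
#'   plotting.
#' @return data.frame with one row per monitored parameter: posterior mean,
#'   effective sample size `ess`, split-chain `rhat`, and (in attribute
#'   `plots`) the files written.
#' @export
convergence_report <- function(chain, dir = NULL) {
  stopifnot(inherits(chain, "mtm_chain"))
  tn <- chain$trait_names
  pars <- list()
  for (j in seq_along(tn)) {
    pars[[paste0("sigma2_a.", tn[j])]] <- chain$Sigma_a[j, j, ]
    pars[[paste0("sigma2_e.", tn[j])]] <- chain$R0[j, j, ]
  }
  if (!is.null(chain$lambda)) {
    for (nm in colnames(chain$lambda)) {
      pars[[paste0("lambda.", nm)]] <- chain$lambda[, nm]
    }
  }
  rep_df <- data.frame(
    parameter = names(pars),
    mean = vapply(pars, mean, 0),
    ess = vapply(pars, ess, 0),
    rhat = vapply(pars, split_rhat, 0),
    row.names = NULL)
  files <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(pars)) {
      f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".png"))
      grDevices::png(f, width = 900, height = 400)
      graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
      graphics::plot(pars[[nm]], type = "l", xlab = "retained sample",
                     ylab = nm, main = "trace")
      graphics::plot(stats::density(pars[[nm]]), main = "posterior density",
                     xlab = nm)
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  attr(rep_df, "plots") <- files
  rep_df
}
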