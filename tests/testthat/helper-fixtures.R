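# Shared fixtures and independent oracles for the test suite.

# --- kinship oracle: recursive Malecot coancestry, memoized per call.
# Independent of the tabular builder in R/pedigree.R: A_ij = 2 * f(i, j).
oracle_A <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + f(si[i], di[i]))
    } else {
      # j is never an ancestor of i when i < j (pedigree is in topo order)
      0.5 * (f(i, si[j]) + f(i, di[j]))
    }
    assign(key, val, envir = memo)
    val
  }
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

# --- DAG oracle: enumerate every DAG on the given nodes (543 for 4 nodes)
# by assigning each unordered pair one of {none, ->, <-} and keeping the
# acyclic assignments.
enumerate_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- utils::combn(p, 2)
  npair <- ncol(pairs)
  states <- as.matrix(expand.grid(rep(list(0:2), npair)))
  out <- list()
  for (r in seq_len(nrow(states))) {
    amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
    for (k in seq_len(npair)) {
      s <- states[r, k]
      if (s == 1L) amat[pairs[1L, k], pairs[2L, k]] <- 1L
      if (s == 2L) amat[pairs[2L, k], pairs[1L, k]] <- 1L
    }
    if (!is.null(bnsem:::dag_topo_order(amat))) {
      out[[length(out) + 1L]] <- amat
    }
  }
  out
}

# Score a raw adjacency matrix with the package's exported scorers.
score_amat <- function(data, amat, score = "bic") {
  nodes <- colnames(amat)
  e <- which(amat == 1L, arr.ind = TRUE)
  dag <- dag_from_edges(nodes, nodes[e[, 1L]], nodes[e[, 2L]])
  if (score == "bic") as.numeric(bic_score(data, dag))
  else as.numeric(bge_score(data, dag))
}

# --- small latent-scale study used by several mixed-model tests
tiny_config <- function(n_families = 30, offspring = 5, traits = c("P", "Q"),
                        Sigma_a = diag(c(0.5, 0.6)), R0 = diag(c(0.5, 0.4)),
                        Lambda = matrix(0, 2, 2), seed = 1L, ...) {
  simulation_config(
    n_founders = n_families, n_families = n_families,
    offspring_per_family = offspring, n_fullsib_families = 0,
    n_snps = 10, trait_names = traits,
    Sigma_a_true = Sigma_a, R0_true = R0, Lambda_true = Lambda,
    group_means = matrix(0, 1, length(traits)),
    design = list(n_reps = 1, n_sets = 1, rep_sd = 0, set_sd = 0),
    trait_missing_rates = stats::setNames(rep(0, length(traits)), traits),
    observation_scale = FALSE, seed = seed, ...)
}

# Gaussian data simulated from a linear DAG model: `edges` is a data.frame
# (from, to, beta); independent standard-normal sources.
simulate_dag_data <- function(n, nodes, edges = NULL, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(nodes)), n, length(nodes),
              dimnames = list(NULL, nodes))
  if (!is.null(edges) && nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      X[, edges$to[k]] <- X[, edges$to[k]] + edges$beta[k] * X[, edges$from[k]]
    }
  }
  X
}
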