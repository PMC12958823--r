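#' Decorrelate breeding values through the Cholesky factor of the kinship
#'
#' Score-based network learning assumes exchangeable (independent) rows, but
#' predicted breeding values inherit the kinship covariance `Sigma_a kron K`.
#' Decomposing `K = L L'` and premultiplying each trait column by `L^{-1}`
#' (equivalently premultiplying the stacked vector by `(I kron L)^{-1}`)
#' removes the across-tree dependence while leaving the trait covariance
#' `Sigma_a` intact.
#'
#' @param bv trees x traits matrix of (posterior-mean) breeding values, row
#'   ids matching `kinship`.
#' @param kinship positive-definite relationship matrix covering the rows.
#' @return matrix of decorrelated breeding values with attribute `provenance`
#'   recording the kinship kind and Cholesky use.
#' @export
decorrelate_bvs <- function(bv, kinship) {
  stopifnot(is.matrix(bv), !is.null(rownames(bv)))
  K <- as_kinship(kinship, ids = rownames(bv))
  L <- tryCatch(t(chol(K)), error = function(e) {
    stop("kinship matrix is not positive definite; regularize before decorrelating")
  })
  out <- forwardsolve(L, bv)
  dimnames(out) <- dimnames(bv)
  attr(out, "provenance") <- list(kinship_kind = attr(kinship, "kind") %||% "K",
                                  transform = "a* = L^{-1} a, K = L L'")
  out
}

# ---- decomposable Gaussian network scores -----------------------------------
#
# Both scores depend on the data only through n, the column means and the
# centered scatter matrix, so a per-dataset cache makes every local score an
# O(|parents|^3) solve. Local scores are memoized by (node, parent set).

score_cache <- function(data, type = c("bic", "bge"),
                        alpha_mu = 1, alpha_w = NULL, t0_scale = 1) {
  stopifnot(is.matrix(data) || is.data.frame(data))
  X <- as.matrix(data)
  if (anyNA(X)) stop("score requires complete data")
  type <- match.arg(type)
  n <- nrow(X); d <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(d))
  xbar <- colMeans(X)
  S <- crossprod(sweep(X, 2L, xbar))
  if (is.null(alpha_w)) alpha_w <- d + 2
  env <- new.env(parent = emptyenv())
  list(n = n, d = d, nodes = colnames(X), S = S, xbar = xbar, type = type,
       alpha_mu = alpha_mu, alpha_w = alpha_w, t0_scale = t0_scale, memo = env)
}

lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# log marginal likelihood of the variable subset `idx` under the
# normal-Wishart prior (prior mean 0, scale t0_scale * I, alpha_mu imaginary
# observations for the mean, alpha_w for the precision). Score-equivalent by
# construction: any DAG score is a sum/difference of these subset terms.
bge_subset_logml <- function(cache, idx) {
  l <- length(idx)
  if (l == 0L) return(0)
  n <- cache$n; d <- cache$d
  am <- cache$alpha_mu; aw <- cache$alpha_w
  mshift <- cache$xbar[idx]  # prior mean is zero
  R <- diag(cache$t0_scale, l) + cache$S[idx, idx, drop = FALSE] +
    (n * am / (n + am)) * tcrossprod(mshift)
  awl <- aw - d + l
  l / 2 * log(am / (n + am)) - n * l / 2 * log(pi) +
    lmvgamma((n + awl) / 2, l) - lmvgamma(awl / 2, l) +
    awl / 2 * (l * log(cache$t0_scale)) -
    (n + awl) / 2 * determinant(R, logarithm = TRUE)$modulus[1]
}

local_score <- function(cache, child, parents) {
  key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
  hit <- cache$memo[[key]]
  if (!is.null(hit)) return(hit)
  n <- cache$n
  ci <- match(child, cache$nodes)
  pi_ <- match(parents, cache$nodes)
  if (anyNA(c(ci, pi_))) stop("unknown node in score request")
  val <- if (cache$type == "bic") {
    if (length(pi_) + 1L >= n) stop("more parents than observations for node ", child)
    rss <- cache$S[ci, ci]
    if (length(pi_)) {
      Spp <- cache$S[pi_, pi_, drop = FALSE]
      Spc <- cache$S[pi_, ci]
      rss <- rss - drop(crossprod(Spc, solve(Spp, Spc)))
    }
    sigma2 <- max(rss / n, .Machine$double.eps)
    loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
    loglik - (length(pi_) + 2) / 2 * log(n)
  } else {
    bge_subset_logml(cache, sort(c(ci, pi_))) - bge_subset_logml(cache, sort(pi_))
  }
  assign(key, val, envir = cache$memo)
  val
}

dag_score_cached <- function(cache, dag) {
  sum(vapply(dag$nodes,
             function(nd) local_score(cache, nd, dag_parents(dag, nd)), 0))
}

#' Gaussian BIC network score
#'
#' Decomposable penalized-likelihood score: for each node, the Gaussian
#' log-likelihood of its linear regression on its parents minus
#' `(parents + 2) / 2 * log(n)` (coefficients, intercept and residual
#' variance). Larger is better. The total score is exactly the sum of the
#' per-node local scores.
#'
#' @param data complete numeric matrix/data.frame (rows exchangeable; use
#'   [decorrelate_bvs()] output).
#' @param dag a `trait_dag` over the columns.
#' @return numeric score (attribute `local` holds the per-node terms).
#' @export
bic_score <- function(data, dag) {
  cache <- score_cache(data, "bic")
  local <- vapply(dag$nodes, function(nd) local_score(cache, nd, dag_parents(dag, nd)), 0)
  structure(sum(local), local = local)
}

#' Bayesian Gaussian equivalent (BGe) network score
#'
#' Log marginal likelihood of the data under a normal-Wishart prior with
#' `alpha_mu` imaginary observations for the mean (prior mean zero),
#' `alpha_w = d + 2` for the precision and prior scale `t0_scale * I`.
#' Markov-equivalent DAGs receive identical scores (score equivalence), and
#' the score decomposes over nodes.
#'
#' @inheritParams bic_score
#' @param alpha_mu,alpha_w,t0_scale prior hyperparameters (see above).
#' @export
bge_score <- function(data, dag, alpha_mu = 1, alpha_w = NULL, t0_scale = 1) {
  cache <- score_cache(data, "bge", alpha_mu = alpha_mu, alpha_w = alpha_w,
                       t0_scale = t0_scale)
  local <- vapply(dag$nodes, function(nd) local_score(cache, nd, dag_parents(dag, nd)), 0)
  structure(sum(local), local = local)
}

resolve_cache <- function(data, score, ...) {
  if (is.list(score) && !is.null(score$memo)) score
  else score_cache(data, match.arg(score, c("bic", "bge")), ...)
}

# All single-arc moves from `dag`, in the deterministic lexicographic order
# (child, parent, move type) used for tie-breaking.
enumerate_moves <- function(dag) {
  nodes <- dag$nodes
  moves <- list()
  for (to in nodes) for (from in nodes) {
    if (from == to) next
    if (dag$amat[from, to] == 1L) {
      moves[[length(moves) + 1L]] <- list(op = "delete", from = from, to = to)
      moves[[length(moves) + 1L]] <- list(op = "reverse", from = from, to = to)
    } else {
      moves[[length(moves) + 1L]] <- list(op = "add", from = from, to = to)
    }
  }
  moves
}

move_admissible <- function(dag, mv) {
  switch(mv$op,
         add = dag_addition_ok(dag$amat, mv$from, mv$to),
         delete = TRUE,
         reverse = {
           am <- dag$amat; am[mv$from, mv$to] <- 0L
           dag_addition_ok(am, mv$to, mv$from)
         })
}

# Score change of a move given the per-node local scores currently in force.
move_delta <- function(cache, dag, mv, local) {
  pa_to <- dag_parents(dag, mv$to)
  switch(mv$op,
    add = local_score(cache, mv$to, c(pa_to, mv$from)) - local[[mv$to]],
    delete = local_score(cache, mv$to, setdiff(pa_to, mv$from)) - local[[mv$to]],
    reverse = {
      pa_from <- dag_parents(dag, mv$from)
      (local_score(cache, mv$to, setdiff(pa_to, mv$from)) - local[[mv$to]]) +
        (local_score(cache, mv$from, c(pa_from, mv$to)) - local[[mv$from]])
    })
}

apply_move <- function(dag, mv) {
  dag <- switch(mv$op,
                add = dag_set_edge(dag, mv$from, mv$to, 1L),
                delete = dag_set_edge(dag, mv$from, mv$to, 0L),
                reverse = dag_set_edge(dag_set_edge(dag, mv$from, mv$to, 0L),
                                       mv$to, mv$from, 1L))
  dag
}

greedy_ascent <- function(cache, dag, max_iter) {
  local <- vapply(dag$nodes, function(nd) local_score(cache, nd, dag_parents(dag, nd)), 0)
  local <- as.list(local)
  for (it in seq_len(max_iter)) {
    best <- NULL; best_delta <- 1e-10
    for (mv in enumerate_moves(dag)) {
      if (!move_admissible(dag, mv)) next
      delta <- move_delta(cache, dag, mv, local)
      if (delta > best_delta) { best <- mv; best_delta <- delta }
    }
    if (is.null(best)) break
    dag <- apply_move(dag, best)
    for (nd in unique(c(best$to, best$from))) {
      local[[nd]] <- local_score(cache, nd, dag_parents(dag, nd))
    }
  }
  list(dag = dag, score = sum(unlist(local)), local = local)
}

#' Hill-Climbing structure search
#'
#' Greedy single-arc additions, deletions and reversals; at each step the
#' strictly best-improving admissible move is applied (ties broken
#' lexicographically by child, parent and move type, so the no-restart search
#' is fully deterministic), stopping at a local optimum. Optional random
#' restarts perturb the local optimum with random admissible arc additions
#' and keep the best structure found.
#'
#' @param data complete numeric matrix of exchangeable rows.
#' @param score `"bic"` (default) or `"bge"`, or a prebuilt score cache.
#' @param max_iter cap on moves per ascent.
#' @param restarts number of random restarts.
#' @param seed RNG seed (only consumed when `restarts > 0`).
#' @param start optional starting `trait_dag` (default: empty graph).
#' @return the learned `trait_dag`, with attribute `score`.
#' @export
hill_climb <- function(data, score = "bic", max_iter = 500, restarts = 0,
                       seed = 1L, start = NULL) {
  cache <- resolve_cache(data, score)
  dag <- start %||% empty_dag(cache$nodes)
  res <- greedy_ascent(cache, dag, max_iter)
  if (restarts > 0) {
    set.seed(seed)
    nodes <- cache$nodes
    for (r in seq_len(restarts)) {
      # restart from a random DAG: random topological order, each forward
      # arc kept independently -- explores basins the greedy path cannot
      ord <- sample(nodes)
      keep <- which(upper.tri(diag(length(nodes))) &
                      matrix(stats::runif(length(nodes)^2) < 0.3,
                             length(nodes)), arr.ind = TRUE)
      pert <- dag_from_edges(nodes, ord[keep[, 1L]], ord[keep[, 2L]])
      res_r <- greedy_ascent(cache, pert, max_iter)
      if (res_r$score > res$score + 1e-10) res <- res_r
    }
  }
  structure(res$dag, score = res$score)
}

#' Tabu structure search
#'
#' First ascends greedily to the Hill-Climbing local optimum, then keeps
#' moving for up to `max_iter` steps, at each step taking the best admissible
#' move even when it worsens the score, while forbidding moves that touch an
#' arc modified within the last `tabu_len` steps. The best structure visited
#' anywhere along the walk is returned, so the result never scores below the
#' plain Hill-Climbing optimum.
#'
#' @inheritParams hill_climb
#' @param tabu_len length of the tabu list (recently modified arcs).
#' @return the best `trait_dag` visited, with attribute `score`.
#' @export
tabu_search <- function(data, score = "bic", tabu_len = 10, max_iter = 100,
                        seed = 1L, start = NULL) {
  cache <- resolve_cache(data, score)
  res <- greedy_ascent(cache, start %||% empty_dag(cache$nodes), 500)
  best <- res
  dag <- res$dag
  local <- res$local
  tabu <- character(0)
  for (it in seq_len(max_iter)) {
    best_mv <- NULL; best_delta <- -Inf
    cur_score <- sum(unlist(local))
    for (mv in enumerate_moves(dag)) {
      key <- paste(sort(c(mv$from, mv$to)), collapse = "~")  # arc, undirected
      if (!move_admissible(dag, mv)) next
      delta <- move_delta(cache, dag, mv, local)
      # tabu unless the move beats the best structure seen (aspiration)
      if (key %in% tabu && cur_score + delta <= best$score + 1e-10) next
      if (delta > best_delta) { best_mv <- mv; best_delta <- delta }
    }
    if (is.null(best_mv)) break
    dag <- apply_move(dag, best_mv)
    for (nd in unique(c(best_mv$to, best_mv$from))) {
      local[[nd]] <- local_score(cache, nd, dag_parents(dag, nd))
    }
    tabu <- utils::tail(c(tabu, paste(sort(c(best_mv$from, best_mv$to)),
                                      collapse = "~")), tabu_len)
    sc <- sum(unlist(local))
    if (sc > best$score + 1e-10) best <- list(dag = dag, score = sc, local = local)
  }
  structure(best$dag, score = best$score)
}

#' Bootstrap model averaging of learned networks
#'
#' Learns a network on each of `n_boot` row-resamples (with replacement, at
#' full n). The strength of an arc is the fraction of replicates containing
#' the edge in either direction; its direction confidence is the fraction of
#' the given orientation among replicates containing the edge. The consensus
#' network keeps edges with strength at or above `threshold`, oriented by
#' majority direction; if the thresholded majority orientations close a
#' directed cycle, the arc with the lowest direction confidence is dropped
#' iteratively until the consensus is acyclic.
#'
#' @param data complete numeric matrix of exchangeable rows.
#' @param learner function `(data) -> trait_dag`, e.g.
#'   `function(d) hill_climb(d, "bic")`.
#' @param n_boot number of bootstrap replicates (production default 5,000;
#'   desk analyses typically use a few hundred).
#' @param threshold consensus strength threshold.
#' @param seed RNG seed for the resampling.
#' @return object of class `averaged_network`: data.frame `arcs` (from, to,
#'   strength, direction), the `consensus` DAG, `threshold`, `n_boot`.
#' @export
bootstrap_average <- function(data, learner = function(d) hill_climb(d, "bic"),
                              n_boot = 5000, threshold = 0.95, seed = 1L) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  X <- as.matrix(data)
  nodes <- colnames(X)
  p <- length(nodes)
  cnt <- matrix(0, p, p, dimnames = list(nodes, nodes))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(X), replace = TRUE)
    dag_b <- learner(X[rows, , drop = FALSE])
    cnt <- cnt + dag_b$amat
  }
  undirected <- cnt + t(cnt)
  pairs <- which(upper.tri(undirected) & undirected > 0, arr.ind = TRUE)
  arcs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    fwd <- cnt[i, j]; bwd <- cnt[j, i]
    if (fwd >= bwd) {
      data.frame(from = nodes[i], to = nodes[j],
                 strength = (fwd + bwd) / n_boot, direction = fwd / (fwd + bwd))
    } else {
      data.frame(from = nodes[j], to = nodes[i],
                 strength = (fwd + bwd) / n_boot, direction = bwd / (fwd + bwd))
    }
  }))
  if (is.null(arcs)) {
    arcs <- data.frame(from = character(0), to = character(0),
                       strength = numeric(0), direction = numeric(0))
  }
  arcs <- arcs[order(-arcs$strength, arcs$from, arcs$to), , drop = FALSE]
  rownames(arcs) <- NULL
  keep <- arcs[arcs$strength >= threshold, , drop = FALSE]
  repeat {
    topo <- if (nrow(keep)) {
      am <- matrix(0L, p, p, dimnames = list(nodes, nodes))
      am[cbind(keep$from, keep$to)] <- 1L
      dag_topo_order(am)
    } else nodes
    if (!is.null(topo)) break
    drop_i <- which.min(keep$direction)
    keep <- keep[-drop_i, , drop = FALSE]
  }
  consensus <- dag_from_edges(nodes, keep$from, keep$to)
  structure(list(arcs = arcs, consensus = consensus, threshold = threshold,
                 n_boot = n_boot), class = "averaged_network")
}

#' @export
print.averaged_network <- function(x, ...) {
  cat(sprintf("Averaged network: %d bootstrap replicates, threshold %.2f, %d consensus edges\n",
              x$n_boot, x$threshold, dag_n_edges(x$consensus)))
  print(x$arcs)
  invisible(x)
}

#' Write averaged-network arcs (strength, direction) as CSV
#' @param avg an `averaged_network`.
#' @param path output path.
#' @export
write_arcs_csv <- function(avg, path) {
  utils::write.csv(avg$arcs, path, row.names = FALSE)
  invisible(path)
}

#' Score change from removing each arc of a network
#'
#' For every arc of `dag`, reports `delta = score(dag) - score(dag without
#' arc)`; by decomposability only the child's local score changes. Large
#' positive values flag the arcs most influential for the network's fit,
#' sorted descending.
#'
#' @inheritParams hill_climb
#' @param dag the learned `trait_dag`.
#' @return data.frame `from`, `to`, `delta`, sorted by decreasing `delta`.
#' @export
arc_removal_delta <- function(data, dag, score = "bic") {
  cache <- resolve_cache(data, score)
  e <- dag_edges(dag)
  if (!nrow(e)) return(data.frame(from = character(0), to = character(0),
                                  delta = numeric(0)))
  e$delta <- vapply(seq_len(nrow(e)), function(k) {
    pa <- dag_parents(dag, e$to[k])
    local_score(cache, e$to[k], pa) -
      local_score(cache, e$to[k], setdiff(pa, e$from[k]))
  }, 0)
  e <- e[order(-e$delta), , drop = FALSE]
  rownames(e) <- NULL
  e
}
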