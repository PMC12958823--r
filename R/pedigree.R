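#' Construct and validate a pedigree
#'
#' A pedigree is a table of individuals with optional sire and dam links and a
#' genetic-group label per individual (founder lineages carry the group of
#' their founder ancestors). Unknown parents are coded `NA` and treated as
#' unrelated founders when relationship matrices are built.
#'
#' @param id character vector of individual identifiers (unique).
#' @param sire,dam character vectors of parent identifiers; `NA` = unknown.
#'   Every non-`NA` parent must itself appear in `id`.
#' @param group character vector of genetic-group labels (recycled if length 1).
#' @return A `data.frame` of class `bnsem_pedigree` with columns
#'   `id`, `sire`, `dam`, `group`, ordered so that parents precede offspring,
#'   with the topological order cached in attribute `topo_order`.
#' @examples
#' ped <- pedigree(id = c("m1", "o1", "o2"), sire = c(NA, NA, NA),
#'                 dam = c(NA, "m1", "m1"), group = "G1")
#' build_A(ped)
#' @export
pedigree <- function(id, sire = NA, dam = NA, group = "G1") {
  id <- as.character(id)
  n <- length(id)
  if (n == 0L) stop("pedigree must contain at least one individual")
  if (anyDuplicated(id)) {
    stop("duplicated individual ids: ",
         paste(utils::head(unique(id[duplicated(id)]), 10L), collapse = ", "))
  }
  sire <- rep_len(as.character(sire), n)
  dam <- rep_len(as.character(dam), n)
  group <- rep_len(as.character(group), n)
  for (p in c("sire", "dam")) {
    bad <- !is.na(get(p)) & !(get(p) %in% id)
    if (any(bad)) {
      stop("unknown ", p, " id(s): ",
           paste(utils::head(get(p)[bad], 10L), collapse = ", "))
    }
  }
  ord <- pedigree_topo_order(id, sire, dam)
  ped <- data.frame(id = id, sire = sire, dam = dam, group = group,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(ped) <- NULL
  attr(ped, "topo_order") <- ped$id
  class(ped) <- c("bnsem_pedigree", "data.frame")
  ped
}

# Kahn topological sort; errors on pedigree loops (an individual that is its
# own ancestor).
pedigree_topo_order <- function(id, sire, dam) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  parents <- cbind(ifelse(is.na(sire), 0L, idx[sire]),
                   ifelse(is.na(dam), 0L, idx[dam]))
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (parents[, 1L] == 0L | placed[pmax(parents[, 1L], 1L)]) &
      (parents[, 2L] == 0L | placed[pmax(parents[, 2L], 1L)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (!all(placed)) {
    stop("pedigree contains a loop involving: ",
         paste(utils::head(id[!placed], 10L), collapse = ", "))
  }
  ord
}

#' @export
print.bnsem_pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "individuals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders,",
      length(unique(x$group)), "genetic group(s)\n")
  NextMethod()
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A by the recursive
#' tabular method: founders are unrelated and non-inbred, and for individual i
#' with parents s and d, `A[i, j] = (A[s, j] + A[d, j]) / 2` for previously
#' processed j, with `A[i, i] = 1 + A[s, d] / 2` (diagonal `1 + F_i`).
#' Unknown parents contribute zero relationship.
#'
#' @param ped a [pedigree()].
#' @return A symmetric matrix of class `kinship_matrix` with ids as dimnames
#'   and attributes `kind = "A"` and `epsilon = 0`.
#' @references Henderson's tabular method for the numerator relationship
#'   matrix, as used throughout tree and animal breeding.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "bnsem_pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (s > 0L) rel <- rel + A[s, j]
      if (d > 0L) rel <- rel + A[d, j]
      A[i, j] <- A[j, i] <- rel / 2
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) A[s, d] / 2 else 0
  }
  structure(A, kind = "A", epsilon = 0, class = c("kinship_matrix", "matrix", "array"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("%s relationship matrix: %d individuals (epsilon = %g)\n",
              attr(x, "kind"), nrow(x), attr(x, "epsilon")))
  if (nrow(x) <= 10L) print(unclass(x)[, , drop = FALSE]) else utils::str(unclass(x))
  invisible(x)
}

# Coerce a kinship argument (kinship_matrix or plain symmetric matrix) to a
# validated dense matrix with dimnames, optionally subset/reordered to ids.
as_kinship <- function(K, ids = NULL) {
  if (!is.matrix(K)) stop("kinship must be a matrix")
  if (nrow(K) != ncol(K)) stop("kinship must be square")
  if (is.null(rownames(K))) stop("kinship must carry ids as dimnames")
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(K))
    if (length(miss)) {
      stop("ids absent from kinship: ", paste(utils::head(miss, 10L), collapse = ", "))
    }
    K <- K[ids, ids, drop = FALSE]
  }
  K
}
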