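#' Construct a trait table
#'
#' Holds phenotypes of one or more traits for a set of trees, together with
#' the experimental-design factors (replication, set within replication) and a
#' provenance record of the transformations applied. The canonical pipeline
#' order is `log_transform()` then `normal_score()` then `design_adjust()`
#' then `standardize()`; applying a stage after a later one is rejected.
#'
#' @param data data.frame with a `tree` id column, optional `rep` and `set`
#'   design columns, and one numeric column per trait (`NA` = missing record).
#' @param traits character vector naming the trait columns; default: every
#'   column other than `tree`, `rep`, `set`.
#' @return data.frame of class `trait_table` with attribute `transforms`.
#' @export
trait_table <- function(data, traits = NULL) {
  stopifnot(is.data.frame(data))
  if (!"tree" %in% names(data)) stop("trait table needs a 'tree' column")
  data$tree <- as.character(data$tree)
  if (anyDuplicated(data$tree)) stop("duplicated tree ids in trait table")
  if (is.null(traits)) traits <- setdiff(names(data), c("tree", "rep", "set"))
  if (!length(traits)) stop("no trait columns")
  miss <- setdiff(traits, names(data))
  if (length(miss)) stop("trait columns absent: ", paste(miss, collapse = ", "))
  for (tr in traits) {
    if (!is.numeric(data[[tr]])) stop("trait column not numeric: ", tr)
  }
  structure(data, traits = traits, transforms = list(),
            class = c("trait_table", "data.frame"))
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table:", nrow(x), "trees x", length(attr(x, "traits")), "traits;",
      "stages applied:",
      if (length(attr(x, "transforms")))
        paste(vapply(attr(x, "transforms"), `[[`, "", "stage"), collapse = " -> ")
      else "(none)", "\n")
  NextMethod()
}

#' Trait column names of a trait table
#' @param tab a [trait_table()].
#' @export
trait_cols <- function(tab) attr(tab, "traits")

# Pipeline stages in canonical order; check_stage() rejects out-of-order use.
.stage_rank <- c(log = 1, normal_score = 2, design_adjust = 3, standardize = 4)

check_stage <- function(tab, stage) {
  done <- vapply(attr(tab, "transforms"), `[[`, "", "stage")
  if (length(done) && max(.stage_rank[done]) > .stage_rank[[stage]]) {
    stop(sprintf("stage '%s' must come before '%s' in the preprocessing pipeline",
                 stage, done[which.max(.stage_rank[done])]))
  }
  invisible(tab)
}

record_stage <- function(tab, stage, ...) {
  attr(tab, "transforms") <- c(attr(tab, "transforms"),
                               list(c(list(stage = stage), list(...))))
  tab
}

#' Natural-log transform of positive-valued traits
#'
#' Applied before any other stage, to traits whose distributions are strongly
#' right-skewed (by default the growth-decline index and the monoterpene
#' concentrations). Missing records are preserved.
#'
#' @param tab a [trait_table()].
#' @param traits trait columns to transform.
#' @return the transformed trait table.
#' @export
log_transform <- function(tab, traits = intersect(c("DECL", "LIMO", "T_MONO"),
                                                  trait_cols(tab))) {
  stopifnot(inherits(tab, "trait_table"))
  check_stage(tab, "log")
  traits <- match.arg(traits, trait_cols(tab), several.ok = TRUE)
  for (tr in traits) {
    v <- tab[[tr]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop(sprintf("non-positive value for trait '%s' at tree '%s'; cannot log-transform",
                   tr, tab$tree[bad[1L]]))
    }
    tab[[tr]] <- log(v)
  }
  record_stage(tab, "log", traits = traits)
}

#' Normal-score transform of an ordered categorical trait
#'
#' Maps each ordered category c (coded 1..K) to the expected value of a
#' standard-normal observation falling inside its empirical cumulative-
#' frequency band: `z(c) = (phi(qnorm(F[c-1])) - phi(qnorm(F[c]))) /
#' (F[c] - F[c-1])`, with `F` the cumulative category proportions. Scores are
#' strictly increasing in c and their frequency-weighted mean is exactly zero.
#'
#' @param tab a [trait_table()].
#' @param trait the categorical trait column (default the gall-rust rating).
#' @param n_categories number of ordered categories K.
#' @return trait table with the scored column.
#' @export
normal_score <- function(tab, trait = "WGR", n_categories = 4) {
  stopifnot(inherits(tab, "trait_table"))
  check_stage(tab, "normal_score")
  trait <- match.arg(trait, trait_cols(tab))
  v <- tab[[trait]]
  obs <- v[!is.na(v)]
  if (!all(obs %in% seq_len(n_categories))) {
    stop(sprintf("trait '%s' must contain ordered categories 1..%d", trait, n_categories))
  }
  counts <- tabulate(obs, nbins = n_categories)
  present <- which(counts > 0L)
  Fc <- cumsum(counts[present]) / sum(counts)
  Flo <- c(0, Fc[-length(Fc)])
  z <- (stats::dnorm(stats::qnorm(Flo)) - stats::dnorm(stats::qnorm(Fc))) / (Fc - Flo)
  scores <- rep(NA_real_, n_categories)
  scores[present] <- z
  tab[[trait]] <- scores[v]
  record_stage(tab, "normal_score", trait = trait, scores = scores)
}

#' Design adjustment of phenotypes
#'
#' Removes the experimental-design effects from each trait: replication and
#' set-within-replication effects are estimated per trait by ordinary least
#' squares (sum-to-zero constraints) on the non-missing records, and the
#' fitted effects are subtracted while the grand mean is retained. With a
#' single replication and set the data are returned unchanged.
#'
#' @param tab a [trait_table()] with `rep` and `set` columns.
#' @return trait table of design-adjusted phenotypes.
#' @export
design_adjust <- function(tab) {
  stopifnot(inherits(tab, "trait_table"))
  check_stage(tab, "design_adjust")
  if (!all(c("rep", "set") %in% names(tab))) {
    stop("design columns 'rep' and 'set' are required for design adjustment")
  }
  rep_f <- factor(tab$rep)
  set_f <- factor(paste(tab$rep, tab$set, sep = ":"))
  for (tr in trait_cols(tab)) {
    y <- tab[[tr]]
    obs <- !is.na(y)
    if (sum(obs) < 2L) next
    r <- droplevels(rep_f[obs]); s <- droplevels(set_f[obs])
    terms <- list()
    if (nlevels(r) > 1L) terms$r <- r
    if (nlevels(s) > nlevels(r)) terms$s <- s
    if (!length(terms)) next  # single replication and set: nothing to adjust
    df <- data.frame(y = y[obs], terms)
    form <- stats::reformulate(names(terms), response = "y")
    fit <- stats::lm(form, data = df,
                     contrasts = lapply(terms, function(.) "contr.sum"))
    adj <- rep(NA_real_, length(y))
    adj[obs] <- stats::coef(fit)[["(Intercept)"]] + stats::residuals(fit)
    tab[[tr]] <- adj
  }
  record_stage(tab, "design_adjust")
}

#' Standardize traits to zero mean and unit variance
#'
#' Per-trait z-scoring over the non-missing records (sample variance, n - 1
#' denominator). Centering and scaling constants are stored in the provenance
#' record so estimates can be mapped back to the original scale.
#'
#' @param tab a [trait_table()].
#' @return standardized trait table.
#' @export
standardize <- function(tab) {
  stopifnot(inherits(tab, "trait_table"))
  centers <- scales <- stats::setNames(numeric(0), character(0))
  for (tr in trait_cols(tab)) {
    y <- tab[[tr]]
    obs <- y[!is.na(y)]
    if (length(obs) < 2L) stop("trait '", tr, "' has fewer than 2 records")
    s <- stats::sd(obs)
    if (s == 0) stop("trait '", tr, "' has zero variance; cannot standardize")
    centers[tr] <- mean(obs)
    scales[tr] <- s
    tab[[tr]] <- (y - centers[tr]) / s
  }
  record_stage(tab, "standardize", center = centers, scale = scales)
}

#' Standard preprocessing pipeline
#'
#' Convenience wrapper applying, in order: log transform of skewed traits,
#' normal scoring of the categorical trait, design adjustment, and
#' standardization. Each stage is skipped when its target columns are absent.
#'
#' @param tab a [trait_table()].
#' @param log_traits,score_trait,n_categories passed to the respective stages.
#' @return fully preprocessed trait table.
#' @export
preprocess_traits <- function(tab,
                              log_traits = intersect(c("DECL", "LIMO", "T_MONO"),
                                                     trait_cols(tab)),
                              score_trait = intersect("WGR", trait_cols(tab)),
                              n_categories = 4) {
  if (length(log_traits)) tab <- log_transform(tab, log_traits)
  if (length(score_trait)) tab <- normal_score(tab, score_trait, n_categories)
  if (all(c("rep", "set") %in% names(tab))) tab <- design_adjust(tab)
  standardize(tab)
}

#' Numeric trait matrix (trees x traits, rownames = tree ids) from a table
#' @param tab a [trait_table()].
#' @return numeric matrix of the trait columns.
#' @export
trait_matrix <- function(tab) {
  stopifnot(inherits(tab, "trait_table"))
  m <- as.matrix(as.data.frame(tab)[trait_cols(tab)])
  rownames(m) <- tab$tree
  m
}
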