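#' Compare breeding values from two fitted models
#'
#' Per trait: Pearson correlation, least-squares regression (slope, intercept)
#' and R-squared of the posterior-mean breeding values of model B on model A,
#' plus the Spearman rank correlation over the elite set — the top
#' `ceiling(top_fraction * n)` trees. By default the elite set is taken from
#' model A's ranking and the two models' ranks of those same trees are
#' correlated (`top_set = "first"`); `top_set = "intersection"` restricts to
#' trees elite under both models.
#'
#' @param model_a,model_b `mtm_chain` objects (or trees x traits BV matrices).
#' @param top_fraction elite fraction for the rank comparison.
#' @param top_set `"first"` or `"intersection"` (see above).
#' @return data.frame of class `bv_comparison`: one row per trait with
#'   `pearson`, `slope`, `intercept`, `r_squared`, `spearman_top`, `top_n`.
#' @export
compare_bvs <- function(model_a, model_b, top_fraction = 0.10,
                        top_set = c("first", "intersection")) {
  top_set <- match.arg(top_set)
  bv_a <- if (inherits(model_a, "mtm_chain")) breeding_values(model_a) else model_a
  bv_b <- if (inherits(model_b, "mtm_chain")) breeding_values(model_b) else model_b
  if (!identical(colnames(bv_a), colnames(bv_b))) {
    stop("the two models carry different traits")
  }
  common <- intersect(rownames(bv_a), rownames(bv_b))
  if (!identical(sort(rownames(bv_a)), sort(rownames(bv_b)))) {
    stop("the two models carry different trees")
  }
  bv_a <- bv_a[common, , drop = FALSE]
  bv_b <- bv_b[common, , drop = FALSE]
  n <- length(common)
  k <- ceiling(top_fraction * n)
  out <- do.call(rbind, lapply(colnames(bv_a), function(tr) {
    x <- bv_a[, tr]; y <- bv_b[, tr]
    fit <- stats::lm(y ~ x)
    top_a <- names(sort(x, decreasing = TRUE))[seq_len(k)]
    set <- if (top_set == "first") top_a else {
      intersect(top_a, names(sort(y, decreasing = TRUE))[seq_len(k)])
    }
    sp <- if (length(set) >= 3L) {
      stats::cor(rank(-x[set]), rank(-y[set]), method = "spearman")
    } else NA_real_
    data.frame(trait = tr,
               pearson = stats::cor(x, y),
               slope = stats::coef(fit)[[2L]],
               intercept = stats::coef(fit)[[1L]],
               r_squared = stats::cor(x, y)^2,
               spearman_top = sp, top_n = length(set))
  }))
  rownames(out) <- NULL
  class(out) <- c("bv_comparison", "data.frame")
  out
}

#' K-fold cross-validated predictive ability
#'
#' Randomly partitions the phenotyped trees into `k` validation folds. For
#' each fold, all trait records of the validation trees are masked, the model
#' is refitted on the training records, and predicted breeding values for the
#' validation trees are obtained through their kinship relationships.
#' Predictive ability per trait is the Pearson correlation between the
#' (design-adjusted) phenotypes of the validation trees and their predicted
#' breeding values, averaged over folds.
#'
#' @param traits a preprocessed [trait_table()] or numeric phenotype matrix.
#' @param kinship relationship matrix covering all phenotyped trees.
#' @param model_spec an [mtm_spec()] used for every refit (a short chain is
#'   usual here).
#' @param k number of folds (>= 2).
#' @param seed seed for the fold assignment.
#' @param mask optional [build_lambda_mask()] / `trait_dag`: when given, the
#'   structural model is refitted per fold instead of the MTM.
#' @return list of class `cv_result`: `folds` (named fold assignment),
#'   `per_fold` (trait x fold correlation matrix; a trait-fold with fewer
#'   than 3 phenotyped validation trees is `NA` with a warning),
#'   `predictive_ability` (per-trait mean over folds), `model`.
#' @export
kfold_predictive_ability <- function(traits, kinship, model_spec = mtm_spec(),
                                     k = 10, seed = 1L, mask = NULL) {
  stopifnot(k >= 2)
  Y <- if (inherits(traits, "trait_table")) trait_matrix(traits) else traits
  ids <- rownames(Y)
  set.seed(seed)
  folds <- stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids)
  per_fold <- matrix(NA_real_, ncol(Y), k,
                     dimnames = list(colnames(Y), paste0("fold", seq_len(k))))
  for (f in seq_len(k)) {
    val_ids <- ids[folds == f]
    Ytrain <- Y
    Ytrain[val_ids, ] <- NA_real_
    spec_f <- model_spec
    spec_f$seed <- model_spec$seed + f
    chain <- if (is.null(mask)) fit_mtm(Ytrain, kinship, spec_f)
             else fit_sem(Ytrain, kinship, spec_f, mask = mask)
    pred <- breeding_values(chain, val_ids)
    for (tr in colnames(Y)) {
      obs <- !is.na(Y[val_ids, tr])
      if (sum(obs) < 3L) {
        warning(sprintf("trait %s, fold %d: fewer than 3 phenotyped validation trees; skipped",
                        tr, f))
        next
      }
      per_fold[tr, f] <- stats::cor(Y[val_ids, tr][obs], pred[obs, tr])
    }
  }
  structure(list(folds = folds,
                 per_fold = per_fold,
                 predictive_ability = rowMeans(per_fold, na.rm = TRUE),
                 model = if (is.null(mask)) "MTM" else "SEM",
                 k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 3, ...) {
  cat(sprintf("%d-fold cross-validation (%s)\nPredictive ability per trait:\n",
              x$k, x$model))
  print(round(x$predictive_ability, digits))
  invisible(x)
}

#' Percent gain in predictive ability of one model over another
#'
#' @param cv_base,cv_alt [kfold_predictive_ability()] results sharing traits
#'   (typically MTM as base and SEM as alternative).
#' @return data.frame per trait: both predictive abilities and
#'   `percent_gain = 100 * (alt - base) / |base|`.
#' @export
cv_gain <- function(cv_base, cv_alt) {
  stopifnot(identical(names(cv_base$predictive_ability),
                      names(cv_alt$predictive_ability)))
  base <- cv_base$predictive_ability
  alt <- cv_alt$predictive_ability
  data.frame(trait = names(base), base = unname(base), alt = unname(alt),
             percent_gain = 100 * (alt - base) / abs(base), row.names = NULL)
}

#' DIC difference table between the multitrait and structural models
#'
#' Reports `DIC(MTM) - DIC(SEM)`; a positive difference favours the
#' structural model.
#'
#' @param summary_mtm,summary_sem summaries (or chains) carrying a `dic`
#'   component.
#' @return data.frame with both models' `Dbar`, `pD`, `DIC` and the
#'   difference.
#' @export
compare_dic <- function(summary_mtm, summary_sem) {
  get_dic <- function(x) {
    if (!is.null(x$dic)) x$dic
    else if (inherits(x, "mtm_chain")) dic(x)
    else stop("no DIC available; fit with trace_deviance = TRUE")
  }
  d1 <- get_dic(summary_mtm); d2 <- get_dic(summary_sem)
  data.frame(model = c("MTM", "SEM"),
             Dbar = c(d1$Dbar, d2$Dbar),
             pD = c(d1$pD, d2$pD),
             DIC = c(d1$DIC, d2$DIC),
             difference = c(d1$DIC - d2$DIC, NA_real_))
}
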