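#' Configuration of the end-to-end pipeline
#'
#' Drives [run_pipeline()]: simulate (or read) a study, preprocess the
#' phenotypes, build the relationship matrix, fit the multitrait model,
#' decorrelate the predicted breeding values and learn the trait network,
#' fit the structural model on the learned (or supplied) structure, and
#' compare the two fits.
#'
#' @param outdir output directory (created).
#' @param seed global seed propagated to every stochastic stage.
#' @param stages ordered subset of
#'   `c("simulate", "preprocess", "kinship", "mtm", "bn", "sem", "evaluate")`.
#' @param sim a [simulation_config()] for the simulate stage.
#' @param input_paths alternatively, named list of files for [read_inputs()]
#'   (`pedigree`, `genotypes` or `vcf`, `traits`) replacing the simulate stage.
#' @param kinship_kind `"G"` (genomic) or `"A"` (pedigree).
#' @param mtm,sem chain specifications ([mtm_spec()]).
#' @param bn_score,bn_n_boot,bn_threshold network-learning settings.
#' @param dag_file optional edge-list CSV fixing the structural network (the
#'   bn stage is then skipped even if listed).
#' @param cv_folds folds for the predictive-ability comparison; 0 disables
#'   the (slow) cross-validation part of the evaluate stage.
#' @param force rerun stages whose outputs already exist.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "bnsem_run",
                            seed = 1L,
                            stages = c("simulate", "preprocess", "kinship",
                                       "mtm", "bn", "sem", "evaluate"),
                            sim = NULL,
                            input_paths = NULL,
                            kinship_kind = c("G", "A"),
                            mtm = mtm_spec(),
                            sem = mtm_spec(),
                            bn_score = c("bic", "bge"),
                            bn_n_boot = 500,
                            bn_threshold = 0.95,
                            dag_file = NULL,
                            cv_folds = 0,
                            force = FALSE) {
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 sim = sim, input_paths = input_paths,
                 kinship_kind = match.arg(kinship_kind),
                 mtm = mtm, sem = sem,
                 bn_score = match.arg(bn_score),
                 bn_n_boot = bn_n_boot, bn_threshold = bn_threshold,
                 dag_file = dag_file, cv_folds = cv_folds, force = force),
            class = "pipeline_config")
}

#' Read and cross-validate the pipeline input files
#'
#' @param paths named list: `pedigree` (CSV), `genotypes` (TSV) or `vcf`
#'   (minimal VCF), `traits` (CSV, with optional provenance sidecar).
#' @return list with `pedigree`, `genotypes`, `traits`; tree ids are
#'   cross-checked between files.
#' @export
read_inputs <- function(paths) {
  ped <- if (!is.null(paths$pedigree)) read_pedigree_csv(paths$pedigree)
  geno <- if (!is.null(paths$genotypes)) read_genotypes_tsv(paths$genotypes)
          else if (!is.null(paths$vcf)) read_vcf_dosages(paths$vcf)
  traits <- if (!is.null(paths$traits)) read_traits_csv(paths$traits)
  if (!is.null(ped) && !is.null(traits)) {
    off <- setdiff(traits$tree, ped$id)
    if (length(off)) {
      stop("phenotyped trees absent from pedigree: ",
           paste(utils::head(off, 10L), collapse = ", "))
    }
  }
  if (!is.null(geno) && !is.null(traits)) {
    off <- setdiff(traits$tree, rownames(geno))
    if (length(off)) {
      stop("phenotyped trees absent from genotypes: ",
           paste(utils::head(off, 10L), collapse = ", "))
    }
  }
  list(pedigree = ped, genotypes = geno, traits = traits)
}

#' Run the integrated evaluation pipeline
#'
#' Executes the enabled stages in order and writes every artifact plus a JSON
#' manifest (`manifest.json`: package version, seed, per-stage status and
#' outputs, input checksums) into `config$outdir`. Completed stages (their
#' output files present) are skipped on re-runs unless `config$force`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the manifest and the in-memory results of
#'   the stages that ran (`study`, `traits`, `kinship`, `chain_mtm`,
#'   `network`, `chain_sem`, `evaluation`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  manifest <- list(package = "bnsem",
                   version = as.character(utils::packageVersion("bnsem")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = config$seed, stages = list())
  res <- list()
  note <- function(stage, status, outputs = character(0), info = NULL) {
    # record outputs relative to outdir so manifests are location independent
    prefix <- paste0(config$outdir, "/")
    rel <- ifelse(startsWith(outputs, prefix),
                  substring(outputs, nchar(prefix) + 1L), outputs)
    manifest$stages[[stage]] <<- list(status = status,
                                      outputs = as.list(rel),
                                      info = info)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  run_stage <- function(stage, outputs, fun) {
    if (!config$force && length(outputs) && all(file.exists(outputs))) {
      note(stage, "skipped (outputs exist)", outputs)
      return(invisible(NULL))
    }
    status <- tryCatch({ fun(); "ok" },
                       error = function(e) paste("failed:", conditionMessage(e)))
    note(stage, status, outputs)
    if (status != "ok") stop("stage '", stage, "' ", status, call. = FALSE)
  }

  if ("simulate" %in% config$stages && is.null(config$input_paths)) {
    cfg <- config$sim %||% simulation_config(seed = config$seed)
    run_stage("simulate",
              out(c("pedigree.csv", "genotypes.tsv", "traits_raw.csv",
                    "sim_config.yaml")), function() {
      res$study <<- simulate_study(cfg)
      write_pedigree_csv(res$study$pedigree, out("pedigree.csv"))
      write_genotypes_tsv(res$study$genotypes, out("genotypes.tsv"))
      write_traits_csv(res$study$traits, out("traits_raw.csv"))
      write_config_yaml(cfg, out("sim_config.yaml"))
    })
    if (is.null(res$study)) {  # stage skipped: reload from disk
      res$study <- list(pedigree = read_pedigree_csv(out("pedigree.csv")),
                        genotypes = read_genotypes_tsv(out("genotypes.tsv")),
                        traits = read_traits_csv(out("traits_raw.csv")))
    }
  } else if (!is.null(config$input_paths)) {
    inputs <- read_inputs(config$input_paths)
    files <- unlist(config$input_paths)
    manifest$inputs <- as.list(tools::md5sum(files[file.exists(files)]))
    res$study <- inputs
    note("read_inputs", "ok", files)
  }

  if ("preprocess" %in% config$stages) {
    run_stage("preprocess", out("traits_preprocessed.csv"), function() {
      res$traits <<- preprocess_traits(res$study$traits)
      write_traits_csv(res$traits, out("traits_preprocessed.csv"))
    })
    if (is.null(res$traits)) res$traits <- read_traits_csv(out("traits_preprocessed.csv"))
  } else res$traits <- res$study$traits

  if ("kinship" %in% config$stages) {
    kf <- out(paste0("kinship_", config$kinship_kind, ".tsv"))
    run_stage("kinship", kf, function() {
      res$kinship <<- if (config$kinship_kind == "G") {
        g <- impute_mean(filter_snps(res$study$genotypes))
        build_G(g)
      } else build_A(res$study$pedigree)
      write_kinship_tsv(res$kinship, kf)
    })
    if (is.null(res$kinship)) {
      res$kinship <- structure(read_kinship_tsv(kf), kind = config$kinship_kind,
                               epsilon = NA_real_,
                               class = c("kinship_matrix", "matrix", "array"))
    }
  }

  if ("mtm" %in% config$stages) {
    run_stage("mtm", out(c("mtm_varcomp.csv")), function() {
      spec <- config$mtm; spec$seed <- config$seed
      res$chain_mtm <<- fit_mtm(res$traits, res$kinship, spec)
      sm <- posterior_summary(res$chain_mtm)
      utils::write.csv(sm$varcomp, out("mtm_varcomp.csv"), row.names = FALSE)
      utils::write.csv(sm$genetic_correlations, out("mtm_genetic_correlations.csv"))
      utils::write.csv(convergence_report(res$chain_mtm,
                                          dir = out("diagnostics_mtm")),
                       out("mtm_convergence.csv"), row.names = FALSE)
    })
  }

  dag <- NULL
  if (!is.null(config$dag_file)) {
    dag <- read_dag_csv(config$dag_file,
                        nodes = trait_cols(res$traits))
    note("bn", "skipped (user-supplied network)", config$dag_file)
  } else if ("bn" %in% config$stages) {
    run_stage("bn", out(c("network_consensus.csv", "network_arcs.csv")), function() {
      bv <- breeding_values(res$chain_mtm, trees = res$traits$tree)
      bv_dec <- decorrelate_bvs(bv, res$kinship)
      avg <- bootstrap_average(
        bv_dec, learner = function(d) hill_climb(d, config$bn_score),
        n_boot = config$bn_n_boot, threshold = config$bn_threshold,
        seed = config$seed)
      res$network <<- avg
      write_arcs_csv(avg, out("network_arcs.csv"))
      write_dag_csv(avg$consensus, out("network_consensus.csv"))
      write_dag_dot(avg$consensus, out("network_consensus.dot"))
      utils::write.csv(arc_removal_delta(bv_dec, avg$consensus, config$bn_score),
                       out("network_arc_removal.csv"), row.names = FALSE)
    })
    dag <- res$network$consensus
  }

  if ("sem" %in% config$stages) {
    run_stage("sem", out("sem_lambda.csv"), function() {
      if (is.null(dag)) stop("no network available for the SEM stage")
      spec <- config$sem; spec$seed <- config$seed
      res$chain_sem <<- fit_sem(res$traits, res$kinship, spec, mask = dag)
      sm <- structural_summary(res$chain_sem)
      write_lambda_csv(sm, out("sem_lambda.csv"))
      utils::write.csv(sm$varcomp, out("sem_varcomp.csv"), row.names = FALSE)
    })
  }

  if ("evaluate" %in% config$stages &&
      !is.null(res$chain_mtm) && !is.null(res$chain_sem)) {
    run_stage("evaluate", out("evaluation_bv_comparison.csv"), function() {
      cmp <- compare_bvs(res$chain_mtm, res$chain_sem)
      dics <- compare_dic(res$chain_mtm, res$chain_sem)
      ev <- list(bv_comparison = cmp, dic = dics)
      utils::write.csv(cmp, out("evaluation_bv_comparison.csv"), row.names = FALSE)
      utils::write.csv(dics, out("evaluation_dic.csv"), row.names = FALSE)
      if (config$cv_folds >= 2) {
        cvm <- kfold_predictive_ability(res$traits, res$kinship, config$mtm,
                                        k = config$cv_folds, seed = config$seed)
        cvs <- kfold_predictive_ability(res$traits, res$kinship, config$sem,
                                        k = config$cv_folds, seed = config$seed,
                                        mask = dag)
        ev$cv <- cv_gain(cvm, cvs)
        utils::write.csv(ev$cv, out("evaluation_cv.csv"), row.names = FALSE)
      }
      res$evaluation <<- ev
    })
  }
  manifest$finished <- TRUE
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(c(list(manifest = manifest), res))
}
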