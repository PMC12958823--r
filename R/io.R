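#' @title Readers and writers for the pipeline's plain-text formats
#' @description Pedigree CSV (`id,sire,dam,group`), genotype TSV (trees in
#'   rows, dosage 0/1/2, `NA` missing), minimal VCF (GT field only,
#'   unphased, `./.` missing), trait CSV with a JSON provenance sidecar,
#'   kinship TSV and YAML simulation configs.
#' @name io
NULL

#' @rdname io
#' @param ped a [pedigree()].
#' @param path file path.
#' @export
write_pedigree_csv <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname io
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("id", "sire", "dam", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pedigree CSV lacks column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.na(df$sire) & !(df$sire %in% df$id) |
               !is.na(df$dam) & !(df$dam %in% df$id))
  if (length(bad)) {
    stop("malformed parent id at line(s) ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "), " of ", path)
  }
  pedigree(df$id, df$sire, df$dam, df$group)
}

#' @rdname io
#' @param M genotype dosage matrix.
#' @export
write_genotypes_tsv <- function(M, path) {
  utils::write.table(M, path, sep = "\t", quote = FALSE, na = "NA",
                     col.names = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  check_genotypes(as.matrix(df))
}

#' @rdname io
#' @export
write_genotypes_vcf <- function(M, path) {
  M <- check_genotypes(M)
  gt <- matrix("./.", ncol(M), nrow(M))
  gt[t(M) == 0] <- "0/0"; gt[t(M) == 1] <- "0/1"; gt[t(M) == 2] <- "1/1"
  body <- cbind(CHROM = "0", POS = seq_len(ncol(M)), ID = colnames(M),
                REF = "A", ALT = "C", QUAL = ".", FILTER = ".", INFO = ".",
                FORMAT = "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(M)), collapse = "\t")), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1")] <- 2
  out <- t(dos)  # trees in rows
  check_genotypes(out)
}

#' @rdname io
#' @param tab a [trait_table()].
#' @export
write_traits_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE, na = "NA")
  side <- paste0(path, ".provenance.json")
  jsonlite::write_json(list(traits = trait_cols(tab),
                            transforms = attr(tab, "transforms")),
                       side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname io
#' @export
read_traits_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".provenance.json")
  traits <- NULL
  transforms <- list()
  if (file.exists(side)) {
    prov <- jsonlite::read_json(side, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    traits <- unlist(prov$traits)
    transforms <- prov$transforms
  }
  tab <- trait_table(df, traits = traits)
  attr(tab, "transforms") <- transforms
  tab
}

#' @rdname io
#' @param K kinship matrix.
#' @export
write_kinship_tsv <- function(K, path) {
  utils::write.table(unclass(K), path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_kinship_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                              check.names = FALSE))
}

#' @rdname io
#' @param config a [simulation_config()].
#' @export
write_config_yaml <- function(config, path) {
  lst <- unclass(config)
  lst$Sigma_a_true <- as.data.frame(lst$Sigma_a_true)
  lst$R0_true <- as.data.frame(lst$R0_true)
  lst$Lambda_true <- as.data.frame(lst$Lambda_true)
  lst$group_means <- data.frame(group = rownames(config$group_means),
                                as.data.frame(config$group_means),
                                check.names = FALSE)
  lst$trait_missing_rates <- as.list(config$trait_missing_rates)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname io
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  to_mat <- function(df, rn) {
    m <- as.matrix(as.data.frame(df))
    rownames(m) <- rn
    m
  }
  tn <- unlist(lst$trait_names)
  args <- lst
  args$trait_names <- tn
  args$Sigma_a_true <- to_mat(lst$Sigma_a_true, tn)
  args$R0_true <- to_mat(lst$R0_true, tn)
  args$Lambda_true <- to_mat(lst$Lambda_true, tn)
  gmdf <- as.data.frame(lst$group_means)
  gm <- as.matrix(gmdf[setdiff(names(gmdf), "group")])
  rownames(gm) <- gmdf$group
  args$group_means <- gm
  args$trait_missing_rates <- stats::setNames(unlist(lst$trait_missing_rates), tn)
  do.call(simulation_config, args)
}
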