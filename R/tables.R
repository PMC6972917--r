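#' Read a phenotype/covariate table
#'
#' Tab-delimited table with header; requires `sample_id` and
#' `case_status` (0 = control, 1 = case) and passes through any further
#' covariate columns (sex, age, principal components `PC1..PCk`,
#' clinical flags).
#'
#' @param path phenotype file path.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "case_status") %in% names(ph))) {
    stop_input("phenotype table requires sample_id and case_status columns")
  }
  ph$sample_id <- as.character(ph$sample_id)
  if (anyDuplicated(ph$sample_id)) stop_input("duplicate sample ids")
  if (!all(ph$case_status %in% c(0L, 1L))) {
    stop_input("case_status must be 0/1")
  }
  ph
}

#' Write a phenotype/covariate table
#' @param phenotypes data frame with `sample_id` and `case_status`.
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a drug–gene interaction table
#'
#' Tab-delimited DGidb-style table with header columns `drug_name`,
#' `gene_id`, `interaction_score` (confidence, non-negative),
#' `approved` (TRUE/FALSE or 1/0) and `atc_code` (may be empty).
#' Duplicate (drug, gene) pairs are rejected.
#'
#' @param path interaction file path.
#' @export
read_drug_interactions <- function(path) {
  di <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = character(0))
  need <- c("drug_name", "gene_id", "interaction_score", "approved", "atc_code")
  if (!all(need %in% names(di))) {
    stop_input("interaction table must have columns: ",
               paste(need, collapse = ", "))
  }
  di$drug_name <- as.character(di$drug_name)
  di$gene_id <- as.character(di$gene_id)
  di$interaction_score <- as.numeric(di$interaction_score)
  di$approved <- as.logical(di$approved)
  di$atc_code <- as.character(di$atc_code)
  if (any(di$interaction_score < 0, na.rm = TRUE)) {
    stop_input("interaction_score must be non-negative")
  }
  if (anyDuplicated(di[, c("drug_name", "gene_id")])) {
    stop_input("duplicate (drug_name, gene_id) pairs")
  }
  di
}

#' Read an expression matrix
#'
#' Genes-by-individuals tab-delimited matrix: first column `gene_id`,
#' remaining columns one per sample.
#'
#' @param path expression file path.
#' @return numeric matrix, rows named by gene, columns by sample.
#' @export
read_expression <- function(path) {
  ex <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(ex)[1] != "gene_id") {
    stop_input("expression matrix must start with a gene_id column")
  }
  m <- as.matrix(ex[, -1, drop = FALSE])
  rownames(m) <- ex$gene_id
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' A single YAML file naming input paths, summary-statistic column maps
#' and analysis thresholds.  Unknown keys pass through untouched.
#'
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
read_pes_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_input("configuration must be a YAML mapping")
  cfg
}
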