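#' Read gene sets from a GMT file
#'
#' GMT is the MSigDB interchange format: one set per line, tab-separated
#' as `name<TAB>description<TAB>gene1<TAB>gene2...`.  Duplicate genes
#' within a line are removed (first occurrence kept); duplicate set
#' names across lines are rejected.
#'
#' @param path GMT file path.
#' @return list of gene sets; each element is a list with `name`,
#'   `description`, `genes` (character vector) and `druggable_genes`
#'   (filled by [flag_druggable()], initially empty).
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop_input("GMT parse error at line ", i, ": fewer than 3 fields")
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      stop_input("GMT parse error at line ", i, ": no genes")
    }
    sets[[i]] <- gene_set(f[[1]], f[[2]], genes)
  }
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop_input("duplicate gene-set name(s): ",
               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(sets) <- nm
  sets
}

#' Construct a gene set
#'
#' @param name set name (unique within a collection).
#' @param description free-text description.
#' @param genes character vector of gene ids (deduplicated).
#' @param druggable_genes subset of `genes` flagged clinically actionable.
#' @export
gene_set <- function(name, description = "", genes,
                     druggable_genes = character(0)) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop_input("gene set '", name, "' has no genes")
  if (!all(druggable_genes %in% genes)) {
    stop_input("druggable_genes must be a subset of genes")
  }
  structure(list(name = as.character(name),
                 description = as.character(description),
                 genes = genes,
                 druggable_genes = as.character(druggable_genes)),
            class = "gene_set")
}

#' Write gene sets to a GMT file
#' @param sets list of gene sets.
#' @param path output path.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Flag clinically actionable genes and filter pathways
#'
#' Annotates each set with its intersection against a druggable-gene
#' list (e.g. genes classified T_Clin: high-confidence targets of
#' approved drugs) and partitions the collection into sets retained for
#' pharmagenic scoring (at least one druggable gene) and discarded sets.
#'
#' @param sets list of gene sets.
#' @param druggable_gene_list non-empty character vector of gene ids.
#' @return list with `retained` and `discarded` lists of gene sets;
#'   retained sets carry populated `druggable_genes`.
#' @export
flag_druggable <- function(sets, druggable_gene_list) {
  druggable_gene_list <- unique(as.character(druggable_gene_list))
  if (length(druggable_gene_list) == 0L) {
    stop_input("druggable_gene_list is empty")
  }
  annotated <- lapply(sets, function(s) {
    s$druggable_genes <- intersect(s$genes, druggable_gene_list)
    s
  })
  keep <- vapply(annotated, function(s) length(s$druggable_genes) > 0L,
                 logical(1))
  list(retained = annotated[keep], discarded = annotated[!keep])
}

#' Read a gene annotation table
#'
#' BED-like tab-delimited table with header columns `gene_id`, `chrom`,
#' `start`, `end`, `strand`; coordinates are 1-based inclusive.  Strand
#' is `+`, `-` or `.`/`*` for unknown (treated as `+` downstream).
#'
#' @param path annotation file path.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(ann))) {
    stop_input("gene annotation must have columns: ",
               paste(need, collapse = ", "))
  }
  ann <- ann[, need]
  ann$gene_id <- as.character(ann$gene_id)
  ann$chrom <- as.character(ann$chrom)
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  ann$strand <- as.character(ann$strand)
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  if (any(ann$start > ann$end)) stop_input("annotation rows with start > end")
  if (anyDuplicated(ann$gene_id)) stop_input("duplicate gene_id in annotation")
  ann
}

#' Write a gene annotation table
#' @param annotation data frame from [read_gene_annotation()].
#' @param path output path.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
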