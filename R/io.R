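# Plain-text (TSV) readers and writers for every pipeline artefact.

#' Read / write cohort genotypes
#'
#' TSV with columns `individual_id`, `locus`, `allele1`, `allele2` (four-
#' digit allele names such as `A*11:01`).
#'
#' @param genotypes `hla_genotypes` data.frame.
#' @param path File path.
#' @return `read_genotypes_tsv` returns an `hla_genotypes` data.frame;
#'   `write_genotypes_tsv` returns the path invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  write_tsv(as.data.frame(genotypes), path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  out <- check_genotypes(read_tsv(path))
  class(out) <- c("hla_genotypes", "data.frame")
  out
}

#' Read / write an allele translation table
#'
#' TSV with columns `locus`, `position`, `level` (`snp` / `amino_acid`),
#' `allele`, `symbol`.
#'
#' @param table `allele_table` data.frame.
#' @param path File path.
#' @export
write_translation_tsv <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}

#' @rdname write_translation_tsv
#' @export
read_translation_tsv <- function(path) {
  out <- read_tsv(path)
  req <- c("locus", "position", "level", "allele", "symbol")
  if (!all(req %in% names(out))) {
    stop_user("translation table needs columns ", paste(req, collapse = ", "))
  }
  class(out) <- c("allele_table", "data.frame")
  out
}

#' Read / write a dosage matrix
#'
#' The main TSV has a header of variant ids and a leading `individual_id`
#' column; variant metadata (`variant_id`, `locus`, `level`, `position`,
#' `ref_symbol`) goes to a sidecar TSV, by default `<path>.variants.tsv`.
#' A write followed by a read reproduces values and metadata exactly.
#'
#' @param dosages A [dosage_matrix].
#' @param path Main TSV path.
#' @param meta_path Sidecar path (default derived from `path`).
#' @export
write_dosage_tsv <- function(dosages, path,
                             meta_path = paste0(path, ".variants.tsv")) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  df <- data.frame(individual_id = rownames(dosages$values),
                   dosages$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(dosages$variants, meta_path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path, meta_path = paste0(path, ".variants.tsv")) {
  df <- read_tsv(path)
  meta <- read_tsv(meta_path)
  meta$position <- as.integer(meta$position)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$individual_id
  dosage_matrix(values, meta)
}

#' Read / write a usage matrix
#'
#' The main TSV has a leading `individual_id` column and one column per
#' gene; the sidecar (default `<path>.genes.tsv`) stores each gene's family
#' tag and pseudo-usage constant.
#'
#' @param usage A [usage_matrix].
#' @param path Main TSV path.
#' @param meta_path Sidecar path.
#' @export
write_usage_tsv <- function(usage, path,
                            meta_path = paste0(path, ".genes.tsv")) {
  stopifnot(inherits(usage, "usage_matrix"))
  df <- data.frame(individual_id = rownames(usage$usage), usage$usage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(data.frame(gene_id = names(usage$family),
                       family = unname(usage$family),
                       pseudo_usage = unname(usage$pseudo[usage$family]),
                       stringsAsFactors = FALSE),
            meta_path)
  invisible(path)
}

#' @rdname write_usage_tsv
#' @export
read_usage_tsv <- function(path, meta_path = paste0(path, ".genes.tsv")) {
  df <- read_tsv(path)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$individual_id
  family <- NULL
  pseudo <- c(target = 0.01, control = 1e-5)
  if (file.exists(meta_path)) {
    meta <- read_tsv(meta_path)
    family <- setNames(meta$family, meta$gene_id)
    for (fam in c("target", "control")) {
      ps <- unique(meta$pseudo_usage[meta$family == fam])
      if (length(ps) == 1) pseudo[[fam]] <- ps
    }
  }
  usage_matrix(values, family = family, pseudo = pseudo)
}

#' Read contact records and rosters
#'
#' Contact records: TSV with columns `complex_id`, `locus`, `position`,
#' `partner`. Roster: TSV with columns `locus`, `complex_id`.
#'
#' @param path File path.
#' @export
read_contacts_tsv <- function(path) read_tsv(path)
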