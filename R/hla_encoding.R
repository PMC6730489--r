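# Dosage encoding of HLA genotypes at the three genetic levels
# (four-digit allele, SNP, amino acid).

#' Construct a dosage matrix
#'
#' Pairs an individuals-by-variants integer matrix of additive dosages
#' (counts in 0/1/2 of each variant's reference symbol) with the variant
#' metadata that defines those columns.
#'
#' @param values Integer matrix, individuals in rows (rownames = individual
#'   ids), variants in columns (colnames = variant ids); values in 0, 1, 2.
#' @param variants data.frame with columns `variant_id`, `locus`, `level`,
#'   `position`, `ref_symbol`, one row per column of `values`, same order.
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(values, variants) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  req <- c("variant_id", "locus", "level", "position", "ref_symbol")
  if (!all(req %in% names(variants))) {
    stop_user("`variants` needs columns ", paste(req, collapse = ", "))
  }
  variants <- as.data.frame(variants)[, req]
  if (ncol(values) != nrow(variants) ||
      (ncol(values) > 0 && !identical(colnames(values), variants$variant_id))) {
    stop_user("column names of `values` must equal `variants$variant_id`")
  }
  if (anyDuplicated(variants$variant_id)) stop_user("duplicated variant ids")
  if (length(values) && (anyNA(values) || any(values < 0L | values > 2L))) {
    stop_user("dosage values must be 0, 1 or 2")
  }
  structure(list(values = values, variants = variants), class = "dosage_matrix")
}

#' @rdname dosage_matrix
#' @param x A `dosage_matrix`.
#' @export
dosage_values <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(inherits(x, "dosage_matrix"))
  x$values
}

#' @rdname dosage_matrix
#' @export
dosage_variants <- function(x) {
  stopifnot(inherits(x, "dosage_matrix"))
  x$variants
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x$values), "individuals x", ncol(x$values),
      "variants\n")
  tab <- table(x$variants$level)
  cat("  levels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.dosage_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  dosage_matrix(v, x$variants[match(colnames(v), x$variants$variant_id), ,
                              drop = FALSE])
}

check_genotypes <- function(genotypes) {
  req <- c("individual_id", "locus", "allele1", "allele2")
  if (!all(req %in% names(genotypes))) {
    stop_user("genotypes need columns ", paste(req, collapse = ", "))
  }
  if (anyNA(genotypes[req])) {
    stop_user("missing genotype entries are not allowed; complete the calls ",
              "upstream (no silent imputation is performed)")
  }
  dup <- duplicated(genotypes[c("individual_id", "locus")])
  if (any(dup)) stop_user("duplicated individual/locus genotype rows")
  genotypes
}

genotype_individuals <- function(genotypes) unique(genotypes$individual_id)

#' Encode four-digit allele dosages
#'
#' One variant per distinct four-digit allele observed in the cohort; an
#' individual's dosage is the number of copies (0, 1, 2) of that allele it
#' carries. Per individual and locus the dosages sum to 2.
#'
#' @param genotypes `hla_genotypes` data.frame (two alleles per locus per
#'   individual; missing entries are an error).
#' @return A [dosage_matrix] at level `"allele"`.
#' @export
encode_allele_dosage <- function(genotypes) {
  genotypes <- check_genotypes(genotypes)
  ids <- genotype_individuals(genotypes)
  cols <- list(); meta <- list()
  for (locus in unique(genotypes$locus)) {
    g <- genotypes[genotypes$locus == locus, ]
    g <- g[match(ids, g$individual_id), ]
    if (anyNA(g$allele1)) {
      stop_user("locus ", locus, ": missing genotype for ",
                paste(ids[is.na(g$allele1)], collapse = ", "))
    }
    alleles <- sort(unique(c(g$allele1, g$allele2)))
    for (a in alleles) {
      cols[[length(cols) + 1L]] <- (g$allele1 == a) + (g$allele2 == a)
      meta[[length(meta) + 1L]] <- data.frame(
        variant_id = make_variant_id(locus, "allele", NA, a), locus = locus,
        level = "allele", position = NA_integer_, ref_symbol = a,
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, meta)
  values <- do.call(cbind, cols)
  if (is.null(values)) values <- matrix(0L, nrow = length(ids), ncol = 0)
  dimnames(values) <- list(ids, variants$variant_id)
  dosage_matrix(values, variants)
}

#' Encode per-site SNP or amino-acid dosages
#'
#' Translates each individual's two alleles into symbols at every position
#' of the translation table and counts copies of a reference symbol. Each
#' polymorphic site is expanded to one variant per observed symbol, taking
#' that symbol as reference and all others as alternative — so a bi-allelic
#' site with symbols A and C yields two columns (genotypes AA/AC/CC count
#' 2/1/0 for the A column) and a tri-allelic site yields exactly three.
#' Monomorphic sites yield no variants. Per site the expanded dosages of one
#' individual always sum to 2.
#'
#' @param genotypes `hla_genotypes` data.frame.
#' @param table `allele_table` data.frame mapping alleles to symbols.
#' @param level `"snp"` or `"amino_acid"`.
#' @return A [dosage_matrix].
#' @export
encode_site_dosage <- function(genotypes, table,
                               level = c("amino_acid", "snp")) {
  level <- match.arg(level)
  genotypes <- check_genotypes(genotypes)
  ids <- genotype_individuals(genotypes)
  tab <- table[table$level == level, , drop = FALSE]
  cols <- list(); meta <- list()
  for (locus in unique(genotypes$locus)) {
    g <- genotypes[genotypes$locus == locus, ]
    g <- g[match(ids, g$individual_id), ]
    t_loc <- tab[tab$locus == locus, , drop = FALSE]
    if (nrow(t_loc) == 0) next
    known <- unique(t_loc$allele)
    absent <- setdiff(unique(c(g$allele1, g$allele2)), known)
    if (length(absent)) {
      stop_user("locus ", locus, ": allele(s) absent from translation table: ",
                paste(absent, collapse = ", "))
    }
    for (pos in sort(unique(t_loc$position))) {
      t_pos <- t_loc[t_loc$position == pos, ]
      map <- setNames(t_pos$symbol, t_pos$allele)
      s1 <- unname(map[g$allele1]); s2 <- unname(map[g$allele2])
      symbols <- sort(unique(c(s1, s2)))
      if (length(symbols) < 2) next  # monomorphic in this cohort
      for (s in symbols) {
        cols[[length(cols) + 1L]] <- (s1 == s) + (s2 == s)
        meta[[length(meta) + 1L]] <- data.frame(
          variant_id = make_variant_id(locus, level, pos, s), locus = locus,
          level = level, position = as.integer(pos), ref_symbol = s,
          stringsAsFactors = FALSE)
      }
    }
  }
  variants <- if (length(meta)) do.call(rbind, meta) else
    data.frame(variant_id = character(), locus = character(),
               level = character(), position = integer(),
               ref_symbol = character(), stringsAsFactors = FALSE)
  values <- if (length(cols)) do.call(cbind, cols) else
    matrix(0L, nrow = length(ids), ncol = 0)
  dimnames(values) <- list(ids, variants$variant_id)
  dosage_matrix(values, variants)
}

#' Filter variants by minor allele frequency
#'
#' Column frequency is `mean(dosage) / 2` (allele counting); the minor
#' allele frequency is `min(f, 1 - f)`. Columns with MAF strictly below the
#' threshold are removed; a MAF exactly at the threshold is kept. Column
#' order is preserved and the operation is idempotent.
#'
#' @param matrix A [dosage_matrix].
#' @param threshold MAF threshold in `[0, 0.5]`; default 0.05.
#' @return Filtered [dosage_matrix].
#' @export
filter_maf <- function(matrix, threshold = 0.05) {
  stopifnot(inherits(matrix, "dosage_matrix"))
  if (!is_fraction(threshold, 0, 0.5)) {
    stop_user("`threshold` must be in [0, 0.5]")
  }
  if (nrow(matrix$values) == 0) stop_user("empty dosage matrix")
  f <- colMeans(matrix$values) / 2
  keep <- pmin(f, 1 - f) >= threshold
  dosage_matrix(matrix$values[, keep, drop = FALSE],
                matrix$variants[keep, , drop = FALSE])
}

#' Import SNP dosages from a VCF
#'
#' Reads genotype (GT) calls and expands every record into one dosage
#' column per declared REF/ALT symbol, following the same multi-allelic
#' rule as [encode_site_dosage()]: a bi-allelic record yields two
#' complementary columns, a record with two ALT alleles yields three.
#' Missing or half genotype calls are an error listing the offending
#' records; phased and unphased separators are both accepted.
#'
#' @param vcf_path Path to a VCF (v4.x) file.
#' @param region Optional `"CHROM"` or `"CHROM:START-END"` restriction.
#' @return A [dosage_matrix] at level `"snp"` (CHROM is used as the locus).
#' @export
import_vcf_snp_dosage <- function(vcf_path, region = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (nrow(fix) == 0) {
    return(dosage_matrix(matrix(0L, 0, 0),
                         data.frame(variant_id = character(),
                                    locus = character(), level = character(),
                                    position = integer(),
                                    ref_symbol = character())))
  }
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    parts <- strsplit(region, "[:-]")[[1]]
    keep <- fix$CHROM == parts[1]
    if (length(parts) == 3) {
      pos <- as.integer(fix$POS)
      keep <- keep & pos >= as.integer(parts[2]) & pos <= as.integer(parts[3])
    }
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  cols <- list(); meta <- list()
  for (i in seq_len(nrow(fix))) {
    symbols <- c(fix$REF[i], strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    calls <- strsplit(gsub("|", "/", gt[i, ], fixed = TRUE), "/", fixed = TRUE)
    bad <- vapply(calls, function(cc) {
      length(cc) != 2 || anyNA(cc) || any(cc == ".") ||
        anyNA(suppressWarnings(as.integer(cc)))
    }, logical(1)) | is.na(gt[i, ])
    if (any(bad)) {
      stop_user("missing or half genotype call at ", fix$CHROM[i], ":",
                fix$POS[i], " for sample(s) ",
                paste(samples[bad], collapse = ", "))
    }
    idx <- vapply(calls, function(cc) as.integer(cc) + 1L, integer(2))
    if (any(idx > length(symbols))) {
      stop_user("allele index beyond declared ALT at ", fix$CHROM[i], ":",
                fix$POS[i])
    }
    for (s in seq_along(symbols)) {
      cols[[length(cols) + 1L]] <- as.integer(colSums(idx == s))
      meta[[length(meta) + 1L]] <- data.frame(
        variant_id = make_variant_id(fix$CHROM[i], "snp", fix$POS[i],
                                     symbols[s]),
        locus = fix$CHROM[i], level = "snp", position = as.integer(fix$POS[i]),
        ref_symbol = symbols[s], stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(meta)) do.call(rbind, meta) else
    data.frame(variant_id = character(), locus = character(),
               level = character(), position = integer(),
               ref_symbol = character(), stringsAsFactors = FALSE)
  values <- if (length(cols)) do.call(cbind, cols) else
    matrix(0L, nrow = length(samples), ncol = 0)
  dimnames(values) <- list(samples, variants$variant_id)
  dosage_matrix(values, variants)
}
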