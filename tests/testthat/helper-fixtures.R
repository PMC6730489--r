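# Shared fixtures and independent oracles used across test files.

# Local seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# -- small deterministic cohorts ---------------------------------------------

toy_pool <- function() {
  haplotype_pool(list(
    "HLA-A" = c("A*01:01" = 0.35, "A*02:01" = 0.3, "A*03:01" = 0.2,
                "A*11:01" = 0.1, "A*24:02" = 0.05),
    "HLA-B" = c("B*07:02" = 0.5, "B*08:01" = 0.3, "B*15:01" = 0.2)))
}

# Hand-built genotypes: 3 individuals, 1 locus.
toy_genotypes <- function() {
  g <- data.frame(
    individual_id = c("i1", "i2", "i3"),
    locus = "HLA-A",
    allele1 = c("A*01:01", "A*01:01", "A*11:01"),
    allele2 = c("A*01:01", "A*11:01", "A*11:01"),
    stringsAsFactors = FALSE)
  class(g) <- c("hla_genotypes", "data.frame")
  g
}

# Translation table for a 5-allele locus with one bi-allelic, one
# tri-allelic and one monomorphic amino-acid position.
toy_table <- function() {
  alleles <- c("A*01:01", "A*02:01", "A*03:01", "A*11:01", "A*24:02")
  rbind(
    data.frame(locus = "HLA-A", position = 9, level = "amino_acid",
               allele = alleles, symbol = c("F", "F", "Y", "Y", "Y")),
    data.frame(locus = "HLA-A", position = 97, level = "amino_acid",
               allele = alleles, symbol = c("I", "M", "R", "I", "M")),
    data.frame(locus = "HLA-A", position = 150, level = "amino_acid",
               allele = alleles, symbol = "L"),
    data.frame(locus = "HLA-A", position = 1012, level = "snp",
               allele = alleles, symbol = c("A", "C", "T", "A", "C")))
}

# Random cohort genotypes over a pool (for property tests).
random_genotypes <- function(pool, n, seed) sample_genotypes(pool, n, seed)

# -- independent oracles ------------------------------------------------------

# Brute-force simple OLS of y on intercept + d via lm(); the reference the
# vectorised scan must match.
lm_oracle <- function(y, d) {
  fit <- summary(stats::lm(y ~ d))
  list(beta = unname(fit$coefficients["d", "Estimate"]),
       se = unname(fit$coefficients["d", "Std. Error"]),
       t_stat = unname(fit$coefficients["d", "t value"]),
       p_value = unname(fit$coefficients["d", "Pr(>|t|)"]))
}

# Brute-force site dosage: for one individual's two alleles, count copies of
# `symbol` at `position` by translating each allele separately.
count_symbol_oracle <- function(a1, a2, table, locus, position, level, symbol) {
  t_pos <- table[table$locus == locus & table$position == position &
                   table$level == level, ]
  map <- setNames(t_pos$symbol, t_pos$allele)
  sum(map[[a1]] == symbol, map[[a2]] == symbol)
}

# Step-up BH by the textbook formula: sort, p * m / rank, cumulative min
# from the largest p, restore order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(ord)]
}

# -- planted-effect experiment used by recovery tests -------------------------

# Two loci with few common alleles (a realistic scale for class II loci such
# as DPA1/DQA1): all amino-acid columns of a locus are linear functions of
# its allele dosages, giving the strong low-rank LD typical of the MHC.
recovery_pool <- function() {
  haplotype_pool(list(
    "HLA-A" = c("A*01:01" = 0.45, "A*02:01" = 0.35, "A*03:01" = 0.20),
    "HLA-DRB1" = c("DRB1*01:01" = 0.45, "DRB1*04:01" = 0.30,
                   "DRB1*15:01" = 0.25)))
}

# One bi-allelic locus: every encoded column is a perfect-linkage coding of
# the same polymorphism, the tightest LD block possible.
single_block_pool <- function() {
  haplotype_pool(list("HLA-A" = c("A*01:01" = 0.6, "A*02:01" = 0.4)))
}

# One replicate of the planted-signal experiment: n individuals, amino-acid
# dosages from the two-locus pool (>= 20 linkage passengers), two (or one)
# planted effects of the given variance fractions on the first target gene,
# null phenotypes for the remaining genes.
recovery_instance <- function(seed, n = 200, fractions = c(0.1, 0.1),
                              n_null_genes = 47, n_positions = 14,
                              pool = recovery_pool()) {
  genotypes <- sample_genotypes(pool, n, seed = seed)
  table <- synthesize_translation_table(pool, n_aa_positions = n_positions,
                                        n_snp_positions = 1, seed = seed + 1L)
  dosages <- filter_maf(encode_site_dosage(genotypes, table, "amino_acid"),
                        0.05)
  planted <- choose_planted_variants(dosages, n = length(fractions),
                                     max_abs_cor = 0.75, seed = seed + 2L)
  y <- plant_phenotype(dosages, planted, fractions, seed = seed + 3L)
  U <- with_seed(seed + 4L, {
    m <- cbind(y, matrix(rnorm(n * n_null_genes), nrow = n))
    colnames(m) <- sprintf("TRBV%02d", seq_len(n_null_genes + 1L))
    rownames(m) <- rownames(dosage_values(dosages))
    m
  })
  # phenotypes enter the scan as plain matrices (already on analysis scale)
  list(dosages = dosages, planted = planted, phenotypes = U, y = y)
}
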