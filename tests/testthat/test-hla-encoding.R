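test_that("allele dosage counts copies of each four-digit allele", {
  d <- encode_allele_dosage(toy_genotypes())
  D <- dosage_values(d)
  # homozygote A*01:01/A*01:01 -> 2 for that allele, 0 for the other
  expect_equal(unname(D["i1", ]), c(2, 0))
  # heterozygote -> 1 and 1
  expect_equal(unname(D["i2", ]), c(1, 1))
  # hand-enumerated column sums for the X/X, X/Y, Y/Y cohort
  expect_equal(unname(colSums(D)), c(3, 3))
  # per-individual per-locus sum is always 2
  expect_true(all(rowSums(D) == 2))
  meta <- dosage_variants(d)
  expect_equal(meta$level, rep("allele", 2))
  expect_equal(meta$ref_symbol, c("A*01:01", "A*11:01"))
})

test_that("missing genotype entries are an explicit error", {
  g <- toy_genotypes()
  g$allele2[2] <- NA
  expect_error(encode_allele_dosage(g), "missing genotype")
  # an individual absent at one locus of a two-locus cohort
  g2 <- rbind(toy_genotypes(),
              data.frame(individual_id = c("i1", "i2"), locus = "HLA-B",
                         allele1 = "B*07:02", allele2 = "B*07:02"))
  expect_error(encode_allele_dosage(g2), "i3")
})

test_that("site dosage follows the reference-allele coding at a bi-allelic site", {
  # genotypes FF / FY / YY at position 9 via allele translation
  g <- data.frame(individual_id = c("i1", "i2", "i3"), locus = "HLA-A",
                  allele1 = c("A*01:01", "A*01:01", "A*03:01"),
                  allele2 = c("A*02:01", "A*03:01", "A*11:01"))
  d <- encode_site_dosage(g, toy_table(), "amino_acid")
  D <- dosage_values(d)
  expect_equal(unname(D[, "HLA-A.amino_acid.9.F"]), c(2, 1, 0))
  expect_equal(unname(D[, "HLA-A.amino_acid.9.Y"]), c(0, 1, 2))
})

test_that("a tri-allelic site expands to exactly three complementary columns", {
  alleles <- c("a1", "a2", "a3")
  tab <- data.frame(locus = "L", position = 5, level = "snp",
                    allele = alleles, symbol = c("A", "C", "T"))
  g <- data.frame(individual_id = paste0("i", 1:5), locus = "L",
                  allele1 = c("a1", "a1", "a1", "a3", "a2"),
                  allele2 = c("a1", "a3", "a2", "a3", "a2"))
  d <- encode_site_dosage(g, tab, "snp")
  D <- dosage_values(d)
  expect_equal(ncol(D), 3)
  # with reference A: AA -> 2, AT -> 1, AC -> 1, TT -> 0, CC -> 0
  expect_equal(unname(D[, "L.snp.5.A"]), c(2, 1, 1, 0, 0))
  # complementarity: per site the expanded dosages sum to 2
  expect_true(all(rowSums(D) == 2))
})

test_that("monomorphic sites yield no variants", {
  g <- toy_genotypes()
  d <- encode_site_dosage(g, toy_table(), "amino_acid")
  expect_false(any(dosage_variants(d)$position == 150))
})

test_that("alleles absent from the translation table are named in the error", {
  g <- toy_genotypes()
  tab <- toy_table()
  tab <- tab[tab$allele != "A*11:01", ]
  expect_error(encode_site_dosage(g, tab, "amino_acid"), "A\\*11:01")
})

test_that("site encoding matches brute-force counting on random small cohorts", {
  tab <- toy_table()
  for (seed in 1:8) {
    g <- sample_genotypes(toy_pool(), 10, seed = seed)
    g <- g[g$locus == "HLA-A", ]
    d <- encode_site_dosage(g, tab, "amino_acid")
    D <- dosage_values(d)
    meta <- dosage_variants(d)
    for (j in seq_len(ncol(D))) {
      expected <- vapply(seq_len(nrow(g)), function(i) {
        count_symbol_oracle(g$allele1[i], g$allele2[i], tab, meta$locus[j],
                            meta$position[j], meta$level[j],
                            meta$ref_symbol[j])
      }, numeric(1))
      expect_equal(unname(D[, j]), expected)
    }
    # complementarity holds at every site
    site <- paste(meta$locus, meta$position)
    for (s in unique(site)) {
      expect_true(all(rowSums(D[, site == s, drop = FALSE]) == 2))
    }
  }
})

test_that("MAF filtering drops rare columns, keeps the boundary, and is idempotent", {
  vals <- cbind(a = c(0L, 0L, 0L, 0L, 0L),        # f = 0, dropped
                b = c(0L, 0L, 1L, 2L, 1L),        # f = 0.4, kept
                c = c(2L, 2L, 2L, 2L, 2L),        # f = 1, dropped
                d = c(1L, 0L, 0L, 0L, 0L))        # f = 0.1, kept at 0.05
  meta <- data.frame(variant_id = colnames(vals), locus = "L", level = "snp",
                     position = 1:4, ref_symbol = c("A", "C", "G", "T"))
  dm <- dosage_matrix(vals, meta)
  f1 <- filter_maf(dm, 0.05)
  expect_equal(colnames(dosage_values(f1)), c("b", "d"))
  # boundary: f exactly at the threshold is retained (strict "<" drop rule)
  f2 <- filter_maf(dm, 0.1)
  expect_true("d" %in% colnames(dosage_values(f2)))  # MAF = 0.1 kept
  # idempotence
  expect_identical(filter_maf(f1, 0.05), f1)
  expect_error(filter_maf(dm, 0.7), "0, 0.5")
})

test_that("dosage TSV round trip is exact", {
  g <- sample_genotypes(toy_pool(), 15, seed = 4)
  d <- encode_site_dosage(g, synthesize_translation_table(toy_pool(), 5, 5,
                                                          seed = 4),
                          "amino_acid")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(d, path)
  d2 <- read_dosage_tsv(path)
  expect_identical(dosage_values(d2), dosage_values(d))
  expect_identical(dosage_variants(d2), dosage_variants(d))
  # allele level round trip too (ids contain '*' and ':')
  da <- encode_allele_dosage(g)
  write_dosage_tsv(da, path)
  da2 <- read_dosage_tsv(path)
  expect_identical(dosage_values(da2), dosage_values(da))
  expect_identical(dosage_variants(da2), dosage_variants(da))
})

test_that("variant id construction and parsing are inverse, shorthand accepted", {
  id <- make_variant_id("HLA-DRB1", "amino_acid", 71, "R")
  expect_equal(id, "HLA-DRB1.amino_acid.71.R")
  p <- parse_variant_id(c(id, "HLA-A.allele.A*11:01", "HLA-A.I97M"))
  expect_equal(p$locus, c("HLA-DRB1", "HLA-A", "HLA-A"))
  expect_equal(p$level, c("amino_acid", "allele", "amino_acid"))
  expect_equal(p$position, c(71L, NA, 97L))
  expect_equal(p$ref_symbol, c("R", "A*11:01", "M"))
  expect_error(parse_variant_id("garbage"), "cannot parse")
})

write_test_vcf <- function(path, records,
                           samples = c("s1", "s2", "s3")) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
}

test_that("VCF import expands multi-allelic records and validates calls", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    "chr6\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr6\t200\t.\tA\tC,T\t.\tPASS\t.\tGT\t0/0\t0/2\t1/2"))
  d <- import_vcf_snp_dosage(path)
  D <- dosage_values(d)
  # bi-allelic record: complementary REF and ALT columns
  expect_equal(unname(D[, "chr6.snp.100.A"]), c(2, 1, 0))
  expect_equal(unname(D[, "chr6.snp.100.C"]), c(0, 1, 2))
  # two ALTs -> three columns
  expect_equal(sum(dosage_variants(d)$position == 200), 3)
  expect_equal(unname(D[, "chr6.snp.200.T"]), c(0, 1, 1))
  # empty region -> zero columns
  d0 <- import_vcf_snp_dosage(path, region = "chr6:300-400")
  expect_equal(ncol(dosage_values(d0)), 0)
  # region restriction keeps only spanning records
  d1 <- import_vcf_snp_dosage(path, region = "chr6:150-250")
  expect_true(all(dosage_variants(d1)$position == 200))
})

test_that("VCF missing and half calls are rejected with the record named", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, "chr6\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/0\t./.\t1/1")
  expect_error(import_vcf_snp_dosage(path), "chr6:100.*s2")
})
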