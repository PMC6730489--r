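test_that("haplotype pool validation rejects malformed frequency sets", {
  expect_error(haplotype_pool(list("HLA-A" = c("X" = 0.5, "Y" = 0.4))),
               "sum to 1")
  expect_error(haplotype_pool(list("HLA-A" = c("X" = -0.2, "Y" = 1.2))),
               "> 0")
  expect_error(haplotype_pool(list(c("X" = 1))), "named list")
  expect_silent(haplotype_pool(list("HLA-A" = c("X" = 0.3, "Y" = 0.7))))
})

test_that("genotype sampling covers degenerate, empty and stochastic cases", {
  # degenerate single-allele pool: everyone homozygous
  pool1 <- haplotype_pool(list("HLA-A" = c("A*01:01" = 1)))
  g <- sample_genotypes(pool1, 5, seed = 3)
  expect_equal(nrow(g), 5)
  expect_true(all(g$allele1 == "A*01:01" & g$allele2 == "A*01:01"))

  # empty cohort
  g0 <- sample_genotypes(pool1, 0, seed = 1)
  expect_equal(nrow(g0), 0)

  # binomial sampling oracle: empirical frequency of X within 3 SE of 0.3
  pool2 <- haplotype_pool(list("L" = c("X" = 0.3, "Y" = 0.7)))
  g2 <- sample_genotypes(pool2, 2000, seed = 11)
  f <- mean(c(g2$allele1, g2$allele2) == "X")
  se <- sqrt(0.3 * 0.7 / 4000)
  expect_lt(abs(f - 0.3), 3 * se)

  # determinism: identical seed, identical draw
  expect_identical(sample_genotypes(toy_pool(), 50, seed = 9),
                   sample_genotypes(toy_pool(), 50, seed = 9))
})

test_that("Hardy-Weinberg: homozygote fraction matches p^2 at n = 5000", {
  pool <- haplotype_pool(list("L" = c("X" = 0.3, "Y" = 0.7)))
  g <- sample_genotypes(pool, 5000, seed = 21)
  hom_x <- mean(g$allele1 == "X" & g$allele2 == "X")
  se <- sqrt(0.09 * 0.91 / 5000)
  expect_lt(abs(hom_x - 0.3^2), 3 * se)
})

test_that("translation tables respect pigeonhole and multi-allelic bounds", {
  # single-allele locus: all positions monomorphic
  t1 <- synthesize_translation_table(
    haplotype_pool(list("L" = c("X" = 1))), 5, 5, seed = 2)
  n_sym <- tapply(t1$symbol, paste(t1$level, t1$position),
                  function(s) length(unique(s)))
  expect_true(all(n_sym == 1))

  # two-allele locus: every position has at most 2 symbols
  t2 <- synthesize_translation_table(
    haplotype_pool(list("L" = c("X" = 0.5, "Y" = 0.5))), 8, 8, seed = 2)
  n_sym2 <- tapply(t2$symbol, paste(t2$level, t2$position),
                   function(s) length(unique(s)))
  expect_true(all(n_sym2 <= 2))

  # five-allele locus: at least one position with >= 3 distinct residues,
  # at least one polymorphic position
  t5 <- synthesize_translation_table(toy_pool(), 6, 6, seed = 2)
  t5a <- t5[t5$locus == "HLA-A" & t5$level == "amino_acid", ]
  n_sym5 <- tapply(t5a$symbol, t5a$position, function(s) length(unique(s)))
  expect_true(any(n_sym5 >= 3))
  expect_true(any(n_sym5 >= 2))

  # every allele is mapped at every position
  counts <- table(t5$locus, paste(t5$level, t5$position))
  expect_true(all(counts[1, counts[1, ] > 0] == 5))
})

test_that("generated usage is compositional with exact zero dropout", {
  pool <- toy_pool()
  g <- sample_genotypes(pool, 60, seed = 5)
  tab <- synthesize_translation_table(pool, 6, 6, seed = 5)
  d <- encode_site_dosage(g, tab, "amino_acid")
  cfg <- simulation_config(n_individuals = 60, n_target_genes = 10,
                           n_control_genes = 4, noise_sd = 0.3,
                           dropout_rate = 0.15, seed = 8)
  gen <- generate_usage(d, config = cfg)
  u <- usage_values(gen$usage)
  expect_true(all(u >= 0 & u <= 1))
  expect_equal(unname(rowSums(u)), rep(1, 60), tolerance = 1e-9)
  # dropped genes are exactly zero; detected rows renormalised over the rest
  expect_true(all(u[gen$truth$dropout] == 0))
  expect_true(all(u[!gen$truth$dropout] > 0))
  # determinism
  gen2 <- generate_usage(d, config = cfg)
  expect_identical(gen$usage$usage, gen2$usage$usage)
})

test_that("no-signal, no-noise usage reproduces baseline proportions exactly", {
  pool <- toy_pool()
  g <- sample_genotypes(pool, 12, seed = 5)
  tab <- synthesize_translation_table(pool, 4, 4, seed = 5)
  d <- encode_site_dosage(g, tab, "amino_acid")
  cfg <- simulation_config(n_individuals = 12, n_target_genes = 6,
                           n_control_genes = 2, noise_sd = 0,
                           dropout_rate = 0, seed = 8)
  gen <- generate_usage(d, config = cfg)
  expect_equal(usage_values(gen$usage),
               matrix(rep(gen$truth$baseline, each = 12), nrow = 12,
                      dimnames = dimnames(usage_values(gen$usage))),
               tolerance = 1e-12)
})

test_that("a planted positive effect makes usage increase with dosage", {
  pool <- toy_pool()
  g <- sample_genotypes(pool, 80, seed = 6)
  tab <- synthesize_translation_table(pool, 4, 4, seed = 6)
  d <- filter_maf(encode_site_dosage(g, tab, "amino_acid"), 0.05)
  v <- colnames(dosage_values(d))[1]
  cfg <- simulation_config(n_individuals = 80, n_target_genes = 6,
                           n_control_genes = 2, noise_sd = 0,
                           dropout_rate = 0, seed = 8)
  gen <- generate_usage(d, effects = data.frame(variant_id = v,
                                                gene_id = "TRBV01",
                                                beta = 1.0),
                        config = cfg)
  u <- usage_values(gen$usage)[, "TRBV01"]
  dos <- dosage_values(d)[, v]
  means <- tapply(u, dos, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
  # softmax monotone in its own score: every dosage-2 carrier above every
  # dosage-0 carrier (noise-free)
  if (any(dos == 2) && any(dos == 0)) {
    expect_gt(min(u[dos == 2]), max(u[dos == 0]))
  }
})

test_that("effects targeting control genes or unknown variants are rejected", {
  pool <- toy_pool()
  g <- sample_genotypes(pool, 20, seed = 6)
  tab <- synthesize_translation_table(pool, 4, 4, seed = 6)
  d <- encode_site_dosage(g, tab, "amino_acid")
  cfg <- simulation_config(n_individuals = 20, n_target_genes = 4,
                           n_control_genes = 2, seed = 8)
  v <- colnames(dosage_values(d))[1]
  expect_error(generate_usage(d, data.frame(variant_id = v, gene_id = "IGHV01",
                                            beta = 1), cfg),
               "control")
  expect_error(generate_usage(d, data.frame(variant_id = "nope",
                                            gene_id = "TRBV01", beta = 1),
                              cfg),
               "unknown effect variant")
})

test_that("planted linear phenotypes carry the requested variance fractions", {
  inst <- recovery_instance(seed = 301, fractions = c(0.1, 0.1),
                            n_null_genes = 0)
  D <- dosage_values(inst$dosages)
  betas <- attr(inst$y, "betas")
  for (v in names(betas)) {
    expect_equal(betas[[v]], sqrt(0.1) / sd(D[, v]), tolerance = 1e-12)
  }
  # realised variance share of the planted part is near 20% over many seeds
  share <- vapply(1:30, function(s) {
    inst <- recovery_instance(seed = 1000 + s, fractions = c(0.1, 0.1),
                              n_null_genes = 0)
    D <- dosage_values(inst$dosages)
    b <- attr(inst$y, "betas")
    g <- as.numeric(D[, names(b), drop = FALSE] %*% b)
    var(g) / var(inst$y)
  }, numeric(1))
  expect_equal(mean(share), 0.2, tolerance = 0.03)
})

test_that("simulation config validates its ranges", {
  expect_error(simulation_config(n_individuals = -1), "n_individuals")
  expect_error(simulation_config(noise_sd = -0.1), "noise_sd")
  expect_error(simulation_config(dropout_rate = 1), "dropout_rate")
})
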