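# Synthetic cohort generation: HLA haplotype pools, Hardy-Weinberg genotype
# sampling, allele-linked residue/SNP variation, and compositional V-gene
# usage phenotypes with planted additive effects.

#' Construct a haplotype pool
#'
#' A haplotype pool lists, for each classical HLA locus, the four-digit
#' alleles segregating in the population together with their frequencies.
#' Genotypes are later drawn from it under Hardy-Weinberg equilibrium
#' (two independent draws per individual per locus).
#'
#' @param alleles Named list; one element per locus (e.g. `"HLA-A"`), each a
#'   named numeric vector of strictly positive allele frequencies summing
#'   to 1 (within 1e-9).
#' @return An object of class `haplotype_pool`.
#' @examples
#' haplotype_pool(list("HLA-A" = c("A*01:01" = 0.4, "A*11:01" = 0.6)))
#' @export
haplotype_pool <- function(alleles) {
  if (!is.list(alleles) || length(alleles) == 0 || is.null(names(alleles)) ||
      anyDuplicated(names(alleles))) {
    stop_user("`alleles` must be a non-empty named list with unique locus names")
  }
  for (locus in names(alleles)) {
    f <- alleles[[locus]]
    if (!is.numeric(f) || length(f) == 0 || is.null(names(f)) ||
        anyDuplicated(names(f))) {
      stop_user("locus ", locus, ": allele frequencies must be a named ",
                "numeric vector with unique allele names")
    }
    if (any(f <= 0)) stop_user("locus ", locus, ": frequencies must be > 0")
    if (abs(sum(f) - 1) > 1e-9) {
      stop_user("locus ", locus, ": frequencies must sum to 1 (got ", sum(f), ")")
    }
  }
  structure(list(alleles = alleles), class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("haplotype_pool:", length(x$alleles), "loci\n")
  for (locus in names(x$alleles)) {
    cat(" ", locus, ":", length(x$alleles[[locus]]), "alleles\n")
  }
  invisible(x)
}

#' Default cohort-scale haplotype pool
#'
#' Builds a pool over the eight classical HLA loci with per-locus allele
#' counts matching the diversity reported for a cohort of ~200 unrelated
#' individuals (23 HLA-A, 46 HLA-B, 21 HLA-C, 28 DRB1, 16 DPB1, 4 DPA1,
#' 14 DQB1, 15 DQA1). Frequencies are drawn once from a symmetric Dirichlet
#' and sorted, giving the usual few-common-many-rare HLA spectrum.
#'
#' @param seed RNG seed for the frequency draw.
#' @param n_alleles Named integer vector of allele counts per locus.
#' @param concentration Dirichlet concentration for allele frequencies;
#'   smaller values give more skew.
#' @return A [haplotype_pool()].
#' @export
default_haplotype_pool <- function(seed = 1,
                                   n_alleles = c("HLA-A" = 23, "HLA-B" = 46,
                                                 "HLA-C" = 21, "HLA-DRB1" = 28,
                                                 "HLA-DPB1" = 16, "HLA-DPA1" = 4,
                                                 "HLA-DQB1" = 14, "HLA-DQA1" = 15),
                                   concentration = 0.5) {
  with_seed(seed, {
    alleles <- lapply(names(n_alleles), function(locus) {
      k <- n_alleles[[locus]]
      g <- rgamma(k, shape = concentration)
      f <- sort(g / sum(g), decreasing = TRUE)
      gene <- sub("^HLA-", "", locus)
      names(f) <- sprintf("%s*%02d:01", gene, seq_len(k))
      f
    })
    names(alleles) <- names(n_alleles)
    haplotype_pool(alleles)
  })
}

#' Sample cohort genotypes under Hardy-Weinberg equilibrium
#'
#' Each individual receives two alleles per locus, drawn independently from
#' the pool frequencies. The two alleles are stored as an unordered pair
#' (sorted byte-wise).
#'
#' @param pool A [haplotype_pool()].
#' @param n Number of individuals (>= 0).
#' @param seed RNG seed; the draw is deterministic given `pool`, `n`, `seed`.
#' @return A data.frame of class `hla_genotypes` with columns
#'   `individual_id`, `locus`, `allele1`, `allele2`.
#' @export
sample_genotypes <- function(pool, n, seed = 1) {
  if (!inherits(pool, "haplotype_pool")) stop_user("`pool` must be a haplotype_pool")
  if (!is_count(n)) stop_user("`n` must be a non-negative integer")
  empty <- data.frame(individual_id = character(), locus = character(),
                      allele1 = character(), allele2 = character(),
                      stringsAsFactors = FALSE)
  if (n == 0) {
    class(empty) <- c("hla_genotypes", "data.frame")
    return(empty)
  }
  ids <- sprintf(paste0("ind%0", max(3L, nchar(as.character(max(n, 1)))), "d"),
                 seq_len(n))
  with_seed(seed, {
    rows <- lapply(names(pool$alleles), function(locus) {
      f <- pool$alleles[[locus]]
      a1 <- sample(names(f), n, replace = TRUE, prob = f)
      a2 <- sample(names(f), n, replace = TRUE, prob = f)
      data.frame(individual_id = ids, locus = locus,
                 allele1 = pmin(a1, a2), allele2 = pmax(a1, a2),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(match(out$individual_id, ids)), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("hla_genotypes", "data.frame")
    out
  })
}

AA_LETTERS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# Randomly partition k alleles into g non-empty groups; returns group index
# per allele.
random_partition <- function(k, g) {
  if (g >= k) return(sample(seq_len(k)))
  grp <- c(seq_len(g), sample(seq_len(g), k - g, replace = TRUE))
  sample(grp)
}

#' Synthesize an allele translation table
#'
#' Assigns to every allele of every locus one residue per amino-acid
#' position and one base per SNP position. Positions partition the allele
#' set into symbol groups, so alleles sharing a residue are correlated at
#' every other position they co-occur in: this is the mechanism that gives
#' MHC amino acids their strong linkage disequilibrium, and it is inherited
#' by the synthetic tables. For loci with at least two alleles the first
#' position is forced polymorphic, and with at least three alleles the
#' second is forced multi-allelic (>= 3 residues).
#'
#' @param pool A [haplotype_pool()].
#' @param n_aa_positions Number of amino-acid positions per locus (>= 1); the default yields roughly 300 testable amino-acid dosage columns at cohort scale after MAF filtering.
#' @param n_snp_positions Number of SNP positions per locus (>= 1).
#' @param seed RNG seed.
#' @return A data.frame of class `allele_table` with columns `locus`,
#'   `position`, `level`, `allele`, `symbol`.
#' @export
synthesize_translation_table <- function(pool, n_aa_positions = 18,
                                         n_snp_positions = 40, seed = 1) {
  if (!inherits(pool, "haplotype_pool")) stop_user("`pool` must be a haplotype_pool")
  if (!is_count(n_aa_positions, 1) || !is_count(n_snp_positions, 1)) {
    stop_user("position counts must be >= 1")
  }
  with_seed(seed, {
    one_level <- function(locus, alleles, n_pos, level, symbols, max_groups) {
      k <- length(alleles)
      positions <- sort(sample.int(if (level == "snp") 6000L else 400L, n_pos))
      rows <- lapply(seq_len(n_pos), function(i) {
        gmax <- min(max_groups, k, length(symbols))
        g <- if (k == 1) 1L else if (i == 1L) min(2L, gmax) else if (i == 2L) {
          min(3L, gmax)
        } else {
          # mostly bi-allelic, some multi-allelic, occasional monomorphic
          sample(seq_len(gmax), 1, prob = c(0.15, 0.55, 0.2, 0.1)[seq_len(gmax)])
        }
        grp <- if (g == 1) rep(1L, k) else random_partition(k, g)
        sym <- sample(symbols, g)
        data.frame(locus = locus, position = positions[i], level = level,
                   allele = alleles, symbol = sym[grp],
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    out <- do.call(rbind, lapply(names(pool$alleles), function(locus) {
      alleles <- names(pool$alleles[[locus]])
      rbind(one_level(locus, alleles, n_aa_positions, "amino_acid",
                      AA_LETTERS, 4L),
            one_level(locus, alleles, n_snp_positions, "snp",
                      c("A", "C", "G", "T"), 4L))
    }))
    rownames(out) <- NULL
    class(out) <- c("allele_table", "data.frame")
    out
  })
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic usage generator. Defaults mirror the
#' study scale: 201 individuals and 48 target (TRBV-like) genes, plus a
#' 20-gene no-effect control family standing in for IGHV.
#'
#' @param n_individuals Cohort size (>= 0).
#' @param n_target_genes Number of target V genes.
#' @param n_control_genes Number of control-family genes (never receive
#'   planted effects).
#' @param noise_sd Standard deviation of the per-individual, per-gene
#'   Gaussian noise on latent log-scores.
#' @param dropout_rate Probability that a gene is undetected in an
#'   individual (recorded as exactly 0 usage); must be in `[0, 1)`.
#' @param baseline_concentration Symmetric Dirichlet concentration for the
#'   baseline gene proportions.
#' @param seed RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 201, n_target_genes = 48,
                              n_control_genes = 20, noise_sd = 0.3,
                              dropout_rate = 0.02,
                              baseline_concentration = 5, seed = 1) {
  if (!is_count(n_individuals)) stop_user("`n_individuals` must be >= 0")
  if (!is_count(n_target_genes, 1)) stop_user("`n_target_genes` must be >= 1")
  if (!is_count(n_control_genes)) stop_user("`n_control_genes` must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_user("`noise_sd` must be >= 0")
  if (!is_fraction(dropout_rate) || dropout_rate >= 1) {
    stop_user("`dropout_rate` must be in [0, 1)")
  }
  if (!is.numeric(baseline_concentration) || baseline_concentration <= 0) {
    stop_user("`baseline_concentration` must be > 0")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_target_genes = as.integer(n_target_genes),
                 n_control_genes = as.integer(n_control_genes),
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 baseline_concentration = baseline_concentration,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sim_gene_names <- function(config) {
  c(sprintf("TRBV%02d", seq_len(config$n_target_genes)),
    if (config$n_control_genes > 0)
      sprintf("IGHV%02d", seq_len(config$n_control_genes)))
}

#' Generate V-gene usage with planted additive MHC effects
#'
#' Usage is generated compositionally, mimicking read proportions: each gene
#' gets a latent log-score `log(baseline) + sum(beta * dosage) + noise`, and
#' an individual's usage row is the softmax of the scores over the genes
#' detected in that individual. Undetected (dropped-out) genes are recorded
#' as exactly 0 and excluded from the normalisation, so each row sums to 1
#' over its detected genes. Control-family genes never receive planted
#' effects.
#'
#' @param dosages A [dosage_matrix] whose rows are the cohort individuals.
#' @param effects `NULL` for a null cohort, or a data.frame with columns
#'   `variant_id`, `gene_id`, `beta` (additive effect per dosage unit on the
#'   latent log-score).
#' @param config A [simulation_config()].
#' @return A list with elements `usage` (a [usage_matrix]) and `truth`
#'   (planted betas, baseline proportions, dropout mask, config echo).
#' @export
generate_usage <- function(dosages, effects = NULL, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  D <- dosage_values(dosages)
  n <- nrow(D)
  if (n != config$n_individuals) {
    stop_user("dosage matrix has ", n, " rows but config expects ",
              config$n_individuals, " individuals")
  }
  genes <- sim_gene_names(config)
  family <- setNames(rep(c("target", "control"),
                         c(config$n_target_genes, config$n_control_genes)),
                     genes)
  if (!is.null(effects)) {
    if (!all(c("variant_id", "gene_id", "beta") %in% names(effects))) {
      stop_user("`effects` needs columns variant_id, gene_id, beta")
    }
    bad_v <- setdiff(effects$variant_id, colnames(D))
    if (length(bad_v)) stop_user("unknown effect variant(s): ",
                                 paste(bad_v, collapse = ", "))
    bad_g <- setdiff(effects$gene_id, genes)
    if (length(bad_g)) stop_user("unknown effect gene(s): ",
                                 paste(bad_g, collapse = ", "))
    if (any(family[effects$gene_id] == "control")) {
      stop_user("effects may not target control-family genes")
    }
  }
  with_seed(config$seed, {
    g <- rgamma(length(genes), shape = config$baseline_concentration)
    baseline <- setNames(g / sum(g), genes)
    s <- matrix(rep(log(baseline), each = n), nrow = n,
                dimnames = list(rownames(D), genes))
    if (!is.null(effects)) {
      for (i in seq_len(nrow(effects))) {
        s[, effects$gene_id[i]] <- s[, effects$gene_id[i]] +
          effects$beta[i] * D[, effects$variant_id[i]]
      }
    }
    if (config$noise_sd > 0) {
      s <- s + matrix(rnorm(n * length(genes), sd = config$noise_sd), nrow = n)
    }
    dropped <- matrix(runif(n * length(genes)) < config$dropout_rate, nrow = n,
                      dimnames = dimnames(s))
    # every individual keeps at least one detected gene
    all_out <- rowSums(!dropped) == 0
    if (any(all_out)) {
      keep <- max.col(s[all_out, , drop = FALSE])
      dropped[cbind(which(all_out), keep)] <- FALSE
    }
    w <- exp(s)
    w[dropped] <- 0
    usage <- w / rowSums(w)
    list(usage = usage_matrix(usage, family = family),
         truth = list(effects = effects, baseline = baseline,
                      dropout = dropped, config = unclass(config)))
  })
}

#' Plant a linear phenotype on chosen dosage columns
#'
#' Builds a quantitative phenotype `y = sum_j b_j d_j + e` in which each
#' chosen variant contributes a prescribed expected fraction of the total
#' variance (`b_j = sqrt(v_j) / sd(d_j)`, residual sd `sqrt(1 - sum v)`).
#' Used by power and recovery experiments where the planted variance
#' fraction must be exact on the phenotype scale.
#'
#' @param dosages A [dosage_matrix].
#' @param variant_ids Variants to plant on (must have nonzero variance).
#' @param fractions Per-variant variance fractions; `sum(fractions) < 1`.
#' @param seed RNG seed for the residual noise.
#' @return Numeric phenotype vector (one value per individual) with an
#'   attribute `betas` carrying the planted coefficients.
#' @export
plant_phenotype <- function(dosages, variant_ids, fractions, seed = 1) {
  D <- dosage_values(dosages)
  if (length(variant_ids) != length(fractions)) {
    stop_user("`variant_ids` and `fractions` must have equal length")
  }
  if (any(fractions < 0) || sum(fractions) >= 1) {
    stop_user("`fractions` must be non-negative and sum to < 1")
  }
  missing <- setdiff(variant_ids, colnames(D))
  if (length(missing)) stop_user("unknown variant(s): ",
                                 paste(missing, collapse = ", "))
  sds <- apply(D[, variant_ids, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) stop_user("planted variants must have nonzero variance")
  betas <- sqrt(fractions) / sds
  with_seed(seed, {
    y <- as.numeric(D[, variant_ids, drop = FALSE] %*% betas) +
      rnorm(nrow(D), sd = sqrt(1 - sum(fractions)))
    attr(y, "betas") <- setNames(betas, variant_ids)
    y
  })
}

#' Choose planted variants that tag distinct signals
#'
#' Selects variants with intermediate frequency whose strongest linkage
#' partner at any *other* site stays below a correlation ceiling, so a
#' planted effect is not perfectly shadowed by a different position. The
#' expanded columns of the variant's own site (the complementary reference
#' codings of the same polymorphism) are the same signal, not passengers;
#' among same-site columns that are perfectly (anti)correlated with the
#' choice, the byte-smallest id is taken, matching the deterministic
#' tie-break of the conditional scan. At most one variant per locus is
#' returned so planted effects are mutually independent.
#'
#' @param dosages A [dosage_matrix].
#' @param n Number of variants to choose.
#' @param max_abs_cor Ceiling on |correlation| with columns of other sites.
#' @param maf_range Allowed minor-allele-frequency interval.
#' @param seed RNG seed for the choice among eligible variants.
#' @return Character vector of `n` variant ids.
#' @export
choose_planted_variants <- function(dosages, n = 2, max_abs_cor = 0.75,
                                    maf_range = c(0.2, 0.45), seed = 1) {
  D <- dosage_values(dosages)
  meta <- dosage_variants(dosages)
  f <- colMeans(D) / 2
  maf <- pmin(f, 1 - f)
  ok_maf <- maf >= maf_range[1] & maf <= maf_range[2]
  if (!any(ok_maf)) stop_user("no variants in the requested MAF range")
  cc <- suppressWarnings(cor(D))
  diag(cc) <- 0
  cc[is.na(cc)] <- 0
  # columns with |r| ~ 1 carry the identical signal (complementary codings
  # of one site, or positions inducing the same allele partition); the
  # ceiling applies to genuinely distinct linkage partners only, and the
  # chosen column must be the byte-smallest of its twin class so that the
  # deterministic tie-break of downstream selection returns the planted id
  ids <- colnames(D)
  twin <- abs(cc) > 0.999
  cross <- abs(cc); cross[twin] <- 0
  ok_cross <- apply(cross, 2, max) <= max_abs_cor
  ok_canonical <- vapply(seq_along(ids), function(j) {
    all(ids[j] <= ids[twin[j, ]])
  }, logical(1))
  eligible <- ids[ok_maf & ok_cross & ok_canonical]
  if (length(eligible) == 0) stop_user("no eligible variants; relax `max_abs_cor`")
  loci <- meta$locus[match(eligible, meta$variant_id)]
  with_seed(seed, {
    picked <- character(0)
    for (locus in sample(unique(loci))) {
      cand <- eligible[loci == locus]
      picked <- c(picked, sample(cand, 1))
      if (length(picked) == n) break
    }
    if (length(picked) < n) {
      stop_user("only ", length(picked), " loci carry eligible variants; ",
                "asked for ", n)
    }
    picked
  })
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running the whole generative chain: genotype sampling
#' from a haplotype pool, translation-table synthesis, dosage encoding at
#' the three genetic levels with MAF filtering, and compositional usage
#' generation (optionally with planted effects).
#'
#' @param config A [simulation_config()].
#' @param pool A [haplotype_pool()]; defaults to [default_haplotype_pool()]
#'   seeded from `config$seed`.
#' @param effects Passed to [generate_usage()].
#' @param n_aa_positions,n_snp_positions Passed to
#'   [synthesize_translation_table()].
#' @param maf MAF threshold applied to every dosage level.
#' @return List with `genotypes`, `table`, `dosages` (list with elements
#'   `allele`, `snp`, `amino_acid`), `usage`, `truth`.
#' @export
simulate_cohort <- function(config = simulation_config(), pool = NULL,
                            effects = NULL, n_aa_positions = 18,
                            n_snp_positions = 40, maf = 0.05) {
  if (is.null(pool)) pool <- default_haplotype_pool(seed = config$seed)
  genotypes <- sample_genotypes(pool, config$n_individuals,
                                seed = config$seed + 1L)
  table <- synthesize_translation_table(pool, n_aa_positions, n_snp_positions,
                                        seed = config$seed + 2L)
  dosages <- list(
    allele = filter_maf(encode_allele_dosage(genotypes), maf),
    snp = filter_maf(encode_site_dosage(genotypes, table, "snp"), maf),
    amino_acid = filter_maf(encode_site_dosage(genotypes, table, "amino_acid"),
                            maf))
  gen <- generate_usage(dosages$amino_acid, effects = effects, config = config)
  list(genotypes = genotypes, table = table, dosages = dosages,
       usage = gen$usage, truth = gen$truth)
}
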