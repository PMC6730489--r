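# Linear-model QTL scan of V-gene usage against HLA dosages, with
# Benjamini-Hochberg FDR per genetic level and genomic-inflation
# diagnostics.

#' Fit one variant-gene pair by ordinary least squares
#'
#' Regresses the phenotype on an intercept and the dosage; the two-sided
#' p-value comes from the t distribution with `n - 2` degrees of freedom.
#' A perfect fit (zero residual) reports the smallest representable
#' positive p-value.
#'
#' @param y Numeric phenotype vector.
#' @param d Numeric dosage vector of the same length (`n >= 3`), with
#'   nonzero variance.
#' @return Named list: `beta`, `se`, `t_stat`, `p_value`, `n`.
#' @examples
#' fit_pair(c(1, 2, 3, 4), c(0, 1, 1, 2))  # beta = 1.5, p ~ 0.0513
#' @export
fit_pair <- function(y, d) {
  n <- length(y)
  if (length(d) != n) stop_user("`y` and `d` must have equal length")
  if (n < 3) stop_user("need at least 3 observations")
  if (anyNA(y) || anyNA(d)) stop_user("missing values are not supported")
  dc <- d - mean(d)
  sxx <- sum(dc^2)
  if (sxx == 0) stop_user("dosage has zero variance")
  yc <- y - mean(y)
  beta <- sum(dc * yc) / sxx
  sse <- max(sum(yc^2) - beta^2 * sxx, 0)
  df <- n - 2
  se <- sqrt(sse / df / sxx)
  t_stat <- if (se > 0) beta / se else sign(beta) * Inf
  p <- 2 * pt(-abs(t_stat), df)
  list(beta = beta, se = se, t_stat = t_stat,
       p_value = max(p, .Machine$double.xmin), n = n)
}

# Vectorised simple OLS of one phenotype against every column of a centred
# dosage matrix. Returns a data.frame; columns with zero variance get NA.
ols_scan_one <- function(yc, Dc, sxx, df) {
  sxy <- as.numeric(crossprod(Dc, yc))
  beta <- sxy / sxx
  sst <- sum(yc^2)
  sse <- pmax(sst - beta * sxy, 0)
  se <- sqrt(sse / df / sxx)
  t_stat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  p <- pmax(2 * pt(-abs(t_stat), df), .Machine$double.xmin)
  data.frame(beta = beta, se = se, t_stat = t_stat, p_value = p)
}

#' Scan all variant-gene pairs
#'
#' Runs the per-pair simple linear model of [fit_pair()] for every
#' combination of dosage column and V gene, on either raw usage proportions
#' or their log2 pseudo-usage transform. Individuals are matched by id
#' (inner join); dosage columns without variance among the matched
#' individuals are skipped with a message. Benjamini-Hochberg q-values are
#' computed within each genetic level across all of that level's tests
#' jointly (set `fdr_scope = "per_gene"` to adjust within each gene
#' instead).
#'
#' @param usage A [usage_matrix] (or plain matrix with individual rownames).
#' @param dosages A [dosage_matrix].
#' @param phenotype_mode `"raw"` (default) or `"log2"`.
#' @param fdr FDR threshold used for the significance flag.
#' @param fdr_scope `"per_level"` (default) or `"per_gene"`.
#' @return A data.frame of class `qtl_scan` with columns `variant_id`,
#'   `gene_id`, `beta`, `se`, `t_stat`, `p_value`, `q_value`, `level`,
#'   `n_used`, `significant`.
#' @export
qtl_scan <- function(usage, dosages, phenotype_mode = c("raw", "log2"),
                     fdr = 0.05, fdr_scope = c("per_level", "per_gene")) {
  phenotype_mode <- match.arg(phenotype_mode)
  fdr_scope <- match.arg(fdr_scope)
  U <- usage_values(usage)
  if (phenotype_mode == "log2") U <- log2_usage(usage)
  D <- dosage_values(dosages)
  ids <- intersect(rownames(U), rownames(D))
  if (length(ids) == 0) stop_user("no shared individuals between usage and dosages")
  U <- U[ids, , drop = FALSE]
  D <- D[ids, , drop = FALSE]
  n <- length(ids)
  if (n < 3) stop_user("need at least 3 shared individuals")
  Dc <- scale(D, center = TRUE, scale = FALSE)
  sxx <- colSums(Dc^2)
  keep <- sxx > 0
  if (any(!keep)) {
    message("skipping ", sum(!keep), " zero-variance dosage column(s): ",
            paste(head(colnames(D)[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ...")
  }
  Dc <- Dc[, keep, drop = FALSE]
  sxx <- sxx[keep]
  meta <- dosage_variants(dosages)
  meta <- meta[keep, , drop = FALSE]
  genes <- colnames(U)
  per_gene <- lapply(genes, function(g) {
    yc <- U[, g] - mean(U[, g])
    res <- ols_scan_one(yc, Dc, sxx, n - 2)
    cbind(data.frame(variant_id = meta$variant_id, gene_id = g,
                     stringsAsFactors = FALSE),
          res,
          data.frame(level = meta$level, n_used = n))
  })
  out <- do.call(rbind, per_gene)
  rownames(out) <- NULL
  out$q_value <- NA_real_
  grp <- if (fdr_scope == "per_level") out$level else
    paste(out$level, out$gene_id)
  for (g in unique(grp)) {
    sel <- grp == g
    out$q_value[sel] <- p.adjust(out$p_value[sel], method = "BH")
  }
  out$significant <- out$q_value <= fdr
  out <- out[, c("variant_id", "gene_id", "beta", "se", "t_stat", "p_value",
                 "q_value", "level", "n_used", "significant")]
  attr(out, "phenotype_mode") <- phenotype_mode
  attr(out, "fdr") <- fdr
  attr(out, "fdr_scope") <- fdr_scope
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("qtl_scan:", nrow(x), "tests (",
    paste(names(table(x$level)), table(x$level), sep = "=", collapse = ", "),
    ") on", length(unique(x$gene_id)), "genes;",
    sum(x$significant), "significant at FDR", attr(x, "fdr"), "\n")
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, n = 10, ...) {
  ord <- order(object$p_value)
  cat("Top associations (phenotype:", attr(object, "phenotype_mode"), ")\n")
  print.data.frame(head(as.data.frame(object)[ord, ], n), digits = 3,
                   row.names = FALSE)
  invisible(object)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity, plus significance
#' flags at the given threshold. Results are invariant to the input order.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @param q_threshold Flagging threshold (default 0.05).
#' @return List with `q_values` and logical `significant`.
#' @export
bh_fdr <- function(p_values, q_threshold = 0.05) {
  if (length(p_values) == 0) {
    return(list(q_values = numeric(0), significant = logical(0)))
  }
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop_user("p-values must lie in (0, 1]")
  }
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, significant = q <= q_threshold)
}

#' Genomic inflation and QQ coordinates
#'
#' Converts p-values to one-degree-of-freedom chi-square statistics and
#' reports the genomic-control inflation factor: the ratio of the median
#' observed statistic to the null median (`qchisq(0.5, 1) = 0.4549364`),
#' together with a bootstrap 95% interval and the QQ-plot coordinates
#' (expected vs observed -log10 p at plotting positions `(i - 0.5) / m`).
#'
#' @param p_values Numeric vector of p-values; zeroes are clamped to the
#'   smallest representable positive double with a warning.
#' @param ci_reps Bootstrap replicates for the lambda interval.
#' @param ci_seed Seed for the bootstrap resampling.
#' @return Object of class `inflation_report`: `lambda`, `lambda_ci`,
#'   `n_tests`, `qq` (data.frame `expected`, `observed`).
#' @export
qq_lambda <- function(p_values, ci_reps = 200, ci_seed = 1) {
  if (length(p_values) == 0) stop_user("empty p-value vector")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop_user("p-values must lie in [0, 1]")
  }
  if (any(p_values == 0)) {
    warning("p-values of 0 clamped to smallest representable double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  chisq <- qchisq(p_values, df = 1, lower.tail = FALSE)
  null_median <- qchisq(0.5, df = 1)
  lambda <- median(chisq) / null_median
  m <- length(p_values)
  ci <- with_seed(ci_seed, {
    boots <- vapply(seq_len(ci_reps), function(i) {
      median(chisq[sample.int(m, m, replace = TRUE)]) / null_median
    }, numeric(1))
    unname(quantile(boots, c(0.025, 0.975)))
  })
  sorted <- sort(p_values)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(sorted))
  structure(list(lambda = lambda, lambda_ci = ci, n_tests = m, qq = qq),
            class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("inflation_report: lambda = %.4f (95%% CI %.4f-%.4f), %d tests\n",
              x$lambda, x$lambda_ci[1], x$lambda_ci[2], x$n_tests))
  invisible(x)
}

#' QQ plot of a scan or p-value vector
#'
#' @param x An `inflation_report` (from [qq_lambda()]).
#' @param ... Passed to [plot()].
#' @export
plot.inflation_report <- function(x, ...) {
  plot(x$qq$expected, x$qq$observed,
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)),
       pch = 20, ...)
  graphics::abline(0, 1, col = "red")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("lambda = %.3f", x$lambda))
  invisible(x)
}
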