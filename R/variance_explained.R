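# Fraction of V-gene usage variance attributable to independent MHC
# signals: adjusted R-squared of single and joint linear models, with an
# overall F-test per gene and FDR flags across genes.

#' Adjusted R-squared and overall F-test of a linear model
#'
#' Ordinary least squares of `y` on an intercept plus the columns of `X`.
#' Reports the coefficient of determination, its small-sample adjustment
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)` (which may be negative and is
#' reported as computed), and the F-test that all slopes are zero.
#'
#' @param y Numeric response vector.
#' @param X Numeric matrix (or vector) of predictors; must be full column
#'   rank with `n > p + 1`.
#' @return Named list: `r2`, `adj_r2`, `f_stat`, `f_p`, `n`, `p`.
#' @examples
#' adjusted_r2(c(1, 2, 3, 4), c(0, 1, 1, 2))  # r2 = 0.9, adj_r2 = 0.85
#' @export
adjusted_r2 <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop_user("`y` and `X` row counts differ")
  if (n <= p + 1) stop_user("need n > p + 1 observations")
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    dep <- colnames(Xi)[qrX$pivot[seq(qrX$rank + 1L, ncol(Xi))]]
    stop_user("predictors are rank deficient; dependent column(s): ",
              paste(dep, collapse = ", "))
  }
  res <- qr.resid(qrX, y)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_user("`y` has zero variance")
  r2 <- 1 - sse / sst
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  f <- (r2 / p) / ((1 - r2) / (n - p - 1))
  f_p <- pf(f, p, n - p - 1, lower.tail = FALSE)
  list(r2 = r2, adj_r2 = adj, f_stat = f,
       f_p = max(f_p, .Machine$double.xmin), n = n, p = p)
}

#' Partition usage variance over independent signals
#'
#' For every gene with at least one conditional signal, reports the
#' adjusted R-squared of each signal's single-predictor model and of the
#' joint model over all the gene's signals, plus the joint model's overall
#' F-test. Per-signal attribution is the single-predictor adjusted
#' R-squared (not sequential), so for correlated signals the parts need not
#' sum to the joint value. Significance flags come from Benjamini-Hochberg
#' adjustment of the joint F-test p-values across genes.
#'
#' @param usage A [usage_matrix].
#' @param signals A `conditional_signals` table (from [finemap_genes()] or
#'   row-bound [conditional_scan()] outputs) with `gene_id`, `step`,
#'   `variant_id`.
#' @param dosages A [dosage_matrix] containing every signal variant.
#' @param phenotype_mode `"raw"` or `"log2"`, matching the scan.
#' @param fdr FDR threshold for the across-gene flag.
#' @return A data.frame of class `variance_report`, one row per gene:
#'   `gene_id`, `n_signals`, `top_variant`, `top_adj_r2`, `second_variant`,
#'   `second_adj_r2`, `combined_adj_r2`, `combined_r2`, `f_stat`, `f_p`,
#'   `significant`. The full per-signal breakdown (all steps) is in
#'   `attr(, "per_signal")`.
#' @export
variance_partition <- function(usage, signals, dosages,
                               phenotype_mode = c("raw", "log2"), fdr = 0.05) {
  phenotype_mode <- match.arg(phenotype_mode)
  if (nrow(signals) == 0) stop_user("`signals` is empty")
  U <- usage_values(usage)
  if (phenotype_mode == "log2") U <- log2_usage(usage)
  D <- dosage_values(dosages)
  missing <- setdiff(signals$variant_id, colnames(D))
  if (length(missing)) {
    stop_user("signal variant(s) absent from dosage matrix: ",
              paste(missing, collapse = ", "))
  }
  ids <- intersect(rownames(U), rownames(D))
  if (length(ids) == 0) stop_user("no shared individuals")
  U <- U[ids, , drop = FALSE]; D <- D[ids, , drop = FALSE]
  per_signal <- list(); rows <- list()
  for (g in unique(signals$gene_id)) {
    sg <- signals[signals$gene_id == g, , drop = FALSE]
    sg <- sg[order(sg$step), , drop = FALSE]
    y <- U[, g]
    singles <- vapply(sg$variant_id, function(v) {
      adjusted_r2(y, D[, v, drop = FALSE])$adj_r2
    }, numeric(1))
    joint <- adjusted_r2(y, D[, sg$variant_id, drop = FALSE])
    per_signal[[g]] <- data.frame(gene_id = g, step = sg$step,
                                  variant_id = sg$variant_id,
                                  adj_r2 = unname(singles),
                                  stringsAsFactors = FALSE)
    rows[[g]] <- data.frame(
      gene_id = g, n_signals = nrow(sg),
      top_variant = sg$variant_id[1], top_adj_r2 = unname(singles[1]),
      second_variant = if (nrow(sg) >= 2) sg$variant_id[2] else NA_character_,
      second_adj_r2 = if (nrow(sg) >= 2) unname(singles[2]) else NA_real_,
      combined_adj_r2 = joint$adj_r2, combined_r2 = joint$r2,
      f_stat = joint$f_stat, f_p = joint$f_p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- bh_fdr(out$f_p, fdr)$significant
  attr(out, "per_signal") <- do.call(rbind, unname(per_signal))
  attr(out, "fdr") <- fdr
  attr(out, "phenotype_mode") <- phenotype_mode
  class(out) <- c("variance_report", "data.frame")
  out
}

#' @export
print.variance_report <- function(x, ...) {
  cat("variance_report:", nrow(x), "gene(s);", sum(x$significant),
      "with joint model significant at FDR", attr(x, "fdr"), "\n")
  print.data.frame(as.data.frame(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Reporting view of a variance report
#'
#' Re-expresses the per-gene variance partition as percentages in the usual
#' top-signal / second-signal / both-signals layout.
#'
#' @param report A `variance_report` from [variance_partition()].
#' @return A data.frame with columns `gene_id`, `top_signal`,
#'   `second_signal`, `pct_top`, `pct_second`, `pct_both`, `significant`.
#' @export
variance_table <- function(report) {
  stopifnot(inherits(report, "variance_report"))
  data.frame(gene_id = report$gene_id,
             top_signal = report$top_variant,
             second_signal = report$second_variant,
             pct_top = 100 * report$top_adj_r2,
             pct_second = 100 * report$second_adj_r2,
             pct_both = 100 * report$combined_adj_r2,
             significant = report$significant,
             stringsAsFactors = FALSE)
}
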