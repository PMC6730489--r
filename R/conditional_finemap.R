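# Forward stepwise conditional regression: resolving a block of linked
# FDR-significant variants into statistically independent signals.

#' Forward stepwise conditional scan for one gene
#'
#' Starting from the candidate with the smallest marginal p-value (the top
#' variant), the procedure repeatedly refits every remaining candidate in a
#' model that contains all previously selected signals as covariates,
#' selects the candidate with the smallest conditional p-value, and admits
#' it as an independent signal if that p-value is below `alpha`; it stops
#' as soon as the best conditional p-value is not below `alpha` (equality
#' stops) or candidates run out. Candidates whose dosage lies within the
#' span of the selected signals (no residual variance, relative tolerance
#' 1e-7 on the residual norm) are excluded from consideration at that step,
#' so duplicated columns are selected at most once. Ties in p-value are
#' broken by byte-wise variant-id order, making the result deterministic.
#'
#' Candidates are intended to be the FDR-significant variants for this gene
#' from the marginal scan; the same contract applies unchanged at the
#' amino-acid and SNP levels.
#'
#' @param y Numeric phenotype vector (one value per individual).
#' @param candidates A [dosage_matrix] or numeric matrix (columns named by
#'   variant id), rows aligned with `y`.
#' @param alpha Conditional admission threshold (default 0.05).
#' @param gene_id Optional label copied into the output.
#' @return A data.frame of class `conditional_signals` with columns
#'   `gene_id`, `step`, `variant_id`, `marginal_p`, `conditional_p`
#'   (p-value at entry; equals `marginal_p` for the first signal) and
#'   `final_p` (p-value in the final joint model), plus an attribute
#'   `stopping_reason`.
#' @export
conditional_scan <- function(y, candidates, alpha = 0.05, gene_id = NA_character_) {
  C <- dosage_values(candidates)
  if (ncol(C) == 0) stop_user("no candidates supplied")
  if (is.null(colnames(C))) stop_user("candidate columns must be named")
  if (nrow(C) != length(y)) {
    stop_user("candidates have ", nrow(C), " rows but `y` has length ",
              length(y))
  }
  if (ncol(C) == 0) stop_user("no candidates supplied")
  if (!is_fraction(alpha, 0, 1)) stop_user("`alpha` must be in [0, 1]")
  # byte-wise column order so which.min tie-breaks lexicographically
  C <- C[, radix_order(colnames(C)), drop = FALSE]
  storage.mode(C) <- "double"
  n <- length(y)
  css <- colSums(scale(C, center = TRUE, scale = FALSE)^2)
  marg <- vapply(seq_len(ncol(C)), function(j) {
    if (css[j] == 0) NA_real_ else fit_pair(y, C[, j])$p_value
  }, numeric(1))
  selected <- integer(0)
  rows <- list()
  remaining <- which(!is.na(marg))
  reason <- "candidates_exhausted"
  repeat {
    if (length(remaining) == 0) break
    if (length(selected) == 0) {
      cond_p <- marg[remaining]
      usable <- rep(TRUE, length(remaining))
      df <- n - 2
    } else {
      X <- cbind(1, C[, selected, drop = FALSE])
      df <- n - length(selected) - 2
      if (df < 1) { reason <- "insufficient_df"; break }
      qrX <- qr(X)
      ry <- qr.resid(qrX, y)
      RC <- qr.resid(qrX, C[, remaining, drop = FALSE])
      sxx <- colSums(RC^2)
      usable <- sxx > (1e-7)^2 * css[remaining] & css[remaining] > 0
      sxy <- as.numeric(crossprod(RC, ry))
      beta <- sxy / sxx
      sse <- pmax(sum(ry^2) - beta * sxy, 0)
      t_stat <- beta / sqrt(sse / df / sxx)
      cond_p <- pmax(2 * pt(-abs(t_stat), df), .Machine$double.xmin)
      cond_p[!usable] <- NA_real_
    }
    if (!any(usable)) { reason <- "candidates_exhausted"; break }
    # ties (e.g. complementary codings of one site have identical p up to
    # rounding) break to the smallest variant id: columns are radix-ordered,
    # so the first candidate within relative tolerance of the minimum wins
    p_min <- min(cond_p, na.rm = TRUE)
    j_rel <- which(!is.na(cond_p) & cond_p <= p_min * (1 + 1e-9))[1]
    p_best <- cond_p[j_rel]
    if (length(selected) > 0 && !(p_best < alpha)) {
      reason <- "conditional_p_not_below_alpha"
      break
    }
    j <- remaining[j_rel]
    selected <- c(selected, j)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_id, step = length(selected),
      variant_id = colnames(C)[j], marginal_p = marg[j],
      conditional_p = p_best, stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, j)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), step = integer(),
               variant_id = character(), marginal_p = numeric(),
               conditional_p = numeric(), stringsAsFactors = FALSE)
  # p-values of each member in the final joint model
  out$final_p <- NA_real_
  if (length(selected) > 0) {
    X <- cbind(`(Intercept)` = 1, C[, selected, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    df <- n - ncol(X)
    if (df > 0) {
      XtX_inv <- chol2inv(chol(crossprod(X)))
      sigma2 <- sum(fit$residuals^2) / df
      se <- sqrt(diag(XtX_inv) * sigma2)
      tv <- fit$coefficients / se
      out$final_p <- pmax(2 * pt(-abs(tv[-1]), df), .Machine$double.xmin)
    }
  }
  attr(out, "stopping_reason") <- reason
  attr(out, "alpha") <- alpha
  class(out) <- c("conditional_signals", "data.frame")
  out
}

#' @export
print.conditional_signals <- function(x, ...) {
  cat("conditional_signals:", nrow(x), "independent signal(s); stopped:",
      attr(x, "stopping_reason"), "\n")
  if (nrow(x)) print.data.frame(as.data.frame(x), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Conditional fine-mapping across genes
#'
#' Applies [conditional_scan()] to every gene that has at least one
#' FDR-significant variant in the marginal scan, restricting candidates to
#' those variants (at one genetic level).
#'
#' @param usage A [usage_matrix].
#' @param dosages A [dosage_matrix].
#' @param assoc A `qtl_scan` table from [qtl_scan()].
#' @param level Genetic level to fine-map (default `"amino_acid"`).
#' @param alpha Conditional admission threshold.
#' @param phenotype_mode Must match the scan's phenotype mode.
#' @return A `conditional_signals` data.frame combining all genes, with a
#'   `stopping_reason` column.
#' @export
finemap_genes <- function(usage, dosages, assoc, level = "amino_acid",
                          alpha = 0.05,
                          phenotype_mode = attr(assoc, "phenotype_mode") %||% "raw") {
  U <- usage_values(usage)
  if (phenotype_mode == "log2") U <- log2_usage(usage)
  D <- dosage_values(dosages)
  ids <- intersect(rownames(U), rownames(D))
  if (length(ids) == 0) stop_user("no shared individuals")
  U <- U[ids, , drop = FALSE]; D <- D[ids, , drop = FALSE]
  sig <- assoc[assoc$level == level & assoc$significant, , drop = FALSE]
  out <- list()
  for (g in unique(sig$gene_id)) {
    cand_ids <- sig$variant_id[sig$gene_id == g]
    cs <- conditional_scan(U[, g], D[, cand_ids, drop = FALSE],
                           alpha = alpha, gene_id = g)
    if (nrow(cs)) {
      cs$stopping_reason <- attr(cs, "stopping_reason")
      out[[length(out) + 1L]] <- as.data.frame(cs)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), step = integer(),
               variant_id = character(), marginal_p = numeric(),
               conditional_p = numeric(), final_p = numeric(),
               stopping_reason = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "level") <- level
  attr(res, "alpha") <- alpha
  class(res) <- c("conditional_signals", "data.frame")
  res
}
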