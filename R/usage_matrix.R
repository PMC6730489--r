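# V-gene usage phenotypes: read proportions per individual, with the
# zero-fill convention for undetected genes and pseudo-usage log views.

#' Construct a usage matrix
#'
#' Holds per-individual V-gene usage: the proportion of uniquely mapped
#' reads assigned to each V gene. Undetected genes are stored as exactly 0
#' and each row sums to 1 over its detected genes. Genes carry a family tag
#' — `"target"` for the TRBV-like genes under study, `"control"` for the
#' IGHV-like negative-control family — and the family-specific pseudo-usage
#' constants used by the log view (0.01 for targets, 1e-5 for controls).
#'
#' @param usage Numeric matrix, individuals x genes, values in `[0, 1]`.
#' @param family Named character vector (`"target"`/`"control"`) per gene;
#'   defaults to all `"target"`.
#' @param pseudo Named numeric vector with elements `target` and `control`.
#' @return An object of class `usage_matrix`.
#' @export
usage_matrix <- function(usage, family = NULL,
                         pseudo = c(target = 0.01, control = 1e-5)) {
  usage <- as.matrix(usage)
  if (is.null(colnames(usage))) stop_user("`usage` needs gene column names")
  if (anyNA(usage) || any(usage < 0) || any(usage > 1)) {
    stop_user("usage values must lie in [0, 1]")
  }
  rs <- rowSums(usage)
  if (nrow(usage) && any(abs(rs - 1) > 1e-6)) {
    stop_user("usage rows must sum to 1 over detected genes (worst deviation ",
              format(max(abs(rs - 1))), ")")
  }
  if (is.null(family)) {
    family <- setNames(rep("target", ncol(usage)), colnames(usage))
  }
  if (!all(colnames(usage) %in% names(family)) ||
      !all(family %in% c("target", "control"))) {
    stop_user("`family` must tag every gene as \"target\" or \"control\"")
  }
  family <- family[colnames(usage)]
  if (!all(c("target", "control") %in% names(pseudo))) {
    stop_user("`pseudo` needs elements \"target\" and \"control\"")
  }
  structure(list(usage = usage, family = family, pseudo = pseudo),
            class = "usage_matrix")
}

#' @rdname usage_matrix
#' @param x A `usage_matrix`.
#' @export
usage_values <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(inherits(x, "usage_matrix"))
  x$usage
}

#' @rdname usage_matrix
#' @export
usage_family <- function(x) {
  stopifnot(inherits(x, "usage_matrix"))
  x$family
}

#' @export
print.usage_matrix <- function(x, ...) {
  cat("usage_matrix:", nrow(x$usage), "individuals x", ncol(x$usage),
      "genes (", sum(x$family == "target"), "target,",
      sum(x$family == "control"), "control )\n")
  cat("  zero (undetected) entries:", sum(x$usage == 0), "\n")
  invisible(x)
}

#' Compute usage proportions from read counts
#'
#' Row-normalises a matrix of per-gene mapped-read counts so each
#' individual's usages sum to 1; genes with zero reads stay exactly 0
#' (the undetected-gene convention). The result is invariant to scaling
#' all of an individual's counts by a positive constant.
#'
#' @param read_counts Non-negative integer matrix, individuals x genes; at
#'   least one nonzero count per individual.
#' @param family,pseudo Passed to [usage_matrix()].
#' @return A [usage_matrix].
#' @export
compute_usage <- function(read_counts, family = NULL,
                          pseudo = c(target = 0.01, control = 1e-5)) {
  counts <- as.matrix(read_counts)
  if (anyNA(counts) || any(counts < 0)) {
    stop_user("read counts must be non-negative")
  }
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop_user("individual(s) with all-zero counts: ",
              paste(rownames(counts)[rs == 0] %||% which(rs == 0),
                    collapse = ", "))
  }
  usage_matrix(counts / rs, family = family, pseudo = pseudo)
}

#' Log2 usage with pseudo-usage
#'
#' Elementwise `log2(usage + pseudo)`. With the default `pseudo = NULL` the
#' family-specific constants stored in the object are used (0.01 for the
#' target family, 1e-5 for controls), so zeroes from undetected genes map
#' to a finite floor. Strictly monotone in usage, so per-gene rank order is
#' preserved.
#'
#' @param usage A [usage_matrix] or plain matrix.
#' @param pseudo Single positive constant overriding the per-family values.
#' @return Numeric matrix of log2-transformed usage.
#' @export
log2_usage <- function(usage, pseudo = NULL) {
  if (is.null(pseudo)) {
    if (!inherits(usage, "usage_matrix")) {
      stop_user("`pseudo` is required for a plain matrix")
    }
    ps <- usage$pseudo[usage$family]
    return(log2(sweep(usage$usage, 2, ps, "+")))
  }
  if (!is.numeric(pseudo) || length(pseudo) != 1 || pseudo <= 0) {
    stop_user("`pseudo` must be a single positive number")
  }
  log2(usage_values(usage) + pseudo)
}
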