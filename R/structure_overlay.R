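# Structural overlay: per-position TCR-beta / peptide contact frequencies
# across solved TCR-pMHC complexes, joined with association strength.

CONTACT_PARTNERS <- c("tcr_beta_v", "peptide")

#' Per-position contact frequencies across TCR-pMHC complexes
#'
#' For every MHC locus position and partner chain (TCR beta V region or
#' presented peptide), counts in how many complexes of the locus roster the
#' position is annotated as contacting that partner at least once, and
#' reports the fraction. Repeated records for the same complex/position/
#' partner collapse to presence (the result is invariant to duplication and
#' record order); positions contacted by one partner but not the other get
#' an explicit frequency of 0 for the latter.
#'
#' @param records data.frame with columns `complex_id`, `locus`, `position`,
#'   `partner` (`"tcr_beta_v"` or `"peptide"`).
#' @param roster data.frame with columns `locus`, `complex_id` listing every
#'   analysed complex per locus; all record complexes must appear in it.
#' @return A data.frame of class `contact_profile` with columns `locus`,
#'   `position`, `partner`, `n_contact`, `n_total`, `frequency`.
#' @export
contact_frequency <- function(records, roster) {
  req_r <- c("complex_id", "locus", "position", "partner")
  if (!all(req_r %in% names(records))) {
    stop_user("records need columns ", paste(req_r, collapse = ", "))
  }
  if (!all(c("locus", "complex_id") %in% names(roster))) {
    stop_user("roster needs columns locus, complex_id")
  }
  if (!all(records$partner %in% CONTACT_PARTNERS)) {
    stop_user("partner must be one of ",
              paste(CONTACT_PARTNERS, collapse = ", "))
  }
  roster <- unique(roster[, c("locus", "complex_id")])
  records <- unique(records[, req_r])
  key_rec <- paste(records$locus, records$complex_id)
  key_ros <- paste(roster$locus, roster$complex_id)
  unknown <- !(key_rec %in% key_ros)
  if (any(unknown)) {
    stop_user("record complex(es) missing from roster: ",
              paste(unique(paste0(records$locus[unknown], "/",
                                  records$complex_id[unknown])),
                    collapse = ", "))
  }
  out <- list()
  for (locus in unique(roster$locus)) {
    n_total <- sum(roster$locus == locus)
    rec <- records[records$locus == locus, , drop = FALSE]
    positions <- sort(unique(rec$position))
    if (length(positions) == 0) next
    grid <- expand.grid(position = positions, partner = CONTACT_PARTNERS,
                        stringsAsFactors = FALSE)
    grid$n_contact <- vapply(seq_len(nrow(grid)), function(i) {
      sum(rec$position == grid$position[i] & rec$partner == grid$partner[i])
    }, numeric(1))
    grid <- cbind(locus = locus, grid)
    grid$n_total <- n_total
    grid$frequency <- grid$n_contact / n_total
    out[[locus]] <- grid
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus = character(), position = integer(),
               partner = character(), n_contact = numeric(),
               n_total = numeric(), frequency = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res <- res[order(res$locus, res$position, res$partner), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("contact_profile", "data.frame")
  res
}

#' Overlay association strength with contact frequencies
#'
#' Summarises amino-acid-level association results per MHC position as the
#' minimum p-value across genes, transforms it to -log10, and joins it with
#' the structural contact frequencies of the TCR beta V region and the
#' peptide. Positions present on only one side are retained with `NA` on
#' the other, so nothing is silently dropped. Set `per_gene = TRUE` to keep
#' one overlay row per gene instead of aggregating by minimum p.
#'
#' @param assoc A `qtl_scan` table; only its `amino_acid` rows are used.
#' @param profile A `contact_profile` from [contact_frequency()].
#' @param per_gene Keep per-gene rows instead of the min-p summary.
#' @return A data.frame with columns `locus`, `position` (plus `gene_id`
#'   when `per_gene`), `minus_log10_p`, `freq_tcr_beta_v`, `freq_peptide`.
#' @export
contact_overlay <- function(assoc, profile, per_gene = FALSE) {
  aa <- assoc[assoc$level == "amino_acid", , drop = FALSE]
  if (nrow(aa) > 0) {
    meta <- parse_variant_id(aa$variant_id)
    aa$locus <- meta$locus
    aa$position <- meta$position
    if (per_gene) {
      agg <- stats::aggregate(p_value ~ locus + position + gene_id, data = aa,
                              FUN = min)
    } else {
      agg <- stats::aggregate(p_value ~ locus + position, data = aa, FUN = min)
    }
    agg$minus_log10_p <- -log10(agg$p_value)
    agg$p_value <- NULL
  } else {
    agg <- data.frame(locus = character(), position = integer(),
                      minus_log10_p = numeric(), stringsAsFactors = FALSE)
  }
  wide <- data.frame(locus = character(), position = integer(),
                     freq_tcr_beta_v = numeric(), freq_peptide = numeric(),
                     stringsAsFactors = FALSE)
  if (nrow(profile) > 0) {
    tcr <- profile[profile$partner == "tcr_beta_v",
                   c("locus", "position", "frequency")]
    names(tcr)[3] <- "freq_tcr_beta_v"
    pep <- profile[profile$partner == "peptide",
                   c("locus", "position", "frequency")]
    names(pep)[3] <- "freq_peptide"
    wide <- merge(tcr, pep, by = c("locus", "position"), all = TRUE)
  }
  out <- merge(agg, wide, by = c("locus", "position"), all = TRUE)
  out <- out[order(out$locus, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
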