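# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_fraction <- function(x, lo = 0, hi = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lo && x <= hi
}

stop_user <- function(...) stop(..., call. = FALSE)

# Byte-wise (C locale) ordering, so tie-breaks do not depend on the session
# locale.
radix_order <- function(x) order(x, method = "radix")

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, ...)
}

#' Build a canonical variant identifier
#'
#' Identifiers have the form `<locus>.<level>.<position>.<symbol>` for
#' positional (SNP / amino-acid) variants and `<locus>.allele.<name>` for
#' four-digit classical alleles.
#'
#' @param locus Locus name, e.g. `"HLA-A"`.
#' @param level `"allele"`, `"snp"` or `"amino_acid"`.
#' @param position Integer coordinate (ignored for allele level).
#' @param symbol The counted reference symbol (allele name, base or residue).
#' @return Character vector of identifiers.
#' @export
make_variant_id <- function(locus, level, position, symbol) {
  ifelse(level == "allele",
         paste(locus, "allele", symbol, sep = "."),
         paste(locus, level, position, symbol, sep = "."))
}

#' Parse a variant identifier
#'
#' Accepts the canonical form produced by [make_variant_id()] as well as the
#' compact reporting shorthand `<locus>.<refAA><position><altAA>` used for
#' amino-acid signals (e.g. `"HLA-A.I97M"`, read as position 97 with counted
#' residue `M` and contextual residue `I`).
#'
#' @param id Character vector of identifiers.
#' @return A data.frame with columns `variant_id`, `locus`, `level`,
#'   `position`, `ref_symbol`.
#' @export
parse_variant_id <- function(id) {
  out <- lapply(id, function(v) {
    parts <- strsplit(v, ".", fixed = TRUE)[[1]]
    if (length(parts) >= 3 && parts[2] == "allele") {
      return(data.frame(variant_id = v, locus = parts[1], level = "allele",
                        position = NA_integer_,
                        ref_symbol = paste(parts[-(1:2)], collapse = "."),
                        stringsAsFactors = FALSE))
    }
    if (length(parts) == 4 && parts[2] %in% c("snp", "amino_acid")) {
      return(data.frame(variant_id = v, locus = parts[1], level = parts[2],
                        position = as.integer(parts[3]), ref_symbol = parts[4],
                        stringsAsFactors = FALSE))
    }
    if (length(parts) == 2 &&
        grepl("^[A-Z\\*][0-9]+[A-Z\\*]$", parts[2], perl = TRUE)) {
      pos <- as.integer(gsub("[^0-9]", "", parts[2]))
      alt <- substr(parts[2], nchar(parts[2]), nchar(parts[2]))
      return(data.frame(variant_id = v, locus = parts[1], level = "amino_acid",
                        position = pos, ref_symbol = alt,
                        stringsAsFactors = FALSE))
    }
    stop_user("cannot parse variant id: ", v)
  })
  do.call(rbind, out)
}
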