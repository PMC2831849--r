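# internal helpers shared across modules

#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Reference-consuming CIGAR length (ops M/D/N/=/X advance the reference).
# Rsamtools exposes no cigar arithmetic, so this stays local.
cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub(".$", "", ops))
    op <- substring(ops, nchar(ops))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Format a p-value from its log10 so that tails far below double underflow
# are still printed in scientific notation, never as 0.
format_pvalue <- function(log10p) {
  out <- character(length(log10p))
  ok <- is.finite(log10p)
  out[!ok] <- ifelse(is.na(log10p[!ok]), NA_character_, "0e+00")
  e <- floor(log10p[ok])
  m <- 10^(log10p[ok] - e)
  # guard mantissa rounding to 10
  bump <- round(m, 4) >= 10
  m[bump] <- m[bump] / 10
  e[bump] <- e[bump] + 1
  out[ok] <- sprintf("%.4ge%+03d", m, e)
  out
}

# chromosome sizes: accept a named vector or a two-column data frame
as_chrom_sizes <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    sz <- as.integer(x[[2L]])
    names(sz) <- as.character(x[[1L]])
    return(sz)
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    abort("chromosome sizes must be a named vector or two-column data frame")
  }
  stats::setNames(as.integer(x), names(x))
}

check_fragments <- function(frs) {
  need <- c("chrom", "start", "end", "token")
  if (!all(need %in% names(frs))) {
    abort(paste0("fragment table must have columns: ", paste(need, collapse = ", ")))
  }
  invisible(frs)
}
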