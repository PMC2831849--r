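#' Poisson enrichment p-value
#'
#' Probability of observing at least `c` fragments in a window of width
#' `w` by chance, under a Poisson background with rate
#' `lambda = w * tpn / gs` (expected fragment starts in `w` when `tpn`
#' uniquely mapped fragments fall on a mappable genome of `gs` bp):
#' `P(X >= c)` for `X ~ Poisson(lambda)`. Evaluated through the upper-tail
#' survival function, so tiny tails are computed without the catastrophic
#' cancellation of `1 - CDF`.
#'
#' @param c Observed fragment count(s); nonnegative integers.
#' @param w Window (signal) width in bp.
#' @param tpn Total number of paired-end fragments in the library.
#' @param gs Mappable genome size in bp.
#' @return Upper-tail probability, vectorized over the inputs.
#' @seealso [fold_enrichment()], [input_scaled_pvalue()]
#' @export
poisson_pvalue <- function(c, w, tpn, gs) {
  check_pois_args(c, w, tpn, gs)
  lambda <- w * (tpn / gs)
  stats::ppois(c - 1, lambda, lower.tail = FALSE)
}

# log10 of the same upper tail; survives underflow of the linear-scale value
poisson_log10_pvalue <- function(c, lambda) {
  stats::ppois(c - 1, lambda, lower.tail = FALSE, log.p = TRUE) / log(10)
}

check_pois_args <- function(c, w, tpn, gs) {
  if (any(c < 0) || any(c != floor(c))) abort("`c` must be nonnegative integer(s)")
  if (any(w <= 0) || any(tpn <= 0) || any(gs <= 0)) {
    abort("`w`, `tpn` and `gs` must be positive")
  }
  invisible(NULL)
}

#' Fold enrichment over the Poisson expectation
#'
#' The ratio between the observed fragment count `c` in a window of width
#' `w` and its expectation `w * (tpn / gs)` under the uniform background.
#'
#' @inheritParams poisson_pvalue
#' @return `c / (w * tpn / gs)`, vectorized.
#' @export
fold_enrichment <- function(c, w, tpn, gs) {
  check_pois_args(c, w, tpn, gs)
  if (any(c < 1)) abort("`c` must be >= 1 for fold enrichment")
  c / (w * (tpn / gs))
}

#' Input-scaled Poisson p-value
#'
#' When an input-DNA control library is available, the local background
#' rate in a window is estimated from the input fragment count `i` in that
#' window, scaled to IP sequencing depth by the normalization ratio
#' `r = tpn_IP / tpn_input` (ratio of total IP to total input fragment
#' counts). The local rate is floored at the global rate
#' `w * tpn / gs`, so sparse input coverage can only make a call harder,
#' never easier: `lambda_local = max(i * r, w * tpn / gs)`.
#'
#' @inheritParams poisson_pvalue
#' @param i Input-DNA fragment count in the window.
#' @param r Normalization ratio of total IP fragment count to total input
#'   fragment count.
#' @return `P(X >= c)` for `X ~ Poisson(lambda_local)`, vectorized.
#' @export
input_scaled_pvalue <- function(c, i, r, w, tpn, gs) {
  check_pois_args(c, w, tpn, gs)
  if (any(i < 0)) abort("`i` must be nonnegative")
  if (any(r <= 0)) abort("`r` must be positive")
  lambda <- pmax(i * r, w * (tpn / gs))
  stats::ppois(c - 1, lambda, lower.tail = FALSE)
}

#' Empirical false discovery rate by sample swapping
#'
#' `n1` is the number of peaks called with ChIP over input; `n2` the
#' number called with the libraries swapped (input over ChIP) at the same
#' cutoffs. Both directions of the ratio are reported: `fdr_n1_over_n2 = n1/n2`
#' (the ratio as historically defined for this method) and
#' `fdr_n2_over_n1 = n2/n1` (null calls over observed calls, the usual
#' empirical-FDR orientation).
#'
#' @param n1 Peak count, ChIP over input.
#' @param n2 Peak count, input over ChIP, same cutoffs.
#' @return One-row tibble: `n1`, `n2`, `fdr_n1_over_n2`, `fdr_n2_over_n1`,
#'   `flag` (`"no_null_peaks"` when `n2 = 0`, `"no_chip_peaks"` when
#'   `n1 = 0`, else `NA`).
#' @export
empirical_fdr <- function(n1, n2) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 0L || n2 < 0L) abort("peak counts must be nonnegative")
  flag <- NA_character_
  if (n2 == 0L) flag <- "no_null_peaks"
  if (n1 == 0L) flag <- "no_chip_peaks"
  tibble(
    n1 = n1, n2 = n2,
    fdr_n1_over_n2 = if (n2 == 0L) NA_real_ else n1 / n2,
    fdr_n2_over_n1 = if (n1 == 0L) NA_real_ else n2 / n1,
    flag = flag
  )
}

#' Null-calibration window p-values
#'
#' Tiles the genome with non-overlapping windows of width `w`, counts
#' fragment starts per window, and returns the Poisson upper-tail p-value
#' of each count under `lambda = w * tpn / gs`. Start counts are used
#' because the background rate models fragment starts per base; counts of
#' any-overlap fragments in a `w` window would have expectation
#' `~ (w + L - 1) * tpn / gs` and would not be calibrated against this
#' rate. Intended for type-I-error checks on simulated null libraries.
#'
#' @param frs Fragment tibble.
#' @param chrom_sizes Chromosome sizes.
#' @param w Window width in bp.
#' @param gm Optional precomputed [genome_metrics()] row.
#' @return Tibble with `chrom`, `window_start`, `count`, `p_value`.
#' @export
null_window_pvalues <- function(frs, chrom_sizes, w = 200L, gm = NULL) {
  check_fragments(frs)
  sizes <- as_chrom_sizes(chrom_sizes)
  if (is.null(gm)) gm <- genome_metrics(frs, chrom_sizes = sizes)
  res <- purrr::imap(as.list(sizes), function(len, chr) {
    n_win <- len %/% w
    if (n_win == 0L) return(NULL)
    starts <- frs$start[frs$chrom == chr]
    idx <- (starts - 1L) %/% w + 1L
    cnt <- tabulate(idx[idx <= n_win], nbins = n_win)
    tibble(chrom = chr, window_start = (seq_len(n_win) - 1L) * w + 1L,
           count = cnt)
  })
  out <- dplyr::bind_rows(res)
  out$p_value <- poisson_pvalue(out$count, w, gm$tpn, gm$gs)
  out
}
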