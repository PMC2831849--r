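#' Per-nucleotide fragment pileup for one chromosome
#'
#' `values[i]` is the number of reconstructed fragments overlapping
#' position `i` (1-based). Computed with a difference array: +1 at each
#' fragment start, -1 just past each end, then a prefix sum — O(N + L)
#' rather than O(N * L).
#'
#' @param frs Fragment tibble for a single chromosome (sorted by start).
#' @param chrom_len Chromosome length in bp.
#' @param chrom Chromosome name; inferred from `frs` when unambiguous.
#' @return A `pileup_track`: list with `chrom`, `chrom_len` and the dense
#'   integer vector `values`.
#' @export
compute_pileup <- function(frs, chrom_len, chrom = NULL) {
  check_fragments(frs)
  chrom_len <- as.integer(chrom_len)
  if (is.null(chrom)) {
    u <- unique(frs$chrom)
    if (length(u) > 1L) abort("fragments span several chromosomes; pass `chrom`")
    chrom <- if (length(u) == 1L) u else NA_character_
  } else {
    frs <- frs[frs$chrom == chrom, , drop = FALSE]
  }
  if (any(frs$end > chrom_len)) {
    bad <- frs$token[frs$end > chrom_len][1L]
    abort(paste0("fragment '", bad, "' extends past chromosome end (",
                 chrom_len, " bp)"))
  }
  if (any(frs$start < 1L)) abort("fragment start below position 1")
  inc <- tabulate(frs$start, nbins = chrom_len)
  dec <- tabulate(frs$end + 1L, nbins = chrom_len)
  new_pileup_track(chrom, cumsum(inc - dec))
}

new_pileup_track <- function(chrom, values) {
  structure(
    list(chrom = chrom, chrom_len = length(values),
         values = as.integer(values)),
    class = "pileup_track"
  )
}

#' @export
print.pileup_track <- function(x, ...) {
  cov <- sum(x$values > 0L)
  cat("<pileup_track> ", x$chrom, ": ", x$chrom_len, " bp, ",
      cov, " covered, max pileup ", max(x$values, 0L), "\n", sep = "")
  invisible(x)
}

#' Pileup tracks for a whole genome
#'
#' @param frs Fragment tibble (any number of chromosomes).
#' @param chrom_sizes Named vector or two-column data frame of chromosome
#'   lengths. Lengths come from the alignment header or a sizes file,
#'   never from the maximum fragment end.
#' @return Named list of `pileup_track`, one per chromosome in
#'   `chrom_sizes` (zero tracks for chromosomes without fragments).
#' @export
pileup_tracks <- function(frs, chrom_sizes) {
  check_fragments(frs)
  sizes <- as_chrom_sizes(chrom_sizes)
  missing <- setdiff(unique(frs$chrom), names(sizes))
  if (length(missing) > 0L) {
    abort(paste0("no chromosome length for: ", paste(missing, collapse = ", ")))
  }
  purrr::imap(as.list(sizes), function(len, chr) {
    compute_pileup(frs[frs$chrom == chr, , drop = FALSE], len, chrom = chr)
  })
}

#' Effective (mappable) genome size
#'
#' The number of genome positions covered by at least one uniquely mapped
#' fragment — the union coverage of the reconstructed fragment intervals,
#' summed over chromosomes. This is the denominator of the Poisson
#' background rate. It is measured from full fragment intervals, not read
#' footprints, because paired-end reconstruction gives exact fragment
#' lengths.
#'
#' @param tracks A `pileup_track` or a list of them.
#' @return Mappable genome size in bp (numeric scalar).
#' @export
effective_genome_size <- function(tracks) {
  if (inherits(tracks, "pileup_track")) tracks <- list(tracks)
  sum(vapply(tracks, function(t) sum(t$values > 0L), numeric(1)))
}

#' Total fragment (pair) count
#'
#' One count per retained mate pair, i.e. per reconstructed fragment. This
#' is the numerator of the Poisson background rate `tpn / gs` (expected
#' fragment starts per base).
#'
#' @param frs Fragment tibble.
#' @return Integer count.
#' @export
total_pairs <- function(frs) {
  check_fragments(frs)
  nrow(frs)
}

#' Genome-level background metrics
#'
#' @param frs Fragment tibble.
#' @param tracks Optional precomputed pileup tracks; required unless
#'   `chrom_sizes` is given.
#' @param chrom_sizes Chromosome sizes, used to build tracks when `tracks`
#'   is `NULL`.
#' @param tpn_mode `"pairs"` (default) counts one per fragment; `"reads"`
#'   doubles the count (both sequenced ends), for sensitivity analysis of
#'   the background rate.
#' @return One-row tibble with `tpn` and `gs`.
#' @export
genome_metrics <- function(frs, tracks = NULL, chrom_sizes = NULL,
                           tpn_mode = c("pairs", "reads")) {
  tpn_mode <- match.arg(tpn_mode)
  if (is.null(tracks)) {
    if (is.null(chrom_sizes)) {
      chrom_sizes <- attr(frs, "chrom_sizes")
      if (is.null(chrom_sizes)) abort("need `tracks` or `chrom_sizes`")
    }
    tracks <- pileup_tracks(frs, chrom_sizes)
  }
  tpn <- total_pairs(frs)
  if (tpn_mode == "reads") tpn <- 2L * tpn
  tibble(tpn = tpn, gs = effective_genome_size(tracks))
}

#' Write pileup tracks as bedGraph
#'
#' One line per constant-value run with nonzero pileup, 0-based half-open
#' coordinates. This is the signal-track output: signal coordinates plus
#' the fragment pileup value, per chromosome.
#'
#' @param tracks A `pileup_track` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  if (inherits(tracks, "pileup_track")) tracks <- list(tracks)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (t in tracks) {
    r <- rle(t$values)
    ends <- cumsum(r$lengths)
    starts0 <- ends - r$lengths  # already 0-based
    nz <- r$values != 0L
    if (!any(nz)) next
    writeLines(sprintf("%s\t%d\t%d\t%d", t$chrom, starts0[nz], ends[nz],
                       r$values[nz]), con)
  }
  invisible(path)
}
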