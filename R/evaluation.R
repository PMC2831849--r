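#' Motif query
#'
#' An IUPAC degenerate DNA pattern and the window used to associate motif
#' occurrences with peak centers. The default `CANNTG` is the E-box, the
#' bHLH transcription-factor consensus; it is its own reverse complement
#' as an IUPAC class, so forward-strand scanning suffices and
#' `both_strands` defaults to `FALSE` (turn it on for asymmetric
#' patterns).
#'
#' @param pattern IUPAC DNA string.
#' @param window_halfwidth Motif-to-center association window, bp (the
#'   default 100 means "within 200 bp of the peak center").
#' @param both_strands Also scan the reverse complement.
#' @return List of class `motif_query`.
#' @export
motif_query <- function(pattern = "CANNTG", window_halfwidth = 100L,
                        both_strands = FALSE) {
  pattern <- toupper(pattern)
  ok <- strsplit(pattern, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (nchar(pattern) < 1L || !all(ok)) {
    abort("pattern must be a nonempty IUPAC DNA string")
  }
  structure(list(pattern = pattern,
                 window_halfwidth = as.integer(window_halfwidth),
                 both_strands = isTRUE(both_strands)),
            class = "motif_query")
}

#' Scan a sequence for a degenerate motif
#'
#' Matches the IUPAC pattern against a literal subject: ambiguity codes
#' are expanded in the pattern only, so an `N` in the sequence matches
#' nothing but an `N` in the pattern.
#'
#' @param seq DNA sequence (character or `DNAString`) over A/C/G/T/N.
#' @param query A [motif_query()].
#' @return Sorted integer vector of 1-based match start positions.
#' @export
scan_motif <- function(seq, query = motif_query()) {
  stopifnot(inherits(query, "motif_query"))
  subject <- if (inherits(seq, "DNAString")) seq else
    Biostrings::DNAString(toupper(as.character(seq)))
  pat <- Biostrings::DNAString(query$pattern)
  hits <- Biostrings::start(
    Biostrings::matchPattern(pat, subject, fixed = "subject"))
  if (query$both_strands) {
    rc <- Biostrings::reverseComplement(pat)
    hits <- c(hits, Biostrings::start(
      Biostrings::matchPattern(rc, subject, fixed = "subject")))
  }
  sort(unique(hits))
}

#' Motif-resolution metrics for called peaks
#'
#' For each peak the center is its `summit_middle`. A peak "has the
#' motif" when at least one motif occurrence has its midpoint within
#' `window_halfwidth` bp of the center; the spatial-resolution score is
#' the mean distance from center to the nearest motif midpoint, over
#' peaks that have one (peaks with no motif in the window are excluded
#' from the mean but counted against the percentage).
#'
#' @param peaks A `peak_calls` object or peaks tibble (needs `chrom` and
#'   `summit_middle`).
#' @param genome Genome sequence: named character vector, `DNAStringSet`,
#'   or path to a FASTA file.
#' @param query A [motif_query()].
#' @return One-row tibble: `n_peaks`, `n_with_motif`, `pct_with_motif`,
#'   `mean_center_to_nearest_motif` (bp; `NA` when no peak has the
#'   motif).
#' @export
peak_motif_metrics <- function(peaks, genome, query = motif_query()) {
  if (inherits(peaks, "peak_calls")) peaks <- peaks$peaks
  stopifnot(all(c("chrom", "summit_middle") %in% names(peaks)))
  seqs <- load_genome_seqs(genome)
  if (nrow(peaks) == 0L) {
    return(tibble(n_peaks = 0L, n_with_motif = 0L,
                  pct_with_motif = NA_real_,
                  mean_center_to_nearest_motif = NA_real_))
  }
  missing <- setdiff(unique(peaks$chrom), names(seqs))
  if (length(missing) > 0L) {
    abort(paste0("no sequence for chromosome(s): ",
                 paste(missing, collapse = ", ")))
  }
  patlen <- nchar(query$pattern)
  mids <- purrr::map(as.list(seqs)[unique(peaks$chrom)], function(s) {
    scan_motif(s, query) + (patlen - 1) / 2
  })
  seq_lens <- vapply(as.list(seqs), length, integer(1))
  dist <- purrr::map_dbl(seq_len(nrow(peaks)), function(k) {
    chr <- peaks$chrom[k]
    ctr <- peaks$summit_middle[k]
    if (ctr < 1 || ctr > seq_lens[[chr]]) {
      abort(paste0("peak center ", ctr, " outside sequence of ", chr))
    }
    m <- mids[[chr]]
    if (length(m) == 0L) return(Inf)
    min(abs(ctr - m))
  })
  has <- dist <= query$window_halfwidth
  tibble(
    n_peaks = nrow(peaks),
    n_with_motif = sum(has),
    pct_with_motif = 100 * mean(has),
    mean_center_to_nearest_motif = if (any(has)) mean(dist[has]) else NA_real_
  )
}

load_genome_seqs <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)) &&
      file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  abort("genome must be a FASTA path, DNAStringSet, or named character vector")
}
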