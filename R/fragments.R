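#' Fragment filter settings
#'
#' Controls which reconstructed fragments are retained. Paired-end mates are
#' accepted when both map to the same chromosome and the reconstructed
#' fragment length (outer mate span) falls inside `[min_len, max_len]`,
#' inclusive at both bounds. The default 80-500 bp window corresponds to the
#' mate-distance range a typical size-selected ChIP library is mapped under;
#' libraries gel-selected to 80-300 bp can tighten `max_len` accordingly.
#'
#' @param min_len Minimum fragment length in bp (inclusive).
#' @param max_len Maximum fragment length in bp (inclusive).
#' @param require_same_chrom Drop pairs whose mates map to different
#'   chromosomes.
#' @param require_unique Keep only pairs where both mates are uniquely
#'   mapped. Uniqueness is trusted from upstream mapping quality
#'   (`MAPQ >= 1`; `MAPQ = 255`, "unavailable", is treated as unique);
#'   mismatch counts are not re-verified.
#' @param dedup Remove fragments with identical coordinates coming from
#'   different read pairs (PCR-duplicate control). Off by default:
#'   coordinate duplicates are legitimate signal in deeply sequenced
#'   libraries.
#' @return A list of class `fragment_filter`.
#' @export
fragment_filter <- function(min_len = 80L, max_len = 500L,
                            require_same_chrom = TRUE,
                            require_unique = TRUE,
                            dedup = FALSE) {
  min_len <- as.integer(min_len)
  max_len <- as.integer(max_len)
  if (!(min_len > 0L && min_len <= max_len)) {
    abort("need 0 < min_len <= max_len")
  }
  structure(
    list(min_len = min_len, max_len = max_len,
         require_same_chrom = isTRUE(require_same_chrom),
         require_unique = isTRUE(require_unique),
         dedup = isTRUE(dedup)),
    class = "fragment_filter"
  )
}

# SAM is read through Rsamtools (conversion to a temporary BAM, then
# scanBam); htslib surfaces its own diagnostics for malformed records.
read_sam_records <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar")
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  list(records = tibble(
    token = x$qname, flag = x$flag, chrom = as.character(x$rname),
    pos = x$pos, mapq = x$mapq, cigar = x$cigar
  ), chrom_sizes = hdr)
}

#' Read chromosome sizes
#'
#' From a SAM/BAM header (`@SQ` lines) or a two-column `chrom<TAB>length`
#' text file.
#'
#' @param path SAM/BAM file, or a tab-separated sizes file.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "@") || grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(read_sam_records(path)$chrom_sizes)
  }
  tab <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         col_types = "ci", progress = FALSE)
  as_chrom_sizes(tab)
}

#' Read mate alignments from a paired-end SAM/BAM file
#'
#' Returns one row per mapped, primary alignment record. Mates of a pair
#' share the same `token` (read name); `end_tag` distinguishes the two
#' sequencing ends. Unmapped, secondary and supplementary records are
#' dropped and counted in the `skip_counts` attribute.
#'
#' @param path SAM or BAM file with paired-end alignments.
#' @return Tibble with columns `token`, `chrom`, `pos` (1-based leftmost),
#'   `aln_len` (reference bp consumed), `strand`, `end_tag`, `mapq`,
#'   `unique`. Attributes: `chrom_sizes` (from the header), `skip_counts`.
#' @export
read_mate_alignments <- function(path) {
  sam <- read_sam_records(path)
  rec <- sam$records
  flag <- rec$flag
  unmapped  <- bitwAnd(flag, 0x4L) != 0L
  secondary <- bitwAnd(flag, 0x100L) != 0L | bitwAnd(flag, 0x800L) != 0L
  unpaired  <- bitwAnd(flag, 0x1L) == 0L
  keep <- !unmapped & !secondary & !unpaired
  skip <- c(unmapped = sum(unmapped), secondary = sum(secondary & !unmapped),
            unpaired = sum(unpaired & !unmapped & !secondary))
  rec <- rec[keep, , drop = FALSE]
  out <- tibble(
    token = rec$token,
    chrom = rec$chrom,
    pos = rec$pos,
    aln_len = cigar_ref_len(rec$cigar),
    strand = ifelse(bitwAnd(rec$flag, 0x10L) != 0L, "-", "+"),
    end_tag = ifelse(bitwAnd(rec$flag, 0x40L) != 0L, "end1", "end2"),
    mapq = rec$mapq,
    unique = is.na(rec$mapq) | rec$mapq >= 1L
  )
  attr(out, "chrom_sizes") <- sam$chrom_sizes
  attr(out, "skip_counts") <- skip
  out
}

#' Pair mate alignments by read name
#'
#' Joins end-1 and end-2 records sharing a token into one row per pair.
#' Tokens without exactly one record per end are dropped as orphans (with a
#' warning). Pairs failing the filter's chromosome/uniqueness requirements
#' are dropped and counted. Mates on the same strand are accepted (only the
#' coordinate constraints matter for fragment reconstruction) but counted
#' under `same_strand` in `pair_stats`.
#'
#' @param mates Tibble from [read_mate_alignments()].
#' @param filter A [fragment_filter()].
#' @return Tibble with one row per pair: `token`, `chrom1`, `pos1`,
#'   `aln_len1`, `strand1`, `chrom2`, `pos2`, `aln_len2`, `strand2`.
#'   Attribute `pair_stats` counts dropped orphans/cross-chromosome/
#'   non-unique pairs.
#' @export
pair_mates <- function(mates, filter = fragment_filter()) {
  wide <- mates |>
    mutate(.ord = dplyr::row_number()) |>
    group_by(.data$token, .data$end_tag) |>
    slice_head(n = 1L) |>
    ungroup()
  dup_records <- nrow(mates) - nrow(wide)

  e1 <- wide |> filter(.data$end_tag == "end1")
  e2 <- wide |> filter(.data$end_tag == "end2")
  pairs <- inner_join(
    e1 |> select("token", chrom1 = "chrom", pos1 = "pos",
                 aln_len1 = "aln_len", strand1 = "strand",
                 unique1 = "unique", ".ord"),
    e2 |> select("token", chrom2 = "chrom", pos2 = "pos",
                 aln_len2 = "aln_len", strand2 = "strand",
                 unique2 = "unique"),
    by = "token"
  ) |> arrange(.data$.ord)
  orphans <- nrow(e1) + nrow(e2) - 2L * nrow(pairs)
  if (orphans > 0L) {
    warn(paste0(orphans, " alignment record(s) had no mapped mate; dropped"))
  }

  cross <- pairs$chrom1 != pairs$chrom2
  nonuniq <- !(pairs$unique1 & pairs$unique2)
  same_strand <- !cross & pairs$strand1 == pairs$strand2
  keep <- rep(TRUE, nrow(pairs))
  if (filter$require_same_chrom) keep <- keep & !cross
  if (filter$require_unique) keep <- keep & !nonuniq
  out <- pairs[keep, , drop = FALSE] |>
    select(-"unique1", -"unique2", -".ord")
  attr(out, "pair_stats") <- c(
    orphans = orphans, duplicate_records = dup_records,
    cross_chromosome = sum(cross), non_unique = sum(nonuniq & !cross),
    same_strand = sum(same_strand)
  )
  out
}

#' Reconstruct DNA fragments from mate pairs
#'
#' The sequenced fragment is bounded exactly by its outer mate coordinates:
#' `start` is the minimum leftmost position over both mates and `end` the
#' maximum rightmost position (`pos + aln_len - 1`). Coordinates are
#' 1-based and fully inclusive. The operation is symmetric in the two
#' mates.
#'
#' @param pairs Tibble from [pair_mates()].
#' @return Tibble of fragments: `chrom`, `start`, `end`, `token`.
#' @export
reconstruct_fragments <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), token = character()))
  }
  if (any(pairs$chrom1 != pairs$chrom2)) {
    bad <- pairs$token[pairs$chrom1 != pairs$chrom2][1L]
    abort(paste0("mates of pair '", bad, "' map to different chromosomes"))
  }
  tibble(
    chrom = pairs$chrom1,
    start = pmin(pairs$pos1, pairs$pos2),
    end = pmax(pairs$pos1 + pairs$aln_len1 - 1L,
               pairs$pos2 + pairs$aln_len2 - 1L),
    token = pairs$token
  )
}

#' Filter fragments by length
#'
#' Retains fragments whose length (`end - start + 1`) lies in the filter's
#' inclusive `[min_len, max_len]` window; optionally removes coordinate
#' duplicates when `filter$dedup` is set.
#'
#' @param frs Fragment tibble.
#' @param filter A [fragment_filter()].
#' @return Filtered fragment tibble; attribute `filter_counts` reports
#'   kept/dropped numbers.
#' @export
filter_fragments <- function(frs, filter = fragment_filter()) {
  check_fragments(frs)
  len <- frs$end - frs$start + 1L
  keep <- len >= filter$min_len & len <= filter$max_len
  out <- frs[keep, , drop = FALSE]
  n_dedup <- 0L
  if (filter$dedup) {
    before <- nrow(out)
    out <- out |> distinct(.data$chrom, .data$start, .data$end,
                           .keep_all = TRUE)
    n_dedup <- before - nrow(out)
  }
  attr(out, "filter_counts") <- c(kept = nrow(out),
                                  dropped_length = sum(!keep),
                                  dropped_duplicate = n_dedup)
  out
}

#' Sort fragments
#'
#' Groups by chromosome and orders by start, with deterministic tie-breaks
#' on end then token.
#'
#' @param frs Fragment tibble.
#' @return Sorted fragment tibble.
#' @export
sort_fragments <- function(frs) {
  check_fragments(frs)
  arrange(frs, .data$chrom, .data$start, .data$end, .data$token)
}

#' Read, reconstruct, filter and sort fragments from a paired-end SAM/BAM
#'
#' Convenience chain of [read_mate_alignments()], [pair_mates()],
#' [reconstruct_fragments()], [filter_fragments()] and [sort_fragments()].
#'
#' @param path Paired-end SAM or BAM file.
#' @param filter A [fragment_filter()].
#' @return Sorted fragment tibble with attributes `chrom_sizes`,
#'   `skip_counts`, `pair_stats` and `filter_counts`.
#' @export
read_fragments <- function(path, filter = fragment_filter()) {
  mates <- read_mate_alignments(path)
  pairs <- pair_mates(mates, filter)
  frs <- reconstruct_fragments(pairs) |>
    filter_fragments(filter) |>
    sort_fragments()
  attr(frs, "chrom_sizes") <- attr(mates, "chrom_sizes")
  attr(frs, "skip_counts") <- attr(mates, "skip_counts")
  attr(frs, "pair_stats") <- attr(pairs, "pair_stats")
  frs
}

#' Export fragments as BED
#'
#' Writes 6-column BED (0-based half-open, name = token, score = 0,
#' strand = "."). The core keeps 1-based inclusive coordinates; conversion
#' happens only here.
#'
#' @param frs Fragment tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
fragments_to_bed <- function(frs, path) {
  check_fragments(frs)
  bed <- tibble(chrom = frs$chrom, start = frs$start - 1L, end = frs$end,
                name = frs$token, score = 0L, strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
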