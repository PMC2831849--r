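#' Peak-caller configuration
#'
#' The dynamic baseline sweeps cut levels `bs..be` through the pileup
#' track; higher baselines split broad maps at shallow valleys and so
#' discriminate closely adjacent binding sites. `be` (the maximum
#' baseline, often written t) is the main resolution knob: peak results
#' improve as it grows, and peak counts stabilise once it exceeds the
#' valley depths between neighbouring sites, so high values are
#' recommended when runtime allows.
#'
#' @param bs Starting baseline (pileup cut level, >= 1).
#' @param be Maximum baseline (>= `bs`).
#' @param p_cutoff Candidates require `p < p_cutoff` (strict).
#' @param fold_cutoff Candidates require `fold > fold_cutoff` (strict).
#' @return List of class `caller_config`.
#' @export
caller_config <- function(bs = 1L, be = 25L, p_cutoff = 1e-5,
                          fold_cutoff = 2) {
  bs <- as.integer(bs); be <- as.integer(be)
  if (!(bs >= 1L && be >= bs)) abort("need 1 <= bs <= be")
  if (!(p_cutoff > 0 && p_cutoff <= 1)) abort("need 0 < p_cutoff <= 1")
  if (fold_cutoff < 0) abort("fold_cutoff must be >= 0")
  structure(list(bs = bs, be = be, p_cutoff = p_cutoff,
                 fold_cutoff = fold_cutoff),
            class = "caller_config")
}

#' Summit of a pileup slice
#'
#' The summit is the plateau of positions attaining the slice maximum.
#' `single_global_max` is `TRUE` iff those positions form one contiguous
#' run; when they form several runs, the reported summit bounds describe
#' the leftmost run.
#'
#' @param values Integer pileup values of the region.
#' @param offset Genomic position of `values[1]` (default 1).
#' @return One-row tibble: `summit_start`, `summit_end`, `summit_middle`
#'   (`floor((start+end)/2)`), `summit_width`, `single_global_max`.
#' @export
find_summit <- function(values, offset = 1L) {
  if (length(values) == 0L) abort("empty region")
  m <- max(values)
  r <- rle(values == m)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  hits <- which(r$values)
  s <- run_start[hits[1L]] + offset - 1L
  e <- run_end[hits[1L]] + offset - 1L
  tibble(
    summit_start = s, summit_end = e,
    summit_middle = (s + e) %/% 2L,
    summit_width = e - s + 1L,
    single_global_max = length(hits) == 1L
  )
}

#' Signal maps at one baseline
#'
#' A signal map is a maximal contiguous run of positions whose pileup is
#' at or above the baseline `b` (membership is `pileup >= b`, so a
#' baseline of 2 splits a valley of height 1). One row per map, with
#' geometry and summit fields filled in.
#'
#' @param track A `pileup_track`.
#' @param b Baseline (cut level), >= 1.
#' @return Tibble of signal maps: `chrom`, `start`, `end`, `width`,
#'   `max_pileup`, `baseline`, summit fields as in [find_summit()].
#' @export
signal_maps_at_baseline <- function(track, b) {
  stopifnot(inherits(track, "pileup_track"))
  b <- as.integer(b)
  if (b < 1L) abort("baseline must be >= 1")
  v <- track$values
  r <- rle(v >= b)
  if (!any(r$values)) {
    return(empty_signal_maps())
  }
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  maps <- purrr::map(keep, function(k) {
    s <- run_start[k]; e <- run_end[k]
    sm <- find_summit(v[s:e], offset = s)
    dplyr::bind_cols(
      tibble(chrom = track$chrom, start = s, end = e,
             width = e - s + 1L, max_pileup = max(v[s:e]),
             baseline = b),
      sm
    )
  })
  dplyr::bind_rows(maps)
}

empty_signal_maps <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         width = integer(), max_pileup = integer(), baseline = integer(),
         summit_start = integer(), summit_end = integer(),
         summit_middle = integer(), summit_width = integer(),
         single_global_max = logical())
}

#' Count fragments overlapping each signal map
#'
#' `reads_in_signal` is the number of fragments whose interval overlaps
#' the map interval by at least 1 bp (any overlap, not full containment).
#'
#' @param maps Signal-map tibble (one chromosome set or mixed; matched by
#'   `chrom`).
#' @param frs Fragment tibble.
#' @return `maps` with a `reads_in_signal` column added.
#' @export
reads_in_signal <- function(maps, frs) {
  check_fragments(frs)
  if (nrow(maps) == 0L) {
    maps$reads_in_signal <- integer()
    return(maps)
  }
  cnt <- integer(nrow(maps))
  for (chr in unique(maps$chrom)) {
    mi <- which(maps$chrom == chr)
    fi <- frs$chrom == chr
    cnt[mi] <- IRanges::countOverlaps(
      IRanges::IRanges(maps$start[mi], maps$end[mi]),
      IRanges::IRanges(frs$start[fi], frs$end[fi])
    )
  }
  maps$reads_in_signal <- cnt
  maps
}

# score maps: p (via log10 for deep tails) and fold against the global or
# input-scaled background
score_maps <- function(maps, gm, input_frs = NULL, r_norm = NULL) {
  if (nrow(maps) == 0L) {
    maps$reads_in_signal <- maps$reads_in_signal %||% integer()
    maps$p_value <- numeric(); maps$log10_p <- numeric()
    maps$fold <- numeric()
    return(maps)
  }
  lambda_g <- maps$width * (gm$tpn / gm$gs)
  lambda <- lambda_g
  if (!is.null(input_frs)) {
    im <- reads_in_signal(maps[c("chrom", "start", "end")], input_frs)
    lambda <- pmax(im$reads_in_signal * r_norm, lambda_g)
  }
  maps$log10_p <- poisson_log10_pvalue(maps$reads_in_signal, lambda)
  maps$p_value <- 10^maps$log10_p
  maps$fold <- maps$reads_in_signal / lambda_g
  maps
}

#' Call peaks with a dynamic baseline sweep
#'
#' For each baseline `b` in `bs..be`, signal maps are cut from the pileup
#' track and scored. A map is a candidate when it passes both thresholds
#' (`p < p_cutoff`, `fold > fold_cutoff`) and either sits at the top
#' baseline (`b = be`) or has a single global maximum. Because nested maps
#' from successive baselines describe the same apex, candidates are then
#' grouped by global-maximum position — candidates whose summit plateaus
#' overlap are one site — and the candidate with the highest fold in each
#' group is recorded as the peak. Peaks are ranked by fold, descending.
#'
#' @param frs Fragment tibble (whole genome), as from [read_fragments()].
#' @param chrom_sizes Chromosome sizes (named vector or data frame); taken
#'   from `attr(frs, "chrom_sizes")` when `NULL`.
#' @param config A [caller_config()].
#' @param gm Optional precomputed [genome_metrics()] row.
#' @param tracks Optional precomputed [pileup_tracks()].
#' @param input_frs Optional input-DNA control fragments; switches the
#'   p-value to the input-scaled background of [input_scaled_pvalue()].
#' @return A `peak_calls` object; see [tidy.peak_calls()] /
#'   [glance.peak_calls()]. Its `$peaks` tibble carries the signal-map
#'   geometry plus `p_value`, `fold` and `rank`.
#' @export
call_peaks <- function(frs, chrom_sizes = NULL, config = caller_config(),
                       gm = NULL, tracks = NULL, input_frs = NULL) {
  check_fragments(frs)
  stopifnot(inherits(config, "caller_config"))
  chrom_sizes <- chrom_sizes %||% attr(frs, "chrom_sizes")
  if (is.null(tracks)) {
    if (is.null(chrom_sizes)) abort("need `chrom_sizes` or `tracks`")
    tracks <- pileup_tracks(frs, chrom_sizes)
  }
  if (is.null(gm)) gm <- genome_metrics(frs, tracks = tracks)
  if (gm$tpn <= 0 || gm$gs <= 0) abort("genome metrics must be positive")
  r_norm <- NULL
  if (!is.null(input_frs)) {
    check_fragments(input_frs)
    if (nrow(input_frs) == 0L) abort("input control has no fragments")
    r_norm <- gm$tpn / nrow(input_frs)
  }

  cands <- purrr::map(tracks, function(tr) {
    purrr::map(seq.int(config$bs, config$be), function(b) {
      maps <- signal_maps_at_baseline(tr, b)
      if (nrow(maps) == 0L) return(NULL)
      maps <- reads_in_signal(maps, frs)
      maps <- score_maps(maps, gm, input_frs, r_norm)
      ok <- maps$log10_p < log10(config$p_cutoff) &
        maps$fold > config$fold_cutoff &
        (b == config$be | maps$single_global_max)
      maps[ok, , drop = FALSE]
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  if (nrow(cands) == 0L) {
    peaks <- empty_signal_maps() |>
      mutate(reads_in_signal = integer(), p_value = numeric(),
             log10_p = numeric(), fold = numeric(), rank = integer())
  } else {
    peaks <- cands |>
      group_by(.data$chrom) |>
      group_modify(~ dedup_by_summit(.x)) |>
      ungroup() |>
      arrange(desc(.data$fold), .data$log10_p, .data$chrom, .data$start) |>
      mutate(rank = dplyr::row_number())
  }

  structure(
    list(peaks = peaks, config = config, genome_metrics = gm,
         n_candidates = if (is.null(cands)) 0L else nrow(cands),
         single_max_pct = single_max_fraction(peaks),
         tracks = tracks),
    class = "peak_calls"
  )
}

# group candidates whose summit plateaus overlap (transitively) and keep
# the highest-fold candidate of each group
dedup_by_summit <- function(cands) {
  ir <- IRanges::IRanges(cands$summit_start, cands$summit_end)
  red <- IRanges::reduce(ir, min.gapwidth = 0L)
  grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
  cands$.grp <- grp
  cands |>
    group_by(.data$.grp) |>
    arrange(desc(.data$fold), .data$log10_p, .data$baseline,
            .by_group = TRUE) |>
    slice_head(n = 1L) |>
    ungroup() |>
    select(-".grp")
}

#' Percentage of peaks with a single global maximum
#'
#' A diagnostic for whether the maximum baseline is set high enough: the
#' percentage grows towards 100 as `be` increases and multi-summit maps
#' get split into their component sites.
#'
#' @param peaks A `peak_calls` object or its peaks tibble.
#' @return Percentage in `[0, 100]`; `NA` when there are no peaks.
#' @export
single_max_fraction <- function(peaks) {
  if (inherits(peaks, "peak_calls")) peaks <- peaks$peaks
  if (nrow(peaks) == 0L) return(NA_real_)
  100 * mean(peaks$single_global_max)
}

#' Write the peak table
#'
#' Tab-separated, one header line. Column order: a leading `chrom`, then
#' signal start, signal end, signal width, reads in signal, max fragment
#' pileup value, summit start, summit end, summit middle, summit width,
#' p-value and fold-enrichment, then a trailing `rank`. Coordinates are
#' 1-based inclusive. P-values are printed in scientific notation from
#' their log10, so deep tails are never truncated to 0.
#'
#' @param x A `peak_calls` object or peaks tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(x, path) {
  if (inherits(x, "peak_calls")) x <- x$peaks
  out <- tibble(
    chrom = x$chrom,
    signal_start = x$start, signal_end = x$end, signal_width = x$width,
    reads_in_signal = x$reads_in_signal, max_pileup = x$max_pileup,
    summit_start = x$summit_start, summit_end = x$summit_end,
    summit_middle = x$summit_middle, summit_width = x$summit_width,
    p_value = format_pvalue(x$log10_p), fold = x$fold, rank = x$rank
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Export peaks as BED
#'
#' 0-based half-open; the summit plateau goes into thickStart/thickEnd,
#' score is the fold capped at 1000.
#'
#' @inheritParams write_peak_table
#' @return `path`, invisibly.
#' @export
peaks_to_bed <- function(x, path) {
  if (inherits(x, "peak_calls")) x <- x$peaks
  bed <- tibble(
    chrom = x$chrom, start = x$start - 1L, end = x$end,
    name = paste0("peak_", x$rank),
    score = pmin(1000L, as.integer(round(x$fold))), strand = ".",
    thickStart = x$summit_start - 1L, thickEnd = x$summit_end
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
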