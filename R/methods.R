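#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the peaks of a `peak_calls` object
#'
#' @param x A `peak_calls` object.
#' @param ... Unused.
#' @return The peaks tibble (one row per called binding site, ranked by
#'   fold, descending).
#' @export
tidy.peak_calls <- function(x, ...) {
  x$peaks
}

#' One-row summary of a peak-calling run
#'
#' @param x A `peak_calls` object.
#' @param ... Unused.
#' @return Tibble with `n_peaks`, `n_candidates`, `tpn`, `gs`,
#'   `single_max_pct`, and the configuration (`bs`, `be`, `p_cutoff`,
#'   `fold_cutoff`).
#' @export
glance.peak_calls <- function(x, ...) {
  tibble(
    n_peaks = nrow(x$peaks),
    n_candidates = x$n_candidates,
    tpn = x$genome_metrics$tpn,
    gs = x$genome_metrics$gs,
    single_max_pct = x$single_max_pct,
    bs = x$config$bs, be = x$config$be,
    p_cutoff = x$config$p_cutoff, fold_cutoff = x$config$fold_cutoff
  )
}

#' @export
print.peak_calls <- function(x, ...) {
  g <- glance(x)
  cat("<peak_calls> ", g$n_peaks, " peak(s) from ", g$n_candidates,
      " candidate signal maps\n", sep = "")
  cat("  baselines ", g$bs, "..", g$be, ", p < ",
      format(g$p_cutoff), ", fold > ", g$fold_cutoff, "\n", sep = "")
  cat("  tpn = ", g$tpn, ", gs = ", format(g$gs, big.mark = ","),
      " bp, single-summit ", round(g$single_max_pct, 1), "%\n", sep = "")
  if (nrow(x$peaks) > 0L) print(utils::head(x$peaks, 5L))
  invisible(x)
}

#' Plot a pileup track
#'
#' Step plot of per-nucleotide fragment pileup, optionally restricted to
#' a region and annotated with called peaks (span segments plus summit
#' marks).
#'
#' @param object A `pileup_track`.
#' @param start,end Region to draw (defaults: whole chromosome).
#' @param peaks Optional `peak_calls` or peaks tibble to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pileup_track <- function(object, start = 1L,
                                  end = object$chrom_len, peaks = NULL,
                                  ...) {
  pos <- seq.int(start, end)
  df <- tibble(pos = pos, pileup = object$values[pos])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$pileup)) +
    ggplot2::geom_step(colour = "grey25") +
    ggplot2::labs(x = paste0(object$chrom, " position (bp)"),
                  y = "fragment pileup") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    if (inherits(peaks, "peak_calls")) peaks <- peaks$peaks
    pk <- peaks[peaks$chrom == object$chrom &
                  peaks$end >= start & peaks$start <= end, , drop = FALSE]
    if (nrow(pk) > 0L) {
      p <- p +
        ggplot2::geom_segment(
          data = pk,
          ggplot2::aes(x = .data$start, xend = .data$end, y = 0, yend = 0),
          colour = "firebrick", linewidth = 2, inherit.aes = FALSE) +
        ggplot2::geom_point(
          data = pk,
          ggplot2::aes(x = .data$summit_middle, y = .data$max_pileup),
          colour = "firebrick", shape = 17, inherit.aes = FALSE)
    }
  }
  p
}

#' Plot called peaks by rank
#'
#' Fold enrichment against rank, colored by whether the summit is a
#' single global maximum.
#'
#' @param object A `peak_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peak_calls <- function(object, ...) {
  pk <- object$peaks
  ggplot2::ggplot(pk, ggplot2::aes(x = .data$rank, y = .data$fold,
                                   colour = .data$single_global_max)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "peak rank", y = "fold enrichment",
                  colour = "single summit") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
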