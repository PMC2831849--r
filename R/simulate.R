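#' Configuration for a synthetic paired-end ChIP library
#'
#' Emulates a size-selected ChIP-Seq library: background fragments placed
#' uniformly over the genome, plus fragments piled around planted binding
#' sites. Fragment lengths are uniform on `[frag_len_min, frag_len_max]`
#' (default 80-300 bp, the usual gel size-selection window) and each
#' fragment is sequenced as two 40 bp mates whose outer coordinates
#' reproduce the fragment exactly.
#'
#' `enrichment_fold` is the target pileup at the site centre relative to
#' the mean background pileup: a site receives
#' `round(enrichment_fold * n_background * mean_len / genome_len)`
#' dedicated fragments, each covering the centre (the centre is uniform
#' within the fragment, modelling a point-source binding site).
#'
#' @param genome Named vector or two-column data frame of chromosome
#'   lengths.
#' @param sites Tibble with columns `chrom`, `center`, `enrichment_fold`
#'   (may be `NULL` for a null library).
#' @param n_background_fragments Background fragment count.
#' @param frag_len_min,frag_len_max Size-selection window in bp.
#' @param read_len Sequenced mate length in bp.
#' @param seed RNG seed; the emitted SAM is byte-identical for equal
#'   seeds.
#' @param boundary `"reject"` resamples site fragments that would cross a
#'   chromosome end; `"shift"` slides them back inside.
#' @param n_orphans Extra mate-less records to inject, to exercise parser
#'   skip paths.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(genome, sites = NULL,
                              n_background_fragments = 1000L,
                              frag_len_min = 80L, frag_len_max = 300L,
                              read_len = 40L, seed = 1L,
                              boundary = c("reject", "shift"),
                              n_orphans = 0L) {
  genome <- as_chrom_sizes(genome)
  boundary <- match.arg(boundary)
  if (!is.null(sites)) {
    sites <- as_tibble(sites)
    stopifnot(all(c("chrom", "center", "enrichment_fold") %in% names(sites)))
    if (any(!sites$chrom %in% names(genome))) abort("site on unknown chromosome")
    if (any(sites$center < 1 | sites$center > genome[sites$chrom])) {
      abort("site center outside chromosome bounds")
    }
    if (any(sites$enrichment_fold < 1)) abort("enrichment_fold must be >= 1")
  }
  if (frag_len_min < 2L * read_len) {
    abort("frag_len_min must be >= 2 * read_len so both mates fit")
  }
  structure(
    list(genome = genome, sites = sites,
         n_background_fragments = as.integer(n_background_fragments),
         frag_len_min = as.integer(frag_len_min),
         frag_len_max = as.integer(frag_len_max),
         read_len = as.integer(read_len), seed = as.integer(seed),
         boundary = boundary, n_orphans = as.integer(n_orphans)),
    class = "simulation_config"
  )
}

#' Simulate a paired-end ChIP-Seq library with known ground truth
#'
#' Draws background and site fragments per the configuration, writes them
#' as properly paired SAM records (two 40 bp mates per fragment, outer
#' coordinates equal to the fragment ends), and returns the exact planted
#' intervals so tests can join on token.
#'
#' @param cfg A [simulation_config()].
#' @param sam_path Where to write the SAM (default: a tempfile).
#' @param truth_path Optional path for the ground-truth TSV.
#' @return List of class `chip_simulation`: `sam` (path), `fragments`
#'   (truth tibble: `token`, `chrom`, `start`, `end`, `length`, `label`,
#'   `site_id`), `sites` (with the per-site fragment count), `config`.
#' @export
simulate_library <- function(cfg, sam_path = tempfile(fileext = ".sam"),
                             truth_path = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  genome <- cfg$genome
  genome_len <- sum(as.numeric(genome))
  mean_len <- (cfg$frag_len_min + cfg$frag_len_max) / 2

  draw_len <- function(n) {
    sample(seq.int(cfg$frag_len_min, cfg$frag_len_max), n, replace = TRUE)
  }

  # background: uniform fragment placement, chromosome weighted by length
  n_bg <- cfg$n_background_fragments
  bg <- NULL
  if (n_bg > 0L) {
    chr <- sample(names(genome), n_bg, replace = TRUE,
                  prob = as.numeric(genome) / genome_len)
    len <- draw_len(n_bg)
    len <- pmin(len, genome[chr])
    start <- vapply(seq_len(n_bg), function(k) {
      sample.int(genome[chr[k]] - len[k] + 1L, 1L)
    }, integer(1))
    bg <- tibble(chrom = chr, start = start, end = start + len - 1L,
                 label = "background", site_id = NA_integer_)
  }

  # site fragments: each covers its site centre
  bg_pileup <- n_bg * mean_len / genome_len
  site_frs <- NULL
  sites <- cfg$sites
  if (!is.null(sites) && nrow(sites) > 0L) {
    sites$n_fragments <- pmax(1L, as.integer(round(
      sites$enrichment_fold * bg_pileup)))
    site_frs <- purrr::map(seq_len(nrow(sites)), function(s) {
      chr <- sites$chrom[s]; ctr <- as.integer(sites$center[s])
      L <- genome[chr]
      n <- sites$n_fragments[s]
      out <- vector("list", n)
      for (k in seq_len(n)) {
        for (try in 1:200) {
          len <- draw_len(1L)
          start <- ctr - sample.int(len, 1L) + 1L
          end <- start + len - 1L
          if (start >= 1L && end <= L) break
          if (cfg$boundary == "shift") {
            start <- max(1L, min(start, L - len + 1L))
            end <- start + len - 1L
            break
          }
          if (try == 200L) abort("cannot place site fragment inside chromosome")
        }
        out[[k]] <- c(start = start, end = end)
      }
      m <- do.call(rbind, out)
      tibble(chrom = chr, start = as.integer(m[, "start"]),
             end = as.integer(m[, "end"]), label = "site",
             site_id = s)
    }) |> dplyr::bind_rows()
  }

  truth <- dplyr::bind_rows(bg, site_frs)
  if (is.null(truth) || nrow(truth) == 0L) abort("simulation produced no fragments")
  truth$token <- sprintf("frag%06d", seq_len(nrow(truth)))
  truth$length <- truth$end - truth$start + 1L
  truth <- truth[, c("token", "chrom", "start", "end", "length",
                     "label", "site_id")]

  write_sim_sam(truth, genome, cfg, sam_path)
  if (!is.null(truth_path)) {
    readr::write_tsv(truth, truth_path, progress = FALSE)
  }
  sites_out <- if (!is.null(sites)) sites else
    tibble(chrom = character(), center = integer(),
           enrichment_fold = numeric(), n_fragments = integer())
  structure(list(sam = sam_path, fragments = truth, sites = sites_out,
                 config = cfg),
            class = "chip_simulation")
}

write_sim_sam <- function(truth, genome, cfg, path) {
  rl <- cfg$read_len
  seqstr <- strrep("A", rl)
  qual <- strrep("I", rl)
  cig <- paste0(rl, "M")
  p1 <- truth$start
  p2 <- truth$end - rl + 1L
  tlen <- truth$length
  lines1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                    truth$token, truth$chrom, p1, cig, p2, tlen,
                    seqstr, qual)
  lines2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                    truth$token, truth$chrom, p2, cig, p1, -tlen,
                    seqstr, qual)
  body <- as.vector(rbind(lines1, lines2))
  if (cfg$n_orphans > 0L) {
    ch <- sample(names(genome), cfg$n_orphans, replace = TRUE)
    op <- vapply(ch, function(c) sample.int(genome[c] - rl, 1L), integer(1))
    # paired flag set, mate unmapped (0x1 + 0x8 + 0x40 = 73)
    orphans <- sprintf("orphan%04d\t73\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       seq_len(cfg$n_orphans), ch, op, cig, seqstr, qual)
    body <- c(body, orphans)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), genome))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Build a pileup track (and a matching fragment set) from a shape vector
#'
#' For caller unit tests: takes an integer profile and returns a
#' `pileup_track` holding exactly those values, together with a fragment
#' set whose pileup reproduces the profile (horizontal-slab
#' decomposition: for every level `l`, each maximal run of values
#' `>= l` becomes one fragment). This lets fixture shapes drive the full
#' calling path, including fragment-overlap counting.
#'
#' @param shape Nonnegative integer vector.
#' @param chrom Chromosome name for the fixture.
#' @return List with `track` (`pileup_track`) and `fragments` (tibble).
#' @export
make_track_fixture <- function(shape, chrom = "chrF") {
  shape <- as.integer(shape)
  if (any(shape < 0L)) abort("shape values must be nonnegative")
  frs <- track_to_fragments(shape, chrom)
  list(track = new_pileup_track(chrom, shape), fragments = frs)
}

#' @rdname make_track_fixture
#' @export
track_to_fragments <- function(shape, chrom = "chrF") {
  shape <- as.integer(shape)
  out <- list()
  mx <- max(shape, 0L)
  k <- 0L
  for (l in seq_len(mx)) {
    r <- rle(shape >= l)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      k <- k + 1L
      out[[k]] <- tibble(chrom = chrom, start = starts[i], end = ends[i],
                         token = sprintf("slab%04d", k))
    }
  }
  if (k == 0L) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), token = character()))
  }
  sort_fragments(dplyr::bind_rows(out))
}
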