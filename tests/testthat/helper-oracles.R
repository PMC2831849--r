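# Independent oracles and shared fixtures. These deliberately use the
# slowest, most literal formulation of each quantity so they stay
# independent of the implementation they check.

# Poisson upper tail by direct log-space series summation
pois_upper_series <- function(c, lambda, n_terms = 2000L) {
  if (c == 0L) return(1)
  k <- seq.int(c, c + n_terms)
  sum(exp(k * log(lambda) - lambda - lgamma(k + 1)))
}

# per-position pileup by counting every fragment at every position
naive_pileup <- function(frs, chrom_len) {
  v <- integer(chrom_len)
  for (k in seq_len(nrow(frs))) {
    idx <- seq.int(frs$start[k], frs$end[k])
    v[idx] <- v[idx] + 1L
  }
  v
}

# union coverage by materializing the covered position set
naive_union_size <- function(frs) {
  pos <- unlist(lapply(seq_len(nrow(frs)), function(k) {
    seq.int(frs$start[k], frs$end[k])
  }))
  length(unique(pos))
}

# literal sliding-window IUPAC match (subject treated as fixed letters)
naive_scan <- function(seq, pattern) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  s <- strsplit(toupper(seq), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  hits <- integer(0)
  if (length(s) < length(p)) return(hits)
  for (i in seq_len(length(s) - length(p) + 1L)) {
    ok <- TRUE
    for (j in seq_along(p)) {
      sub <- s[i + j - 1L]
      allowed <- if (sub == "N") "N" else sub
      # subject letter matches iff it is one of the pattern code's bases,
      # except subject N which only matches pattern N
      pat_set <- strsplit(iupac[[p[j]]], "")[[1]]
      hit <- if (sub == "N") p[j] == "N" else sub %in% pat_set
      if (!hit) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

random_fragments <- function(n, chrom_len, max_len = 300L, chrom = "chr1") {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(chrom_len - l + 1L, 1L),
                  integer(1))
  sort_fragments(tibble::tibble(
    chrom = chrom, start = start, end = start + len - 1L,
    token = sprintf("r%05d", seq_len(n))
  ))
}

# the two reference dynamic-baseline shapes used throughout the caller
# tests: (a) two bumps joined by a valley of height 1; (b) three summits
# (heights 15 / 13 / 13) with valleys of heights 11 and 9
shape_two_bump <- function() c(0, 1, 2, 3, 3, 2, 1, 2, 3, 4, 2, 1, 0)
shape_three_summit <- function() {
  c(0, 2, 5, 9, 12, 15, 12, 11, 12, 13, 12, 9, 10, 13, 10, 5, 2, 0)
}

# standard small simulated library: 3 well-separated planted sites at a
# realistic TF-ChIP depth (background pileup ~9.5, site apex ~75), so
# the default baseline sweep stays below the site cores
sim_three_sites <- function(seed, fold = 8, nbg = 1000L,
                            chrom_len = 20000L) {
  cfg <- simulation_config(
    c(simchr = chrom_len),
    sites = tibble::tibble(chrom = "simchr",
                           center = c(4000L, 10000L, 16000L),
                           enrichment_fold = fold),
    n_background_fragments = nbg, seed = seed
  )
  simulate_library(cfg)
}

# match called peaks to planted sites: a site is recovered when a peak
# summit_middle lies within +/- tol of its center
match_sites <- function(peaks, centers, tol) {
  vapply(centers, function(ctr) {
    sum(abs(peaks$summit_middle - ctr) <= tol)
  }, integer(1))
}
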