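test_that("a minimal properly paired SAM yields one reconstructed fragment", {
  f <- system.file("extdata", "worked_example_pair.sam",
                   package = "fragpeaks")
  mates <- read_mate_alignments(f)
  expect_equal(nrow(mates), 2L)
  expect_setequal(mates$end_tag, c("end1", "end2"))

  frs <- read_fragments(f)
  expect_equal(nrow(frs), 1L)
  expect_equal(frs$chrom, "Chr5")
  expect_equal(frs$start, 15902154L)
  expect_equal(frs$end, 15902413L)
  expect_equal(attr(frs, "chrom_sizes"), c(Chr5 = 26975502L))
})

test_that("fragment reconstruction takes the outer mate coordinates", {
  pairs <- tibble::tibble(
    token = c("a", "b"),
    chrom1 = "chr1", pos1 = c(1000L, 100L), aln_len1 = 40L, strand1 = "+",
    chrom2 = "chr1", pos2 = c(1220L, 100L), aln_len2 = 40L, strand2 = "-"
  )
  frs <- reconstruct_fragments(pairs)
  # min/max over the four endpoint coordinates
  expect_equal(frs$start, c(1000L, 100L))
  expect_equal(frs$end, c(1259L, 139L))
  expect_equal(frs$end - frs$start + 1L, c(260L, 40L))
})

test_that("reconstruction is symmetric in the two mates and contains both", {
  set.seed(11)
  n <- 50L
  pos1 <- sample.int(5000L, n)
  off <- sample.int(400L, n)
  pairs <- tibble::tibble(
    token = sprintf("t%02d", seq_len(n)), chrom1 = "chr2",
    pos1 = pos1, aln_len1 = sample(30:45, n, TRUE), strand1 = "+",
    chrom2 = "chr2", pos2 = pos1 + off,
    aln_len2 = sample(30:45, n, TRUE), strand2 = "-"
  )
  swapped <- pairs |>
    dplyr::rename(chrom1 = chrom2, pos1 = pos2, aln_len1 = aln_len2,
                  strand1 = strand2, chrom2 = chrom1, pos2 = pos1,
                  aln_len2 = aln_len1, strand2 = strand1)
  expect_equal(reconstruct_fragments(pairs), reconstruct_fragments(swapped))

  frs <- reconstruct_fragments(pairs)
  expect_true(all(frs$start <= pairs$pos1 &
                    pairs$pos1 + pairs$aln_len1 - 1L <= frs$end))
  expect_true(all(frs$start <= pairs$pos2 &
                    pairs$pos2 + pairs$aln_len2 - 1L <= frs$end))
})

test_that("mates on different chromosomes are rejected", {
  pairs <- tibble::tibble(
    token = "x", chrom1 = "chr1", pos1 = 10L, aln_len1 = 40L,
    strand1 = "+", chrom2 = "chr2", pos2 = 500L, aln_len2 = 40L,
    strand2 = "-"
  )
  expect_error(reconstruct_fragments(pairs), "different chromosomes")

  # and filtered out (with a count) when pairing from records
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:10000", "@SQ\tSN:chr2\tLN:10000",
    "p1\t97\tchr1\t100\t60\t40M\tchr2\t500\t0\t*\t*",
    "p1\t145\tchr2\t500\t60\t40M\tchr1\t100\t0\t*\t*"
  ), sam)
  mates <- read_mate_alignments(sam)
  pairs2 <- pair_mates(mates)
  expect_equal(nrow(pairs2), 0L)
  expect_equal(unname(attr(pairs2, "pair_stats")["cross_chromosome"]), 1L)
})

test_that("length filtering is inclusive at both bounds", {
  lens <- c(79L, 80L, 500L, 501L)
  frs <- tibble::tibble(chrom = "c", start = 1L, end = lens,
                        token = paste0("t", lens))
  kept <- filter_fragments(frs)
  expect_equal(kept$end - kept$start + 1L, c(80L, 500L))
  expect_equal(unname(attr(kept, "filter_counts")[c("kept", "dropped_length")]),
               c(2L, 2L))
  # empty in, empty out
  expect_equal(nrow(filter_fragments(frs[0, ])), 0L)
})

test_that("filter kept-count matches a brute-force recount", {
  set.seed(5)
  n <- 1000L
  len <- sample(60:520, n, TRUE)
  frs <- tibble::tibble(chrom = "c", start = 1000L, end = 999L + len,
                        token = sprintf("f%04d", seq_len(n)))
  expect_equal(nrow(filter_fragments(frs)), sum(len >= 80 & len <= 500))
  # non-default window
  f2 <- fragment_filter(min_len = 80, max_len = 300)
  expect_equal(nrow(filter_fragments(frs, f2)), sum(len >= 80 & len <= 300))
})

test_that("dedup removes coordinate duplicates only when asked", {
  frs <- tibble::tibble(chrom = "c", start = c(10L, 10L, 20L),
                        end = c(200L, 200L, 210L),
                        token = c("a", "b", "c"))
  expect_equal(nrow(filter_fragments(frs)), 3L)
  expect_equal(nrow(filter_fragments(frs, fragment_filter(dedup = TRUE))), 2L)
})

test_that("sorting is stable, deterministic and idempotent", {
  set.seed(7)
  frs <- random_fragments(500L, 40000L)
  shuffled <- frs[sample.int(nrow(frs)), ]
  sorted <- sort_fragments(shuffled)
  oracle <- shuffled[order(shuffled$chrom, shuffled$start, shuffled$end,
                           shuffled$token), ]
  expect_equal(as.data.frame(sorted), as.data.frame(oracle),
               ignore_attr = TRUE)
  expect_equal(sort_fragments(sorted), sorted)
})

test_that("parse-reconstruct-filter round-trips the simulator's truth", {
  sim <- sim_three_sites(seed = 301L)
  frs <- read_fragments(sim$sam)
  truth <- sort_fragments(sim$fragments[, c("chrom", "start", "end", "token")])
  expect_equal(as.data.frame(frs), as.data.frame(truth), ignore_attr = TRUE)
  expect_equal(nrow(frs), nrow(sim$fragments))
})

test_that("orphan records are skipped with a warning, pairs survive", {
  cfg <- simulation_config(c(chrZ = 30000L), n_background_fragments = 100L,
                           seed = 9L, n_orphans = 5L)
  sim <- simulate_library(cfg)
  mates <- read_mate_alignments(sim$sam)
  expect_warning(pairs <- pair_mates(mates), "no mapped mate")
  expect_equal(nrow(pairs), 100L)
  expect_equal(unname(attr(pairs, "pair_stats")["orphans"]), 5L)
})

test_that("BED export converts to 0-based half-open coordinates", {
  frs <- tibble::tibble(chrom = "chr1", start = 101L, end = 300L,
                        token = "t1")
  path <- tempfile(fileext = ".bed")
  fragments_to_bed(frs, path)
  bed <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(bed[1:4], c("chr1", "100", "300", "t1"))
})
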