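test_that("summit detection finds the maximal plateau", {
  s <- find_summit(c(1L, 3L, 3L, 1L), offset = 10L)
  expect_equal(s$summit_start, 11L)
  expect_equal(s$summit_end, 12L)
  expect_equal(s$summit_middle, 11L)
  expect_equal(s$summit_width, 2L)
  expect_true(s$single_global_max)

  two <- find_summit(c(2L, 5L, 2L, 5L, 2L))
  expect_false(two$single_global_max)
  expect_equal(two$summit_start, 2L)  # leftmost maximal run reported

  set.seed(51)
  for (rep in 1:20) {
    v <- sample.int(6L, sample(3:40, 1), replace = TRUE)
    s <- find_summit(v)
    is_max <- which(v == max(v))
    runs <- split(is_max, cumsum(c(1L, diff(is_max) != 1L)))
    expect_equal(s$single_global_max, length(runs) == 1L)
    expect_equal(s$summit_start, runs[[1]][1])
    expect_equal(s$summit_end, runs[[1]][length(runs[[1]])])
  }
})

test_that("signal maps are maximal runs at or above the baseline", {
  fx <- make_track_fixture(shape_two_bump())
  expect_equal(nrow(signal_maps_at_baseline(fx$track, 1L)), 1L)
  expect_equal(nrow(signal_maps_at_baseline(fx$track, 2L)), 2L)

  zero <- make_track_fixture(rep(0L, 30))
  for (b in c(1L, 3L)) {
    expect_equal(nrow(signal_maps_at_baseline(zero$track, b)), 0L)
  }

  set.seed(52)
  for (rep in 1:15) {
    v <- rpois(sample(100:400, 1), lambda = 2)
    tr <- make_track_fixture(v)$track
    b <- sample.int(4L, 1L)
    maps <- signal_maps_at_baseline(tr, b)
    # linear-scan oracle for runs of positions >= b
    r <- rle(v >= b)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    expect_equal(maps$start, starts[r$values])
    expect_equal(maps$end, ends[r$values])
    expect_true(all(maps$max_pileup >= b))
    expect_true(all(maps$start <= maps$summit_start &
                      maps$summit_start <= maps$summit_middle &
                      maps$summit_middle <= maps$summit_end &
                      maps$summit_end <= maps$end))
  }
})

test_that("reads_in_signal counts any-overlap fragments", {
  frs <- tibble::tibble(chrom = "c", start = c(5L, 1L, 30L),
                        end = c(15L, 9L, 60L), token = c("a", "b", "d"))
  maps <- tibble::tibble(chrom = "c", start = 10L, end = 20L)
  expect_equal(reads_in_signal(maps, frs)$reads_in_signal, 1L)

  set.seed(53)
  frs2 <- random_fragments(300L, 10000L)
  maps2 <- tibble::tibble(chrom = "chr1",
                          start = sample.int(9000L, 25L))
  maps2$end <- maps2$start + sample(50:800, 25L, TRUE)
  got <- reads_in_signal(maps2, frs2)$reads_in_signal
  want <- vapply(seq_len(25L), function(k) {
    sum(frs2$start <= maps2$end[k] & frs2$end >= maps2$start[k])
  }, integer(1))
  expect_equal(got, want)
})

test_that("the dynamic baseline separates adjacent and merged summits", {
  fb <- make_track_fixture(shape_three_summit())
  gm <- tibble::tibble(tpn = nrow(fb$fragments), gs = 1e6)
  sizes <- c(chrF = fb$track$chrom_len)
  n_at <- function(be) {
    nrow(call_peaks(fb$fragments, sizes, caller_config(1L, be), gm = gm)$peaks)
  }
  expect_equal(n_at(5L), 1L)
  expect_equal(n_at(9L), 1L)
  expect_equal(n_at(10L), 2L)
  expect_equal(n_at(12L), 3L)
})

test_that("dedup collapses all baselines of an isolated rectangular signal", {
  shape <- c(rep(0L, 10), rep(8L, 40), rep(0L, 10))
  fx <- make_track_fixture(shape)
  gm <- tibble::tibble(tpn = nrow(fx$fragments), gs = 1e6)
  for (be in c(1L, 4L, 8L, 20L)) {
    pc <- call_peaks(fx$fragments, c(chrF = length(shape)),
                     caller_config(1L, be), gm = gm)
    expect_equal(nrow(pc$peaks), 1L)
  }
})

test_that("maps nest across baselines and split counts never decrease", {
  set.seed(54)
  for (rep in 1:10) {
    v <- rpois(300, lambda = 3)
    tr <- make_track_fixture(v)$track
    prev <- signal_maps_at_baseline(tr, 1L)
    n_prev <- nrow(prev)
    for (b in 2:6) {
      cur <- signal_maps_at_baseline(tr, b)
      if (nrow(cur) == 0L) break
      # each map at b is contained in exactly one map at b-1
      for (k in seq_len(nrow(cur))) {
        parent <- prev$start <= cur$start[k] & prev$end >= cur$end[k]
        expect_equal(sum(parent), 1L)
      }
      expect_gte(nrow(cur), 0L)
      prev <- cur
    }
  }
})

test_that("no two peaks share an overlapping summit plateau", {
  set.seed(55)
  for (rep in 1:5) {
    v <- rpois(500, lambda = 4)
    fx <- make_track_fixture(v)
    gm <- tibble::tibble(tpn = nrow(fx$fragments), gs = 5e5)
    pc <- call_peaks(fx$fragments, c(chrF = 500L),
                     caller_config(1L, 8L, p_cutoff = 0.05,
                                   fold_cutoff = 0.5), gm = gm)
    pk <- pc$peaks
    if (nrow(pk) < 2L) next
    ir <- IRanges::IRanges(pk$summit_start, pk$summit_end)
    expect_equal(sum(IRanges::countOverlaps(ir, ir) > 1L), 0L)
  }
})

test_that("every reported peak satisfies both thresholds strictly", {
  sim <- sim_three_sites(seed = 401L)
  frs <- read_fragments(sim$sam)
  cfg <- caller_config(1L, 25L, p_cutoff = 1e-5, fold_cutoff = 2)
  pc <- call_peaks(frs, c(simchr = 20000L), cfg)
  expect_gt(nrow(pc$peaks), 0L)
  expect_true(all(pc$peaks$p_value < cfg$p_cutoff))
  expect_true(all(pc$peaks$fold > cfg$fold_cutoff))
  # ranked by fold, descending
  expect_true(all(diff(pc$peaks$fold) <= 0))
  expect_equal(pc$peaks$rank, seq_len(nrow(pc$peaks)))
})

test_that("no candidates yields an empty peak set, not an error", {
  frs <- tibble::tibble(chrom = "c", start = 1L, end = 100L, token = "a")
  pc <- call_peaks(frs, c(c = 1000L),
                   caller_config(1L, 2L, p_cutoff = 1e-10,
                                 fold_cutoff = 50))
  expect_equal(nrow(pc$peaks), 0L)
  expect_true(is.na(single_max_fraction(pc)))
})

test_that("single-max percentage summarises the final peaks", {
  pk <- tibble::tibble(single_global_max = c(TRUE, TRUE))
  expect_equal(single_max_fraction(pk), 100)
  pk2 <- tibble::tibble(single_global_max = c(TRUE, FALSE))
  expect_equal(single_max_fraction(pk2), 50)
})

test_that("tidy/glance expose peaks and run summary", {
  sim <- sim_three_sites(seed = 402L)
  frs <- read_fragments(sim$sam)
  pc <- call_peaks(frs, c(simchr = 20000L))
  expect_identical(tidy(pc), pc$peaks)
  g <- glance(pc)
  expect_equal(g$n_peaks, nrow(pc$peaks))
  expect_equal(g$tpn, nrow(frs))
  expect_equal(g$be, 25L)
})

test_that("autoplot returns ggplot objects for tracks and calls", {
  sim <- sim_three_sites(seed = 403L)
  frs <- read_fragments(sim$sam)
  tr <- compute_pileup(frs, 20000L)
  pc <- call_peaks(frs, c(simchr = 20000L))
  expect_s3_class(autoplot(tr, peaks = pc), "ggplot")
  expect_s3_class(autoplot(pc), "ggplot")
})

test_that("peak table uses the canonical column order and deep-tail p format", {
  sim <- sim_three_sites(seed = 404L)
  frs <- read_fragments(sim$sam)
  pc <- call_peaks(frs, c(simchr = 20000L))
  path <- tempfile(fileext = ".tsv")
  write_peak_table(pc, path)
  header <- readLines(path, n = 1L)
  expect_equal(header, paste(
    c("chrom", "signal_start", "signal_end", "signal_width",
      "reads_in_signal", "max_pileup", "summit_start", "summit_end",
      "summit_middle", "summit_width", "p_value", "fold", "rank"),
    collapse = "\t"))
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(p_value = "c"))
  expect_equal(nrow(tab), nrow(pc$peaks))
  # scientific notation from log10, never a literal zero
  expect_true(all(grepl("e[+-]\\d+$", tab$p_value)))
  expect_false(any(tab$p_value == "0"))
})
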