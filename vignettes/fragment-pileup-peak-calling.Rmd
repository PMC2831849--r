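---
title: "Fragment-pileup peak calling from paired-end ChIP-Seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-pileup peak calling from paired-end ChIP-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragpeaks)
library(dplyr)
```

## The model

Paired-end sequencing reads both ends of every immunoprecipitated DNA
fragment. Because mates share a read name, the physical fragment is
bounded *exactly* by its outer mate coordinates: `start` is the minimum
leftmost position over both mates, `end` the maximum rightmost position
(`pos + aligned_length - 1`). No fragment-size estimation or 3'-end
extension — the staple of single-end peak callers — is needed, and two
quantities that single-end methods can only guess become measurable:

* the **fragment pileup**: the number of reconstructed fragments
  overlapping each nucleotide, computed exactly with a difference array;
* the **effective (mappable) genome size** `gs`: the number of positions
  covered by at least one uniquely mapped fragment, i.e. the union
  coverage of the fragment intervals. This is the denominator of the
  background rate, measured from the data instead of taken from a
  genome-fraction rule of thumb.

A **signal map** at baseline `b` is a maximal contiguous run of
positions with pileup `>= b`. Sweeping the baseline over `bs..be` (the
*dynamic baseline*) cuts the profile at every level: a broad region that
merges two adjacent binding sites at `b = 1` splits into its component
sites once `b` exceeds the valley between them. The **summit** of a map
is the plateau of positions attaining its maximum pileup;
`single_global_max` records whether that plateau is one contiguous run.

Each map is scored against a Poisson background. With `tpn` retained
fragment pairs on a mappable genome of `gs` bp, the chance of seeing at
least `c` fragments in a map of width `w` is

$$p = P(X \ge c), \qquad X \sim \mathrm{Poisson}\!\left(\lambda = w\,\frac{tpn}{gs}\right),$$

and the fold enrichment is $c / (w \cdot tpn/gs)$. A map is a
*candidate* when `p < p_cutoff` and `fold > fold_cutoff` (both strict)
and either it sits at the top baseline (`b = be`) or its global maximum
is single. Candidates from successive baselines are nested and share an
apex, so they are grouped by global-maximum position — candidates whose
summit plateaus overlap are one site — and the highest-fold candidate of
each group becomes the peak. Peaks are ranked by fold, descending.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_len`, `max_len` | 80, 500 | bp | mate-distance window accepted at mapping time, inclusive at both bounds. Libraries gel-selected to 80–300 bp can tighten `max_len`; both bounds are exposed because which of the two windows governed a given library is usually unknowable downstream. |
| `bs`, `be` | 1, 25 | pileup units | the baseline sweep. `be` is the resolution knob: summit-splitting improves and the peak count stabilises as it grows, at linear cost in runtime. Choose it at least as large as the deepest valley you want to split. |
| `p_cutoff`, `fold_cutoff` | 1e-5, 2 | — | strict thresholds on the Poisson tail and fold enrichment, standard operating points for transcription-factor calling. |
| `tpn_mode` | `"pairs"` | — | `lambda = w * tpn/gs` models *fragment starts* per base, so `tpn` counts pairs (one per fragment). `"reads"` doubles it for sensitivity analysis; p-values shift accordingly. |
| `window_halfwidth` | 100 | bp | motif-association window for the resolution metrics ("within 200 bp of the peak center"). |

## Decisions on genuinely open points

* **Inclusive length bounds.** "80 to 500 bp" does not state
  inclusivity; both bounds are treated as inclusive and tested at the
  boundary.
* **`tpn` counts pairs, not end reads.** The phrase "total number of
  paired-end reads (end-1, end-2)" is ambiguous by a factor of two;
  pair-count is used because the rate models fragment starts per base.
  The `--tpn-mode reads` switch exists for the other reading.
* **Dedup key.** "Same global maximum position" is implemented as
  *overlapping summit plateaus*: nested maps share an apex plateau, and
  plateau overlap is the only key stable across baselines. Two
  candidates whose plateaus merely touch different positions of the same
  apex run still group; disjoint plateaus are distinct sites.
* **Multi-summit maps at `b = be`** are emitted as one peak with
  `single_global_max = FALSE` and summit fields describing the leftmost
  maximal run, rather than being split further.
* **`reads_in_signal` counts any overlap** (>= 1 bp), not full
  containment. A config-level consequence is discussed under
  *Limitations*.
* **Input-scaled background.** With an input-DNA control, the local
  rate is `lambda_local = max(i * r, w * tpn/gs)` where `i` is the input
  fragment count in the window and `r = tpn_IP / tpn_input` scales input
  counts to IP depth. The `max(...)` floor is this package's decision:
  sparse input coverage can only make calls harder, never easier.
* **The baseline does not enter `lambda`.** The global rate is used at
  every `b`; no defensible baseline-conditioned background presented
  itself, and conditioning on `b` would double-count the evidence that
  the baseline sweep already encodes.
* **Empirical FDR orientation.** Both `n1/n2` (the ratio as historically
  written for this method) and the conventional null-over-observed
  `n2/n1` are reported; they are labelled `fdr_n1_over_n2` and
  `fdr_n2_over_n1` and neither is silently preferred.
* **Duplicate fragments are kept** by default (no deduplication step is
  part of the model); `dedup = TRUE` removes coordinate duplicates for
  PCR-duplicate control.
* **Peak centers are summits.** The motif metrics anchor on
  `summit_middle`, the method's positional claim, not the midpoint of
  the signal span; motif distance is measured to the motif *midpoint*.

## What the simulator emulates — and what it does not

`simulate_library()` draws background fragments uniformly over the
genome and plants point-source binding sites: each site fragment covers
the site center, with the center uniform within the fragment, so the
site-only pileup is unimodal with its apex at the center. Fragment
lengths are uniform on 80–300 bp (the size-selection window; the true
post-amplification length distribution of a real library is unknown) and
every fragment is emitted as two properly paired 40 bp SAM records whose
outer coordinates reproduce the fragment exactly. `enrichment_fold` sets
the target apex pileup relative to the mean background pileup. The
generator is deterministic per seed, down to the SAM bytes.

It does **not** simulate sequencing errors, mapping ambiguity or
mappability holes, GC or chromatin-accessibility bias, or motif sequence
content (coordinates only; the motif metrics take a user FASTA). Passing
tests on this generator therefore demonstrate the *algorithmic*
contract — reconstruction, pileup arithmetic, baseline splitting,
dedup, calibration of the Poisson tail under its own assumptions — not
robustness to the biases of real libraries.

### Study sizes used by the test-suite and acceptance script

Recovery: 20 seeded libraries, 20 kb genome, 1000 background fragments
(mean background pileup ≈ 9.5), three sites at fold 8 (apex ≈ 75)
separated by 6 kb, called at `bs=1, be=25, p<1e-5, fold>2`. Null
calibration: 100 kb, 2000 fragments, 200 bp windows, three seeds
(1500 windows). Oracle grids: 50 random fragment sets for the pileup
check; `lambda in {0.1, 1, 2, 10, 50}, c in 0..200` for the Poisson
check. The depth matters: at an apex of ~75 the default sweep
(`be = 25`) stays below the site cores, so within-site noise dips are
never cut. At shallow depth (apex ≈ 30) baselines near the apex
*honestly* split noisy site tops into adjacent mini-summits — the same
mechanism that separates genuinely adjacent sites — and a site can
yield several nearby calls. That is a property of the method, not a
bug, and is why high `be` belongs with deep libraries.

## Numerical notes

* The Poisson tail is evaluated via `ppois(c - 1, lambda, lower.tail =
  FALSE)`; agreement with direct series summation is pointwise better
  than 1e-12 relative wherever the tail is representable as a normal
  double. Below ~2.2e-308 doubles are subnormal and *any* double-valued
  route loses digits to the representation itself; comparisons stop
  there.
* Written p-values are formatted from `log10(p)` (computed with
  `log.p = TRUE`), so tails far below double underflow still print in
  scientific notation and are never truncated to 0.
* Summit ties: when several runs attain the maximum, the leftmost run is
  reported and flagged (`single_global_max = FALSE`). `summit_middle`
  is `floor((summit_start + summit_end)/2)`.
* Candidate ordering is fully deterministic: groups keep the highest
  fold, ties broken by smaller p, then lower baseline; final ranking by
  fold descending, then p ascending, then coordinate.
* Degenerate inputs: an empty candidate set returns an empty peak table
  (not an error); a flat-zero track yields no maps at any baseline;
  fragments extending past the declared chromosome length are an error
  naming the offending token (chromosome lengths always come from the
  header or a sizes file, never from the data).

## Limitations

* **Narrow maps are anti-conservative without an input control.**
  `reads_in_signal` counts fragments overlapping the map by >= 1 bp, so
  its expectation in a `w`-window is ~`(w + L - 1) * tpn/gs` (`L` the
  mean fragment length) while the test's `lambda` is `w * tpn/gs`. For
  broad maps (`w >> L`) the difference vanishes; for narrow,
  high-baseline maps in deep libraries it lets background through — at
  default cutoffs a deeply covered null region can clear `p` and `fold`
  on width alone. An input-DNA control (which floors `lambda` with the
  local input count) or stricter cutoffs restore specificity; the null
  calibration tests therefore count fragment *starts* per window, the
  quantity `lambda` actually models.
* Broad-domain (histone-mark-style) enrichment is out of scope: wide
  shallow regions cannot clear a point-source Poisson test, and the
  baseline sweep is designed for punctate sources.
* Single-end data are not supported; fragment reconstruction *is* the
  method.
* The empirical FDR needs an input library of comparable depth; with
  none, only the global Poisson background is available.

## A worked run

```{r example, eval = FALSE}
library(fragpeaks)
library(tibble)

cfg <- simulation_config(
  c(simchr = 20000L),
  sites = tibble(chrom = "simchr", center = c(4000L, 10000L, 16000L),
                 enrichment_fold = 8),
  n_background_fragments = 1000L, seed = 42L
)
sim <- simulate_library(cfg)

frs <- read_fragments(sim$sam)
pc <- call_peaks(frs, c(simchr = 20000L),
                 caller_config(bs = 1, be = 25, p_cutoff = 1e-5,
                               fold_cutoff = 2))
glance(pc)
tidy(pc) |> dplyr::slice_head(n = 3)
autoplot(pc$tracks$simchr, peaks = pc)
```
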