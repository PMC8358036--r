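---
title: "Mapping and classifying DNA break hotspots from strand-resolved END-seq signal"
author: "endlesion package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and classifying DNA break hotspots from strand-resolved END-seq signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement and its model

END-seq captures blunted DNA ends genome-wide at base-pair resolution. A
recurrent double-strand break (DSB) at position $x$ exposes two ends: reads
into the retained fragment produce plus-strand 5' tags to the right of $x$
and minus-strand tags to the left, in roughly equal numbers. A single-strand
lesion (SSB) exposes an end on one strand only, so its signal is dominated
by one strand. Sporadic, non-recurrent breakage contributes a diffuse
background indistinguishable from noise. This strand asymmetry is the core
observable: it lets one pipeline both locate lesions and say whether each is
double- or single-stranded.

`endlesion` implements that pipeline end to end: strand-resolved tag
simulation with planted ground truth, binned RPKM signal tracks, Poisson
peak calling, blacklist filtering, cross-clone consensus, strand-ratio
classification, and two hypergeometric enrichment statistics with a
permutation oracle. Tags are width-1 `GRanges` (the 5' end of each read,
reduced on load: plus strand uses the interval start, minus strand the
end), genomes are `Seqinfo` objects, and all interval algebra goes through
`GenomicRanges`. BED and bedGraph I/O goes through `rtracklayer`, which
owns the 0-based half-open to 1-based closed conversion; all BED-facing
semantics (half-open adjacency is not overlap) are preserved and tested.

## The synthetic data generator

The generator's defaults define the package's reference desk-scale study;
they are the conditions under which every end-to-end claim in the test
suite is made.

| parameter | default | meaning |
|---|---|---|
| genome | 2 x 10 Mb | two chromosomes, desk-scale stand-in for a mammalian genome |
| `n_lesions` | 200 | planted recurrent lesions |
| `frac_dsb` | 0.7 | fraction of lesions that are DSBs |
| `mu` | 80 | expected tags per strand side of a lesion |
| `resection_scale` | 50 bp | mean of the geometric tag-offset law |
| `background_rate` | 2e-4 /bp/strand | homogeneous Poisson background |
| `n_replicates`, `replicate_jaccard` | 2, 0.85 | clones; per-clone lesion carriage probability |
| `f_prox`, `w_prox` | 0.3, 10 kb | fraction of lesions planted near a TF site; edge distance |
| `n_tf_sites`, `tf_site_width` | 100, 400 bp | simulated TF binding-site map |
| `n_genes`, `n_upregulated`, `upreg_enrichment` | 2000, 200, 8 | gene universe; upregulated-set bias toward lesions |

Model choices, and why:

* **Offset law.** Tag offsets from the break are geometric with mean
  `resection_scale` (50 bp). Nothing quantitative is established about
  END-seq signal shape; the geometric law is this package's own model —
  simple, discrete, heavy-enough tailed — and is labeled as such. DSB plus
  tags go right of the break and minus tags left; the classifier only uses
  the magnitude of the ratio, so the orientation convention is
  inconsequential downstream.
* **Per-lesion intensity** is held constant at `mu`; Poisson tag counts
  already give per-replicate count noise, and a lesion-level intensity
  distribution would add a dispersion parameter with nothing to calibrate
  it against.
* **Clone sharing.** Each lesion enters each clone independently with
  probability `replicate_jaccard`. This is the simplest mechanism with a
  single knob controlling the expected consensus size; it also means
  "shared" is defined by construction (`lesion_inclusion()`), so recovery
  can be scored exactly.
* **TF-site density.** Two constraints pin `n_tf_sites = 100` on 20 Mb.
  Proximal lesions are placed within `w_prox` of a site while lesions keep
  a minimum spacing of `2 * w_prox`, so each padded site accommodates
  roughly one proximal lesion: the 60 proximal lesions of the default study
  need at least ~60 sites. Conversely, too many sites make the +/-10 kb
  padded target cover so much of a 20 Mb genome that planted proximity is
  indistinguishable from chance (at 300 sites the target is ~26% of the
  genome). 100 sites (~10% target coverage) leaves a clear margin on both
  sides.
* **Upregulated genes** are drawn with weight `upreg_enrichment` for genes
  whose TSS lies within `w_prox` of a lesion, giving the gene-set test a
  true signal whose strength is a stated dial (weight 1 recovers a uniform
  draw).

What the generator does **not** emulate: fragment-length geometry and
sonication, PCR duplicates, mappability and copy-number artifacts (hence
no meaningful blacklist on simulated data), local background variation
(chromatin accessibility), and sequence context. Passing tests therefore
demonstrate correctness of the algorithms under a clean, homogeneous
background — not robustness to the artifact structure of real libraries,
which is exactly what blacklist filtering and the optional control-track
lambda exist to absorb on real data.

## Peak calling

`call_peaks()` mirrors the behavior of MACS run with no local lambda, no
fragment-shift model, and all duplicates kept, the standard configuration
for end-capture data where the 5' end *is* the signal:

* both strands pooled; global background
  $\lambda = \text{total tags} \times \text{window} / G$;
* sliding windows (default 200 bp, step 50 bp) tested with the exact
  Poisson upper tail $P(X \ge k;\lambda)$, computed in log space;
* raw p-value threshold (default 1e-5), **no multiple-testing correction**,
  matching MACS v1 semantics — the threshold is a config knob, not a fixed
  constant;
* significant windows unioned, merged across gaps <= 100 bp, regions
  < 50 bp dropped; summit = center of the maximum-count step bin, leftmost
  on ties (a determinism rule, not a biological claim);
* per-strand intensities recomputed over the final interval;
* `lambda_mode = "control"` takes lambda from a depth-scaled control track
  over the same window, floored at the global rate — a control-referenced
  approximation, not a re-implementation of SEACR's block/FDR algorithm.

## Classification

For a peak with per-strand counts $(n_+, n_-)$ the statistic is
$\mathrm{LR} = \log_2\frac{n_+ + c}{n_- + c}$ with pseudocount $c = 1$.
The symmetric (DSB) band is $\mathrm{LR} \in [-1, 1]$: a plain positive
ratio cannot lie "between -1 and 1" around a symmetric point, so the band
is read on the signed log2 scale, where it corresponds to at most a
two-fold strand imbalance. The boundary is closed (|LR| exactly 1 is
symmetric) and both the band and the pseudocount are configurable, since
neither choice is externally fixed; with `mu = 80` per side the decision
is far from the boundary anyway. Raw counts are used rather than RPKM —
the ratio is depth-invariant within a sample, and normalization would only
move both counts by the same factor.

Cross-clone concordance pairs calls by best overlap and reports the
Pearson correlation of paired log-ratios, the class-agreement fraction,
and the 2x2 class table.

## Consensus and differencing

Consensus is A-anchored: clone 1's peaks that overlap (>= 1 bp, the
half-open BED rule) a clone 2 peak, reported in clone 1 coordinates. A
single anchoring convention is required for a well-defined consensus
count; merged spans are available behind `merged = TRUE` for workflows
that prefer neutral coordinates. Condition differencing (`lost` =
untreated-only, `gained` = treated-only) and the two-clone intersection of
difference sets reuse the same overlap rule, and are checked in the tests
against a brute-force all-pairs scan.

## Enrichment statistics

**Proximity.** The genome is modeled as $N = \lfloor G / \bar{L} \rfloor$
slots of mean-peak-length size $\bar{L}$; the target region $T$ (sites
padded by the proximity window and merged) contributes
$K = \lfloor |T| / \bar{L} \rfloor$ slots; $n$ peaks are drawn and $k$
overlap $T$. The upper-tail hypergeometric $P(X \ge k)$ is the reported
p-value. This slot construction is a committed interpretation — built from
the two stated ingredients, mean peak length and genome size — and is the
only self-consistent hypergeometric framing of those ingredients we found;
precisely because it is an interpretation, `permutation_oracle()`
(length-preserving uniform re-placement within chromosomes) is provided as
the assumption-free reference, and the tests require agreement within
three Monte-Carlo standard errors on null data. "Within 10 kb" is realized
as edge distance (overlap with the padded target); $N$ and $K$ are rounded
down, both documented choices where midpoint distance or other roundings
would also have been defensible.

**Gene set.** Peaks are associated to the single nearest gene by TSS-to-
midpoint distance, capped at 1000 kb (closed at the cap: exactly 1000 kb
associates), ties broken to the lexicographically smaller gene id. The
deduplicated associated set is then tested against the upregulated set by
hypergeometric overlap in a fixed gene universe. The full GREAT regulatory-
domain model (basal + extension) is out of scope; single-nearest-gene at
1000 kb is the association rule this pipeline commits to.

Both tests report `log10_p` computed directly in log space, so extreme
tails (beyond double-precision underflow, p < 1e-308) remain informative.

## Numerical and reproducibility choices

* All Poisson and hypergeometric tails use `ppois()`/`phyper()` with
  `log.p = TRUE`; nothing is exponentiated before thresholding.
* Track smoothing is a centered moving average whose edge bins average
  over the available (truncated) window; zero-padding was rejected because
  it depresses chromosome ends.
* Downsampling samples tags jointly over strands, matching whole-library
  depth normalization.
* One top-level seed drives everything: clone seeds are
  `seed XOR replicate_index`, and every stochastic function scopes its RNG
  with `withr::with_seed`, so identical configs give byte-identical
  outputs (asserted on the emitted `report.json`).
* Degenerate inputs are defined, not accidental: zero tags in a window
  give p = 1; zero counts on both strands give log-ratio 0 via the
  pseudocount; an empty blacklist is the identity filter; concordance with
  no matched pairs reports n = 0 with an undefined correlation flagged as
  `NA`.

## Problem sizes

The reference study (20 Mb, ~30,000 tags per clone) was chosen so that the
full simulate-to-enrichment pipeline runs in a few seconds and the whole
test suite, including three end-to-end replicate studies and a
1000-permutation oracle comparison on ten null datasets, completes in
about a minute. These sizes are the package's desk-scale study design;
all of them scale through `sim_params()` and the config.

## Known limitations

* The peak caller is calibrated and validated against a homogeneous
  Poisson background; real END-seq background is locally structured, and
  the raw-p threshold semantics (no FDR control) are inherited
  deliberately from the MACS v1 convention.
* The slot-based hypergeometric treats peak placements as exchangeable
  slots; it ignores peak-length variance and chromosome-edge effects. The
  permutation oracle is the arbiter whenever the two disagree.
* The classifier reports strand asymmetry, not mechanism: an asymmetric
  call says one-strand-dominant signal, it does not distinguish a nick
  from one-sided resection.
* Consensus is defined for two clones; multi-way consensus is out of
  scope.
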