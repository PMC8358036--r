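# endlesion

Strand-resolved mapping and classification of recurrent DNA break hotspots
from END-seq-style end-capture sequencing.

END-seq detects blunted DNA ends genome-wide at base-pair resolution. A
recurrent double-strand break (DSB) yields balanced plus/minus 5'-tag
signal flanking the break; a single-strand lesion (SSB) yields
one-strand-dominant signal. `endlesion` turns strand-annotated tag
positions into classified lesion calls and enrichment statistics, for
analysts studying where and why programmed or stress-induced DNA damage
recurs (for example at transcription-factor binding sites during induced
cell-state transitions).

The pipeline:

1. **Peak calling** — both strands pooled, duplicates kept, sliding
   windows tested against a genome-wide Poisson background
   (λ = tags × window / G), raw upper-tail p < 1e-5; significant windows
   merged, blacklisted regions removed.
2. **Cross-clone consensus** — peaks of clone 1 overlapping (≥ 1 bp) a
   peak of clone 2.
3. **Classification** — per peak, LR = log2((n₊+1)/(n₋+1));
   LR ∈ [−1, 1] ⇒ symmetric (DSB), otherwise asymmetric (SSB) with
   dominant strand sign(LR). Cross-clone concordance is reported as the
   Pearson r of paired log-ratios and the class-agreement fraction.
4. **Enrichment** — (a) proximity: with N = ⌊G/L̄⌋ genome slots of
   mean-peak-length size and K = ⌊|T|/L̄⌋ slots in the ±10 kb padded site
   target T, the upper-tail hypergeometric P(X ≥ k | N, K, n); validated
   by a length-preserving permutation oracle. (b) gene set: single nearest
   gene by TSS-to-midpoint distance (≤ 1000 kb), hypergeometric overlap
   with an upregulated gene set in a fixed universe.

A first-class synthetic-data module (`sim_params()`, `make_truth()`,
`simulate_endseq()`) plants lesions with known positions, classes, and
TF-site proximity, so every stage is testable without sequencing data.

## Worked example

The `analysis/` scripts run the reference desk-scale study (20 Mb genome,
200 lesions, 70% DSB, 80 tags/side, background 2e-4 tags/bp/strand, two
clones sharing lesions at 0.85):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_coverage_tracks.R
Rscript analysis/03_call_peaks.R
Rscript analysis/04_consensus_classify.R
Rscript analysis/05_enrichment.R
```

Output of the consensus/classification and enrichment stages:

```
consensus: 144 of 178/161 clone peaks
consensus classes: 98 symmetric (DSB-like) / 46 asymmetric (SSB-like)
Cross-clone concordance: 144 matched pairs
  Pearson r (log-ratios): 0.994
  class agreement: 1

proximity: 45/144 peaks (31%) within 10 kb of a TF site
Hypergeometric enrichment: k=45 of n=144 (expected 13.46; N=34951, K=3268)
  upper-tail p = 1.58e-13 (log10 p = -12.80)
permutation oracle: empirical p = 0.000999 (MC se 0.000999), model p = 1.58e-13
genes: 144 associated, 45 also upregulated
Hypergeometric enrichment: k=45 of n=144 (expected 14.40; N=2000, K=200)
  upper-tail p = 1.07e-13 (log10 p = -12.97)
```

Reading this: both clones' peak sets are dominated by the planted lesions
each clone carries; the 144 consensus peaks are the lesions shared by both
clones. The symmetric/asymmetric split recovers the planted 70/30 DSB/SSB
mix, and the two clones agree on every matched call. Proximity to TF sites
(31% observed vs 9% expected by chance) and overlap of peak-associated
genes with the upregulated set are both far beyond chance; the permutation
oracle caps its empirical p at 1/(n_perm+1), consistent with the
vanishingly small model p. Equivalent single calls: `run_pipeline()`
drives the whole chain from one config (see `validate_config()` /
`default_config()`).

The same functions accept real data: tag BED6 files (one clone per file),
a chrom.sizes table, blacklist/TF-site BEDs, a TSS table, and a gene list,
via the `input:` block of the pipeline config.

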