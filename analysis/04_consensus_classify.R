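#!/usr/bin/env Rscript
# Stage 4: cross-clone consensus and symmetric/asymmetric classification.
#
# Consensus = clone-1 peaks overlapping a clone-2 peak by >= 1 bp. Each
# consensus peak is classified from its per-strand tag counts:
# log2((plus+1)/(minus+1)) in [-1, 1] = symmetric (double-strand break),
# outside = asymmetric (single-strand) with the sign giving the dominant
# strand. Concordance compares the two clones' independent classifications.

suppressMessages(library(endlesion))

genome <- read_chrom_sizes("scratch/sim/genome.chrom.sizes")
tags <- lapply(1:2, function(r)
  read_tags(sprintf("scratch/sim/tags_clone%d.bed", r), genome))
peaks <- lapply(tags, call_peaks, genome = genome, params = caller_params())

cons <- consensus_peaks(peaks[[1]], peaks[[2]])
cat(sprintf("consensus: %d of %d/%d clone peaks\n", length(cons),
            length(peaks[[1]]), length(peaks[[2]])))

calls <- lapply(seq_along(peaks), function(r)
  classify_lesions(peaks[[r]], pseudocount = 1, band = 1))
cons_calls <- classify_lesions(peak_intensities(cons, tags[[1]]))
tab <- table(cons_calls$class)
cat(sprintf("consensus classes: %d symmetric (DSB-like) / %d asymmetric (SSB-like)\n",
            tab[["symmetric"]], tab[["asymmetric"]]))

conc <- concordance(calls[[1]], calls[[2]])
print(conc)

write_lesion_calls(cons_calls, "results/lesion_calls_consensus.tsv")
jsonlite::write_json(list(n_matched_pairs = conc$n_matched_pairs,
                          pearson_r = conc$pearson_r,
                          class_agreement = conc$class_agreement),
                     "results/concordance.json", auto_unbox = TRUE,
                     digits = NA)
cat("wrote results/lesion_calls_consensus.tsv and results/concordance.json\n")
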