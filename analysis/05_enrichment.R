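#!/usr/bin/env Rscript
# Stage 5: proximity and gene-set enrichment of the consensus lesions.
#
# Proximity: are consensus peaks within 10 kb of a TF binding site more
# often than chance? Tested with the slot-based hypergeometric model
# (genome and padded-target sizes divided by the mean peak length) and
# cross-checked with a length-preserving permutation oracle.
# Gene set: single-nearest-gene association (TSS within 1000 kb of the
# peak midpoint), then hypergeometric overlap with the upregulated set.

suppressMessages(library(endlesion))

genome <- read_chrom_sizes("scratch/sim/genome.chrom.sizes")
tags <- lapply(1:2, function(r)
  read_tags(sprintf("scratch/sim/tags_clone%d.bed", r), genome))
peaks <- lapply(tags, call_peaks, genome = genome, params = caller_params())
cons <- consensus_peaks(peaks[[1]], peaks[[2]])

tf_sites <- read_bed("results/truth/tf_sites.bed", genome)
genes <- read_tss_table("results/truth/genes.tsv", genome)
upreg <- read_gene_list("results/truth/upregulated.txt")

prox <- proximity_enrichment(cons, tf_sites, genome, window = 10000)
cat(sprintf("proximity: %d/%d peaks (%.0f%%) within 10 kb of a TF site\n",
            prox$k, prox$n, 100 * prox$fraction))
print(prox)

perm <- permutation_oracle(cons, tf_sites, genome, window = 10000,
                           n_perm = 1000, seed = 42)
cat(sprintf("permutation oracle: empirical p = %.3g (MC se %.3g), model p = %.3g\n",
            perm$p_empirical, perm$se, prox$p_upper))

assoc <- nearest_gene(cons, genes, max_dist = 1e6)
gs <- geneset_enrichment(assoc$gene_id, upreg, nrow(genes))
cat(sprintf("genes: %d associated, %d also upregulated\n",
            length(unique(assoc$gene_id)), gs$k))
print(gs)

jsonlite::write_json(list(
  proximity = prox[c("N", "K", "n", "k", "expected", "p_upper", "log10_p",
                     "fraction")],
  permutation = list(p_empirical = perm$p_empirical, se = perm$se),
  geneset = gs[c("N", "K", "n", "k", "expected", "p_upper", "log10_p")],
  associated_gene_count = length(unique(assoc$gene_id))),
  "results/enrichment.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/enrichment.json\n")
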