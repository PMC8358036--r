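#!/usr/bin/env Rscript
# Stage 1: generate the reference desk-scale study.
#
# Two 10-Mb chromosomes; 200 planted lesions (70% double-strand breaks with
# balanced plus/minus end signal, 30% single-strand lesions on one strand),
# 80 expected tags per side, Poisson background at 2e-4 tags/bp/strand, and
# two clones each carrying a lesion with probability 0.85. 30% of lesions
# are planted within 10 kb of a simulated TF binding site.
#
# Tag libraries (large) go to scratch/sim/; the ground-truth tables and a
# summary go to results/.

suppressMessages(library(endlesion))

seed <- 11L
genome <- genome_def(c("chr1", "chr2"), c(1e7, 1e7))
params <- sim_params(seed = seed)

truth <- make_truth(params, genome)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

writeLines(sprintf("%s\t%d", GenomeInfoDb::seqnames(genome),
                   GenomeInfoDb::seqlengths(genome)),
           "scratch/sim/genome.chrom.sizes")
write_truth(truth, "results/truth")

for (r in 1:2) {
  tags <- simulate_endseq(truth, r)
  write_tags(tags, sprintf("scratch/sim/tags_clone%d.bed", r))
  inc <- S4Vectors::metadata(tags)$included
  cat(sprintf("clone %d: %d tags, %d/%d lesions present\n",
              r, length(tags), sum(inc), length(inc)))
}

shared <- lesion_inclusion(truth, 1) & lesion_inclusion(truth, 2)
cat(sprintf("planted: %d lesions (%d DSB / %d SSB), %d shared by both clones\n",
            nrow(truth$lesions), sum(truth$lesions$class == "DSB"),
            sum(truth$lesions$class == "SSB"), sum(shared)))
cat(sprintf("%d TF sites; %d/%d genes upregulated\n",
            length(truth$tf_sites), length(truth$upregulated),
            nrow(truth$genes)))
cat("wrote scratch/sim/tags_clone{1,2}.bed and results/truth/\n")
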