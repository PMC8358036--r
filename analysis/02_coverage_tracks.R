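#!/usr/bin/env Rscript
# Stage 2: depth-matched, strand-resolved signal tracks.
#
# Libraries are downsampled to the shallower clone (the convention for
# comparing depth-mismatched libraries), then binned at 25 bp, smoothed
# over 75 bp, and RPKM-normalized, separately per strand. Tracks go to
# scratch/sim/ as bedGraph.

suppressMessages(library(endlesion))

genome <- read_chrom_sizes("scratch/sim/genome.chrom.sizes")
tags <- lapply(1:2, function(r)
  read_tags(sprintf("scratch/sim/tags_clone%d.bed", r), genome))

depth <- min(vapply(tags, length, integer(1)))
cat(sprintf("library sizes %s; downsampling to %d\n",
            paste(vapply(tags, length, integer(1)), collapse = "/"), depth))
tags <- lapply(seq_along(tags), function(r)
  downsample_tags(tags[[r]], depth, seed = 100L + r))

for (r in seq_along(tags)) {
  for (s in c("+", "-")) {
    tr <- make_track(tags[[r]], genome, bin_size = 25, smooth_length = 75,
                     normalization = "rpkm", strand_filter = s)
    path <- sprintf("scratch/sim/clone%d_%s.bedgraph", r,
                    if (s == "+") "plus" else "minus")
    write_bedgraph(tr, path)
    nz <- sum(unlist(tr$values) > 0)
    cat(sprintf("clone %d strand %s: %d non-zero bins -> %s\n", r, s, nz, path))
  }
}
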