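#' Simulation parameters for synthetic END-seq data
#'
#' Defaults define the package's reference desk-scale study: 200 lesions
#' (70% double-strand breaks, 30% single-strand lesions), 80 expected tags
#' per side, background 2e-4 tags/bp/strand, two clones each carrying a
#' lesion with probability 0.85, and 30% of lesions planted within 10 kb of
#' a transcription-factor binding site.
#'
#' @param n_lesions number of planted lesions.
#' @param frac_dsb fraction of lesions that are double-strand breaks.
#' @param f_prox fraction of lesions placed within `w_prox` of a TF site.
#' @param w_prox proximity window in bp.
#' @param mu expected tag count per strand side of a lesion.
#' @param resection_scale mean of the geometric tag-offset law in bp.
#' @param background_rate background tag rate, tags/bp/strand.
#' @param n_replicates number of simulated clones.
#' @param replicate_jaccard probability a lesion is present in a given clone.
#' @param n_genes number of genes in the simulated universe.
#' @param n_upregulated number of upregulated genes.
#' @param upreg_enrichment weight multiplier for genes near lesions when
#'   drawing the upregulated set (1 = uniform draw).
#' @param n_tf_sites number of TF binding-site intervals.
#' @param tf_site_width width of each TF site in bp.
#' @param min_spacing minimum distance between lesions; default `2 * w_prox`.
#' @param seed integer seed governing all randomness downstream.
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(n_lesions = 200, frac_dsb = 0.7, f_prox = 0.3,
                       w_prox = 10000, mu = 80, resection_scale = 50,
                       background_rate = 2e-4, n_replicates = 2,
                       replicate_jaccard = 0.85, n_genes = 2000,
                       n_upregulated = 200, upreg_enrichment = 8,
                       n_tf_sites = 100, tf_site_width = 400,
                       min_spacing = NULL, seed = 1L) {
  if (is.null(min_spacing)) min_spacing <- 2 * w_prox
  p <- list(n_lesions = n_lesions, frac_dsb = frac_dsb, f_prox = f_prox,
            w_prox = w_prox, mu = mu, resection_scale = resection_scale,
            background_rate = background_rate, n_replicates = n_replicates,
            replicate_jaccard = replicate_jaccard, n_genes = n_genes,
            n_upregulated = n_upregulated, upreg_enrichment = upreg_enrichment,
            n_tf_sites = n_tf_sites, tf_site_width = tf_site_width,
            min_spacing = min_spacing, seed = as.integer(seed))
  stopifnot(is_count(p$n_lesions), is_count(p$n_genes), is_count(p$n_upregulated),
            is_count(p$n_tf_sites), is_count(p$n_replicates))
  if (!is_fraction(p$frac_dsb)) stop("frac_dsb must be in [0,1]")
  if (!is_fraction(p$f_prox)) stop("f_prox must be in [0,1]")
  if (!is_fraction(p$replicate_jaccard)) stop("replicate_jaccard must be in [0,1]")
  if (p$mu < 0 || p$background_rate < 0 || p$resection_scale < 0)
    stop("rates must be >= 0")
  if (p$n_upregulated > p$n_genes) stop("n_upregulated exceeds n_genes")
  class(p) <- "sim_params"
  p
}

# edge distance (bp) from 1-bp positions to the nearest interval in a
# per-chromosome list of sorted (start, end) matrices; Inf when none.
.dist_to_sites <- function(chrom, pos, site_list) {
  vapply(seq_along(pos), function(i) {
    m <- site_list[[chrom[i]]]
    if (is.null(m) || nrow(m) == 0L) return(Inf)
    d <- pmax(0, m[, 1] - pos[i], pos[i] - m[, 2])
    min(d)
  }, numeric(1))
}

#' Plant lesions, TF sites, and a gene universe (ground truth)
#'
#' Places `n_lesions` lesion positions on the genome with a guaranteed
#' `floor(f_prox * n_lesions)` of them within `w_prox` (edge distance) of a
#' simulated TF binding site and the remainder farther than `w_prox` from
#' every site; lesions are at least `min_spacing` apart. Classes are drawn
#' Bernoulli(`frac_dsb`); single-strand lesions get a dominant strand. The
#' gene universe is generated in the same seeded stream. The whole object is
#' deterministic given (params, genome, seed).
#'
#' @param params a [sim_params()] object.
#' @param genome a `Seqinfo`.
#' @return a `sim_truth` list: `genome`, `lesions` (data.frame: chrom, pos,
#'   class, ssb_strand, intensity), `tf_sites` (`GRanges`), `genes`
#'   (data.frame: gene_id, chrom, tss, strand), `upregulated` (character),
#'   `params`.
#' @export
make_truth <- function(params, genome) {
  stopifnot(inherits(params, "sim_params"))
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  names(lens) <- chroms
  with_seed(params$seed, {
    ## TF sites: chromosome by length, start uniform
    sc <- sample(chroms, params$n_tf_sites, replace = TRUE, prob = lens)
    sstart <- floor(stats::runif(params$n_tf_sites) *
                      (lens[sc] - params$tf_site_width)) + 1
    tf_sites <- GenomicRanges::sort(GenomicRanges::GRanges(
      sc, IRanges::IRanges(sstart, width = params$tf_site_width),
      seqinfo = genome), ignore.strand = TRUE)
    site_list <- lapply(stats::setNames(as.list(chroms), chroms), function(ch) {
      s <- tf_sites[GenomicRanges::seqnames(tf_sites) == ch]
      cbind(GenomicRanges::start(s), GenomicRanges::end(s))
    })

    ## lesion placement
    n <- params$n_lesions
    n_prox <- floor(params$f_prox * n)
    is_prox <- rep(FALSE, n)
    if (n_prox > 0) is_prox[sample.int(n, n_prox)] <- TRUE
    pos <- numeric(n); chr <- character(n)
    placed <- lapply(stats::setNames(as.list(chroms), chroms),
                     function(.) numeric(0))
    tries <- 0L; max_tries <- 1000L * max(n, 1L)
    site_chr <- as.character(GenomicRanges::seqnames(tf_sites))
    for (i in seq_len(n)) {
      repeat {
        tries <- tries + 1L
        if (tries > max_tries) stop("infeasible lesion placement: genome too ",
                                    "small for n_lesions at min_spacing")
        if (is_prox[i]) {
          j <- sample.int(length(tf_sites), 1L)
          ch <- site_chr[j]
          lo <- max(1, GenomicRanges::start(tf_sites)[j] - params$w_prox)
          hi <- min(lens[ch], GenomicRanges::end(tf_sites)[j] + params$w_prox)
          cand <- floor(stats::runif(1) * (hi - lo + 1)) + lo
        } else {
          ch <- sample(chroms, 1L, prob = lens)
          cand <- floor(stats::runif(1) * lens[ch]) + 1
          if (.dist_to_sites(ch, cand, site_list) <= params$w_prox) next
        }
        if (length(placed[[ch]]) &&
            min(abs(placed[[ch]] - cand)) < params$min_spacing) next
        placed[[ch]] <- c(placed[[ch]], cand)
        pos[i] <- cand; chr[i] <- ch
        break
      }
    }

    cls <- ifelse(stats::runif(n) < params$frac_dsb, "DSB", "SSB")
    ssb_strand <- rep(".", n)
    n_ssb <- sum(cls == "SSB")
    if (n_ssb > 0)
      ssb_strand[cls == "SSB"] <- sample(c("+", "-"), n_ssb, replace = TRUE)
    lesions <- data.frame(chrom = chr, pos = pos, class = cls,
                          ssb_strand = ssb_strand,
                          intensity = rep(params$mu, n),
                          stringsAsFactors = FALSE)

    gu <- .gene_universe(params, genome, lesions)

    structure(list(genome = genome, lesions = lesions, tf_sites = tf_sites,
                   genes = gu$genes, upregulated = gu$upregulated,
                   params = params),
              class = "sim_truth")
  })
}

# gene universe; draws from the current RNG stream
.gene_universe <- function(params, genome, lesions) {
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  names(lens) <- chroms
  ng <- params$n_genes
  gc <- sample(chroms, ng, replace = TRUE, prob = lens)
  tss <- floor(stats::runif(ng) * lens[gc]) + 1
  genes <- data.frame(gene_id = sprintf("gene%05d", seq_len(ng)),
                      chrom = gc, tss = tss,
                      strand = sample(c("+", "-"), ng, replace = TRUE),
                      stringsAsFactors = FALSE)
  w <- rep(1, ng)
  if (nrow(lesions) > 0 && params$upreg_enrichment != 1) {
    les_list <- split(lesions$pos, lesions$chrom)
    near <- vapply(seq_len(ng), function(i) {
      p <- les_list[[genes$chrom[i]]]
      !is.null(p) && length(p) > 0 && min(abs(p - genes$tss[i])) <= params$w_prox
    }, logical(1))
    w[near] <- params$upreg_enrichment
  }
  up <- sample(genes$gene_id, params$n_upregulated, prob = w)
  list(genes = genes, upregulated = sort(up))
}

#' Generate a gene universe with an optionally lesion-enriched upregulated set
#'
#' TSS positions are uniform over the genome. When `upreg_enrichment > 1`
#' and lesion positions are supplied, genes whose TSS lies within `w_prox`
#' of a lesion are that many times more likely to be drawn into the
#' upregulated set, giving the downstream gene-set test real signal.
#'
#' @param params a [sim_params()] object.
#' @param genome a `Seqinfo`.
#' @param lesions optional lesion data.frame (`chrom`, `pos`) to enrich near.
#' @param seed seed; defaults to `params$seed`.
#' @return list with `genes` (data.frame) and `upregulated` (character).
#' @export
make_gene_universe <- function(params, genome, lesions = NULL, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(lesions))
    lesions <- data.frame(chrom = character(0), pos = numeric(0))
  with_seed(seed, .gene_universe(params, genome, lesions))
}

#' Which lesions are present in a given clone
#'
#' Each lesion is carried by each clone independently with probability
#' `replicate_jaccard`; the draw is pinned to the clone seed
#' (`seed XOR replicate_index`) so that [simulate_endseq()] and truth-based
#' evaluation agree on the shared set.
#'
#' @param truth a `sim_truth`.
#' @param replicate_index clone index (1-based).
#' @return logical vector over lesions.
#' @export
lesion_inclusion <- function(truth, replicate_index) {
  n <- nrow(truth$lesions)
  with_seed(derive_seed(truth$params$seed, replicate_index),
            stats::runif(n) < truth$params$replicate_jaccard)
}

#' Simulate one clone's stranded END-seq tags
#'
#' Double-strand breaks at position x emit Poisson(`mu`) plus-strand tags at
#' `x + delta` and Poisson(`mu`) minus-strand tags at `x - delta`, with
#' `delta >= 0` geometric with mean `resection_scale` (independent per tag);
#' single-strand lesions emit tags on their dominant strand only, same
#' offset law. Background is a homogeneous Poisson process per strand at
#' `background_rate`. Deterministic given (truth, replicate_index).
#'
#' @param truth a `sim_truth` from [make_truth()].
#' @param replicate_index clone index (1-based).
#' @return sorted width-1 `GRanges` of tags; `S4Vectors::metadata()` carries
#'   `included` (logical over truth lesions) and `replicate`.
#' @export
simulate_endseq <- function(truth, replicate_index = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  params <- truth$params
  genome <- truth$genome
  chroms <- GenomeInfoDb::seqnames(genome)
  lens <- as.numeric(GenomeInfoDb::seqlengths(genome))
  names(lens) <- chroms
  gprob <- 1 / (1 + params$resection_scale)  # geometric mean = resection_scale
  include <- lesion_inclusion(truth, replicate_index)

  with_seed(derive_seed(params$seed, replicate_index), {
    stats::runif(nrow(truth$lesions))  # consume the inclusion draws
    les <- truth$lesions[include, , drop = FALSE]
    chr <- character(0); pos <- numeric(0); std <- character(0)
    if (nrow(les) > 0) {
      for (i in seq_len(nrow(les))) {
        x <- les$pos[i]; ch <- les$chrom[i]; mu <- les$intensity[i]
        if (les$class[i] == "DSB") {
          np <- stats::rpois(1, mu); nm <- stats::rpois(1, mu)
          pp <- x + stats::rgeom(np, gprob)
          pm <- x - stats::rgeom(nm, gprob)
          chr <- c(chr, rep(ch, np + nm))
          pos <- c(pos, pp, pm)
          std <- c(std, rep("+", np), rep("-", nm))
        } else {
          nt <- stats::rpois(1, mu)
          off <- stats::rgeom(nt, gprob)
          pt <- if (les$ssb_strand[i] == "+") x + off else x - off
          chr <- c(chr, rep(ch, nt))
          pos <- c(pos, pt)
          std <- c(std, rep(les$ssb_strand[i], nt))
        }
      }
    }
    ## background: homogeneous Poisson per chromosome per strand
    for (ch in chroms) {
      for (s in c("+", "-")) {
        nb <- stats::rpois(1, params$background_rate * lens[ch])
        if (nb > 0) {
          chr <- c(chr, rep(ch, nb))
          pos <- c(pos, floor(stats::runif(nb) * lens[ch]) + 1)
          std <- c(std, rep(s, nb))
        }
      }
    }
    pos <- pmin(pmax(pos, 1), lens[chr])
    tags <- make_tags(chr, pos, std, genome)
    S4Vectors::metadata(tags)$included <- include
    S4Vectors::metadata(tags)$replicate <- replicate_index
    tags
  })
}

#' Write ground truth to plain-text files
#'
#' Writes `lesions.tsv`, `genes.tsv`, `upregulated.txt`, and `tf_sites.bed`
#' under `dir`.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(truth$lesions, file.path(dir, "lesions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(truth$upregulated, file.path(dir, "upregulated.txt"))
  write_bed(truth$tf_sites, file.path(dir, "tf_sites.bed"))
  invisible(dir)
}

#' Read a gene TSS table (gene_id, chrom, tss, strand TSV)
#' @param path TSV with header columns gene_id, chrom, tss, strand.
#' @param genome optional `Seqinfo` for bounds checking.
#' @return data.frame.
#' @export
read_tss_table <- function(path, genome = NULL) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss")
  if (!all(need %in% names(g)))
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  if (!is.null(genome)) {
    lens <- GenomeInfoDb::seqlengths(genome)[g$chrom]
    if (any(is.na(lens)) || any(g$tss < 1) || any(g$tss > lens))
      stop("TSS outside genome bounds")
  }
  g
}

#' Read a one-id-per-line gene list
#' @param path text file.
#' @return character vector (unique, sorted).
#' @export
read_gene_list <- function(path) {
  sort(unique(readLines(path)))
}
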