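#' Read a UCSC chrom.sizes file
#'
#' Parses a two-column whitespace-delimited table of chromosome names and
#' lengths into a [GenomeInfoDb::Seqinfo] object, the genome definition used
#' throughout the package. Input order is preserved.
#'
#' @param path path to a chrom.sizes file.
#' @return a `Seqinfo` with one entry per chromosome.
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1\t1000", "chr2\t500"), tf)
#' g <- read_chrom_sizes(tf)
#' genome_size(g)  # 1500
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no chromosomes in ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 2L || is.na(suppressWarnings(as.numeric(f[2]))))
      stop("malformed chrom.sizes line ", i, ": '", lines[i], "'")
  }
  nm <- vapply(fields, `[`, character(1), 1L)
  len <- as.numeric(vapply(fields, `[`, character(1), 2L))
  if (anyDuplicated(nm)) stop("duplicate chromosome name: ", nm[duplicated(nm)][1])
  if (any(len <= 0)) stop("non-positive chromosome length for ", nm[len <= 0][1])
  genome_def(nm, len)
}

#' Construct a genome definition
#'
#' @param chroms character vector of chromosome names (unique).
#' @param lengths numeric vector of chromosome lengths in bp (> 0).
#' @return a [GenomeInfoDb::Seqinfo].
#' @export
genome_def <- function(chroms, lengths) {
  stopifnot(length(chroms) == length(lengths))
  if (anyDuplicated(chroms)) stop("duplicate chromosome name")
  if (any(lengths <= 0)) stop("non-positive chromosome length")
  GenomeInfoDb::Seqinfo(seqnames = as.character(chroms),
                        seqlengths = as.integer(lengths))
}

#' Total genome size in bp
#' @param genome a `Seqinfo`.
#' @return numeric total length.
#' @export
genome_size <- function(genome) {
  sum(as.numeric(GenomeInfoDb::seqlengths(genome)))
}

#' Read a BED3/BED6 file into a validated, sorted GRanges
#'
#' Intervals are validated against the genome: zero- or negative-width
#' records are an error, records on chromosomes absent from the genome are
#' skipped with a warning (or raise an error), and out-of-bounds records are
#' rejected by default or clipped on request.
#'
#' @param path BED file path.
#' @param genome optional `Seqinfo`; when supplied, coordinates are checked
#'   against it and the result carries its seqinfo.
#' @param on_unknown `"skip"` (warn and drop) or `"error"` for records on
#'   chromosomes not in `genome`.
#' @param clip clip out-of-bounds intervals to the chromosome instead of
#'   erroring.
#' @return a sorted `GRanges`.
#' @export
read_bed <- function(path, genome = NULL, on_unknown = c("skip", "error"),
                     clip = FALSE) {
  on_unknown <- match.arg(on_unknown)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("BED parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (any(GenomicRanges::width(gr) < 1))
    stop("BED record with start >= end in ", path)
  if (!is.null(genome)) {
    known <- as.character(GenomicRanges::seqnames(gr)) %in%
      GenomeInfoDb::seqnames(genome)
    if (!all(known)) {
      bad <- unique(as.character(GenomicRanges::seqnames(gr))[!known])
      if (on_unknown == "error")
        stop("unknown chromosome(s) in ", path, ": ", paste(bad, collapse = ", "))
      warning("skipping ", sum(!known), " record(s) on unknown chromosome(s): ",
              paste(bad, collapse = ", "))
      gr <- gr[known]
    }
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
    lens <- GenomeInfoDb::seqlengths(genome)[
      as.character(GenomicRanges::seqnames(gr))]
    oob <- GenomicRanges::start(gr) < 1 | GenomicRanges::end(gr) > lens
    if (any(oob)) {
      if (!clip) stop("out-of-bounds interval in ", path)
      gr <- gr[!oob | GenomicRanges::start(gr) <= lens]
      GenomicRanges::start(gr) <- pmax(GenomicRanges::start(gr), 1L)
      GenomicRanges::end(gr) <- pmin(
        GenomicRanges::end(gr),
        GenomeInfoDb::seqlengths(genome)[as.character(GenomicRanges::seqnames(gr))])
    }
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges to BED
#'
#' BED6 when name/score/strand information is present; round-trips through
#' [read_bed()] up to float formatting of scores.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Load stranded END-seq tags from a BED6 file
#'
#' Each BED record is reduced to its 5' end (plus strand: interval start;
#' minus strand: interval end), the position the end-capture assay actually
#' measures. The result is a width-1 `GRanges` with strand, the tag container
#' consumed by the rest of the pipeline.
#'
#' @param path BED6 file of read intervals or pre-reduced tag positions.
#' @param genome a `Seqinfo`.
#' @return sorted width-1 `GRanges` with strand `+`/`-`.
#' @export
read_tags <- function(path, genome) {
  gr <- read_bed(path, genome)
  std <- as.character(GenomicRanges::strand(gr))
  if (any(std == "*"))
    stop("tag BED must be stranded (BED6 with +/- in column 6)")
  pos <- ifelse(std == "+", GenomicRanges::start(gr), GenomicRanges::end(gr))
  tg <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                               IRanges::IRanges(pos, width = 1L),
                               strand = std, seqinfo = genome)
  GenomicRanges::sort(tg, ignore.strand = TRUE)
}

#' Construct a stranded tag set from positions
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based tag positions.
#' @param strand character vector of `+`/`-`.
#' @param genome a `Seqinfo`.
#' @return sorted width-1 `GRanges`.
#' @export
make_tags <- function(chrom, pos, strand, genome) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(strand))
  lens <- GenomeInfoDb::seqlengths(genome)[chrom]
  if (length(pos) && (any(pos < 1) || any(pos > lens)))
    stop("tag position outside chromosome bounds")
  tg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               strand = strand, seqinfo = genome)
  GenomicRanges::sort(tg, ignore.strand = TRUE)
}

#' Write stranded tags as BED6 (one line per tag)
#' @param tags width-1 `GRanges` with strand.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  out <- tags
  S4Vectors::mcols(out)$name <- "tag"
  S4Vectors::mcols(out)$score <- 0
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
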