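#' Default pipeline configuration (simulated desk-scale study)
#'
#' Two 10-Mb chromosomes, the [sim_params()] defaults, and conventional
#' caller/classifier/enrichment settings.
#'
#' @param seed top-level seed.
#' @return a validated config list.
#' @export
default_config <- function(seed = 1L) {
  validate_config(list(
    seed = as.integer(seed),
    simulation = list(genome = list(chr1 = 1e7, chr2 = 1e7))))
}

.allowed_keys <- list(
  top = c("seed", "outdir", "simulation", "input", "caller", "classify",
          "enrichment", "consensus"),
  simulation = c("genome", "n_lesions", "frac_dsb", "f_prox", "w_prox", "mu",
                 "resection_scale", "background_rate", "n_replicates",
                 "replicate_jaccard", "n_genes", "n_upregulated",
                 "upreg_enrichment", "n_tf_sites", "tf_site_width",
                 "min_spacing", "seed"),
  input = c("chrom_sizes", "tags", "blacklist", "tf_sites", "genes",
            "upregulated"),
  caller = c("window", "step", "p_threshold", "min_gap", "min_length"),
  classify = c("pseudocount", "band"),
  enrichment = c("window", "max_gene_dist", "population"),
  consensus = c("min_overlap"))

.check_keys <- function(x, where) {
  bad <- setdiff(names(x), .allowed_keys[[where]])
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "))
}

.fill <- function(x, defaults) {
  for (k in names(defaults)) if (is.null(x[[k]])) x[[k]] <- defaults[[k]]
  x
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list. Exactly one of a `simulation` block
#' or an `input` block (paths to real data files) must be present; unknown
#' keys are rejected; defaults are filled; referenced files must exist.
#'
#' @param config YAML path or config list.
#' @return normalized config list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML file path")
  .check_keys(config, "top")
  if (is.null(config$seed)) stop("config requires a seed")
  if (!is_count(config$seed)) stop("seed must be a non-negative integer")
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    stop("config must contain exactly one of 'simulation' or 'input'")

  if (has_sim) {
    .check_keys(config$simulation, "simulation")
    if (is.null(config$simulation$genome))
      stop("simulation block requires a genome (named chromosome lengths)")
    sp <- config$simulation
    sp$genome <- NULL
    sp$seed <- config$seed
    defaults <- unclass(do.call(sim_params, sp))
    config$simulation <- c(list(genome = config$simulation$genome), defaults)
  } else {
    .check_keys(config$input, "input")
    need <- c("chrom_sizes", "tags", "tf_sites", "genes", "upregulated")
    miss <- setdiff(need, names(config$input))
    if (length(miss))
      stop("input block missing: ", paste(miss, collapse = ", "))
    paths <- c(config$input$chrom_sizes, unlist(config$input$tags),
               config$input$blacklist, config$input$tf_sites,
               config$input$genes, config$input$upregulated)
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }

  config$caller <- .fill(config$caller, list(window = 200, step = 50,
                                             p_threshold = 1e-5,
                                             min_gap = 100, min_length = 50))
  .check_keys(config$caller, "caller")
  if (config$caller$window <= 0) stop("caller window must be positive")
  do.call(caller_params, config$caller)  # full validation

  config$classify <- .fill(config$classify, list(pseudocount = 1, band = 1))
  .check_keys(config$classify, "classify")
  if (config$classify$pseudocount <= 0) stop("pseudocount must be > 0")

  config$enrichment <- .fill(config$enrichment,
                             list(window = 10000, max_gene_dist = 1e6,
                                  population = NULL))
  .check_keys(config$enrichment, "enrichment")
  if (config$enrichment$window < 0) stop("enrichment window must be >= 0")

  config$consensus <- .fill(config$consensus, list(min_overlap = 1))
  .check_keys(config$consensus, "consensus")

  class(config) <- "pipeline_config"
  config
}

#' Fingerprint of the semantic config fields
#' @param config a validated config.
#' @return hex string.
#' @export
config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL  # output location is not semantic
  sprintf("%08x", str_hash32(as.character(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))))
}

.log_stage <- function(lines, stage, t0, msg) {
  line <- sprintf("[%s] %.2fs %s", stage,
                  as.numeric(Sys.time()) - t0, msg)
  message(line)
  c(lines, line)
}

#' Run the full lesion-mapping pipeline
#'
#' Stages: (optional) simulation -> per-clone peak calling -> blacklist
#' filtering -> cross-clone consensus -> lesion classification ->
#' concordance -> proximity and gene-set enrichment. Deterministic given
#' the config and its seed. When `outdir` is set, all intermediates (tag
#' BEDs, truth TSVs, peak tables, consensus BED, lesion-call TSVs), a
#' `report.json`, and a `run.log` are written.
#'
#' @param config a config list/path (see [validate_config()]).
#' @param outdir optional output directory.
#' @return a `run_report` list (stage counts, concordance, enrichment,
#'   config hash); when simulating, the attribute `"state"` holds the truth
#'   and intermediate objects for programmatic inspection.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- validate_config(config)
  if (is.null(outdir)) outdir <- cfg$outdir
  t0 <- as.numeric(Sys.time())
  logl <- character(0)

  ## --- inputs -------------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    genome <- genome_def(names(cfg$simulation$genome),
                         unlist(cfg$simulation$genome))
    sp_args <- cfg$simulation
    sp_args$genome <- NULL
    params <- do.call(sim_params, sp_args)
    truth <- make_truth(params, genome)
    tags <- lapply(seq_len(params$n_replicates),
                   function(r) simulate_endseq(truth, r))
    tf_sites <- truth$tf_sites
    genes <- truth$genes
    upregulated <- truth$upregulated
    blacklist <- GenomicRanges::GRanges(seqinfo = genome)
    logl <- .log_stage(logl, "simulate", t0,
                       sprintf("%d lesions, %d clones, %s tags",
                               nrow(truth$lesions), length(tags),
                               paste(vapply(tags, length, integer(1)),
                                     collapse = "/")))
  } else {
    genome <- read_chrom_sizes(cfg$input$chrom_sizes)
    truth <- NULL
    tags <- lapply(unlist(cfg$input$tags), read_tags, genome = genome)
    tf_sites <- read_bed(cfg$input$tf_sites, genome)
    genes <- read_tss_table(cfg$input$genes, genome)
    upregulated <- read_gene_list(cfg$input$upregulated)
    blacklist <- if (!is.null(cfg$input$blacklist))
      read_bed(cfg$input$blacklist, genome)
    else GenomicRanges::GRanges(seqinfo = genome)
    logl <- .log_stage(logl, "load", t0,
                       sprintf("%d clones, %s tags", length(tags),
                               paste(vapply(tags, length, integer(1)),
                                     collapse = "/")))
  }

  ## --- peak calling + blacklist -------------------------------------------
  cp <- do.call(caller_params, cfg$caller)
  raw_peaks <- lapply(tags, call_peaks, genome = genome, params = cp)
  peaks <- lapply(raw_peaks, filter_blacklist, blacklist = blacklist)
  removed <- vapply(raw_peaks, length, integer(1)) -
    vapply(peaks, length, integer(1))
  logl <- .log_stage(logl, "peaks", t0,
                     sprintf("peaks per clone: %s (blacklist removed %s)",
                             paste(vapply(peaks, length, integer(1)),
                                   collapse = "/"),
                             paste(removed, collapse = "/")))

  ## --- consensus ------------------------------------------------------------
  consensus <- if (length(peaks) >= 2)
    consensus_peaks(peaks[[1]], peaks[[2]],
                    min_overlap = cfg$consensus$min_overlap)
  else peaks[[1]]
  logl <- .log_stage(logl, "consensus", t0,
                     sprintf("%d consensus peaks", length(consensus)))

  ## --- classification -------------------------------------------------------
  pc <- cfg$classify
  calls <- lapply(peaks, classify_lesions, pseudocount = pc$pseudocount,
                  band = pc$band)
  cons_calls <- classify_lesions(peak_intensities(consensus, tags[[1]]),
                                 pseudocount = pc$pseudocount, band = pc$band)
  tallies <- table(factor(cons_calls$class, c("symmetric", "asymmetric")))
  conc <- if (length(calls) >= 2) concordance(calls[[1]], calls[[2]]) else NULL
  logl <- .log_stage(logl, "classify", t0,
                     sprintf("consensus classes: %d symmetric / %d asymmetric",
                             tallies[["symmetric"]], tallies[["asymmetric"]]))

  ## --- enrichment ------------------------------------------------------------
  prox <- if (length(consensus) > 0 && length(tf_sites) > 0)
    proximity_enrichment(consensus, tf_sites, genome,
                         window = cfg$enrichment$window)
  else NULL
  assoc <- nearest_gene(consensus, genes,
                        max_dist = cfg$enrichment$max_gene_dist)
  popN <- if (!is.null(cfg$enrichment$population)) cfg$enrichment$population
  else nrow(genes)
  gs <- geneset_enrichment(assoc$gene_id, upregulated, popN)
  logl <- .log_stage(logl, "enrich", t0,
                     sprintf("proximity k/n = %s; %d associated genes",
                             if (is.null(prox)) "NA" else
                               sprintf("%d/%d", prox$k, prox$n),
                             length(unique(assoc$gene_id))))

  report <- list(
    package_version = as.character(utils::packageVersion("endlesion")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    counts = list(
      tags_per_clone = vapply(tags, length, integer(1)),
      peaks_per_clone = vapply(peaks, length, integer(1)),
      blacklist_removed = removed,
      consensus_size = length(consensus),
      class_tallies = as.list(tallies)),
    concordance = if (is.null(conc)) NULL else list(
      n_matched_pairs = conc$n_matched_pairs,
      pearson_r = conc$pearson_r,
      class_agreement = conc$class_agreement),
    enrichment = list(
      proximity = if (is.null(prox)) NULL else
        prox[c("N", "K", "n", "k", "expected", "p_upper", "log10_p",
               "fraction")],
      geneset = gs[c("N", "K", "n", "k", "expected", "p_upper", "log10_p")],
      associated_gene_count = length(unique(assoc$gene_id))))
  class(report) <- "run_report"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_along(tags))
      write_tags(tags[[r]], file.path(outdir, sprintf("tags_clone%d.bed", r)))
    if (!is.null(truth)) write_truth(truth, file.path(outdir, "truth"))
    for (r in seq_along(calls)) {
      write_peaks(peaks[[r]], file.path(outdir,
                                        sprintf("peaks_clone%d.tsv", r)))
      write_lesion_calls(calls[[r]],
                         file.path(outdir, sprintf("lesions_clone%d.tsv", r)))
    }
    write_bed(GenomicRanges::granges(consensus),
              file.path(outdir, "consensus.bed"))
    write_lesion_calls(cons_calls, file.path(outdir, "lesions_consensus.tsv"))
    jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    writeLines(logl, file.path(outdir, "run.log"))
  }

  attr(report, "state") <- list(genome = genome, truth = truth, tags = tags,
                                peaks = peaks, consensus = consensus,
                                calls = calls, consensus_calls = cons_calls,
                                concordance = conc, proximity = prox,
                                geneset = gs, associations = assoc)
  report
}
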