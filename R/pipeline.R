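# End-to-end pipeline driver: simulate -> detect -> index -> motif ->
# structure, one run directory, one manifest, one seed.

#' Pipeline configuration
#'
#' Either supply a [sim_config()] (synthetic run) or paths to an
#' existing genome FASTA plus RNA/DNA SAM files. Stage seeds are derived
#' deterministically from the one top-level seed.
#'
#' @param outdir Run directory (created if missing).
#' @param seed Top-level integer seed.
#' @param sim Optional [sim_config()]; its seed is overridden by `seed`.
#' @param genome_path,rna_path,dna_path Input paths when `sim` is NULL.
#' @param detection A [detection_params()].
#' @param flank Structure window flank (bp).
#' @param temperatures_c Temperatures (Celsius) for the structure stage;
#'   converted internally as K = C + 273.15.
#' @param max_structure_sites Structure stage folds at most this many
#'   sites (seeded subsample) to keep runs desk-scale.
#' @param motif_k Motif flank size.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = NULL,
                            genome_path = NULL, rna_path = NULL,
                            dna_path = NULL,
                            detection = detection_params(),
                            flank = 400L, temperatures_c = 30,
                            max_structure_sites = 200L, motif_k = 1L) {
  if (is.null(sim)) {
    for (p in c(genome_path, rna_path, dna_path))
      if (is.null(p) || !file.exists(p))
        stop("invalid config: missing input path ", p %||% "(NULL)")
  }
  if (any(!is.finite(temperatures_c)))
    stop("invalid config: temperatures must be finite")
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 genome_path = genome_path, rna_path = rna_path,
                 dna_path = dna_path, detection = detection,
                 flank = flank, temperatures_c = temperatures_c,
                 max_structure_sites = max_structure_sites,
                 motif_k = motif_k),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> pileup/detection -> editing index ->
#' motif -> per-temperature substructure dG, writing every stage output
#' plus a JSON manifest (inputs, parameters, seed, per-stage row counts
#' and md5 checksums) under the run directory. Re-running with the same
#' configuration and seed reproduces identical site tables and indexes.
#'
#' @param config A [pipeline_config()].
#' @return The run report (manifest contents), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("editscan")))
  res <- try({
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- config$seed
      genome <- generate_genome(sim)
      planted <- plant_editing_sites(genome, sim)
      genome <- planted$genome
      truth <- planted$truth
      rna <- simulate_reads(genome, truth, sim)
      dna <- simulate_dna_reads(genome, sim)
      write_genome_fasta(genome, file.path(outdir, "genome.fa"))
      write_truth_table(truth, file.path(outdir, "truth.tsv"))
      write_sam(rna, genome, file.path(outdir, "rna.sam"))
      write_fastq(rna, file.path(outdir, "rna.fastq"))
      write_sam(dna, genome, file.path(outdir, "dna.sam"))
      report$simulate <- list(contigs = length(genome),
                              genome_bp = sum(Biostrings::width(genome)),
                              n_truth_sites = nrow(truth),
                              n_rna_reads = nrow(rna),
                              n_dna_reads = nrow(dna))
    } else {
      genome <- read_genome_fasta(config$genome_path)
      rna <- read_sam(config$rna_path)
      dna <- read_sam(config$dna_path)
      report$simulate <- list(skipped = TRUE)
    }

    stage <- "detect"
    bq <- config$detection$base_quality_min
    rna_pile <- build_pileup(rna, genome, bq)
    dna_pile <- build_pileup(dna, genome, bq)
    sites <- detect_sites(rna_pile, dna_pile, genome, config$detection)
    write_site_table(sites, file.path(outdir, "sites.tsv"))
    report$detect <- list(n_sites = nrow(sites),
                          spectrum = as.list(mismatch_spectrum(sites)$counts))

    stage <- "index"
    idx <- editing_index(rna_pile, genome)
    write.table(idx$per_class, file.path(outdir, "index.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$index <- list(index_percent = idx$index,
                         numerator = idx$numerator,
                         denominator = idx$denominator)

    stage <- "motif"
    motif <- neighbor_motif(sites, genome, config$motif_k)
    mm <- data.frame(offset = rownames(motif$freq), motif$freq,
                     check.names = FALSE)
    write.table(mm, file.path(outdir, "motif.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$motif <- list(n_sites = motif$n_sites,
                         n_skipped = motif$n_skipped)

    stage <- "structure"
    set.seed(config$seed + 17L)
    use <- sites
    if (nrow(use) > config$max_structure_sites)
      use <- use[sort(sample.int(nrow(use), config$max_structure_sites)), ]
    model <- energy_model()
    report$structure <- list()
    for (tc in config$temperatures_c) {
      tk <- tc + 273.15
      dg <- site_structure_dG(genome, use, config$flank, tk, model)
      f <- file.path(outdir, sprintf("structure_%gC.tsv", tc))
      write.table(dg, f, sep = "\t", quote = FALSE, row.names = FALSE)
      report$structure[[sprintf("%gC", tc)]] <-
        list(n_sites = nrow(dg),
             median_dG = if (nrow(dg)) median(dg$dG) else NA_real_)
    }
    TRUE
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    report$failed_stage <- stage
    report$error <- attr(res, "condition")$message
    jsonlite::write_json(report, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ", report$error)
  }
  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  report$checksums <- as.list(stats::setNames(
    unname(tools::md5sum(outputs)), basename(outputs)))
  jsonlite::write_json(report, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
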