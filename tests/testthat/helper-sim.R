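# shared fixture builders: everything is generated in code at test time

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(seed = 101L, contig_lengths = 5000L, n_sites = 20L,
                   coverage = 30, dna_coverage = 30, read_length = 50L,
                   error_rate = 0)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# build a read_set data frame by hand (Q30 unless stated)
manual_reads <- function(seqs, pos0, contig = "contig01", flag = 0L,
                         qual = NULL) {
  n <- length(seqs)
  data.frame(qname = sprintf("r%03d", seq_len(n)),
             flag = rep_len(flag, n), contig = rep_len(contig, n),
             pos0 = pos0, seq = seqs,
             qual = qual %||% strrep("?", nchar(seqs)),  # "?" = Q30
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_genome <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("contig%02d", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

# a site table row as detect_sites() would emit it
manual_sites <- function(contig, position, ref, class,
                         level = 0.5, depth = 20L) {
  n <- length(position)
  level <- rep_len(level, n); depth <- rep_len(depth, n)
  data.frame(contig = rep_len(contig, n), position = position,
             ref = rep_len(ref, n), class = rep_len(class, n),
             depth = depth, alt_count = as.integer(round(level * depth)),
             level = level, stringsAsFactors = FALSE)
}

# end-to-end simulation bundle
simulate_bundle <- function(cfg) {
  g <- generate_genome(cfg)
  pl <- plant_editing_sites(g, cfg)
  rna <- simulate_reads(pl$genome, pl$truth, cfg)
  dna <- simulate_dna_reads(pl$genome, cfg)
  list(cfg = cfg, genome = pl$genome, truth = pl$truth, rna = rna,
       dna = dna,
       rna_pile = build_pileup(rna, pl$genome),
       dna_pile = build_pileup(dna, pl$genome))
}
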