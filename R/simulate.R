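# Synthetic-data module: genomes, planted A-to-I sites, truth-aligned reads.
#
# All randomness flows from a single integer seed in the configuration;
# each generation stage re-seeds with a fixed offset of that seed so the
# stages are individually reproducible.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults
#' describe a small yeast-like experiment: a GC-poor genome (yeast is
#' ~38% GC), editing levels skewed over (0,1], 75 bp single-end
#' unstranded reads (a typical NextSeq short-read design), uniform
#' per-base sequencing error, and matched unedited DNA-seq coverage.
#'
#' @param seed Integer seed; fixes every downstream byte.
#' @param contig_lengths Integer vector of contig lengths (bp), all > 0.
#' @param gc_content Genome GC fraction in \[0,1\];
#'   P(G)=P(C)=gc/2, P(A)=P(T)=(1-gc)/2, i.i.d. bases.
#' @param n_sites Number of editing sites to plant.
#' @param level_distribution Per-site editing-level law. A list with
#'   `kind` one of `"uniform"` (`lo`, `hi`), `"twopoint"` (`values`,
#'   `probs`), `"constant"` (`value`) or `"beta"` (`shape1`, `shape2`).
#' @param motif_bias Probability in \[0,1\] that a candidate site whose
#'   5' neighbour (on the site's strand) is G is rejected and resampled,
#'   mimicking the upstream-G depletion of the ADAR motif.
#' @param hairpin_fraction Fraction of sites embedded mid-arm in planted
#'   inverted repeats (confidently foldable hairpins).
#' @param coverage Mean RNA-seq depth (x).
#' @param read_length Read length in bp; must not exceed the shortest
#'   contig.
#' @param error_rate Per-base substitution error `e` in \[0,1); each
#'   erroneous base is replaced by one of the three alternatives with
#'   equal probability `e/3`.
#' @param dna_coverage Mean DNA-seq depth (x).
#' @param base_quality Fixed Phred quality written for every base.
#' @param hairpin_arm,hairpin_loop Arm and loop lengths (bp) of planted
#'   hairpins.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       contig_lengths = 50000L,
                       gc_content = 0.38,
                       n_sites = 500L,
                       level_distribution = list(kind = "uniform",
                                                 lo = 0.05, hi = 0.9),
                       motif_bias = 0,
                       hairpin_fraction = 0,
                       coverage = 50,
                       read_length = 75L,
                       error_rate = 0.001,
                       dna_coverage = 50,
                       base_quality = 30L,
                       hairpin_arm = 30L,
                       hairpin_loop = 10L) {
  contig_lengths <- as.integer(contig_lengths)
  if (length(contig_lengths) == 0L || any(contig_lengths <= 0L))
    stop("invalid config: contig_lengths must be positive integers")
  if (gc_content < 0 || gc_content > 1)
    stop("invalid config: gc_content must be in [0,1]")
  if (error_rate < 0 || error_rate >= 1)
    stop("invalid config: error_rate must be in [0,1)")
  if (read_length > min(contig_lengths))
    stop("invalid config: read_length exceeds the shortest contig")
  if (n_sites < 0)
    stop("invalid config: n_sites must be non-negative")
  if (motif_bias < 0 || motif_bias > 1 ||
      hairpin_fraction < 0 || hairpin_fraction > 1)
    stop("invalid config: motif_bias and hairpin_fraction must be in [0,1]")
  structure(list(seed = as.integer(seed),
                 contig_lengths = contig_lengths,
                 gc_content = gc_content,
                 n_sites = as.integer(n_sites),
                 level_distribution = level_distribution,
                 motif_bias = motif_bias,
                 hairpin_fraction = hairpin_fraction,
                 coverage = coverage,
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 dna_coverage = dna_coverage,
                 base_quality = as.integer(base_quality),
                 hairpin_arm = as.integer(hairpin_arm),
                 hairpin_loop = as.integer(hairpin_loop)),
            class = "sim_config")
}

.draw_levels <- function(n, law) {
  kind <- law$kind %||% "uniform"
  lv <- switch(kind,
    uniform  = runif(n, law$lo, law$hi),
    twopoint = sample(law$values, n, replace = TRUE, prob = law$probs),
    constant = rep(law$value, n),
    beta     = rbeta(n, law$shape1, law$shape2),
    stop("unknown level_distribution kind: ", kind))
  if (any(lv <= 0) || any(lv > 1))
    stop("level_distribution produced levels outside (0,1]")
  lv
}

#' Generate a random genome
#'
#' Bases are i.i.d. with the configured GC content. Contigs are named
#' `contig01`, `contig02`, ...
#'
#' @param config A [sim_config()].
#' @return A [Biostrings::DNAStringSet] (FASTA-writable).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gc <- config$gc_content
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- vapply(config$contig_lengths, function(L) {
    paste(sample(BASES, L, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("contig%02d", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

# split a genome into per-contig character vectors of single bases
.contig_chars <- function(genome) {
  lapply(as.character(genome), function(s) strsplit(s, "", fixed = TRUE)[[1]])
}

#' Plant editing sites (and optional hairpin substrates) in a genome
#'
#' Sites are distinct adenosine positions counted on both strands
#' (reference A on '+', reference T on '-'). With probability
#' `motif_bias` a candidate whose 5' neighbour on its own strand is G is
#' rejected and redrawn. A `hairpin_fraction` of sites is embedded
#' mid-arm in inverted repeats written into the genome *before* site
#' selection, so the returned genome may differ from the input.
#'
#' @param genome A `DNAStringSet`.
#' @param config A [sim_config()].
#' @return A list with elements `genome` (possibly modified
#'   `DNAStringSet`) and `truth`, a data frame with columns `contig`,
#'   `position` (0-based), `strand`, `level` and `in_hairpin`. Every
#'   recorded position carries reference base A on its recorded strand.
#' @export
plant_editing_sites <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  chars <- .contig_chars(genome)
  contigs <- names(genome)
  lens <- lengths(chars)
  n_sites <- config$n_sites
  if (n_sites == 0L) {
    truth <- data.frame(contig = character(0), position = integer(0),
                        strand = character(0), level = numeric(0),
                        in_hairpin = logical(0), stringsAsFactors = FALSE)
    return(list(genome = genome, truth = truth))
  }

  n_hp <- round(config$hairpin_fraction * n_sites)
  hp_rows <- NULL
  hp_mask <- lapply(lens, function(L) logical(L))  # genome bp inside hairpins
  if (n_hp > 0L) {
    arm <- config$hairpin_arm; loop <- config$hairpin_loop
    span <- 2L * arm + loop
    mid <- arm %/% 2L + 1L
    placed <- 0L; tries <- 0L
    hp_list <- vector("list", n_hp)
    while (placed < n_hp) {
      tries <- tries + 1L
      if (tries > 100L * n_hp)
        stop("infeasible config: could not place requested hairpins")
      ci <- sample.int(length(contigs), 1L, prob = lens)
      if (lens[ci] < span + 2L) next
      start <- sample.int(lens[ci] - span + 1L, 1L)  # 1-based
      if (any(hp_mask[[ci]][start:(start + span - 1L)])) next
      arm1 <- sample(BASES, arm, replace = TRUE)
      arm1[mid] <- "A"
      lp <- sample(BASES, loop, replace = TRUE)
      arm2 <- rev(comp_base(arm1))
      chars[[ci]][start:(start + span - 1L)] <- c(arm1, lp, arm2)
      hp_mask[[ci]][start:(start + span - 1L)] <- TRUE
      placed <- placed + 1L
      hp_list[[placed]] <- data.frame(contig = contigs[ci],
                                      position = start + mid - 2L,  # 0-based
                                      strand = "+", in_hairpin = TRUE,
                                      stringsAsFactors = FALSE)
    }
    hp_rows <- do.call(rbind, hp_list)
  }

  # candidate adenosines outside hairpin regions, both strands; up_g
  # flags a G immediately 5' of the site on the site's own strand
  cand <- do.call(rbind, lapply(seq_along(contigs), function(ci) {
    cc <- chars[[ci]]
    free <- !hp_mask[[ci]]
    pa <- which(cc == "A" & free)   # 1-based
    pt <- which(cc == "T" & free)
    up_a <- pa > 1L & c("X", cc)[pa] == "G"          # base at pa - 1
    up_t <- pt < length(cc) & c(cc, "X")[pt + 1L] == "C"  # base at pt + 1
    data.frame(ci = ci,
               position = c(pa, pt) - 1L,
               strand = rep(c("+", "-"), c(length(pa), length(pt))),
               up_g = c(up_a, up_t),
               stringsAsFactors = FALSE)
  }))
  n_rand <- n_sites - n_hp
  if (n_rand > nrow(cand))
    stop("infeasible config: n_sites exceeds available adenosine positions")

  chosen <- integer(0)
  if (n_rand > 0L) {
    up_g <- cand$up_g
    taken <- logical(nrow(cand))
    while (length(chosen) < n_rand) {
      need <- n_rand - length(chosen)
      avail <- which(!taken)
      if (length(avail) == 0L)
        stop("infeasible config: candidate adenosines exhausted")
      draw <- if (length(avail) == 1L) avail else
        sample(avail, min(length(avail), 2L * need))
      rej <- up_g[draw] & (runif(length(draw)) < config$motif_bias)
      keep <- draw[!rej]
      keep <- head(keep, need)
      taken[keep] <- TRUE
      # rejected candidates stay in the pool (resampling with replacement)
      chosen <- c(chosen, keep)
    }
  }

  rows <- rbind(hp_rows,
                if (n_rand > 0L)
                  data.frame(contig = contigs[cand$ci[chosen]],
                             position = cand$position[chosen],
                             strand = cand$strand[chosen],
                             in_hairpin = FALSE, stringsAsFactors = FALSE))
  rows$level <- .draw_levels(nrow(rows), config$level_distribution)
  rows <- rows[order(rows$contig, rows$position), ]
  rownames(rows) <- NULL
  truth <- rows[, c("contig", "position", "strand", "level", "in_hairpin")]

  seqs <- vapply(chars, paste, character(1), collapse = "")
  names(seqs) <- contigs
  list(genome = Biostrings::DNAStringSet(seqs), truth = truth)
}

# shared engine for RNA and DNA read simulation
.simulate_read_set <- function(genome, truth, config, coverage, seed,
                               prefix) {
  set.seed(seed)
  chars <- .contig_chars(genome)
  L <- config$read_length
  qual <- strrep(rawToChar(as.raw(config$base_quality + 33L)), L)
  out <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    clen <- length(chars[[ci]])
    n_reads <- as.integer(round(coverage * clen / L))
    if (n_reads == 0L) next
    start0 <- sort(sample.int(clen - L + 1L, n_reads, replace = TRUE)) - 1L
    flag <- sample(c(0L, 16L), n_reads, replace = TRUE)
    # base matrix: L rows (read offsets) x n_reads columns, ref-oriented
    idx <- rep(start0, each = L) + seq_len(L)  # 1-based genome positions
    m <- matrix(chars[[ci]][idx], nrow = L)

    tr <- truth[truth$contig == contig, , drop = FALSE]
    if (nrow(tr) > 0L) {
      # reads overlapping each site (starts are sorted)
      lo <- findInterval(tr$position - L + 1L, start0,
                         left.open = TRUE) + 1L
      hi <- findInterval(tr$position, start0)
      for (s in seq_len(nrow(tr))) {
        if (hi[s] < lo[s]) next
        rid <- lo[s]:hi[s]
        edited <- rid[runif(length(rid)) < tr$level[s]]
        if (length(edited) == 0L) next
        off <- tr$position[s] - start0[edited] + 1L
        # inosine reads as G on the edited strand; in reference
        # orientation that is G for '+' sites and C for '-' sites
        m[cbind(off, edited)] <- if (tr$strand[s] == "+") "G" else "C"
      }
    }

    e <- config$error_rate
    if (e > 0) {
      nb <- L * n_reads
      n_err <- rbinom(1L, nb, e)
      if (n_err > 0L) {
        at <- sample.int(nb, n_err)
        cur <- match(m[at], BASES)
        m[at] <- BASES[(cur - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L + 1L]
      }
    }

    seqs <- do.call(paste0, lapply(seq_len(L), function(r) m[r, ]))
    out[[ci]] <- data.frame(
      qname = sprintf("%s_%s_%06d", prefix, contig, seq_len(n_reads)),
      flag = flag, contig = contig, pos0 = start0,
      seq = seqs, qual = qual, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out)
  if (is.null(reads))
    reads <- data.frame(qname = character(0), flag = integer(0),
                        contig = character(0), pos0 = integer(0),
                        seq = character(0), qual = character(0),
                        stringsAsFactors = FALSE)
  class(reads) <- c("read_set", "data.frame")
  reads
}

#' Simulate unstranded RNA-seq reads over a genome with planted editing
#'
#' Read starts are uniform; the reported strand of each read is chosen
#' uniformly (the library is unstranded). For every read overlapping a
#' truth site, the base at the site is the edited base with probability
#' equal to the site's true level, independently per read; every base is
#' then substituted by a uniformly chosen different base with
#' probability `error_rate`. Sequences are stored reference-oriented
#' (SAM convention), so an edited '+' site reads G and an edited '-'
#' site reads C in the returned `seq`.
#'
#' @param genome A `DNAStringSet`.
#' @param truth Truth table from [plant_editing_sites()] (may be empty).
#' @param config A [sim_config()].
#' @return A `read_set` data frame (`qname`, `flag`, `contig`, `pos0`,
#'   `seq`, `qual`), coordinate-sorted; write with [write_sam()] /
#'   [write_fastq()].
#' @export
simulate_reads <- function(genome, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  .simulate_read_set(genome, truth, config, config$coverage,
                     config$seed + 2L, "rna")
}

#' Simulate DNA-seq reads (sequencing errors, no editing)
#'
#' @inheritParams simulate_reads
#' @return A `read_set` data frame, as [simulate_reads()] with an empty
#'   truth table and `dna_coverage` depth.
#' @export
simulate_dna_reads <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  empty <- data.frame(contig = character(0), position = integer(0),
                      strand = character(0), level = numeric(0),
                      stringsAsFactors = FALSE)
  .simulate_read_set(genome, empty, config, config$dna_coverage,
                     config$seed + 3L, "dna")
}
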