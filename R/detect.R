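# De novo editing-site detection from RNA/DNA pileups: a re-implementation
# of the mismatch-test core of RNA/DNA comparative editing callers, with
# an exact binomial sequencing-error test and a genome-scale
# Benjamini-Hochberg correction.

#' Build a per-position pileup from aligned reads
#'
#' Counts A/C/G/T reads at every reference position; bases below the
#' base-quality threshold are excluded. Reverse-strand reads contribute
#' their stored (reference-oriented) bases, so no re-complementing takes
#' place here.
#'
#' @param reads A `read_set` data frame (see [read_sam()]).
#' @param genome `DNAStringSet` the reads were aligned to.
#' @param base_quality_min Minimum Phred quality for a base to count.
#' @return An object of class `pileup`: per contig an integer matrix
#'   with rows A, C, G, T and one column per reference position.
#' @export
build_pileup <- function(reads, genome, base_quality_min = 20L) {
  bad <- setdiff(unique(reads$contig), names(genome))
  if (length(bad) > 0L)
    stop("format error: reads reference unknown contig(s): ",
         paste(bad, collapse = ", "))
  counts <- lapply(Biostrings::width(genome), function(L) {
    matrix(0L, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
  })
  names(counts) <- names(genome)
  for (contig in unique(reads$contig)) {
    r <- reads[reads$contig == contig, , drop = FALSE]
    lens <- nchar(r$seq)
    gpos <- rep(r$pos0, lens) + sequence(lens)  # 1-based genome positions
    bases <- strsplit(paste(r$seq, collapse = ""), "", fixed = TRUE)[[1]]
    quals <- utf8ToInt(paste(r$qual, collapse = "")) - 33L
    code <- match(bases, BASES)
    keep <- !is.na(code) & quals >= base_quality_min
    L <- ncol(counts[[contig]])
    if (any(gpos[keep] > L))
      stop("format error: read extends beyond contig ", contig)
    tab <- tabulate((gpos[keep] - 1L) * 4L + code[keep], nbins = 4L * L)
    counts[[contig]] <- matrix(as.integer(tab), nrow = 4L,
                               dimnames = list(BASES, NULL))
  }
  structure(list(counts = counts,
                 contig_lengths = stats::setNames(Biostrings::width(genome),
                                                  names(genome)),
                 base_quality_min = base_quality_min),
            class = "pileup")
}

#' Collapse an ordered mismatch into one of six unstranded classes
#'
#' With an unstranded library a mismatch and its reverse complement are
#' indistinguishable, so the 12 ordered ref-to-alt pairs collapse into 6
#' classes; the canonical label puts the A- or C-reference member first
#' (e.g. `"A>G/T>C"`).
#'
#' @param ref,alt Reference and alternative bases (vectorized).
#' @return Character vector of class labels.
#' @export
classify_mismatch <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% BASES) || any(!alt %in% BASES))
    stop("invalid call: bases must be A/C/G/T")
  if (any(ref == alt))
    stop("invalid call: ref and alt must differ")
  flip <- !ref %in% c("A", "C")
  r <- ifelse(flip, comp_base(ref), ref)
  a <- ifelse(flip, comp_base(alt), alt)
  paste0(r, ">", a, "/", comp_base(r), ">", comp_base(a))
}

MISMATCH_CLASSES <- c("A>G/T>C", "A>C/T>G", "A>T/T>A",
                      "C>A/G>T", "C>G/G>C", "C>T/G>A")

#' Exact binomial p-value for an editing candidate
#'
#' Tests whether `k` reads of one specific alternative allele among `n`
#' could arise from sequencing error alone: the upper tail
#' `P(X >= k)` for `X ~ Binomial(n, e/3)`, since an error hits each of
#' the three alternative bases with probability `e/3`.
#'
#' @param n Read depth (vectorized).
#' @param k Alternative-allele read count.
#' @param e Per-base sequencing error rate in \[0,1).
#' @return Raw p-values in (0,1\].
#' @export
site_pvalue <- function(n, k, e) {
  if (any(k > n) || any(k < 0) || any(n < 0))
    stop("invalid call: need 0 <= k <= n")
  if (any(e < 0) || any(e >= 1))
    stop("invalid call: need 0 <= e < 1")
  pbinom(k - 1, n, e / 3, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment with an external test count
#'
#' Step-up BH where the multiplier uses `m_tests` (e.g. the genome size,
#' a conservative bound on the number of positions examined) rather than
#' the length of the candidate list:
#' `q_(i) = min_{j >= i} p_(j) * m_tests / j`, capped at 1.
#'
#' @param p Raw p-values in (0,1\].
#' @param m_tests Total number of tests; must be >= `length(p)`.
#' @return Adjusted q-values, in the original order of `p`.
#' @export
bh_adjust <- function(p, m_tests) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p <= 0) || any(p > 1)) stop("invalid call: p must be in (0,1]")
  if (m_tests < length(p))
    stop("invalid config: m_tests smaller than the number of p-values")
  o <- order(p)
  qs <- p[o] * m_tests / seq_along(p)
  q <- pmin(1, rev(cummin(rev(qs))))
  q[order(o)]
}

#' Detection parameters
#'
#' Defaults mirror the published filter set for editing-naive yeast:
#' RNA depth >= 5 with no minimum editing level (`--editLevel 0
#' --editDepth 5`), plus conservative additions where the published
#' pipeline delegates to its caller: at least 2 supporting reads, DNA
#' homozygous-reference requirement (depth >= 5, zero reads of the
#' candidate allele) and an FDR cut of 0.05 after BH adjustment.
#'
#' @param min_depth Minimum RNA depth at a candidate.
#' @param min_level Minimum editing level (alt fraction).
#' @param min_alt_reads Minimum alternative-allele reads.
#' @param base_quality_min Phred threshold used when building pileups.
#' @param error_rate Assumed per-base error `e`; default is the
#'   Phred-implied error at the quality threshold, `10^(-Q/10)`.
#' @param m_tests Number of tests for BH; default the genome length.
#' @param fdr_level Report sites with `q <= fdr_level`.
#' @param dna_min_depth Minimum DNA depth for the genomic check.
#' @param dna_max_alt Maximum DNA reads of the candidate allele.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_depth = 5L, min_level = 0,
                             min_alt_reads = 2L, base_quality_min = 20L,
                             error_rate = NULL, m_tests = NULL,
                             fdr_level = 0.05, dna_min_depth = 5L,
                             dna_max_alt = 0L) {
  if (fdr_level <= 0 || fdr_level >= 1)
    stop("invalid config: fdr_level must be in (0,1)")
  structure(list(min_depth = min_depth, min_level = min_level,
                 min_alt_reads = min_alt_reads,
                 base_quality_min = base_quality_min,
                 error_rate = error_rate %||% 10^(-base_quality_min / 10),
                 m_tests = m_tests, fdr_level = fdr_level,
                 dna_min_depth = dna_min_depth, dna_max_alt = dna_max_alt),
            class = "detection_params")
}

#' Detect editing sites from RNA and DNA pileups
#'
#' A position is a candidate iff its RNA depth, alternative-allele count
#' (single most frequent non-reference allele, alphabetical tie-break
#' with an `ambiguous` flag) and level pass the thresholds, and the DNA
#' pileup supports a homozygous-reference genotype (depth >=
#' `dna_min_depth` with at most `dna_max_alt` reads of the candidate
#' allele). Candidates receive an exact binomial p-value
#' ([site_pvalue()]) and a genome-scale BH q-value ([bh_adjust()]);
#' sites with `q <= fdr_level` are reported, sorted by (contig,
#' position). Candidates with no DNA coverage at all are dropped and
#' counted in the `n_dna_uncovered` attribute.
#'
#' @param rna_pileup,dna_pileup `pileup` objects built against `genome`.
#' @param genome The reference `DNAStringSet`.
#' @param params A [detection_params()].
#' @return A `site_table` data frame: `contig`, `position` (0-based),
#'   `ref`, `class`, `depth`, `alt_count`, `level`, `p`, `q`,
#'   `dna_depth`, `dna_alt`, `ambiguous`.
#' @export
detect_sites <- function(rna_pileup, dna_pileup, genome,
                         params = detection_params()) {
  stopifnot(inherits(rna_pileup, "pileup"), inherits(dna_pileup, "pileup"))
  chars <- .contig_chars(genome)
  cand_list <- list()
  n_dna_uncovered <- 0L
  for (contig in names(genome)) {
    cnt <- rna_pileup$counts[[contig]]
    if (is.null(cnt)) next
    depth <- colSums(cnt)
    refcode <- match(chars[[contig]], BASES)
    covered <- which(depth >= params$min_depth & !is.na(refcode))
    if (length(covered) == 0L) next
    sub <- cnt[, covered, drop = FALSE]
    rc <- refcode[covered]
    alt <- sub
    alt[cbind(rc, seq_along(covered))] <- -1L  # mask the reference row
    top <- max.col(t(alt), ties.method = "first")
    k <- alt[cbind(top, seq_along(covered))]
    n_top <- colSums(alt == rep(k, each = 4L) & alt >= 0L)
    lev <- k / depth[covered]
    ok <- k >= params$min_alt_reads & lev >= params$min_level & lev > 0
    if (!any(ok)) next
    idx <- which(ok)
    dna <- dna_pileup$counts[[contig]]
    pos <- covered[idx]
    if (is.null(dna)) {
      dna_depth <- rep(0L, length(pos)); dna_alt <- rep(0L, length(pos))
    } else {
      dna_depth <- colSums(dna[, pos, drop = FALSE])
      dna_alt <- dna[cbind(top[idx], pos)]
    }
    uncov <- dna_depth == 0L
    n_dna_uncovered <- n_dna_uncovered + sum(uncov)
    keep <- !uncov & dna_depth >= params$dna_min_depth &
      dna_alt <= params$dna_max_alt
    if (!any(keep)) next
    idx <- idx[keep]
    cand_list[[contig]] <- data.frame(
      contig = contig, position = covered[idx] - 1L,
      ref = BASES[rc[idx]], alt_base = BASES[top[idx]],
      depth = as.integer(depth[covered[idx]]), alt_count = as.integer(k[idx]),
      level = lev[idx], dna_depth = as.integer(dna_depth[keep]),
      dna_alt = as.integer(dna_alt[keep]),
      ambiguous = n_top[idx] > 1L, stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand_list)
  if (is.null(cand) || nrow(cand) == 0L) {
    out <- data.frame(contig = character(0), position = integer(0),
                      ref = character(0), class = character(0),
                      depth = integer(0), alt_count = integer(0),
                      level = numeric(0), p = numeric(0), q = numeric(0),
                      dna_depth = integer(0), dna_alt = integer(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("site_table", "data.frame")
    attr(out, "n_dna_uncovered") <- n_dna_uncovered
    if (n_dna_uncovered > 0L)
      message(n_dna_uncovered,
              " candidate(s) dropped for missing DNA coverage")
    return(out)
  }
  m_tests <- params$m_tests %||% sum(Biostrings::width(genome))
  if (m_tests < nrow(cand))
    stop("invalid config: m_tests smaller than the number of candidates")
  cand$class <- classify_mismatch(cand$ref, cand$alt_base)
  cand$p <- site_pvalue(cand$depth, cand$alt_count, params$error_rate)
  cand$q <- bh_adjust(cand$p, m_tests)
  out <- cand[cand$q <= params$fdr_level, , drop = FALSE]
  out <- out[order(out$contig, out$position), , drop = FALSE]
  out$alt_base <- NULL
  out <- out[, c("contig", "position", "ref", "class", "depth",
                 "alt_count", "level", "p", "q", "dna_depth", "dna_alt",
                 "ambiguous")]
  rownames(out) <- NULL
  if (n_dna_uncovered > 0L)
    message(n_dna_uncovered, " candidate(s) dropped for missing DNA coverage")
  class(out) <- c("site_table", "data.frame")
  attr(out, "n_dna_uncovered") <- n_dna_uncovered
  out
}

#' Mismatch spectrum over the six unstranded classes
#'
#' @param sites A site table.
#' @return A list with `counts` (named integer vector over the six
#'   classes) and `ag_fraction`, the A>G/T>C share of all sites (NA for
#'   an empty table).
#' @export
mismatch_spectrum <- function(sites) {
  counts <- table(factor(sites$class, levels = MISMATCH_CLASSES))
  counts <- stats::setNames(as.integer(counts), MISMATCH_CLASSES)
  total <- sum(counts)
  list(counts = counts,
       ag_fraction = if (total > 0) counts[["A>G/T>C"]] / total else NA_real_)
}
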