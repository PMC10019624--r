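# Genome-wide editing quantification: editing index, per-site level
# histogram, replicate recurrence and the neighbour-nucleotide motif.

# the six unstranded classes as (ref1, alt1) with ref1 in {A, C}; the
# complementary orientation (comp(ref1) -> comp(alt1)) is pooled in.
.class_defs <- function() {
  data.frame(class = MISMATCH_CLASSES,
             ref1 = c("A", "A", "A", "C", "C", "C"),
             alt1 = c("G", "C", "T", "A", "G", "T"),
             stringsAsFactors = FALSE)
}

#' Genome-wide editing index
#'
#' The editing index is the read-weighted fraction of nucleotides
#' expressed from genomically encoded adenosines that is observed as
#' guanosine, reported as a percentage. For an unstranded library the
#' A-reference and T-reference contributions are pooled: the numerator
#' is the G-read count at reference-A positions plus the C-read count at
#' reference-T positions, the denominator the matching (A+G) plus (T+C)
#' informative read counts. The analogous ratio is reported for each of
#' the six mismatch classes in `per_class`.
#'
#' @param rna_pileup A `pileup` from [build_pileup()].
#' @param genome The reference `DNAStringSet`.
#' @param dna_pileup Optional DNA `pileup`; used only when
#'   `exclude_dna_variants` is `TRUE`.
#' @param exclude_dna_variants If `TRUE`, positions where the DNA pileup
#'   shows any non-reference read are excluded from numerator and
#'   denominator (removes genomic polymorphisms from the baseline).
#' @return A list: `index` (percent, A>G/T>C class), `numerator`,
#'   `denominator`, and `per_class`, a data frame of the same triple for
#'   all six classes.
#' @export
editing_index <- function(rna_pileup, genome, dna_pileup = NULL,
                          exclude_dna_variants = FALSE) {
  stopifnot(inherits(rna_pileup, "pileup"))
  defs <- .class_defs()
  chars <- .contig_chars(genome)
  num <- stats::setNames(numeric(6), defs$class)
  den <- stats::setNames(numeric(6), defs$class)
  for (contig in names(genome)) {
    cnt <- rna_pileup$counts[[contig]]
    if (is.null(cnt)) next
    ref <- chars[[contig]]
    keep <- rep(TRUE, length(ref))
    if (exclude_dna_variants && !is.null(dna_pileup)) {
      dna <- dna_pileup$counts[[contig]]
      if (!is.null(dna)) {
        refcode <- match(ref, BASES)
        refc <- refcode; refc[is.na(refc)] <- 1L
        nonref <- colSums(dna) - dna[cbind(refc, seq_along(ref))]
        keep <- keep & (nonref == 0L) & !is.na(refcode)
      }
    }
    for (ci in seq_len(6)) {
      r1 <- defs$ref1[ci]; a1 <- defs$alt1[ci]
      r2 <- comp_base(r1); a2 <- comp_base(a1)
      i1 <- which(ref == r1 & keep); i2 <- which(ref == r2 & keep)
      num[ci] <- num[ci] + sum(cnt[a1, i1]) + sum(cnt[a2, i2])
      den[ci] <- den[ci] + sum(cnt[r1, i1]) + sum(cnt[a1, i1]) +
        sum(cnt[r2, i2]) + sum(cnt[a2, i2])
    }
  }
  if (den[["A>G/T>C"]] == 0)
    stop("undefined index: no informative reads at adenosine positions")
  per_class <- data.frame(class = defs$class, numerator = num,
                          denominator = den,
                          index = ifelse(den > 0, 100 * num / den, NA_real_),
                          row.names = NULL, stringsAsFactors = FALSE)
  list(index = per_class$index[per_class$class == "A>G/T>C"],
       numerator = num[["A>G/T>C"]], denominator = den[["A>G/T>C"]],
       per_class = per_class)
}

#' Histogram of per-site editing levels
#'
#' @param sites A site table with a `level` column in \[0,1\].
#' @param bin_width Bin width; bins are `(lo, hi]` with the lowest bin
#'   closed at 0.
#' @return Data frame `bin_lo`, `bin_hi`, `count`; counts sum to the
#'   number of sites.
#' @export
level_histogram <- function(sites, bin_width = 0.05) {
  if (any(sites$level < 0 | sites$level > 1))
    stop("invalid call: levels must be in [0,1]")
  breaks <- unique(c(seq(0, 1, by = bin_width), 1))
  bin <- cut(sites$level, breaks, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(bin))
  data.frame(bin_lo = head(breaks, -1), bin_hi = tail(breaks, -1),
             count = counts)
}

#' Replicate recurrence of editing sites
#'
#' Site identity is (contig, position, class); strand is not observable
#' from an unstranded library.
#'
#' @param tables A list of >= 2 site tables (biological replicates).
#' @return A list: `n_replicates`, `union_size`, `intersection_size`,
#'   `exactly_k` (sites found in exactly k replicates, k = 1..n),
#'   `at_least_k`, and `fraction_in_all` =
#'   intersection/union.
#' @export
replicate_recurrence <- function(tables) {
  if (length(tables) < 2L)
    stop("invalid call: need at least two replicate site tables")
  keys <- lapply(tables, function(s)
    unique(paste(s$contig, s$position, s$class, sep = ":")))
  occ <- table(unlist(keys))
  n <- length(tables)
  exactly <- vapply(seq_len(n), function(k) sum(occ == k), integer(1))
  at_least <- rev(cumsum(rev(exactly)))
  list(n_replicates = n, union_size = length(occ),
       intersection_size = exactly[n],
       exactly_k = exactly, at_least_k = at_least,
       fraction_in_all = if (length(occ) > 0) exactly[n] / length(occ)
                         else NA_real_)
}

#' Neighbour-nucleotide motif around edited adenosines
#'
#' Accumulates nucleotide frequencies at offsets -k..-1 and +1..+k
#' around A>G/T>C sites. Sites whose reference base is T arise from
#' editing on the minus strand and are reverse-complemented before
#' accumulation, so every site contributes in the edited-A orientation.
#' The background is computed over all genomic adenosine positions (both
#' strands) under the same convention. Sites too close to a contig edge
#' for the full flank are skipped and counted.
#'
#' @param sites A site table; only A>G/T>C sites are used.
#' @param genome The reference `DNAStringSet`.
#' @param k Flank size in bp (immediate neighbours: `k = 1`).
#' @return An object of class `motif_matrix`: list with `freq` and `bg`
#'   (offset x base frequency matrices, rows summing to 1), `n_sites`,
#'   `n_skipped`.
#' @export
neighbor_motif <- function(sites, genome, k = 1L) {
  chars <- .contig_chars(genome)
  offsets <- setdiff(-k:k, 0L)
  onames <- ifelse(offsets > 0, paste0("+", offsets), as.character(offsets))
  freq <- matrix(0, nrow = length(offsets), ncol = 4L,
                 dimnames = list(onames, BASES))
  bg <- freq
  n_used <- 0L; n_skipped <- 0L

  accumulate <- function(mat, ci, pos1, strand) {
    # pos1: 1-based site positions; strand "+" uses the bases as-is,
    # "-" takes the complement at the mirrored offset
    for (oi in seq_along(offsets)) {
      o <- offsets[oi]
      b <- ifelse(strand == "+",
                  chars[[ci]][pos1 + o],
                  comp_base(chars[[ci]][pos1 - o]))
      tb <- table(factor(b, levels = BASES))
      mat[oi, ] <- mat[oi, ] + as.integer(tb)
    }
    mat
  }

  ag <- sites[sites$class == "A>G/T>C", , drop = FALSE]
  for (contig in unique(ag$contig)) {
    s <- ag[ag$contig == contig, , drop = FALSE]
    L <- length(chars[[contig]])
    pos1 <- s$position + 1L
    inb <- pos1 - k >= 1L & pos1 + k <= L
    n_skipped <- n_skipped + sum(!inb)
    s <- s[inb, , drop = FALSE]; pos1 <- pos1[inb]
    if (nrow(s) == 0L) next
    n_used <- n_used + nrow(s)
    strand <- ifelse(s$ref == "A", "+", "-")
    freq <- accumulate(freq, contig, pos1, strand)
  }
  for (contig in names(genome)) {
    L <- length(chars[[contig]])
    pa <- which(chars[[contig]] == "A")
    pt <- which(chars[[contig]] == "T")
    pa <- pa[pa - k >= 1L & pa + k <= L]
    pt <- pt[pt - k >= 1L & pt + k <= L]
    if (length(pa) > 0L)
      bg <- accumulate(bg, contig, pa, rep("+", length(pa)))
    if (length(pt) > 0L)
      bg <- accumulate(bg, contig, pt, rep("-", length(pt)))
  }
  norm <- function(m) {
    rs <- rowSums(m)
    m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
    m
  }
  structure(list(k = k, counts = freq, freq = norm(freq),
                 bg_counts = bg, bg = norm(bg),
                 n_sites = n_used, n_skipped = n_skipped),
            class = "motif_matrix")
}
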