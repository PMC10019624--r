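# File-format boundaries. Internally everything is 0-based half-open;
# SAM/BED/TSV positions are converted at these functions only.

#' Write a genome to FASTA
#' @param genome A `DNAStringSet`.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write aligned reads as SAM
#'
#' Emits a minimal valid SAM: `@HD`/`@SQ` header and one ungapped record
#' per read (single `<len>M` CIGAR, FLAG bit 16 for reverse-strand
#' reads, mapping quality 60). Sequences are stored reference-oriented.
#'
#' @param reads A `read_set` data frame.
#' @param genome The `DNAStringSet` the reads are aligned to.
#' @param path Output file.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome)))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$contig, reads$pos0 + 1L,
                  nchar(reads$seq), reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ungapped SAM file into a read set
#'
#' Supports the subset this package emits: single-run `<len>M` CIGARs,
#' no indels or clipping. Unmapped records are skipped.
#'
#' @param path SAM file.
#' @return A `read_set` data frame.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    reads <- data.frame(qname = character(0), flag = integer(0),
                        contig = character(0), pos0 = integer(0),
                        seq = character(0), qual = character(0),
                        stringsAsFactors = FALSE)
    class(reads) <- c("read_set", "data.frame")
    return(reads)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  cigar <- get(6)
  keep <- bitwAnd(flag, 4L) == 0L
  if (any(!grepl("^\\d+M$", cigar[keep])))
    stop("format error: only ungapped (<len>M) SAM records are supported")
  reads <- data.frame(qname = get(1)[keep], flag = flag[keep],
                      contig = get(3)[keep],
                      pos0 = as.integer(get(4)[keep]) - 1L,
                      seq = get(10)[keep], qual = get(11)[keep],
                      stringsAsFactors = FALSE)
  class(reads) <- c("read_set", "data.frame")
  reads
}

#' Write reads as FASTQ (Sanger Phred+33)
#'
#' Reverse-strand reads (FLAG bit 16) are reverse-complemented back to
#' read orientation; quality strings are reversed accordingly.
#'
#' @param reads A `read_set` data frame.
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  seqs <- reads$seq
  quals <- reads$qual
  rev_mask <- bitwAnd(reads$flag, 16L) != 0L
  if (any(rev_mask)) {
    seqs[rev_mask] <- revcomp(seqs[rev_mask])
    quals[rev_mask] <- vapply(quals[rev_mask], function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  }
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$qname)
  out[seq(2, length(out), 4)] <- seqs
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- quals
  writeLines(out, path)
  invisible(path)
}

#' Write a truth table as BED-like TSV
#'
#' Six columns: contig, start (0-based), end, name, level, strand.
#'
#' @param truth Truth data frame from [plant_editing_sites()].
#' @param path Output file.
#' @export
write_truth_table <- function(truth, path) {
  bed <- data.frame(truth$contig, truth$position, truth$position + 1L,
                    sprintf("site%06d", seq_len(nrow(truth))),
                    truth$level, truth$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth_table()]
#' @param path BED-like TSV file.
#' @return A truth data frame (`contig`, `position`, `strand`, `level`).
#' @export
read_truth_table <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(contig = bed[[1]], position = as.integer(bed[[2]]),
             strand = bed[[6]], level = as.numeric(bed[[5]]),
             stringsAsFactors = FALSE)
}

#' Write a site table as TSV
#'
#' Positions are written 1-based (`pos_1based`); all other columns are
#' carried through unchanged.
#'
#' @param sites Site table from [detect_sites()].
#' @param path Output file.
#' @export
write_site_table <- function(sites, path) {
  out <- sites
  out$pos_1based <- out$position + 1L
  out$position <- NULL
  cols <- c("contig", "pos_1based", "ref", "class", "depth", "alt_count",
            "level", "p", "q", "dna_depth", "dna_alt", "ambiguous")
  out <- out[, intersect(cols, names(out)), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site table written by [write_site_table()]
#' @param path TSV file.
#' @return A site table data frame with 0-based `position`.
#' @export
read_site_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  x$position <- as.integer(x$pos_1based) - 1L
  x$pos_1based <- NULL
  x[, c("position", setdiff(names(x), "position"))]
  x <- x[, c("contig", "position",
             setdiff(names(x), c("contig", "position")))]
  x
}
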