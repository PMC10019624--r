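test_that("generate_genome honours composition limits and sampling bounds", {
  g0 <- generate_genome(tiny_config(gc_content = 0))
  expect_true(grepl("^[AT]+$", as.character(g0[[1]])))
  g1 <- generate_genome(tiny_config(gc_content = 1))
  expect_true(grepl("^[GC]+$", as.character(g1[[1]])))

  cfg <- tiny_config(seed = 1L, contig_lengths = 100000L, gc_content = 0.5)
  g <- generate_genome(cfg)
  gc <- Biostrings::letterFrequency(g, "GC", as.prob = TRUE)[1]
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 100000))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(contig_lengths = 0L), "positive")
  expect_error(sim_config(error_rate = 1), "error_rate")
  expect_error(sim_config(contig_lengths = 50L, read_length = 75L),
               "read_length")
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 77L, n_sites = 10L, error_rate = 0.002)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$rna, b2$rna)
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(b1$rna, b1$genome, f1)
  write_sam(b2$rna, b2$genome, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("planted truth sites are adenosines on their recorded strand", {
  cfg <- tiny_config(seed = 3L, contig_lengths = c(4000L, 3000L),
                     n_sites = 60L, hairpin_fraction = 0.25)
  pl <- plant_editing_sites(generate_genome(cfg), cfg)
  tr <- pl$truth
  expect_equal(nrow(tr), 60L)
  expect_false(any(duplicated(tr[, c("contig", "position", "strand")])))
  base <- substring(as.character(pl$genome[tr$contig]),
                    tr$position + 1L, tr$position + 1L)
  expect_true(all(ifelse(tr$strand == "+", base == "A", base == "T")))
  expect_true(all(tr$level > 0 & tr$level <= 1))
  expect_equal(sum(tr$in_hairpin), 15L)
})

test_that("n_sites = 0 and infeasible n_sites behave per contract", {
  cfg <- tiny_config(n_sites = 0L)
  pl <- plant_editing_sites(generate_genome(cfg), cfg)
  expect_equal(nrow(pl$truth), 0L)
  cfg2 <- tiny_config(contig_lengths = 200L, read_length = 50L,
                      n_sites = 100000L)
  expect_error(plant_editing_sites(generate_genome(cfg2), cfg2),
               "infeasible")
})

test_that("motif bias depletes upstream G at planted sites", {
  cfg <- tiny_config(seed = 11L, contig_lengths = 200000L,
                     n_sites = 2000L, motif_bias = 0.9)
  pl <- plant_editing_sites(generate_genome(cfg), cfg)
  ch <- strsplit(as.character(pl$genome[[1]]), "")[[1]]
  tr <- pl$truth
  # two-proportion count oracle: upstream-G at sites vs at all A/T sites
  up_site <- ifelse(tr$strand == "+",
                    c("X", ch)[tr$position + 1L] == "G",
                    c(ch, "X")[tr$position + 2L] == "C")
  pa <- which(ch == "A"); pt <- which(ch == "T")
  up_bg <- c(c("X", ch)[pa] == "G", c(ch, "X")[pt + 1L] == "C")
  p1 <- mean(up_site); p2 <- mean(up_bg)
  pool <- (sum(up_site) + sum(up_bg)) / (length(up_site) + length(up_bg))
  z <- (p2 - p1) / sqrt(pool * (1 - pool) *
                          (1 / length(up_site) + 1 / length(up_bg)))
  expect_gt(z, 3)
})

test_that("error-free reads match the reference except at edited sites", {
  cfg <- tiny_config(seed = 21L, n_sites = 0L, error_rate = 0)
  g <- generate_genome(cfg)
  empty <- plant_editing_sites(g, cfg)$truth
  rna <- simulate_reads(g, empty, cfg)
  ref <- substring(rep(as.character(g[[1]]), nrow(rna)),
                   rna$pos0 + 1L, rna$pos0 + cfg$read_length)
  expect_identical(rna$seq, ref)
})

test_that("a certain-conversion site edits every overlapping read", {
  g <- as_genome(paste(rep("ACGT", 500), collapse = ""))
  cfg <- tiny_config(contig_lengths = 2000L, error_rate = 0)
  truth <- data.frame(contig = "contig01", position = 100L, strand = "+",
                      level = 1.0, stringsAsFactors = FALSE)
  rna <- simulate_reads(g, truth, cfg)
  cover <- rna$pos0 <= 100L & rna$pos0 + cfg$read_length > 100L
  at_site <- substring(rna$seq[cover], 100L - rna$pos0[cover] + 1L,
                       100L - rna$pos0[cover] + 1L)
  expect_true(all(at_site == "G"))  # reference orientation
  # and in read orientation a reverse read shows C
  fq <- tempfile()
  write_fastq(rna[cover, ], fq)
  lines <- readLines(fq)
  seqs <- lines[seq(2, length(lines), 4)]
  offs <- ifelse(bitwAnd(rna$flag[cover], 16L) != 0L,
                 cfg$read_length - (100L - rna$pos0[cover]),
                 100L - rna$pos0[cover] + 1L)
  rb <- substring(seqs, offs, offs)
  expect_true(all(rb == ifelse(bitwAnd(rna$flag[cover], 16L) != 0L,
                               "C", "G")))
})

test_that("coverage, strand balance and DNA error rate match their laws", {
  cfg <- tiny_config(seed = 31L, contig_lengths = 50000L, n_sites = 0L,
                     coverage = 50, read_length = 100L,
                     dna_coverage = 50, error_rate = 0.003)
  g <- generate_genome(cfg)
  empty <- plant_editing_sites(g, cfg)$truth
  rna <- simulate_reads(g, empty, cfg)
  # depth oracle from read intervals
  cov <- numeric(50000)
  for (i in seq_len(nrow(rna))) {
    idx <- (rna$pos0[i] + 1L):(rna$pos0[i] + 100L)
    cov[idx] <- cov[idx] + 1
  }
  expect_lt(abs(mean(cov) - 50) / 50, 0.05)
  pile <- build_pileup(rna, g)
  expect_equal(unname(colSums(pile$counts[["contig01"]])), cov)

  # strand balance at large read count
  cfg2 <- tiny_config(seed = 8L, contig_lengths = 100000L, n_sites = 0L,
                      coverage = 75, read_length = 75L)
  g2 <- generate_genome(cfg2)
  rna2 <- simulate_reads(g2, plant_editing_sites(g2, cfg2)$truth, cfg2)
  expect_gt(nrow(rna2), 99000)
  frac_plus <- mean(bitwAnd(rna2$flag, 16L) == 0L)
  expect_gt(frac_plus, 0.48); expect_lt(frac_plus, 0.52)

  # specific-alt error-rate law in the DNA pileup: e/3 per alternative
  dna <- simulate_dna_reads(g, cfg)
  dpile <- build_pileup(dna, g)
  cnt <- dpile$counts[["contig01"]]
  ch <- strsplit(as.character(g[[1]]), "")[[1]]
  ref_idx <- cbind(match(ch, c("A", "C", "G", "T")), seq_along(ch))
  alt_frac <- (sum(cnt) - sum(cnt[ref_idx])) / sum(cnt)
  expect_lt(abs(alt_frac - 0.003) / 0.003, 0.1)
})

test_that("allele-frequency recovery matches the binomial law", {
  cfg <- tiny_config(seed = 13L, contig_lengths = 150000L,
                     n_sites = 1000L, coverage = 50, error_rate = 0,
                     level_distribution = list(kind = "uniform",
                                               lo = 0.1, hi = 0.9))
  b <- simulate_bundle(cfg)
  cnt <- b$rna_pile$counts[["contig01"]]
  tr <- b$truth
  dep <- colSums(cnt)[tr$position + 1L]
  edited <- ifelse(tr$strand == "+", cnt["G", tr$position + 1L],
                   cnt["C", tr$position + 1L])
  ok <- dep >= 10
  phat <- edited[ok] / dep[ok]
  mad <- mean(abs(phat - tr$level[ok]))
  se <- mean(sqrt(tr$level[ok] * (1 - tr$level[ok]) / dep[ok]))
  expect_lt(mad, 1.5 * se)
  expect_gt(mad, se / 1.5)
})

test_that("SAM and truth-table round trips preserve the data", {
  cfg <- tiny_config(seed = 55L, n_sites = 10L, error_rate = 0.001)
  b <- simulate_bundle(cfg)
  sam <- tempfile(fileext = ".sam")
  write_sam(b$rna, b$genome, sam)
  back <- read_sam(sam)
  expect_equal(back$seq, b$rna$seq)
  expect_equal(back$pos0, b$rna$pos0)
  expect_equal(back$flag, b$rna$flag)
  tsv <- tempfile(fileext = ".tsv")
  write_truth_table(b$truth, tsv)
  tr <- read_truth_table(tsv)
  expect_equal(tr$position, b$truth$position)
  expect_equal(tr$level, b$truth$level, tolerance = 1e-12)
  expect_equal(tr$strand, b$truth$strand)
})
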