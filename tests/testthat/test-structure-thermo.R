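test_that("fold_mfe handles degenerate and ordering cases", {
  # no complementarity -> open chain at dG = 0
  pa <- fold_mfe(strrep("A", 50), 303.15)
  expect_equal(pa$dG, 0)
  expect_true(all(pa$pair_table == 0L))
  # too short to fold
  expect_equal(fold_mfe("ACGU", 303.15)$dG, 0)
  # GC hairpin beats AU hairpin of the same shape
  gc <- fold_mfe("GGGGGGAAAACCCCCC", 303.15)
  au <- fold_mfe("AUAUAUAAAAAUAUAU", 303.15)
  expect_lt(gc$dG, au$dG)
  expect_lt(gc$dG, 0)
  # N never pairs
  fn <- fold_mfe(strrep("N", 40), 303.15)
  expect_equal(fn$dG, 0)
  fN <- fold_mfe("GGGGGGAAAANNNNNN", 303.15)
  expect_equal(fN$dG, 0)
})

test_that("DP MFE equals exhaustive enumeration on a seeded battery", {
  set.seed(2024)
  lens <- c(8, 10, 12, 14, 16, 18, 20, 22, 25, 28, 30)
  for (len in lens) {
    s <- oracle_battery_seq(len)
    f <- fold_mfe(s, 303.15)
    expect_equal(f$dG, oracle_mfe(s, 303.15), tolerance = 1e-9,
                 info = paste("len", len, s))
    # the returned structure itself scores to the reported dG
    expect_equal(structure_energy(f$sequence, f$pair_table, 303.15),
                 f$dG, tolerance = 1e-9)
  }
  # designed hairpins with interior loops/bulges, both temperatures
  designed <- c("GGGCGCAAAUAGCGCCCAAAAAAAAAAAAA",
                "GCGCGCGCAAAAAAGCGCGCGCAAAAAAAA",
                "GGCGAGCAAAAGCACGCC")
  for (s in designed) for (tk in c(298.15, 303.15, 307.15)) {
    expect_equal(fold_mfe(s, tk)$dG, oracle_mfe(s, tk),
                 tolerance = 1e-9, info = paste(s, tk))
  }
})

test_that("dG is never positive and grows with temperature", {
  set.seed(77)
  for (r in 1:20) {
    s <- paste(sample(c("A", "C", "G", "U"), 60, replace = TRUE),
               collapse = "")
    f <- fold_mfe(s, 303.15)
    expect_lte(f$dG, 0)
    # re-score the fixed structure across temperatures: non-decreasing
    if (f$dG < 0) {
      es <- vapply(c(293.15, 298.15, 303.15, 308.15, 313.15),
                   function(tk) structure_energy(s, f$pair_table, tk),
                   numeric(1))
      expect_true(all(diff(es) >= -1e-9))
    }
  }
  # a fixed GC helix is less stable when warmer (MFE refolds too)
  helix <- "GGCGCCGCGGCCAAAAGGCCGCGGCGCC"
  expect_lt(fold_mfe(helix, 298.15)$dG, fold_mfe(helix, 307.15)$dG)
})

test_that("extending a helix with complementary ends never raises dG", {
  core <- c("GCGC", "AAAA", "GCGC")  # stem-loop seed
  prev <- fold_mfe(paste0(core[1], core[2], core[3]), 303.15)$dG
  left <- core[1]; right <- core[3]
  for (i in 1:6) {
    left <- paste0("G", left); right <- paste0(right, "C")
    cur <- fold_mfe(paste0(left, core[2], right), 303.15)$dG
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("extract_window clamps, offsets and orients correctly", {
  g <- as_genome(paste(rep("ACGTATTGCA", 200), collapse = ""))  # 2000 bp
  w <- extract_window(g, "contig01", 1000L, "+", flank = 400L)
  expect_equal(nchar(w$sequence), 801L)
  expect_equal(w$offset, 401L)
  w0 <- extract_window(g, "contig01", 0L, "+", flank = 400L)
  expect_equal(nchar(w0$sequence), 401L)
  expect_equal(w0$offset, 1L)
  # minus-strand orientation: + context TTT[T]GGG reverse-complements
  g2 <- as_genome("TTTTGGG")
  wm <- extract_window(g2, "contig01", 3L, "-", flank = 10L)
  expect_equal(wm$sequence, "CCCAAAA")
  expect_equal(substring(wm$sequence, wm$offset, wm$offset), "A")
  expect_error(extract_window(g2, "contig01", 99L), "outside")
})

test_that("substructure extraction finds the site-containing duplex", {
  # perfect 20-bp stem with a tetraloop; site mid-stem
  stem5 <- "GCGCGCGCGCGCGCGCGCAC"
  stem3 <- "GUGCGCGCGCGCGCGCGCGC"
  f <- fold_mfe(paste0(stem5, "AAAA", stem3), 303.15)
  sub <- extract_substructure(f, 10L)
  expect_equal(sub$verdict, "paired")
  expect_true(sub$contiguous)
  expect_equal(sub$outer_pair, c(1L, 44L))
  # site in the exterior loop of an otherwise folded window
  g <- paste0(strrep("A", 10), "GGGGGGCCCCAACCCCCC", strrep("A", 10))
  fe <- fold_mfe(g, 303.15)
  expect_equal(fe$pair_table[5], 0L)
  sub_e <- extract_substructure(fe, 5L)
  expect_equal(sub_e$verdict, "unpaired")
  expect_equal(substructure_dG(sub_e), 0)
})

test_that("join_arms applies the 7-N linker contract", {
  # two-helix multiloop: outer helix arms are discontiguous
  s <- paste0("GGGGGGGG",                       # outer 5' arm
              "AA", "GGGGCCAAAAGGCCCC", "AA",   # branch 1
              "AA", "GCGCAAAAGCGC", "AA",       # branch 2
              "CCCCCCCC")                       # outer 3' arm
  f <- fold_mfe(s, 303.15)
  sub <- extract_substructure(f, 1L)
  expect_equal(sub$verdict, "paired")
  expect_false(sub$contiguous)
  j <- join_arms(sub)
  expect_true(j$linker_used)
  expect_equal(nchar(j$sequence),
               diff(sub$arm5)[1] + diff(sub$arm3)[1] + 2L + 7L)
  expect_equal(substring(j$sequence, diff(sub$arm5)[1] + 2L,
                         diff(sub$arm5)[1] + 8L), "NNNNNNN")
  # two 10-nt arms join into 27 nt
  sub10 <- structure(list(verdict = "paired", contiguous = FALSE,
                          arm5 = c(1L, 10L), arm3 = c(31L, 40L),
                          fragments = c("GGGGGGGGGG", "CCCCCCCCCC"),
                          site_offset = 5L),
                     class = "substructure")
  j10 <- join_arms(sub10)
  expect_equal(nchar(j10$sequence), 27L)
  # linker positions never pair on refold
  fj <- fold_mfe(j10$sequence, 303.15)
  linker <- 11:17
  expect_true(all(fj$pair_table[linker] == 0L))
  expect_false(all(fj$pair_table == 0L))
  # contiguous substructures pass through unchanged
  subc <- structure(list(verdict = "paired", contiguous = TRUE,
                         arm5 = c(3L, 10L), arm3 = NULL,
                         fragments = "GGGAAACCC", site_offset = 5L),
                    class = "substructure")
  expect_false(join_arms(subc)$linker_used)
  expect_equal(join_arms(subc)$sequence, "GGGAAACCC")
})

test_that("hairpin-planted sites fold into the planted arm pairing", {
  cfg <- tiny_config(seed = 33L, contig_lengths = 30000L, n_sites = 40L,
                     hairpin_fraction = 1)
  pl <- plant_editing_sites(generate_genome(cfg), cfg)
  tr <- pl$truth
  hit <- 0L
  for (i in seq_len(nrow(tr))) {
    w <- extract_window(pl$genome, tr$contig[i], tr$position[i],
                        tr$strand[i], flank = 60L)
    f <- fold_mfe(w$sequence, 303.15)
    sub <- extract_substructure(f, w$offset)
    if (sub$verdict == "paired") hit <- hit + 1L
  }
  expect_gte(hit / nrow(tr), 0.9)
})

test_that("substructure_dG separates structured from unstructured sites", {
  cfg <- tiny_config(seed = 37L, contig_lengths = 60000L, n_sites = 60L,
                     hairpin_fraction = 0.5)
  pl <- plant_editing_sites(generate_genome(cfg), cfg)
  dg <- site_structure_dG(pl$genome, pl$truth, flank = 60L,
                          temperature = 303.15)
  sets <- split(dg$dG, ifelse(pl$truth$in_hairpin, "hairpin", "background"))
  cmp <- compare_stability(sets)
  expect_lt(cmp$medians[["hairpin"]], cmp$medians[["background"]])
  row <- cmp$comparisons
  expect_lte(row$p[1], 0.001)
})

test_that("compare_stability and star labels follow the legend", {
  expect_equal(star_label(c(0.2, 0.05, 0.03, 0.01, 0.001, 0.0001, 1e-6)),
               c("ns", "*", "*", "**", "***", "****", "****"))
  # monotone step function of p
  ps <- sort(runif(50))
  stars <- factor(star_label(ps), levels = c("****", "***", "**", "*", "ns"),
                  ordered = TRUE)
  expect_true(all(diff(as.integer(stars)) >= 0))
  # identical sets -> ns; shifted sets -> strong significance
  set.seed(10)
  a <- rnorm(200, -5, 1)
  same <- compare_stability(list(x = a, y = a))
  expect_equal(same$comparisons$label, "ns")
  shifted <- compare_stability(list(x = a, y = a - 3))
  expect_lte(shifted$comparisons$p, 0.001)
  expect_lt(shifted$medians[["y"]], shifted$medians[["x"]])
  expect_warning(compare_stability(list(x = a, y = a, z = 1)), "excluding")
})

test_that("temperature-sweep medians respect stability ordering", {
  cfg <- tiny_config(seed = 39L, contig_lengths = 20000L, n_sites = 15L,
                     hairpin_fraction = 1)
  pl <- plant_editing_sites(generate_genome(cfg), cfg)
  meds <- vapply(c(25, 30, 34) + 273.15, function(tk) {
    median(site_structure_dG(pl$genome, pl$truth, flank = 50L,
                             temperature = tk)$dG)
  }, numeric(1))
  expect_true(all(diff(meds) >= -1e-9))
})
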