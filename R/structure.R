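# Thermodynamics of the duplex substructure around edited sites.
#
# The energy model is a compact embedded nearest-neighbour set:
# Watson-Crick stacks carry published (dH, dS) pairs so that
# dG(T) = dH - T*dS; GU-containing stacks use a flat simplified value;
# loop penalties are tabulated at 310.15 K, extrapolated
# logarithmically beyond the table, and treated as purely entropic
# (scaled by T/310.15). This is an explicit stand-in for a full Turner
# parameter set: absolute dG values are not comparable with
# RNAStructure, but orderings and distribution shifts are.

#' Nearest-neighbour energy model
#'
#' @param ml_a,ml_b,ml_c Affine multiloop penalties (offset, per branch,
#'   per unpaired base) at 310.15 K, kcal/mol.
#' @param asym_per_nt,asym_max Internal-loop asymmetry penalty per
#'   unpaired-length difference and its cap, kcal/mol.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(ml_a = 3.4, ml_b = 0.4, ml_c = 0.4,
                         asym_per_nt = 0.5, asym_max = 3.0) {
  ptypes <- c("AU", "UA", "CG", "GC", "GU", "UG")
  dG37 <- matrix(NA_real_, 6, 6, dimnames = list(ptypes, ptypes))
  dH <- dG37
  set_stack <- function(p1, p2, g, h) {
    # a stack and its rotated view from the other strand share energy
    flip <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG",
              GU = "UG", UG = "GU")
    dG37[p1, p2] <<- g; dH[p1, p2] <<- h
    dG37[flip[p2], flip[p1]] <<- g; dH[flip[p2], flip[p1]] <<- h
  }
  # Watson-Crick x Watson-Crick stacks (Turner-style dG37/dH, kcal/mol)
  set_stack("AU", "AU", -0.93, -6.82)
  set_stack("AU", "UA", -1.10, -9.38)
  set_stack("UA", "AU", -1.33, -7.69)
  set_stack("CG", "AU", -2.11, -10.44)
  set_stack("CG", "UA", -2.08, -10.48)
  set_stack("GC", "AU", -2.35, -12.44)
  set_stack("GC", "UA", -2.24, -11.40)
  set_stack("CG", "GC", -2.36, -10.64)
  set_stack("GC", "GC", -3.26, -13.39)
  set_stack("GC", "CG", -3.42, -14.88)
  # simplified flat values for wobble-containing stacks
  gu <- c("GU", "UG")
  for (p1 in ptypes) for (p2 in ptypes) {
    n_gu <- (p1 %in% gu) + (p2 %in% gu)
    if (n_gu == 1L) { dG37[p1, p2] <- -1.3; dH[p1, p2] <- -8.0 }
    if (n_gu == 2L) { dG37[p1, p2] <- -0.5; dH[p1, p2] <- -6.0 }
  }
  dS <- (dH - dG37) / 310.15

  R <- 0.0019872  # kcal/mol/K
  js <- function(base_n, base_g, n) base_g + 1.75 * R * 310.15 * log(n / base_n)
  hairpin37 <- rep(Inf, 1000)
  hairpin37[3:9] <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)
  hairpin37[10:1000] <- js(9, 6.4, 10:1000)
  bulge37 <- numeric(30)
  bulge37[1:6] <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)
  bulge37[7:30] <- js(6, 4.4, 7:30)
  internal37 <- rep(Inf, 30)
  internal37[2:9] <- c(1.5, 1.8, 1.7, 1.8, 2.0, 2.2, 2.3, 2.4)
  internal37[10:30] <- js(9, 2.4, 10:30)

  # pair-type lookup over codes A=1, C=2, G=3, U=4
  pair_type <- matrix(0L, 4, 4, dimnames = list(c("A","C","G","U"),
                                                c("A","C","G","U")))
  pair_type["A", "U"] <- 1L; pair_type["U", "A"] <- 2L
  pair_type["C", "G"] <- 3L; pair_type["G", "C"] <- 4L
  pair_type["G", "U"] <- 5L; pair_type["U", "G"] <- 6L

  structure(list(stack_dG37 = dG37, stack_dH = dH, stack_dS = dS,
                 hairpin37 = hairpin37, bulge37 = bulge37,
                 internal37 = internal37,
                 ml_a = ml_a, ml_b = ml_b, ml_c = ml_c,
                 asym_per_nt = asym_per_nt, asym_max = asym_max,
                 min_hairpin = 3L, max_internal = 30L,
                 pair_type = pair_type),
            class = "energy_model")
}

.seq_codes <- function(sequence) {
  s <- chartr("Tt", "Uu", toupper(sequence))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  code <- match(ch, c("A", "C", "G", "U"))
  code[ch == "N"] <- 0L
  if (any(is.na(code)))
    stop("invalid sequence: only A/C/G/U/T/N allowed")
  code
}

#' Fold a sequence into its minimum-free-energy structure
#'
#' Computes the MFE nested structure at temperature `temperature`
#' (Kelvin) under the embedded nearest-neighbour model. `N` bases never
#' pair; `T` is treated as `U`. Sequences too short to form a hairpin
#' return the open chain with `dG = 0`. The open chain is always
#' feasible, so `dG <= 0`.
#'
#' @param sequence A single character string over A/C/G/U/T/N.
#' @param temperature Temperature in Kelvin (30 degrees C = 303.15 K).
#' @param model An [energy_model()].
#' @return An object of class `fold_result`: `sequence` (RNA alphabet),
#'   `pair_table` (1-based partner index, 0 = unpaired), `dot_bracket`,
#'   `dG` (kcal/mol) and `temperature`.
#' @export
fold_mfe <- function(sequence, temperature = 303.15,
                     model = energy_model()) {
  stopifnot(length(sequence) == 1L, inherits(model, "energy_model"))
  code <- .seq_codes(sequence)
  n <- length(code)
  if (n < model$min_hairpin + 2L) {
    res <- list(pairs = integer(n), dG = 0)
  } else {
    res <- fold_mfe_cpp(code, temperature,
                        model$stack_dH, model$stack_dS,
                        model$hairpin37, model$bulge37, model$internal37,
                        model$ml_a, model$ml_b, model$ml_c,
                        model$min_hairpin, model$max_internal,
                        model$asym_per_nt, model$asym_max,
                        model$pair_type)
  }
  pt <- res$pairs
  db <- rep(".", n)
  db[pt > seq_len(n)] <- "("
  db[pt > 0 & pt < seq_len(n)] <- ")"
  structure(list(sequence = chartr("T", "U", toupper(sequence)),
                 pair_table = pt,
                 dot_bracket = paste(db, collapse = ""),
                 dG = res$dG, temperature = temperature),
            class = "fold_result")
}

# loop decomposition of a pair table: for every pair, its parent pair
# (NA at top level) via a single stack scan; also the enclosing pair of
# every unpaired position.
.decompose <- function(pt) {
  n <- length(pt)
  opens <- which(pt > seq_len(n))
  parent <- rep(NA_integer_, n)        # per opening position
  enclosing <- rep(NA_integer_, n)     # per position: innermost open pair
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (pt[i] > i) {
      parent[i] <- if (length(stack)) stack[length(stack)] else NA_integer_
      enclosing[i] <- parent[i]
      stack <- c(stack, i)
    } else if (pt[i] > 0 && pt[i] < i) {
      stack <- stack[-length(stack)]
      enclosing[i] <- if (length(stack)) stack[length(stack)] else NA_integer_
    } else {
      enclosing[i] <- if (length(stack)) stack[length(stack)] else NA_integer_
    }
  }
  children <- vector("list", n)
  for (i in opens) {
    p <- parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  list(opens = opens, parent = parent, enclosing = enclosing,
       children = children)
}

#' Score a fixed structure under the energy model
#'
#' Evaluates the free energy of a given pair table at a given
#' temperature by loop decomposition (hairpin, stack, bulge, internal
#' and multiloop terms), without re-folding. Useful for re-scoring one
#' structure across temperatures.
#'
#' @param sequence Sequence string (A/C/G/U/T/N).
#' @param pair_table 1-based partner indices, 0 for unpaired.
#' @param temperature Kelvin.
#' @param model An [energy_model()].
#' @return Free energy in kcal/mol.
#' @export
structure_energy <- function(sequence, pair_table, temperature = 303.15,
                             model = energy_model()) {
  code <- .seq_codes(sequence)
  n <- length(code)
  stopifnot(length(pair_table) == n)
  pt <- pair_table
  scale <- temperature / 310.15
  ptype <- function(i, j) {
    if (code[i] == 0L || code[j] == 0L) return(0L)
    model$pair_type[code[i], code[j]]
  }
  lookup <- function(tab, size) {
    if (size < 1L || size > length(tab)) return(Inf)
    tab[size] * scale
  }
  dec <- .decompose(pt)
  e <- 0
  for (i in dec$opens) {
    j <- pt[i]
    if (ptype(i, j) == 0L)
      stop("invalid structure: non-pairable bases paired")
    kids <- dec$children[[i]]
    if (length(kids) == 0L) {
      e <- e + lookup(model$hairpin37, j - i - 1L)
    } else if (length(kids) == 1L) {
      k <- kids[1]; l <- pt[k]
      u1 <- k - i - 1L; u2 <- j - l - 1L
      if (u1 + u2 == 0L) {
        p1 <- ptype(i, j); p2 <- ptype(k, l)
        e <- e + model$stack_dH[p1, p2] -
          temperature * model$stack_dS[p1, p2]
      } else if (u1 + u2 > model$max_internal) {
        e <- e + Inf
      } else if (u1 == 0L || u2 == 0L) {
        e <- e + lookup(model$bulge37, u1 + u2)
      } else {
        e <- e + lookup(model$internal37, u1 + u2) +
          min(model$asym_max, model$asym_per_nt * abs(u1 - u2)) * scale
      }
    } else {
      spans <- sum(vapply(kids, function(k) pt[k] - k + 1L, integer(1)))
      unpaired <- (j - i - 1L) - spans
      e <- e + (model$ml_a + model$ml_b * (1L + length(kids)) +
                  model$ml_c * unpaired) * scale
    }
  }
  e
}

#' Extract the sequence window around an editing site
#'
#' Returns up to `flank` bases on each side of the site, clamped at the
#' contig ends. Minus-strand sites (reference base T) are
#' reverse-complemented so the window always reads in the edited-A
#' orientation.
#'
#' @param genome The reference `DNAStringSet`.
#' @param contig Contig name.
#' @param position 0-based site position.
#' @param strand `"+"` or `"-"`.
#' @param flank Flank size in bp (400 gives the classic 801 bp window).
#' @return A list: `sequence`, `offset` (1-based site position within
#'   the window), `start0`, `end0` (window bounds, 0-based inclusive).
#' @export
extract_window <- function(genome, contig, position, strand = "+",
                           flank = 400L) {
  L <- Biostrings::width(genome)[match(contig, names(genome))]
  if (is.na(L) || position < 0L || position >= L)
    stop("site outside genome")
  s0 <- max(0L, position - flank)
  e0 <- min(L - 1L, position + flank)
  seq <- as.character(Biostrings::subseq(genome[[contig]],
                                         start = s0 + 1L, end = e0 + 1L))
  offset <- position - s0 + 1L
  if (strand == "-") {
    seq <- revcomp(seq)
    offset <- (e0 - s0 + 1L) - offset + 1L
  }
  list(sequence = seq, offset = offset, start0 = s0, end0 = e0)
}

#' Extract the site-containing duplex substructure from a fold
#'
#' If the site is paired, the element is the maximal helix run
#' containing it, extended through interior loops and bulges until a
#' multiloop or exterior-loop boundary. If the site is unpaired but lies
#' inside a hairpin, bulge or interior loop, the enclosing helix element
#' is returned; sites in the exterior loop or a multiloop interior get
#' an `"unpaired"` verdict.
#'
#' @param fold A `fold_result`.
#' @param site_offset 1-based position of the site within the folded
#'   sequence.
#' @return An object of class `substructure`: `verdict` (`"paired"` or
#'   `"unpaired"`), `contiguous`, arm ranges `arm5`/`arm3` (1-based
#'   inclusive), the corresponding `fragments` and `site_offset`.
#' @export
extract_substructure <- function(fold, site_offset) {
  stopifnot(inherits(fold, "fold_result"))
  pt <- fold$pair_table
  n <- length(pt)
  stopifnot(site_offset >= 1L, site_offset <= n)
  dec <- .decompose(pt)
  unpaired_verdict <- structure(list(verdict = "unpaired",
                                     site_offset = site_offset),
                                class = "substructure")

  nkids <- function(i) length(dec$children[[i]])
  if (pt[site_offset] > 0L) {
    anchor <- min(site_offset, pt[site_offset])  # opening position
  } else {
    enc <- dec$enclosing[site_offset]
    if (is.na(enc) || nkids(enc) >= 2L) return(unpaired_verdict)
    anchor <- enc
  }
  # walk outward while the parent chains through a stack/bulge/internal
  outer <- anchor
  repeat {
    p <- dec$parent[outer]
    if (is.na(p) || nkids(p) != 1L) break
    outer <- p
  }
  # walk inward while the element continues as a single child chain
  inner <- anchor
  while (nkids(inner) == 1L) inner <- dec$children[[inner]][1]

  contiguous <- nkids(inner) == 0L  # innermost pair closes a hairpin
  oi <- outer; oj <- pt[outer]; ii <- inner; ij <- pt[inner]
  chs <- strsplit(fold$sequence, "", fixed = TRUE)[[1]]
  if (contiguous) {
    arm5 <- c(oi, oj)  # single fragment spanning the whole element
    frag <- paste(chs[oi:oj], collapse = "")
    res <- list(verdict = "paired", contiguous = TRUE,
                arm5 = arm5, arm3 = NULL,
                fragments = frag,
                site_offset = site_offset,
                outer_pair = c(oi, oj), inner_pair = c(ii, ij))
  } else {
    res <- list(verdict = "paired", contiguous = FALSE,
                arm5 = c(oi, ii), arm3 = c(ij, oj),
                fragments = c(paste(chs[oi:ii], collapse = ""),
                              paste(chs[ij:oj], collapse = "")),
                site_offset = site_offset,
                outer_pair = c(oi, oj), inner_pair = c(ii, ij))
  }
  structure(res, class = "substructure")
}

#' Join the two arms of a discontiguous substructure with an N linker
#'
#' A contiguous substructure is returned unchanged (no linker). For a
#' discontiguous one the 5' arm and 3' arm are joined by seven `N`
#' bases, which the energy model bars from pairing.
#'
#' @param sub A `substructure` with verdict `"paired"`.
#' @param linker_length Number of N bases (default 7).
#' @return A list: `sequence`, `linker_used`, and `map`, the original
#'   within-window position of every joined base (NA for linker bases).
#' @export
join_arms <- function(sub, linker_length = 7L) {
  stopifnot(inherits(sub, "substructure"))
  if (sub$verdict != "paired")
    stop("invalid substructure: nothing to join for an unpaired verdict")
  if (sub$contiguous) {
    return(list(sequence = sub$fragments[1], linker_used = FALSE,
                map = sub$arm5[1]:sub$arm5[2]))
  }
  if (sub$arm3[1] <= sub$arm5[2])
    stop("invalid substructure: overlapping arms")
  list(sequence = paste0(sub$fragments[1], strrep("N", linker_length),
                         sub$fragments[2]),
       linker_used = TRUE,
       map = c(sub$arm5[1]:sub$arm5[2], rep(NA_integer_, linker_length),
               sub$arm3[1]:sub$arm3[2]))
}

#' Free energy of a substructure
#'
#' Refolds the (possibly linker-joined) substructure sequence at the
#' given temperature and returns its MFE free energy; an `"unpaired"`
#' verdict is assigned `dG = 0`.
#'
#' @param sub A `substructure`.
#' @param temperature Kelvin.
#' @param model An [energy_model()].
#' @return Free energy in kcal/mol.
#' @export
substructure_dG <- function(sub, temperature = 303.15,
                            model = energy_model()) {
  stopifnot(inherits(sub, "substructure"))
  if (sub$verdict == "unpaired") return(0)
  joined <- join_arms(sub)
  fold_mfe(joined$sequence, temperature, model)$dG
}

#' Per-site substructure free energies
#'
#' Convenience driver: for each site, extract the window, fold it,
#' extract the site-containing substructure and compute its dG.
#'
#' @param genome The reference `DNAStringSet`.
#' @param sites A site table (orientation from `ref`: A = '+', T = '-')
#'   or a truth table with a `strand` column.
#' @param flank Window flank in bp.
#' @param temperature Kelvin.
#' @param model An [energy_model()].
#' @return A data frame: site coordinates, `paired`, `contiguous`,
#'   `linker_used`, `dG`, `temperature`.
#' @export
site_structure_dG <- function(genome, sites, flank = 400L,
                              temperature = 303.15,
                              model = energy_model()) {
  empty <- data.frame(contig = character(0), position = integer(0),
                      strand = character(0), paired = logical(0),
                      contiguous = logical(0), linker_used = logical(0),
                      dG = numeric(0), temperature = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) return(empty)
  strand <- if ("strand" %in% names(sites)) sites$strand
            else ifelse(sites$ref == "A", "+", "-")
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    w <- extract_window(genome, sites$contig[i], sites$position[i],
                        strand[i], flank)
    fold <- fold_mfe(w$sequence, temperature, model)
    sub <- extract_substructure(fold, w$offset)
    paired <- sub$verdict == "paired"
    out[[i]] <- data.frame(
      contig = sites$contig[i], position = sites$position[i],
      strand = strand[i], paired = paired,
      contiguous = if (paired) sub$contiguous else NA,
      linker_used = if (paired) !sub$contiguous else NA,
      dG = substructure_dG(sub, temperature, model),
      temperature = temperature, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Significance-star label for a p-value
#'
#' Thresholds follow the usual figure-legend convention, inclusive on
#' the starred side: ns for p > 0.05, `*` for p <= 0.05, `**` for
#' p <= 0.01, `***` for p <= 0.001, `****` for p <= 0.0001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of labels.
#' @export
star_label <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) NA_character_
    else if (x <= 0.0001) "****"
    else if (x <= 0.001) "***"
    else if (x <= 0.01) "**"
    else if (x <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' Rank-based comparison of dG distributions
#'
#' Pairwise two-sided Mann-Whitney (Wilcoxon rank-sum) tests between
#' labeled sets of substructure free energies, with per-set medians and
#' significance stars. Sites without a duplex substructure carry
#' `dG = 0`; set `include_zeros = FALSE` to drop them.
#'
#' @param dG_sets Named list of numeric vectors (kcal/mol).
#' @param include_zeros Keep dG == 0 entries?
#' @return A list: `medians` (named) and `comparisons`, a data frame
#'   with `set1`, `set2`, `p`, `label`.
#' @export
compare_stability <- function(dG_sets, include_zeros = TRUE) {
  stopifnot(is.list(dG_sets), length(dG_sets) >= 2L,
            !is.null(names(dG_sets)))
  if (!include_zeros)
    dG_sets <- lapply(dG_sets, function(x) x[x != 0])
  small <- lengths(dG_sets) < 2L
  if (any(small)) {
    warning("excluding set(s) with < 2 values: ",
            paste(names(dG_sets)[small], collapse = ", "))
    dG_sets <- dG_sets[!small]
  }
  if (length(dG_sets) < 2L)
    stop("fewer than two usable sets remain")
  meds <- vapply(dG_sets, median, numeric(1))
  pairs <- utils::combn(names(dG_sets), 2)
  comparisons <- data.frame(set1 = pairs[1, ], set2 = pairs[2, ],
                            p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- dG_sets[[pairs[1, i]]]; b <- dG_sets[[pairs[2, i]]]
    comparisons$p[i] <- if (length(unique(c(a, b))) == 1L) 1
      else suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }
  comparisons$label <- star_label(comparisons$p)
  list(medians = meds, comparisons = comparisons)
}
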