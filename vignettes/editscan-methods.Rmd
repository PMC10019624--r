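---
title: "Methods: detecting and quantifying A-to-I editing in an editing-naive genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying A-to-I editing in an editing-naive genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA.
Because reverse transcriptase and sequencers read inosine as guanosine,
A-to-I editing shows up as A-to-G mismatches between RNA-seq reads and
the reference genome. An organism with no endogenous ADAR — baker's
yeast being the canonical choice — is an *editing-naive* testbed: any
excess of A-to-G mismatch sites that appears when a heterologous ADAR
is expressed, and is absent from matched DNA sequencing, is attributable
to that enzyme. editscan implements the complete computational side of
such an experiment: simulation of a ground-truth dataset, de novo site
detection, genome-wide quantification, sequence-context and recurrence
summaries, thermodynamic analysis of the RNA structure around edited
sites, and growth-assay statistics.

## Detection model

For every reference position with RNA depth $n \ge 5$ we take the
single most frequent non-reference allele with count $k$ (alphabetical
tie-break, flagged `ambiguous`). With an unstranded library a mismatch
and its reverse complement are indistinguishable, so the 12 ordered
mismatch types collapse into 6 classes; A>G/T>C is the editing class.

The null hypothesis is that all $k$ alternative reads are sequencing
errors. With a uniform per-base error rate $e$ a specific alternative
base occurs with probability $e/3$, so the raw p-value is the exact
binomial upper tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(n, e/3).$$

The default $e = 10^{-Q/10}$ at the base-quality cutoff $Q = 20$ is
deliberately conservative (real post-filter error rates are lower);
users simulating or observing a better-calibrated $e$ can pass it
explicitly. p-values are corrected by a Benjamini–Hochberg step-up in
which the multiplier uses `m_tests` — by default the full genome length,
the conservative choice used at genome scale, where the number of
positions examined is bounded by the genome size — rather than the
candidate-list length. Sites with $q \le 0.05$ are reported.

A candidate must also look homozygous-reference in DNA: depth $\ge 5$
and zero DNA reads of the *candidate* allele. Counting only the
candidate allele (rather than any non-reference base) is intentional:
a genomic SNP masquerading as editing produces exactly the candidate
allele in DNA, while unrelated DNA sequencing errors at the same column
should not veto an RNA signal. Three published filter values are kept
as defaults (`min_depth = 5`, `min_level = 0`, unstranded handling);
the remaining knobs (`min_alt_reads = 2`, FDR 0.05, the DNA
homozygosity rule) are this package's own choices where the original
pipeline delegates to its caller, and are all configurable.

## Editing index

The genome-wide editing index is the read-weighted fraction of
adenosine-derived nucleotides observed as guanosine, in percent:

$$\mathrm{index} = 100 \cdot
  \frac{\sum_{i \in A} G_i + \sum_{i \in T} C_i}
       {\sum_{i \in A} (A_i + G_i) + \sum_{i \in T} (T_i + C_i)}.$$

Pooling the T-reference (minus-strand) terms is the unstranded analogue
of the stranded index used in the literature. It is algebraically the
depth-weighted mean of per-position mismatch rates, which the tests
check numerically. An optional flag excludes positions with any
DNA-supported variant, making the baseline of a polymorphism-bearing
sample interpretable; both behaviours are provided because published
genome-wide indexes do not always state which was used.

## Synthetic data: the stated world

The generator emulates the sequencing design of an editing-naive yeast
experiment and nothing more:

* i.i.d. genome at configurable GC (default 0.38, yeast-like);
* editing sites planted at adenosines on both strands with per-site
  editing level $\varphi$; with probability `motif_bias` a candidate
  with a 5' G (on its own strand) is rejected and redrawn, mimicking
  the upstream-G depletion of the ADAR motif;
* optionally, sites embedded mid-arm in planted inverted repeats (30 bp
  arms, 10 bp loop by default — the geometry is not specified anywhere,
  and these values fold confidently) to create bona fide dsRNA
  substrates;
* single-end 75 bp unstranded reads (read orientation uniform), start
  positions uniform, depth set by a mean coverage (default 50x; no
  depth is published for the original libraries, so this is an explicit
  choice and fully configurable);
* per-read editing at each overlapped truth site
  (Bernoulli($\varphi$)), then uniform substitution error $e$ with
  equal weight $e/3$ on each alternative base, fixed Q30 qualities;
* matched DNA reads: same model, no editing.

Reads are emitted pre-aligned (truth SAM, ungapped, single `M` run):
alignment is out of scope and removing the aligner keeps the tests
hermetic. Not modelled, deliberately: splicing, indels, paired ends,
PCR duplicates, GC-coverage bias, quality decay, expression-level
variation between loci. A green test therefore establishes correctness
of the statistics on this idealised world, not robustness to alignment
artefacts or library pathologies.

Determinism contract: one integer seed fixes every output byte; each
generation stage re-seeds with a fixed offset of it so stages remain
individually reproducible.

## RNA structure thermodynamics

For each site the package extracts a window (default 400 bp per side,
an 801 bp window; minus-strand sites are reverse-complemented into the
edited-A orientation), folds it at temperature $T$, extracts the
site-containing duplex element and reports that element's free energy.

The folder is a Zuker-style MFE dynamic programme over a compact
nearest-neighbour model: Watson–Crick stacks carry published
$(\Delta H, \Delta S)$ pairs so that $\Delta G(T) = \Delta H - T\Delta
S$; GU-containing stacks use flat simplified values; hairpin, bulge and
internal-loop initiation are tabulated at 310.15 K with logarithmic
extrapolation beyond the tables, plus a capped internal-loop asymmetry
term and an affine multiloop. Loop penalties are treated as purely
entropic, scaled by $T/310.15$ — the standard approximation when loop
enthalpies are unavailable. Internal loops are capped at 30 unpaired
bases; no pseudoknots, coaxial stacking or dangles. This is an
explicit, documented stand-in for a full Turner/RNAStructure parameter
set: absolute $\Delta G$ values are not comparable with RNAStructure
output, and only orderings and distribution shifts are claimed.
Temperatures enter the CLI in Celsius and are converted as
$K = {}^\circ C + 273.15$.

Numerical choices: the DP fills with strict-improvement updates over a
fixed candidate scan order, and the traceback re-scans in the same
order taking the first candidate that achieves the stored energy, so
tie-breaking is deterministic. Sequences shorter than a minimal hairpin
return the open chain at $\Delta G = 0$; since the open chain is always
feasible, $\Delta G \le 0$ everywhere. `N` never pairs.

The *substructure* around a site is the maximal helix run containing
the site's pair, extended through interior loops and bulges and
stopping at a multiloop or exterior-loop boundary. An unpaired site
inside a hairpin/bulge/interior loop inherits the enclosing element; a
site in the exterior loop or inside a multiloop is "unpaired" and is
assigned $\Delta G = 0$, following the published convention. When the
element's two arms are discontiguous they are joined by seven `N`
bases before refolding. The source text for this procedure is
ambiguous about whether the linker is seven forced N·N pairs or an
unpairable spacer; we implement the unpairable 7-N spacer, which is
well-defined under any energy model (the alternative would require
assigning an energy to N·N pairs). Likewise "the most probable
structure" of the refolded substructure is implemented as the MFE
structure: it is deterministic and testable, where a
partition-function maximiser would not be resolvable from the text.
Group comparisons of $\Delta G$ distributions use two-sided
Mann–Whitney tests with the figure-legend star convention.

## Growth assays

Liquid-culture growth is summarised by the plain trapezoidal AUC of
the OD600 time series — no logistic fit, matching how published AUCs
over a fixed 22 h span are computed in practice. Spot assays reduce to
the pixel-density ratio inducing/repressing. Pairwise comparisons use
two-sided Welch t-tests (the published figures show stars but never
name the test; Welch is the defensible default at $n = 3$ replicates),
unpaired and uncorrected for multiple comparisons — also unstated in
the source, and flagged here. Star labels are inclusive on the starred
side: `*` for $p \le 0.05$ through `****` for $p \le 0.0001$.

## Tunable parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `min_depth` | 5 | reads | published filter (`editDepth 5`) |
| `min_level` | 0 | fraction | published filter (`editLevel 0`) |
| `min_alt_reads` | 2 | reads | singleton errors are indefensible support |
| `base_quality_min` | 20 | Phred | standard pileup hygiene |
| `error_rate` | 1e-2 | /base | Phred-implied at Q20; override when known |
| `m_tests` | genome length | tests | conservative genome-scale BH |
| `fdr_level` | 0.05 | — | conventional FDR cut |
| `dna_min_depth` / `dna_max_alt` | 5 / 0 | reads | strict homozygous-reference rule |
| `flank` | 400 | bp | 801 bp folding window |
| folding `temperature` | 303.15 | K | 30 °C culture temperature |
| `coverage` | 50 | x | unpublished; explicit simulator choice |
| `read_length` | 75 | bp | matches the published sequencing design |
| `gc_content` | 0.38 | fraction | yeast-like composition |

## Known limitations

* The detector is a defined stand-in for the published caller's core
  test, not a byte-compatible clone; its additional heuristics
  (positional trimming, etc.) are undocumented and not reproduced.
* The energy model is simplified; do not compare absolute kcal/mol
  against Turner-parameter implementations.
* O(n³) folding makes 801 bp windows cost seconds each; the CLI
  exposes `--max-window` to cap the window for large site sets.
* No splice-aware pileup, indel handling, strand-specific libraries or
  hyper-editing cluster rescue.
* Region-restricted indexes (e.g. the Alu editing index) and
  gene-level annotation of sites are out of scope.
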