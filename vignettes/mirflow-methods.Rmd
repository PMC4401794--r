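---
title: "mirflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirflow)
```

# The problem

Small RNA sequencing of two pooled libraries — here called P
(pre-receptive) and R (receptive), after the two endometrial states such a
design typically contrasts — yields tens of millions of 36 bp adapter-ligated
reads per condition and no biological replicates. Turning those reads into a
defensible list of differentially expressed microRNAs requires a chain of
small, well-defined decisions: which reads are usable, which derive from
other RNA classes, which match known mature miRNAs (and how to name their
isomiR variants), which unannotated reads sit in genomic loci that can fold
into miRNA-like hairpins, and how to test two single counts against each
other. `mirflow` implements that chain end to end, together with a seeded
synthetic-data generator so every stage can be verified against planted
ground truth without any external download.

# Read cleaning

Reads are processed in a fixed order so that each read receives exactly one
fate and the accounting report partitions the input:

1. **Adapter trimming.** The insert is the prefix before the leftmost exact
   occurrence of at least `min_overlap` (default 8) bases of the 3' adapter's
   5' end. Reads with no such match are discarded ("3' adapter not found").
   No mismatches are allowed in the adapter seed; the bound is configurable.
2. **Length filter.** Inserts outside 18–26 nt are discarded; this is the
   canonical animal mature-miRNA length window, and 22 nt is expected to be
   the modal length.
3. **Junk filter.** Low-complexity inserts are discarded when any rule
   holds, tested in this order: at least 2 `N` bases in total; a homopolymer
   run of ≥7 A, ≥8 C, ≥6 G or ≥7 T; a tandem repeat of a 2-mer unit ≥10
   times, a 3-mer unit ≥6 times, or a 4-mer unit ≥5 times. The repeat rules
   are read as *consecutive* tandem copies. Homopolymeric repeat units never
   reach the repeat rules because the (earlier) run rules already catch any
   homopolymer long enough to constitute such a repeat.

Survivors are collapsed to unique tags with counts. The "unique" columns of
the cleaning report count distinct *raw* read sequences per fate, which is
what makes the uniqueness accounting partition exactly.

# Contaminant annotation

Tags are 18–26 nt, so full-scale alignment heuristics are unnecessary:
classification is ungapped full-tag substring search against each reference
set, on both strands, with 0 (default) or 1 substitution. Because the same
tag can match several classes (rRNA fragments inside repeat consensus
sequences, for instance), categories are made disjoint by a priority order —
rRNA, tRNA, snRNA, snoRNA, other ncRNA, mRNA, repeats by default,
configurable — and each tag goes to the first category it hits. Published
reports of this kind acknowledge the same overlap without stating a
resolution; an explicit priority makes the partition reproducible.

# Known miRNA identification

Retained tags are aligned (ungapped, sense strand) onto the reference
precursors with at most one substitution, and end offsets of at most ±3 nt
relative to the annotated mature sequence. Among feasible placements the
match minimizing (substitutions, total absolute offset, mature id) wins,
which makes output deterministic. Variant names follow the field's isomiR
convention: `base_L+1R-1` for end shifts, `_1ss12TA` for a substitution at
tag position 12 with reference T observed as A; a parser is provided and
round-trips are tested.

Each reported miRNA receives an evidence group: **gp1b** when its reference
precursor occurs in the genome; **gp2a** when the precursor does not but the
tag does, at a locus whose flank-extended sequence can form a hairpin;
**gp3a** when neither maps; **gp4a** for tags matching no known miRNA but
sitting in a hairpin-forming genomic locus (the novel candidates).

# Novel miRNA candidates

Unannotated tags are located in the genome by exact search (both strands)
and the locus is extended by 80 nt. Folding uses a deliberately simple,
pluggable backend: a dynamic-programming maximizer of weighted base pairs
(GC = 3, AU = 2, GU = 1, minimum loop 3) with free energy defined as
−(pair-weight sum) × 0.35 kcal/mol. The calibration constant was chosen once
so that typical miRNA-like hairpins — stems of 25–40 pairs — land inside the
published plausibility band (−80.5 to −17.7 kcal/mol); it is irrelevant when
an external thermodynamic folder is plugged in through the `backend`
argument of `fold_sequence()`.

A candidate passes when the *trimmed hairpin* (the maximal single-terminal-
loop span of paired bases enclosing the mature, not the 80 nt search window)
satisfies all of: length 50–123 nt, GC fraction 0.23–0.77, free energy
−80.5 to −17.7 kcal/mol, a single terminal loop, and the mature entirely on
one arm with at most 4 unpaired mature bases (the last bound is our choice;
the source material is silent). Failure reasons are reported exhaustively,
and the reasons list is empty exactly when a candidate passes.

One design decision deserves emphasis: folding the entire 160+ nt search
window lets distant flank sequence pair across a genuine stem, so candidate
evaluation scans *mature-anchored subwindows* of the search window (smallest
extensions first; `candidate_windows()`), accepting the first window whose
excised hairpin passes. This mirrors how hairpin-excision tools behave in
practice and makes recovery of genuine precursors robust; the
shuffled-sequence negative control (pass rate below 25%) guards the other
side.

# Differential expression

Counts are normalized to reads per million of the library's clean reads
(NE). Pairs with NE below 1 in both libraries are discarded; a zero NE is
replaced by 0.001 when a ratio must be formed. The fold change is
NE~R~/NE~P~ with its log2; classes are **down** (ratio ≤ 1/2), **mid**
(1/2 < ratio ≤ 2) and **up** (ratio > 2).

The significance test is the exact conditional two-library count test: given
`x` counts among `N1` reads, the count `y` among `N2` reads follows

$$p(y\,|\,x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}.$$

Computed in log space, the lower tail $C = \sum_{y' \le y} p(y'|x)$ and
upper tail $D = \sum_{y' \ge y} p(y'|x)$ give the reported two-sided
p-value $\min(1, 2\min(C, D))$; one-sided tails are also exposed. Three
numerical decisions are documented here:

* **Counts, not NE, feed the test.** The factorials require integers;
  normalized expression drives only the fold change and the filters.
* **The two-sided rule** is ours (the construction defines both tails but
  not their combination); `2 min(C, D)` capped at 1 is the standard choice.
* **The swap identity** `p(y|x; N1, N2) = p(x|y; N2, N1)` holds term by term
  only at equal depths; the tail-based two-sided p-value is not exchangeable
  under the swap, a known property of this conditional construction. Tests
  assert the exact term-level symmetry at `N1 = N2`.

miRNAs detected in exactly one library (and passing the expression filter)
are reported as *specific*, without fold change or p-value. Significance is
raw `p < 0.05` with `|log2 ratio| > 1`; no multiple-testing correction is
applied by default because the upstream convention uses raw p-values (a
Benjamini–Hochberg adjustment can be applied downstream by the user).
Ordering is deterministic: decreasing |log2 ratio|, ties by name, specific
rows last.

# Targets, enrichment, network

Animal miRNA targeting is dominated by seed pairing, so the built-in
predictor reports exact 3'UTR occurrences of the reverse complement of
miRNA positions 2–7 (6-mer) or 2–8 (7-mer). "Strict" mode requires both
spans to match somewhere in the UTR — emulating the usual two-program
intersection rule — and "loose" mode either. Full TargetScan/miRanda
scoring is deliberately out of scope; the seed definition keeps the
pipeline self-contained and testable against planted sites.

Term enrichment is the upper-tail hypergeometric probability

$$P = 1 - \sum_{i=0}^{m-1}
  \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}$$

with `N` annotated background genes, `n` annotated targets, `M` term
carriers in the background and `m` among targets, computed in log space
via `lchoose` and verified against exhaustive subset enumeration for all
`N ≤ 12`. GO-style and pathway-style namespaces share the same machinery.
No term-graph propagation is attempted.

The miRNA–gene network is the bipartite adjacency `a[i, j] = |log2 ratio|`
of miRNA *i* when gene *j* is among its predicted targets (binary weights
optional — the upstream weighting convention is undefined, so ours is a
documented choice). Gene degree equals the number of targeting miRNAs.

# qPCR validation

Relative expression is the plain `2^-ddCt` model with
`ddCt = (Ct_miRNA − Ct_ref)_R − (Ct_miRNA − Ct_ref)_P`; the baseline
condition evaluates to 1 by construction and the statistic is invariant to
adding a constant to all four Ct values. Replicates are aggregated by
averaging delta-Ct within condition before forming ddCt; per-replicate
relative expressions against the mean baseline delta-Ct supply the reported
spread. No amplification-efficiency correction is applied. Direction
concordance with sequencing compares `relative expression > 1` against
`DE ratio > 1`, with a "flat" flag when either side is exactly 1.

# The synthetic world

The generator emulates the stated experimental design, and its defaults are
fixed once:

* **Reads** are 36 bp, mature sequence plus a 20-mer 3' adapter, constant
  quality `I` (the pipeline ignores quality, so none is simulated).
* **Counts** per miRNA are negative binomial around design means with
  dispersion 1e-4 — near-Poisson, because a pooled two-library design has
  no replicate-level biological variance to model; dispersion is
  configurable for stress tests.
* **Composition**: 30% of raw reads lack the adapter, 0.1% are junk
  (cycling through the eight junk rules), 15% are contaminants split by
  the category proportions of a typical mammalian small RNA report (rRNA
  dominating), and the rest are miRNA reads. Lengths follow a distribution
  with mode 22 nt.
* **References**: each mature (18–26 nt) sits on one arm of a perfect-stem
  hairpin precursor (loop drawn from {A, C} so it cannot pair internally);
  a subset of precursors is embedded in ≥1 kb genome contigs on alternating
  strands, with classes constructed for each evidence group; 3'UTRs carry
  planted 7-mer seed sites, and stray occurrences of any known miRNA's
  seed site are scrubbed so strict-mode target prediction recovers exactly
  the planted gene sets.
* **Cleanliness by construction**: miRNA and contaminant reads are
  rejection-sampled against the junk rules and the adapter seed, and junk
  reads are built to violate a specific rule, so the cleaning and
  annotation reports can be compared with the ground truth *exactly*, not
  approximately. Hairpin inserts that must provide hairpin evidence (gp2a
  and novel loci) are validated in their genomic context at embedding time
  and rebuilt if the screen fails — the generator's contract is that
  planted loci pass, and it enforces that contract by rejection.

What the generator does **not** emulate: sequencing error profiles, quality
degradation, barcodes, strand-specific transcription models, replicate
structure, or the long tail of partially-degraded RNA fragments in real
libraries. A green end-to-end test therefore establishes that the pipeline's
logic is correct and internally consistent on data obeying its stated
assumptions — not that it is robust to every artifact of a real sequencing
run.

All randomness flows from one integer seed through R's generator; identical
seeds give byte-identical FASTA/FASTQ/TSV output.

# Numerical and degenerate-input choices

* Tail sums of the exact test run over at most `x + y + 1` log-space terms;
  the upper tail is `1 − C + p(y|x)`, avoiding an infinite sum.
* `hypergeom_enrich` clamps to [0, 1] against rounding at the boundaries
  (`m = 0` and `M = N` are exact closed forms).
* Empty inputs are first-class: zero clean reads, zero edges, zero novel
  candidates all produce empty, correctly-typed tables.
* Ties anywhere (reference matching, known-miRNA placement, report
  ordering) are broken lexicographically so reruns are bit-identical.
* The folder treats T and U as the same base and is deterministic; its
  traceback prefers pairing and the smallest partner index on equal scores.

# Known limitations

* The built-in folder maximizes weighted pairs; it is not a thermodynamic
  model. Its energies are calibrated, not physical, and candidate
  evaluation with the default backend should be read as a structural
  plausibility screen. A ViennaRNA-style folder can be plugged in.
* With no replicates, the exact conditional test measures sampling
  variability only; its p-values say nothing about biological variance
  (the usual caveat for two-library designs).
* The "selected vs specific species" reference distinction used by some
  published groupings is not implementable without the underlying species
  lists; a single known-miRNA bundle is exposed instead.
* Enrichment treats terms independently: no GO DAG propagation, no pathway
  topology.
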