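---
title: "Methods: C-terminal Cys/Sec motif analysis and neighbourhood enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: C-terminal Cys/Sec motif analysis and neighbourhood enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selotools)
```

## The problem

Selenoprotein O (SELO; bacterial ydiU, yeast FMP40) is a kinase-like protein
family whose members frequently end with a thioredoxin-reminiscent redox
motif: a cysteine or selenocysteine three residues before the C-terminus,
often paired with a second cysteine a short, variable distance upstream
(CxxCxx>, CxxUxx>, CxCxx>, or Cx(3,10)Cxx>, where `>` marks the polypeptide
terminus).  Characterising such a family from public sequence data requires
a chain of small, individually verifiable computations:

1. classify and census anchored C-terminal motifs over a sequence set;
2. ask whether a motif is overrepresented against a reference composition,
   with p-values that remain meaningful when they are astronomically small;
3. reduce a redundant homologue collection to a representative set at an
   identity threshold;
4. rescue selenoproteins whose Sec codon (UGA) was misannotated as a stop,
   truncating the deposited protein;
5. test whether particular gene families (COGs) cluster in the genomic
   neighbourhood of the family's genes, and whether particular lifestyles
   are overrepresented among the organisms carrying them.

`selotools` implements each stage as a plain R function over ordinary
containers (named character vectors of sequences, data frames of genes and
traits), plus seeded generators that produce synthetic inputs with known
ground truth for every stage.

## Anchored motif grammar and ring classification

Patterns use the conventional compact syntax: residue letters (including
`U`), classes like `[CU]`, wildcards `x`, bounded gaps `x(m,n)`, and a
trailing `>` anchoring the final element at the C-terminus.  Matching is
exact set membership — no scoring.  Two grammar decisions matter:

* **`C` never matches `U`.**  The analyses distinguish CxxCxx> from
  CxxUxx> throughout, so a bare letter matches only itself and `[CU]` is
  written where either residue is acceptable.
* **Bounds of `x(m,n)` are inclusive at both ends**, so `C-x(3,10)-[CU]-x-x>`
  spans between 9 and 14 residues.  Because of that 14-residue maximal
  span, classification requires sequences of at least 14 residues, and the
  outer-ring call depends on at most the final 14.

`classify_terminus()` reports two nested categories, mirroring the usual
two-ring annotation of family trees: the *inner* ring is the identity of
the residue at position −3 (`U_TERM`, `C_TERM`, `NONE`); the *outer* ring
records an additional upstream cysteine with precedence to the smallest
gap (CXXC, then CXC, then CX_RANGE_C), which makes the categories mutually
exclusive.  Case is folded and a trailing `*` or `>` in input FASTA is
stripped with a warning.

The matcher compiles patterns to regular expressions; its correctness is
established in the test suite against an oracle that exhaustively
enumerates every assignment of the bounded gaps on patterns of span up to
15.

Kinase-fold fingerprints (`annotate_kinase_fingerprint()`) locate the six
ordered motifs of the family's kinase-like domain — the Walker-A-like
glycine loop `GxxGxG`, the β3 lysine, the αC glutamate, the `[HQ]G[VNS]`
catalytic-loop variant that replaces the canonical HRD, the Mg-binding
asparagine, and the strictly conserved `D[YF]G`.  Search is greedy-earliest
with each slot constrained to start after the previous placed slot; no
tie-breaking information beyond that exists, so the first admissible
occurrence wins.  `column_conservation()` supplies the per-column residue
frequencies and information content (`log2 20 − H`, in bits, gaps excluded
from the distribution, columns over 50% gaps flagged) that sequence logos
display.

## Enrichment statistics

All tail probabilities are computed in log space.
`log10_binomial_tail(k, n, p)` evaluates `log10 P(X ≥ k)` by log-sum-exp
over log-gamma terms, so values far below the double-precision underflow
limit (10^−500 and beyond) remain finite and comparable — necessary
because the family's motif nulls genuinely reach such magnitudes (12 of
143 sequences carrying Cxx[CU]xx> against a background of 585 in half a
million yields about 10^−18.3; the generalised [CU]xx> terminus reaches
below 10^−189).  Correctness is pinned by two independent routes: exact
integer-arithmetic summation on a small grid, and R's own log-scale
`pbinom` survival function.

`expected_count()` turns a residue-composition model into the expected
number of database sequences matching an anchored pattern: the product of
class frequency sums over fixed elements, and for a bounded gap the match
may occur at any of the `M − m + 1` widths, treated as independent
(`1 − Π(1 − p_fixed)`), a deliberate simplification validated against
simulation to within Monte-Carlo error.

`fisher_exact()` implements the two-sided probability-mass definition (sum
of hypergeometric probabilities of tables at most as probable as observed,
margins fixed) via `dhyper`, with a 1e−7 relative slack for ties in
floating point; the suite checks it against exhaustive integer-exact
enumeration on all tables with margins ≤ 12.  Bonferroni correction is
applied on the log scale (`min(0, log10 p + log10 m)`) so extreme tails
survive the correction; the zero-background policy is to refuse a test
with a warning rather than silently pseudo-count.

Trait (lifestyle) enrichment counts trait-positive organisms among a
selected set against stated background frequencies, one binomial upper
tail per trait, Bonferroni over the traits tested, and attaches pairwise
Fisher independence tests among the significant traits.

## Representative sets

`global_identity()` is Needleman–Wunsch global alignment (match +1,
mismatch 0, linear gap −1 by default — linear so that the brute-force
alignment-enumeration oracle in the tests stays tractable) with identity
defined as identical columns over alignment length *including* gap
columns: the conservative convention, stated explicitly because published
redundancy filters rarely document theirs.  `greedy_reduce()` follows the
CD-HIT convention — longest first, ties by identifier, each sequence
joining the most similar admissible representative — which makes the
result deterministic.  Two invariants are asserted in the verification
mode and checked throughout the suite: no representative pair reaches the
threshold, and every removed sequence reaches it to its assigned
representative.

## Sec stop-codon rescue

The rescue rule formalises how a truncated selenoprotein betrays itself in
a family with a conserved `[CU]xx>` terminus.  A call of `LIKELY_SEC`
requires all four of:

1. the annotated terminus sits exactly three consensus columns short of
   the family consensus terminus (consensus columns are those with ≤ 50%
   gaps; the consensus terminus is the last of them);
2. the annotated stop codon is TGA;
3. reading through the TGA (as U) yields exactly two further sense codons
   followed by an in-frame TAA or TAG — a second TGA is rejected rather
   than chained;
4. the column the readthrough U would occupy carries C or U in at least
   50% of its non-gap rows.

The rescued protein appends `U` plus the two readthrough residues,
restoring the `[CU]-x-x>` terminus, and is required by the tests to
re-translate exactly from the CDS under TGA→U.  Only this 3-residue
(Uxx>) geometry is rescued; longer truncations are reported
`NOT_CANDIDATE` with a note, since no comparable family signature
constrains them.  The 50% column-support threshold is a design choice —
it is the weakest majority rule, and planted fixtures in the suite show
the verdicts are insensitive to it when the misannotated records are a
small minority, which is the regime in which a family consensus exists at
all.

## Genomic-neighbourhood COG enrichment

One window of total width 22 kbp (half-width 11 kbp each side, the
conventional choice for operon-scale context) is anchored at the midpoint
of each focal gene; anchoring at the midpoint keeps the window symmetric
since nothing in the method distinguishes upstream from downstream, and
strand is ignored.  A gene belongs to the window when its interval
overlaps it by at least 1 bp.  The census statistic is *presence* per
window, not gene count — duplicated neighbours never inflate it — and the
focal gene's own COG is excluded by default to avoid self-enrichment.
Windows truncate at replicon ends; no circular wrap is attempted because
replicon topology is not part of the inputs.

Backgrounds come from reference genomes in either of two modes:
`poisson` uses the closed form `p_c = 1 − exp(−n_c · W / L_total)` (gene
density times window width), `montecarlo` drops seeded random windows and
reports the empirical presence fraction; the two agree within Monte-Carlo
error on uniform synthetic genomes, apart from a small edge deficit of
the truncated random windows.  Raw tails are `log10_binomial_tail(k,
n_windows, p_c)`, Bonferroni-corrected over `m_tested`, which defaults to
the number of COGs censused but is exposed as a parameter: published
analyses differ in whether they correct over the COGs observed or the
full catalogue, and the two differ by a constant factor on the log scale.

One calibration caveat is worth stating because the tests quantify it.
The binomial test treats `p_c` as known.  When the reference panel is
small, per-COG counts carry large relative error, and the COGs whose
background happens to be under-estimated are tested against too low a
threshold: with a 200-genome synthetic panel (per-COG counts ≈ Poisson
with mean 15) the aggregate null rejection rate at 0.05 measurably drifts
to ≈ 0.054, while with a 1000-genome panel it sits at ≈ 0.032, inside
binomial tolerance.  The calibration checks therefore use the
well-estimated regime; users applying the method with few reference
genomes should expect the same mild anti-conservativeness.

## Presence summaries and the pipeline

`summarize_presence()` converts per-domain homologue counts into integer
percentages, rounding half-up (79/121 → 65%, 1101/2780 → 40%, 3/107 → 3%);
R's banker's rounding is deliberately avoided because reported percentages
conventionally round half away from zero.  `run_pipeline()` wires the
stages over file inputs, validates every path before writing anything,
records every resolved parameter in a JSON manifest, and is byte-identical
across reruns at a fixed seed.  A thin command-line wrapper
(`inst/scripts/selo-pipeline.R`) exposes `simulate` and `run`.

## The synthetic-data generators

Every generator is a pure function of its configuration: sub-seeds are
derived from the root seed and a fixed per-generator label, so adding one
generator never perturbs another's stream.

* **Proteomes** (`gen_proteome`): i.i.d. residues from a SwissProt-like
  composition (Cys at 1.37%), lengths uniform over a configured range
  (the simplest distribution compatible with the 14-residue terminal
  window).  Planting overwrites the final 14 residues, drawing
  non-fixed positions from the composition *excluding* C and U so that a
  planted class is never contaminated into a different one; the planted
  label is the ground truth and classification recovers it with
  sensitivity 1 by construction.
* **Genomes** (`gen_genome_tables`): one linear replicon per genome,
  gamma-distributed gene lengths (mean 900 bp), exponential spacers
  (mean 150 bp), 30 genes, a 400-label COG vocabulary — chosen so a
  22 kbp window covers ≈ 20 genes and a random COG's window presence sits
  near 5%, a realistic microbial gene density and a convenient null.
  Exactly one focal gene per genome (background labels exclude the focal
  COG); planted COGs relabel a random gene overlapping the focal window
  with the configured probability.
* **Traits** (`gen_trait_table`): independent Bernoulli traits at stated
  background frequencies, with a designated subset drawn at enriched
  frequencies — the aquatic-lifestyle configuration (47% in the subset vs
  16% background, subset 200) has exact-binomial power above 0.99 at the
  10^−6 level, which the suite verifies before asserting rejections.
* **Readthrough CDS** (`gen_readthrough_cds`): a family with a conserved
  terminal block, C or U at position −3; flagged records encode the U as
  TGA and are annotated truncated; codons are drawn uniformly among
  synonyms.  The generator also emits the gapped C-terminal alignment of
  the *annotated* proteins that the detector consumes (truncated rows end
  three columns short).  With the misannotated records in the minority the
  consensus terminus is the full-length one; at `sec_fraction` above 50%
  no meaningful family consensus exists and detection is not expected to
  work — a limitation shared with the real procedure.
* **Clusters** (`gen_protein_clusters`): centroid sequences with
  per-position mutation at a configured rate, giving within-cluster
  identities near `100(1 − µ)`% and between-cluster identities at the
  random-alignment baseline, for redundancy-reduction tests.

What the generators deliberately do **not** model: phylogenetic
correlation among sequences (everything is i.i.d.), operon structure or
strand bias in gene order, codon-usage bias, and compositional
heterogeneity along sequences.  Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under the stated
models, not robustness to the dependence structures of real data.

## Numerical and degenerate-input conventions

Log-sum-exp is max-factored; `log1p` is used for `(1 − p)` powers;
`k = 0` returns log-probability 0 exactly; background probabilities of 0
refuse testing with a warning, and 1 yields a tail of 1.  Fisher's test
requires positive margins.  Ragged alignments, empty sequences, residues
outside the 21-letter alphabet, and CDS/protein discordance are errors
that name the offending token.  Ties in greedy reduction are broken
lexicographically; ties in fingerprint search by earliest position.

## Problem sizes

The test suite exercises: exact-oracle grids up to n = 12 (binomial) and
margins ≤ 12 (Fisher, all 5,240 valid tables); 250–300 random
pattern/sequence pairs against the enumeration oracle; alignment
enumeration up to length 6; 100 planted genomes plus a 1000-genome
background panel and 1000 null replicates of 10 genomes for the
neighbourhood calibration; 1000 replicate seeds for trait-null
super-uniformity; 100 null seeds for rescue specificity and a 143-record
fixture with 6 planted readthroughs.  These sizes were chosen as the
smallest at which each statistical assertion has clear power.

```{r example}
# the headline motif null: 12 of 143 sequences, background 585 / 500000
log10_binomial_tail(12, 143, background_from_reference(585, 5e5))
```
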