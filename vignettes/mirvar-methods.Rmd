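---
title: "Models and methods behind mirvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvar)
```

`mirvar` takes small RNA sequencing profiles from raw FASTQ records to a
catalog of miRNA precursors and per-position mutation/editing (M/E)
sites. This vignette explains the models and the decisions behind each
stage: what is assumed, which parameters matter, where the design was
genuinely open and what was chosen, and what the synthetic-data
validation does and does not demonstrate.

## Read preprocessing

Reads are gated on quality before anything else: a read passes iff every
one of its **first 25** base qualities is at least **Q30** (Phred+33).
The rationale is that all downstream variant evidence lives in the first
~25 nt (mature miRNAs are 20–24 nt); bases beyond position 25 are
adapter-dominated and not inspected. Records shorter than 25 nt fail the
gate rather than raising an error.

The 3' adapter (default `TGGAATTCTCGAGTGCCAAGGAACTCC`, the Illumina
TruSeq small RNA adapter) is trimmed at the **leftmost occurrence of the
longest matching adapter prefix**, with a minimum accepted match of
**6 nt**. Matching is exact: the adapter string is known, and exact
matching keeps the operation bit-stable; the 6-nt floor is our choice (a
shorter floor trims random 3' sequence at rate 4^-k per position).
Trimmed reads are collapsed to unique sequences with summed counts, and
sequences of 18 nt or shorter are dropped.

## Hairpin folding

Candidate precursors are folded with a native minimum-free-energy (MFE)
dynamic program over nested (pseudoknot-free) structures:

* Turner-style stacking energies for the 16 nearest-neighbor pair steps,
  with G·U wobble pairs (standard for RNA hairpins);
* length-dependent hairpin-loop, bulge and interior-loop penalties, with
  a Jacobson–Stockmayer `1.75·RT·ln(n/n0)` extrapolation for long loops,
  an interior-loop asymmetry term (0.5 kcal/mol per unpaired-nucleotide
  difference, capped at 3.0), and an affine multibranch penalty
  (3.4 kcal/mol closing + 0.4 per branch);
* hairpin loops of at least 3 nt; bulge/interior loops of at most 30 nt
  (part of the model definition, as in standard folding engines);
* all energies as integer centi-kcal/mol, so the dynamic program is
  *exact* for its model — the test suite verifies equality with an
  exhaustive enumeration of all nested structures on hundreds of short
  random sequences.

Ties in energy are broken toward the structure with more base pairs and
then by a fixed traceback order, so folding is deterministic. Degenerate
inputs behave sensibly: a homopolymer folds to the open chain at energy
0, and the empty structure is always admissible, so reported energies
are never positive.

The discovery gate applies three clauses to a folded candidate: energy
< **−40 kcal/mol**, at least **18 paired nucleotides**, and at most
**one terminal loop**. The −40 threshold originates from a full
Zuker-style folding engine; our simplified model (no dangles, no
terminal-AU penalties, no coaxial stacking) has its own energy scale, so
the threshold is configurable (`hairpin_criteria()`) rather than
silently rescaled. On perfect-stem hairpins of the size this package
simulates (~37 bp), our model produces energies around −60 to −80
kcal/mol, comfortably across the gate; for marginal real candidates the
threshold should be calibrated against the user's folding engine of
choice.

Mature placement uses MIRcheck-style limits — ≤ 2 bulged nucleotides,
≤ 5 mismatched or asymmetrically unpaired, ≤ 3 consecutive mismatches
within the mature. An unpaired run is a *bulge* when the opposite strand
contributes no unpaired nucleotide between the bracketing pairs, and a
mismatch otherwise; runs without a paired flank on both sides (e.g.
reaching into the terminal loop) count as mismatches, the conservative
reading.

The duplex 3' overhang check measures, for a 5p/3p mature pair, the 3'
overhang each strand leaves past its partner's pairing anchor; both must
be within a tolerance (default ±1 nt) of the canonical 2 nt left by
Drosha/Dicer. When a terminal anchor is unpaired the nearest paired
position is used with the offset compensated.

## Precursor discovery

**Homology route.** Known matures (deduplicated first) are mapped to the
genome end-to-end with ≤ 2 substitutions and no indels, on both strands.
Each hit's ±80 nt window is folded; the candidate survives when the
mature does not overlap a terminal loop (i.e. it lies on one arm) and
passes the placement limits. Windows truncated at chromosome edges are
flagged but still evaluated.

**Species-specific route.** The ordered filter chain is: (1) quality
gate; (2) trim + collapse; (3) genome mappability on either strand (≤ 2
substitutions, matching the homology budget); (4–7) removal of reads
matching any supplied blocklist (mRNA, known pre-miRNA, ncRNA, repeats)
— a missing blocklist is skipped with a warning; (8) a ≥ 10 total-read
floor per unique sequence across profiles; (9) clustering of surviving
genomic hits into loci (gap ≤ 10 nt) and extraction of ±80 nt flanks;
(10) folding; (11) the hairpin gate; (12) read accumulation plus the
duplex overhang. Each step only removes candidates, so attrition is
monotone, and per-step counts are returned.

Three design points in step 10–12 deserve explanation:

* *Excision.* Folding a flanked window almost always adds spurious side
  hairpins from the flanking sequence, which would fail the single-loop
  clause for every candidate. The candidate precursor is therefore
  excised as the innermost stem enclosing the expressed span (padded by
  2 nt for the 3' overhang) and re-folded; the criteria apply to the
  excised precursor, which is how excision-based discovery tools
  operate.
* *Consensus mature spans.* The mature is estimated as the
  count-weighted median of read starts and ends within the isomiR cloud
  around the best-supported span (both ends within twice the admissible
  2-nt shift). The median is robust to symmetric end jitter, where the
  modal span is an arbitrary draw; the cloud restriction keeps
  off-mature reads from dragging the estimate. The star span comes from
  a second read cluster when one exists, and otherwise is inferred from
  the structure with the canonical 2-nt overhang (in which case the
  overhang clause is vacuous — read-defined arms are the informative
  case).
* *Strand deduplication.* A hairpin's reverse complement is itself a
  hairpin, and every read from one arm maps antisense onto the other
  arm, so each genuine precursor is recovered from both strands. Among
  passing candidates that overlap genomically, the better-supported one
  is kept (ties prefer the plus strand).

Under the default physical energy scale, the energy and paired-count
clauses cannot be violated in isolation: a structure with ≥ 18 paired
nucleotides and mature-length arms is already far below −40 kcal/mol,
and one above −40 cannot hold 18 pairs. The validation suite therefore
isolates those two clauses against configured thresholds
(`mfe_max = -80`, `min_paired = 100`), while the loop, accumulation and
abundance clauses are isolated by construction (a two-hairpin multiloop
decoy, a 64%-accumulation decoy, a 9-read decoy).

`merge_annotations()` unifies discovered and imported precursor sets by
strand-aware locus overlap, with deterministic representative selection
(lexicographically smallest id) so the result is independent of input
order; records lacking matures can inherit them from aligned known
matures, and precursors still lacking matures are excluded from editing
analysis.

## Alignment and cross-mapping correction

Reads are aligned to precursors end-to-end with at most **1 internal
substitution** (mirroring single-mismatch short-read alignment; indels
are not modeled because editing calls are substitution-based) after
splitting off a maximal non-templated 3' suffix of at most **3 nt**
(covering mono-/di-/tri-nucleotide tailing while bounding ambiguity;
configurable) as a soft tail. The trailing run of contiguous mismatches
— including any overhang past the precursor 3' end — becomes the tail;
mismatches beyond the cap count against the internal budget.

Multi-mapped read sequences are reassigned across their candidate loci
proportionally to each locus's perfectly mapped (mismatch-free,
untailed) read support, with a uniform fallback when no locus has
perfect support and weight 1 for single-locus reads. This is a
single-pass proportional allocation: when expression is estimated from
perfect reads only, the iterative reweighting scheme's fixed point
coincides with the single pass, so no iteration is performed. Weights
sum to one per read sequence, which makes weighted tallies conserve read
counts exactly (a property the test suite checks on random
configurations).

## M/E site identification

For each precursor position, the weighted depth and the weighted support
of every observed substitution are tallied; non-templated tails are
tallied separately per tail nucleotide at the positions following each
read's templated end (reference `-` beyond the precursor), and tail
reads extend the depth at the positions their tails span.

The significance test is a one-sided exact binomial tail against the
sequencing-error null: `P(X >= ceiling(k))` for
`X ~ Binomial(n, p_e)` with `p_e = 10^(-30/10)/3` — the probability
that a base passing the Q30 gate is misread as one *specific* other
nucleotide. The test form is this package's decision (the natural null
given the quality gate, and exactly checkable against direct summation);
the correction is Benjamini–Hochberg across all (position, alternative)
tests within one sample, standard and less conservative than
Bonferroni, and both are exposed in `editing_config()`. Fractional
(weight-corrected) support is rounded *up* before the tail sum and the
depth is rounded to the nearest integer (never below the support) —
both conservative. The four significance criteria are: level ≥ 5%,
support ≥ 10 reads, reads gated at Q30, corrected p < 0.05, applied per
sample (a site then only needs to be significant in one sample to enter
the combined catalog, matching how multi-sample catalogs are built).

Classification follows a fixed decision order, so every significant site
receives exactly one category: (a) sites whose supporting reads carry at
least half of their cross-map weight at other loci are `Pseudo`
(majority-origin rule, configurable; the operational definition of a
cross-mapping artifact is our interpretation); (b) tail sites beyond the
mature 3' end are `3'-A`/`3'-U`/`3'-Other` by tail nucleotide; (c)
substitutions at or upstream of the mature 5' terminus are `5' site`;
(d) internal A→G is `A-to-I` (inosine reads as guanosine) and C→U is
`C-to-U`; (e) anything else is `Other` with the substitution subtype
recorded (e.g. G-to-U). Site ids are
`{precursor}_{position}_{REF}_{alt}` with an uppercase RNA reference and
lowercase alternative.

SNP relabeling requires all three clauses: same genomic position as an
annotated variant (strand-aware coordinate mapping), same alleles
(complemented for minus-strand precursors), and a **100% editing level
in at least one sample**. Because a single sequencing error read breaks
an exact 100% in one profile (at depth 300 and Q30 this happens in
roughly one run in ten), the package's validation calls SNPs on several
replicate profiles and applies the clause to the per-site maximum across
samples — which is also how a multi-sample study design behaves. A
high-level editing site (e.g. 97%) is deliberately *not* an SNP; that
asymmetry is the point of the clause.

Cross-species site matching pairs sites that share a normalized miRNA
family key (species prefix and locus-copy suffix stripped), the same
1-based position within the mature, and the same substitution —
precursors of different lengths in the two species still match through
the mature-relative position.

## Quantification, targets, enrichment

RPTM is *reads per ten million*: `count * 1e7 / total`, with the
denominator defaulting to the reads mapped to the mature miRNA set in
that sample (the definition is not standardized; a per-genome-mapped
denominator can be supplied instead). The expression filter keeps
matures with mean RPTM ≥ 5 and sample standard deviation (n−1) ≥ 1
across samples, with absent records counting as zero.

Target prediction implements the seed rule: a 3'UTR window is a target
iff, aligned antiparallel to miRNA positions 1–8, it contains a run of
at least **7 consecutive Watson–Crick pairs** (G:U not counted)
intersecting the seed (positions 2–8). Operationally the admissible
runs are positions 1–7, 2–8 and 1–8, i.e. the UTR contains the reverse
complement of one of those mature segments; allowing the 1–7 run
tolerates both common seed conventions. Set comparison is
transcript-level, with percent shared defined as
`100·|A∩B|/|A∪B|` (100 when both sets are empty, which can only arise
when comparing identical empty predictions). Enrichment is a generic
annotation-driven hypergeometric upper tail with BH correction — any
term→gene table can be supplied, so no external pathway database is
required at analysis time.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes:
hairpin precursor loci planted on both genome strands (a full
complementary stem with an unpairable A/C loop; the 5p mature 4 nt into
the stem and the 3p mature placed so both duplex 3' overhangs are
exactly 2 nt), optional shuffled decoy loci verified to fail the
hairpin gate, mature-arm reads with uniform end jitter on −2..+2 nt,
editing events applied per read with probability equal to the planted
level, homozygous SNP alleles on every read, non-templated 3' tails at
configured fractions, per-base sequencing errors at `10^(-Q/10)`
(uniform over the three other bases), and the literal 3' adapter
appended so trimming is exercised bit-exactly. Quality strings are
constant at the configured Phred score, which makes the Q30 gate and
the error null analytically checkable. Every read's provenance is
recorded, planted positions sit inside the 5p mature (so they are
always covered), and a fixed seed reproduces all outputs byte for byte.

Reference conditions used throughout validation: 50 precursors of 82 nt
with 22-nt matures on both arms, 500 reads per mature, Q30. These sizes
put binomial level noise near the 4-SD acceptance window at the lowest
planted level while keeping a full end-to-end run in seconds.

What the generator does **not** model: ligation bias, PCR duplicates,
realistic isomiR end distributions (real profiles concentrate on a
canonical end; uniform ±2 jitter is *harder* for span estimation, which
is why consensus spans use medians), tissue expression distributions,
RNA degradation, or indels. Passing tests on synthetic data therefore
demonstrate correctness of the statistical machinery under its stated
assumptions — not performance on real libraries, where adapter
variants, composition bias and reference errors add failure modes this
package does not attempt to emulate.

One consequence of the reference conditions is worth stating plainly:
with edits planted *exactly at* the 5% level filter and depth ~500, the
observed level falls below the filter in roughly half the draws
(`P[Bin(500, 0.05) >= 25]` ≈ 0.53), so overall recovery across planted
levels {0.05, 0.10, 0.30, 0.60} plateaus near 88% no matter how good
the caller is; strata strictly above the boundary recover at ~100%.
The validation reports both numbers rather than moving the planted
levels off the boundary.

## Known limitations

* The folding model is a single-sequence MFE engine without dangles,
  special hairpin sequences, or partition-function pair probabilities;
  the −40 kcal/mol gate is interpreted on this model's scale.
* Alignment is substitution-only; edited isomiRs with indels are
  invisible.
* The Pseudo rule is a one-parameter majority-origin heuristic, not a
  joint model of locus origin.
* Conserved-site matching relies on a name-based family key; gene
  families with inconsistent nomenclature need an explicit key function.
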