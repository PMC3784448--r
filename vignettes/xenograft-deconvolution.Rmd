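---
title: "Methods: species-of-origin read partitioning for xenograft sequencing"
author: "xenopart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-of-origin read partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenopart)
```

## The problem and the model

A xenograft library is a mixture: most fragments come from the engrafted
human tumour (the graft), a minority from infiltrating mouse stroma (the
host). `xenopart` resolves the mixture by *dual-reference alignment
comparison* rather than k-mer classification: every read pair is aligned
independently to the graft and the host genome, and fragments are
partitioned by comparing the sets of read identities that map to each
reference.

Let $U$ be the fragment universe and $G, H \subseteq U$ the fragments
mapped to graft and host. The partition is pure set algebra:

$$
\text{graft-specific} = G \setminus H,\quad
\text{host-specific} = H \setminus G,\quad
\text{common} = G \cap H,\quad
\text{unmapped} = U \setminus (G \cup H).
$$

The four sets are disjoint and cover $U$; this is asserted on every run.
The historical workflow reached the same sets sequentially — primary
alignment to the graft, realignment of the graft-mapped and graft-unmapped
subsets to the host, then subtraction of the common set.
`partition_sequential()` implements that stepwise flow as genuinely
restricted realignment, and the test suite verifies it is extensionally
identical to `partition_ids()`; the equivalence is a checked property, not
an assumption.

**What "mapped" means.** The unit of classification is the fragment
(pair), since downstream read-identity comparison operates on pair files; a
single-end mode exists for completeness. Under the default
`classify_config()` a fragment counts as mapped to a genome when both
primary mate records are FLAG-mapped, properly paired, and
$\min(\mathrm{MAPQ}_1, \mathrm{MAPQ}_2) \ge 20$. Choices behind this:

* *MAPQ gate (default 20).* The gate discards multiple-hit reads, whose
  placements are untrustworthy for species assignment. Whether a
  production workflow enforces MAPQ as a filter or merely reports it is a
  judgement call; here it is an enforced, configurable filter, with
  `min_mapq = 0` recovering the report-only behaviour.
* *MAPQ 255.* The SAM sentinel for "quality unavailable" counts as mapped
  for partitioning (the aligner asserted a location) but such records are
  excluded from pileup depth, where miscounting has direct consequences.
  Both behaviours are configurable.
* *Proper-pair requirement.* Defaults to TRUE for DNA workflows
  (concordant pairs), FALSE is recommended for RNA-seq, where spliced
  mates are legitimately discordant against the genome.
* *Common membership.* A fragment is "common" if it maps to both genomes,
  regardless of whether the two placements are homologous loci; requiring
  positional concordance would need a whole-genome correspondence map,
  which real workflows do not have.

## Quality trimming

`sliding_window_trim()` scans 5'→3' windows of 6 bases and truncates the
read before the first window whose mean Phred score drops below 20; reads
shorter than 50 nt afterwards are discarded, and a discarded mate discards
the pair (classification is pair-based). This is the single-pass
SLIDINGWINDOW reading of windowed average-quality trimming — no leading
trim, no adapter logic. Output is always a prefix of the input and the
operation is idempotent, both tested properties. Quality encoding is fixed
at Phred+33; other encodings are rejected rather than guessed.

## The micro-aligner and the simulator

Real libraries arrive as SAM/BAM from production aligners. The built-in
seed-and-extend aligner exists so that the complete workflow — including
the host-contamination check — runs on synthetic data with no downloads,
and so the classifier can be shown to treat any SAM producer identically.

* Seeds are non-overlapping 21-mers from the read and its reverse
  complement (plus one seed flush with the 3' end); candidates are
  extended ungapped; the fewest-mismatch placement wins, ties broken by
  lowest coordinate then forward strand.
* `mapq_like` $= \min(60,\, 10\,(m_2 - m_1))$ for best/second-best
  mismatch counts, 0 on ties, 60 when no competitor was seen. This is an
  internal score, documented as such — not a claim about production
  aligner MAPQs. Its load-bearing property is that reads from exact
  repeats get 0 and are removed by the MAPQ gate.
* Ungapped extension only: indel-containing reads may go unaligned. The
  aligner is a fixture generator, not a contribution.

The simulator draws a uniform-random ancestor and substitutes each lineage
independently with per-site probability $q$ solving
$d = 2q(1-q) + \tfrac{2}{3}q^2$, so pairwise divergence at corresponding
sites has expectation $d$ under the uniform exchange model; a
transition/transversion weight exercises spectrum recovery with
non-uniform truth. Defaults emulate the workflow's native conditions:
divergence 0.12 as a human/mouse-like stand-in (a knob, not a biological
claim), 101 nt paired reads on 200 bp inserts (s.d. 30 nt, a typical
short-insert library; only the mean is conventionally quoted), per-base
error 0.1%, constant base quality Phred 35. Fragment origins are
Bernoulli(host fraction); ids (`FRAG000001`…) encode nothing about origin —
truth lives in a separate label table. Spike-in variants are applied as
fragment-level Bernoulli(VAF) draws so both mates agree, exactly as
sequencing a subclonal cell population would.

What the simulator does **not** emulate: position-dependent quality decay,
indel sequencing errors, PCR-duplicate families beyond exact-copy
injection, splice junctions, capture bias, and real human/mouse homology
structure (conserved exons are far less divergent than 12% while
intergenic sequence is more). Passing tests therefore demonstrate the
*logic* of partitioning, filtering and rescue under controlled conditions,
not the empirical mouse-read percentages of any particular tissue, which
depend on stromal content and library chemistry.

## Expression quantification

Fragments (not reads) are counted: a fragment's span from leftmost to
rightmost aligned base is assigned to the single gene with maximal exonic
overlap in bases; ties across genes are discarded as ambiguous and
reported; strand is ignored (non-directional libraries). RPKM uses
$10^9 \cdot c / (N \cdot L)$ with $L$ the exon-union length and $N$
defaulting to the number of mapped fragments in the category being
quantified — quantification happens after species separation, so the
denominator is species-specific by construction; `denominator =
"assigned"` is available. The exported log2 matrices use pseudocount 1.0;
Spearman correlation is computed after the log transform for fidelity to
the conventional presentation even though rank correlation is invariant to
it. Host-side quantification runs the identical code path as graft-side,
which is what makes stromal expression profiling structurally symmetric.

## Variant post-processing

The package deliberately does **not** re-implement variant calling
(genotype likelihoods, recalibration, realignment); it consumes VCF and
implements the post-call layers:

* *Hard filters*: `LowDepth` (depth < 5), `LowQual` (QUAL < 50),
  `StrandBias` (FS ≥ 60), `SnpCluster`. FS is $-10\log_{10}p$ of the
  two-sided Fisher exact test on the ref/alt × forward/reverse table,
  computed by full enumeration of the conditional hypergeometric
  distribution (no mid-p), capped at 10,000 to avoid $\log 0$; a sum
  within $10^{-12}$ of 1 is reported as exactly 0 so balanced tables are
  exactly unbiased. Filters are recomputed from record fields, making the
  operation idempotent.
* *SNP clusters*: "cluster size = 10" is ambiguous between a count and a
  window; it is read here as window = 10 nt with count = 3 (the
  conventional pairing), both exposed as parameters. A run of ≥ 3 SNVs
  spanning < 10 bases is tagged; indels are excluded from the rule.
* *Germline subtraction* is an exact (chrom, pos, ref, alt) anti-join
  against the matched-normal call set; *known/novel annotation* is the
  same key join against a dbSNP-like table, reporting the known:novel
  ratio.
* *Mutation spectrum* collapses the 12 raw substitutions onto 6 classes by
  complementing pyrimidine-reference records (C>T counts as G>A/C>T);
  complementing every record is an involution on class counts, a tested
  property. Indels are counted separately.
* *Rescue classification* re-examines a variant absent from one sample by
  direct pileup in that sample: `CALLED` at alt fraction ≥ 0.2 and depth
  ≥ 10; `DETECTED_BELOW_THRESHOLD` when alt evidence exists at adequate
  depth below that fraction (subclonal presence); `NOT_DETECTED_LOW_DEPTH`
  below depth 10; `NOT_DETECTED_NO_ALT` at adequate depth with zero alt
  reads. The 0.2 threshold is implemented as this post-hoc rule, not as a
  caller-internal filter.
* *Host-contamination window check*: reads aligned within ±1,000 bp of a
  suspect locus are re-aligned against the host genome. Its default
  mismatch budget is 2, stricter than the general aligner default of 5,
  because the op is a detector: a genuine host read carries only
  sequencing errors (≈0.1 expected mismatches per 101 nt at 0.1% error)
  while a graft read over a homologous region at percent-scale divergence
  carries an order of magnitude more. At budget 5 roughly 1% of homolog
  reads would sneak under the bar (a clean 21-mer seed plus ≤5 mismatches
  is a modest coincidence at 12% divergence), making "zero host-alignable
  reads" fragile; at budget 2 the homolog pass rate is ~$10^{-5}$ while
  true host reads still align essentially always.
* Duplicate marking (coordinate-keyed, best-summed-base-quality kept,
  deterministic id tie-break) runs only in the DNA path; RNA-seq
  quantification is performed without de-duplication.

Pileups count bases ≥ Q20 from primary, properly paired records with
available MAPQ, excluding duplicates when requested; MAPQ-255 exclusions
are tallied separately. Pileup offsets assume full-length-match alignments
(true for the built-in aligner); gapped records would need CIGAR walking,
a known limitation.

## Problem sizes and determinism

Every simulator operation is a pure function of its inputs and seed. The
shipped test suite and acceptance script use: 200 kb genomes with 50,000
pairs per mixing level for mixture recovery (accuracy and host-fraction
estimation), 20 kb genomes with 10,000 pairs (~100× depth) across 20 seeds
for rescue-rate estimation, all $\sim$246,000 2×2 tables with per-allele
strand totals ≤ 30 for the Fisher score, and 10,000 reads for the trimming
oracle. These sizes give binomial standard errors comfortably inside the
asserted tolerances while keeping a full run in tens of seconds on one
CPU.

## Known limitations

* Ungapped toy alignment: no indels, splices or clipping in synthetic SAM.
* The "common" category is defined by mapping status only; no
  homologous-locus concordance is required or reported beyond a
  diagnostic.
* Known/novel annotation is exact-key matching; no normalization of indel
  representation.
* The simulator's uniform divergence overstates exonic human/mouse
  divergence and understates repeat content; real common-category
  fractions will differ from synthetic ones.
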