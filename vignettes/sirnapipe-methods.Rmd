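---
title: "Methods: siRNA discovery and heat-stress differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: siRNA discovery and heat-stress differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the package computes

`sirnapipe` re-implements, as one tested pipeline, the computational path
from raw plant small RNA-seq libraries to heat-responsive siRNAs and their
predicted targets. The experimental design it assumes is a pooled
(replicate-free) time course: one library per timepoint at 0 h (control)
and 1, 6 and 12 h of heat stress. The stages are:

1. **Read cleanup** — mean-Phred quality filter, 3' adapter trimming,
   length window, collapse to unique tags with per-library counts.
2. **Exact mapping and structural subtraction** — tags are placed on the
   genome by exact full-length match on both strands; any tag overlapping
   an annotated rRNA, tRNA, snRNA, snoRNA or miRNA locus by at least 1 bp
   is removed entirely.
3. **Duplex calling** — an siRNA locus is a plus-strand tag paired with a
   minus-strand tag in the canonical Dicer geometry (2-nt 3' overhangs on
   both ends), supported by more than five raw reads per library.
4. **Differential expression** — TPM normalisation, a TPM-30 expression
   floor, an exact conditional binomial test of each heat timepoint
   against control, and the DE-siRNA rule |log2 ratio| >= 1 with p < 0.05.
5. **Temporal structure** — three-set intersection (UpSet-style) regions
   and fuzzy c-means clustering of the common DE set's log2-ratio
   profiles.
6. **Target prediction, GO enrichment, qPCR cross-validation.**

Every stage is exercised end to end on a synthetic world with a planted
truth table, so the pipeline is testable without any external download.

## The duplex criterion

Dicer processing leaves a signature the caller exploits: two complementary
strands whose 3' ends each extend exactly two nucleotides past the
partner's 5' end. With 0-based half-open genomic intervals, a plus-strand
tag at `[s, e)` and a minus-strand tag at `[s', e')` form a duplex iff

```
s - s' = 2   and   e - e' = 2
```

which forces equal tag lengths. The source criterion — "two overhanging
bases that were complemented" — underdetermines the geometry; we adopt the
strict standard duplex reading. A relaxed option (each overhang
independently 1-3 nt, unequal lengths possible) exists behind a flag and is
off by default; it is an explicitly different model, not a tuning knob.
The abundance half of the criterion ("more than five reads per sample") is
applied to raw counts, strictly greater than 5, in **all four** libraries
by default; "per sample" could also be read as "in at least one sample",
so `mode = "any"` is exposed. Raw rather than normalised counts are used
because normalisation only enters the workflow at the DE stage.

The guide strand is the more abundant strand over all libraries (ties go
to plus); guide length and 5' first base feed the length x first-base
summary table. Identifiers (`novel_sirNNNNN`) are serial after sorting by
genomic position, so they are reproducible run to run.

## Differential expression on pooled libraries

With one pooled library per condition there are no replicates, so
dispersion-based tests (negative binomial) are out of scope. The default
test is the exact conditional binomial: conditional on the total count
`k = k_t + k_c`, under the null of equal proportions

```
k_t ~ Binomial(k, n_t / (n_t + n_c))
```

where `n_t`, `n_c` are library sizes; the two-sided p-value sums the
probabilities of all outcomes at most as probable as the observed one
(both counts zero gives p = 1 by convention). Fisher's exact test on the
2x2 table is available behind `test = "fisher"`. The source publication
delegates its DE test to a citation without printing the formula, so this
default is a documented choice, validated in tests against exhaustive
enumeration and shown to be conservative (null rejection rate <= 0.06 at
alpha 0.05) under an equal-rate Poisson simulation.

Choices a user should know, with defaults and rationale:

* **Library size** (TPM denominator): total cleaned *mapped* reads per
  library. The publication says only "transcripts per million in each
  library"; mapped reads is the widest denominator the pipeline itself can
  compute deterministically.
* **Expression floor 30** is applied on the TPM scale *before* testing,
  because the source describes excluding "normalized sequence reads with
  read counts <30" upstream of the DE analysis. Boundary is inclusive-keep.
* **Pseudocount 0.01 TPM** in the log2 ratio avoids infinities at zero
  counts; it is far below the floor of 30, so it never affects a record
  that survives filtering by more than ~5e-4 log2 units.
* **No multiple-testing correction** in DE calling, mirroring the stated
  raw "p < 0.05" rule; a BH flag exists (`adjust = TRUE`).

One behaviour of TPM on this design deserves a note: planting (or
observing) asymmetric up/down mass shifts every record's log2 ratio by the
log ratio of library masses. In the synthetic world the 60 up-loci at
4-6x outweigh the 60 down-loci at 0.17-0.25x, giving flat loci a common
offset of about -0.7 log2 units. This is a property of TPM on pooled
libraries, not a bug; the DE thresholds still separate the planted classes
with margin, which is exactly what the planted-recovery criterion checks.

## Fuzzy c-means

The source text calls the Fig 4 analysis "hierarchical cluster analysis
using the Mfuzz package". Mfuzz implements fuzzy c-means — a soft
partitioner, not hierarchical clustering. We implement fuzzy c-means,
matching the named tool, and record the contradiction here rather than
resolving it silently.

Profiles are the three log2 ratios (1, 6, 12 h vs control) of the common
DE set, row-standardised to mean 0, population sd 1 (the Mfuzz
convention); zero-variance rows are excluded and reported. The algorithm
is the standard alternation with Euclidean distance and membership
exponent `m = 2`:

```
u_ik = 1 / sum_j (d_ik / d_jk)^(2 / (m - 1)),   c_k = sum_i u_ik^m x_i / sum_i u_ik^m
```

Exact-zero distances give that cluster full membership (split equally if
several). Initialisation draws `c` distinct data rows by seeded sampling;
5 restarts keep the best objective; iteration stops when the largest
centre movement falls below `tol = 1e-6`. Hard labels are membership
argmax with ties to the lowest cluster index. `c = 4` is the default,
matching the four temporal patterns the source reports; `m`-estimation
heuristics and cluster-number selection are out of scope. The published
cluster sizes (28/19/31/66) depend on the real libraries and are not
reproduction targets.

## Target-site scoring

The original analysis ran two external predictors (TargetFinder, psRobot)
and kept only sites both agreed on. To stay self-contained and testable,
this package re-implements two *representative* position-weighted schemes
rather than shelling out; cutoffs and cost tables are configuration,
documented as approximations of — not bit-exact ports of — those tools.

Pairing is antiparallel (guide position 1 at the site's 3' end), penalties
per paired position: Watson-Crick 0, G:U wobble 0.5, mismatch 1.0.

* **Scheme A** (TargetFinder-like): penalties doubled at guide positions
  2-13; at most one single-nucleotide target bulge (penalty 1.0, also
  doubled in the core), interior positions only; cutoff 4.0.
* **Scheme B** (psRobot-like): ungapped; hard seed constraint of at most
  1 penalty point within guide positions 2-8 (violations reject the site
  outright); cutoff 2.5.

The scanner slides each guide's reverse complement along every transcript
and evaluates both schemes at every offset (plus all bulge placements for
scheme A), using prefix/suffix decomposition so bulge evaluation stays
O(length) per offset. A site is **consensus** when an A-passing and a
B-passing site coincide — intervals with at least 50 % reciprocal overlap
— which reduces to "both schemes pass at the same interval" in the common
ungapped case. Tests enforce exact equality with a full-offset brute-force
oracle.

## GO enrichment and qPCR validation

Enrichment of consensus target genes is the hypergeometric upper tail
`P(X >= k)` per term, corrected within each of the three namespaces
separately; significance is adjusted p <= 0.05. The source says only
"corrected", so Benjamini-Hochberg is the default with Bonferroni behind a
flag. The background defaults to all genes in the supplied GO map
(configurable); no GO-graph ancestor propagation is performed — the map is
taken as-is.

qPCR validation follows Livak 2^-ddCt with replicates averaged on the Ct
scale before dCt, the reference RNA playing the 5S rRNA role, and the 0 h
timepoint as calibrator (relative expression exactly 1 there). Agreement
with sequencing is OLS of sequencing log2FC on qPCR log2FC with r² the
squared Pearson correlation, pooling the panel's three heat timepoints
into one set of pairs (whether the published r² pools timepoints is
unstated; pooling is our documented choice).

## The synthetic world

The generator's defaults *are* the reference conditions of the acceptance
criteria: a 100-kb random genome; 50 structural loci across the five
classes; 200 planted siRNA loci — 60 up at >= 4-fold, 60 down at <=
0.25-fold, 80 flat (within 0.9-1.1x) — with guide lengths drawn 20-24 nt,
21 nt modal and 24 nt next, mirroring the reported length distribution;
four libraries of 200,000 reads. Counts are Poisson around expectations
(the minimal noise model consistent with a count-based test on pooled
libraries); 5 % of reads are random unalignable junk, 2 % carry
sub-threshold quality (mean Phred < 20, our concretisation of
"low-quality"); the 3' adapter defaults to the Illumina TruSeq small-RNA
adapter string and every insert is adapter-ligated and truncated to a
50-nt read. Guide:passenger reads split 75:25. Temporal fold profiles vary
per locus within their class constraints so the clustering stage sees
heterogeneous shapes. Per-locus baselines are log-normal (sd 0.5), wide
enough to spread expression over ~1.5 orders of magnitude while keeping
the weakest passenger strand above the >5-read criterion at reference
depth.

What the generator does **not** emulate — and hence what a green test does
not establish: sequencing errors beyond none (no substitution model by
default), ligation bias, multi-mapping repeat structure of a real Brassica
genome, genuinely hierarchical siRNA classes (phased ta-siRNAs,
hc-siRNAs), GO-term dependency structure, or amplification-efficiency
artefacts in qPCR. Passing the planted-recovery criterion demonstrates the
pipeline's internal consistency at realistic scale, not concordance with
the original biological dataset.

Determinism: every generator stage seeds the RNG from `config$seed` plus a
stage offset, so each stage is independently reproducible and a fixed
configuration yields byte-identical output files. The byte-identity
acceptance test runs a scaled-down configuration (30-kb genome, 26 loci,
10,000 reads per library) to stay inside the suite's runtime budget;
determinism does not depend on scale, and the reference scale is already
run once by the planted-recovery criterion.

## Numerical and degenerate-input conventions

* Boundary semantics are inclusive-keep everywhere a threshold admits a
  boundary case: mean Phred exactly at the threshold, insert length at the
  window edges, TPM exactly 30, |log2 ratio| exactly 1. The p-value
  threshold is strict (p < 0.05), as stated by the source.
* Reads with no detectable adapter are rejected ("invalid adapter"): an
  insert shorter than the read must expose the adapter. `keep_untrimmed`
  exists for other chemistries. Inserts containing N are dropped (exact
  matching downstream cannot place them).
* Tags mapping to more than 20 positions (configurable) are dropped and
  logged as pathological repeats; multi-mapping below the cap is retained
  with all hits carried forward.
* The exact binomial test compares pmf values with a 1e-7 relative slack
  when summing "outcomes at most as probable as observed", the standard
  guard against ties lost to floating-point.
* Hypergeometric tails use the log-space-stable `phyper`; tests pin it to
  direct pmf summation at 1e-12.
* Empty inputs return empty, well-typed results (empty FASTQ, empty tag
  list, zero-feature GFF3, empty call set → all-zero statistics table);
  degenerate statistical inputs (zero library size, all-constant profiles,
  zero-variance agreement vectors, missing qPCR control) raise errors
  rather than propagate NaN.

## Known limitations

* Exact-match-only mapping means a single sequencing error hides a tag;
  at real error rates a small sensitivity loss per locus is expected —
  mitigated by tag-level redundancy, but not modelled here.
* The two scoring schemes approximate the published tools' behaviour;
  absolute target counts are not comparable with TargetFinder/psRobot
  output, only the consensus *rule* is reproduced.
* TPM on pooled libraries confounds global expression shifts with
  per-locus changes (see the DE section); interpreting absolute log2
  ratios requires that caveat.
* The qPCR stage assumes perfect amplification efficiency (no Pfaffl
  correction) and a stable reference RNA.
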