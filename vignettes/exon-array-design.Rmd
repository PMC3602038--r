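---
title: "Designing an exon array from a fragmented assembly, and selecting varieties from field trials"
author: "exonforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing an exon array from a fragmented assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonforge)
```

# The problem

A species with a large, repeat-rich genome and no finished assembly can
still be given a genome-wide expression array if the design unit is the
exon rather than the gene. Methyl-filtered genome survey sequencing
enriches for gene space; the resulting low-coverage assembly is highly
fragmented, so most contigs carry only gene fragments, often truncated
at contig ends. The design task is therefore: clean the reads, mask
repeats, find every contig interval that plausibly belongs to an exon,
score it by how much independent evidence supports it, merge in
transcript (EST) fragments not represented in the assembly, and place a
fixed number of probes on each candidate. Alongside the array design,
the same study design needs field-trial statistics to pick contrasting
varieties: a spatial correction of plot data, a genotype-by-environment
(GGE) biplot, and variety contrasts.

`exonforge` implements both halves as one tested package, with seeded
synthetic-data generators so every stage can be verified against planted
ground truth.

# Conventions and containers

Coordinates are held in `GRanges`/`IRanges` objects (1-based, closed),
the native Bioconductor convention, so all interval algebra (union,
intersection, overlap queries) comes from `IRanges` rather than
hand-written code. GFF3 (1-based inclusive) imports as a coordinate
identity; BED (0-based half-open) is converted by `rtracklayer` at the
file boundary only. Sequences travel as named character vectors rather
than `DNAStringSet` because lowercase letters carry soft-mask state and
must survive round-trips; mask intervals are additionally carried as
`GRanges`, which are authoritative for all overlap arithmetic.

All numeric thresholds live in one `DesignParams` object:

```{r}
designParams()
```

* `minReadLen = 100` bp and `maxAmbiguityFrac = 0.03` — removal of short
  and ambiguous reads. The ambiguity rule is a *strict* inequality: a
  100-mer with exactly 3 N's is kept.
* `endTrim = 60` bp per end. The wording of the original cleaning
  protocol is ambiguous about whether the trim was unconditional or
  applied only when terminal bases were masked; it is implemented
  unconditionally, which is deterministic and strictly more
  conservative. Reads that fall below `minReadLen` after trimming are
  counted in their own `trim_casualty` ledger category.
* `minExonLen = 60` bp, `shortExonPenaltyLen = 100` bp — consensus
  regions shorter than 60 bp are dropped; regions in [60, 100) keep
  their interval but lose one score point. The size of the penalty is
  not quantified in the protocol this reimplements; one point on the
  0–7 integer scale is the smallest meaningful penalty and keeps the
  score interpretable as "supporting sources, discounted".
* `minOrfLen = 150` bp — an ORF is ATG-initiated and stop-terminated,
  with the stop codon counted inside the 150 (150 is divisible by 3,
  consistent with codon counting).
* `redundancyIdentity = 0.98` — two candidates are redundant at ≥98%
  identity. Identity alone over an arbitrarily short window would
  over-trigger, so redundancy additionally requires the matched segment
  to cover ≥80% of the shorter sequence.
* `maxRepeatOverlapFrac = 0.25`, strict: a 200 bp region overlapping
  repeats by exactly 50 bp is kept; by 51 bp it is filtered.
* `probesPerExon = 4`, `probeLen = 25` — the probe count matches the
  design target; 25-mers are the convention for the platform family
  this design targets (the probeset target regions quoted in array
  summaries are longer and are not probe lengths).

# Read cleaning

`cleanReads()` applies a fixed cascade — vector, contaminant, organelle,
short, ambiguous, end trim — removing each read at the *first* stage
that claims it. Published cleaning summaries report disjoint
per-category counts; first-match-wins is what makes such counts
well-defined. The `CleaningLedger` class refuses to construct if
`input != kept + Σ removed`, so conservation is checked on every run,
not just in tests.

The screens use a shared seed-and-extend matcher: exact 12-mers seed
diagonals, and each seed run is extended ungapped with +1/−3
match/mismatch scoring under a 12-point X-drop, which trims segments at
true copy boundaries instead of drifting into flanking chance matches.
Vector hits qualify at 60 bp internally or 30 bp near read ends
(cloning-vector remnants sit at ends); contaminant and organellar
screens instead require the hit to cover ≥80% of the read, since those
reads originate wholly from the reference. Defaults (96% identity) are
configurable; the original tooling's exact heuristics are documented as
out of scope. Test oracles recompute hit presence with
`Biostrings::pairwiseAlignment` local alignments on desk-scale cases.

# Repeat masking

`findTandemRepeats()` detects *perfect* tandem arrays (period 1–6,
total length ≥18, ≥4 unit copies, partial trailing copies included) via
the period-shift self-match profile; alignment-scored degenerate arrays
are out of scope because perfect-array detection is exactly verifiable
against an exhaustive oracle. `maskWithLibrary()` reuses the
seed-and-extend matcher at an 80% identity floor and 50 bp minimum,
both strands, labelling masks by repeat family. `applySoftmask()`
lowercases masked positions (invertible, length-preserving);
`overlapFraction()` computes union coverage so overlapping masks are
never double-counted.

# Evidence integration

`buildConsensusRegions()` is the heart of the design. Supporting
intervals from all sources are merged by contiguity: positions covered
by at least one interval form runs, and each maximal run becomes one
candidate region. This is exactly a positionwise union followed by
connected components, which is what the property tests check against a
bitmap oracle; it also means two intervals that merely abut are merged,
a deliberate choice that keeps the operation identical to its oracle.
Region boundaries are the union span — boundary refinement by
re-running a hint-driven gene predictor is an external-tool step and
out of scope.

Each region records its distinct supporting sources (up to seven,
configurable; the default set is two ab initio predictors, three
transcript sources, protein homology, and genomic conservation — the
exact identity of the seven scored sources is an inference and fully
configurable). The score is `#sources − shortPenalty`, clamped to
[0, 7]. Repeats are negative evidence, carried as
`repeatOverlapFrac`.

`filterRegions()` applies four rules, logged per removal: (a) genomic
regions supported only by EST evidence are dropped (their content
survives through the EST branch, where strand can be inferred from an
ORF); (b) regions supported only by the ab initio predictor that also
touch a repeat are dropped; (c) regions flagged by a precomputed
transposable-element protein track are dropped; (d) regions more than
25% repeat-covered are dropped. Rules (c) and (d) are applied
independently — a stricter reading than a combined TE-and-overlap rule,
chosen so each filter is individually testable.

`assignStrand()` votes among stranded supporting intervals with
priority weights (transcript > ab initio > homology > conservation);
weights are powers of two in priority rank so any higher-priority
source outweighs all lower ones combined. Regions with no stranded
evidence keep `*`; exact ties resolve to `+` for determinism.

`exonEval()` scores predictions in the gene-prediction convention:
sensitivity is the fraction of true exons with both boundaries matched
(within an optional tolerance), specificity is the matched fraction of
predictions (precision).

# The EST branch and the merged candidate set

EST contigs pass the same TE/repeat rules, then redundancy removal
against the genomic candidates (genomic precedence — when the same exon
is represented in both, the assembly copy survives), then the six-frame
longest-ORF search, which both qualifies a contig (≥150 bp) and infers
its strand. Ties in ORF length prefer the plus strand, then the
smallest forward-strand coordinate, so results are deterministic.
`buildCandidateSet()` joins both origins and removes within-set
redundancy (precedence: genomic, then higher score, then longer) with a
full status ledger; the `CandidateSet` validity check enforces
conservation of every EST and genomic count.

# Probe selection

`selectProbes()` is a documented heuristic (the commercial selection
criteria behind the original array are not public): candidate 25-mer
windows must be uppercase ACGT and free of blacklisted background
k-mers; windows with GC in [0.3, 0.7] are preferred; targets are spread
evenly across the exon; probes are disjoint whenever the exon is long
enough (`4 × 25` bp), otherwise overlap is allowed and the probeset is
flagged. Selection is deterministic and seedless.
`probesetAccounting()` totals probesets and probes — with complete
4-probe probesets the totals satisfy `probes = 4 × probesets` exactly.

# Field-trial statistics

Within each environment (field × year), plot values are corrected for
smooth spatial trends with `mgcv`:
`value ~ variety + te(row, column, bs = "cr")`, a penalized
tensor-product cubic regression spline with basis dimension adapted to
the grid (capped at 5 per margin) and smoothness chosen by generalized
cross-validation. The corrected value is the observation minus the
centered spatial component; surfaces in the spline's unpenalized null
space are recovered exactly at zero noise, which the tests exploit as
an exactness oracle.

Corrected plots aggregate to genotype means per environment, and each
environment column is divided by the standard deviation of its genotype
means (unit-sd scaling, the common GGE "scaled" option), so
environments with different trait scales contribute equally.
`ggeDecompose()` subtracts environment means (removing E, leaving
G + G×E) and takes the SVD with *symmetric* scaling — both sides carry
√σ — since no scaling convention was specified and the symmetric biplot
treats genotypes and environments even-handedly. Axis signs are fixed
by making summed environment loadings non-negative, so results are
reproducible. Variance explained per axis is `100·σᵢ²/Σσⱼ²` and sums to
100 by construction.

`rankIdealCultivars()` projects genotypes onto the average-environment
axis (trait level) and its orthogonal complement (instability); the
ideal low cultivar has the lowest level and minimal instability, ranked
lexicographically. `varietyContrast()` reports group means, t-based 95%
confidence intervals, a Welch two-sided p-value (no test was named in
the tables this mirrors; Welch avoids the equal-variance assumption),
and the relative decrease `100 × (1 − meanA/meanB)`. Applying the same
contrast to spatially corrected values gives the "corrected data"
p-value column of such tables.

# What the generators emulate — and what they do not

Each generator is a pure function of (plan, seed) and returns exact
truth labels.

* `generateGssReads()` plants one removal cause per read: a spliced
  vector prefix, an exact contaminant/organelle substring, a 50–99 bp
  length, >3% N content, a length that survives screening but not
  trimming, or nothing (clean). Read lengths follow a truncated normal
  (mean 650, sd 100), a realistic single-pass Sanger profile. Base-call
  errors, chimeras and quality-dependent trimming are *not* modelled:
  passing tests show the cascade classifies and accounts correctly, not
  that the screens are robust to sequencing noise beyond the planted
  mutation rates.
* `generateAnnotatedContigs()` plants non-overlapping exons (60–400 bp)
  with ≥200 bp gaps and corrupts each evidence source independently:
  dropout (sensitivity 0.8), false intervals placed in gaps (FDR 0.1),
  Gaussian boundary jitter (sd 10 bp). Real evidence errors are
  correlated across sources and concentrated at splice boundaries;
  planted corruption is independent, so recovery results bound the
  easier regime.
* `truncateContigs()` cuts contigs to sampled lengths (default
  log-normal with median ≈ 990 bp, the fragment scale of a low-coverage
  survey assembly) at uniform offsets, splitting planted exons and
  updating truth — the mechanism for studying truncated genes.
* `generateEstContigs()` plants qualifying 210 bp ORFs, verified
  ORF-free contigs, 99%-identity copies of genomic candidates, and
  30%-repeat-covered contigs. EST assembly itself, polyA tails and
  splice-aware alignment are out of scope.
* `generateFieldTrial()` lays out a randomized complete block design
  (default 45 varieties × 6 blocks × 8 environments) and sums planted
  components: `μ + G + E + G×E + block + spatial + ε` with a smooth
  `sin·cos` spatial field (amplitude 1, noise sd 0.3, G sd 0.6 ≫ G×E
  sd 0.1 — a genotype-dominated regime in which ordering recovery is
  the meaningful check). Real fields have non-smooth spatial structure
  (soil patches, irrigation lines) that a spline cannot fully remove.

# Problem sizes and numerical choices

The test suite runs entirely on synthetic data at desk scale: 100-read
cleaning plans, contigs up to 50 kb for the consensus-oracle
equivalence (50 random evidence sets), 1,000 random sequences for the
ORF oracle, sequences up to 2 kb for the tandem oracle, 20 seeded
45 × 6 trials for spatial recovery, and a 45 × 8 trial for GGE
recovery. Tie-breaks are specified everywhere randomness could creep
in: region ranking (score, length, contig, start), ORF ties (strand,
then coordinate), strand votes (priority, then `+`), probe windows
(distance to target after GC preference). Degenerate inputs error
early and informatively: empty reads, duplicate ids, zero-variance
environments, grids smaller than the spline basis, rank-deficient GGE
axis requests (truncated with a warning).

# Known limitations

* The seed-and-extend screens require a shared exact 12-mer; matches
  more diverged than ~90% with no conserved 12-mer can be missed. The
  oracle-agreement properties are stated (and tested) at desk scale.
* Consensus regions take union boundaries; no attempt is made to
  recover exact splice sites, and gene structure (introns, UTRs) is
  explicitly out of scope.
* Probe selection is a transparent heuristic, not a thermodynamic
  model; cross-hybridization is only controlled through the optional
  background k-mer blacklist.
* The GGE analysis treats the genotype-mean matrix as complete;
  incomplete trials must be completed or subset upstream.
* Dataset-scale counts from the original tobacco design (hundreds of
  thousands of candidates) depend on the real survey data and external
  gene predictors, and are not reproduced here; the package reproduces
  the *arithmetic* and the *procedures*, verified on labeled synthetic
  data.
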