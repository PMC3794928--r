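---
title: "Methods: simulating and analysing a sparse gene-body methylome"
author: "methatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a sparse gene-body methylome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`methatlas` implements the full analysis chain for whole-genome bisulfite
sequencing (WGBS) of a sparsely methylated invertebrate genome of the kind
found in hymenopteran insects: methylation is confined to CpG dinucleotides,
occurs on the bodies of a minority of genes, is strongly biased toward the
5' coding region and toward exons, is nearly absent from transposable
elements, and marks constitutively expressed genes. The package provides a
synthetic-data generator with exactly this structure, a desk-scale bisulfite
read mapper, per-cytosine methylation calling, sequence-feature detection
(CpG islands, methylated-CpG clusters), gene-level status calling and
metagene profiles, permutation statistics for the spatial clustering of
methylated genes, expression integration, and comparative statistics.
Everything downstream of the mapper also accepts externally produced SAM
alignments.

## The synthetic-data generator

The generator is first-class, tested code: its outputs define the study
conditions every other module is validated against.

### Genome and gene models

Scaffolds are i.i.d. base sequences at a configurable GC content (default
0.42, a typical insect genome composition). Gene models are packed left to
right: 2–8 coding exons of 120–600 bp, introns of 60–450 bp, and 5'/3' UTRs
of 100–300 bp, giving transcripts of roughly 1–6 kbp. Genes never overlap;
if the requested number cannot be packed the generator stops with an
explicit error rather than silently truncating.

Methylation labels follow a two-state chain along each scaffold: a gene
copies its 5' neighbour's label with probability `cluster_stickiness`,
otherwise it draws fresh from `p_methylated_gene`. The stationary methylated
fraction is `p` and the mean methylated-run length is
`1 / (1 - (s + (1 - s) p))`. The defaults (`p = 0.30`, `s = 0.42`) give a
methylated gene fraction near 30% and a mean run length near 2.5,
matching the clustering regime the analysis is designed to detect. A gene
that copies its neighbour's label is also placed closer to it (gap 300–800
bp versus 900–2400 bp for a fresh draw), so co-methylated tandem genes are
physically clustered — mirroring the observation that same-status neighbour
pairs sit closer together than label permutation would predict. A
configurable number of genes is flagged as expressed transposable-element
(TE) genes and forced non-methylated, since TE methylation is essentially
absent in this kind of methylome. A fraction of genes receives a CpG-rich
promoter insert so that island detection has true positives to find.

### True methylome

Every CpG dyad gets one true methylation fraction shared by both strands.
Inside methylated (non-TE) genes the probability that a dyad is a
*methylated site* follows a piecewise region profile (defaults in
parentheses): 1 kbp upstream flank (0.02), 5' UTR (0.03), spliced CDS
plateau over the first `cds_plateau` bp (0.80 over 1000 bp) decaying
exponentially 3' of the plateau with scale `cds_decay_bp` (700 bp), introns
discounted by `intron_discount` (0.35) relative to the local CDS level,
3' UTR (0.05) and downstream flank (0.02). A site drawn methylated receives
a within-site fraction from Beta(8, 1.5), i.e. biased toward high
methylation, since observed methylated CpGs concentrate above 75%
methylation; all other dyads sit at the background fraction (0.005). The
plateau/decay pair is a deliberate parametric rendering of a profile for
which only the shape is known (high in the first ~1 kbp of coding sequence,
declining 3', discounted in introns); the intron discount and UTR levels
are single scalars for the same reason.

### Bisulfite reads

Reads are single-end, read-1 sense, sampled uniformly from both strands.
At each template cytosine the read shows C with probability
`frac + (1 - frac) * conversion_failure` and T otherwise; Crick-origin
fragments are reverse complements whose conversion applies to the template
strand's cytosines. Sequencing substitution errors (default 0.002/bp) are
applied after conversion. A configurable fraction of reads (default 0.5%)
is drawn from a bundled *synthetic* 48.5 kbp fully unmethylated control
sequence — a stand-in for an unmethylated phage spike-in library; no
external sequence is shipped. Read names record the true origin so that
placement accuracy is testable without side channels. Fragments are
ungapped; indel errors, PCR duplicates and quality miscalibration are out
of scope.

### Expression

Methylated genes draw stage profiles around a high gene-level mean with a
small across-stage standard deviation (constitutive expression, low CV).
Non-methylated genes are a mixture of silent, stage-specific and broadly
expressed classes; stage-specific genes are additionally off in the adult
with the complementary probability, which makes the adult FPKM marginal
distribution bimodal while the methylated subset stays unimodal. Transcript
abundance fractions (for splicing calls) are drawn independently of
methylation status, so splicing-association tests have a true null.

### What the generator does not emulate

Simulated sequence is i.i.d., so it lacks the genome-wide CpG depletion of
real animal genomes; CpG O/E hovers near 1 everywhere and mammalian-criteria
island detection therefore fires much more densely than on a real assembly.
Genome-wide island and cluster counts from simulations are consequently not
comparable to real-genome counts, and the tests treat them only through
self-consistency audits. Coverage is uniform (no GC bias), scaffolds carry
no assembly gaps, and the expression generator has no batch or dye effects.
Passing tests demonstrate the correctness of the computations under these
idealized conditions, not robustness to every artefact of real libraries.

## Bisulfite alignment

Four converted references are built: Watson and Crick strands, each in a
`meth` variant (Cs in CpG context retained) and an `unmeth` variant (all Cs
converted). Candidate placements are generated by exact seed matches in
fully converted (three-letter) space — a provable superset of all
placements within the mismatch cap, using `max_mismatches + 1` seeds per
read so the pigeonhole principle guarantees one clean seed. Candidates are
re-scored against the meth and unmeth variants under the mismatch policy:

* `"bisulfite"` (default): a read T over a reference C (read A over
  reference G for Crick placements in Watson orientation) is a match.
  This treats conversion state as unknown at every cytosine and never
  penalizes a methylated non-CpG position.
* `"strict"`: flat equality against the partially converted references,
  reproducing a plain mismatch-capped aligner over converted genomes.

Both are retained because the flat policy is what a generic aligner over
converted references effectively implements, while the asymmetric policy is
the fidelity-preserving choice; they differ only for reads spanning many
CpGs of mixed methylation state. Equal-best placements on the meth/unmeth
variants of the same locus collapse into one placement (the pair
intentionally co-maps); equal-best placements at different loci make the
read non-unique, and only unique, indel-free placements feed methylation
quantification. Duplicate reads are not removed. Coordinates are 0-based
half-open internally in the mapper core and 1-based closed in every
user-facing table.

## Cytosine report and conversion efficiency

Watson-strand reads inform Watson cytosines (C = unconverted, T =
converted); Crick-strand reads inform Crick cytosines, which sit at Watson
G positions. Coverage counts any aligned base at the site; the methylation
fraction is unconverted/coverage. Contexts are assigned from the reference
(CpG versus non-CpG); a Watson CpG C pairs with a Crick CpG C one base 3'.
The report is validated against a brute-force per-column recount in the
test-suite.

Conversion efficiency is estimated from the spike-in control, fully
unmethylated by assumption: the raw unconverted fraction pooled over all
control cytosines is corrected by subtracting the background T-to-C error
rate — estimated from reference-T positions of the same alignments when not
supplied — and efficiency is 100% minus the corrected fraction.

## Methylome features

* **mCpG calls**: a site is covered at >= 10 reads and methylated (mCpG)
  when strictly more than 10% of covering reads are unconverted; with these
  thresholds an mCpG needs at least two unconverted reads, so one T-to-C
  sequencing error can never create a methylated site.
* **CpG islands** use the mammalian criteria (length 200 bp – 10 kbp,
  GC > 50%, CpG O/E > 0.6). The scan is a 200 bp window at 1 bp steps;
  qualifying windows are unioned; a merged region is kept if it still meets
  all criteria and otherwise trimmed greedily from whichever end leaves the
  larger criterion margin, with exact ties trimming both ends so the
  procedure is strand-invariant; regions over 10 kbp split at the weakest
  O/E valley. Published island scans differ in exactly these details, so
  the variant here is fully specified and deterministic rather than an
  attempt to match any particular implementation's counts.
* **Methylated CpG clusters** (mCpG fraction among covered CpGs > 80%,
  pooled methylation > 40%, >= 2 mCpGs) are grown greedily from each mCpG
  seed over neighbouring covered CpGs while both criteria hold, then merged
  across gaps under 200 bp that contain no run of 3+ covered non-mCpGs.
  "Average methylation" pools reads (total unconverted over total coverage)
  rather than averaging per-site fractions, matching the region-level
  methylation-percentage convention used everywhere else in the package.
* **Non-CpG screening** reports the global unconverted fraction over
  adequately covered (>= 10, same as CpG) non-CpG cytosines and
  re-examines candidates above 30% against read evidence: a read-consensus
  G immediately 3' of the C where the reference disagrees marks a
  reference-error CpG; a haplotype-like split of the covering reads marks
  collapsed paralogs; anything else stays a candidate.

## Gene-level methylation

Gene status pools CpG-dyad evidence (Watson + Crick strands summed per
dyad, which maximizes coverage symmetry) over the first 1 kbp of the
*spliced* CDS, concatenated 5'->3' in coding orientation — a fixed window
in coding coordinates, not a genomic span. A gene with >= 4 covered dyads
is methylated when > 10% of them are mCpGs; genes with fewer covered
dyads, no CDS, or overlap with another gene model are undetermined (genes
in overlapping models are excluded from all genic CpG accounting). Genes
with under 1 kbp of CDS contribute all their CDS CpGs; there is no minimum
CDS length.

Metagene profiles aggregate covered dyads into flank distance bins, UTRs,
spliced-CDS distance bins, intron junction-distance bins, coding-exon and
intron ranks from both gene ends, and a length-rescaled canonical layout;
both percent-of-mCpGs and pooled methylation percentage are emitted
unsmoothed. Start/stop-codon window statistics and the transcript-length
association (full transcript versus first 1 kbp, Spearman) follow directly;
the latter demonstrates that a negative length correlation arises purely
from 5'-restricted methylation and disappears in the fixed window.
Repeat-element methylation is quantified from the reads that failed unique
genome placement, against a repeat database filtered to elements > 100 bp
with >= 4 CpGs and average depth >= 4; elements above 5% pooled CpG
methylation are flagged hypermethylated.

## Clustering statistics

Determinable genes on the largest scaffolds (default top 100) are ordered
by position; adjacent pairs are classified MM/MN/NM/NN with the distance
taken as the gap between gene spans (0 for overlapping pairs). Null
distributions permute labels *within* scaffolds, holding positions fixed,
which preserves per-scaffold label counts and removes scaffold-composition
confounding. Two-sided permutation p-values use
`(1 + #{|null - mean(null)| >= |obs - mean(null)|}) / (N + 1)`. Run-length
expectations are available both by permutation and in closed form (the
expected number of maximal runs of each length in a random arrangement of
the observed labels); the two agree within Monte-Carlo error and are
cross-checked against each other in the tests. Orientation classes take
the side of each gene facing the shared gap (head = 5' end): divergent
pairs are head-head, convergent pairs tail-tail.

## Expression integration

Tiling-array normalization rescales arrays to a common random-probe mean,
quantile-normalizes all probes across replicates, scores each gene as the
median log2 intensity over the probes of its largest transcript, and calls
a gene expressed when more than half its tiled probes exceed the 99th
percentile of the random-probe background. The expression baseline of 9 is
interpreted on this normalized log2 scale and kept configurable; breadth
counts stages strictly above baseline; CV uses the sample standard
deviation (the population/sample choice is undocumented in most array
pipelines, so the sample convention is fixed here and stated). Five
developmental stages are the default, with `n_stages` exposed because
stage counts differ between array designs. The adult FPKM >= 1 expressed
flag and the normalized-scale baseline are independent knobs: no mapping
between the two scales is assumed.

The dip test for unimodality is implemented in C from its definition: the
dip is the smallest sup-norm distance between the empirical cdf and any
unimodal cdf. Writing the step midpoints as band centres, a candidate cdf
within distance d is a convex band interpolation left of the mode and a
concave one right of it, joined monotonically; convex-side feasibility
reduces to a greatest-convex-minorant test, the minimal feasible junction
value has a closed form over steepest forward extrapolations, and the dip
is a binary search over d. The implementation was validated against a
direct linear-programming solution of the defining minimisation
(enumerating mode positions) on hundreds of samples, a set of which is
frozen into the test-suite. p-values are Monte-Carlo from the uniform null
(the calibration the test was defined against) with a seeded generator;
reported analyses use at least 5000 draws, and each null draw costs a
single feasibility test at the observed statistic rather than a full dip
computation. Exact ties in the data are spread by a relative epsilon of
1e-12 before the hull passes.

The association battery reports, each with its n: rank-sum of expression
level by methylation status; CV by status within median-level strata
(9–11, 11–13, >13 by default, strata under 10 genes reported as
insufficient without a p-value); chi-square of alternative splicing by
status; Kolmogorov–Smirnov of major-isoform fraction by status; Spearman
correlation of percent mCpG with level among methylated genes; logistic
regression of status on level and CV; dip tests per class; and
breadth-by-status counts. Alternative splicing is called when the second
most abundant isoform exceeds 10% of transcript abundance, restricted to
genes above 2 FPKM; annotation-based calls (>= 2 annotated transcripts) are
kept in parallel.

## Comparative statistics

Conservation categories are a pure function of the ortholog presence
matrix (all species / sister-clade-specific / focal-specific / other).
Cross-species concordance compares the observed both-methylated fraction
with the product of the marginals; methylation statuses from other species
are consumed as given, with their calling convention treated as metadata,
because cross-species calls are typically made under different windows and
thresholds and recomputing them is not possible from status tables. Paralog
methylation-loss analysis takes per-pair N-minus-M differences in median
expression, CV, largest stage difference and branch length, excludes
flagged pseudogene pairs, and applies the exact two-sided Wilcoxon
matched-pairs signed-rank test (enumeration-validated in the tests); below
5 pairs the exact test still runs with a power warning.

## Orchestration

`run_pipeline()` executes simulate -> align (control first, then genome)
-> cytosine report -> features -> gene status -> clustering -> expression
-> comparative, writing stage outputs and a JSON manifest with input
digests and output checksums. Re-runs skip stages whose digests match and
whose outputs are intact; a corrupted intermediate invalidates its stage
and everything downstream. The exported functions are the package's
interface; the pipeline is a convenience wrapper over them.

## Numerical choices and problem sizes

All thresholds default to the conventions stated above (10x coverage,
>10% mCpG, 1 kbp status window, 4 covered CpGs, 80%/40% cluster criteria,
5000 permutations, baseline 9) and every one is an explicit argument.
Degenerate inputs are handled explicitly: empty genomes error in reference
construction, zero-coverage controls error in conversion estimation,
constant methylation percentages report a correlation of 0 with a flag,
single-class status tables skip two-sample tests with an insufficient-n
note, and all-equal samples have dip 1/(2n) by construction.

The packaged test-suite and the acceptance script run the full chain on
genomes of roughly 0.1–1 Mbp at 20x coverage with 150–200 genes — sizes
chosen so that status recovery, conversion-efficiency recovery and the
calibration suites are statistically meaningful while a complete run stays
in the minutes range on a laptop. Expression-only analyses (dip tests,
association battery) use label-only gene tables of 1200–1500 genes, the
scale at which the dip test has useful power. Statements about real
genome-scale quantities (millions of CpGs, thousands of islands) are out of
desk scale and are not reproduced by the simulations.
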