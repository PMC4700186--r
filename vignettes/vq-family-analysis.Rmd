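---
title: "Genome-wide VQ gene-family analysis: methods and design"
author: "VQFamily maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide VQ gene-family analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VQFamily)
```

# Background

VQ proteins are small plant cofactors that bind WRKY transcription factors
through a short conserved motif whose consensus is written FxxxVQxLTG.
Families of VQ genes have been catalogued genome-wide in several species;
the reference family shipped with this package is the 61-member maize
(*Zea mays*) ZmVQ family, provided as a curated per-gene table
(`zmvqFamilyTable()`) with chromosome positions, copy and intron numbers,
protein length, isoelectric point, molecular weight and each gene's
conserved decamer.

This vignette documents the models and procedures behind each analysis
stage, the tunable parameters and their defaults, what the synthetic-data
generators emulate, and the numerical choices and limitations a user should
know about.

# Motif model and classification

The family-defining unit is a ten-residue window, the *decamer*. The
loosest published consensus (FxxxVxxxTx) floods random sequence with
matches, so the package works with a tightened **master pattern**

```
F - x(3) - V - [QH] - x(2) - T - x
```

(positions 1, 5 and 9 fixed as F, V, T; the *core* position 6 restricted to
Q or H). Every decamer in the curated maize table satisfies this pattern,
so the tightening introduces no false negatives on the reference family
while sharply reducing spurious windows.

Master-pattern decamers are partitioned into exactly one of five classes,
by precedence:

1. `CANONICAL` — positions (1,5,6,8,9,10) = (F,V,Q,L,T,G), i.e. FxxxVQxLTG;
2. `VH_VARIANT` — core position 6 is H rather than Q;
3. `TG_VARIANT` — ends in TG but position 8 is not L (FxxxVQxxTG);
4. `LTX_VARIANT` — positions 8–9 are LT but position 10 is not G
   (FxxxVQxLTx);
5. `OTHER` — anything else in the master language.

`VH_VARIANT` outranks `TG_VARIANT` deliberately: VH-core decamers usually
also end in TG and would otherwise be absorbed into the TG class.
`scanProteins()` reports *every* matching window (overlapping windows
included); for family-level summaries `summarizeFamily()` selects one hit
per protein, the one with the lowest start position — a deterministic rule
with no possible ties. Position indices are 1-based throughout.

On the curated table this reproduces the published composition: 61/61
master-pattern decamers, 42 canonical, 3 VH cores, and an anchor-residue
(position 8) histogram with 8 F and 6 V. The anchor histogram also shows
43 L — the published running text quotes a larger figure that is
arithmetically inconsistent with its own table, so the table-derived count
is the one the package stands behind.

# Gene structure and copy number

Gene models are exon sets (`GRangesList`, 1-based inclusive coordinates,
mapping directly onto GFF3). The intron count is exons − 1 and is
strand-invariant. `intronlessSummary()` partitions genes into intronless
(no introns) and introned; on the curated table this yields 54 intronless
genes and the seven listed introned genes.

The published study does not state its copy-number criterion.
`copyNumberGroups()` therefore defines copy number by **single-linkage
clustering of global pairwise identity** with a default threshold of 1.0
(exact duplicates); the threshold is a parameter for users who want a
looser notion of "copy". Identity is computed from a Needleman–Wunsch
global alignment (BLOSUM62, affine gaps) as identities over the full
alignment length, which equals 1 exactly when sequences are identical, so
the default behaves like exact-equality grouping while remaining
continuous in the threshold.

# Protein properties

`molecularWeight()` sums isotope-averaged residue masses plus one water.
`netCharge()` is the Henderson–Hasselbalch sum over the N-terminus,
C-terminus and the ionizable side chains (D, E, C, Y, H, K, R); cysteines
are treated as reduced. Two pKa scales are provided — EMBOSS (default) and
Bjellqvist — because published pI values rarely state their scale; the
curated table's pI column is treated as fixture data, not as a
recomputation target, since the generating tool is unknown and the
underlying full-length sequences are not part of the table.

`isoelectricPoint()` finds the unique zero crossing of the net charge
(strictly decreasing in pH) by bisection on (0, 14) to an interval
tolerance of 1e-4 pH units; the returned pI leaves a residual charge below
1e-3 elementary charges for ordinary sequences. The test suite checks the
bisection root against an independent 1e-4 grid search.

# Phylogeny

The alignment is an input (the reference study aligned with MUSCLE); this
package starts from aligned FASTA. Distances are **p-distances with
pairwise gap deletion**: mismatches over the columns where neither sequence
of a pair is gapped. A pair with no comparable columns is an error naming
the pair. A Poisson correction (−log(1 − p)) is available for users who
prefer corrected distances; the reference study does not state its distance
model, which is why the published tree topology is not treated as a
reproduction target.

`njTree()` implements Saitou–Nei neighbor joining: at each step the pair
minimising Q(i,j) = (r−2)·d(i,j) − R(i) − R(j) is joined, with ties broken
towards the lowest index pair so results are deterministic; branch lengths
use the standard formulas with negative lengths clamped to zero (standard
practice; the clamp only triggers on non-additive input). On additive
matrices the generating topology and all path lengths are recovered
exactly; the test suite verifies agreement with an exhaustive
least-squares-best topology search over all 15 (5-taxon) and 105 (6-taxon)
unrooted topologies.

`bootstrapSupport()` resamples alignment columns with replacement,
rebuilds the distance + NJ tree per replicate and reports, for every
internal split of the full-data tree, the fraction of replicate trees
containing it. Replicates whose resample leaves some pair with zero
comparable columns are skipped with a warning and removed from the
denominator. The resampling stream is seeded, so supports are
bit-reproducible. Group labels for published clades are user-supplied
annotations, not something the package infers.

# Promoter cis-element scanning

Promoters default to the 2000 bp immediately upstream of the gene start
(minus-strand promoters are reverse-complemented so they read 5'→3'
towards the gene); promoters truncated by a chromosome edge are flagged.
The default element set is the seven stress-related elements of the
reference study, bit-exact:

| element | pattern |
|---|---|
| W-box | `TTGAC[CT]` |
| DRE | `[AG]CCGAC` |
| CG-box | `[ACG]CGCG[CGT]` |
| MBS | `CAACTG` |
| ABRE | `[CT]ACGTG[GT]` |
| SARE | `TGACG` |
| G-box | `CACGTG` |

Both strands are scanned by default (the study does not say which
convention it used, which is also why its genome-wide promoter percentages
are not reproduction targets); all overlapping occurrences are reported;
`N` never matches. Hit coordinates are 1-based from the promoter's 5' end,
not genomic. Note that palindromic or self-complementary patterns (the
G-box always; every CG-box instance, whose reverse complement is again a
valid CG-box instance) produce a hit on each strand at the same site;
`summarizeElements(collapsePalindromes = TRUE)` counts such sites once,
and planted-count recovery in the test suite uses that convention so one
planted instance counts as one occurrence.

# Expression analysis

All expression work is done on log2(FPKM + 1); replicate arms are averaged
*after* the log transform (variance-stabilising before differencing).

**Tissue grouping.** The published normalisation behind the reference
study's tissue heat map is described only by citation, so `tissueGroups()`
adopts a standard, configurable pipeline: log2(FPKM + 1), per-gene
z-score, average-linkage hierarchical clustering on correlation distance,
tree cut into *k* groups. Genes with zero variance (notably all-zero,
silent genes) are assigned to a dedicated `"silent"` group first,
mirroring the study's "no detectable expression" group.

**Drought response.** The relative expression is Crelative =
Ctreatment − Ccontrol per gene and timepoint, with each arm the mean
log2(FPKM + 1) over its replicates. Classification over the three-point
design (day 3, day 6, re-watered) calls a gene responsive at a timepoint
when |Crelative| ≥ threshold, and assigns: responsive at both drought
timepoints → `SUSTAINED`; day 3 only → `EARLY`; day 6 only → `LATE`;
only after re-watering → `REWATER_ONLY`; otherwise `NON_RESPONSIVE`.
The default threshold is 1.0 log2 unit — the study states no numeric
criterion for its drought-responsive count, so the threshold is a
parameter, and the published 41-of-61 figure is validated only on
synthetic cohorts planted to that design. The classification is monotone:
raising the threshold never makes a gene responsive.

**qPCR.** `ddct()` implements 2^−ΔΔCt: per replicate ΔCt = Ct(target) −
Ct(reference); per group ΔΔCt = mean ΔCt(group) − mean ΔCt(calibrator);
fold = 2^−ΔΔCt. Groups are compared with the calibrator by a two-sided
Welch t-test on replicate ΔCt values at α = 0.05. Rows missing a
reference Ct are rejected with a warning; groups with fewer than two
replicates get no p-value.

# Co-expression network

`pearsonMatrix()` computes standard Pearson correlation across samples
(≥ 3 samples required; zero-variance genes are excluded and listed), and
`buildNetwork()` keeps edges with r **strictly greater** than the
threshold (default 0.90, matching the study's "> 0.90" wording); negative
correlations never create edges. Edges are typed from family labels
(VQ–VQ, VQ–WRKY, WRKY–WRKY) and the summary reports, per VQ gene, its
WRKY partner count. Correlation is computed over all drought-design
samples (both arms, all timepoints, replicates as separate columns) by
default, with the sample subset under user control. With only a dozen
samples, r > 0.90 has a non-trivial chance level, so published network
sizes depend on the exact sample set and are not reproduction targets;
the network stage is instead validated by planted-block recovery.

# What the synthetic generators emulate

Each generator seeds its own stream as (global seed + a fixed per-generator
offset), so outputs are byte-identical under a fixed seed and adding a
generator never shifts another's draws. Defaults are the reference study's
design; they are fixed design choices, not tuning knobs:

- `simProteins()`: i.i.d. uniform residue backgrounds, rejection-sampled to
  be motif-free, with one decamer of an assigned class planted per positive
  protein at a recorded position (re-drawn if planting creates junction
  windows). Default class mix 42/15/1/3 — the curated family's composition.
  Lengths are uniform on 80–300 residues, the family's typical range.
- `simGenomeGff()`: non-overlapping genes on both strands; default intron
  design 54 intronless + seven genes with one or two introns; optional
  planted duplicate groups for copy-number tests.
- `simPromoters()`: backgrounds locally resampled until no element occurs
  on either strand, then requested occurrences planted at recorded
  positions/strands; a candidate is accepted only when a scan recovers
  exactly the planted (element, start) sites.
- `simTissueExpression()`: archetype mean log2 profiles plus Gaussian noise
  (default sd 0.25 log2 units, a typical RNA-seq replicate spread),
  back-transformed to FPKM; default 61 genes × 78 tissues in groups of
  6/6/6/43 with one silent group — the study's panel shape.
- `simDroughtExpression()`: three timepoints × two arms × 2 replicates;
  planted Crelative effects of ±2 log2 units per response class, noise sd
  0.1; default class sizes 6/10/11/14/20, i.e. 41 of 61 responsive.
- `simCoexpression()`: block genes are positive affine images of a shared
  latent factor plus noise (default sd 0.05); background genes independent.
- `simQpcr()`: treatment target Ct = baseline − log2(true fold) + noise,
  constant reference Ct, triplicates, Ct noise sd 0.1 cycles.

Gaussian noise on the log2 scale (lognormal FPKM) is the simplest model
consistent with the pipeline's log2 transforms. What these generators do
**not** emulate: real codon usage or GC content, read-level sampling noise,
library-size effects, correlated tissue profiles, batch structure, or the
heavy-tailed dispersion of real RNA-seq. Passing recovery tests therefore
demonstrates correctness of the algorithms under their stated models, not
robustness to every property of real data.

# Numerical choices and degenerate inputs

- pI bisection tolerance 1e-4 pH units; residual charge checked below 1e-3.
- NJ Q-minimisation tie-break: lowest (i, j) index pair; negative branch
  lengths clamped to 0; branch lengths serialised at full double precision.
- p-distance errors on pairs with zero comparable columns; bootstrap
  replicates that trigger this are skipped and counted.
- Empty inputs: empty hit sets summarise to zero counts; empty protein sets
  give empty copy-number groupings; all-zero expression rows go to the
  silent group rather than producing NaN correlations.
- Strict ">" at the co-expression threshold: a pair at exactly r = 0.90
  gets no edge.

# Problem sizes used in validation

The shipped validation suite exercises: the full 61-row curated table; 200
random additive matrices of 5–6 taxa against exhaustive topology
enumeration; 1,000 random sequences per scanner against brute-force window
oracles; 200 random 30-mers for the pI grid comparison; and single
synthetic cohorts at the study's design sizes (61 genes, 12 drought
samples, 20-gene co-expression sets). These sizes were chosen to give the
oracle comparisons good coverage while keeping the whole suite fast on a
laptop.

# Known limitations

- Identification is by decamer pattern only; no profile-HMM or homology
  search, so highly diverged family members without the master pattern are
  not found.
- One gene model per gene: no UTR modelling or alternative transcripts;
  "gene start" is the model start, assumed to be the start codon.
- The published tree topology, promoter percentages and network counts
  depend on unstated tool settings and on data not redistributable here;
  they are deliberately out of the validation surface.

# Session info

```{r}
sessionInfo()
```
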