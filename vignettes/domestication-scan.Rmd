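---
title: "Scanning variant cohorts for the footprint of domestication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning variant cohorts for the footprint of domestication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Crop domestication is a population bottleneck followed by recurrent
directional selection. Two complementary signals record it in sequence
data. First, *allele erosion*: positions where every surviving wild
relative carries one and the same variant allele while no cultivated
accession carries it at all. Such "common wild variants" are strong
candidates for functional variation lost (or selected against) on the
path to the crop. Second, *frequency-spectrum distortion*: regions the
crop keeps under purifying selection show an excess of rare alleles among
cultivars, measurable as strongly negative Tajima's D; regions under
balancing selection show the opposite.

`domesticscan` implements both scans over per-accession VCFs, plus the
supporting machinery: a high-confidence call filter, within-species and
cross-cohort set algebra, gene-model annotation with codon-level effect
prediction, and SNP-index sliding-window statistics with threshold-merged
selection regions. A simulator generates complete synthetic studies with
planted truth, so every stage is verifiable end to end.

## Identity of a variant

All set operations work on the four-field key *(chromosome, position,
reference allele, alternate allele)*. Two accessions carry "the same
variant" only under full key equality; they share "the same position"
under (chromosome, position) equality. The distinction matters: the scan
separates positions where all wild accessions carry an *identical* allele
from positions where all are variant but alleles differ, and only the
former can be "absent from the cultivated panel" in a well-defined way.
Multi-allelic VCF rows are split into one record per alternate allele
(with genotypes re-coded against that allele) before any comparison, and
indels are trimmed and left-aligned against the reference so the same
haplotypic change always yields the same key. Normalization is
idempotent, which the test suite asserts on random indels.

## The confidence filter

Wild-accession calls pass the stringent criterion *depth ≥ 5, site
quality ≥ 30, 100% non-reference*. "100% non-reference" is interpreted as
a homozygous-alternate genotype with zero reference-supporting reads when
the `AD` field is present (genotype alone suffices when it is absent);
site `QUAL` is used rather than per-genotype `GQ`. A record with missing
depth or quality fails when the policy requires them, and a missing
genotype in a wild accession breaks commonality — a variant an accession
cannot be shown to possess is not common. Cultivated accessions are
deliberately read *unfiltered*: their calls serve as allele observations
that veto candidate differential variants, and for that purpose more
observations are strictly better. Relaxing either threshold can only
grow the passing set (a tested monotonicity property).

## Cohort set algebra

For each wild species the package intersects its accessions' filtered
sets under full key equality (`common_within_species`); a
single-accession species contributes its own set unchanged. The
*percent-common* statistic is `100 × |intersection| / |union|` over SNPs;
the union denominator is a configurable choice (`"mean"` and `"min"` are
available) because the statistic's normalization is not canonical.
*Species-specific* variants are the species' common set minus every key
seen in any other accession, wild or cultivated; by default the target
species must have at least two accessions, since one accession cannot
distinguish species-specific from accession-private.

Across the whole wild panel, positions variant in *every* wild accession
are partitioned into `same_allele` (one universal key) and
`variable_allele` (discordant alleles); the partition law
`|same| + |variable| = |all-wild positions|` holds on every input and is
cross-checked against a naive loop implementation on random mini-cohorts.
The *differential* set is the same-allele keys whose alternate allele
never occurs among cultivated allele calls at that position — both
alleles of a het call count, a hom-alt call contributes its alternate
allele, an explicitly missing call contributes nothing (absence of a call
is not evidence of an allele, so it does not veto), and a position absent
from a cultivated VCF contributes only the implicit reference allele,
which can never equal the wild alternate.

## Gene annotation and coding effects

"Genic" means within the annotated gene span, UTRs and introns included —
the coarse counting unit for genic/total ratios — with CDS membership a
finer label. Flanks are the 2 kb upstream/downstream of the span on the
gene's strand, exclusive of all gene spans; everything else is
intergenic. When spans overlap, the primary hit is the smallest span,
ties broken by gene id.

Effect prediction translates the affected codon before and after a CDS
SNP (standard nuclear code, strand-aware): new stop → `stop_gained`, lost
terminal stop → `stop_lost`, destroyed initiator ATG → `start_lost`,
otherwise synonymous/missense by amino-acid identity. Intronic SNPs
within 2 bp of an internal CDS boundary (the canonical donor/acceptor
dinucleotides; window configurable) are `splice_site`. CDS indels are
`frameshift` when the length change is not a multiple of three, else
`inframe_indel`. `start_gained` — an SNP creating an ATG in the genic
region 5' of the annotated start — is assessed only in the differential
report (off elsewhere), since upstream ATG creation is speculative
without transcript evidence. Impact tiers are the conventional
HIGH (stop/start/splice/frameshift), MODERATE (missense, in-frame
indel), LOW (synonymous), MODIFIER (non-coding). Genes whose CDS length
is not a multiple of three are classified on the available frame and
flagged. The incremental classifier is tested against an independent
whole-CDS re-translation oracle on both strands, and a
reverse-complement-the-genome symmetry test guards the strand logic.

## Window statistics

Sites enter as per-position allele counts *(n, k)*: each called diploid
genotype contributes two copies, missing genotypes are excluded per site,
an accession without a record at a site counts as homozygous reference
(the convention for single-sample VCFs that emit variant sites only; a
`"missing"` mode is available). Positions showing more than one alternate
allele across the panel are dropped (counted), as are sites with fewer
than 4 allele copies.

Windows are 500 SNPs wide with step 100 (SNP-index space, per
chromosome); trailing partial windows are computed and flagged but
excluded from region calling by default — their variance at small S is
unstable. Per window: S, window pi, Watterson's theta, Tajima's D, and
optionally Hudson's Fst between two groups. Tajima's D needs a single n;
with per-site n varying through missingness the rounded mean over the
window's segregating sites is used (exact when n is constant, as in the
oracle tests). Hudson's Fst uses the ratio-of-averages form
`1 − mean(Hw)/mean(Hb)` with *expected* within-group heterozygosity
(no n/(n−1) pair correction), so identical sample frequencies give
exactly 0 and fixed differences exactly 1. For the default
wild-vs-cultivated grouping, sites absent from every wild VCF enter with
k = 0 at full wild sample size, and a wild panel carrying a different
allele contributes 0 for the cultivated allele.

Threshold comparisons are deliberately asymmetric — purifying regions
require `D < −3` strictly, balancing regions `D ≥ 2` — and both
thresholds are configurable. Passing windows are projected to the bp span
from their first to last SNP (windows are SNP-index objects, so spans are
data-dependent) and overlapping or adjacent spans are merged per
direction; resident genes are genes whose span overlaps the merged
region.

## What the simulator emulates — and what it does not

`simulation_config()` defaults encode the study conditions: a 3 × 5 Mb
genome at 36% GC with ~150 spaced gene models (1–5 CDS segments, valid
start/stop, UTRs, mixed strands, ~10% resistance-related annotations); 12
wild species with 1–7 accessions each (29 total) whose within-species
allele sharing is high for self-compatible species and low for
self-incompatible ones; 40 cultivated accessions drawing background
variation from a shared pool under the neutral 1/k site-frequency
spectrum. Planted on top, at positions mutually exclusive by
construction: 50 species-specific SNPs per multi-accession species with a
controlled genic fraction; 120 differential alleles spanning every region
class and every HIGH-impact effect class (designed at the codon level, so
the planted label is true by construction, not by running the
classifier); 80 common-wild alleles also segregating in the cultivated
panel; 30 discordant all-wild positions (two alleles split across
species); 40 negative controls whose every wild call fails exactly one
filter criterion; and a 2 Mb sweep segment on ch03 whose 700 sites are
cultivated singletons.

Three design choices deserve justification. *Neutral spectrum*: sampling
carrier counts with probability ∝ 1/k makes the expected window pi equal
theta_W, so background Tajima's D is centred at zero; a uniform allele
frequency would inflate intermediate-frequency sites and push background
D near +2, manufacturing balancing-selection regions everywhere. *Sweep
as singletons*: assigning each sweep site exactly one carrier chromosome
is the strongest rare-allele skew expressible in genotypes; for n = 80
copies and a full 500-singleton window D ≈ −3.04, just below the −3
threshold — exactly the regime the scan targets. With 700 segment sites,
at least two full windows fit entirely inside the segment regardless of
how window starts align, which keeps the recovered region's bp overlap
with the planted span above 0.8. *No linkage*: sites are independent;
there is no recombination structure, LD, coalescent demography or
read-level error. Passing tests therefore demonstrate correctness of the
set algebra, annotation and statistics on realistic call *tables* — not
robustness to LD-induced variance of D, reference bias, or genotyping
error correlation, which real cohorts have.

Confident planted calls sample depth from 5 + Poisson(15) and quality
from Uniform(40, 90); negative controls sample one failing field (depth
< 5, quality < 30, a het genotype, or reference-supporting reads under a
hom-alt call). A small fraction of cultivated calls is emitted as
explicit `./.` to exercise missing-data handling. Everything is
deterministic given the seed, byte-for-byte.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive everywhere internally; BED/bedGraph
writers convert at the boundary. Tajima's D is NA for S = 0 or n < 4
(with the sign property sign(D) = sign(pi − S/a1) asserted whenever
defined); percent-common is NA for an empty union or a single accession;
genic ratio is NA for zero variants; Fst is NA when no site has two
usable groups. Empty VCFs, empty windows and empty region sets propagate
as empty tables, not errors. Ties in primary-hit gene assignment break by
span size then lexicographic gene id, making outputs order-independent.

## Problem sizes used by the verification suite

The acceptance tests run the statistics oracles on 200 random matrices
(n ∈ [4, 80], S ∈ [1, 200]), the set-algebra cross-check on 50 random
mini-cohorts, the effect oracle on 500 coding SNPs plus 200 indels, and
five full-scale simulated studies (~45 s each) for exact ground-truth
recovery and sweep detection. Unit tests use a scaled-down study (3 ×
0.4 Mb, 30 genes) that exercises every stage in a few seconds.

## Limitations

The effect predictor covers the headline coding classes only — no UTR
sub-classes, regulatory motifs, or multi-transcript reconciliation; one
representative mRNA per gene (first, ties by id). No coalescent p-values
for D, no haplotype statistics, no imputation, no phasing. Differential
calls inherit the confidence filter's blind spots: a wild accession with
a missing call at a truly shared position removes that position from the
common set, so the scan is conservative by design.
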