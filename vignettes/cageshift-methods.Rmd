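---
title: "cageshift: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cageshift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cageshift)
```

# Scope and data model

`cageshift` analyses promoter usage from CAGE tag data in a two-strain
design: two inbred parental strains (called A and B throughout; B is the
reference-genome strain), each sequenced in replicate, optionally with
reciprocal F1 hybrids and a recombinant-inbred (RI) panel derived from the
same cross. All internal coordinates are 1-based inclusive, matching
GTF/VCF conventions; only BED emission converts to 0-based half-open, at
the writer boundary. This single-convention rule is deliberate: most
off-by-one defects in TSS pipelines come from mixing coordinate systems
mid-analysis.

The central object is the CTSS matrix: one row per (chromosome, position,
strand) with one tag count column per sample. Everything downstream —
clusters, promoters, shift profiles — is derived from it, and every
cluster's members are recoverable as the matrix rows inside its span
(single-linkage clustering partitions each strand into disjoint spans, so
no explicit membership table is needed).

# From alignments to promoters

**CTSS extraction.** A retained alignment is first-in-pair, primary,
non-supplementary, non-duplicate, and mapped with quality exactly 255 (the
unique-mapper code of STAR-style aligners; `mapq_unique` is exposed
because other aligners encode uniqueness differently, and guessing a
universal proxy would be worse than asking). The 5' end is the leftmost
aligned base on the plus strand, rightmost on the minus strand. An
optional `softclip_aware` mode shifts the 5' end outward by the leading
soft clip; this approximates correction for the template-free extra G
that reverse transcriptase adds during CAGE library preparation when that
base was *not* trimmed before mapping. It is off by default because the
canonical protocol trims the G upstream of alignment, where the
information needed to replay it is lost.

**Support filter.** Positions with at least one tag in at least three
samples are kept. With 12 parental samples this removes most singleton
noise while keeping genuinely strain-specific positions (which appear in
six samples). The filter is idempotent and its per-row logic is tested
against a brute-force scan.

**Clustering.** CTSSs within 20 bp on the same strand merge by single
linkage (chained distances, boundary inclusive) into tag clusters; tag
clusters whose edge-to-edge gap is at most 100 bp merge into promoter
regions. Single linkage was chosen because the 20 bp rule is stated as a
pairwise distance, and the `distclu` convention of CAGE analysis makes
chains, not fixed windows, the standard reading. Both steps are verified
against an O(n^2) transitive-closure oracle on random inputs, and obey
three properties worth stating: permutation invariance of input rows,
exactness at gap 0 (clusters = distinct positions), and refinement
monotonicity (clusters at a smaller gap nest inside clusters at a larger
gap).

**Normalisation.** Counts become tags per million with the per-sample
total of *retained* CTSS counts as denominator. Mapped-read totals would
be an equally defensible denominator, but they are not reconstructible
from the CTSS matrix alone; using retained totals keeps every number in
the pipeline reproducible from one artifact. Clusters reaching 1 TPM in
at least one sample (boundary inclusive) are kept.

**Gene assignment and ranking.** A gene region is the span of the gene's
longest transcript (maximal genomic span, not summed exon length — the
simpler rule, and the difference only matters for genes whose longest
genomic transcript is not the longest mature one) extended 1 kb upstream
of the transcript 5' end. Upstream is strand-aware: for a minus-strand
gene the extension is to the right. Promoters intersecting the region on
the same strand are assigned; per gene they are ranked P1, P2, ... by
mean TPM over all parental samples, pooled across strains (ranking
per-strain would make "P1" ambiguous in exactly the genes the alternative
usage test cares about), with positional left-to-right order breaking
ties. Intergenic promoters are independent P1 promoters. A promoter
hitting two gene regions goes to the gene whose region start is nearest —
an arbitrary but deterministic rule, logged when it fires.

**TSS distance and architecture classes.** Distance to annotation is the
minimum over the gene's annotated TSSs of the distance to the nearest
promoter edge (0 = containment = "exact"); bins at 100 and 1000 bp give
the within_100 / within_1000 / unannotated classes, and the same logic
with configurable bins serves comparisons against external TSS sets. A
promoter is CpG-positive when its span, extended 200 bp both sides,
touches a CpG island, and TATA-positive when the window from 500 bp
upstream to 200 bp downstream of its dominant CTSS (transcript
orientation, promoter strand only) matches the IUPAC consensus TATAWAWR.
An exact consensus match replaces the usual position-weight-matrix scan;
the matcher accepts any IUPAC pattern so a PWM-with-threshold matcher can
be slotted in. Expect the consensus to be slightly more conservative than
a tuned PWM.

# Differential promoter use and alternative usage calls

Promoter counts (sums of member-cluster counts) are tested between
strains with a self-contained negative-binomial Wald test: size factors
by median-of-ratios; per-promoter dispersion by method of moments pooled
within groups, floored at 1e-8; group means by maximum likelihood (Newton
iterations vectorised across promoters); the Wald statistic on the log2
fold change. One deliberate deviation from the usual large-sample recipe:
the statistic is referred to a t distribution with residual degrees of
freedom (n - 2) rather than the normal. With six replicates per group the
plug-in dispersion is noisy, and the normal reference yields an empirical
type-I error of about 0.08 at the 0.05 level; the t reference (the
quasi-likelihood convention familiar from edgeR's QL pipeline) restores
calibration (0.051 in a 10,000-promoter null simulation, and the
acceptance suite enforces [0.04, 0.06]). No fold-change shrinkage and no
independent filtering are applied; estimates are raw Wald MLEs and BH
adjustment runs across all tested promoters.

A gene is then called by composition of three rules: promoters with at
least 20% of the gene's pooled activity are "active"; a gene with fewer
than two active promoters is `single_predominant`; otherwise the gene is
`alternative_usage` when some active pair has adjusted p <= 0.05 on both
members with opposite fold-change signs *and includes P1* (requiring both
members significant is the stricter of the two readings the rule admits;
we chose it because a single-significant pair cannot evidence a switch,
only a change), else `multi_no_de` or `multi_same_direction`.

# Promoter shift detection

For each tag cluster, per-position counts are aggregated over the six
replicates of each strain and the two count-weighted empirical CDFs are
compared: `D` is the maximal absolute CDF difference over member
positions, the shift position is the smallest position attaining it, and
the direction compares count-weighted mean positions, strand-adjusted so
"upstream_in_A" means strain A initiates 5' of strain B. A shift is
significant when `D > 0.3` and `D` exceeds the large-sample two-sample
critical value `sqrt(-ln(alpha/2)/2) * sqrt((n_A+n_B)/(n_A n_B))` with
tag totals as effective sizes. Tags from one library are not independent
observations, so this critical value is anticonservative in principle —
which is precisely why the absolute `D > 0.3` gate does the real work at
realistic tag depths (at 1,000 tags per strain the critical value is
~0.06). No multiple-testing correction is applied across clusters,
matching the two-gate design. The ECDFs are computed directly from count
vectors in O(positions); the test suite checks them against an oracle
that expands counts into pseudo-observations.

# Allelic imbalance and RI association

Variants enter the F1 analysis when (i) every parental replicate has
depth >= 10, (ii) the pooled majority allele differs between the parental
strains (our operationalisation of "variable between strains" — exact
homozygosity would be brittle against stray error reads), and (iii) at
least 9 of 12 F1 replicates have depth >= 10. Ref/alt counts are then
pooled across the 12 F1s (the reciprocal-cross structure is carried as
metadata but not modelled; no parent-of-origin term) and tested with the
exact two-sided binomial at p0 = 0.5, implemented in closed form
(`p = 2 P(X <= min(k, n-k))`, 1 at equality) and verified against
`binom.test` — at p0 = 0.5 the minimum-likelihood and central two-sided
conventions coincide. `AI = (ref - alt)/(ref + alt)` is positive toward
the reference (strain B) allele. Variants are classed by their containing
promoter (shifting / strongly differential, i.e. padj <= 0.05 and
|log2fc| > 1 / other); the class comparison reports Fisher's exact test
on significant-AI proportions and a Mann–Whitney test on |AI|. RI
genotype–phenotype association is a two-sided Mann–Whitney test between
the two homozygous genotype groups.

Worth knowing: the exact binomial test is discrete, so its true size sits
below the nominal level at any fixed depth — 0.033 at n = 50, approaching
0.05 from below as depth grows. Calibration statements in the tests are
therefore made at the pipeline's actual pooled depths (~360), where the
size is ~0.044.

# The synthetic-data generator

The generator emits the stated experimental world: 12 parental samples (2
strains x 2 sexes x 3 replicates), and for the F1 module 12 hybrids (2
reciprocal crosses x 2 sexes x 3 replicates). Defaults: 60 genes with 1–3
promoters (probabilities 0.5/0.35/0.15), half sharp (geometric positional
decay 0.5 per bp — a 1–5 bp effective width) and half broad (discretised
Gaussian, sigma 15 bp); 300 expected tags per promoter per sample, NB
dispersion 0.05 (typical replicate variability for inbred animals); 10
planted alternative-usage genes (two promoters at 0.55/0.45 of gene
activity with opposite strain effects of |log2fc| = 1.5); 10 planted
shifts of 40 bp on broad promoters (a sharp profile shifted 40 bp would
split into two tag clusters at the 20 bp rule — within-cluster shifts are
a broad-promoter phenomenon by construction); 60 variants of which 20
carry |AI| = 0.5 (alternating sign), parental replicate depth ~50, F1
depth ~30; ~30 RI strains with a 2 SD genotype effect. Sharp promoters
get a TATAWAWR motif planted 31–24 bp upstream of the mode (the canonical
TATA position), broad promoters an overlapping CpG island record.
Sub-seeds are derived deterministically per entity, so enlarging a design
does not perturb existing entities and a fixed seed is byte-reproducible.

What the generator does **not** emulate: mapping bias and multi-mapping,
sequence-error models, PCR artefacts, overlapping genes and antisense
transcription, chromatin-driven covariance between promoters, and
realistic genome composition (CpG islands are interval records, not
CG-rich sequence). A green end-to-end test therefore establishes that the
statistical machinery recovers planted truth under the stated noise
model — not that the pipeline is robust to alignment pathology.

# Numerical conventions

Ties in dominant-CTSS selection and in promoter ranking break toward the
smaller coordinate; the KS shift position takes the smallest maximising
position. Degenerate inputs are contracts, not accidents: an empty CTSS
matrix flows through to empty outputs, an all-zero promoter is excluded
from testing and reported NA, a cluster with zero tags in either strain
is flagged untestable, and zero-total TPM normalisation is an error
rather than a silent NaN. Fixed-seed stochastic checks in the test suite
use a 4 SD band on oracle z-statistics package-wide; the acceptance
criteria run at their stated rates (recall >= 0.8/0.9, false positives
<= 5%, type-I in [0.04, 0.06]) under seed 42.

# Limitations

The KS gate inherits the anticonservative effective-size convention
described above; treat `D` and the 0.3 gate, not the critical value, as
the scientific filter. The NB test's moment dispersion is unshrunken, so
per-promoter power is below what an empirical-Bayes engine achieves at
the same replicate count; the package's claims are calibration and
effect recovery, not DESeq2-equivalence. The alternative-usage rules
operate on promoter regions, not transcripts, so a called gene localises
a switch without identifying the affected isoforms. Heterozygous parents
violate the homozygosity assumptions of both the pseudo-genome step and
the parental-variability filter and are out of scope.
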