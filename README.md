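# cageshift

Promoter-level analysis of CAGE (Cap Analysis of Gene Expression) tag data
for two-strain rodent designs, built around the HXB/BXH setting: two inbred
parental strains (e.g., SHR and BN rats), reciprocal F1 crosses, and a
recombinant-inbred (RI) panel.

CAGE sequences the 5' capped ends of transcripts, so the 5' end of each
first-in-pair read marks a transcription start site at single-base
resolution. `cageshift` turns aligned CAGE reads into promoter calls and
asks three questions about strain differences:

1. **Alternative promoter usage** — does a gene switch its predominant
   promoter between strains? Promoter-level counts are tested with a
   two-group negative-binomial Wald test (median-of-ratios size factors
   `s_j`, per-promoter moment dispersion `alpha`, model
   `y_ij ~ NB(s_j q_g(j), alpha)`); a gene is called when two promoters
   with >= 20% of the gene's activity change in opposite directions
   (BH-adjusted p <= 0.05 on both) and the pair includes the dominant
   promoter P1.
2. **Promoter shifting** — does TSS usage move *within* a promoter?
   Per-strain CTSS profiles are aggregated over replicates and compared by
   a count-weighted two-sample Kolmogorov–Smirnov statistic
   `D = max_x |F_A(x) - F_B(x)|`, significant when `D > 0.3` and
   `D > c(alpha) sqrt((n_A + n_B)/(n_A n_B))`, `c(0.05) ~ 1.358`.
3. **Allelic imbalance in F1s** — do variants in shifting promoters show
   biased allele usage? `AI = (ref - alt)/(ref + alt)` with an exact
   two-sided binomial test at p0 = 0.5 on pooled F1 allele depths.

Supporting stages: pseudo-genome construction (SNV substitution that
preserves coordinates, for allele-aware mapping), CTSS extraction from
SAM/BAM (MAPQ-255 unique R1 5' ends), the support filter (>= 1 tag in >= 3
samples), single-linkage tag clustering (20 bp) and promoter grouping
(100 bp), tags-per-million normalisation, gene assignment and P1/P2/...
ranking, TSS-annotation distance classes, CpG/TATA architecture classes,
and Mann–Whitney genotype–phenotype association in RI strains. A
synthetic-data generator with planted ground truth (architectures, fold
changes, shift offsets, imbalances, phenotype effects) makes the whole
pipeline testable end to end.

## Worked example

```r
library(cageshift)
cfg <- sim_config(seed = 1)                 # 60 genes, 12 parental samples
sim <- simulate_ctss_experiment(cfg)        # genome, GTF, CpG, CTSS matrix
ase <- simulate_f1_ase(cfg)                 # 24-sample variant set
res <- run_pipeline(pipeline_config(), sim$ctss, sim$samples, sim$genes,
                    genome = sim$genome, cpg = sim$cpg,
                    variants = ase$variants)
res$summary
```

prints (abridged):

```
tag clusters: 91
promoters: 91  genic: 91
single_predominant: 34  multi_no_de: 16  multi_same_direction: 0  alternative_usage: 10
significant shifts: 10   P1 share: 1
ASE variants tested: 60  significant: 21
arch classes: both 7  CpG_only 50  TATA_only 34
```

All 10 planted alternative-usage genes and all 10 planted 40 bp shifts are
recovered; the 21 significant ASE variants are the 20 planted-imbalance
variants plus one null (the test runs at the 0.05 level). The
strand-aware distance helper reproduces positions the way a genome browser
would report them:

```r
feature_distance(1816432, 1816086, "-")
#> $distance 346    $orientation "upstream"
```

## Command line

`exec/cageshift` wraps the R API:

```sh
Rscript exec/cageshift simulate --seed 1 --outdir fixtures/
Rscript exec/cageshift run --ctss fixtures/ctss.matrix.tsv \
    --samplesheet fixtures/samples.tsv --gtf fixtures/genes.gtf \
    --fasta fixtures/genome.fa --cpg fixtures/cpg.bed \
    --vcf fixtures/f1.vcf --outdir run/
```

Other subcommands: `pseudogenome`, `ctss`, `ctss-merge`, `cluster`,
`shift`, `assoc` (see the script header).

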