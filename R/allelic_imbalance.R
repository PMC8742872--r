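#' Filter variants for allelic-imbalance analysis
#'
#' Retains variants that (i) are covered by at least `min_reads` reads
#' (ref + alt) in every parental replicate, (ii) are variable between the
#' two parental strains (the majority allele pooled per strain differs),
#' and (iii) are covered by at least `min_reads` reads in at least
#' `f1_min_replicates` of the F1 replicates.
#'
#' @param vs a `variant_set` (see [read_variants()]).
#' @param parental_samples_a,parental_samples_b per-strain parental sample
#'   names (strain A = alternate-carrying strain, strain B = reference).
#' @param f1_samples F1 sample names.
#' @param min_reads per-replicate depth threshold (inclusive).
#' @param f1_min_replicates F1 replicates that must reach it (inclusive).
#' @return Logical vector marking retained variants.
#' @export
filter_variants_for_ase <- function(vs, parental_samples_a,
                                    parental_samples_b, f1_samples,
                                    min_reads = 10L,
                                    f1_min_replicates = 9L) {
  par <- c(parental_samples_a, parental_samples_b)
  depth <- vs$ref_counts + vs$alt_counts
  crit1 <- rowSums(depth[, par, drop = FALSE] >= min_reads) == length(par)
  fr_a <- rowSums(vs$ref_counts[, parental_samples_a, drop = FALSE]) /
    pmax(1, rowSums(depth[, parental_samples_a, drop = FALSE]))
  fr_b <- rowSums(vs$ref_counts[, parental_samples_b, drop = FALSE]) /
    pmax(1, rowSums(depth[, parental_samples_b, drop = FALSE]))
  crit2 <- (fr_a >= 0.5) != (fr_b >= 0.5)  # pooled majority allele differs
  crit3 <- rowSums(depth[, f1_samples, drop = FALSE] >= min_reads) >=
    f1_min_replicates
  crit1 & crit2 & crit3
}

#' Exact binomial allelic-imbalance test
#'
#' `AI = (ref - alt) / (ref + alt)` (positive toward the reference allele)
#' and the exact two-sided binomial p-value at `p0 = 0.5`:
#' `p = 2 * P(X <= min(k, n - k))`, 1 when `k = n / 2`. At `p0 = 0.5` the
#' minimum-likelihood and central two-sided conventions coincide; the
#' closed form equals `stats::binom.test()`. Vectorised.
#'
#' @param ref_total,alt_total summed allele counts (total >= 1).
#' @return list with `ai` and `p`.
#' @examples
#' ai_test(15, 5)  # AI 0.5, p ~ 0.0414
#' @export
ai_test <- function(ref_total, alt_total) {
  n <- ref_total + alt_total
  if (any(n < 1)) stop("zero total coverage")
  m <- pmin(ref_total, alt_total)
  p <- 2 * stats::pbinom(m, n, 0.5)
  p[2 * m == n] <- 1
  list(ai = (ref_total - alt_total) / n, p = pmin(p, 1))
}

#' Assign promoter classes to variants
#'
#' Each variant is mapped to the promoter (or tag cluster) containing it on
#' either strand; variants in no promoter are dropped. Class `shifting`
#' when the promoter has a significant shift call, else `diff_expressed`
#' when `padj <= alpha` and `|log2fc| > lfc_min`, else `other`.
#'
#' @param variants data.frame with `chrom`, `pos`.
#' @param promoters `promoter_regions`/`tag_clusters` data.frame.
#' @param shifts [call_shifts()] output matched to `promoters` by id.
#' @param de [test_differential()] output matched by `feature`.
#' @param alpha,lfc_min differential-expression thresholds.
#' @return data.frame of the retained variants with `promoter_id` and
#'   `promoter_class` appended.
#' @export
classify_variant_promoters <- function(variants, promoters, shifts, de,
                                       alpha = 0.05, lfc_min = 1) {
  df <- as.data.frame(promoters)
  idcol <- if ("promoter_id" %in% names(df)) "promoter_id" else "tc_id"
  vg <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  pg <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  hits <- GenomicRanges::findOverlaps(vg, pg, select = "first")
  keep <- !is.na(hits)
  out <- variants[keep, , drop = FALSE]
  pid <- df[[idcol]][hits[keep]]
  sig_shift <- shifts$tc_id[shifts$significant]
  i <- match(pid, de$feature)
  sig_de <- !is.na(de$padj[i]) & de$padj[i] <= alpha &
    abs(de$log2fc[i]) > lfc_min
  out$promoter_id <- pid
  out$promoter_class <- ifelse(pid %in% sig_shift, "shifting",
                               ifelse(sig_de, "diff_expressed", "other"))
  rownames(out) <- NULL
  out
}

#' Compare allelic imbalance across promoter classes
#'
#' Fisher's exact test on the 2x2 table of significant-AI counts in
#' `shifting` versus `other` promoters, plus a two-sided Mann-Whitney test
#' on the `|AI|` distributions. Empty classes yield `NA` for the affected
#' comparison.
#'
#' @param ase data.frame with columns `ai`, `p`, `promoter_class`.
#' @param alpha AI significance threshold on `p`.
#' @return list with `table` (class x significance counts), `fisher_p`,
#'   `mw_p`.
#' @export
compare_promoter_classes <- function(ase, alpha = 0.05) {
  ase$sig <- ase$p <= alpha
  tab <- table(factor(ase$promoter_class,
                      levels = c("shifting", "diff_expressed", "other")),
               factor(ase$sig, levels = c(TRUE, FALSE)))
  sh <- ase$promoter_class == "shifting"
  ot <- ase$promoter_class == "other"
  fisher_p <- mw_p <- NA_real_
  if (any(sh) && any(ot)) {
    m <- rbind(c(sum(sh & ase$sig), sum(sh & !ase$sig)),
               c(sum(ot & ase$sig), sum(ot & !ase$sig)))
    fisher_p <- stats::fisher.test(m)$p.value
    mw_p <- stats::wilcox.test(abs(ase$ai[sh]), abs(ase$ai[ot]),
                               exact = FALSE)$p.value
  }
  list(table = tab, fisher_p = fisher_p, mw_p = mw_p)
}

#' Ratio of a target region count to a reference region count
#'
#' Used to normalise read counts from a strain-specific transcript region
#' to a constitutive region (e.g., a first exon) of the same gene.
#'
#' @param target_region_count,reference_region_count non-negative counts;
#'   the reference must be positive.
#' @return `target / reference`.
#' @export
region_normalized_count <- function(target_region_count,
                                    reference_region_count) {
  if (any(reference_region_count <= 0))
    stop("reference region count must be positive")
  target_region_count / reference_region_count
}

#' Genotype-phenotype association in recombinant-inbred strains
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between exactly two
#' genotype groups, exact when no ties and small samples, with tie
#' correction otherwise.
#'
#' @param genotypes character vector of genotype labels (two distinct
#'   values, each with >= 2 strains).
#' @param values numeric phenotype measurements aligned with `genotypes`.
#' @return list with `statistic` (rank-sum U of the first group by label
#'   order), `p`, and `group_medians`.
#' @export
genotype_association <- function(genotypes, values) {
  g <- sort(unique(genotypes))
  if (length(g) != 2L) stop("exactly two genotype groups required")
  v1 <- values[genotypes == g[1L]]; v2 <- values[genotypes == g[2L]]
  if (length(v1) < 2L || length(v2) < 2L)
    stop("each genotype group needs >= 2 strains")
  if (stats::var(c(v1, v2)) == 0) {
    # fully tied data: no evidence either way
    wt <- list(statistic = length(v1) * length(v2) / 2, p.value = 1)
  } else {
    wt <- stats::wilcox.test(v1, v2)
  }
  list(statistic = unname(wt$statistic), p = wt$p.value,
       group_medians = stats::setNames(c(stats::median(v1),
                                         stats::median(v2)), g))
}
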