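#' Promoter activity proportions within a gene
#'
#' `proportion_i = expr_i / sum(expr)`; proportions sum to one.
#'
#' @param expression non-negative per-promoter expression (e.g., mean TPM
#'   pooled over all parental samples); at least one value must be positive.
#' @return Numeric vector of proportions in the input order.
#' @export
activity_proportions <- function(expression) {
  if (any(expression < 0)) stop("expression must be non-negative")
  tot <- sum(expression)
  if (tot <= 0) stop("all-zero expression: proportions undefined")
  expression / tot
}

#' Median-of-ratios size factors
#'
#' Per-sample median of the ratios to the row-wise geometric mean, computed
#' over features with a positive geometric mean.
#'
#' @param counts feature x sample matrix of non-negative counts.
#' @return Named numeric vector of size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  lg <- log(counts)
  ref <- exp(rowMeans(lg))          # -Inf rows (any zero) drop out below
  use <- is.finite(ref) & ref > 0
  if (!any(use)) stop("no feature with all-positive counts; cannot ",
                      "estimate size factors")
  sf <- apply(sweep(counts[use, , drop = FALSE], 1, ref[use], "/"), 2,
              stats::median)
  if (any(sf <= 0)) stop("non-positive size factor estimated")
  sf
}

moment_dispersion <- function(counts, sf, group) {
  z <- sweep(counts, 2, sf, "/")
  num <- 0; den <- 0
  for (g in unique(group)) {
    zg <- z[, group == g, drop = FALSE]
    m <- rowMeans(zg)
    v <- rowSums((zg - m)^2) / (ncol(zg) - 1L)
    ag <- ifelse(m > 0, (v - m) / m^2, 0)
    num <- num + ag * (ncol(zg) - 1L)
    den <- den + (ncol(zg) - 1L)
  }
  pmax(num / den, 1e-8)
}

nb_group_fit <- function(counts, sf, alpha) {
  # MLE of the common-scale group mean q under NB(mu = sf*q, dispersion
  # alpha), Newton iterations vectorised over features
  q <- pmax(rowMeans(sweep(counts, 2, sf, "/")), 1e-8)
  for (it in 1:100) {
    mu <- q * rep(1, nrow(counts)) %o% sf
    denom <- 1 + alpha * mu
    score <- rowSums((counts - mu) / denom) / q
    info <- rowSums(sweep(1 / denom, 2, sf, "*")) / q
    qnew <- pmax(q + score / info, 1e-10)
    if (max(abs(qnew - q) / pmax(q, 1e-8)) < 1e-12) { q <- qnew; break }
    q <- qnew
  }
  mu <- q * rep(1, nrow(counts)) %o% sf
  list(q = q, info = rowSums(mu / (1 + alpha * mu)))  # info for log q
}

#' Two-group negative-binomial Wald test for differential promoter use
#'
#' A self-contained differential-expression engine filling the role usually
#' played by DESeq2-style tools: median-of-ratios size factors, per-feature
#' method-of-moments dispersion (floored at 1e-8), maximum-likelihood group
#' means under a two-group NB model, and a Wald test on the log2 fold change
#' (group A over group B). Because the plug-in dispersion is estimated from
#' few replicates, the Wald statistic is referred to a t distribution with
#' residual degrees of freedom `n - 2` (quasi-likelihood convention), which
#' restores type-I calibration at typical replicate numbers. P-values are
#' BH-adjusted across all tested features; all-zero features are excluded
#' and reported `NA`.
#'
#' @param counts feature x sample matrix of non-negative integer counts;
#'   row names identify features.
#' @param group character/factor of length `ncol(counts)` with exactly two
#'   levels; the first level (alphabetically, or the factor's first level)
#'   is the "A" (numerator) group.
#' @param size_factors optional pre-computed size factors.
#' @return data.frame `feature`, `base_mean` (mean of normalised counts),
#'   `log2fc`, `se`, `stat`, `p`, `padj`.
#' @export
test_differential <- function(counts, group, size_factors = NULL) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (min(table(group)) < 2L) stop("need >= 2 replicates per group")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  feat <- rownames(counts)
  if (is.null(feat)) feat <- as.character(seq_len(nrow(counts)))
  ok <- rowSums(counts) > 0
  out <- data.frame(feature = feat, base_mean = NA_real_,
                    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                    p = NA_real_, padj = NA_real_, stringsAsFactors = FALSE)
  if (any(ok)) {
    y <- counts[ok, , drop = FALSE]
    a <- levels(group)[1L]; b <- levels(group)[2L]
    alpha <- moment_dispersion(y, size_factors, group)
    fa <- nb_group_fit(y[, group == a, drop = FALSE],
                       size_factors[group == a], alpha)
    fb <- nb_group_fit(y[, group == b, drop = FALSE],
                       size_factors[group == b], alpha)
    lfc <- (log(fa$q) - log(fb$q)) / log(2)
    se <- sqrt(1 / fa$info + 1 / fb$info) / log(2)
    stat <- lfc / se
    df_resid <- ncol(y) - 2L
    p <- 2 * stats::pt(-abs(stat), df = df_resid)
    out$base_mean[ok] <- rowMeans(sweep(y, 2, size_factors, "/"))
    out$log2fc[ok] <- lfc; out$se[ok] <- se; out$stat[ok] <- stat
    out$p[ok] <- p
    out$padj[ok] <- stats::p.adjust(p, method = "BH")
  }
  out
}

#' Call alternative promoter usage for one gene
#'
#' Active promoters are those with an activity proportion of at least
#' `min_prop` (default 20%). A gene is an alternative-usage gene when an
#' active promoter pair exists whose members are both significantly
#' differential (`padj <= alpha`), change in opposite directions, and
#' include the gene's dominant promoter (P1). Otherwise the gene is
#' `single_predominant` (fewer than two active promoters), `multi_no_de`
#' (no active promoter significant), or `multi_same_direction`.
#'
#' @param promoter_ids promoter ids of the gene.
#' @param ranks integer ranks (P1 = 1) aligned with `promoter_ids`.
#' @param expression per-promoter pooled expression used for proportions.
#' @param de [test_differential()] output (matched by `feature`).
#' @param min_prop activity-proportion threshold.
#' @param alpha significance threshold on `padj`.
#' @return list with `category`, `active_promoters`, and `evidence` (the
#'   opposite-direction pair including P1, or `NULL`).
#' @export
call_alt_usage <- function(promoter_ids, ranks, expression, de,
                           min_prop = 0.2, alpha = 0.05) {
  prop <- activity_proportions(expression)
  active <- promoter_ids[prop >= min_prop]
  if (length(active) < 2L)
    return(list(category = "single_predominant",
                active_promoters = active, evidence = NULL))
  i <- match(active, de$feature)
  padj <- de$padj[i]; lfc <- de$log2fc[i]
  sig <- !is.na(padj) & padj <= alpha
  if (!any(sig))
    return(list(category = "multi_no_de", active_promoters = active,
                evidence = NULL))
  p1 <- promoter_ids[ranks == 1L][1L]
  if (p1 %in% active) {
    k <- match(p1, active)
    if (sig[k]) {
      opp <- which(sig & sign(lfc) == -sign(lfc[k]) & sign(lfc[k]) != 0)
      opp <- setdiff(opp, k)
      if (length(opp))
        return(list(category = "alternative_usage",
                    active_promoters = active,
                    evidence = c(p1, active[opp[1L]])))
    }
  }
  list(category = "multi_same_direction", active_promoters = active,
       evidence = NULL)
}

#' Call alternative promoter usage across all genes
#'
#' Runs [test_differential()] on promoter counts and applies
#' [call_alt_usage()] per gene. Proportions use mean TPM pooled over all
#' samples in `group` (both strains).
#'
#' @param promoters output of [assign_and_rank()] (needs `gene_id`,
#'   `rank`, per-sample `count_`/`tpm_` columns).
#' @param group two-level factor over the promoter samples (strain of each
#'   sample).
#' @param min_prop,alpha see [call_alt_usage()].
#' @return list with `de` (per-promoter differential results) and `genes`
#'   (data.frame `gene_id`, `n_promoters`, `n_active`, `category`,
#'   `evidence`).
#' @export
call_alt_usage_all <- function(promoters, group, min_prop = 0.2,
                               alpha = 0.05) {
  s <- attr(promoters, "samples")
  df <- as.data.frame(promoters)
  if (nrow(df) == 0L) {
    return(list(de = data.frame(feature = character(),
                                base_mean = numeric(), log2fc = numeric(),
                                se = numeric(), stat = numeric(),
                                p = numeric(), padj = numeric()),
                genes = data.frame(gene_id = character(),
                                   n_promoters = integer(),
                                   n_active = integer(),
                                   category = character(),
                                   evidence = character())))
  }
  cnt <- as.matrix(df[, paste0("count_", s), drop = FALSE])
  rownames(cnt) <- df$promoter_id
  cnt <- round(cnt)
  de <- test_differential(cnt, group)
  tpm <- as.matrix(df[, paste0("tpm_", s), drop = FALSE])
  pooled <- rowMeans(tpm)
  genes <- unique(stats::na.omit(df$gene_id))
  calls <- lapply(genes, function(g) {
    idx <- which(df$gene_id == g)
    call_alt_usage(df$promoter_id[idx], df$rank[idx], pooled[idx], de,
                   min_prop, alpha)
  })
  data_out <- data.frame(
    gene_id = genes,
    n_promoters = vapply(genes, function(g) sum(df$gene_id %in% g), 1L),
    n_active = vapply(calls, function(x) length(x$active_promoters), 1L),
    category = vapply(calls, `[[`, "", "category"),
    evidence = vapply(calls, function(x)
      if (is.null(x$evidence)) NA_character_ else
        paste(x$evidence, collapse = ","), ""),
    stringsAsFactors = FALSE)
  list(de = de, genes = data_out)
}
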