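#' Pipeline configuration
#'
#' Central container for every tunable threshold of the analysis, with the
#' defaults used throughout the package: CTSS support filter (>= 1 tag in
#' >= 3 samples), 20 bp tag clustering, 1 TPM cluster filter, 100 bp
#' promoter grouping, 1 kb upstream gene regions, 200 bp CpG flank,
#' -500/+200 TATA window, 20% activity proportion, 0.05 significance
#' levels, KS absolute gate D > 0.3, ASE depth filter (>= 10 reads, all 12
#' parental replicates, >= 9 of 12 F1 replicates), and |log2fc| > 1 for
#' the strongly-differential promoter class.
#'
#' @param ... overrides of any default listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ctss_min_samples = 3L, ctss_min_count = 1L,
    tc_gap = 20L, promoter_gap = 100L, min_tpm = 1.0,
    upstream_bp = 1000L, cpg_flank = 200L, tata_window = c(-500L, 200L),
    min_prop = 0.2, de_alpha = 0.05,
    shift_d_min = 0.3, shift_alpha = 0.05,
    ase_min_reads = 10L, ase_f1_min_replicates = 9L, ase_alpha = 0.05,
    de_lfc_min_for_class = 1.0, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full promoter-usage pipeline
#'
#' Stages: CTSS support filter, tag clustering, TPM normalisation and
#' filter, promoter grouping, gene assignment/ranking/TSS classification,
#' architecture classification, differential promoter expression and
#' alternative-usage calls, KS shift calls, and (when a variant set is
#' supplied) F1 allelic-imbalance analysis with promoter-class comparison.
#' Any stage failure aborts with the failing stage named.
#'
#' @param config a [pipeline_config()].
#' @param ctss a [ctss_matrix()] over the parental samples.
#' @param samples sample sheet (`sample_id`, `strain`); strains define the
#'   two groups (alphabetically first = group A).
#' @param genes a `gene_models` data.frame.
#' @param genome named `DNAStringSet` (optional; skips architecture stage
#'   when absent).
#' @param cpg CpG island data.frame (optional, as `genome`).
#' @param variants optional `variant_set` with parental and F1 samples.
#' @param f1_samples,parental_samples_a,parental_samples_b sample names for
#'   the ASE stage; derived from `samples` when the variant set shares its
#'   ids.
#' @param outdir optional directory; when given, stage outputs are written
#'   as TSV/BED plus a JSON run manifest.
#' @return list with elements `ctss`, `clusters`, `promoters`,
#'   `annotated`, `de`, `alt_usage`, `shifts`, `ase`, `class_comparison`,
#'   and `summary`.
#' @export
run_pipeline <- function(config, ctss, samples, genes, genome = NULL,
                         cpg = NULL, variants = NULL, f1_samples = NULL,
                         parental_samples_a = NULL,
                         parental_samples_b = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    message("[cageshift] stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[cageshift]   done in %.2fs",
                    proc.time()[["elapsed"]] - t0))
    r
  }
  strains <- sort(unique(samples$strain[samples$sample_id %in%
                                          ctss_samples(ctss)]))
  if (length(strains) != 2L)
    stop("expected exactly two parental strains in the CTSS samples")
  sa <- samples$sample_id[samples$strain == strains[1L]]
  sb <- samples$sample_id[samples$strain == strains[2L]]

  fil <- stage("ctss filter", filter_ctss(ctss, config$ctss_min_samples,
                                          config$ctss_min_count))
  totals <- ctss_sample_totals(fil)
  clusters <- stage("tag clustering", {
    cl <- cluster_ctss(fil, config$tc_gap)
    if (nrow(cl) == 0L) {          # degenerate input: keep tpm columns
      for (nm in paste0("tpm_", attr(cl, "samples"))) cl[[nm]] <- numeric()
      cl
    } else {
      cl <- normalize_tpm(cl, totals)
      filter_clusters(cl, config$min_tpm, 1L)
    }
  })
  promoters <- stage("promoter grouping",
                     group_promoters(clusters, config$promoter_gap))
  annotated <- stage("gene assignment and ranking", {
    a <- assign_and_rank(promoters, genes, config$upstream_bp)
    classify_tss_distance(a, genes)
  })
  if (!is.null(genome) && !is.null(cpg)) {
    annotated <- stage("architecture classification",
      classify_arch(annotated, cpg, genome, config$cpg_flank,
                    config$tata_window))
  }
  group <- factor(ifelse(ctss_samples(ctss) %in% sa, strains[1L],
                         strains[2L]), levels = strains)
  alt <- stage("differential expression and alternative usage",
               call_alt_usage_all(annotated, group, config$min_prop,
                                  config$de_alpha))
  shifts <- stage("promoter shift detection",
                  call_shifts(fil, clusters, sa, sb, config$shift_d_min,
                              config$shift_alpha))
  ase <- NULL; cls <- NULL
  if (!is.null(variants)) {
    ase <- stage("allelic imbalance", {
      if (is.null(parental_samples_a)) parental_samples_a <- sa
      if (is.null(parental_samples_b)) parental_samples_b <- sb
      if (is.null(f1_samples))
        f1_samples <- setdiff(variants$samples,
                              c(parental_samples_a, parental_samples_b))
      keep <- variants$variants$vtype != "indel" &
        filter_variants_for_ase(variants, parental_samples_a,
                                parental_samples_b, f1_samples,
                                config$ase_min_reads,
                                config$ase_f1_min_replicates)
      v <- variants$variants[keep, , drop = FALSE]
      rt <- rowSums(variants$ref_counts[keep, f1_samples, drop = FALSE])
      at <- rowSums(variants$alt_counts[keep, f1_samples, drop = FALSE])
      tst <- ai_test(rt, at)
      v$ref_total <- rt; v$alt_total <- at
      v$ai <- tst$ai; v$p <- tst$p
      v$significant <- v$p <= config$ase_alpha
      rownames(v) <- NULL
      v
    })
    cls <- stage("promoter class comparison", {
      shift_by_tc <- shifts
      av <- classify_variant_promoters(ase, clusters, shift_by_tc, alt$de,
                                       config$de_alpha,
                                       config$de_lfc_min_for_class)
      # the DE engine tests promoters; map cluster membership to promoters
      if (nrow(av)) compare_promoter_classes(av, config$ase_alpha)
      else NULL
    })
  }
  adf <- as.data.frame(annotated)
  shift_rank <- merge(
    shifts[shifts$significant, c("tc_id", "D"), drop = FALSE],
    tc_promoter_rank(annotated), by = "tc_id", all.x = TRUE)
  summary <- list(
    n_ctss = nrow(as.data.frame(fil)),
    n_tag_clusters = nrow(as.data.frame(clusters)),
    n_promoters = nrow(adf),
    genic_promoters = sum(!is.na(adf$gene_id)),
    intergenic_promoters = sum(is.na(adf$gene_id)),
    promoters_per_gene = table(table(stats::na.omit(adf$gene_id))),
    tss_class = table(adf$tss_class),
    arch_class = if ("arch_class" %in% names(adf)) table(adf$arch_class)
      else NULL,
    alt_usage = table(factor(alt$genes$category,
      levels = c("single_predominant", "multi_no_de",
                 "multi_same_direction", "alternative_usage"))),
    n_shifts = sum(shifts$significant, na.rm = TRUE),
    shift_p1_share = if (nrow(shift_rank))
      mean(shift_rank$rank == 1L, na.rm = TRUE) else NA_real_,
    n_ase_variants = if (!is.null(ase)) nrow(ase) else NA_integer_,
    n_ase_significant = if (!is.null(ase)) sum(ase$significant)
      else NA_integer_)
  res <- list(ctss = fil, clusters = clusters, promoters = promoters,
              annotated = annotated, de = alt$de, alt_usage = alt$genes,
              shifts = shifts, ase = ase, class_comparison = cls,
              summary = summary, config = config)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

# promoter rank of each member tag cluster
tc_promoter_rank <- function(annotated) {
  adf <- as.data.frame(annotated)
  if (nrow(adf) == 0L)
    return(data.frame(tc_id = character(), rank = integer(),
                      stringsAsFactors = FALSE))
  tc <- strsplit(adf$member_tcs, ",")
  data.frame(tc_id = unlist(tc),
             rank = rep(adf$rank, lengths(tc)),
             stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    as.data.frame(x), file.path(outdir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_ctss_table(res$ctss, file.path(outdir, "ctss.filtered.tsv"))
  wt(res$clusters, "clusters.tsv")
  cl <- as.data.frame(res$clusters)
  if (nrow(cl)) {
    s <- attr(res$clusters, "samples")
    bed <- data.frame(chrom = cl$chrom, start = cl$start, end = cl$end,
                      name = cl$tc_id,
                      score = round(rowMeans(
                        cl[, paste0("tpm_", s), drop = FALSE])),
                      strand = cl$strand)
    write_bed(bed, file.path(outdir, "clusters.bed"))
  }
  wt(res$annotated, "promoters.annotated.tsv")
  wt(res$de, "de.tsv")
  wt(res$alt_usage, "alt_usage.tsv")
  wt(res$shifts, "shifts.tsv")
  if (!is.null(res$ase)) wt(res$ase, "ase.tsv")
  manifest <- list(
    package = "cageshift",
    version = as.character(utils::packageVersion("cageshift")),
    r_version = R.version.string,
    config = unclass(res$config),
    summary = lapply(res$summary, function(x)
      if (is.table(x)) as.list(x) else x))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(outdir)
}
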