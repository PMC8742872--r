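#' Configuration for the synthetic CAGE experiment generator
#'
#' Defaults emulate the design the pipeline targets: 12 parental samples
#' (2 strains x 2 sexes x 3 replicates) and 12 F1 samples (2 reciprocal
#' crosses x 2 sexes x 3 replicates); sharp promoters with geometric
#' positional decay and broad promoters with discretised-Gaussian profiles;
#' negative-binomial replicate noise; planted alternative-usage genes
#' (opposite log2 fold changes on P1/P2), planted within-promoter shifts,
#' planted F1 allelic imbalance, and a planted recombinant-inbred phenotype
#' effect. Sub-seeds are derived deterministically per entity, so the same
#' seed always yields byte-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes.
#' @param prom_probs probabilities of 1, 2, 3 promoters per gene.
#' @param sharp_frac fraction of promoters with sharp architecture.
#' @param sharp_decay geometric decay per bp of sharp profiles.
#' @param broad_sigma SD (bp) of broad Gaussian profiles.
#' @param mean_tags expected tags per promoter per sample.
#' @param dispersion NB dispersion of replicate counts.
#' @param n_alt_genes planted alternative-usage genes (two promoters,
#'   proportions 0.55/0.45, opposite strain effects).
#' @param alt_lfc planted |log2 fold change| on each of the two promoters.
#' @param n_shift planted shifting promoters (broad architecture).
#' @param shift_offset planted shift offset in bp (strain A displaced
#'   toward larger coordinates).
#' @param n_variants,n_ai,planted_ai,parental_depth,f1_depth,depth_size
#'   F1 allelic-imbalance design: variant count, number with planted
#'   imbalance, planted AI value, per-replicate depth means, and NB size of
#'   the depth distribution.
#' @param n_ri,ri_effect,ri_baseline,ri_sd recombinant-inbred design:
#'   number of strains, genotype effect in SD units, baseline, residual SD.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 60L,
                       prom_probs = c(0.5, 0.35, 0.15),
                       sharp_frac = 0.5, sharp_decay = 0.5,
                       broad_sigma = 15, mean_tags = 300,
                       dispersion = 0.05,
                       n_alt_genes = 10L, alt_lfc = 1.5,
                       n_shift = 10L, shift_offset = 40L,
                       n_variants = 60L, n_ai = 20L, planted_ai = 0.5,
                       parental_depth = 50, f1_depth = 30,
                       depth_size = 10,
                       n_ri = 30L, ri_effect = 2, ri_baseline = 100,
                       ri_sd = 10) {
  cfg <- as.list(environment())
  stopifnot(cfg$shift_offset >= 0, cfg$sharp_frac >= 0, cfg$sharp_frac <= 1,
            abs(sum(cfg$prom_probs) - 1) < 1e-9,
            abs(cfg$planted_ai) <= 1)
  structure(cfg, class = "sim_config")
}

sub_seed <- function(seed, tag, i) {
  (as.integer(seed) * 7919L + tag * 104729L + i * 31L) %% 214748329L
}

profile_weights <- function(arch, decay, sigma) {
  if (arch == "sharp") {
    d <- -6:6
    w <- decay^abs(d)
  } else {
    r <- ceiling(3 * sigma)
    d <- -r:r
    w <- stats::dnorm(d, 0, sigma)
  }
  list(offsets = d, w = w / sum(w))
}

#' Simulate a complete two-strain CAGE experiment with planted truth
#'
#' Generates a genome, gene models, CpG islands, and a 12-sample parental
#' CTSS matrix. Sharp promoters carry a planted TATAWAWR motif 31-24 bp
#' upstream of the mode TSS; broad promoters carry an overlapping CpG
#' island record. Planted alternative-usage genes get opposite-sign strain
#' effects on their two promoters; planted shift promoters have strain A's
#' profile displaced by `shift_offset` bp within the same cluster.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `genes` (`gene_models`),
#'   `cpg` (data.frame), `ctss` ([ctss_matrix()]), `samples` (sample
#'   sheet), and `truth` (list with `genes` and `promoters` tables).
#' @export
simulate_ctss_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  samples <- expand.grid(replicate = 1:3, sex = c("M", "F"),
                         strain = c("A", "B"), stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%s%d", samples$strain,
                               tolower(samples$sex), samples$replicate)
  samples <- samples[, c("sample_id", "strain", "sex", "replicate")]

  gene_spacing <- 4000L
  glen <- cfg$n_genes * gene_spacing + 2000L
  set.seed(sub_seed(cfg$seed, 1L, 0L))
  genome_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)

  set.seed(sub_seed(cfg$seed, 2L, 0L))
  n_prom <- sample(1:3, cfg$n_genes, replace = TRUE, prob = cfg$prom_probs)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  if (cfg$n_alt_genes > cfg$n_genes) stop("n_alt_genes exceeds n_genes")
  alt_genes <- seq_len(cfg$n_alt_genes)
  n_prom[alt_genes] <- 2L
  # shifts planted on the first promoter of genes not used for alt usage
  shift_genes <- cfg$n_alt_genes + seq_len(cfg$n_shift)
  if (length(shift_genes) && max(shift_genes) > cfg$n_genes)
    stop("n_alt_genes + n_shift exceeds n_genes")

  prom_rows <- list(); ctss_rows <- list()
  cpg <- data.frame(chrom = character(), start = integer(),
                    end = integer(), stringsAsFactors = FALSE)
  gene_tab <- data.frame(gene_id = sprintf("g%03d", seq_len(cfg$n_genes)),
                         chrom = "chr1", strand = strand,
                         tx_start = 0L, tx_end = 0L,
                         stringsAsFactors = FALSE)
  tss_list <- vector("list", cfg$n_genes)
  is_a <- samples$strain == "A"

  for (g in seq_len(cfg$n_genes)) {
    set.seed(sub_seed(cfg$seed, 3L, g))
    base <- (g - 1L) * gene_spacing + 1000L
    k <- n_prom[g]
    tss <- base + (seq_len(k) - 1L) * 600L
    planted <- if (g %in% alt_genes) "alt_usage"
      else if (g %in% shift_genes) "shift" else "null"
    arch <- sample(c("sharp", "broad"), k, replace = TRUE,
                   prob = c(cfg$sharp_frac, 1 - cfg$sharp_frac))
    if (planted == "shift") arch[1L] <- "broad"
    if (planted == "alt_usage") {
      rel <- c(0.55, 0.45)
    } else {
      rel <- c(1, 0.6, 0.35)[seq_len(k)] * exp(stats::rnorm(k, 0, 0.2))
      rel <- rel / sum(rel)
    }
    expr <- cfg$mean_tags * k * rel
    mult_a <- rep(1, k); mult_b <- rep(1, k)
    if (planted == "alt_usage") {
      mult_a <- 2^(c(cfg$alt_lfc, -cfg$alt_lfc) / 2)
      mult_b <- 2^(c(-cfg$alt_lfc, cfg$alt_lfc) / 2)
    }
    for (j in seq_len(k)) {
      pw <- profile_weights(arch[j], cfg$sharp_decay, cfg$broad_sigma)
      off_a <- if (planted == "shift" && j == 1L) cfg$shift_offset else 0L
      pos_b <- tss[j] + pw$offsets
      pos_a <- tss[j] + off_a + pw$offsets
      upos <- sort(unique(c(pos_a, pos_b)))
      wa <- wb <- numeric(length(upos))
      wa[match(pos_a, upos)] <- pw$w
      wb[match(pos_b, upos)] <- pw$w
      cnt <- matrix(0L, length(upos), nrow(samples))
      for (sidx in seq_len(nrow(samples))) {
        mult <- if (is_a[sidx]) mult_a[j] else mult_b[j]
        w <- if (is_a[sidx]) wa else wb
        mu <- expr[j] * mult * w
        cnt[, sidx] <- as.integer(stats::rnbinom(length(upos), mu = mu,
                                                 size = 1 / cfg$dispersion))
      }
      keep <- rowSums(cnt) > 0
      if (any(keep))
        ctss_rows[[length(ctss_rows) + 1L]] <-
          cbind(data.frame(pos = upos[keep], strand = strand[g]),
                as.data.frame(cnt[keep, , drop = FALSE]))
      # plant architecture signals in the genome / island list
      if (arch[j] == "sharp") {
        motif <- c("T", "A", "T", "A", sample(c("A", "T"), 1), "A",
                   sample(c("A", "T"), 1), sample(c("A", "G"), 1))
        if (strand[g] == "+") {
          at <- (tss[j] - 31L):(tss[j] - 24L)
          genome_chars[at] <- motif
        } else {
          at <- (tss[j] + 24L):(tss[j] + 31L)
          genome_chars[at] <- rev(chartr("ACGT", "TGCA", motif))
        }
      } else {
        cpg <- rbind(cpg, data.frame(
          chrom = "chr1", start = min(upos) - 100L,
          end = max(upos) + 100L, stringsAsFactors = FALSE))
      }
      prom_rows[[length(prom_rows) + 1L]] <- data.frame(
        gene_id = gene_tab$gene_id[g], prom_index = j, tss = tss[j],
        chrom = "chr1", strand = strand[g], architecture = arch[j],
        base_expr = expr[j], planted = planted,
        lfc_a_vs_b = log2(mult_a[j] / mult_b[j]),
        shift_offset = off_a, stringsAsFactors = FALSE)
    }
    span <- range(tss)
    if (strand[g] == "+") {
      gene_tab$tx_start[g] <- span[1L]
      gene_tab$tx_end[g] <- span[2L] + 1500L
      tss_list[[g]] <- tss[1L]
    } else {
      gene_tab$tx_start[g] <- span[1L] - 1500L
      gene_tab$tx_end[g] <- span[2L]
      tss_list[[g]] <- tss[k]
    }
  }

  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- "chr1"
  genes <- gene_tab
  genes$annotated_tss <- I(tss_list)

  ct <- do.call(rbind, ctss_rows)
  names(ct)[-(1:2)] <- samples$sample_id
  # collapse rows that landed on the same (pos, strand) from different genes
  agg <- rowsum(as.matrix(ct[, samples$sample_id]),
                paste(ct$pos, ct$strand))
  key <- do.call(rbind, strsplit(rownames(agg), " "))
  ctss <- ctss_matrix(rep("chr1", nrow(agg)), as.integer(key[, 1L]),
                      key[, 2L], agg)
  truth_prom <- do.call(rbind, prom_rows)
  truth_genes <- data.frame(
    gene_id = gene_tab$gene_id,
    planted = ifelse(seq_len(cfg$n_genes) %in% alt_genes, "alt_usage",
              ifelse(seq_len(cfg$n_genes) %in% shift_genes, "shift",
                     "null")),
    n_promoters = n_prom, stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, cpg = cpg, ctss = ctss,
       samples = samples,
       truth = list(genes = truth_genes, promoters = truth_prom))
}

#' Simulate F1 allele counts with planted allelic imbalance
#'
#' Per variant and F1 replicate, depth is NB-distributed around
#' `f1_depth` and the reference count is binomial with success probability
#' `(1 + AI) / 2`. Parental replicates are homozygous (strain B all
#' reference, strain A all alternate) at NB depths around
#' `parental_depth`. The first `n_ai` variants carry the planted AI
#' (alternating sign); the rest are null.
#'
#' @param config a [sim_config()].
#' @param positions optional data.frame `chrom`, `pos` to place the
#'   variants at (recycled/truncated to `n_variants`); by default variants
#'   sit at 1000, 2000, ... on `chr1`.
#' @return list with `variants` (a `variant_set`), `samples` (sample
#'   sheet with strains A, B, F1), and `truth` (per-variant planted AI).
#' @export
simulate_f1_ase <- function(config, positions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(sub_seed(cfg$seed, 4L, 0L))
  par <- expand.grid(replicate = 1:3, sex = c("M", "F"),
                     strain = c("A", "B"), stringsAsFactors = FALSE)
  par$sample_id <- sprintf("%s_%s%d", par$strain, tolower(par$sex),
                           par$replicate)
  f1 <- expand.grid(replicate = 1:3, sex = c("M", "F"),
                    cross = c("AxB", "BxA"), stringsAsFactors = FALSE)
  f1$sample_id <- sprintf("F1%s_%s%d", f1$cross, tolower(f1$sex),
                          f1$replicate)
  f1$strain <- "F1"
  sheet <- rbind(par[, c("sample_id", "strain", "sex", "replicate")],
                 f1[, c("sample_id", "strain", "sex", "replicate")])
  n <- cfg$n_variants
  if (is.null(positions)) {
    positions <- data.frame(chrom = "chr1", pos = 1000L * seq_len(n))
  } else {
    positions <- positions[rep_len(seq_len(nrow(positions)), n), ,
                           drop = FALSE]
  }
  ai <- rep(0, n)
  if (cfg$n_ai > 0)
    ai[seq_len(min(cfg$n_ai, n))] <-
      cfg$planted_ai * rep_len(c(1, -1), min(cfg$n_ai, n))
  nsamp <- nrow(sheet)
  refc <- altc <- matrix(0L, n, nsamp, dimnames = list(NULL, sheet$sample_id))
  for (i in seq_len(n)) {
    set.seed(sub_seed(cfg$seed, 5L, i))
    dpar <- as.integer(stats::rnbinom(12, mu = cfg$parental_depth,
                                      size = cfg$depth_size))
    refc[i, par$sample_id[par$strain == "B"]] <- dpar[1:6]
    altc[i, par$sample_id[par$strain == "A"]] <- dpar[7:12]
    dp <- as.integer(stats::rnbinom(12, mu = cfg$f1_depth,
                                    size = cfg$depth_size))
    r <- as.integer(stats::rbinom(12, dp, (1 + ai[i]) / 2))
    refc[i, f1$sample_id] <- r
    altc[i, f1$sample_id] <- dp - r
  }
  variants <- data.frame(chrom = positions$chrom, pos = positions$pos,
                         ref = "A", alt = "G", vtype = "SNV",
                         stringsAsFactors = FALSE)
  vs <- structure(list(variants = variants, ref_counts = refc,
                       alt_counts = altc, samples = sheet$sample_id),
                  class = "variant_set")
  truth <- data.frame(chrom = variants$chrom, pos = variants$pos,
                      planted_ai = ai, stringsAsFactors = FALSE)
  list(variants = vs, samples = sheet, truth = truth)
}

#' Simulate recombinant-inbred genotypes and phenotypes
#'
#' About `n_ri` strains receive genotype `AA` or `GG` with probability 1/2
#' each (redrawn until both groups have at least two strains); the
#' phenotype is `ri_baseline + ri_effect * ri_sd * [genotype == GG] +
#' N(0, ri_sd)`.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (data.frame `strain_id`, `genotype`),
#'   `phenotypes` (data.frame `strain_id`, `phenotype`), and `truth`
#'   (planted effect in phenotype units).
#' @export
simulate_ri_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(sub_seed(cfg$seed, 6L, 0L))
  repeat {
    geno <- sample(c("AA", "GG"), cfg$n_ri, replace = TRUE)
    if (min(table(factor(geno, c("AA", "GG")))) >= 2L) break
  }
  eff <- cfg$ri_effect * cfg$ri_sd
  pheno <- cfg$ri_baseline + eff * (geno == "GG") +
    stats::rnorm(cfg$n_ri, 0, cfg$ri_sd)
  ids <- sprintf("RI%02d", seq_len(cfg$n_ri))
  list(genotypes = data.frame(strain_id = ids, genotype = geno,
                              stringsAsFactors = FALSE),
       phenotypes = data.frame(strain_id = ids, phenotype = pheno,
                               stringsAsFactors = FALSE),
       truth = list(effect = eff))
}

#' Write synthetic paired-end read placements as SAM
#'
#' Emits one R1 alignment per simulated tag so that the standard
#' SAM/BAM extraction path ([extract_ctss()]) can be exercised: flags mark
#' paired, proper, first-in-pair (plus reverse for minus-strand tags),
#' mapping quality 255, CIGAR `<read_len>M`, with the 5' end of the
#' alignment at the CTSS position.
#'
#' @param ctss a [ctss_matrix()].
#' @param sample_id which sample's counts to realise.
#' @param genome named `DNAStringSet` providing `@SQ` lengths.
#' @param path output SAM path.
#' @param read_len read length in bp.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(ctss, sample_id, genome, path, read_len = 100L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (nm in names(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm,
                       length(genome[[nm]])), con)
  df <- as.data.frame(ctss)
  cnt <- df[[sample_id]]
  rid <- 0L
  for (i in which(cnt > 0)) {
    L <- length(genome[[df$chrom[i]]])
    if (df$strand[i] == "+") {
      pos <- df$pos[i]; flag <- 67L
      w <- min(read_len, L - pos + 1L)
    } else {
      pos <- max(1L, df$pos[i] - read_len + 1L); flag <- 83L
      w <- df$pos[i] - pos + 1L
    }
    for (k in seq_len(cnt[i])) {
      rid <- rid + 1L
      writeLines(sprintf("r%06d\t%d\t%s\t%d\t255\t%dM\t=\t%d\t%d\t%s\t*",
                         rid, flag, df$chrom[i], pos, w, pos, w,
                         strrep("A", w)), con)
    }
  }
  invisible(path)
}

#' Write a variant set (with genotypes inferred from strain design) as VCF
#'
#' Parental strain B samples are written `0/0`, strain A samples `1/1`,
#' and F1 samples `0/1`; every sample carries `AD` and `DP`.
#'
#' @param vs a `variant_set`.
#' @param samples sample sheet with `sample_id` and `strain`.
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(vs, samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">'), con)
  ids <- vs$samples
  strain <- samples$strain[match(ids, samples$sample_id)]
  gt <- ifelse(strain == "B", "0/0", ifelse(strain == "A", "1/1", "0/1"))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  v <- vs$variants
  for (i in seq_len(nrow(v))) {
    cells <- sprintf("%s:%d,%d:%d", gt, vs$ref_counts[i, ids],
                     vs$alt_counts[i, ids],
                     vs$ref_counts[i, ids] + vs$alt_counts[i, ids])
    writeLines(paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
                       "PASS", ".", "GT:AD:DP", cells), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Write all synthetic fixtures of a simulated experiment to a directory
#'
#' @param sim output of [simulate_ctss_experiment()].
#' @param ase optional output of [simulate_f1_ase()].
#' @param ri optional output of [simulate_ri_phenotypes()].
#' @param dir output directory (created if missing).
#' @return Named vector of written paths.
#' @export
write_sim_fixtures <- function(sim, dir, ase = NULL, ri = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "genes.gtf"),
    cpg = file.path(dir, "cpg.bed"),
    ctss = file.path(dir, "ctss.matrix.tsv"),
    samples = file.path(dir, "samples.tsv"))
  write_fasta(sim$genome, paths["genome"])
  write_gene_models_gtf(sim$genes, paths["gtf"])
  write_bed(sim$cpg, paths["cpg"])
  write_ctss_table(sim$ctss, paths["ctss"])
  utils::write.table(sim$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ase)) {
    paths["vcf"] <- file.path(dir, "f1.vcf")
    write_variants_vcf(ase$variants, ase$samples, paths["vcf"])
  }
  if (!is.null(ri)) {
    paths["ri_geno"] <- file.path(dir, "ri_geno.tsv")
    paths["ri_pheno"] <- file.path(dir, "ri_pheno.tsv")
    utils::write.table(ri$genotypes, paths["ri_geno"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ri$phenotypes, paths["ri_pheno"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  paths
}
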