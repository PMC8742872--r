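#' Read and write genome sequences (FASTA)
#'
#' Thin wrappers over Biostrings keeping the package's I/O surface in one
#' place.
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param genome a named `DNAStringSet` (or named character vector).
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Build a pseudo-genome by substituting SNV alternate alleles
#'
#' Substitutes every single-nucleotide variant's alternate allele into the
#' reference sequence, leaving insertions and deletions untouched so that the
#' coordinate system of the reference is preserved. Used to construct an
#' alternate-strain genome for allele-aware read mapping.
#'
#' @param genome named `DNAStringSet` (or named character vector) of
#'   reference sequences.
#' @param variants a `variant_set` (see [read_variants()]) or a data.frame
#'   with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @return A `DNAStringSet` of identical lengths with SNV positions replaced
#'   by the alternate base; the number of substituted SNVs and skipped indels
#'   is attached as attributes `n_snv` and `n_indel` and reported with
#'   `message()`.
#' @export
build_pseudo_genome <- function(genome, variants) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  v <- as_variant_table(variants)
  is_snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
  n_indel <- sum(!is_snv)
  v <- v[is_snv, , drop = FALSE]
  out <- genome
  for (chr in unique(v$chrom)) {
    if (!chr %in% names(out))
      stop("variant on unknown chromosome: ", chr)
    vc <- v[v$chrom == chr, , drop = FALSE]
    L <- length(out[[chr]])
    bad <- vc$pos > L | vc$pos < 1L
    if (any(bad))
      stop("SNV beyond chromosome end: ", chr, ":", vc$pos[which(bad)[1L]])
    have <- as.character(Biostrings::extractAt(
      out[[chr]], IRanges::IRanges(vc$pos, vc$pos)))
    mism <- toupper(have) != toupper(vc$ref)
    if (any(mism)) {
      i <- which(mism)[1L]
      stop("reference allele mismatch at ", chr, ":", vc$pos[i],
           " (expected ", vc$ref[i], ", found ", have[i], ")")
    }
    out[[chr]] <- Biostrings::replaceLetterAt(
      out[[chr]], vc$pos, toupper(vc$alt))
  }
  message(sprintf("pseudo-genome: substituted %d SNVs, skipped %d indels",
                  nrow(v), n_indel))
  structure(out, n_snv = nrow(v), n_indel = n_indel)
}

as_variant_table <- function(variants) {
  if (inherits(variants, "variant_set")) variants$variants else
    as.data.frame(variants)
}

#' Read gene models from GTF/GFF
#'
#' Builds one model per gene: the longest transcript (by genomic span)
#' defines the transcript span, and the strand-aware 5' end of every
#' transcript is collected as an annotated TSS. Genes without transcript (or
#' exon) features are skipped with a warning.
#'
#' @param path GTF/GFF file path.
#' @return A `gene_models` data.frame with columns `gene_id`, `chrom`,
#'   `strand`, `tx_start`, `tx_end` and a list column `annotated_tss`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  tx <- gr[type %in% c("transcript", "mRNA")]
  if (length(tx) == 0L) {
    # derive transcript spans from exons
    ex <- gr[type == "exon"]
    if (length(ex) == 0L) stop("no transcript or exon features in ", path)
    sp <- split(ex, S4Vectors::mcols(ex)$transcript_id)
    rg <- unlist(range(sp))
    S4Vectors::mcols(rg)$gene_id <- S4Vectors::mcols(ex)$gene_id[
      match(names(rg), S4Vectors::mcols(ex)$transcript_id)]
    tx <- rg
  }
  gid <- as.character(S4Vectors::mcols(tx)$gene_id)
  if (anyNA(gid)) stop("transcript feature without gene_id")
  all_genes <- unique(as.character(md$gene_id[type == "gene"]))
  orphan <- setdiff(all_genes, gid)
  if (length(orphan))
    warning("skipping ", length(orphan),
            " gene(s) with no transcript features: ",
            paste(utils::head(orphan, 5L), collapse = ", "))
  st <- GenomicRanges::start(tx); en <- GenomicRanges::end(tx)
  strand <- as.character(GenomicRanges::strand(tx))
  tss <- ifelse(strand == "+", st, en)
  chrom <- as.character(GenomicRanges::seqnames(tx))
  res <- lapply(split(seq_along(tx), gid), function(i) {
    span <- en[i] - st[i]
    j <- i[which.max(span)]
    list(chrom = chrom[j], strand = strand[j],
         tx_start = st[j], tx_end = en[j],
         annotated_tss = sort(unique(tss[i])))
  })
  data.frame(
    gene_id = names(res),
    chrom = vapply(res, `[[`, "", "chrom"),
    strand = vapply(res, `[[`, "", "strand"),
    tx_start = vapply(res, function(r) as.integer(r$tx_start), 1L),
    tx_end = vapply(res, function(r) as.integer(r$tx_end), 1L),
    annotated_tss = I(lapply(res, `[[`, "annotated_tss")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write gene models back to GTF
#'
#' Emits one `gene` line and one `transcript` line per model (span = longest
#' transcript), plus one transcript per additional annotated TSS so that
#' [read_gene_models()] regenerates an equivalent model set.
#'
#' @param genes a `gene_models` data.frame.
#' @param path output path.
#' @export
write_gene_models_gtf <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tss <- genes$annotated_tss[[i]]
    attr_g <- sprintf('gene_id "%s";', g$gene_id)
    writeLines(sprintf("%s\tcageshift\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$chrom, g$tx_start, g$tx_end, g$strand, attr_g), con)
    k <- 0L
    for (t in tss) {
      k <- k + 1L
      if (g$strand == "+") {
        ts <- t; te <- max(g$tx_end, t)
      } else {
        ts <- min(g$tx_start, t); te <- t
      }
      a <- sprintf('gene_id "%s"; transcript_id "%s.t%d";', g$gene_id,
                   g$gene_id, k)
      writeLines(sprintf("%s\tcageshift\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                         g$chrom, ts, te, g$strand, a), con)
      writeLines(sprintf("%s\tcageshift\texon\t%d\t%d\t.\t%s\t.\t%s",
                         g$chrom, ts, te, g$strand, a), con)
    }
  }
  invisible(path)
}

#' Strand-aware gene region (transcript span plus upstream flank)
#'
#' @param genes `gene_models` data.frame.
#' @param upstream bp added upstream of the transcript 5' end (strand-aware).
#' @return data.frame with `region_start`, `region_end` columns appended.
#' @export
gene_regions <- function(genes, upstream = 1000L) {
  plus <- genes$strand == "+"
  genes$region_start <- ifelse(plus, pmax(1L, genes$tx_start - upstream),
                               genes$tx_start)
  genes$region_end <- ifelse(plus, genes$tx_end, genes$tx_end + upstream)
  genes
}

#' Read variants with per-sample allele depths from VCF
#'
#' Multi-allelic records are split into biallelic records (the allelic
#' imbalance test is inherently biallelic); each alternate allele keeps its
#' own AD column. Records are typed `SNV` when both alleles have length 1,
#' otherwise `indel`.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @return A `variant_set`: list with `variants` (data.frame `chrom`, `pos`,
#'   `ref`, `alt`, `vtype`), `ref_counts` and `alt_counts` (variant x sample
#'   integer matrices) and `samples`.
#' @export
read_variants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)  # split multi-allelic records
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (any(GenomicRanges::start(rr) < 1L)) stop("malformed coordinates: pos < 1")
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF lacks the AD (allele depth) FORMAT field")
  samples <- colnames(vcf)
  n <- length(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  refc <- matrix(NA_integer_, n, length(samples),
                 dimnames = list(NULL, samples))
  altc <- refc
  if (is.array(ad) && length(dim(ad)) == 3L) {
    # expand() reshapes Number=R AD into variant x sample x (ref, alt)
    refc[, ] <- ad[, samples, 1L]
    altc[, ] <- ad[, samples, 2L]
  } else {
    for (j in seq_along(samples)) {
      cell <- ad[, j]
      lens <- lengths(cell)
      if (any(lens < 2L)) {
        i <- which(lens < 2L)[1L]
        stop("missing allele-depth field for sample ", samples[j],
             " at record ", i)
      }
      refc[, j] <- vapply(cell, `[`, 0L, 1L)
      altc[, j] <- vapply(cell, `[`, 0L, 2L)
    }
  }
  if (any(is.na(refc)))
    stop("missing allele-depth field for sample ",
         samples[which(colSums(is.na(refc)) > 0)[1L]])
  if (any(is.na(refc)) || any(is.na(altc)) || any(refc < 0L) || any(altc < 0L))
    stop("allele depths must be non-negative integers")
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr), ref = ref, alt = alt,
    vtype = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "indel"),
    stringsAsFactors = FALSE)
  structure(list(variants = variants, ref_counts = refc, alt_counts = altc,
                 samples = samples),
            class = "variant_set")
}

#' Read genomic intervals from BED (e.g., CpG islands)
#'
#' BED input is 0-based half-open; the returned intervals are 1-based
#' inclusive, matching the package's internal convention.
#'
#' @param path BED path.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and `name` if present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write intervals as BED (1-based inclusive in, 0-based half-open out)
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  bed <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end,
                    name = if ("name" %in% names(x)) x$name else ".",
                    score = if ("score" %in% names(x)) x$score else 0L,
                    strand = if ("strand" %in% names(x)) x$strand else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `strain`, `sex`, `replicate` (and optionally
#' `group`). Sample ids must be unique.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id in sample sheet")
  x
}
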