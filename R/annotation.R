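#' Assign promoters to genes and rank them by expression
#'
#' A promoter is assigned to a gene when its span intersects the
#' strand-aware gene region (the longest-transcript span extended
#' `upstream` bp beyond the transcript 5' end) and the strands match.
#' Within each gene, promoters are ranked P1, P2, ... by descending mean
#' TPM over `rank_samples` (default: all samples), ties broken toward the
#' leftmost genomic start. Promoters assigned to no gene are marked
#' intergenic and carry rank 1 (independent promoters). A promoter
#' overlapping several gene regions goes to the gene whose region start is
#' nearest to the promoter start; such cases are reported with `message()`.
#'
#' @param promoters a `promoter_regions` data.frame (see
#'   [group_promoters()]).
#' @param genes a `gene_models` data.frame (see [read_gene_models()]).
#' @param upstream bp added upstream of the transcript 5' end.
#' @param rank_samples samples whose mean TPM defines the ranking
#'   (typically the parental samples).
#' @return `promoters` with columns `gene_id` (`NA` for intergenic),
#'   `rank`, and `mean_tpm` appended.
#' @export
assign_and_rank <- function(promoters, genes, upstream = 1000L,
                            rank_samples = NULL) {
  s <- attr(promoters, "samples")
  if (is.null(rank_samples)) rank_samples <- s
  df <- as.data.frame(promoters)
  gr <- gene_regions(genes, upstream)
  df$gene_id <- rep(NA_character_, nrow(df))
  n_multi <- 0L
  if (nrow(df) && nrow(gr)) {
    pg <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end),
                                 strand = df$strand)
    gg <- GenomicRanges::GRanges(gr$chrom,
                                 IRanges::IRanges(gr$region_start,
                                                  gr$region_end),
                                 strand = gr$strand)
    hits <- GenomicRanges::findOverlaps(pg, gg)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (i in unique(qh)) {
      cand <- sh[qh == i]
      if (length(cand) > 1L) {
        n_multi <- n_multi + 1L
        cand <- cand[order(abs(gr$region_start[cand] - df$start[i]))]
      }
      df$gene_id[i] <- gr$gene_id[cand[1L]]
    }
  }
  if (n_multi > 0L)
    message(n_multi, " promoter(s) overlapped multiple gene regions; ",
            "assigned to the gene with the nearest region start")
  tpm <- as.matrix(df[, paste0("tpm_", rank_samples), drop = FALSE])
  df$mean_tpm <- rowMeans(tpm)
  df$rank <- rep(1L, nrow(df))
  for (g in unique(stats::na.omit(df$gene_id))) {
    idx <- which(df$gene_id == g)
    ord <- order(-df$mean_tpm[idx], df$start[idx])
    df$rank[idx[ord]] <- seq_along(idx)
  }
  structure(df, samples = s, class = class(promoters))
}

#' Classify promoter distance to annotated TSSs
#'
#' Per promoter, the distance is the minimum over the assigned gene's
#' annotated TSSs of the bp distance to the nearest edge of the promoter
#' span (0 when a TSS falls inside the span). With the default bins the
#' classes are `exact` (0), `within_100` (1-100), `within_1000` (101-1000),
#' `unannotated` (farther), and `intergenic` for unassigned promoters.
#'
#' @param promoters output of [assign_and_rank()].
#' @param genes the `gene_models` used for assignment.
#' @param bins increasing distance cut points; `bins[1]` must be 0.
#' @return `promoters` with `tss_distance` and `tss_class` appended.
#' @export
classify_tss_distance <- function(promoters, genes, bins = c(0L, 100L, 1000L)) {
  stopifnot(bins[1] == 0, !is.unsorted(bins))
  df <- as.data.frame(promoters)
  df$tss_distance <- rep(NA_integer_, nrow(df))
  df$tss_class <- rep("intergenic", nrow(df))
  tssmap <- stats::setNames(genes$annotated_tss, genes$gene_id)
  labs <- c("exact", paste0("within_", bins[-1]), "unannotated")
  for (i in which(!is.na(df$gene_id))) {
    tss <- tssmap[[df$gene_id[i]]]
    d <- min(pmax(0L, pmax(df$start[i] - tss, tss - df$end[i])))
    df$tss_distance[i] <- d
    df$tss_class[i] <- labs[findInterval(d, c(bins, Inf),
                                         left.open = TRUE) + 1L]
  }
  structure(df, samples = attr(promoters, "samples"),
            class = class(promoters))
}

#' Classify promoter proximity to an external TSS set
#'
#' Same binning logic as [classify_tss_distance()] but against an arbitrary
#' set of positions (de novo transcript TSSs, external CAGE peaks), with
#' configurable cut points (default 0/100/500).
#'
#' @param promoters a `promoter_regions` data.frame.
#' @param external_tss data.frame with columns `chrom`, `pos`.
#' @param bins increasing cut points starting at 0.
#' @return Character vector of classes per promoter (`overlap`,
#'   `within_<b>` per bin, `outside`).
#' @export
classify_proximity <- function(promoters, external_tss,
                               bins = c(0L, 100L, 500L)) {
  stopifnot(bins[1] == 0, !is.unsorted(bins))
  df <- as.data.frame(promoters)
  labs <- c("overlap", paste0("within_", bins[-1]), "outside")
  vapply(seq_len(nrow(df)), function(i) {
    tss <- external_tss$pos[external_tss$chrom == df$chrom[i]]
    if (!length(tss)) return("outside")
    d <- min(pmax(0L, pmax(df$start[i] - tss, tss - df$end[i])))
    labs[findInterval(d, c(bins, Inf), left.open = TRUE) + 1L]
  }, "")
}

#' Classify promoter architecture (CpG island / TATA box)
#'
#' A promoter is CpG-positive when its span extended by `cpg_flank` bp on
#' both sides intersects a CpG island, and TATA-positive when the
#' strand-oriented window `tata_window` around its dominant CTSS contains a
#' match to the TATA consensus (IUPAC `TATAWAWR` by default) on the promoter
#' strand. Windows truncated at a chromosome edge are scanned as truncated.
#'
#' @param promoters a `promoter_regions` data.frame with `dominant_pos`.
#' @param cpg_islands data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive; see [read_bed()]).
#' @param genome named `DNAStringSet` covering the promoter windows.
#' @param cpg_flank bp added to each side of the span before the CpG
#'   overlap.
#' @param tata_window `c(upstream, downstream)` of the scan window relative
#'   to the dominant CTSS in transcript orientation (negative = upstream).
#' @param tata_pattern IUPAC consensus scanned on the promoter strand; the
#'   matcher is pluggable (any pattern accepted by
#'   [Biostrings::matchPattern()] with `fixed = FALSE`).
#' @return `promoters` with logicals `cpg`, `tata` and `arch_class`
#'   (`CpG_only`, `TATA_only`, `both`, `neither`) appended.
#' @export
classify_arch <- function(promoters, cpg_islands, genome,
                          cpg_flank = 200L, tata_window = c(-500L, 200L),
                          tata_pattern = "TATAWAWR") {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  df <- as.data.frame(promoters)
  n <- nrow(df)
  df$cpg <- rep(FALSE, n); df$tata <- rep(FALSE, n)
  if (n) {
    pg <- GenomicRanges::GRanges(df$chrom,
      IRanges::IRanges(pmax(1L, df$start - cpg_flank), df$end + cpg_flank))
    if (nrow(cpg_islands)) {
      ig <- GenomicRanges::GRanges(cpg_islands$chrom,
        IRanges::IRanges(cpg_islands$start, cpg_islands$end))
      df$cpg <- GenomicRanges::countOverlaps(pg, ig) > 0L
    }
    n_trunc <- 0L
    for (i in seq_len(n)) {
      chr <- df$chrom[i]
      if (!chr %in% names(genome)) next
      L <- length(genome[[chr]])
      dom <- df$dominant_pos[i]
      if (df$strand[i] == "+") {
        w <- c(dom + tata_window[1L], dom + tata_window[2L])
      } else {
        w <- c(dom - tata_window[2L], dom - tata_window[1L])
      }
      if (w[1L] < 1L || w[2L] > L) n_trunc <- n_trunc + 1L
      w <- c(max(1L, w[1L]), min(L, w[2L]))
      seqw <- Biostrings::subseq(genome[[chr]], w[1L], w[2L])
      if (df$strand[i] == "-") seqw <- Biostrings::reverseComplement(seqw)
      df$tata[i] <- length(Biostrings::matchPattern(
        tata_pattern, seqw, fixed = FALSE)) > 0L
    }
    if (n_trunc > 0L)
      message(n_trunc, " TATA scan window(s) truncated at chromosome edges")
  }
  df$arch_class <- ifelse(df$cpg & df$tata, "both",
                   ifelse(df$cpg, "CpG_only",
                   ifelse(df$tata, "TATA_only", "neither")))
  structure(df, samples = attr(promoters, "samples"),
            class = class(promoters))
}

#' Strand-aware distance and orientation between two genomic positions
#'
#' Distance is `|a - b|`; orientation says where `a` lies relative to `b` in
#' transcript orientation: on the plus strand smaller coordinates are
#' upstream, on the minus strand larger coordinates are upstream.
#'
#' @param position_a,position_b 1-based positions on the same chromosome.
#' @param strand `"+"` or `"-"`.
#' @return list with `distance` (non-negative integer bp) and `orientation`
#'   (`"upstream"`, `"downstream"`, or `"same"`).
#' @examples
#' feature_distance(1816432, 1816086, "-")  # 346 bp upstream
#' @export
feature_distance <- function(position_a, position_b, strand) {
  stopifnot(strand %in% c("+", "-"))
  d <- abs(position_a - position_b)
  orient <- if (d == 0) "same"
    else if (xor(position_a < position_b, strand == "-")) "upstream"
    else "downstream"
  list(distance = as.integer(d), orientation = orient)
}
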