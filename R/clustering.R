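#' Single-linkage tag clustering of CTSS positions
#'
#' CTSSs on the same chromosome and strand are merged into one tag cluster
#' whenever a chain of CTSSs with successive distances `<= gap` connects
#' them (the `distclu`-style convention; default 20 bp). Every retained CTSS
#' belongs to exactly one cluster.
#'
#' @param x a filtered [ctss_matrix()].
#' @param gap maximum inter-CTSS distance (bp, inclusive) for merging.
#' @return A `tag_clusters` data.frame: `tc_id`, `chrom`, `strand`, `start`,
#'   `end`, `n_ctss`, `dominant_pos`, then one `count_<sample>` column per
#'   sample. The sample names are carried in `attr(x, "samples")`. Member
#'   CTSSs of a cluster are exactly the matrix rows within its span on its
#'   chromosome and strand (spans of clusters never overlap).
#' @export
cluster_ctss <- function(x, gap = 20L) {
  stopifnot(gap >= 0L)
  s <- ctss_samples(x)
  df <- as.data.frame(x)
  if (nrow(df) == 0L) return(empty_clusters(s))
  df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
  newgrp <- c(TRUE, df$chrom[-1L] != df$chrom[-nrow(df)] |
                df$strand[-1L] != df$strand[-nrow(df)] |
                df$pos[-1L] - df$pos[-nrow(df)] > gap)
  cid <- cumsum(newgrp)
  cnt <- as.matrix(df[, s, drop = FALSE])
  agg <- rowsum(cnt, cid, reorder = TRUE)
  tot <- rowSums(cnt)
  first <- which(newgrp)
  last <- c(first[-1L] - 1L, nrow(df))
  dom <- vapply(seq_along(first), function(i) {
    idx <- first[i]:last[i]
    # max aggregate count, ties to the smaller coordinate
    idx[which.max(tot[idx])]
  }, 1L)
  out <- data.frame(
    tc_id = paste0("tc", seq_along(first)),
    chrom = df$chrom[first], strand = df$strand[first],
    start = df$pos[first], end = df$pos[last],
    n_ctss = last - first + 1L, dominant_pos = df$pos[dom],
    stringsAsFactors = FALSE)
  colnames(agg) <- paste0("count_", s)
  out <- cbind(out, as.data.frame(agg, row.names = NULL))
  structure(out, samples = s, class = c("tag_clusters", "data.frame"))
}

empty_clusters <- function(samples) {
  out <- data.frame(tc_id = character(), chrom = character(),
                    strand = character(), start = integer(), end = integer(),
                    n_ctss = integer(), dominant_pos = integer(),
                    stringsAsFactors = FALSE)
  for (s in samples) out[[paste0("count_", s)]] <- numeric()
  structure(out, samples = samples,
            class = c("tag_clusters", "data.frame"))
}

#' Dominant CTSS of a genomic window
#'
#' The member position with maximal aggregate (all-sample) count; ties are
#' broken toward the smaller coordinate.
#'
#' @param x a [ctss_matrix()].
#' @param chrom,strand,start,end the window (1-based inclusive).
#' @return The dominant position (integer), or `NA` if the window holds no
#'   CTSS.
#' @export
dominant_ctss <- function(x, chrom, strand, start, end) {
  df <- as.data.frame(x)
  sel <- df$chrom == chrom & df$strand == strand &
    df$pos >= start & df$pos <= end
  if (!any(sel)) return(NA_integer_)
  df <- df[sel, , drop = FALSE]
  df <- df[order(df$pos), , drop = FALSE]
  tot <- rowSums(as.matrix(df[, ctss_samples(x), drop = FALSE]))
  df$pos[which.max(tot)]
}

#' Normalise tag-cluster counts to tags per million (TPM)
#'
#' `tpm = count / sample_total * 1e6`. The denominator is the per-sample
#' total of retained CTSS counts (see [ctss_sample_totals()]), keeping the
#' pipeline reproducible from the CTSS matrix alone.
#'
#' @param clusters a `tag_clusters` data.frame.
#' @param sample_totals named numeric vector of per-sample totals; all must
#'   be positive.
#' @return `clusters` with one `tpm_<sample>` column appended per sample.
#' @export
normalize_tpm <- function(clusters, sample_totals) {
  s <- attr(clusters, "samples")
  if (any(sample_totals[s] <= 0) || anyNA(sample_totals[s]))
    stop("zero or missing total for sample(s): ",
         paste(s[is.na(sample_totals[s]) | sample_totals[s] <= 0],
               collapse = ", "))
  cnt <- as.matrix(as.data.frame(clusters)[, paste0("count_", s),
                                           drop = FALSE])
  tpm <- sweep(cnt, 2, sample_totals[s], "/") * 1e6
  colnames(tpm) <- paste0("tpm_", s)
  out <- cbind(as.data.frame(clusters), as.data.frame(tpm, row.names = NULL))
  structure(out, samples = s, class = class(clusters))
}

#' Expression filter on tag clusters
#'
#' Keeps clusters reaching `min_tpm` in at least `min_samples` samples
#' (default: 1 TPM in at least one sample, boundary inclusive).
#'
#' @param clusters a `tag_clusters` data.frame with TPM columns.
#' @param min_tpm TPM threshold (inclusive).
#' @param min_samples number of samples required to reach it.
#' @return The filtered `tag_clusters`.
#' @export
filter_clusters <- function(clusters, min_tpm = 1, min_samples = 1L) {
  s <- attr(clusters, "samples")
  tpm <- as.matrix(as.data.frame(clusters)[, paste0("tpm_", s), drop = FALSE])
  keep <- rowSums(tpm >= min_tpm) >= min_samples
  out <- as.data.frame(clusters)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, samples = s, class = class(clusters))
}

#' Group tag clusters into promoter regions
#'
#' Single-linkage over the edge-to-edge distance between clusters on the
#' same chromosome and strand: clusters whose gap (start of the right
#' cluster minus end of the left) is `<= gap` join one promoter region
#' (default 100 bp). Promoter expression is the per-sample sum of member
#' TPMs.
#'
#' @param clusters a filtered `tag_clusters` data.frame with TPM columns.
#' @param gap maximum edge-to-edge distance (bp, inclusive).
#' @return A `promoter_regions` data.frame: `promoter_id`, `chrom`,
#'   `strand`, `start`, `end`, `n_tc`, `member_tcs` (comma-separated tc ids),
#'   `dominant_pos` (of the member cluster with the highest aggregate
#'   count), per-sample `count_<s>` and `tpm_<s>` sums.
#' @export
group_promoters <- function(clusters, gap = 100L) {
  s <- attr(clusters, "samples")
  df <- as.data.frame(clusters)
  if (nrow(df) == 0L) {
    out <- data.frame(promoter_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_tc = integer(),
                      member_tcs = character(), dominant_pos = integer())
    for (nm in c(paste0("count_", s), paste0("tpm_", s))) out[[nm]] <- numeric()
    return(structure(out, samples = s,
                     class = c("promoter_regions", "data.frame")))
  }
  df <- df[order(df$chrom, df$strand, df$start), , drop = FALSE]
  runmax <- df$end
  newgrp <- logical(nrow(df)); newgrp[1L] <- TRUE
  for (i in seq_len(nrow(df))[-1L]) {
    same <- df$chrom[i] == df$chrom[i - 1L] &&
      df$strand[i] == df$strand[i - 1L]
    newgrp[i] <- !(same && df$start[i] - runmax[i - 1L] <= gap)
    runmax[i] <- if (newgrp[i]) df$end[i] else max(runmax[i - 1L], df$end[i])
  }
  pid <- cumsum(newgrp)
  cnt <- as.matrix(df[, paste0("count_", s), drop = FALSE])
  tpm <- as.matrix(df[, paste0("tpm_", s), drop = FALSE])
  cagg <- rowsum(cnt, pid); tagg <- rowsum(tpm, pid)
  tot <- rowSums(cnt)
  first <- which(newgrp); last <- c(first[-1L] - 1L, nrow(df))
  dom <- vapply(seq_along(first), function(i) {
    idx <- first[i]:last[i]
    df$dominant_pos[idx[which.max(tot[idx])]]
  }, 1L)
  out <- data.frame(
    promoter_id = paste0("pr", seq_along(first)),
    chrom = df$chrom[first], strand = df$strand[first],
    start = df$start[first],
    end = vapply(seq_along(first), function(i) max(df$end[first[i]:last[i]]), 1L),
    n_tc = last - first + 1L,
    member_tcs = vapply(seq_along(first), function(i)
      paste(df$tc_id[first[i]:last[i]], collapse = ","), ""),
    dominant_pos = dom, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cagg, row.names = NULL),
               as.data.frame(tagg, row.names = NULL))
  structure(out, samples = s, class = c("promoter_regions", "data.frame"))
}
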