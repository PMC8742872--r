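#' CTSS count matrix
#'
#' The central data container of the pipeline: one row per CAGE-defined
#' transcription start site (CTSS), keyed by `(chrom, pos, strand)` with
#' 1-based positions, and one integer count column per sample. Rows are kept
#' sorted by `(chrom, pos, strand)` and keys are unique.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based genomic positions.
#' @param strand character vector, `"+"` or `"-"`.
#' @param counts matrix or data.frame of non-negative counts, one column per
#'   sample; column names are the sample identifiers.
#' @return A `ctss_matrix`: a data.frame with columns `chrom`, `pos`,
#'   `strand` followed by one count column per sample, carrying the sample
#'   names in `attr(x, "samples")`.
#' @examples
#' m <- ctss_matrix("chr1", 100L, "+", cbind(s1 = 5L, s2 = 0L))
#' ctss_samples(m)
#' @export
ctss_matrix <- function(chrom, pos, strand, counts) {
  counts <- as.data.frame(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("count columns must be named by sample")
  x <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  strand = as.character(strand), check.names = FALSE,
                  stringsAsFactors = FALSE)
  x <- cbind(x, counts)
  validate_ctss(x, samples = names(counts))
  x <- x[order(x$chrom, x$pos, x$strand), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, samples = names(counts),
            class = c("ctss_matrix", "data.frame"))
}

validate_ctss <- function(x, samples) {
  if (any(x$pos < 1L)) stop("malformed coordinates: pos < 1")
  if (!all(x$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  key <- paste(x$chrom, x$pos, x$strand)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, strand) rows")
  cnt <- as.matrix(x[, samples, drop = FALSE])
  if (any(is.na(cnt)) || any(cnt < 0)) stop("counts must be non-negative")
  invisible(x)
}

#' @rdname ctss_matrix
#' @param x a `ctss_matrix`.
#' @export
ctss_samples <- function(x) attr(x, "samples")

#' Per-sample totals of retained CTSS counts
#'
#' Column sums over the current rows; after [filter_ctss()] these are the
#' library sizes used as the tags-per-million denominator.
#'
#' @param x a `ctss_matrix`.
#' @return Named numeric vector of per-sample totals.
#' @export
ctss_sample_totals <- function(x) {
  s <- ctss_samples(x)
  colSums(as.matrix(as.data.frame(x)[, s, drop = FALSE]))
}

#' Read and write CTSS count tables
#'
#' Plain TSV with header `chrom  pos  strand  <sample> ...`; positions are
#' 1-based. `write_ctss_table()` then `read_ctss_table()` is the identity on
#' content.
#'
#' @param path file path.
#' @return `read_ctss_table()` returns a [ctss_matrix()].
#' @export
read_ctss_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = NA, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand")
  if (!all(need %in% names(x)[1:3]))
    stop("CTSS table must start with columns chrom, pos, strand")
  samples <- setdiff(names(x), need)
  if (nrow(x) == 0L) {
    cnt <- matrix(integer(), 0, length(samples), dimnames = list(NULL, samples))
    return(ctss_matrix(character(), integer(), character(), cnt))
  }
  ctss_matrix(x$chrom, x$pos, x$strand, x[, samples, drop = FALSE])
}

#' @rdname read_ctss_table
#' @param x a `ctss_matrix`.
#' @export
write_ctss_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Merge single-sample CTSS matrices into one multi-sample matrix
#'
#' @param matrices list of single- or multi-sample `ctss_matrix` objects with
#'   disjoint sample names.
#' @return A `ctss_matrix` over the union of positions (absent positions get
#'   zero counts).
#' @export
merge_ctss <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  samples <- unlist(lapply(matrices, ctss_samples))
  if (anyDuplicated(samples)) stop("duplicate sample names across matrices")
  keys <- unique(do.call(rbind, lapply(matrices, function(m)
    as.data.frame(m)[, c("chrom", "pos", "strand")])))
  keys <- keys[order(keys$chrom, keys$pos, keys$strand), , drop = FALSE]
  id <- paste(keys$chrom, keys$pos, keys$strand)
  cnt <- matrix(0L, nrow(keys), length(samples),
                dimnames = list(NULL, samples))
  for (m in matrices) {
    mid <- paste(m$chrom, m$pos, m$strand)
    cnt[match(mid, id), ctss_samples(m)] <-
      as.matrix(as.data.frame(m)[, ctss_samples(m), drop = FALSE])
  }
  ctss_matrix(keys$chrom, keys$pos, keys$strand, cnt)
}
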