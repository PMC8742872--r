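#' Extract CAGE-defined TSS counts from an alignment file
#'
#' Each retained alignment contributes one count at the 5' end of the
#' cap-proximal read: the leftmost aligned base for plus-strand reads, the
#' rightmost aligned base for minus-strand reads. Retained alignments are
#' first-in-pair (unless `single_end`), primary, non-supplementary,
#' non-duplicate, and mapped with mapping quality exactly `mapq_unique`
#' (255 is the unique-mapper code of STAR-style aligners).
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param sample_id name for the single count column.
#' @param mapq_unique mapping quality that marks a uniquely mapped read.
#' @param single_end set `TRUE` for unpaired data; otherwise reads without
#'   first-in-pair flags are an error.
#' @param softclip_aware if `TRUE`, the 5' end is shifted outward by the
#'   length of the 5' soft clip, approximating removal of the
#'   reverse-transcriptase extra G performed upstream of mapping in the CAGE
#'   protocol. Off by default.
#' @return A single-sample [ctss_matrix()].
#' @export
extract_ctss <- function(path, sample_id, mapq_unique = 255L,
                         single_end = FALSE, softclip_aware = FALSE) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("flag", "mapq"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  fl <- S4Vectors::mcols(ga)$flag
  paired <- bitwAnd(fl, 1L) > 0L
  if (!single_end) {
    if (!all(paired))
      stop("unpaired alignments present; set single_end = TRUE for ",
           "single-end data")
    ga <- ga[bitwAnd(fl, 64L) > 0L]  # first in pair (R1)
  }
  mq <- S4Vectors::mcols(ga)$mapq
  ga <- ga[!is.na(mq) & mq == mapq_unique]
  if (length(ga) == 0L) {
    cnt <- matrix(integer(), 0, 1, dimnames = list(NULL, sample_id))
    return(ctss_matrix(character(), integer(), character(), cnt))
  }
  strand <- as.character(GenomicAlignments::strand(ga))
  p5 <- ifelse(strand == "+", GenomicAlignments::start(ga),
               GenomicAlignments::end(ga))
  if (softclip_aware) {
    cig <- GenomicAlignments::cigar(ga)
    lead <- trail <- integer(length(cig))
    has_lead <- grepl("^[0-9]+S", cig)
    lead[has_lead] <- as.integer(sub("^([0-9]+)S.*", "\\1",
                                     cig[has_lead]))
    has_trail <- grepl("[0-9]+S$", cig)
    trail[has_trail] <- as.integer(sub(".*[MIDNSHP=X]([0-9]+)S$", "\\1",
                                       cig[has_trail]))
    p5 <- ifelse(strand == "+", pmax(1L, p5 - lead), p5 + trail)
  }
  key <- data.frame(chrom = as.character(GenomicAlignments::seqnames(ga)),
                    pos = p5, strand = strand, stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n = rep(1L, nrow(key))), key, sum)
  cnt <- matrix(as.integer(agg$n), ncol = 1, dimnames = list(NULL, sample_id))
  ctss_matrix(agg$chrom, agg$pos, agg$strand, cnt)
}

#' Cross-sample support filter for CTSS positions
#'
#' Retains positions where at least `min_samples` samples have a count of at
#' least `min_count` (defaults: at least three samples with at least one
#' tag). Idempotent.
#'
#' @param x a [ctss_matrix()].
#' @param min_samples minimum number of supporting samples.
#' @param min_count minimum count per supporting sample.
#' @return The filtered `ctss_matrix`.
#' @export
filter_ctss <- function(x, min_samples = 3L, min_count = 1L) {
  s <- ctss_samples(x)
  if (min_samples > length(s))
    stop("min_samples (", min_samples, ") exceeds number of samples (",
         length(s), ")")
  cnt <- as.matrix(as.data.frame(x)[, s, drop = FALSE])
  keep <- rowSums(cnt >= min_count) >= min_samples
  out <- as.data.frame(x)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, samples = s, class = c("ctss_matrix", "data.frame"))
}
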