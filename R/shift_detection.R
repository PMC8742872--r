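#' Aggregate per-strain CTSS profiles for one tag cluster
#'
#' Sums CTSS counts per position over each strain's replicates, restricted
#' to the cluster span. A cluster with zero tags in either strain is flagged
#' untestable.
#'
#' @param x a [ctss_matrix()].
#' @param chrom,strand,start,end the cluster span.
#' @param samples_a,samples_b disjoint, nonempty sample-name vectors.
#' @return A `strain_profile`: list with `positions` (sorted), `counts_a`,
#'   `counts_b`, `n_a`, `n_b`, and `testable`.
#' @export
aggregate_profiles <- function(x, chrom, strand, start, end,
                               samples_a, samples_b) {
  if (!length(samples_a) || !length(samples_b))
    stop("both sample groups must be nonempty")
  if (length(intersect(samples_a, samples_b)))
    stop("sample groups must be disjoint")
  df <- as.data.frame(x)
  sel <- df$chrom == chrom & df$strand == strand &
    df$pos >= start & df$pos <= end
  df <- df[sel, , drop = FALSE]
  df <- df[order(df$pos), , drop = FALSE]
  ca <- rowSums(as.matrix(df[, samples_a, drop = FALSE]))
  cb <- rowSums(as.matrix(df[, samples_b, drop = FALSE]))
  structure(list(positions = df$pos, counts_a = ca, counts_b = cb,
                 n_a = sum(ca), n_b = sum(cb),
                 testable = sum(ca) > 0 && sum(cb) > 0),
            class = "strain_profile")
}

#' Count-weighted two-sample Kolmogorov-Smirnov shift statistic
#'
#' Empirical CDFs are computed directly from the per-position count vectors
#' over the union of member positions in coordinate order; `D` is the
#' maximal absolute CDF difference and `shift_pos` the smallest position
#' attaining it. The raw direction compares count-weighted mean positions
#' (`a_left` when strain A's mass sits at smaller coordinates); strand
#' adjustment to transcript orientation happens in [call_shifts()].
#'
#' @param profile a `strain_profile` with positive totals in both strains.
#' @return list with `D`, `shift_pos`, and `direction_raw` (`a_left`,
#'   `a_right`, or `none`).
#' @export
ks_shift_statistic <- function(profile) {
  if (profile$n_a <= 0 || profile$n_b <= 0)
    stop("both strains need positive tag totals")
  fa <- cumsum(profile$counts_a) / profile$n_a
  fb <- cumsum(profile$counts_b) / profile$n_b
  gap <- abs(fa - fb)
  D <- max(gap)
  shift_pos <- profile$positions[which.max(gap)]  # smallest pos at max
  ma <- sum(profile$positions * profile$counts_a) / profile$n_a
  mb <- sum(profile$positions * profile$counts_b) / profile$n_b
  dir <- if (ma < mb) "a_left" else if (ma > mb) "a_right" else "none"
  list(D = D, shift_pos = shift_pos, direction_raw = dir)
}

#' Large-sample two-sample Kolmogorov-Smirnov critical value
#'
#' `c(alpha) * sqrt((n_a + n_b) / (n_a * n_b))` with
#' `c(alpha) = sqrt(-log(alpha / 2) / 2)` (~1.3581 at alpha = 0.05).
#' Effective sizes are the aggregated tag totals per strain; tags are not
#' independent observations, so the gate is anticonservative in principle
#' and is paired with the absolute `D > d_min` gate in [call_shifts()].
#'
#' @param n_a,n_b per-strain tag totals (>= 1).
#' @param alpha significance level in (0, 1).
#' @return The critical value.
#' @export
ks_critical_value <- function(n_a, n_b, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stopifnot(n_a >= 1, n_b >= 1)
  sqrt(-log(alpha / 2) / 2) * sqrt((n_a + n_b) / (n_a * n_b))
}

#' Call within-promoter TSS shifts between two strains
#'
#' One call per testable tag cluster; a shift is significant when
#' `D > d_min` (absolute gate, default 0.3) and `D` exceeds the
#' large-sample critical value at `alpha`. Direction is reported in
#' transcript orientation (`upstream_in_A` means strain A's profile is
#' 5'-shifted). `shift_distance` is the absolute distance between the two
#' strains' dominant CTSSs.
#'
#' @param x a [ctss_matrix()].
#' @param clusters a `tag_clusters` (or `promoter_regions`) data.frame.
#' @param samples_a,samples_b per-strain sample names.
#' @param d_min absolute minimum on `D`.
#' @param alpha level of the critical-value gate.
#' @return data.frame with one row per cluster: `tc_id`, `D`,
#'   `critical_value`, `shift_pos`, `direction`, `significant`,
#'   `n_a`, `n_b`, `shift_distance`, `testable`.
#' @export
call_shifts <- function(x, clusters, samples_a, samples_b,
                        d_min = 0.3, alpha = 0.05) {
  df <- as.data.frame(clusters)
  idcol <- if ("tc_id" %in% names(df)) "tc_id" else "promoter_id"
  n <- nrow(df)
  out <- data.frame(tc_id = df[[idcol]], D = rep(NA_real_, n),
                    critical_value = rep(NA_real_, n),
                    shift_pos = rep(NA_integer_, n),
                    direction = rep("none", n),
                    significant = rep(FALSE, n),
                    n_a = rep(0, n), n_b = rep(0, n),
                    shift_distance = rep(NA_integer_, n),
                    testable = rep(FALSE, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pr <- aggregate_profiles(x, df$chrom[i], df$strand[i], df$start[i],
                             df$end[i], samples_a, samples_b)
    out$n_a[i] <- pr$n_a; out$n_b[i] <- pr$n_b
    out$testable[i] <- pr$testable
    if (!pr$testable) next
    ks <- ks_shift_statistic(pr)
    crit <- ks_critical_value(pr$n_a, pr$n_b, alpha)
    out$D[i] <- ks$D
    out$critical_value[i] <- crit
    out$shift_pos[i] <- ks$shift_pos
    out$direction[i] <- if (ks$direction_raw == "none") "none"
      else if (xor(ks$direction_raw == "a_left", df$strand[i] == "-"))
        "upstream_in_A" else "downstream_in_A"
    out$significant[i] <- ks$D > d_min && ks$D > crit
    dom_a <- weighted_dominant(pr$positions, pr$counts_a)
    dom_b <- weighted_dominant(pr$positions, pr$counts_b)
    out$shift_distance[i] <- abs(dom_a - dom_b)
  }
  out
}

weighted_dominant <- function(positions, counts) positions[which.max(counts)]
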