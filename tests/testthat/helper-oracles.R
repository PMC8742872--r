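# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive algorithms (transitive closure, observation
# expansion, all-pairs scans) rather than the package's code paths.

# single-linkage clustering of positions by transitive closure of the
# "distance <= gap" relation, O(n^2)
bf_cluster_positions <- function(positions, gap) {
  n <- length(positions)
  if (n == 0L) return(integer())
  adj <- abs(outer(positions, positions, "-")) <= gap
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# interval grouping: transitive closure of "edge gap <= gap" over intervals
bf_group_intervals <- function(start, end, gap) {
  n <- length(start)
  if (n == 0L) return(integer())
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- max(start[i] - end[j], start[j] - end[i], 0)
  adj <- d <= gap
  comp <- rep(NA_integer_, n); k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L; queue <- i
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# KS statistic by expanding counts to pseudo-observations and evaluating
# both ECDFs at every member position
bf_ks <- function(positions, counts_a, counts_b) {
  xa <- rep(positions, counts_a)
  xb <- rep(positions, counts_b)
  fa <- stats::ecdf(xa); fb <- stats::ecdf(xb)
  gap <- abs(fa(positions) - fb(positions))
  list(D = max(gap), shift_pos = positions[which.max(gap)])
}

# brute-force row scan for the CTSS support filter
bf_support_filter <- function(counts, min_samples, min_count) {
  apply(counts, 1, function(r) sum(r >= min_count) >= min_samples)
}

# two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins
bf_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- stats::dhyper(ks, r1, n - r1, c1)
  obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# a tiny deterministic multi-sample matrix used across tests
make_toy_ctss <- function() {
  cnt <- cbind(s1 = c(5L, 0L, 2L, 1L, 0L),
               s2 = c(3L, 1L, 0L, 1L, 0L),
               s3 = c(0L, 1L, 0L, 1L, 7L))
  ctss_matrix(chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
              pos = c(100L, 112L, 140L, 50L, 90L),
              strand = c("+", "+", "+", "-", "-"),
              counts = cnt)
}

# random CTSS matrix on one chromosome/strand for property tests
random_ctss <- function(n_pos, n_samples = 4L, max_pos = 500L) {
  pos <- sort(sample.int(max_pos, n_pos))
  cnt <- matrix(rpois(n_pos * n_samples, 2),
                ncol = n_samples,
                dimnames = list(NULL, paste0("s", seq_len(n_samples))))
  ctss_matrix(rep("chr1", n_pos), pos, rep("+", n_pos), cnt)
}
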