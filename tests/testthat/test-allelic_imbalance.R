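test_that("ai_test is the exact two-sided binomial at p0 = 0.5", {
  r <- ai_test(10, 10)
  expect_equal(r$ai, 0)
  expect_equal(r$p, 1)
  r2 <- ai_test(15, 5)
  expect_equal(r2$ai, 0.5)
  expect_equal(r2$p, 0.04138947, tolerance = 1e-6)
  r3 <- ai_test(10, 0)
  expect_equal(r3$ai, 1)
  expect_equal(r3$p, 2 * 0.5^10, tolerance = 1e-12)
  expect_error(ai_test(0, 0), "zero total")

  # closed form equals the reference implementation over a grid
  set.seed(77)
  for (i in 1:200) {
    n <- sample(1:400, 1); k <- rbinom(1, n, 0.5)
    expect_equal(ai_test(k, n - k)$p,
                 stats::binom.test(k, n, 0.5)$p.value, tolerance = 1e-12)
  }
  # sign convention: positive AI points to the reference allele
  expect_gt(ai_test(30, 10)$ai, 0)
  expect_lt(ai_test(10, 30)$ai, 0)
})

test_that("ai_test attains its exact analytic size at n = 50", {
  # the test is discrete: at n = 50 the achievable size below 0.05 is
  # 2 * P(X <= 17) = 0.0328, attained exactly; verify empirically
  analytic <- 2 * pbinom(17, 50, 0.5)
  set.seed(99)
  k <- rbinom(10000, 50, 0.5)
  emp <- mean(ai_test(k, 50 - k)$p <= 0.05)
  expect_lt(abs(emp - analytic), 0.01)
  expect_lte(emp, 0.05)
})

test_that("ASE variant filter applies the three criteria inclusively", {
  mk_vs <- function(ref, alt) {
    structure(list(variants = data.frame(chrom = "chr1",
                                         pos = seq_len(nrow(ref)),
                                         ref = "A", alt = "G",
                                         vtype = "SNV"),
                   ref_counts = ref, alt_counts = alt,
                   samples = colnames(ref)), class = "variant_set")
  }
  pa <- paste0("A", 1:6); pb <- paste0("B", 1:6); f1 <- paste0("F", 1:12)
  nm <- c(pa, pb, f1)
  base_ref <- matrix(0L, 1, 24, dimnames = list(NULL, nm))
  base_ref[, pb] <- 20L; base_ref[, f1] <- 10L
  base_alt <- matrix(0L, 1, 24, dimnames = list(NULL, nm))
  base_alt[, pa] <- 20L; base_alt[, f1] <- 10L
  expect_true(filter_variants_for_ase(mk_vs(base_ref, base_alt),
                                      pa, pb, f1))
  # (i) one parental replicate at 8 reads -> excluded
  lo <- base_alt; lo[, "A1"] <- 8L
  expect_false(filter_variants_for_ase(mk_vs(base_ref, lo), pa, pb, f1))
  # (ii) both parents homozygous reference -> excluded
  hom_ref <- base_ref; hom_ref[, pa] <- 20L
  hom_alt <- base_alt; hom_alt[, pa] <- 0L
  expect_false(filter_variants_for_ase(mk_vs(hom_ref, hom_alt),
                                       pa, pb, f1))
  # (iii) >= 10 reads in exactly 9 of 12 F1s -> retained (boundary)
  f9_ref <- base_ref; f9_ref[, f1[1:3]] <- 2L
  f9_alt <- base_alt; f9_alt[, f1[1:3]] <- 2L
  expect_true(filter_variants_for_ase(mk_vs(f9_ref, f9_alt), pa, pb, f1))
  f8_ref <- base_ref; f8_ref[, f1[1:4]] <- 2L
  f8_alt <- base_alt; f8_alt[, f1[1:4]] <- 2L
  expect_false(filter_variants_for_ase(mk_vs(f8_ref, f8_alt), pa, pb, f1))
})

test_that("ASE filter equals a brute-force row scan on random depths", {
  set.seed(41)
  pa <- paste0("A", 1:6); pb <- paste0("B", 1:6); f1 <- paste0("F", 1:12)
  nm <- c(pa, pb, f1)
  n <- 200
  ref <- matrix(rpois(n * 24, 12), n, dimnames = list(NULL, nm))
  alt <- matrix(rpois(n * 24, 12), n, dimnames = list(NULL, nm))
  vs <- structure(list(variants = data.frame(chrom = "chr1", pos = 1:n,
                                             ref = "A", alt = "G",
                                             vtype = "SNV"),
                       ref_counts = ref, alt_counts = alt, samples = nm),
                  class = "variant_set")
  got <- filter_variants_for_ase(vs, pa, pb, f1)
  want <- vapply(seq_len(n), function(i) {
    d <- ref[i, ] + alt[i, ]
    c1 <- all(d[c(pa, pb)] >= 10)
    fa <- sum(ref[i, pa]) / sum(d[pa]); fb <- sum(ref[i, pb]) / sum(d[pb])
    c2 <- (fa >= 0.5) != (fb >= 0.5)
    c3 <- sum(d[f1] >= 10) >= 9
    c1 && c2 && c3
  }, TRUE)
  expect_equal(got, want)
})

test_that("promoter-class comparison reproduces Fisher and rank-sum results", {
  # Fisher p for ((8,2),(2,8)) against hypergeometric enumeration
  m <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  expect_equal(stats::fisher.test(m)$p.value, bf_fisher(m),
               tolerance = 1e-9)
  ase <- data.frame(
    ai = c(rep(0.6, 8), rep(0.05, 2), rep(0.6, 2), rep(0.05, 8)),
    p = c(rep(0.01, 8), rep(0.8, 2), rep(0.01, 2), rep(0.8, 8)),
    promoter_class = rep(c("shifting", "other"), each = 10))
  r <- compare_promoter_classes(ase)
  expect_equal(r$fisher_p, bf_fisher(m), tolerance = 1e-9)
  # identical |AI| distributions give p ~ 1
  same <- data.frame(ai = rep(c(0.1, 0.2, 0.3), 2),
                     p = rep(0.5, 6),
                     promoter_class = rep(c("shifting", "other"), each = 3))
  expect_gt(compare_promoter_classes(same)$mw_p, 0.99)
  # empty class -> NA
  no_shift <- transform(same, promoter_class = "other")
  expect_true(is.na(compare_promoter_classes(no_shift)$fisher_p))
})

test_that("planted AI confined to shifting promoters yields a Fisher signal", {
  set.seed(61)
  n_per <- 60
  depth <- 400
  ai_eff <- 0.35
  sh_ref <- rbinom(n_per, depth, (1 + ai_eff) / 2)
  ot_ref <- rbinom(n_per, depth, 0.5)
  tst_sh <- ai_test(sh_ref, depth - sh_ref)
  tst_ot <- ai_test(ot_ref, depth - ot_ref)
  ase <- data.frame(ai = c(tst_sh$ai, tst_ot$ai),
                    p = c(tst_sh$p, tst_ot$p),
                    promoter_class = rep(c("shifting", "other"),
                                         each = n_per))
  expect_lt(compare_promoter_classes(ase)$fisher_p, 0.05)
})

test_that("variants map to containing promoters and inherit their class", {
  pr <- data.frame(promoter_id = c("p1", "p2", "p3"), chrom = "chr1",
                   strand = "+", start = c(100L, 300L, 500L),
                   end = c(150L, 350L, 550L))
  shifts <- data.frame(tc_id = c("p1", "p2", "p3"),
                       significant = c(TRUE, FALSE, FALSE))
  de <- data.frame(feature = c("p1", "p2", "p3"),
                   padj = c(0.5, 0.01, 0.5), log2fc = c(0, 2, 0))
  v <- data.frame(chrom = "chr1", pos = c(120L, 320L, 520L, 900L))
  got <- classify_variant_promoters(v, pr, shifts, de)
  expect_equal(nrow(got), 3L)  # variant outside any promoter dropped
  expect_equal(got$promoter_class, c("shifting", "diff_expressed", "other"))
})

test_that("region-normalised counts behave as a plain scale-invariant ratio", {
  expect_equal(region_normalized_count(50, 200), 0.25)
  expect_equal(region_normalized_count(0, 200), 0)
  expect_error(region_normalized_count(5, 0), "positive")
  expect_equal(region_normalized_count(50 * 3, 200 * 3),
               region_normalized_count(50, 200))
})

test_that("genotype association is an exact two-group Mann-Whitney", {
  r <- genotype_association(rep(c("AA", "GG"), each = 3),
                            c(1, 2, 3, 4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)
  expect_equal(unname(r$group_medians), c(2, 5))
  same <- suppressWarnings(
    genotype_association(rep(c("AA", "GG"), each = 3), rep(1, 6)))
  expect_equal(same$p, 1)
  expect_error(genotype_association(rep("AA", 4), 1:4), "two genotype")

  # power: planted 2 SD shift, n = 15 vs 15
  set.seed(123)
  hits <- vapply(1:200, function(i) {
    x <- rnorm(15); y <- rnorm(15, 2)
    genotype_association(rep(c("AA", "GG"), each = 15), c(x, y))$p <= 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
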