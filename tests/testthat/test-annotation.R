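# build a promoter_regions object directly from spans and per-sample TPM
make_promoters <- function(chrom, strand, start, end, tpm,
                           dominant = NULL) {
  n <- length(start)
  tpm <- as.matrix(tpm)
  out <- data.frame(promoter_id = paste0("pr", seq_len(n)), chrom = chrom,
                    strand = strand, start = start, end = end,
                    n_tc = 1L, member_tcs = paste0("pr", seq_len(n)),
                    dominant_pos = if (is.null(dominant)) start else dominant,
                    stringsAsFactors = FALSE)
  cnt <- tpm; colnames(cnt) <- paste0("count_", colnames(tpm))
  colnames(tpm) <- paste0("tpm_", colnames(tpm))
  out <- cbind(out, cnt, tpm)
  structure(out, samples = sub("^tpm_", "", colnames(tpm)),
            class = c("promoter_regions", "data.frame"))
}

genes1 <- data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
                     tx_start = 5000L, tx_end = 10000L,
                     annotated_tss = I(list(10000L)),
                     stringsAsFactors = FALSE)

test_that("gene regions extend 1 kb upstream strand-aware", {
  gr <- gene_regions(genes1, 1000L)
  expect_equal(c(gr$region_start, gr$region_end), c(5000L, 11000L))
  gp <- gene_regions(data.frame(gene_id = "g2", chrom = "chr1",
                                strand = "+", tx_start = 5000L,
                                tx_end = 10000L), 1000L)
  expect_equal(c(gp$region_start, gp$region_end), c(4000L, 10000L))
})

test_that("promoters assign by strand-aware overlap and rank by expression", {
  pr <- make_promoters("chr1", c("-", "-", "-", "+"),
                       start = c(10480L, 6000L, 7000L, 6000L),
                       end = c(10520L, 6040L, 7040L, 6040L),
                       tpm = cbind(s1 = c(10, 30, 5, 50)))
  ann <- assign_and_rank(pr, genes1, upstream = 1000L)
  adf <- as.data.frame(ann)
  # promoter at 10,500 sits in the upstream extension of the minus gene
  expect_equal(adf$gene_id[1:3], rep("g1", 3))
  expect_equal(adf$rank[1:3], c(2L, 1L, 3L))       # TPM 10,30,5 -> P2,P1,P3
  # same coordinates, wrong strand: intergenic with rank 1
  expect_true(is.na(adf$gene_id[4]))
  expect_equal(adf$rank[4], 1L)
  cls <- as.data.frame(classify_tss_distance(ann, genes1))
  expect_equal(cls$tss_class[4], "intergenic")
})

test_that("ranks are gap-free and expression-sorted (property)", {
  set.seed(31)
  genes <- data.frame(gene_id = paste0("g", 1:5), chrom = "chr1",
                      strand = "+",
                      tx_start = seq(1000L, 41000L, by = 10000L),
                      tx_end = seq(9000L, 49000L, by = 10000L))
  genes$annotated_tss <- I(as.list(genes$tx_start))
  n <- 30
  st <- sort(sample(seq(500L, 48500L), n))
  pr <- make_promoters("chr1", "+", st, st + 20L,
                       cbind(s1 = runif(n, 0, 100)))
  ann <- as.data.frame(assign_and_rank(pr, genes))
  for (g in unique(na.omit(ann$gene_id))) {
    sub <- ann[!is.na(ann$gene_id) & ann$gene_id == g, ]
    expect_setequal(sub$rank, seq_len(nrow(sub)))
    expect_false(is.unsorted(-sub$mean_tpm[order(sub$rank)]))
  }
})

test_that("TSS distance classes use nearest-edge distance with containment", {
  g <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                  tx_start = 1L, tx_end = 100000L)
  mk <- function(tss) { g$annotated_tss <- I(list(tss)); g }
  pr <- make_promoters("chr1", "+", 200L, 230L, cbind(s1 = 1))
  ann <- assign_and_rank(pr, mk(210L))
  expect_equal(as.data.frame(classify_tss_distance(ann, mk(210L)))$tss_class,
               "exact")
  expect_equal(as.data.frame(classify_tss_distance(ann, mk(150L)))$tss_distance,
               50L)
  expect_equal(as.data.frame(classify_tss_distance(ann, mk(150L)))$tss_class,
               "within_100")
  expect_equal(as.data.frame(classify_tss_distance(ann, mk(5000L)))$tss_class,
               "unannotated")
})

test_that("external-TSS proximity classes match an all-pairs scan", {
  pr <- make_promoters("chr1", "+", c(200L, 200L), c(230L, 230L),
                       cbind(s1 = c(1, 1)))
  ext <- data.frame(chrom = "chr1", pos = c(230L, 700L))
  cls <- classify_proximity(pr, ext)
  expect_equal(cls[1], "overlap")

  # TSS at 700 vs span [200,230]: distance 470 falls in the 500 bp bin
  expect_equal(classify_proximity(pr, data.frame(chrom = "chr1",
                                                 pos = 700L))[1],
               "within_500")
  expect_equal(classify_proximity(pr, data.frame(chrom = "chr1",
                                                 pos = 1200L))[1],
               "outside")
  set.seed(17)
  st <- sort(sample.int(5000, 25))
  prs <- make_promoters("chr1", "+", st, st + 30L,
                        cbind(s1 = rep(1, 25)))
  ext2 <- data.frame(chrom = "chr1", pos = sample.int(5000, 40))
  got <- classify_proximity(prs, ext2, bins = c(0L, 100L, 500L))
  want <- vapply(seq_len(25), function(i) {
    d <- min(vapply(ext2$pos, function(t)
      max(st[i] - t, t - (st[i] + 30L), 0L), 0L))
    if (d == 0) "overlap" else if (d <= 100) "within_100"
    else if (d <= 500) "within_500" else "outside"
  }, "")
  expect_equal(got, want)
})

test_that("architecture classification: CpG flanks, TATA consensus, strand", {
  set.seed(23)
  base <- paste(sample(c("A", "C", "G"), 3000, replace = TRUE),
                collapse = "")  # no T: no spurious TATA match
  # plant TATAAATA 30 bp upstream of a plus-strand dominant CTSS at 2000
  seq_plus <- paste0(substr(base, 1, 1969), "TATAAATA",
                     substr(base, 1978, 3000))
  genome <- c(chr1 = seq_plus)
  pr <- make_promoters("chr1", "+", c(1600L, 1990L), c(1650L, 2010L),
                       cbind(s1 = c(1, 1)), dominant = c(1600L, 2000L))
  cpg <- data.frame(chrom = "chr1", start = 1000L, end = 1500L)
  got <- as.data.frame(classify_arch(pr, cpg, genome))
  # island [1000,1500] vs span [1600,1650] flank 200 -> overlap at 1400-1500
  expect_true(got$cpg[1])
  expect_equal(got$arch_class[1], "CpG_only")
  expect_true(got$tata[2])
  expect_equal(got$arch_class[2], "TATA_only")

  # minus-strand promoter sees the motif only via reverse complement
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  genome_m <- c(chr1 = rc(seq_plus))
  dom_m <- 3000L - 2000L + 1L
  prm <- make_promoters("chr1", "-", dom_m - 10L, dom_m + 10L,
                        cbind(s1 = 1), dominant = dom_m)
  gotm <- as.data.frame(classify_arch(prm, cpg[0, ], genome_m))
  expect_true(gotm$tata)

  # no island, no motif -> neither; classes partition the set
  none <- as.data.frame(classify_arch(
    make_promoters("chr1", "+", 500L, 520L, cbind(s1 = 1)),
    cpg[0, ], genome))
  expect_equal(none$arch_class, "neither")
  expect_equal(sum(table(got$arch_class)), nrow(got))
})

test_that("feature_distance reproduces strand-aware orientation", {
  expect_equal(feature_distance(1816432, 1816086, "-"),
               list(distance = 346L, orientation = "upstream"))
  expect_equal(feature_distance(1816500, 1816086, "-"),
               list(distance = 414L, orientation = "upstream"))
  expect_equal(feature_distance(500, 500, "+"),
               list(distance = 0L, orientation = "same"))
  expect_equal(feature_distance(100, 200, "+")$orientation, "upstream")
  expect_equal(feature_distance(100, 200, "-")$orientation, "downstream")
})
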