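test_that("pseudo-genome substitutes SNVs and skips indels", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  v <- data.frame(chrom = "chr1", pos = 2L, ref = "C", alt = "T")
  out <- suppressMessages(build_pseudo_genome(g, v))
  expect_equal(as.character(out[["chr1"]]), "ATGT")
  expect_equal(attr(out, "n_snv"), 1L)

  # deletion untouched, counted as skipped
  v2 <- data.frame(chrom = "chr1", pos = 3L, ref = "GT", alt = "G")
  out2 <- suppressMessages(build_pseudo_genome(g, v2))
  expect_equal(as.character(out2[["chr1"]]), "ACGT")
  expect_equal(attr(out2, "n_indel"), 1L)
  expect_equal(attr(out2, "n_snv"), 0L)
})

test_that("pseudo-genome errors name the offending site", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  expect_error(suppressMessages(build_pseudo_genome(
    g, data.frame(chrom = "chr1", pos = 2L, ref = "A", alt = "T"))),
    "chr1:2")
  expect_error(suppressMessages(build_pseudo_genome(
    g, data.frame(chrom = "chr1", pos = 9L, ref = "A", alt = "T"))),
    "beyond chromosome end")
})

test_that("pseudo-genome: Hamming distance equals applied SNV count", {
  set.seed(11)
  L <- 100000L
  ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  pos <- sort(sample.int(L, 1000L))
  refb <- substring(ref, pos, pos)
  altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1L), "")
  out <- suppressMessages(build_pseudo_genome(
    c(chr1 = ref), data.frame(chrom = "chr1", pos = pos, ref = refb,
                              alt = unname(altb))))
  res <- as.character(out[["chr1"]])
  expect_equal(nchar(res), L)
  # position-wise string diff oracle
  diff_pos <- which(strsplit(ref, "")[[1]] != strsplit(res, "")[[1]])
  expect_equal(diff_pos, pos)
})

test_that("gene models take the longest transcript span and strand-aware TSSs", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0('chr1\tx\ttranscript\t100\t500\t.\t+\t.\tgene_id "gA"; ',
           'transcript_id "tA1";'),
    paste0('chr1\tx\texon\t100\t500\t.\t+\t.\tgene_id "gA"; ',
           'transcript_id "tA1";'),
    paste0('chr1\tx\ttranscript\t150\t900\t.\t+\t.\tgene_id "gA"; ',
           'transcript_id "tA2";'),
    paste0('chr1\tx\texon\t150\t900\t.\t+\t.\tgene_id "gA"; ',
           'transcript_id "tA2";'),
    paste0('chr1\tx\ttranscript\t100\t500\t.\t-\t.\tgene_id "gB"; ',
           'transcript_id "tB1";'),
    paste0('chr1\tx\texon\t100\t500\t.\t-\t.\tgene_id "gB"; ',
           'transcript_id "tB1";')), gtf)
  gm <- read_gene_models(gtf)
  a <- gm[gm$gene_id == "gA", ]
  expect_equal(c(a$tx_start, a$tx_end), c(150L, 900L))
  expect_setequal(a$annotated_tss[[1]], c(100L, 150L))
  b <- gm[gm$gene_id == "gB", ]
  expect_equal(b$annotated_tss[[1]], 500L)  # minus strand: 5' end = end
})

test_that("simulator GTF round-trips through write/read", {
  sim <- simulate_ctss_experiment(sim_config(seed = 3, n_genes = 10,
                                             n_alt_genes = 2, n_shift = 2))
  gtf <- tempfile(fileext = ".gtf")
  write_gene_models_gtf(sim$genes, gtf)
  back <- read_gene_models(gtf)
  back <- back[match(sim$genes$gene_id, back$gene_id), ]
  expect_equal(back$tx_start, sim$genes$tx_start)
  expect_equal(back$tx_end, sim$genes$tx_end)
  expect_equal(back$strand, sim$genes$strand)
  for (i in seq_len(nrow(back)))
    expect_setequal(back$annotated_tss[[i]], sim$genes$annotated_tss[[i]])
})

test_that("CTSS table round-trips", {
  # empty
  p <- tempfile()
  writeLines("chrom\tpos\tstrand\ts1\ts2", p)
  expect_equal(nrow(read_ctss_table(p)), 0L)

  # 3-row fixture: byte-identical body after read/write
  m <- ctss_matrix(c("chr1", "chr1", "chr2"), c(10L, 20L, 5L),
                   c("+", "-", "+"), cbind(s1 = 1:3, s2 = c(0L, 5L, 2L)))
  f1 <- tempfile(); f2 <- tempfile()
  write_ctss_table(m, f1)
  write_ctss_table(read_ctss_table(f1), f2)
  expect_identical(readLines(f1), readLines(f2))

  # large simulated matrix: checksum stable across a round-trip
  sim <- simulate_ctss_experiment(sim_config(seed = 5, n_genes = 30))
  expect_gt(nrow(sim$ctss), 1000L)
  g1 <- tempfile(); g2 <- tempfile()
  write_ctss_table(sim$ctss, g1)
  write_ctss_table(read_ctss_table(g1), g2)
  expect_identical(unname(tools::md5sum(g1)), unname(tools::md5sum(g2)))
})

test_that("CTSS readers reject malformed input", {
  expect_error(ctss_matrix("chr1", 0L, "+", cbind(s1 = 1L)), "pos < 1")
  expect_error(ctss_matrix(c("chr1", "chr1"), c(5L, 5L), c("+", "+"),
                           cbind(s1 = c(1L, 2L))), "duplicate")
  expect_error(ctss_matrix("chr1", 5L, "+", cbind(s1 = -1L)),
               "non-negative")
  p <- tempfile()
  writeLines(c("chrom\tpos\tstrand\ts1", "chr1\t0\t+\t3"), p)
  expect_error(read_ctss_table(p), "pos < 1")
})

test_that("VCF reading assigns types, splits multi-allelics, extracts AD", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    paste0('##FORMAT=<ID=GT,Number=1,Type=String,Description="g">'),
    paste0('##FORMAT=<ID=AD,Number=R,Type=Integer,Description="d">'),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT:AD\t0/1:7,3\t0/0:9,0",
    "chr1\t20\t.\tAT\tA\t.\tPASS\t.\tGT:AD\t0/1:4,4\t0/1:2,6",
    "chr1\t30\t.\tC\tT,G\t.\tPASS\t.\tGT:AD\t1/2:1,2,3\t0/1:5,6,0"), p)
  vs <- read_variants(p)
  expect_s3_class(vs, "variant_set")
  expect_equal(vs$variants$vtype[vs$variants$pos == 10L], "SNV")
  expect_equal(vs$variants$vtype[vs$variants$pos == 20L], "indel")
  expect_equal(sum(vs$variants$pos == 30L), 2L)  # multi-allelic split
  expect_equal(unname(vs$ref_counts[vs$variants$pos == 10L, "s1"]), 7L)
  expect_equal(unname(vs$alt_counts[vs$variants$pos == 10L, "s1"]), 3L)
})

test_that("simulator VCF counts round-trip through read_variants", {
  cfg <- sim_config(seed = 9, n_variants = 50L, n_ai = 10L)
  ase <- simulate_f1_ase(cfg)
  p <- tempfile(fileext = ".vcf")
  write_variants_vcf(ase$variants, ase$samples, p)
  back <- read_variants(p)
  expect_equal(ncol(back$ref_counts), 24L)
  expect_equal(nrow(back$variants), 50L)
  ord <- match(paste(ase$variants$variants$chrom, ase$variants$variants$pos),
               paste(back$variants$chrom, back$variants$pos))
  expect_equal(unname(back$ref_counts[ord, ase$variants$samples]),
               unname(ase$variants$ref_counts))
  expect_equal(unname(back$alt_counts[ord, ase$variants$samples]),
               unname(ase$variants$alt_counts))
})

test_that("BED conversion is 0-based half-open at the boundary only", {
  b <- tempfile(fileext = ".bed")
  write_bed(data.frame(chrom = "chr1", start = 1000L, end = 1500L,
                       name = "cpg1"), b)
  fields <- strsplit(readLines(b)[1], "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(999L, 1500L))
  back <- read_bed(b)
  expect_equal(c(back$start, back$end), c(1000L, 1500L))
})
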