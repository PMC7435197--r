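make_gene_bed <- function(lines) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("gene models derive the TSS from strand and validate input", {
  si <- toy_seqinfo(c(chr1 = 100000L))
  f <- make_gene_bed(c("chr1\t1000\t2000\tgeneA\t0\t+",
                       "chr1\t1000\t2000\tgeneB\t0\t-"))
  genes <- readGeneModels(f, si)
  expect_equal(genes$tss[genes$gene_id == "geneA"], 1001L)  # bed 1000
  expect_equal(genes$tss[genes$gene_id == "geneB"], 2000L)  # bed 1999

  f <- make_gene_bed("chr1\t1000\t2000\tgeneC\t0\t.")
  expect_error(readGeneModels(f, si), "strand")
  f <- make_gene_bed(c("chr1\t1000\t2000\tgA\t0\t+",
                       "chr1\t3000\t4000\tgA\t0\t+"))
  expect_error(readGeneModels(f, si), "[Dd]uplicate")
  f <- make_gene_bed(c("chr1\t1000\t2000\tgA\t0\t+",
                       "chrUn\t10\t20\tgB\t0\t+"))
  expect_message(genes <- readGeneModels(f, si), "dropped")
  expect_equal(genes$gene_id, "gA")
})

test_that("signed TSS distances are oriented by gene strand", {
  si <- toy_seqinfo(c(chr1 = 100000L))
  plus <- fixture_genes(si, 5000, 8000, "+")
  minus <- fixture_genes(si, 5000, 8000, "-")
  # peak with anchor 500 bp left (genomically) of each TSS
  pk_plus <- GRanges("chr1", IRanges(4450, 4550), seqinfo = si)  # anchor 4500
  expect_equal(signedTssDistance(pk_plus, plus), -500L)
  pk_minus <- GRanges("chr1", IRanges(7450, 7550), seqinfo = si) # anchor 7500
  expect_equal(signedTssDistance(pk_minus, minus), 500L)
  at_tss <- GRanges("chr1", IRanges(4950, 5050), seqinfo = si)   # anchor 5000
  expect_equal(signedTssDistance(at_tss, plus), 0L)

  si2 <- toy_seqinfo(c(chr1 = 1000L, chr2 = 1000L))
  pk2 <- GRanges("chr1", IRanges(1, 11), seqinfo = si2)
  g2 <- GRanges("chr2", IRanges(10, 50), strand = "+", seqinfo = si2)
  g2$gene_id <- "gX"; g2$tss <- 10L
  expect_error(signedTssDistance(pk2, g2), "chromosome")
})

test_that("target assignment enforces the strict distance bound", {
  si <- toy_seqinfo(c(chr1 = 100000L))
  genes <- fixture_genes(si, c(10000, 30000), c(12000, 32000), c("+", "+"))
  near <- GRanges("chr1", IRanges(9450, 9550), seqinfo = si)   # d = -500
  res <- assignTargetGenes(near, genes)
  expect_equal(res$targets, "g01")

  boundary <- GRanges("chr1", IRanges(8950, 9050), seqinfo = si) # d = -1000
  expect_equal(length(assignTargetGenes(boundary, genes)$targets), 0L)
  just_in <- GRanges("chr1", IRanges(8951, 9051), seqinfo = si)  # d = -999
  expect_equal(assignTargetGenes(just_in, genes)$targets, "g01")

  expect_error(assignTargetGenes(near, genes[0]), "empty")
})

test_that("target assignment matches the all-pairs oracle on planted peaks", {
  si <- toy_seqinfo(c(chr1 = 500000L))
  set.seed(101)
  starts <- sort(sample(seq(5000, 480000, by = 9000), 50))
  genes <- fixture_genes(si, starts, starts + 3000,
                         sample(c("+", "-"), 50, replace = TRUE))
  # 10 peaks planted within 1 kb of 7 distinct TSSs (3 genes get 2 peaks)
  tss <- genes$tss
  chosen <- sample(50, 7)
  anchor_at <- tss[chosen[c(1:7, 1:3)]] +
    sample(c(-900, -500, 0, 500, 900), 10, replace = TRUE)
  peaks <- GRanges("chr1", IRanges(anchor_at - 100L, width = 201L),
                   seqinfo = si)
  res <- assignTargetGenes(peaks, genes)
  oracle <- oracle_tss_pairs(peaks, genes, 1000)
  expect_equal(sort(res$targets), sort(unique(oracle$gene_id)))
  expect_equal(length(res$targets), 7L)
  expect_equal(
    res$assignments[order(res$assignments$peak, res$assignments$gene_id), ],
    oracle[order(oracle$peak, oracle$gene_id), ],
    ignore_attr = TRUE)
})

test_that("target sets are nested as the distance bound grows", {
  si <- toy_seqinfo(c(chr1 = 200000L))
  set.seed(55)
  genes <- fixture_genes(si, seq(10000, 180000, by = 7000),
                         seq(10000, 180000, by = 7000) + 2500,
                         sample(c("+", "-"), 25, replace = TRUE))
  peaks <- random_intervals(40, si, max_len = 400)
  prev <- character(0)
  for (d in c(200, 500, 1000, 2000, 5000)) {
    cur <- assignTargetGenes(peaks, genes, max_dist = d)$targets
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("target sets survive mirroring the genome", {
  L <- 200000L
  si <- toy_seqinfo(c(chr1 = L))
  set.seed(66)
  st <- seq(10000, 180000, by = 9000)
  strands <- sample(c("+", "-"), length(st), replace = TRUE)
  genes <- fixture_genes(si, st, st + 3000, strands)
  w <- 2L * sample(0:100, 40, replace = TRUE) + 1L  # odd widths mirror exactly
  peaks <- GRanges("chr1", IRanges(sample(L - 300L, 40), width = w),
                   seqinfo = si)

  mirror_gr <- function(gr) {
    GRanges("chr1", IRanges(L - end(gr) + 1L, L - start(gr) + 1L),
            strand = chartr("+-", "-+", as.character(strand(gr))),
            seqinfo = si)
  }
  m_genes <- mirror_gr(genes)
  m_genes$gene_id <- genes$gene_id
  m_genes$tss <- tssPositions(m_genes)
  m_peaks <- mirror_gr(peaks)

  # widths here are odd so the midpoint anchor mirrors exactly
  expect_setequal(assignTargetGenes(peaks, genes)$targets,
                  assignTargetGenes(m_peaks, m_genes)$targets)
  d1 <- sort(abs(assignTargetGenes(peaks, genes)$assignments$distance))
  d2 <- sort(abs(assignTargetGenes(m_peaks, m_genes)$assignments$distance))
  expect_equal(d1, d2)
})

test_that("feature distribution matches the per-base category oracle", {
  si <- toy_seqinfo(c(chrT = 100000L))
  set.seed(77)
  starts <- c(10000, 25000, 40000, 60000, 80000)
  genes <- fixture_genes(si, starts, starts + c(5000, 3000, 8000, 2000, 6000),
                         c("+", "-", "+", "-", "+"),
                         sprintf("g%02d", 1:5))
  peaks <- random_intervals(120, si, max_len = 300)
  fd <- featureDistribution(peaks, genes)
  expect_equal(sum(fd$peak_fractions), 1, tolerance = 1e-9)
  expect_equal(sum(fd$genome_fractions), 1, tolerance = 1e-9)
  oracle <- oracle_feature_category(peaks, genes, si)
  expect_equal(as.character(fd$category), oracle)

  # genome baseline also matches the oracle map base-by-base
  all_bases <- GRanges("chrT", IRanges(seq_len(100000L), width = 1L),
                       seqinfo = si)
  base_cat <- oracle_feature_category(all_bases, genes, si)
  expect_equal(unname(fd$genome_fractions),
               as.numeric(table(factor(base_cat,
                                       c("promoter", "gene_body",
                                         "downstream", "intergenic"))) /
                          100000))
})

test_that("feature distribution handles degenerate layouts", {
  si <- toy_seqinfo(c(chrT = 50000L))
  genes <- fixture_genes(si, 20000, 30000, "+")
  in_prom <- GRanges("chrT", IRanges(c(18000, 19000), width = 101L),
                     seqinfo = si)
  fd <- featureDistribution(in_prom, genes)
  expect_equal(unname(fd$peak_fractions["promoter"]), 1)

  no_genes <- featureDistribution(in_prom, genes[0])
  expect_equal(unname(no_genes$peak_fractions["intergenic"]), 1)
  expect_equal(unname(no_genes$genome_fractions["intergenic"]), 1)

  expect_error(featureDistribution(GRanges(seqinfo = si), genes), "empty")
})

test_that("TSS profiles are normalised histograms of signed distances", {
  si <- toy_seqinfo(c(chr1 = 200000L))
  st <- seq(20000, 180000, by = 20000)
  genes <- fixture_genes(si, st, st + 5000,
                         rep(c("+", "-"), length.out = length(st)))
  at_tss <- GRanges("chr1", IRanges(genes$tss - 50L, width = 101L),
                    seqinfo = si)
  prof <- tssProfile(at_tss, genes, window = 10000, bin = 100)
  expect_equal(sum(prof$density), 1)
  zero_bin <- which(prof$bin_center == 50)  # bin [0, 100)
  expect_equal(prof$density[zero_bin], 1)

  far <- GRanges("chr1", IRanges(st[1] - 15000L, width = 11L), seqinfo = si)
  expect_warning(p0 <- tssProfile(far, genes, window = 1000, bin = 100),
                 "window")
  expect_true(all(p0$density == 0))

  expect_error(tssProfile(at_tss, genes, window = 1000, bin = 300),
               "divide")
})

test_that("uniformly placed anchors give an approximately flat profile", {
  si <- toy_seqinfo(c(chr1 = 2000000L))
  genes <- fixture_genes(si, 1000000, 1005000, "+")
  set.seed(88)
  n <- 20000
  anchors <- 1000000 + sample(-10000:9999, n, replace = TRUE)
  peaks <- GRanges("chr1", IRanges(anchors, width = 1L), seqinfo = si)
  prof <- tssProfile(peaks, genes, window = 10000, bin = 1000)
  expected <- n / nrow(prof)
  dev <- abs(prof$density * n - expected)
  expect_true(all(dev < 5 * sqrt(expected)))
})

test_that("gene-set overlap test reproduces direct set arithmetic", {
  u <- sprintf("gene%04d", 1:1000)
  a <- u[1:100]
  b <- u[c(1:52, 301:548)]
  res <- geneSetOverlapTest(a, b, u)
  expect_equal(res$overlap_fraction, 0.52)
  expect_equal(as.vector(t(contingencyTable(res$contingency))),
               c(52L, 48L, 248L, 652L))

  expect_equal(geneSetOverlapTest(a, a, u)$overlap_fraction, 1)
  expect_equal(geneSetOverlapTest(a, u[900:1000], u)$overlap_fraction, 0)
  expect_error(geneSetOverlapTest(a, b, character(0)), "universe")
  expect_error(geneSetOverlapTest(character(0), b, u), "non-empty")
  expect_error(geneSetOverlapTest(c(a, "zzz"), b, u), "subset")
})
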