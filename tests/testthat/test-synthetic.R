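test_that("simulated genomes honour GC content and determinism", {
  gen0 <- simulateGenome(c(c1 = 5000L), gc = 0, seed = 1)
  freq <- Biostrings::alphabetFrequency(gen0$seqs[[1]])
  expect_equal(sum(freq[c("C", "G")]), 0)
  expect_gt(freq[["A"]], 0)

  g1 <- simulateGenome(c(c1 = 10000L, c2 = 5000L), gc = 0.41, seed = 2)
  g2 <- simulateGenome(c(c1 = 10000L, c2 = 5000L), gc = 0.41, seed = 2)
  expect_equal(as.character(g1$seqs), as.character(g2$seqs))
  expect_false(identical(
    as.character(simulateGenome(c(c1 = 10000L), gc = 0.41, seed = 3)$seqs),
    as.character(simulateGenome(c(c1 = 10000L), gc = 0.41, seed = 4)$seqs)))

  gh <- simulateGenome(c(c1 = 100000L), gc = 0.5, seed = 5)
  obs_gc <- sum(Biostrings::alphabetFrequency(gh$seqs[[1]])[c("C", "G")])
  expect_lt(abs(obs_gc - 50000) / sqrt(100000 * 0.25), 3)

  expect_error(simulateGenome(integer(0), seed = 1), "zero")
})

test_that("simulated genes are non-overlapping with balanced strands", {
  si <- toy_seqinfo(c(c1 = 1000000L, c2 = 500000L))
  empty <- simulateGenes(si, 0, seed = 1)
  expect_equal(length(empty), 0L)

  genes <- simulateGenes(si, 120, seed = 6)
  expect_equal(length(genes), 120L)
  expect_true(GenomicRanges::isDisjoint(genes))
  expect_true(all(end(genes) <= GenomeInfoDb::seqlengths(si)[
    as.character(seqnames(genes))]))
  expect_false(anyDuplicated(genes$gene_id) > 0)

  expect_error(simulateGenes(toy_seqinfo(c(c1 = 10000L)), 50,
                             gene_length = c(2000, 3000), seed = 7),
               "capacity")

  big <- simulateGenes(toy_seqinfo(c(c1 = 30000000L)), 1000, seed = 8)
  n_plus <- sum(as.character(strand(big)) == "+")
  expect_lt(abs(n_plus - 500) / sqrt(1000 * 0.25), 3)
})

test_that("peak simulation plants the requested TSS-proximal share", {
  si <- toy_seqinfo(c(c1 = 1000000L, c2 = 1000000L))
  genes <- simulateGenes(si, 100, seed = 9)
  peaks <- simulatePeaks(si, genes, n_peaks = 150, tss_fraction = 1,
                         seed = 10)
  expect_true(GenomicRanges::isDisjoint(peaks))
  expect_true(all(width(peaks) == 200L))
  anchors <- start(peaks) + width(peaks) %/% 2L
  near <- vapply(seq_along(peaks), function(i) {
    same <- genes[as.character(seqnames(genes)) ==
                    as.character(seqnames(peaks))[i]]
    any(abs(anchors[i] - same$tss) < 1000)
  }, logical(1))
  expect_true(all(near))

  # with no planting, the target-recovery rate matches the by-chance rate
  p0 <- simulatePeaks(si, genes, n_peaks = 400, tss_fraction = 0, seed = 11)
  hit_genes <- assignTargetGenes(p0, genes)$targets
  # by-chance: anchor uniform; each gene's 1999-bp window is ~uniform cover
  window_bp <- 100 * 1999
  p_hit_per_peak <- window_bp / 2000000
  expected_pairs <- 400 * p_hit_per_peak
  n_pairs <- nrow(assignTargetGenes(p0, genes)$assignments)
  expect_lt(abs(n_pairs - expected_pairs) / sqrt(expected_pairs), 4)
  expect_error(simulatePeaks(si, NULL, 10, tss_fraction = 0.5, seed = 1),
               "genes")
})

test_that("co-occurring peaks plant the overlap fraction exactly", {
  si <- toy_seqinfo(c(c1 = 1000000L, c2 = 1000000L, c3 = 1000000L))
  genes <- simulateGenes(si, 90, seed = 12)
  A <- simulatePeaks(si, genes, n_peaks = 120, tss_fraction = 0.3,
                     seed = 13)
  for (q in c(0, 0.25, 0.5917, 1)) {
    B <- simulateCooccurringPeaks(A, q, seed = 14)
    expect_equal(overlapStats(A, B)@fracAHit, round(q * 120) / 120)
  }
  expect_equal(overlapStats(
    A, simulateCooccurringPeaks(A, 0.5917, seed = 15))@fracAHit, 71 / 120)

  overlapping_base <- c(A, A[1])
  expect_error(simulateCooccurringPeaks(overlapping_base, 0.5, seed = 1),
               "disjoint")
})

test_that("expression simulation plants the configured shift", {
  ids <- sprintf("g%04d", 1:1000)
  tg <- ids[1:100]
  e1 <- simulateExpression(ids, tg, lfc_shift = 0.5, lfc_sigma = 0.5,
                           seed = 16)
  e2 <- simulateExpression(ids, tg, lfc_shift = 0.5, lfc_sigma = 0.5,
                           seed = 16)
  expect_identical(e1, e2)
  diff <- mean(e1$log2fc[e1$is_target]) - mean(e1$log2fc[!e1$is_target])
  se <- 0.5 * sqrt(1 / 100 + 1 / 900)
  expect_lt(abs(diff - 0.5), 3 * se)

  e0 <- simulateExpression(ids, tg, lfc_shift = 0, lfc_sigma = 0.5,
                           seed = 17)
  expect_lt(abs(mean(e0$log2fc[e0$is_target]) -
                mean(e0$log2fc[!e0$is_target])), 3 * se)
  expect_error(simulateExpression(ids, "nope", seed = 1), "subset")
})

test_that("motif planting is recovered by the scanner and respects prob = 0", {
  gen <- simulateGenome(c(c1 = 200000L), gc = 0.41, seed = 18)
  genes <- simulateGenes(gen$genome, 30, seed = 19)
  peaks <- simulatePeaks(gen$genome, genes, 50, seed = 20)
  pm0 <- plantMotifs(gen$seqs, peaks, motifDef(), prob = 0, seed = 21)
  expect_equal(as.character(pm0$seqs), as.character(gen$seqs))
  expect_equal(nrow(pm0$planted), 0L)

  pm1 <- plantMotifs(gen$seqs, peaks, motifDef(), prob = 1, seed = 22)
  expect_equal(nrow(pm1$planted), 50L)
  hits <- scanConsensus(pm1$seqs[["c1"]], motifDef())
  expect_true(all(pm1$planted$position %in% hits$position))
  # every peak carries at least one exact hit
  per_peak <- vapply(seq_along(peaks), function(i)
    any(hits$position >= start(peaks)[i] &
        hits$position <= end(peaks)[i] - 5L), logical(1))
  expect_true(all(per_peak))

  tiny <- GenomicRanges::GRanges("c1", IRanges::IRanges(5, 8),
                                 seqinfo = gen$genome)
  expect_error(plantMotifs(gen$seqs, tiny, motifDef(), 1, 1), "longer")
})

test_that("Ct simulation inverts through ddct", {
  fm <- cbind(control = c(1, 1, 1), kd = c(2, 0.5, 1))
  rownames(fm) <- c("up", "down", "REF")
  ct <- simulateCt(fm, "REF", n_rep = 3, noise_sd = 0, seed = 23)
  res <- ddct(ct, "REF", "control")
  expect_equal(res$fold[res$condition == "kd" & res$gene == "up"], 2)
  expect_equal(res$fold[res$condition == "kd" & res$gene == "down"], 0.5)
  expect_equal(res$fold[res$condition == "control"], c(1, 1, 1))

  flat <- fm; flat[, "kd"] <- 1
  resf <- ddct(simulateCt(flat, "REF", 3, 0, seed = 24), "REF", "control")
  expect_true(all(resf$fold == 1))

  # with noise the fold is recovered within a generous band most of the time
  ok <- vapply(1:100, function(s) {
    r <- ddct(simulateCt(fm, "REF", 3, 0.1, seed = 1000 + s),
              "REF", "control")
    f <- r$fold[r$condition == "kd" & r$gene == "up"]
    f >= 1.6 && f <= 2.5
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  bad <- fm; bad["REF", "kd"] <- 2
  expect_error(simulateCt(bad, "REF", 3, 0, 1), "reference")
})

test_that("the assembled study is deterministic and internally consistent", {
  cfg <- syntheticConfig(seed = 99,
                         chrom_lengths = c(c1 = 300000L, c2 = 300000L),
                         n_genes = 80, n_peaks = 100)
  st1 <- simulateStudy(cfg)
  st2 <- simulateStudy(cfg)
  expect_identical(st1$truth, st2$truth)
  expect_identical(as.character(st1$seqs), as.character(st2$seqs))
  expect_equal(overlapStats(st1$peaksA, st1$peaksB)@fracAHit,
               st1$truth$n_A_hit_planted / length(st1$peaksA))

  d <- withr::local_tempdir()
  writeStudy(st1, d)
  expect_setequal(list.files(d),
                  c("genome.chrom.sizes", "genome.fa", "genes.bed",
                    "peaksA.bed", "peaksB.bed", "expr.tsv", "ct.tsv",
                    "truth.json"))
  si <- readChromSizes(file.path(d, "genome.chrom.sizes"))
  back <- readBed(file.path(d, "peaksA.bed"), si)
  expect_equal(start(GenomicRanges::sort(back)),
               start(GenomicRanges::sort(st1$peaksA)))
})
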