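#' Configuration for the synthetic study generator
#'
#' Bundles the knobs of the synthetic-data generators with the default toy
#' scale used throughout the package's tests: 3 chromosomes of 1 Mb, 300
#' genes, 200 peaks of 200 bp, half the peaks planted near TSSs, a planted
#' co-occurrence fraction of 0.5917, an expression shift of +0.5 log2
#' units (SD 0.5) in target genes, guaranteed motif planting, and a
#' human-like background GC of 0.41. A single `seed` fans out to fixed
#' per-generator sub-seeds so adding one generator never perturbs the
#' output of another.
#'
#' @param seed integer master seed (mandatory).
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param n_genes,n_peaks counts.
#' @param peak_length single length (fixed) or `c(min, max)` (uniform).
#' @param tss_fraction fraction of peaks planted within `target_max_dist`
#'   of a TSS.
#' @param target_max_dist strict TSS-proximity bound in bp.
#' @param co_overlap_fraction planted fraction `q` of the first peak set
#'   overlapped by the second.
#' @param lfc_shift,lfc_sigma planted log2 fold-change shift and noise SD.
#' @param motif_prob per-peak motif planting probability.
#' @param gc background GC fraction.
#' @return a named list of class `"reachmap_config"`.
#' @export
syntheticConfig <- function(seed,
                            chrom_lengths = c(chr1 = 1000000L,
                                              chr2 = 1000000L,
                                              chr3 = 1000000L),
                            n_genes = 300L, n_peaks = 200L,
                            peak_length = 200L,
                            tss_fraction = 0.5, target_max_dist = 1000L,
                            co_overlap_fraction = 0.5917,
                            lfc_shift = 0.5, lfc_sigma = 0.5,
                            motif_prob = 1, gc = 0.41) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths >= 1),
            !is.null(names(chrom_lengths)))
  for (f in c(tss_fraction, co_overlap_fraction, motif_prob, gc))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_genes = as.integer(n_genes),
                 n_peaks = as.integer(n_peaks),
                 peak_length = as.integer(peak_length),
                 tss_fraction = tss_fraction,
                 target_max_dist = as.integer(target_max_dist),
                 co_overlap_fraction = co_overlap_fraction,
                 lfc_shift = lfc_shift, lfc_sigma = lfc_sigma,
                 motif_prob = motif_prob, gc = gc),
            class = "reachmap_config")
}

# fixed fan-out of the master seed into independent sub-streams
sub_seed <- function(seed, k) (as.integer(seed) %% 100000000L) * 10L + k

draw_lengths <- function(n, peak_length) {
  if (length(peak_length) == 1L) rep(as.integer(peak_length), n)
  else runif_int(n, as.integer(peak_length[1]), as.integer(peak_length[2]))
}

#' Simulate a random genome sequence
#'
#' I.i.d. nucleotides at the configured GC fraction (`C` and `G` each with
#' probability `gc / 2`). Deterministic given the seed.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return a list: `genome` (a `Seqinfo`) and `seqs` (a named
#'   `DNAStringSet`).
#' @export
simulateGenome <- function(chrom_lengths, gc = 0.41, seed) {
  if (length(chrom_lengths) == 0L) stop("zero chromosomes", call. = FALSE)
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]", call. = FALSE)
  seqs <- with_seed(seed, {
    lapply(chrom_lengths, function(L) {
      paste(sample(c("A", "T", "C", "G"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
            collapse = "")
    })
  })
  list(genome = GenomeInfoDb::Seqinfo(names(chrom_lengths),
                                      as.integer(chrom_lengths)),
       seqs = Biostrings::DNAStringSet(unlist(seqs)))
}

#' Simulate non-overlapping gene models
#'
#' Places `n_genes` mutually non-overlapping genes uniformly (conditional
#' on non-overlap, via the standard gaps construction), with lengths drawn
#' uniformly from `gene_length` and random strands. Genes are distributed
#' across chromosomes proportionally to length.
#'
#' @param genome a `Seqinfo`.
#' @param n_genes number of genes.
#' @param gene_length `c(min, max)` gene length in bp.
#' @param seed integer seed.
#' @return a `GRanges` with `gene_id` and `tss` metadata columns.
#' @export
simulateGenes <- function(genome, n_genes = 300L,
                          gene_length = c(2000L, 10000L), seed) {
  if (n_genes == 0L)
    return(GenomicRanges::GRanges(seqinfo = genome, gene_id = character(0)))
  sl <- GenomeInfoDb::seqlengths(genome)
  alloc <- floor(n_genes * sl / sum(as.numeric(sl)))
  rem <- n_genes - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  with_seed(seed, {
    parts <- lapply(names(sl), function(ch) {
      k <- alloc[[ch]]
      if (k == 0L) return(NULL)
      w <- draw_lengths(k, gene_length)
      free <- sl[[ch]] - sum(w)
      if (free < 0)
        stop("requested genes exceed genome capacity on ", ch,
             call. = FALSE)
      gaps <- sort(runif_int(k, 0L, free))
      starts <- gaps + cumsum(c(0L, w[-k])) + 1L
      GenomicRanges::GRanges(ch, IRanges::IRanges(starts, width = w),
                             strand = sample(c("+", "-"), k,
                                             replace = TRUE),
                             seqinfo = genome)
    })
    gr <- do.call(c, Filter(Negate(is.null), parts))
    gr$gene_id <- sprintf("g%04d", seq_along(gr))
    gr$tss <- tssPositions(gr)
    gr
  })
}

place_anchor_near_tss <- function(gene, w, max_dist, sl) {
  tss <- gene$tss
  L <- sl[[as.character(GenomeInfoDb::seqnames(gene))]]
  half <- w %/% 2L
  lo <- max(tss - (max_dist - 1L), 1L + half)
  hi <- min(tss + (max_dist - 1L), L - w + 1L + half)
  stopifnot(lo <= hi)
  runif_int(1L, lo, hi)
}

#' Simulate peaks with a planted TSS-proximal share
#'
#' A `tss_fraction` share of peaks have their anchor (midpoint) planted
#' strictly within `target_max_dist` of a randomly chosen TSS; the rest
#' are placed uniformly. Peaks are mutually non-overlapping (overlapping
#' draws are re-drawn), mirroring the disjointness of called peak sets.
#'
#' @param genome a `Seqinfo`.
#' @param genes gene models (required when `tss_fraction > 0`).
#' @param n_peaks number of peaks.
#' @param peak_length fixed length or `c(min, max)`.
#' @param tss_fraction fraction planted near TSSs.
#' @param target_max_dist strict proximity bound in bp.
#' @param seed integer seed.
#' @return a `GRanges` with `name` and logical `planted` columns.
#' @export
simulatePeaks <- function(genome, genes = NULL, n_peaks = 200L,
                          peak_length = 200L, tss_fraction = 0.5,
                          target_max_dist = 1000L, seed) {
  if (tss_fraction > 0 && (is.null(genes) || length(genes) == 0L))
    stop("genes required when tss_fraction > 0", call. = FALSE)
  sl <- GenomeInfoDb::seqlengths(genome)
  n_tss <- round(tss_fraction * n_peaks)
  with_seed(seed, {
    w <- draw_lengths(n_peaks, peak_length)
    planted <- seq_len(n_peaks) <= n_tss
    draw_one <- function(i) {
      if (planted[i]) {
        g <- genes[sample(length(genes), 1L)]
        a <- place_anchor_near_tss(g, w[i], as.integer(target_max_dist), sl)
        ch <- as.character(GenomeInfoDb::seqnames(g))
        GenomicRanges::GRanges(ch,
          IRanges::IRanges(a - w[i] %/% 2L, width = w[i]), seqinfo = genome)
      } else {
        ch <- sample(names(sl), 1L, prob = as.numeric(sl))
        GenomicRanges::GRanges(ch,
          IRanges::IRanges(runif_int(1L, 1L, sl[[ch]] - w[i] + 1L),
                           width = w[i]), seqinfo = genome)
      }
    }
    gr <- do.call(c, lapply(seq_len(n_peaks), draw_one))
    for (round in seq_len(200L)) {
      clash <- GenomicRanges::countOverlaps(gr, gr) > 1L
      if (!any(clash)) break
      for (i in which(clash)) gr[i] <- draw_one(i)
      if (round == 200L)
        stop("could not place non-overlapping peaks", call. = FALSE)
    }
    gr$name <- sprintf("peak_%03d", seq_len(n_peaks))
    gr$planted <- planted
    GenomicRanges::sort(gr)
  })
}

#' Simulate a second peak set with an exactly planted overlap fraction
#'
#' Constructs a set `B` of `length(base)` intervals such that exactly
#' `round(q * length(base))` of the (mutually disjoint) `base` intervals
#' overlap at least one `B` interval: the hit share of `B` is planted
#' inside distinct randomly chosen base intervals, and the remainder is
#' placed uniformly avoiding every base interval (rejection-sampled). By
#' construction `overlapStats(base, B)@fracAHit` equals
#' `round(q * n) / n` exactly.
#'
#' @param base a disjoint `GRanges` (set A).
#' @param q planted overlap fraction in `[0, 1]`.
#' @param peak_length length(s) of the B intervals.
#' @param seed integer seed.
#' @return a `GRanges` of the same size as `base`.
#' @export
simulateCooccurringPeaks <- function(base, q, peak_length = 200L, seed) {
  if (q < 0 || q > 1) stop("q must lie in [0, 1]", call. = FALSE)
  if (!GenomicRanges::isDisjoint(base))
    stop("base intervals must be mutually disjoint for exact planting",
         call. = FALSE)
  check_has_genome(base, "base set")
  n <- length(base)
  k <- round(q * n)
  sl <- GenomeInfoDb::seqlengths(base)
  with_seed(seed, {
    chosen <- sample(n, k)
    inside <- lapply(chosen, function(i) {
      wA <- GenomicRanges::width(base)[i]
      wB <- min(draw_lengths(1L, peak_length), wA)
      st <- runif_int(1L, GenomicRanges::start(base)[i],
                      GenomicRanges::end(base)[i] - wB + 1L)
      GenomicRanges::GRanges(GenomeInfoDb::seqnames(base)[i],
                             IRanges::IRanges(st, width = wB),
                             seqinfo = GenomeInfoDb::seqinfo(base))
    })
    avoid <- lapply(seq_len(n - k), function(j) {
      for (try in seq_len(10000L)) {
        wB <- draw_lengths(1L, peak_length)
        ch <- sample(names(sl), 1L, prob = as.numeric(sl))
        st <- runif_int(1L, 1L, sl[[ch]] - wB + 1L)
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = wB),
                                       seqinfo = GenomeInfoDb::seqinfo(base))
        if (sum(GenomicRanges::countOverlaps(cand, base)) == 0L)
          return(cand)
      }
      stop("insufficient base-free space for non-overlapping remainder",
           call. = FALSE)
    })
    GenomicRanges::sort(do.call(c, c(inside, avoid)))
  })
}

#' Simulate an expression table with a planted target shift
#'
#' Background genes draw `log2fc ~ Normal(0, lfc_sigma)`, target genes
#' `Normal(lfc_shift, lfc_sigma)`.
#'
#' @param gene_ids character vector of all gene ids.
#' @param targets character vector of target gene ids (subset).
#' @param lfc_shift,lfc_sigma planted shift and noise SD.
#' @param seed integer seed.
#' @return a data.frame with `gene_id`, `log2fc` and logical `is_target`.
#' @export
simulateExpression <- function(gene_ids, targets, lfc_shift = 0.5,
                               lfc_sigma = 0.5, seed) {
  if (!all(targets %in% gene_ids))
    stop("targets must be a subset of gene_ids", call. = FALSE)
  is_t <- gene_ids %in% targets
  lfc <- with_seed(seed,
    rnorm(length(gene_ids), mean = ifelse(is_t, lfc_shift, 0),
          sd = lfc_sigma))
  data.frame(gene_id = gene_ids, log2fc = lfc, is_target = is_t,
             stringsAsFactors = FALSE)
}

#' Plant consensus motifs inside peaks
#'
#' With probability `prob` per peak, writes the motif consensus at a
#' uniformly drawn offset fully inside the peak. Peaks must be disjoint so
#' the replacements cannot collide, and every peak must be at least as
#' long as the motif.
#'
#' @param seqs a named `DNAStringSet`.
#' @param peaks a disjoint `GRanges`.
#' @param motif a motif from [motifDef()] (concrete consensus, no
#'   ambiguity codes).
#' @param prob per-peak planting probability.
#' @param seed integer seed.
#' @return a list: `seqs` (modified `DNAStringSet`) and `planted`
#'   (data.frame of `chrom`, `position` of each written motif).
#' @export
plantMotifs <- function(seqs, peaks, motif = motifDef(), prob = 1, seed) {
  k <- nchar(motif$consensus)
  if (any(GenomicRanges::width(peaks) < k))
    stop("motif longer than some peak", call. = FALSE)
  if (!GenomicRanges::isDisjoint(peaks))
    stop("peaks must be disjoint", call. = FALSE)
  with_seed(seed, {
    take <- runif(length(peaks)) < prob
    if (!any(take))
      return(list(seqs = seqs,
                  planted = data.frame(chrom = character(0),
                                       position = integer(0))))
    pk <- peaks[take]
    pos <- runif_int(length(pk), GenomicRanges::start(pk),
                     GenomicRanges::end(pk) - k + 1L)
    chrom <- as.character(GenomeInfoDb::seqnames(pk))
    at <- S4Vectors::split(IRanges::IRanges(pos, width = k),
                           factor(chrom, levels = names(seqs)))
    val <- methods::as(lapply(at, function(x)
      rep(motif$consensus, length(x))), "CharacterList")
    seqs2 <- Biostrings::replaceAt(seqs, unname(at), value = unname(val))
    list(seqs = seqs2,
         planted = data.frame(chrom = chrom, position = pos,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate a replicate Ct table with known fold changes
#'
#' Per replicate, `Ct = baseline(gene) - log2(fold(gene, condition)) +
#' Normal(0, noise_sd)`; with `noise_sd = 0`, [ddct()] on the output
#' recovers the fold map exactly (given the control column of the fold map
#' is 1).
#'
#' @param fold_map numeric matrix of true folds, rows = genes (rownames),
#'   columns = conditions (colnames); the `ref_gene` row must be all 1.
#' @param ref_gene reference transcript (a row of `fold_map`).
#' @param n_rep replicates per condition x gene.
#' @param noise_sd Ct noise SD in cycles.
#' @param seed integer seed.
#' @return a data.frame with `condition`, `gene`, `replicate`, `ct`.
#' @export
simulateCt <- function(fold_map, ref_gene, n_rep = 3L, noise_sd = 0,
                       seed) {
  stopifnot(is.matrix(fold_map), !is.null(rownames(fold_map)),
            !is.null(colnames(fold_map)))
  if (!ref_gene %in% rownames(fold_map))
    stop("reference gene missing from fold_map", call. = FALSE)
  if (any(fold_map[ref_gene, ] != 1))
    stop("reference gene fold must be 1 in every condition", call. = FALSE)
  if (any(fold_map <= 0)) stop("folds must be positive", call. = FALSE)
  genes <- rownames(fold_map)
  conditions <- colnames(fold_map)
  with_seed(seed, {
    baseline <- setNames(runif(length(genes), 18, 28), genes)
    grid <- expand.grid(replicate = seq_len(n_rep), gene = genes,
                        condition = conditions, stringsAsFactors = FALSE)
    grid$ct <- baseline[grid$gene] -
      log2(fold_map[cbind(grid$gene, grid$condition)]) +
      rnorm(nrow(grid), 0, noise_sd)
    grid[c("condition", "gene", "replicate", "ct")]
  })
}

#' Simulate a complete synthetic study
#'
#' Runs every generator under the fan-out of the master seed and returns
#' all pieces plus the planted truth: a genome with sequence, gene models,
#' a TSS-enriched peak set `peaksA` (used as both ChIP replicates), a
#' co-occurring set `peaksB` with exactly planted overlap fraction, motifs
#' planted in `peaksA`, an expression table with shifted TSS-proximal
#' target genes, and a Ct table.
#'
#' @param config a [syntheticConfig()].
#' @return a list with elements `genome`, `seqs`, `genes`, `peaksA`,
#'   `peaksB`, `expr`, `ct`, `truth` (list of all planted parameters).
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "reachmap_config"))
  s <- config$seed
  gen <- simulateGenome(config$chrom_lengths, config$gc,
                        seed = sub_seed(s, 1L))
  genes <- simulateGenes(gen$genome, config$n_genes,
                         seed = sub_seed(s, 2L))
  peaksA <- simulatePeaks(gen$genome, genes, config$n_peaks,
                          config$peak_length, config$tss_fraction,
                          config$target_max_dist, seed = sub_seed(s, 3L))
  peaksB <- simulateCooccurringPeaks(peaksA, config$co_overlap_fraction,
                                     config$peak_length,
                                     seed = sub_seed(s, 4L))
  pm <- plantMotifs(gen$seqs, peaksA, motifDef(), config$motif_prob,
                    seed = sub_seed(s, 5L))
  targets <- assignTargetGenes(peaksA, genes, config$target_max_dist)
  expr <- simulateExpression(genes$gene_id, targets$targets,
                             config$lfc_shift, config$lfc_sigma,
                             seed = sub_seed(s, 6L))
  fold_map <- cbind(control = c(1, 1, 1),
                    knockdown = c(2, 4, 1))
  rownames(fold_map) <- c("tA", "tB", "REF")
  ct <- simulateCt(fold_map, ref_gene = "REF", n_rep = 3L, noise_sd = 0.1,
                   seed = sub_seed(s, 7L))
  list(genome = gen$genome, seqs = pm$seqs, genes = genes,
       peaksA = peaksA, peaksB = peaksB, expr = expr, ct = ct,
       truth = list(seed = s,
                    co_overlap_fraction = config$co_overlap_fraction,
                    n_A_hit_planted = round(config$co_overlap_fraction *
                                              length(peaksA)),
                    tss_fraction = config$tss_fraction,
                    lfc_shift = config$lfc_shift,
                    lfc_sigma = config$lfc_sigma,
                    motif_prob = config$motif_prob,
                    planted_motifs = pm$planted,
                    target_genes = targets$targets,
                    ct_fold_map = fold_map))
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits `genome.chrom.sizes`, `genome.fa`, `genes.bed`, `peaksA.bed`,
#' `peaksB.bed`, `expr.tsv`, `ct.tsv` and `truth.json`.
#'
#' @param study a [simulateStudy()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write.table(data.frame(GenomeInfoDb::seqnames(study$genome),
                         GenomeInfoDb::seqlengths(study$genome)),
              p("genome.chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  Biostrings::writeXStringSet(study$seqs, p("genome.fa"))
  genes_bed <- study$genes
  genes_bed$name <- genes_bed$gene_id
  genes_bed$gene_id <- NULL
  genes_bed$tss <- NULL
  writeBed(genes_bed, p("genes.bed"))
  writeBed(study$peaksA, p("peaksA.bed"))
  writeBed(study$peaksB, p("peaksB.bed"))
  write.table(study$expr[c("gene_id", "log2fc")], p("expr.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$ct, p("ct.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- study$truth
  truth$planted_motifs <- NULL
  truth$ct_fold_map <- as.data.frame(truth$ct_fold_map)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
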