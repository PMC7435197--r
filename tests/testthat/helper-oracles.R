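# Brute-force per-base oracles and tiny fixture builders. Everything here
# is deliberately naive (boolean base vectors, all-pairs loops) so it stays
# independent of the interval algebra it is used to check.

library(GenomicRanges)

toy_seqinfo <- function(lengths = c(chrT = 100000L)) {
  GenomeInfoDb::Seqinfo(names(lengths), as.integer(lengths))
}

# random interval set on a small genome, via plain base R
random_intervals <- function(n, genome, max_len = 500L) {
  sl <- GenomeInfoDb::seqlengths(genome)
  chrom <- sample(names(sl), n, replace = TRUE)
  w <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(sl[[chrom[i]]] - w[i] + 1L, 1L), integer(1))
  GRanges(chrom, IRanges(start, width = w), seqinfo = genome)
}

# per-chromosome logical coverage vectors
coverage_bool <- function(gr, genome) {
  sl <- GenomeInfoDb::seqlengths(genome)
  out <- lapply(sl, function(L) logical(L))
  for (i in seq_along(gr)) {
    ch <- as.character(seqnames(gr))[i]
    out[[ch]][start(gr)[i]:end(gr)[i]] <- TRUE
  }
  out
}

oracle_covered_bp <- function(gr, genome)
  sum(vapply(coverage_bool(gr, genome), sum, numeric(1)))

oracle_intersect_bp <- function(A, B, genome) {
  ca <- coverage_bool(A, genome)
  cb <- coverage_bool(B, genome)
  sum(vapply(names(ca), function(ch) sum(ca[[ch]] & cb[[ch]]), numeric(1)))
}

oracle_union_bp <- function(A, B, genome) {
  ca <- coverage_bool(A, genome)
  cb <- coverage_bool(B, genome)
  sum(vapply(names(ca), function(ch) sum(ca[[ch]] | cb[[ch]]), numeric(1)))
}

# number of A intervals sharing >= 1 base with any B interval
oracle_n_hit <- function(A, B, genome) {
  cb <- coverage_bool(B, genome)
  sum(vapply(seq_along(A), function(i) {
    ch <- as.character(seqnames(A))[i]
    any(cb[[ch]][start(A)[i]:end(A)[i]])
  }, logical(1)))
}

# all-pairs signed TSS distance table (anchor = start + floor(width/2))
oracle_tss_pairs <- function(peaks, genes, max_dist) {
  anchors <- start(peaks) + width(peaks) %/% 2L
  tss <- ifelse(as.character(strand(genes)) == "-", end(genes),
                start(genes))
  res <- NULL
  for (i in seq_along(peaks)) for (j in seq_along(genes)) {
    if (as.character(seqnames(peaks))[i] !=
        as.character(seqnames(genes))[j]) next
    d <- anchors[i] - tss[j]
    if (as.character(strand(genes))[j] == "-") d <- -d
    if (abs(d) < max_dist)
      res <- rbind(res, data.frame(peak = i, gene_id = genes$gene_id[j],
                                   distance = d))
  }
  res
}

# per-base category map with promoter > gene body > downstream precedence
oracle_feature_category <- function(peaks, genes, genome,
                                    promoter_up = 3000L,
                                    downstream_bp = 3000L) {
  sl <- GenomeInfoDb::seqlengths(genome)
  maps <- lapply(sl, function(L) rep("intergenic", L))
  clamp <- function(x, L) pmin(pmax(x, 1L), L)
  paint <- function(maps, ch, from, to, lab, only_over) {
    L <- length(maps[[ch]])
    if (to < 1 || from > L) return(maps)
    idx <- clamp(from, L):clamp(to, L)
    idx <- idx[maps[[ch]][idx] %in% only_over]
    maps[[ch]][idx] <- lab
    maps
  }
  for (j in seq_along(genes)) {
    ch <- as.character(seqnames(genes))[j]
    maps <- paint(maps, ch, start(genes)[j], end(genes)[j], "gene_body",
                  c("intergenic", "downstream"))
  }
  for (j in seq_along(genes)) {
    ch <- as.character(seqnames(genes))[j]
    minus <- as.character(strand(genes))[j] == "-"
    dn <- if (minus) c(start(genes)[j] - downstream_bp,
                       start(genes)[j] - 1L)
          else c(end(genes)[j] + 1L, end(genes)[j] + downstream_bp)
    maps <- paint(maps, ch, dn[1], dn[2], "downstream", "intergenic")
  }
  for (j in seq_along(genes)) {
    ch <- as.character(seqnames(genes))[j]
    minus <- as.character(strand(genes))[j] == "-"
    pr <- if (minus) c(end(genes)[j] + 1L, end(genes)[j] + promoter_up)
          else c(start(genes)[j] - promoter_up, start(genes)[j] - 1L)
    maps <- paint(maps, ch, pr[1], pr[2], "promoter",
                  c("intergenic", "downstream", "gene_body"))
  }
  anchors <- start(peaks) + width(peaks) %/% 2L
  vapply(seq_along(peaks), function(i)
    maps[[as.character(seqnames(peaks))[i]]][anchors[i]], character(1))
}

# window-by-window motif oracle for concrete and IUPAC consensi
iupac_expand <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                  S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                  D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

oracle_scan_one_strand <- function(seq_chars, motif_chars) {
  k <- length(motif_chars)
  n <- length(seq_chars)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(n - k + 1)) {
    win <- seq_chars[p:(p + k - 1)]
    match <- all(vapply(seq_len(k), function(i)
      win[i] %in% strsplit(iupac_expand[[motif_chars[i]]], "")[[1]],
      logical(1)))
    if (match) hits <- c(hits, p)
  }
  hits
}

revcomp_chars <- function(chars)
  rev(unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars]))

oracle_scan <- function(sequence, consensus) {
  sc <- strsplit(toupper(as.character(sequence)), "")[[1]]
  mc <- strsplit(toupper(consensus), "")[[1]]
  fwd <- oracle_scan_one_strand(sc, mc)
  rcm <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(consensus))), "")[[1]]
  if (identical(mc, rcm)) {
    data.frame(position = fwd, strand = rep("+", length(fwd)))
  } else {
    rev_hits <- oracle_scan_one_strand(sc, rcm)
    out <- data.frame(position = c(fwd, rev_hits),
                      strand = c(rep("+", length(fwd)),
                                 rep("-", length(rev_hits))))
    out[order(out$position, out$strand), , drop = FALSE]
  }
}

# simple gene fixture: genes at known coordinates on one chromosome
fixture_genes <- function(genome, starts, ends, strands,
                          ids = sprintf("g%02d", seq_along(starts))) {
  gr <- GRanges(GenomeInfoDb::seqnames(genome)[1],
                IRanges(starts, ends), strand = strands, seqinfo = genome)
  gr$gene_id <- ids
  gr$tss <- ifelse(strands == "-", ends, starts)
  gr
}
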