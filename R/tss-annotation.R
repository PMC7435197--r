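#' Peak anchor positions
#'
#' Reduces each peak to a single anchor base used for all TSS-proximity
#' logic. The default anchor is the midpoint
#' (`start + floor(width / 2)`); with `anchor = "summit"` a metadata column
#' `summit` (absolute 1-based position) is used when present, falling back
#' to the midpoint otherwise (plain BED peak files carry no summit).
#'
#' @param peaks a `GRanges`.
#' @param anchor `"midpoint"` or `"summit"`.
#' @return integer vector of 1-based anchor positions.
#' @export
peakAnchors <- function(peaks, anchor = c("midpoint", "summit")) {
  anchor <- match.arg(anchor)
  mid <- GenomicRanges::start(peaks) + GenomicRanges::width(peaks) %/% 2L
  if (anchor == "summit" && "summit" %in% names(S4Vectors::mcols(peaks))) {
    s <- peaks$summit
    ifelse(is.na(s), mid, as.integer(s))
  } else mid
}

anchor_granges <- function(peaks, anchor = "midpoint") {
  pos <- peakAnchors(peaks, anchor)
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                         IRanges::IRanges(pos, width = 1L),
                         seqinfo = GenomeInfoDb::seqinfo(peaks))
}

#' Signed distance from a peak anchor to a TSS
#'
#' Oriented in gene coordinates: negative means the anchor lies upstream
#' (5') of the TSS, positive downstream, regardless of which genomic
#' strand the gene is on.
#'
#' @param peak a `GRanges` of length 1 (or parallel to `gene`).
#' @param gene a gene-model `GRanges` (from [readGeneModels()]) parallel to
#'   `peak`.
#' @param anchor anchor rule, see [peakAnchors()].
#' @return signed integer distance(s) in bp.
#' @export
signedTssDistance <- function(peak, gene, anchor = "midpoint") {
  if (length(peak) != length(gene))
    stop("peak and gene must be parallel", call. = FALSE)
  if (any(as.character(GenomeInfoDb::seqnames(peak)) !=
          as.character(GenomeInfoDb::seqnames(gene))))
    stop("peak and gene on different chromosomes", call. = FALSE)
  d <- peakAnchors(peak, anchor) - tssPositions(gene)
  as.integer(ifelse(as.character(GenomicRanges::strand(gene)) == "-", -d, d))
}

#' Assign TSS-proximal target genes to peaks
#'
#' A gene is a target when some peak anchor lies strictly within
#' `max_dist` bp of its TSS (`|signed distance| < max_dist`; the default
#' 1000 bp encodes the "affinity within 1 kb of the TSS" rule). A peak may
#' qualify several genes and vice versa; all qualifying pairs are listed.
#'
#' @param peaks a `GRanges`.
#' @param genes gene models from [readGeneModels()].
#' @param max_dist strict distance bound in bp (default 1000).
#' @param upstream_only if `TRUE`, only anchors at or upstream of the TSS
#'   (signed distance <= 0) qualify.
#' @param anchor anchor rule, see [peakAnchors()].
#' @return a list with `targets` (sorted unique target gene ids) and
#'   `assignments` (data.frame: peak index, gene_id, signed distance).
#' @export
assignTargetGenes <- function(peaks, genes, max_dist = 1000,
                              upstream_only = FALSE, anchor = "midpoint") {
  if (length(genes) == 0L) stop("empty gene table", call. = FALSE)
  check_same_genome(peaks, genes)
  check_scalar_number(max_dist, "max_dist", lower = 1)
  tss <- tssPositions(genes)
  half <- as.integer(max_dist) - 1L
  sl <- GenomeInfoDb::seqlengths(genes)[
    as.character(GenomeInfoDb::seqnames(genes))]
  win <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(genes),
    IRanges::IRanges(pmax(1L, tss - half), pmin(tss + half, sl)),
    seqinfo = GenomeInfoDb::seqinfo(genes))
  hits <- GenomicRanges::findOverlaps(anchor_granges(peaks, anchor), win)
  pk <- S4Vectors::queryHits(hits)
  gn <- S4Vectors::subjectHits(hits)
  dist <- signedTssDistance(peaks[pk], genes[gn], anchor)
  if (upstream_only) {
    keep <- dist <= 0L
    pk <- pk[keep]; gn <- gn[keep]; dist <- dist[keep]
  }
  assignments <- data.frame(peak = pk, gene_id = genes$gene_id[gn],
                            distance = dist, stringsAsFactors = FALSE)
  list(targets = sort(unique(assignments$gene_id)),
       assignments = assignments)
}

# Precedence-resolved category maps: promoter > gene body > downstream.
feature_maps <- function(genes, promoter_upstream, promoter_downstream,
                         downstream_bp) {
  prom <- GenomicRanges::reduce(GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(genes, upstream = promoter_upstream,
                             downstream = promoter_downstream))))
  body <- GenomicRanges::setdiff(GenomicRanges::reduce(genes), prom)
  down <- GenomicRanges::reduce(GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(genes, width = downstream_bp, start = FALSE))))
  down <- GenomicRanges::setdiff(
    down, GenomicRanges::union(prom, GenomicRanges::reduce(genes)))
  list(promoter = prom, gene_body = body, downstream = down)
}

#' Genomic feature distribution of peak anchors
#'
#' Classifies each peak anchor into exactly one of promoter, gene body,
#' downstream or intergenic (precedence in that order) and reports the
#' fractions, alongside the genome-wide base-pair fraction of each
#' category — the "overall genomic prevalence" baseline against which
#' promoter enrichment is judged.
#'
#' @param peaks non-empty `GRanges`.
#' @param genes gene models on the same genome.
#' @param promoter_upstream,promoter_downstream promoter window around the
#'   TSS in gene orientation (defaults 3000 / 0 bp, i.e. promoters are the
#'   3 kb strictly upstream of the TSS).
#' @param downstream_bp length of the "downstream" window past the gene 3'
#'   end (default 3000 bp).
#' @param anchor anchor rule, see [peakAnchors()].
#' @return a list with `peak_fractions` and `genome_fractions` (each a
#'   named numeric vector over the four categories, summing to 1) and
#'   `category` (per-peak factor).
#' @export
featureDistribution <- function(peaks, genes, promoter_upstream = 3000,
                                promoter_downstream = 0,
                                downstream_bp = 3000,
                                anchor = "midpoint") {
  if (length(peaks) == 0L) stop("empty peak set", call. = FALSE)
  check_has_genome(peaks)
  check_same_genome(peaks, genes)
  cats <- c("promoter", "gene_body", "downstream", "intergenic")
  maps <- feature_maps(genes, promoter_upstream, promoter_downstream,
                       downstream_bp)
  anchors <- anchor_granges(peaks, anchor)
  category <- rep("intergenic", length(peaks))
  for (nm in rev(names(maps)))  # promoter applied last => wins
    category[GenomicRanges::countOverlaps(anchors, maps[[nm]]) > 0L] <- nm
  category <- factor(category, levels = cats)
  total_bp <- sum(as.numeric(GenomeInfoDb::seqlengths(peaks)))
  gbp <- vapply(maps, function(m)
    sum(as.numeric(GenomicRanges::width(m))), numeric(1))
  genome_fractions <- c(gbp, intergenic = total_bp - sum(gbp)) / total_bp
  names(genome_fractions) <- cats
  peak_fractions <- as.numeric(table(category)) / length(peaks)
  names(peak_fractions) <- cats
  list(peak_fractions = peak_fractions,
       genome_fractions = genome_fractions,
       category = category)
}

#' TSS-relative density profile of peak anchors
#'
#' For every peak anchor the nearest TSS on the same chromosome is found
#' (ties broken toward the gene earlier in sorted order), the signed
#' distance is taken in gene orientation, and distances within
#' `[-window, window)` are binned into half-open bins of width `bin` and
#' normalised to unit mass.
#'
#' @param peaks a `GRanges`.
#' @param genes gene models on the same genome.
#' @param window half-width of the profile in bp (default 10000).
#' @param bin bin width in bp (default 100); must divide `2 * window`.
#' @param anchor anchor rule, see [peakAnchors()].
#' @return a data.frame with `bin_center` and `density` (summing to 1, or
#'   all zero with a warning when no anchor falls in-window).
#' @export
tssProfile <- function(peaks, genes, window = 10000, bin = 100,
                       anchor = "midpoint") {
  check_scalar_number(window, "window", lower = 1)
  check_scalar_number(bin, "bin", lower = 1)
  if ((2 * window) %% bin != 0)
    stop("bin must divide 2 * window", call. = FALSE)
  check_same_genome(peaks, genes)
  genes <- GenomicRanges::sort(genes, ignore.strand = TRUE)
  tssGR <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(genes),
    IRanges::IRanges(tssPositions(genes), width = 1L),
    seqinfo = GenomeInfoDb::seqinfo(genes))
  anchors <- anchor_granges(peaks, anchor)
  hits <- GenomicRanges::nearest(anchors, tssGR, select = "all")
  # earliest gene in sorted order wins ties
  first <- tapply(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits),
                  min)
  qi <- as.integer(names(first))
  gi <- as.integer(first)
  d <- signedTssDistance(peaks[qi], genes[gi], anchor)
  nbins <- as.integer(2 * window / bin)
  idx <- floor((d + window) / bin) + 1
  idx <- idx[idx >= 1 & idx <= nbins]
  counts <- tabulate(idx, nbins)
  if (sum(counts) == 0) {
    warning("no peak anchor within the profile window of any TSS",
            call. = FALSE)
    dens <- rep(0, nbins)
  } else dens <- counts / sum(counts)
  data.frame(bin_center = -window + (seq_len(nbins) - 0.5) * bin,
             density = dens)
}

#' Overlap test of two target-gene sets over a gene universe
#'
#' Cross-tabulates membership in `a` versus membership in `b` over the
#' declared universe and tests association with [chi2Yates()]; also
#' reports `|a intersect b| / |a|`, the fraction of `a`'s targets shared
#' with `b` (e.g. the fraction of ligase target genes also occupied by a
#' co-factor).
#'
#' @param a,b character vectors of gene ids, both subsets of `universe`.
#' @param universe character vector of all considered gene ids.
#' @return a list with `contingency` ([ContingencyResult-class]),
#'   `overlap_fraction`, and the set sizes.
#' @export
geneSetOverlapTest <- function(a, b, universe) {
  universe <- unique(universe)
  a <- unique(a); b <- unique(b)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (length(a) == 0L || length(b) == 0L)
    stop("gene sets must be non-empty", call. = FALSE)
  if (!all(a %in% universe) || !all(b %in% universe))
    stop("gene sets must be subsets of the universe", call. = FALSE)
  nab <- length(intersect(a, b))
  ct <- chi2Yates(nab, length(a) - nab, length(b) - nab,
                  length(universe) - length(a) - length(b) + nab)
  list(contingency = ct, overlap_fraction = nab / length(a),
       n_a = length(a), n_b = length(b), n_universe = length(universe),
       n_intersect = nab)
}
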