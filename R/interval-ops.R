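#' Sort and merge an interval set
#'
#' Sorts by (chromosome, start, end) and coalesces overlapping or abutting
#' intervals on the same chromosome into single intervals, leaving total
#' covered base pairs unchanged. Idempotent.
#'
#' @param gr a `GRanges`.
#' @return a sorted, merged `GRanges` (metadata columns are dropped, as the
#'   merged intervals no longer correspond to single inputs).
#' @export
sortAndMerge <- function(gr) {
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Pairwise co-localization summary of two interval sets
#'
#' Computes interval-anchored hit counts/fractions in both directions
#' (an interval "hits" when it shares at least one base with an interval of
#' the other set), the total intersecting base pairs of the merged sets,
#' and the base-wise Jaccard index. Counts are computed on the sets as
#' given; merge first if you want region-level denominators.
#'
#' @param A,B `GRanges` on the same genome.
#' @return an [OverlapResult-class].
#' @examples
#' suppressPackageStartupMessages(library(GenomicRanges))
#' si <- GenomeInfoDb::Seqinfo("chrT", 1000L)
#' A <- GRanges("chrT", IRanges(c(1, 21, 41, 61), c(10, 30, 50, 70)),
#'              seqinfo = si)
#' B <- GRanges("chrT", IRanges(c(6, 26), c(8, 45)), seqinfo = si)
#' overlapStats(A, B)
#' @export
overlapStats <- function(A, B) {
  check_same_genome(A, B)
  nAHit <- sum(GenomicRanges::countOverlaps(A, B) > 0L)
  nBHit <- sum(GenomicRanges::countOverlaps(B, A) > 0L)
  rA <- GenomicRanges::reduce(A)
  rB <- GenomicRanges::reduce(B)
  bpInt <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(rA, rB))))
  bpUni <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::union(rA, rB))))
  methods::new("OverlapResult",
    nA = length(A), nB = length(B),
    nAHit = as.integer(nAHit), nBHit = as.integer(nBHit),
    fracAHit = nAHit / length(A), fracBHit = nBHit / length(B),
    bpIntersect = bpInt, bpUnion = bpUni,
    jaccard = if (bpUni > 0) bpInt / bpUni else NaN)
}

#' Consensus of two replicate peak sets
#'
#' Two replicate-consensus rules are supported. `"anchored"` returns the
#' intervals of `A` (unmodified, metadata kept) that overlap at least one
#' interval of `B` — the peak-anchored reading of a replicate Venn
#' intersection. `"intersect"` returns the base-wise intersection of the
#' merged sets. The underlying data do not dictate one rule; both are
#' exposed and the choice should be recorded with the analysis.
#'
#' @param A,B `GRanges` on the same genome.
#' @param mode `"anchored"` (default) or `"intersect"`.
#' @return a `GRanges`.
#' @export
consensusPeaks <- function(A, B, mode = c("anchored", "intersect")) {
  mode <- match.arg(mode)
  check_same_genome(A, B)
  if (mode == "anchored") {
    A[GenomicRanges::countOverlaps(A, B) > 0L]
  } else {
    GenomicRanges::intersect(GenomicRanges::reduce(A),
                             GenomicRanges::reduce(B))
  }
}
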