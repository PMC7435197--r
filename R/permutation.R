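# Core relocation step: draws new uniform starts for each interval within
# its own chromosome, using the caller's RNG stream. Lengths and
# per-chromosome counts are preserved by construction.
permute_core <- function(gr, allow_self_overlap = TRUE, max_retry = 1000L) {
  sl <- GenomeInfoDb::seqlengths(gr)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  w <- GenomicRanges::width(gr)
  if (any(w > sl[chrom]))
    stop("interval longer than its chromosome", call. = FALSE)
  new_start <- integer(length(gr))
  for (chr in sort(unique(chrom))) {
    idx <- which(chrom == chr)
    L <- sl[[chr]]
    if (allow_self_overlap || length(idx) == 1L) {
      st <- runif_int(length(idx), 1L, L - w[idx] + 1L)
    } else {
      # sequential placement, largest interval first; restart the
      # chromosome when an interval cannot be placed
      ord <- idx[order(w[idx], decreasing = TRUE)]
      st_by_i <- NULL
      for (restart in seq_len(max_retry)) {
        ps <- integer(0); pe <- integer(0)
        st_by_i <- integer(length(ord))
        ok <- TRUE
        for (k in seq_along(ord)) {
          wk <- w[ord[k]]
          placed <- FALSE
          for (try in seq_len(100L)) {
            s <- runif_int(1L, 1L, L - wk + 1L)
            if (!any(s <= pe & (s + wk - 1L) >= ps)) {
              ps <- c(ps, s); pe <- c(pe, s + wk - 1L)
              st_by_i[k] <- s
              placed <- TRUE
              break
            }
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (ok) break
        if (restart == max_retry)
          stop("non-overlapping placement infeasible within ", max_retry,
               " restarts on ", chr, call. = FALSE)
      }
      st <- st_by_i[match(idx, ord)]
    }
    new_start[idx] <- st
  }
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(new_start, width = w),
                                seqinfo = GenomeInfoDb::seqinfo(gr))
  stopifnot(identical(sort(GenomicRanges::width(out)), sort(w)))
  out
}

#' Intra-chromosomal permutation of an interval set
#'
#' Relocates every interval to a uniformly drawn position within its own
#' chromosome, preserving the per-chromosome interval count and the
#' multiset of interval lengths — the "randomized peaks of equal number and
#' size" null used throughout the package. Deterministic given `seed`.
#'
#' @param gr a `GRanges` with a genome attached.
#' @param seed integer RNG seed; `NULL` uses the current RNG stream.
#' @param allow_self_overlap if `FALSE`, placements are rejection-resampled
#'   per chromosome until the relocated intervals are mutually disjoint
#'   (capped at `max_retry` attempts).
#' @param max_retry retry cap for the non-overlapping variant.
#' @return a relocated `GRanges` (metadata dropped).
#' @export
permuteIntrachrom <- function(gr, seed = NULL, allow_self_overlap = TRUE,
                              max_retry = 1000L) {
  check_has_genome(gr)
  with_seed(seed, permute_core(gr, allow_self_overlap, max_retry))
}

overlap_statistic <- function(A, B, statistic, rB = NULL) {
  if (statistic %in% c("frac_A_hit", "n_A_hit")) {
    nhit <- sum(GenomicRanges::countOverlaps(A, B) > 0L)
    return(if (statistic == "frac_A_hit") nhit / length(A)
           else as.numeric(nhit))
  }
  if (is.null(rB)) rB <- GenomicRanges::reduce(B)
  rA <- GenomicRanges::reduce(A)
  bpInt <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(rA, rB))))
  switch(statistic,
         bp_intersect = bpInt,
         jaccard = {
           bpUni <- sum(as.numeric(GenomicRanges::width(
             GenomicRanges::union(rA, rB))))
           if (bpUni > 0) bpInt / bpUni else NaN
         },
         stop("unknown statistic: ", statistic, call. = FALSE))
}

# Vectorised permutation null for the interval-hit statistics: all n_perm
# relocations are drawn in one pass and resolved with a single overlap
# query. Only valid when relocated intervals may overlap each other
# (allow_self_overlap = TRUE), since hits are counted per interval.
perm_null_hits <- function(A, B, n_perm, statistic) {
  sl <- GenomeInfoDb::seqlengths(A)
  chrom <- as.character(GenomeInfoDb::seqnames(A))
  w <- GenomicRanges::width(A)
  if (any(w > sl[chrom]))
    stop("interval longer than its chromosome", call. = FALSE)
  n <- length(A)
  starts <- integer(n * n_perm)
  offsets <- (seq_len(n_perm) - 1L) * n
  for (ch in sort(unique(chrom))) {
    idx <- which(chrom == ch)
    hi <- sl[[ch]] - w[idx] + 1L
    draws <- runif_int(length(idx) * n_perm, 1L, rep(hi, n_perm))
    starts[rep(idx, n_perm) + rep(offsets, each = length(idx))] <- draws
  }
  big <- GenomicRanges::GRanges(
    rep(chrom, n_perm),
    IRanges::IRanges(starts, width = rep(w, n_perm)),
    seqinfo = GenomeInfoDb::seqinfo(A))
  hit <- GenomicRanges::countOverlaps(big, B) > 0L
  per_rep <- as.numeric(rowsum(as.integer(hit),
                               rep(seq_len(n_perm), each = n)))
  if (statistic == "frac_A_hit") per_rep / n else per_rep
}

#' Permutation-calibrated fold enrichment of interval co-localization
#'
#' Compares the observed co-localization of a query set `A` with a fixed
#' landscape `B` against an intra-chromosomal permutation null: `A` is
#' relocated `n_perm` times ([permuteIntrachrom()]), the chosen statistic is
#' recomputed for each relocation, and the observed value is summarised as
#' a fold enrichment (observed / null mean) with an add-one empirical
#' p-value `(1 + #{null at least as extreme}) / (n_perm + 1)`.
#'
#' @param A query `GRanges` (this set is permuted).
#' @param B landscape `GRanges` (held fixed).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param statistic one of `"frac_A_hit"`, `"n_A_hit"`, `"bp_intersect"`,
#'   `"jaccard"`.
#' @param tail `"greater"` tests enrichment, `"less"` depletion.
#' @param allow_self_overlap passed to [permuteIntrachrom()].
#' @return a [PermutationResult-class].
#' @export
foldEnrichment <- function(A, B, n_perm = 1000L, seed,
                           statistic = c("frac_A_hit", "n_A_hit",
                                         "bp_intersect", "jaccard"),
                           tail = c("greater", "less"),
                           allow_self_overlap = TRUE) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  check_scalar_number(n_perm, "n_perm", lower = 1)
  if (length(A) == 0L) stop("query set is empty", call. = FALSE)
  check_same_genome(A, B)
  check_has_genome(A, "query set")
  observed <- overlap_statistic(A, B, statistic)
  null <- with_seed(seed, {
    if (statistic %in% c("frac_A_hit", "n_A_hit") && allow_self_overlap) {
      perm_null_hits(A, B, n_perm, statistic)
    } else {
      rB <- GenomicRanges::reduce(B)
      vapply(seq_len(n_perm), function(i) {
        overlap_statistic(permute_core(A, allow_self_overlap), B,
                          statistic, rB = rB)
      }, numeric(1))
    }
  })
  null_mean <- mean(null)
  null_sd <- sd(null)
  if (is.na(null_sd)) null_sd <- 0
  k <- if (tail == "greater") sum(null >= observed) else sum(null <= observed)
  flags <- character(0)
  if (null_mean == 0 && observed > 0) {
    fold <- Inf
    flags <- "zero-null"
  } else if (null_mean == 0) {
    fold <- 1
    flags <- "zero-signal"
  } else {
    fold <- observed / null_mean
  }
  methods::new("PermutationResult",
    observed = observed, nullMean = null_mean, nullSd = null_sd,
    fold = fold, pEmpirical = (1 + k) / (n_perm + 1),
    nPerm = as.integer(n_perm),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    tail = tail, statistic = statistic, flags = flags)
}

#' Chi-squared test of a 2x2 table with Yates' continuity correction
#'
#' `chi2 = N * (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))`, with
#' the corrected deviation clamped at zero so the statistic is never
#' negative; p from the upper tail of the chi-squared distribution on one
#' degree of freedom. All four margins must be positive.
#'
#' @param a,b,c,d non-negative cell counts, row-wise
#'   (`a` = both conditions, `d` = neither).
#' @return a [ContingencyResult-class].
#' @examples
#' chi2Yates(10, 20, 20, 10)
#' @export
chi2Yates <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop("all margins of the 2x2 table must be positive", call. = FALSE)
  dev <- max(abs(a * d - b * c) - n / 2, 0)
  chi2 <- n * dev^2 / prod(margins)
  methods::new("ContingencyResult",
    table = matrix(as.integer(cells), 2, 2, byrow = TRUE,
                   dimnames = list(c("in", "out"), c("in", "out"))),
    chi2 = chi2, pValue = pchisq(chi2, df = 1, lower.tail = FALSE),
    df = 1L)
}

#' Association of regions with a positive and a negative chromatin mark
#'
#' Runs the permutation framework twice — enrichment (`tail = "greater"`)
#' of `regions` against `mark_pos` and depletion (`tail = "less"`) against
#' `mark_neg` — and additionally cross-tabulates the regions by whether
#' each is hit by the positive and/or the negative mark, testing the 2x2
#' with [chi2Yates()]. This is the analysis pattern for asking whether
#' domains sit in active (e.g. H3K27ac) and avoid repressed (e.g.
#' H3K27me3) chromatin.
#'
#' @param regions query `GRanges` (non-empty).
#' @param mark_pos,mark_neg landscape `GRanges` of the two marks.
#' @param n_perm,seed,statistic,allow_self_overlap passed to
#'   [foldEnrichment()].
#' @return a list with elements `pos`, `neg` ([PermutationResult-class])
#'   and `contingency` ([ContingencyResult-class]).
#' @export
markAssociation <- function(regions, mark_pos, mark_neg, n_perm = 1000L,
                            seed, statistic = "frac_A_hit",
                            allow_self_overlap = TRUE) {
  if (length(regions) == 0L) stop("empty region set", call. = FALSE)
  pos <- foldEnrichment(regions, mark_pos, n_perm = n_perm, seed = seed,
                        statistic = statistic, tail = "greater",
                        allow_self_overlap = allow_self_overlap)
  neg <- foldEnrichment(regions, mark_neg, n_perm = n_perm, seed = seed,
                        statistic = statistic, tail = "less",
                        allow_self_overlap = allow_self_overlap)
  hit_pos <- GenomicRanges::countOverlaps(regions, mark_pos) > 0L
  hit_neg <- GenomicRanges::countOverlaps(regions, mark_neg) > 0L
  tab <- tryCatch(
    chi2Yates(sum(hit_pos & hit_neg), sum(hit_pos & !hit_neg),
              sum(!hit_pos & hit_neg), sum(!hit_pos & !hit_neg)),
    error = function(e) {
      warning("degenerate 2x2 (zero margin); contingency test skipped",
              call. = FALSE)
      NULL
    })
  list(pos = pos, neg = neg, contingency = tab)
}
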