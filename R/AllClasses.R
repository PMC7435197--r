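#' Overlap statistics between two interval sets
#'
#' Container for the pairwise co-localization summary returned by
#' [overlapStats()]: interval-anchored hit counts and fractions in both
#' directions, total intersecting base pairs, and the base-wise Jaccard
#' index.
#'
#' @slot nA,nB number of intervals in each input set.
#' @slot nAHit,nBHit number of intervals of one set overlapping at least one
#'   interval of the other (at least one shared base).
#' @slot fracAHit,fracBHit the corresponding fractions; `NaN` for an empty set.
#' @slot bpIntersect,bpUnion intersecting / union base pairs of the merged
#'   sets.
#' @slot jaccard `bpIntersect / bpUnion`; symmetric in the two sets.
#' @aliases OverlapResult
#' @exportClass OverlapResult
setClass("OverlapResult",
  representation(
    nA = "integer", nB = "integer",
    nAHit = "integer", nBHit = "integer",
    fracAHit = "numeric", fracBHit = "numeric",
    bpIntersect = "numeric", bpUnion = "numeric",
    jaccard = "numeric"
  )
)

setValidity("OverlapResult", function(object) {
  ok <- function(f) is.nan(f) || (f >= 0 && f <= 1)
  if (!ok(object@fracAHit) || !ok(object@fracBHit) || !ok(object@jaccard))
    return("fractions and jaccard must lie in [0, 1]")
  if (object@bpIntersect > object@bpUnion)
    return("bpIntersect cannot exceed bpUnion")
  TRUE
})

#' Permutation-null calibration of a co-localization statistic
#'
#' Result of [foldEnrichment()] or [motifEnrichment()]: the observed
#' statistic, the mean and SD of its intra-chromosomal permutation null,
#' the fold enrichment (observed / null mean) and the add-one empirical
#' p-value `(1 + #{null at least as extreme}) / (nPerm + 1)`.
#'
#' @slot observed observed value of the chosen statistic.
#' @slot nullMean,nullSd moments of the permutation null.
#' @slot fold fold enrichment; `Inf` (flagged) when the null mean is zero
#'   while the observed value is positive, and 1 (flagged `"zero-signal"`)
#'   when both are zero.
#' @slot pEmpirical add-one empirical p-value in `(0, 1]`.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used.
#' @slot tail `"greater"` (enrichment) or `"less"` (depletion).
#' @slot statistic name of the statistic summarised.
#' @slot flags character vector of degeneracy flags (may be empty).
#' @aliases PermutationResult
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(
    observed = "numeric", nullMean = "numeric", nullSd = "numeric",
    fold = "numeric", pEmpirical = "numeric",
    nPerm = "integer", seed = "integer",
    tail = "character", statistic = "character", flags = "character"
  )
)

setValidity("PermutationResult", function(object) {
  if (object@pEmpirical <= 0 || object@pEmpirical > 1)
    return("pEmpirical must lie in (0, 1]")
  if (!is.infinite(object@fold) && object@fold < 0)
    return("fold enrichment must be non-negative")
  if (!object@tail %in% c("greater", "less"))
    return("tail must be 'greater' or 'less'")
  TRUE
})

#' Chi-squared test of a 2x2 table with Yates' continuity correction
#'
#' Result of [chi2Yates()]. The statistic is
#' `N * (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))` on one degree
#' of freedom, with the corrected deviation clamped at zero.
#'
#' @slot table the 2x2 integer table.
#' @slot chi2 the Yates-corrected statistic.
#' @slot pValue upper-tail chi-squared p-value, 1 df.
#' @slot df degrees of freedom (always 1).
#' @aliases ContingencyResult
#' @exportClass ContingencyResult
setClass("ContingencyResult",
  representation(table = "matrix", chi2 = "numeric", pValue = "numeric",
                 df = "integer")
)

setValidity("ContingencyResult", function(object) {
  if (object@chi2 < 0) return("chi2 must be non-negative")
  if (object@pValue < 0 || object@pValue > 1) return("pValue must lie in [0, 1]")
  TRUE
})

#' Wilcoxon rank-sum test result
#'
#' Result of [wilcoxonRankSum()]. `w` is the rank sum of the first sample
#' (mid-ranks for ties). The p-value is exact (from the tie-free null
#' distribution of the Mann-Whitney U) when no ties are present and the
#' enumeration is feasible, otherwise a tie-corrected normal approximation
#' with 0.5 continuity correction is used.
#'
#' @slot w rank sum of sample `x`.
#' @slot nX,nY sample sizes.
#' @slot pValue the p-value.
#' @slot method `"exact"` or `"normal-approx"`.
#' @slot alternative `"two.sided"`, `"greater"` or `"less"`.
#' @aliases RankSumResult
#' @exportClass RankSumResult
setClass("RankSumResult",
  representation(w = "numeric", nX = "integer", nY = "integer",
                 pValue = "numeric", method = "character",
                 alternative = "character")
)

setValidity("RankSumResult", function(object) {
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

# ---- generics / accessors ----------------------------------------------

#' Accessors for reachmap result objects
#'
#' @param x a result object.
#' @return a numeric scalar (or 2x2 matrix for `contingencyTable`).
#' @name reachmap-accessors
#' @aliases pValue pEmpirical enrichment observedStat nullMean nullSd
#'   contingencyTable
NULL

#' @rdname reachmap-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname reachmap-accessors
#' @export
setGeneric("pEmpirical", function(x) standardGeneric("pEmpirical"))
#' @rdname reachmap-accessors
#' @export
setGeneric("enrichment", function(x) standardGeneric("enrichment"))
#' @rdname reachmap-accessors
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))
#' @rdname reachmap-accessors
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))
#' @rdname reachmap-accessors
#' @export
setGeneric("nullSd", function(x) standardGeneric("nullSd"))
#' @rdname reachmap-accessors
#' @export
setGeneric("contingencyTable", function(x) standardGeneric("contingencyTable"))

#' @rdname reachmap-accessors
setMethod("pValue", "ContingencyResult", function(x) x@pValue)
#' @rdname reachmap-accessors
setMethod("pValue", "RankSumResult", function(x) x@pValue)
#' @rdname reachmap-accessors
setMethod("pEmpirical", "PermutationResult", function(x) x@pEmpirical)
#' @rdname reachmap-accessors
setMethod("enrichment", "PermutationResult", function(x) x@fold)
#' @rdname reachmap-accessors
setMethod("observedStat", "PermutationResult", function(x) x@observed)
#' @rdname reachmap-accessors
setMethod("nullMean", "PermutationResult", function(x) x@nullMean)
#' @rdname reachmap-accessors
setMethod("nullSd", "PermutationResult", function(x) x@nullSd)
#' @rdname reachmap-accessors
setMethod("contingencyTable", "ContingencyResult", function(x) x@table)

setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult\n")
  cat(sprintf("  A: %d intervals, %d hit (%.4f)\n",
              object@nA, object@nAHit, object@fracAHit))
  cat(sprintf("  B: %d intervals, %d hit (%.4f)\n",
              object@nB, object@nBHit, object@fracBHit))
  cat(sprintf("  bp intersect: %.0f / union: %.0f (jaccard %.4f)\n",
              object@bpIntersect, object@bpUnion, object@jaccard))
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult (", object@statistic, ", tail=", object@tail, ")\n",
      sep = "")
  cat(sprintf("  observed: %.6g  null: %.6g +/- %.6g (n=%d)\n",
              object@observed, object@nullMean, object@nullSd, object@nPerm))
  cat(sprintf("  fold enrichment: %.4g  empirical p: %.4g\n",
              object@fold, object@pEmpirical))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ContingencyResult", function(object) {
  cat("ContingencyResult (chi-squared, Yates' correction, 1 df)\n")
  print(object@table)
  cat(sprintf("  chi2 = %.4g, p = %.4g\n", object@chi2, object@pValue))
})

setMethod("show", "RankSumResult", function(object) {
  cat(sprintf("RankSumResult: W = %g (nX=%d, nY=%d), p = %.4g [%s, %s]\n",
              object@w, object@nX, object@nY, object@pValue, object@method,
              object@alternative))
})
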