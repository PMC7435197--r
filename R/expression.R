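#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Rank-sum test of two independent samples using mid-ranks for ties. The
#' p-value is exact — from the tie-free null distribution of the
#' Mann-Whitney U statistic — when there are no ties and the enumeration
#' space `choose(nX + nY, nX)` does not exceed 200,000; otherwise a normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction is used. The cutoff and correction are fixed constants so
#' results are deterministic across platforms.
#'
#' @param x,y numeric samples (non-empty, finite).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`; directions
#'   refer to `x` relative to `y`.
#' @return a [RankSumResult-class].
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6), alternative = "less")  # p = 0.05
#' @export
wilcoxonRankSum <- function(x, y,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("samples must be finite", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && choose(n, nx) <= 200000
  if (exact) {
    p_less <- pwilcox(u, nx, ny)
    p_greater <- pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    p <- switch(alternative,
                less = p_less, greater = p_greater,
                two.sided = min(1, 2 * min(p_less, p_greater)))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    sigma2 <- (nx * ny / 12) *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- switch(alternative,
                  two.sided = z - sign(z) * 0.5,
                  greater = z - 0.5,
                  less = z + 0.5) / sqrt(sigma2)
      p <- switch(alternative,
                  less = pnorm(z),
                  greater = pnorm(z, lower.tail = FALSE),
                  two.sided = min(1, 2 * min(pnorm(z),
                                             pnorm(z, lower.tail = FALSE))))
    }
    method <- "normal-approx"
  }
  methods::new("RankSumResult", w = w, nX = nx, nY = ny,
               pValue = max(p, .Machine$double.xmin),
               method = method, alternative = alternative)
}

#' Expression shift of a target gene set
#'
#' Compares the log2 fold changes of a set of target genes against a
#' background (all measured non-target genes by default, or an explicit
#' gene set) with [wilcoxonRankSum()] — the standard question being
#' whether genes whose promoters a factor occupies move coherently when
#' the factor is depleted. Target genes absent from the expression table
#' are dropped with a message.
#'
#' @param expr data.frame with columns `gene_id` and `log2fc` (unique
#'   gene ids, finite values).
#' @param targets character vector of target gene ids.
#' @param background `NULL` (all measured non-target genes) or an explicit
#'   character vector of gene ids.
#' @param alternative passed to [wilcoxonRankSum()]; `"greater"` tests
#'   target upregulation.
#' @return a list: `test` ([RankSumResult-class]), `n_target`,
#'   `n_background`, `median_target`, `median_background`, `n_dropped`.
#' @export
geneSetShiftTest <- function(expr, targets, background = NULL,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  if (!all(c("gene_id", "log2fc") %in% names(expr)))
    stop("expr must have columns gene_id and log2fc", call. = FALSE)
  if (anyDuplicated(expr$gene_id))
    stop("duplicate gene ids in expression table", call. = FALSE)
  if (!all(is.finite(expr$log2fc)))
    stop("log2fc must be finite", call. = FALSE)
  targets <- unique(targets)
  n_dropped <- sum(!targets %in% expr$gene_id)
  if (n_dropped > 0)
    message(n_dropped, " target gene(s) absent from the expression table")
  in_t <- expr$gene_id %in% targets
  if (!any(in_t))
    stop("no target gene present in the expression table", call. = FALSE)
  bg <- if (is.null(background)) expr$log2fc[!in_t]
        else expr$log2fc[expr$gene_id %in% setdiff(unique(background),
                                                   targets)]
  if (length(bg) == 0L) stop("empty background", call. = FALSE)
  tg <- expr$log2fc[in_t]
  list(test = wilcoxonRankSum(tg, bg, alternative),
       n_target = length(tg), n_background = length(bg),
       median_target = median(tg), median_background = median(bg),
       n_dropped = n_dropped)
}

#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' Per replicate, the Ct of each gene is referenced to the Ct of
#' `ref_gene` in the same condition and replicate (delta Ct); delta Ct is
#' then averaged within each condition and referenced to
#' `control_condition` (delta-delta Ct); fold change is `2^(-ddCt)`.
#' Dispersion is the standard deviation of replicate delta Ct. By
#' construction the reference gene has fold 1 in every condition and every
#' gene has fold 1 in the control condition.
#'
#' @param ct_table data.frame with columns `condition`, `gene`,
#'   `replicate`, `ct`.
#' @param ref_gene reference transcript (e.g. a stable ribosomal gene).
#' @param control_condition baseline condition.
#' @return a data.frame with one row per condition x gene: `n_rep`,
#'   `mean_ct`, `delta_ct`, `sd_delta_ct`, `delta_delta_ct`, `fold`.
#' @export
ddct <- function(ct_table, ref_gene, control_condition) {
  need <- c("condition", "gene", "replicate", "ct")
  if (!all(need %in% names(ct_table)))
    stop("ct_table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!ref_gene %in% ct_table$gene)
    stop("reference gene '", ref_gene, "' not measured", call. = FALSE)
  if (!control_condition %in% ct_table$condition)
    stop("control condition '", control_condition, "' not measured",
         call. = FALSE)
  ref <- ct_table[ct_table$gene == ref_gene,
                  c("condition", "replicate", "ct")]
  names(ref)[3] <- "ct_ref"
  if (anyDuplicated(ref[c("condition", "replicate")]))
    stop("multiple reference measurements per condition x replicate",
         call. = FALSE)
  if (!all(unique(ct_table$condition) %in% ref$condition))
    stop("reference gene missing from some condition(s)", call. = FALSE)
  m <- merge(ct_table, ref, by = c("condition", "replicate"))
  if (nrow(m) < nrow(ct_table))
    stop("replicate(s) without a matching reference measurement",
         call. = FALSE)
  m$dct <- m$ct - m$ct_ref
  agg <- do.call(rbind, lapply(
    split(m, list(m$condition, m$gene), drop = TRUE), function(g) {
      data.frame(condition = g$condition[1], gene = g$gene[1],
                 n_rep = nrow(g), mean_ct = mean(g$ct),
                 delta_ct = mean(g$dct),
                 sd_delta_ct = if (nrow(g) > 1) sd(g$dct) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  ctrl <- agg[agg$condition == control_condition, c("gene", "delta_ct")]
  names(ctrl)[2] <- "delta_ct_control"
  if (!all(unique(agg$gene) %in% ctrl$gene))
    stop("gene(s) not measured in the control condition", call. = FALSE)
  agg <- merge(agg, ctrl, by = "gene")
  agg$delta_delta_ct <- agg$delta_ct - agg$delta_ct_control
  agg$fold <- 2^(-agg$delta_delta_ct)
  agg$delta_ct_control <- NULL
  rownames(agg) <- NULL
  agg[order(agg$condition, agg$gene),
      c("condition", "gene", "n_rep", "mean_ct", "delta_ct", "sd_delta_ct",
        "delta_delta_ct", "fold")]
}

#' Two-sample pooled-variance (homoscedastic) t test
#'
#' Two-sided Student t test assuming equal variances, delegated to
#' [stats::t.test()] with `var.equal = TRUE`.
#'
#' @param x,y numeric samples with at least two values each.
#' @return a list with `t`, `df` (`nX + nY - 2`) and `p`.
#' @export
tTestHomoscedastic <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least two values", call. = FALSE)
  pooled <- ((length(x) - 1) * stats::var(x) +
             (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (pooled <= 0)
    stop("zero pooled variance: samples are constant", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Benjamini-Hochberg adjustment of a set of shift tests
#'
#' Convenience wrapper used by the pipeline: runs [geneSetShiftTest()] for
#' each named gene set and returns raw and Benjamini-Hochberg adjusted
#' p-values side by side.
#'
#' @param expr expression table, see [geneSetShiftTest()].
#' @param gene_sets named list of character vectors.
#' @param background,alternative passed to [geneSetShiftTest()].
#' @return a data.frame with one row per gene set: sizes, medians, `p_raw`
#'   and `p_bh`.
#' @export
shiftTestBattery <- function(expr, gene_sets, background = NULL,
                             alternative = "two.sided") {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  rows <- lapply(names(gene_sets), function(nm) {
    res <- geneSetShiftTest(expr, gene_sets[[nm]], background, alternative)
    data.frame(gene_set = nm, n_target = res$n_target,
               n_background = res$n_background,
               median_target = res$median_target,
               median_background = res$median_background,
               p_raw = pValue(res$test), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_raw, method = "BH")
  out
}
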