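# serialisers for the JSON report
perm_as_list <- function(p) {
  if (is.null(p)) return(NULL)
  list(observed = p@observed, null_mean = p@nullMean, null_sd = p@nullSd,
       fold_enrichment = if (is.infinite(p@fold)) "Inf" else p@fold,
       p_empirical = p@pEmpirical, n_perm = p@nPerm, seed = p@seed,
       tail = p@tail, statistic = p@statistic,
       flags = as.list(p@flags))
}

overlap_as_list <- function(o) {
  list(n_A = o@nA, n_B = o@nB, n_A_hit = o@nAHit, n_B_hit = o@nBHit,
       frac_A_hit = o@fracAHit, frac_B_hit = o@fracBHit,
       bp_intersect = o@bpIntersect, bp_union = o@bpUnion,
       jaccard = o@jaccard)
}

ct_as_list <- function(ct) {
  if (is.null(ct)) return(NULL)
  list(table = as.vector(t(ct@table)), chi2_yates = ct@chi2,
       p_value = ct@pValue, df = ct@df)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

read_expression <- function(path) {
  expr <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  if (!all(c("gene_id", "log2fc") %in% names(expr)))
    stop("expression table needs columns gene_id and log2fc",
         call. = FALSE)
  expr
}

#' Run the full reach-based co-localization analysis
#'
#' Orchestrates the whole analysis from a single declarative config:
#' replicate consensus, reach-based extension, co-localization of the
#' extended domains with each landscape set (permutation-calibrated),
#' positive/negative mark association, feature distribution, TSS profile,
#' TSS-proximal target-gene assignment, target overlap with a co-factor's
#' targets, expression shift tests (raw and BH-adjusted), and consensus
#' motif enrichment. Stages run in fixed order; a failing stage aborts
#' with its name. Intermediate artifacts and a JSON report are written
#' when `out_dir` is set, and rerunning with an identical config
#' reproduces all values exactly.
#'
#' @param config a named list of file paths and parameters:
#'   `genome` (chrom.sizes), `peaks_rep1`, `peaks_rep2` (BED),
#'   `genes` (BED6), `seed`; optional `landscapes` (named list of BED
#'   paths), `mark_pos`, `mark_neg`, `cofactor` (BED), `fasta`,
#'   `expr` (TSV), `gene_sets` (named list of character vectors);
#'   numeric knobs `reach_angstrom`, `packing_ratio`, `flank_bp`
#'   (overrides the reach conversion), `consensus_mode`, `max_dist`,
#'   `n_perm`, `statistic`, `profile_window`, `profile_bin`,
#'   `shift_alternative`, `motif` (a [motifDef()]).
#' @param out_dir optional output directory for `report.json`,
#'   `extended.bed`, `targets.tsv`, `profile.tsv`, `shift.tsv`.
#' @return the report, an (invisibly JSON-serialisable) nested list.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  req <- c("genome", "peaks_rep1", "peaks_rep2", "genes", "seed")
  missing_keys <- setdiff(req, names(config))
  if (length(missing_keys))
    stop("config is missing: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  for (key in c("genome", "peaks_rep1", "peaks_rep2", "genes",
                "mark_pos", "mark_neg", "cofactor", "fasta", "expr")) {
    pth <- config[[key]]
    if (!is.null(pth) && is.character(pth) && !file.exists(pth))
      stop("config file for '", key, "' does not exist: ", pth,
           call. = FALSE)
  }
  cfg <- function(key, default) if (is.null(config[[key]])) default
                                else config[[key]]
  seed <- as.integer(config$seed)
  n_perm <- cfg("n_perm", 1000L)
  statistic <- cfg("statistic", "frac_A_hit")
  max_dist <- cfg("max_dist", 1000L)
  flank <- cfg("flank_bp",
               reachToBp(cfg("reach_angstrom", 100),
                         packing_ratio = cfg("packing_ratio", 102)))

  genome <- stage("load-genome", readChromSizes(config$genome))
  rep1 <- stage("load-peaks", readBed(config$peaks_rep1, genome))
  rep2 <- stage("load-peaks", readBed(config$peaks_rep2, genome))
  genes <- stage("load-genes", readGeneModels(config$genes, genome))
  landscapes <- stage("load-landscapes", lapply(
    cfg("landscapes", list()), function(p)
      if (is.character(p)) readBed(p, genome) else setGenome(p, genome)))

  cons <- stage("consensus",
                consensusPeaks(rep1, rep2,
                               mode = cfg("consensus_mode", "anchored")))
  if (length(cons) == 0L)
    stop("pipeline stage 'consensus' failed: no common peaks",
         call. = FALSE)
  extended <- stage("extend", extendIntervals(cons, flank))

  coloc <- stage("colocalization", lapply(landscapes, function(B)
    list(peak_overlap = overlap_as_list(overlapStats(cons, B)),
         region_overlap = overlap_as_list(overlapStats(extended, B)),
         permutation = perm_as_list(
           foldEnrichment(extended, B, n_perm = n_perm, seed = seed,
                          statistic = statistic)))))

  marks <- NULL
  if (!is.null(config$mark_pos) && !is.null(config$mark_neg)) {
    marks <- stage("mark-association", {
      mp <- readBed(config$mark_pos, genome)
      mn <- readBed(config$mark_neg, genome)
      ma <- markAssociation(extended, mp, mn, n_perm = n_perm,
                            seed = seed, statistic = statistic)
      list(pos = perm_as_list(ma$pos), neg = perm_as_list(ma$neg),
           contingency = ct_as_list(ma$contingency))
    })
  }

  feat <- stage("feature-distribution",
                featureDistribution(cons, genes))
  profile <- stage("tss-profile",
                   tssProfile(cons, genes,
                              window = cfg("profile_window", 10000),
                              bin = cfg("profile_bin", 100)))
  targets <- stage("target-assignment",
                   assignTargetGenes(cons, genes, max_dist = max_dist))

  cofactor_report <- NULL
  if (!is.null(config$cofactor)) {
    cofactor_report <- stage("cofactor-overlap", {
      cf <- readBed(config$cofactor, genome)
      cft <- assignTargetGenes(cf, genes, max_dist = max_dist)
      gsot <- geneSetOverlapTest(targets$targets, cft$targets,
                                 genes$gene_id)
      list(n_cofactor_targets = length(cft$targets),
           overlap_fraction = gsot$overlap_fraction,
           n_intersect = gsot$n_intersect,
           contingency = ct_as_list(gsot$contingency))
    })
  }

  shift <- NULL
  if (!is.null(config$expr)) {
    shift <- stage("shift-tests", {
      expr <- if (is.character(config$expr)) read_expression(config$expr)
              else config$expr
      sets <- c(list(chip_targets = targets$targets),
                cfg("gene_sets", list()))
      shiftTestBattery(expr, sets,
                       alternative = cfg("shift_alternative", "greater"))
    })
  }

  motif_report <- NULL
  if (!is.null(config$fasta)) {
    motif_report <- stage("motif-enrichment", perm_as_list(
      motifEnrichment(cons, config$fasta, cfg("motif", motifDef()),
                      n_perm = n_perm, seed = seed)))
  }

  report <- list(
    provenance = list(package = "reachmap",
                      version = as.character(packageVersion("reachmap")),
                      seed = seed, n_perm = n_perm, flank_bp = flank,
                      max_dist = max_dist, statistic = statistic,
                      consensus_mode = cfg("consensus_mode", "anchored")),
    counts = list(n_rep1 = length(rep1), n_rep2 = length(rep2),
                  n_consensus = length(cons),
                  n_extended = length(extended),
                  bp_extended = sum(as.numeric(
                    GenomicRanges::width(extended)))),
    colocalization = coloc,
    mark_association = marks,
    feature_distribution = list(
      peaks = as.list(feat$peak_fractions),
      genome = as.list(feat$genome_fractions)),
    tss_profile = profile,
    targets = list(n = length(targets$targets), ids = targets$targets),
    cofactor = cofactor_report,
    shift_tests = shift,
    motif = motif_report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeBed(extended, file.path(out_dir, "extended.bed"))
    write.table(targets$assignments, file.path(out_dir, "targets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(profile, file.path(out_dir, "profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(shift))
      write.table(shift, file.path(out_dir, "shift.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Compare bona fide versus reach-extended target definitions
#'
#' Target genes can be defined two ways: (i) from the bona fide replicate
#' consensus peaks that are also occupied by a co-factor (peak anchors
#' within `max_dist` of the TSS), or (ii) from the reach-extended domains
#' (a gene is a target when its TSS falls inside an extended region). The
#' extended definition sweeps in many more genes, diluting any coherent
#' expression shift carried by the narrowly defined targets; this function
#' runs [geneSetShiftTest()] under both definitions and reports them side
#' by side.
#'
#' @param rep1,rep2 replicate peak `GRanges`.
#' @param cofactor co-factor peak `GRanges` (non-empty).
#' @param genes gene models.
#' @param expr expression table (data.frame `gene_id`, `log2fc`).
#' @param max_dist strict TSS distance bound for the bona fide route.
#' @param flank_bp extension flank for the extended route.
#' @param alternative shift-test alternative.
#' @param consensus_mode passed to [consensusPeaks()].
#' @return a list with `bona_fide` and `extended`, each carrying the
#'   target count and the shift-test result.
#' @export
compareBonaFideVsExtended <- function(rep1, rep2, cofactor, genes, expr,
                                      max_dist = 1000, flank_bp = 3000,
                                      alternative = "greater",
                                      consensus_mode = "anchored") {
  if (length(cofactor) == 0L)
    stop("empty co-factor peak set", call. = FALSE)
  cons <- consensusPeaks(rep1, rep2, mode = consensus_mode)
  bona <- cons[GenomicRanges::countOverlaps(cons, cofactor) > 0L]
  bona_targets <- assignTargetGenes(bona, genes,
                                    max_dist = max_dist)$targets
  ext <- extendIntervals(cons, flank_bp)
  tssGR <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(genes),
    IRanges::IRanges(tssPositions(genes), width = 1L),
    seqinfo = GenomeInfoDb::seqinfo(genes))
  ext_targets <- genes$gene_id[
    GenomicRanges::countOverlaps(tssGR, ext) > 0L]
  list(
    bona_fide = list(
      n_targets = length(bona_targets),
      shift = geneSetShiftTest(expr, bona_targets,
                               alternative = alternative)),
    extended = list(
      n_targets = length(ext_targets),
      shift = geneSetShiftTest(expr, ext_targets,
                               alternative = alternative)))
}
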