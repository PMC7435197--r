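#' Define an IUPAC consensus motif
#'
#' @param consensus IUPAC consensus string, default the E-box `"CACGTG"`
#'   (the palindromic recognition site of bHLH-Zip dimers such as
#'   c-MYC/MAX).
#' @param name motif name.
#' @return a list with `consensus`, `name` and the derived `palindromic`
#'   flag (true when the consensus equals its own reverse complement).
#' @export
motifDef <- function(consensus = "CACGTG", name = "E-box") {
  if (!nzchar(consensus)) stop("empty consensus", call. = FALSE)
  ok <- strsplit(consensus, "")[[1]] %in%
    names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok))
    stop("invalid IUPAC character(s) in motif: ",
         paste(unique(strsplit(consensus, "")[[1]][!ok]), collapse = ""),
         call. = FALSE)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
  list(consensus = toupper(consensus), name = name,
       palindromic = toupper(consensus) == rc)
}

#' Scan a sequence for an IUPAC consensus motif on both strands
#'
#' Reports every match start (1-based, forward-strand coordinates) with
#' its strand; overlapping matches are allowed. `N` in the subject never
#' matches. For palindromic motifs each site matches both strands at the
#' same position and is reported once, on the forward strand.
#'
#' @param sequence a `DNAString` or character over `{A,C,G,T,N}`.
#' @param motif a motif from [motifDef()].
#' @return a data.frame with columns `position` and `strand`, sorted by
#'   position.
#' @examples
#' scanConsensus("CACGTGCACGTG", motifDef())  # hits at 1 and 7
#' @export
scanConsensus <- function(sequence, motif) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  fixed <- c(pattern = FALSE, subject = TRUE)  # IUPAC pattern, literal N
  fwd <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(motif$consensus), sequence, fixed = fixed))
  if (motif$palindromic) {
    out <- data.frame(position = fwd,
                      strand = rep("+", length(fwd)))
  } else {
    rev <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(motif$consensus)),
      sequence, fixed = fixed))
    out <- data.frame(position = c(fwd, rev),
                      strand = c(rep("+", length(fwd)),
                                 rep("-", length(rev))))
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

count_peak_hits <- function(peaks, seqs, motif, statistic) {
  if (length(peaks) == 0L) return(0)
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  if (!all(chrom %in% names(seqs)))
    stop("missing chromosome sequence(s): ",
         paste(setdiff(unique(chrom), names(seqs)), collapse = ", "),
         call. = FALSE)
  seq_len_by_chrom <- setNames(Biostrings::width(seqs), names(seqs))
  if (any(GenomicRanges::end(peaks) > seq_len_by_chrom[chrom]))
    stop("peak(s) beyond FASTA bounds", call. = FALSE)
  ir <- IRanges::IRanges(GenomicRanges::start(peaks),
                         GenomicRanges::end(peaks))
  pieces <- as.list(S4Vectors::split(ir, chrom))
  peak_seqs <- do.call(c, unname(lapply(names(pieces), function(ch)
    Biostrings::extractAt(seqs[[ch]], pieces[[ch]]))))
  fixed <- c(pattern = FALSE, subject = TRUE)
  hits <- Biostrings::vcountPattern(
    Biostrings::DNAString(motif$consensus), peak_seqs, fixed = fixed)
  if (!motif$palindromic)
    hits <- hits + Biostrings::vcountPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(motif$consensus)),
      peak_seqs, fixed = fixed)
  if (statistic == "total_hits") sum(hits) else mean(hits > 0)
}

#' Motif enrichment in peaks against a relocation null
#'
#' Counts consensus-motif occurrences in peak sequences and calibrates the
#' count against the same intra-chromosomal relocation null used for
#' interval co-localization: peaks are relocated within their chromosomes
#' ([permuteIntrachrom()]) and re-scanned against the same genome
#' sequence. When the motif is absent from both the peaks and every
#' relocation, the fold is reported as 1 with a `"zero-signal"` flag.
#'
#' @param peaks a `GRanges` with a genome attached.
#' @param seqs genome sequence as a named `DNAStringSet` (or path to a
#'   FASTA file).
#' @param motif a motif from [motifDef()].
#' @param n_perm,seed as in [foldEnrichment()].
#' @param statistic `"total_hits"` (total motif count) or
#'   `"frac_peaks_hit"` (fraction of peaks with at least one hit).
#' @param window if positive, peaks are first re-centred to windows of
#'   this many bp around their anchors (off by default).
#' @return a [PermutationResult-class].
#' @export
motifEnrichment <- function(peaks, seqs, motif = motifDef(),
                            n_perm = 1000L, seed,
                            statistic = c("total_hits", "frac_peaks_hit"),
                            window = 0) {
  statistic <- match.arg(statistic)
  check_scalar_number(n_perm, "n_perm", lower = 1)
  if (is.character(seqs) && length(seqs) == 1L)
    seqs <- Biostrings::readDNAStringSet(seqs)
  if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  check_has_genome(peaks, "peak set")
  if (window > 0) {
    anchors <- anchor_granges(peaks)
    peaks <- GenomicRanges::trim(suppressWarnings(
      GenomicRanges::resize(anchors, width = as.integer(window),
                            fix = "center")))
  }
  observed <- count_peak_hits(peaks, seqs, motif, statistic)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    count_peak_hits(permute_core(peaks), seqs, motif, statistic)
  }, numeric(1)))
  null_mean <- mean(null)
  null_sd <- sd(null)
  if (is.na(null_sd)) null_sd <- 0
  k <- sum(null >= observed)
  flags <- character(0)
  if (null_mean == 0 && observed > 0) {
    fold <- Inf; flags <- "zero-null"
  } else if (null_mean == 0) {
    fold <- 1; flags <- "zero-signal"
  } else fold <- observed / null_mean
  methods::new("PermutationResult",
    observed = observed, nullMean = null_mean, nullSd = null_sd,
    fold = fold, pEmpirical = (1 + k) / (n_perm + 1),
    nPerm = as.integer(n_perm),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    tail = "greater", statistic = statistic, flags = flags)
}
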