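#' Read a chrom.sizes file into a Seqinfo genome definition
#'
#' Parses a two-column whitespace-delimited table of chromosome name and
#' length (the UCSC "chrom.sizes" convention) into a
#' [GenomeInfoDb::Seqinfo] object, the coordinate universe used by all
#' interval operations in the package. Input order is preserved.
#'
#' @param path path to the chrom.sizes file.
#' @return a `Seqinfo` with one entry per line.
#' @examples
#' f <- tempfile()
#' writeLines(c("chrA\t5000", "chrB\t3000"), f)
#' readChromSizes(f)
#' @export
readChromSizes <- function(path) {
  tab <- tryCatch(
    read.table(path, header = FALSE, colClasses = "character",
               col.names = c("chrom", "length"), strip.white = TRUE),
    error = function(e) stop("cannot parse chrom.sizes file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(tab) == 0L) stop("empty chrom.sizes file: ", path, call. = FALSE)
  if (anyDuplicated(tab$chrom))
    stop("duplicate chromosome name(s): ",
         paste(unique(tab$chrom[duplicated(tab$chrom)]), collapse = ", "),
         call. = FALSE)
  len <- suppressWarnings(as.numeric(tab$length))
  if (anyNA(len) || any(len != floor(len)) || any(len < 1))
    stop("chromosome lengths must be positive integers", call. = FALSE)
  GenomeInfoDb::Seqinfo(seqnames = tab$chrom, seqlengths = as.integer(len))
}

#' Read a BED3/BED6 file into a GRanges
#'
#' Thin wrapper around [rtracklayer::import] that enforces the package's
#' interval contract: every record must span at least one base, and when a
#' genome is supplied every interval must fall on a known chromosome within
#' its length. Track/browser/comment lines are skipped by the importer.
#'
#' @param path path to the BED file.
#' @param genome optional `Seqinfo`; when supplied, intervals are validated
#'   against it and the returned object carries it.
#' @return a `GRanges` (with `name`/`score` metadata columns when present).
#' @export
readBed <- function(path, genome = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("cannot parse BED file '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (any(GenomicRanges::width(gr) < 1L))
    stop("BED record(s) with end <= start in ", path, call. = FALSE)
  if (!is.null(genome)) {
    bad <- !as.character(GenomeInfoDb::seqnames(gr)) %in%
      GenomeInfoDb::seqnames(genome)
    if (any(bad))
      stop("interval(s) on chromosome(s) absent from the genome: ",
           paste(unique(as.character(GenomeInfoDb::seqnames(gr))[bad]),
                 collapse = ", "), call. = FALSE)
    gr <- setGenome(gr, genome)
    sl <- GenomeInfoDb::seqlengths(genome)[
      as.character(GenomeInfoDb::seqnames(gr))]
    if (any(GenomicRanges::end(gr) > sl))
      stop("interval(s) extend beyond chromosome length", call. = FALSE)
  }
  gr
}

#' Write a GRanges to BED
#'
#' Writes BED6 (name, score, strand) when any of those attributes is
#' present, BED3 otherwise. Coordinates are converted to the BED 0-based
#' half-open convention, so `readBed(writeBed(x))` reproduces coordinates
#' exactly.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  mc <- S4Vectors::mcols(gr)
  has_extra <- "name" %in% names(mc) || "score" %in% names(mc) ||
    any(as.character(GenomicRanges::strand(gr)) != "*")
  if (has_extra && length(gr)) {
    df$name <- if ("name" %in% names(mc)) as.character(mc$name) else "."
    df$name[is.na(df$name)] <- "."
    df$score <- if ("score" %in% names(mc)) mc$score else 0
    df$score[is.na(df$score)] <- 0
    strand <- as.character(GenomicRanges::strand(gr))
    df$strand <- ifelse(strand == "*", ".", strand)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach a genome definition to a GRanges
#'
#' Replaces the `Seqinfo` of `gr` with `genome` (levels are harmonised so
#' that all genome chromosomes are present, in genome order).
#'
#' @param gr a `GRanges`.
#' @param genome a `Seqinfo`.
#' @return `gr` with `seqinfo(gr) == genome`.
#' @export
setGenome <- function(gr, genome) {
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- genome)
  gr
}

#' Read strand-annotated gene models from BED6
#'
#' Genes are BED6 records whose name column carries the gene id; the
#' transcription start site (TSS) is the 5' end in gene orientation (the
#' interval start on `+`, the last base on `-`). Genes on chromosomes
#' absent from `genome` are dropped with a message reporting the count.
#'
#' @param path BED6 file of gene models.
#' @param genome a `Seqinfo`.
#' @return a `GRanges` with metadata columns `gene_id` and `tss` (1-based
#'   TSS position).
#' @export
readGeneModels <- function(path, genome) {
  gr <- readBed(path, genome = NULL)
  if (!"name" %in% names(S4Vectors::mcols(gr)) || anyNA(gr$name))
    stop("gene models require a name column carrying the gene id",
         call. = FALSE)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("gene models require an explicit strand (+ or -)", call. = FALSE)
  if (anyDuplicated(gr$name))
    stop("duplicate gene id(s): ",
         paste(unique(gr$name[duplicated(gr$name)]), collapse = ", "),
         call. = FALSE)
  known <- as.character(GenomeInfoDb::seqnames(gr)) %in%
    GenomeInfoDb::seqnames(genome)
  if (any(!known)) {
    message(sum(!known), " gene(s) on unknown chromosomes dropped")
    gr <- gr[known]
  }
  gr <- setGenome(gr, genome)
  if (any(GenomicRanges::end(gr) >
          GenomeInfoDb::seqlengths(genome)[
            as.character(GenomeInfoDb::seqnames(gr))]))
    stop("gene model(s) extend beyond chromosome length", call. = FALSE)
  names(S4Vectors::mcols(gr))[names(S4Vectors::mcols(gr)) == "name"] <-
    "gene_id"
  gr$tss <- tssPositions(gr)
  gr
}

#' TSS positions of gene models
#'
#' @param genes a stranded `GRanges` of gene models.
#' @return integer vector of 1-based TSS positions (start on `+`, end on
#'   `-`).
#' @export
tssPositions <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "-",
         GenomicRanges::end(genes), GenomicRanges::start(genes))
}
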