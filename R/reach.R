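#' Convert a physical bridging reach to a genomic flank length
#'
#' Cullin-RING ligases are rigid scaffolds that can bridge a substrate and
#' the ubiquitin-conjugating enzyme over a physical distance on the order
#' of 100 angstrom. On compacted chromatin (a solenoid fibre) this physical
#' reach spans far more linear DNA than naked B-DNA would: with a B-DNA
#' rise of `rise_nm_per_bp` nanometres per base pair and a fibre packing
#' ratio `packing_ratio` (fold-compaction of linear DNA within the fibre),
#' a reach of `reach_angstrom` angstrom corresponds to
#'
#'   `round(reach_angstrom * 0.1 * packing_ratio / rise_nm_per_bp)`
#'
#' base pairs. The defaults (100 A, 0.34 nm/bp, packing 102) give 3000 bp,
#' the flank used to delimit domains plausibly under the ligase's control.
#'
#' @param reach_angstrom physical bridging distance in angstrom (>= 0).
#' @param rise_nm_per_bp B-DNA rise in nm per base pair (> 0); 0.34 is the
#'   canonical value.
#' @param packing_ratio dimensionless solenoid compaction factor (>= 1).
#' @return integer flank length in bp; linear in reach and packing ratio.
#' @examples
#' reachToBp()            # 3000
#' reachToBp(50)          # 1500
#' @export
reachToBp <- function(reach_angstrom = 100, rise_nm_per_bp = 0.34,
                      packing_ratio = 102) {
  check_scalar_number(reach_angstrom, "reach_angstrom", lower = 0)
  check_scalar_number(rise_nm_per_bp, "rise_nm_per_bp", lower = 0,
                      strict = TRUE)
  check_scalar_number(packing_ratio, "packing_ratio", lower = 1)
  as.integer(round(reach_angstrom * 0.1 * packing_ratio / rise_nm_per_bp))
}

#' Extend peaks symmetrically into putative control domains
#'
#' Each interval is widened by `flank_bp` on both sides and clipped to its
#' chromosome, so no coordinate leaves `[1, chromosome length]`. With
#' `merge_after = TRUE` (default) the result is sorted and merged so that
#' downstream overlap fractions have unambiguous region denominators.
#'
#' @param gr a `GRanges` carrying a genome (`Seqinfo` with lengths).
#' @param flank_bp non-negative integer flank, e.g. from [reachToBp()].
#' @param merge_after merge overlapping/abutting extended intervals?
#' @return a `GRanges` of extended (optionally merged) domains.
#' @export
extendIntervals <- function(gr, flank_bp, merge_after = TRUE) {
  check_scalar_number(flank_bp, "flank_bp", lower = 0)
  check_has_genome(gr)
  ext <- suppressWarnings(gr + as.integer(flank_bp))
  ext <- GenomicRanges::trim(ext)
  if (merge_after) sortAndMerge(ext) else ext
}
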