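#' @import methods
#' @importFrom stats pchisq pnorm pwilcox rnorm runif
#' @importFrom utils read.table write.table packageVersion
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Uniform integer draw on [lo, hi], vectorised over n. sample.int is avoided
# because its behaviour for very large ranges differs across R versions.
runif_int <- function(n, lo, hi) {
  stopifnot(all(hi >= lo))
  as.integer(pmin(lo + floor(runif(n) * (hi - lo + 1)), hi))
}

check_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if ((strict && x <= lower) || (!strict && x < lower))
    stop(sprintf("'%s' must be %s %s", name, if (strict) ">" else ">=", lower),
         call. = FALSE)
  invisible(x)
}

# Two interval sets are comparable only over the same coordinate universe.
check_same_genome <- function(A, B) {
  sa <- GenomeInfoDb::seqinfo(A)
  sb <- GenomeInfoDb::seqinfo(B)
  la <- GenomeInfoDb::seqlengths(sa)
  lb <- GenomeInfoDb::seqlengths(sb)
  shared <- intersect(names(la), names(lb))
  if (!identical(sort(names(la)), sort(names(lb))) ||
      !identical(la[sort(shared)], lb[sort(shared)]))
    stop("interval sets are defined on different genomes", call. = FALSE)
  invisible(TRUE)
}

check_has_genome <- function(gr, what = "interval set") {
  sl <- GenomeInfoDb::seqlengths(gr)
  if (length(sl) == 0L || anyNA(sl))
    stop(what, " must carry a genome (Seqinfo with chromosome lengths)",
         call. = FALSE)
  invisible(TRUE)
}
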