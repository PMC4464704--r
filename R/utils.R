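#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.5 -> 1), the
#' convention used for the percentages in the pipeline reports, rather than
#' R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(100 * 728 / 2267)   # 32
#' round_half_up(0.5)                # 1
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Named integer chromosome lengths -> validated
check_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome must be a named vector of chromosome lengths")
  }
  if (any(genome <= 0)) stop("chromosome lengths must be positive")
  genome
}

# Attach seqlengths to a GRanges (tolerant of extra levels in `genome`)
set_genome <- function(gr, genome) {
  genome <- check_genome(genome)
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- genome
  gr
}

stopifnot_fraction <- function(x, nm) {
  if (any(x < 0 | x > 1)) stop(sprintf("%s must lie in [0, 1]", nm))
  invisible(x)
}
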