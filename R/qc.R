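#' Replicate concordance: sharing of top-ranked peaks
#'
#' Ranks each replicate's islands by ascending FDR (ties broken by
#' ascending p-value, then coordinate), takes the top `top_frac` of each
#' list, and reports the fraction of one replicate's top islands that
#' overlap (>= 1 bp) any of the other's top islands, in both directions.
#' The criterion passes when both fractions are at least 0.8.
#'
#' @param islands_1,islands_2 island `GRanges` with `fdr` and `p_value`.
#' @param top_frac fraction of top-ranked islands compared (default 0.4).
#' @return list: `sharing_12`, `sharing_21`, `n_top_1`, `n_top_2`, `pass`.
#' @export
top_peak_sharing <- function(islands_1, islands_2, top_frac = 0.4) {
  if (!length(islands_1) || !length(islands_2)) stop("empty island list")
  top <- function(isl) {
    o <- order(isl$fdr, isl$p_value,
               as.character(GenomicRanges::seqnames(isl)),
               GenomicRanges::start(isl))
    isl[o[seq_len(ceiling(top_frac * length(isl)))]]
  }
  t1 <- top(islands_1); t2 <- top(islands_2)
  s12 <- mean(GenomicRanges::countOverlaps(t1, t2,
                                           ignore.strand = TRUE) > 0)
  s21 <- mean(GenomicRanges::countOverlaps(t2, t1,
                                           ignore.strand = TRUE) > 0)
  list(sharing_12 = s12, sharing_21 = s21,
       n_top_1 = length(t1), n_top_2 = length(t2),
       pass = s12 >= 0.8 && s21 >= 0.8)
}

#' Replicate concordance: coverage correlation over random regions
#'
#' Draws `n_regions` non-overlapping regions of `region_bp` uniformly from
#' the genome and computes the Spearman correlation of the two samples'
#' per-base coverage within each. Passes when the mean correlation exceeds
#' 0.9 (set `per_region = TRUE` to require every region to exceed it).
#'
#' @param cov_1,cov_2 `coverage_track`s over the same genome.
#' @param genome named chromosome lengths.
#' @param n_regions number of regions (default 3).
#' @param region_bp region width (default 300000).
#' @param seed integer seed for region selection.
#' @param per_region require each region, rather than the mean, to pass?
#' @return list: `regions` (data.frame), `rho` (per region), `mean_rho`,
#'   `pass`.
#' @export
coverage_spearman <- function(cov_1, cov_2, genome, n_regions = 3,
                              region_bp = 300000, seed = 1,
                              per_region = FALSE) {
  genome <- check_genome(genome)
  ok <- genome >= region_bp
  if (!any(ok)) stop("genome too small for requested region size")
  regions <- with_seed(seed, {
    picked <- GenomicRanges::GRanges()
    tries <- 0
    while (length(picked) < n_regions) {
      tries <- tries + 1
      if (tries > 1000 * n_regions)
        stop("cannot place non-overlapping regions")
      chrom <- sample(names(genome)[ok], 1,
                      prob = (genome[ok] - region_bp + 1))
      st <- floor(runif(1) * (genome[chrom] - region_bp + 1)) + 1
      cand <- GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(st, st + region_bp - 1))
      if (!length(picked) ||
          !any(GenomicRanges::countOverlaps(cand, picked) > 0))
        picked <- c(picked, cand)
    }
    picked
  })
  rho <- vapply(seq_along(regions), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(regions)[i])
    st <- GenomicRanges::start(regions)[i]
    en <- GenomicRanges::end(regions)[i]
    v1 <- as.numeric(IRanges::Views(cov_1$cov[[chrom]], st, en)[[1]])
    v2 <- as.numeric(IRanges::Views(cov_2$cov[[chrom]], st, en)[[1]])
    cor(v1, v2, method = "spearman")
  }, numeric(1))
  pass <- if (per_region) all(rho > 0.9) else mean(rho) > 0.9
  list(regions = data.frame(
         chrom = as.character(GenomicRanges::seqnames(regions)),
         start = GenomicRanges::start(regions),
         end = GenomicRanges::end(regions), rho = rho,
         stringsAsFactors = FALSE),
       rho = rho, mean_rho = mean(rho), pass = pass)
}

#' Replicate concordance: sharing of all retained islands
#'
#' As [top_peak_sharing()] but over the complete retained island lists;
#' passes when both directional fractions exceed 0.8 (strictly, matching
#' the published criterion "greater than 80%").
#'
#' @param islands_1,islands_2 island `GRanges`.
#' @return list: `sharing_12`, `sharing_21`, `pass`.
#' @export
island_sharing <- function(islands_1, islands_2) {
  if (!length(islands_1) || !length(islands_2)) stop("empty island list")
  s12 <- mean(GenomicRanges::countOverlaps(islands_1, islands_2,
                                           ignore.strand = TRUE) > 0)
  s21 <- mean(GenomicRanges::countOverlaps(islands_2, islands_1,
                                           ignore.strand = TRUE) > 0)
  list(sharing_12 = s12, sharing_21 = s21, pass = s12 > 0.8 && s21 > 0.8)
}

#' Both-replicates consensus of per-gene results
#'
#' A result (gene, status) is reported only when it holds in both
#' biological replicates: the consensus is the intersection of the two
#' (gene, status) pair sets.
#'
#' @param result_set_1,result_set_2 data.frames with columns `gene_id`,
#'   `status`.
#' @return data.frame of the shared (gene, status) pairs.
#' @export
replicate_consensus <- function(result_set_1, result_set_2) {
  merge(result_set_1[, c("gene_id", "status")],
        result_set_2[, c("gene_id", "status")],
        by = c("gene_id", "status"), sort = TRUE)
}

#' ChIP-qPCR percent input
#'
#' Percent input is `2^(input Ct - ChIP Ct) x input dilution factor`,
#' optionally normalized by the geometric mean of the reference genes'
#' percent-input values.
#'
#' @param ct_chip,ct_input cycle thresholds (vectors recycle).
#' @param input_dilution_factor fold dilution of the input aliquot (>= 1).
#' @param reference_percent_inputs percent-input values of reference genes;
#'   empty means no reference normalization.
#' @return normalized percent input.
#' @export
pcr_percent_input <- function(ct_chip, ct_input, input_dilution_factor = 1,
                              reference_percent_inputs = numeric(0)) {
  if (any(input_dilution_factor <= 0)) stop("non-positive dilution factor")
  if (any(c(ct_chip, ct_input) <= 0)) stop("Ct values must be positive")
  raw <- 2^(ct_input - ct_chip) * input_dilution_factor
  if (length(reference_percent_inputs))
    raw <- raw / exp(mean(log(reference_percent_inputs)))
  raw
}

#' ChIP-qPCR fold enrichment over the no-antibody control
#'
#' Fold enrichment is `2^(no-antibody Ct - ChIP Ct)`; the assay passes QC
#' only when the fold is strictly greater than 3.
#'
#' @param ct_chip,ct_noab cycle thresholds.
#' @return list: `fold`, `pass`.
#' @export
pcr_fold_enrichment <- function(ct_chip, ct_noab) {
  if (missing(ct_noab) || any(is.na(ct_noab)))
    stop("no-antibody Ct is required")
  fold <- 2^(ct_noab - ct_chip)
  list(fold = fold, pass = fold > 3)
}
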