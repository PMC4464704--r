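#' Hypergeometric test of gene-set overlap
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between two gene sets drawn from a common background universe,
#' with the expected overlap and fold enrichment.
#'
#' @param set_a,set_b character vectors of gene ids, or `NULL` when calling
#'   with explicit counts.
#' @param background character vector (the universe) or a single integer
#'   `N`; sets must lie within the universe when it is given as ids.
#' @param k,n1,n2 explicit counts overriding the sets (all three required
#'   together with a numeric `background`).
#' @return list of class `overlap_result`: `k`, `n1`, `n2`, `N`,
#'   `expected`, `fold`, `p_upper`, `overlap_pct` (percent of `n1`
#'   overlapping, rounded half-up).
#' @export
hypergeometric_overlap <- function(set_a = NULL, set_b = NULL, background,
                                   k = NULL, n1 = NULL, n2 = NULL) {
  if (is.null(k)) {
    N <- if (is.numeric(background) && length(background) == 1)
      as.integer(background) else length(unique(background))
    if (!is.numeric(background)) {
      if (!all(set_a %in% background) || !all(set_b %in% background))
        stop("sets must lie within the background universe")
    }
    set_a <- unique(set_a); set_b <- unique(set_b)
    k <- length(intersect(set_a, set_b))
    n1 <- length(set_a); n2 <- length(set_b)
  } else {
    N <- if (is.numeric(background)) as.integer(background)
         else length(unique(background))
  }
  if (n1 > N || n2 > N) stop("set sizes exceed the background")
  if (k > min(n1, n2)) stop("overlap exceeds the smaller set")
  expected <- n1 * n2 / N
  structure(list(
    k = k, n1 = n1, n2 = n2, N = N, expected = expected,
    fold = if (expected > 0) k / expected else NA_real_,
    p_upper = phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE),
    overlap_pct = if (n1 > 0) round_half_up(100 * k / n1) else NA_real_),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: k=%d of n1=%d, n2=%d (N=%d); expected %.1f, fold %.2f, P=%.3g\n",
    x$k, x$n1, x$n2, x$N, x$expected, x$fold, x$p_upper))
  invisible(x)
}

#' Direct and functional targets of the methyltransferase
#'
#' Direct targets are genes both hypomethylated in the mutant and bound by
#' the enzyme; functional targets are genes both hypomethylated and
#' down-regulated in the mutant. Each intersection is reported with its
#' hypergeometric overlap statistics against the shared background.
#'
#' @param hypo,bound,down character vectors of gene ids.
#' @param background universe of gene ids (or integer N).
#' @return list: `direct_targets`, `functional_targets` (character
#'   vectors), `direct_overlap`, `functional_overlap` (`overlap_result`s).
#' @export
derive_target_sets <- function(hypo, bound, down, background) {
  list(direct_targets = intersect(hypo, bound),
       functional_targets = intersect(hypo, down),
       direct_overlap = hypergeometric_overlap(bound, hypo, background),
       functional_overlap = hypergeometric_overlap(hypo, down, background))
}

#' Partition targets by carbon/light responsiveness
#'
#' Splits a target set into the four disjoint classes (carbon-only,
#' light-only, both, neither) and reports the percent responsive to either
#' signal, rounded half-up to an integer.
#'
#' @param targets,c_set,l_set character vectors of gene ids.
#' @return list: `counts` (named integer vector summing to the target
#'   count), `n_targets`, `n_responsive`, `percent_responsive`.
#' @export
responsiveness_partition <- function(targets, c_set, l_set) {
  targets <- unique(targets)
  in_c <- targets %in% c_set
  in_l <- targets %in% l_set
  counts <- c(c_only = sum(in_c & !in_l), l_only = sum(!in_c & in_l),
              both = sum(in_c & in_l), neither = sum(!in_c & !in_l))
  n_resp <- sum(in_c | in_l)
  list(counts = counts, n_targets = length(targets),
       n_responsive = n_resp,
       percent_responsive = if (length(targets))
         round_half_up(100 * n_resp / length(targets)) else NA_real_)
}

# equal-count binning by ascending `by`, remainder to the lowest bins
.rank_bins <- function(by, n_bins) {
  n <- length(by)
  if (n < n_bins) stop("fewer genes than bins")
  sizes <- rep(n %/% n_bins, n_bins)
  r <- n %% n_bins
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  bin <- integer(n)
  bin[order(by)] <- rep(seq_len(n_bins), sizes)
  bin
}

#' Methylation level across expression-ranked bins
#'
#' Ranks genes by expression, splits them into `n_bins` equal-count bins
#' (remainder genes to the lowest bins), and summarizes the per-bin median
#' methylation with a Spearman trend statistic over the bin medians —
#' the binned view of the methylation-expression correlation.
#'
#' @param expression,methylation named numeric vectors over a common gene
#'   list.
#' @param n_bins number of bins (default 10).
#' @return list of class `bin_summary`: `table` (bin, n, summary),
#'   `trend_rho`, plus the binning variable name.
#' @export
expression_methylation_bins <- function(expression, methylation,
                                        n_bins = 10) {
  common <- intersect(names(expression), names(methylation))
  if (length(common) < n_bins) stop("fewer genes than bins")
  e <- expression[common]; m <- methylation[common]
  bin <- .rank_bins(e, n_bins)
  med <- vapply(seq_len(n_bins), function(b) median(m[bin == b]),
                numeric(1))
  structure(list(
    table = data.frame(bin = seq_len(n_bins),
                       n = as.vector(table(factor(bin, seq_len(n_bins)))),
                       summary = med),
    trend_rho = suppressWarnings(
      cor(seq_len(n_bins), med, method = "spearman")),
    binned_by = "expression", statistic = "median methylation"),
    class = "bin_summary")
}

#' Expression change across hypomethylation-magnitude bins
#'
#' Ranks genes by the magnitude of their methylation loss (`WT - mutant`,
#' i.e. `-delta_methylation` for mutant-minus-WT deltas), bins them into
#' `n_bins` equal-count bins, and summarizes the per-bin mean log2
#' expression change with a Spearman trend over the bin means.
#'
#' @param delta_methylation named numeric, mutant - WT methylation signal.
#' @param delta_expression named numeric, mutant - WT log2 expression.
#' @param n_bins number of bins (default 10).
#' @return a `bin_summary` (see [expression_methylation_bins()]); bin
#'   `n_bins` holds the most hypomethylated genes.
#' @export
hypomethylation_magnitude_bins <- function(delta_methylation,
                                           delta_expression, n_bins = 10) {
  common <- intersect(names(delta_methylation), names(delta_expression))
  if (length(common) < n_bins) stop("fewer genes than bins")
  mag <- -delta_methylation[common]
  de <- delta_expression[common]
  bin <- .rank_bins(mag, n_bins)
  mn <- vapply(seq_len(n_bins), function(b) mean(de[bin == b]), numeric(1))
  structure(list(
    table = data.frame(bin = seq_len(n_bins),
                       n = as.vector(table(factor(bin, seq_len(n_bins)))),
                       summary = mn),
    trend_rho = suppressWarnings(
      cor(seq_len(n_bins), mn, method = "spearman")),
    binned_by = "hypomethylation magnitude",
    statistic = "mean log2 expression change"),
    class = "bin_summary")
}

#' @export
print.bin_summary <- function(x, ...) {
  cat(sprintf("bin_summary: %d bins by %s; trend rho %.3f\n",
              nrow(x$table), x$binned_by, x$trend_rho))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Chromosomal clustering of a gene set
#'
#' Slides a window of `window_genes` consecutive genes (step 1) along each
#' chromosome in gene order and scores the number of set members in the
#' window by the upper-tail hypergeometric probability given the set's
#' genome-wide frequency. Overlapping significant windows (raw
#' `p < alpha`, matching the published procedure) are merged into clusters.
#' Chromosomes with fewer than `window_genes` genes are skipped with a
#' message.
#'
#' @param gene_set character vector of member gene ids.
#' @param annotation gene `GRanges` defining the per-chromosome gene order
#'   (and the universe).
#' @param window_genes window size in genes (default 20).
#' @param alpha raw p-value threshold (default 0.05).
#' @return data.frame, one row per cluster: `chrom`, `start`, `end`
#'   (genomic span of the merged windows), `first_gene`, `last_gene`,
#'   `n_members`, `members` (comma-separated), `best_p`.
#' @export
chromosomal_clusters <- function(gene_set, annotation, window_genes = 20,
                                 alpha = 0.05) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), first_gene = character(),
                      last_gene = character(), n_members = integer(),
                      members = character(), best_p = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(gene_set) || !length(annotation)) return(empty)
  ann <- GenomicRanges::sort(annotation, ignore.strand = TRUE)
  N <- length(ann)
  K <- sum(names(ann) %in% gene_set)
  if (K == 0) return(empty)
  rows <- list()
  for (chrom in unique(as.character(GenomicRanges::seqnames(ann)))) {
    g <- ann[as.character(GenomicRanges::seqnames(ann)) == chrom]
    n_g <- length(g)
    if (n_g < window_genes) {
      message("skipping ", chrom, ": fewer than ", window_genes, " genes")
      next
    }
    member <- names(g) %in% gene_set
    # rolling sum of members over each window of `window_genes` genes
    cm <- cumsum(c(0L, member))
    n_win <- n_g - window_genes + 1L
    k_win <- cm[(window_genes + 1L):(n_g + 1L)] - cm[1:n_win]
    p_win <- phyper(k_win - 1, K, N - K, window_genes, lower.tail = FALSE)
    sig <- which(p_win < alpha)
    if (!length(sig)) next
    # windows i and j overlap iff |i - j| < window_genes
    grp <- cumsum(c(1L, diff(sig) >= window_genes))
    for (gidx in unique(grp)) {
      wins <- sig[grp == gidx]
      gi_first <- min(wins)
      gi_last <- max(wins) + window_genes - 1L
      span <- g[gi_first:gi_last]
      memb <- names(span)[names(span) %in% gene_set]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom,
        start = min(GenomicRanges::start(span)),
        end = max(GenomicRanges::end(span)),
        first_gene = names(span)[1],
        last_gene = names(span)[length(span)],
        n_members = length(memb),
        members = paste(memb, collapse = ","),
        best_p = min(p_win[wins]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
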