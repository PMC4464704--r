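#' Remove genes with extremely low expression everywhere
#'
#' A gene is retained when at least one sample reaches the linear-scale
#' cutoff (boundary inclusive); genes below the cutoff in every sample are
#' removed and listed in the `"removed"` attribute.
#'
#' @param values genes x samples matrix on the linear scale.
#' @param cutoff expression cutoff (default 40).
#' @return filtered matrix with a `"removed"` attribute of dropped gene ids.
#' @export
filter_low_expression <- function(values, cutoff = 40) {
  keep <- apply(values, 1, max) >= cutoff
  out <- values[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(values)[!keep]
  out
}

.anova_terms <- c("G", "C", "L", "GxC", "GxL", "CxL", "GxCxL")

#' Per-gene three-way factorial ANOVA
#'
#' Fits the balanced 2x2x2 fixed-effects ANOVA (genotype x carbon x light)
#' to every gene at once via orthogonal-contrast projection: under the
#' balanced design the seven single-degree-of-freedom term sums of squares
#' are squared contrast sums, so the whole matrix is decomposed in a few
#' matrix products. F and p per term equal the classical ANOVA table
#' (verified against [stats::aov()] in the test suite). Values are analyzed
#' on the log2(x + 1) scale by default, the standard variance-stabilizing
#' transform for linear-scale microarray summaries.
#'
#' @param values genes x samples matrix (linear scale unless
#'   `log2_transform = FALSE`).
#' @param design data.frame with columns `sample`, `genotype` (`WT`/`mut`),
#'   `carbon` (`-`/`+`), `light` (`-`/`+`), `rep`; must be balanced with at
#'   least two replicates per cell.
#' @param log2_transform analyze `log2(values + 1)`?
#' @return data.frame with, per gene, `p_<term>` and `fdr_<term>` for the
#'   terms G, C, L, GxC, GxL, CxL, GxCxL (BH across genes within each
#'   term), and the log2 main-effect contrasts `effect_G` (mut - WT),
#'   `effect_C`, `effect_L`.
#' @export
fit_three_way_anova <- function(values, design, log2_transform = TRUE) {
  if (ncol(values) != nrow(design) ||
      (!is.null(colnames(values)) &&
       !identical(colnames(values), design$sample)))
    stop("values columns must match design samples")
  cells <- table(design$genotype, design$carbon, design$light)
  if (length(cells) != 8 || length(unique(as.vector(cells))) != 1)
    stop("design must be a balanced full 2x2x2 factorial")
  n_rep <- unique(as.vector(cells))
  if (n_rep < 2) stop("at least two replicates per cell are required")

  n <- nrow(design)
  xg <- ifelse(design$genotype == "mut", 1, -1)
  xc <- ifelse(design$carbon == "+", 1, -1)
  xl <- ifelse(design$light == "+", 1, -1)
  X <- cbind(G = xg, C = xc, L = xl, GxC = xg * xc, GxL = xg * xl,
             CxL = xc * xl, GxCxL = xg * xc * xl)

  Y <- if (log2_transform) log2(values + 1) else values
  cs <- Y %*% X                         # contrast sums, genes x 7
  ss <- cs^2 / n                        # per-term SS (1 df each)
  tot <- rowSums((Y - rowMeans(Y))^2)
  ss_res <- pmax(tot - rowSums(ss), 0)
  df_res <- n - 8L
  fstat <- ss / (ss_res / df_res)
  pmat <- pf(fstat, 1, df_res, lower.tail = FALSE)

  out <- data.frame(gene_id = rownames(values), stringsAsFactors = FALSE)
  for (j in seq_along(.anova_terms)) {
    out[[paste0("p_", .anova_terms[j])]] <- pmat[, j]
    out[[paste0("fdr_", .anova_terms[j])]] <- adjust_fdr(pmat[, j])
  }
  out$effect_G <- 2 * cs[, "G"] / n
  out$effect_C <- 2 * cs[, "C"] / n
  out$effect_L <- 2 * cs[, "L"] / n
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment of a p-value column (the
#' procedure applied wherever the pipeline reports an FDR).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted q-values, same order as `p`.
#' @export
adjust_fdr <- function(p) {
  p.adjust(p, method = "BH")
}

#' Derive the factorial response gene sets
#'
#' Splits the genotype-significant genes by the sign of the mutant - WT
#' log2 contrast into down- and up-regulated sets, and collects the
#' carbon-responsive, light-responsive, and genotype-by-light interaction
#' sets at their respective FDR thresholds.
#'
#' @param anova_table output of [fit_three_way_anova()].
#' @param g_fdr FDR threshold for the genotype sets (default 0.05).
#' @param cl_fdr FDR threshold for the carbon/light sets (default 0.05).
#' @param gxl_fdr FDR threshold for the interaction set (default 0.15).
#' @return list of class `response_sets` with character-vector members
#'   `down_in_mut`, `up_in_mut`, `c_responsive`, `l_responsive`, `gxl`, and
#'   a `counts` summary.
#' @export
classify_response_sets <- function(anova_table, g_fdr = 0.05,
                                   cl_fdr = 0.05, gxl_fdr = 0.15) {
  tb <- anova_table
  sets <- list(
    down_in_mut = tb$gene_id[tb$fdr_G < g_fdr & tb$effect_G < 0],
    up_in_mut = tb$gene_id[tb$fdr_G < g_fdr & tb$effect_G > 0],
    c_responsive = tb$gene_id[tb$fdr_C < cl_fdr],
    l_responsive = tb$gene_id[tb$fdr_L < cl_fdr],
    gxl = tb$gene_id[tb$fdr_GxL < gxl_fdr])
  sets$counts <- vapply(sets, length, integer(1))
  class(sets) <- "response_sets"
  sets
}

#' @export
print.response_sets <- function(x, ...) {
  cat("response_sets:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-12s %d genes\n", nm, x$counts[[nm]]))
  invisible(x)
}
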