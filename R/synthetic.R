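#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the desk-scale synthetic study: a small multi-
#' chromosome genome, gene models, the fraction of genes carrying the
#' histone mark in wild type, the subset losing it in the mutant
#' (preferentially over the 3' gene body), the subset of those bound by the
#' methyltransferase, fragment-library geometry, and a 2x2x2 factorial
#' expression design (genotype x carbon x light) with per-gene effects.
#'
#' Defaults mirror the study design being emulated: roughly half of genes
#' marked in wild type, about a third of marked genes hypomethylated in the
#' mutant, about 18% of hypomethylated genes directly bound, two ChIP
#' replicates plus input per genotype/condition, three expression replicates
#' per factorial cell, and a baseline chosen so that ~5% of genes fall below
#' the linear-scale expression cutoff of 40 in every sample.
#'
#' @param n_genes number of gene models to place.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param gene_length_range min/max gene body length (bp).
#' @param intergenic_gap_range min/max gap between consecutive genes (bp).
#' @param frac_marked fraction of genes carrying the mark in wild type.
#' @param frac_hypo fraction of marked genes losing the mark in the mutant.
#' @param frac_bound fraction of hypomethylated genes bound by the enzyme.
#' @param enrichment_fold mean ChIP over background fragment density in
#'   marked gene bodies.
#' @param three_prime_attenuation multiplicative density factor applied to
#'   the 3' 60% of hypomethylated gene bodies in the mutant ChIP library
#'   (0 = complete loss of 3' signal).
#' @param attenuation_from transcript-relative position (0-1) where mutant
#'   attenuation begins; default 0.4 (the 3' 60% of the body).
#' @param fragment_length fixed fragment length (bp).
#' @param library_size expected fragments per library (Poisson-distributed).
#' @param expr_baseline_log2_mean,expr_baseline_log2_sd per-gene baseline
#'   expression on the log2 scale.
#' @param effect_log2 named vector of log2 effect sizes for `G`, `C`, `L`
#'   and `GxL` terms.
#' @param noise_log2_sd residual Gaussian noise on the log2 scale.
#' @param frac_up fraction of non-hypomethylated genes up-regulated in the
#'   mutant.
#' @param frac_c,frac_l,frac_gxl fractions of genes responsive to carbon,
#'   light, and the genotype-by-light interaction.
#' @param n_reps expression replicates per factorial cell.
#' @param seed integer seed making every derived dataset reproducible.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500,
                             chrom_lengths = c(chr1 = 3e6, chr2 = 2e6),
                             gene_length_range = c(1000, 3000),
                             intergenic_gap_range = c(600, 2000),
                             frac_marked = 0.5,
                             frac_hypo = 0.35,
                             frac_bound = 0.18,
                             enrichment_fold = 8,
                             three_prime_attenuation = 0.2,
                             attenuation_from = 0.4,
                             fragment_length = 200,
                             library_size = 2e5,
                             expr_baseline_log2_mean = 8,
                             expr_baseline_log2_sd = 1.6,
                             effect_log2 = c(G = -2, C = 1, L = 1, GxL = 0.5),
                             noise_log2_sd = 0.25,
                             frac_up = 0.1,
                             frac_c = 0.22,
                             frac_l = 0.35,
                             frac_gxl = 0.01,
                             n_reps = 3,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              chrom_lengths = chrom_lengths,
              gene_length_range = as.integer(gene_length_range),
              intergenic_gap_range = as.integer(intergenic_gap_range),
              frac_marked = frac_marked, frac_hypo = frac_hypo,
              frac_bound = frac_bound,
              enrichment_fold = enrichment_fold,
              three_prime_attenuation = three_prime_attenuation,
              attenuation_from = attenuation_from,
              fragment_length = as.integer(fragment_length),
              library_size = library_size,
              expr_baseline_log2_mean = expr_baseline_log2_mean,
              expr_baseline_log2_sd = expr_baseline_log2_sd,
              effect_log2 = effect_log2,
              noise_log2_sd = noise_log2_sd,
              frac_up = frac_up, frac_c = frac_c, frac_l = frac_l,
              frac_gxl = frac_gxl,
              n_reps = as.integer(n_reps),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  check_genome(cfg$chrom_lengths)
  for (nm in c("frac_marked", "frac_hypo", "frac_bound", "frac_up",
               "frac_c", "frac_l", "frac_gxl"))
    stopifnot_fraction(cfg[[nm]], nm)
  stopifnot_fraction(cfg$three_prime_attenuation, "three_prime_attenuation")
  stopifnot_fraction(cfg$attenuation_from, "attenuation_from")
  if (cfg$library_size <= 0) stop("library_size must be positive")
  if (cfg$n_genes < 0) stop("n_genes must be non-negative")
  if (any(!is.finite(cfg$effect_log2))) stop("effects must be finite")
  if (!all(c("G", "C", "L", "GxL") %in% names(cfg$effect_log2)))
    stop("effect_log2 must name G, C, L and GxL")
  if (diff(cfg$gene_length_range) < 0 || cfg$gene_length_range[1] < 40)
    stop("gene_length_range must be increasing and allow >= 40 bp bodies")
  if (cfg$n_reps < 1) stop("n_reps must be >= 1")
  invisible(cfg)
}

# Margin kept free of genes at each chromosome end so 500 bp metagene
# flanks always stay on-chromosome.
.edge_margin <- 600L

#' Place gene models and draw ground-truth labels
#'
#' Lays out non-overlapping gene models in coordinate order across the
#' configured chromosomes (lengths and intergenic gaps drawn uniformly from
#' the configured ranges, strands ~50/50), then draws the per-gene truth
#' labels: `marked` in wild type, `hypo` (mark lost in the mutant; implies
#' marked), `bound` (enzyme-bound; implies hypo), the expression
#' `de_direction` in the mutant (all hypomethylated genes are down-regulated,
#' a further `frac_up` of the remainder up-regulated), and carbon/light/
#' interaction responsiveness flags.
#'
#' @param config a [synthetic_config()].
#' @return list with `annotation` (a `GRanges`, names = gene ids, sorted by
#'   coordinate) and `truth` (a data.frame of per-gene labels).
#' @export
build_annotation <- function(config) {
  cfg <- validate_synthetic_config(config)
  genome <- cfg$chrom_lengths
  if (cfg$n_genes == 0) {
    gr <- GenomicRanges::GRanges()
    gr <- set_genome(gr, genome)
    truth <- data.frame(gene_id = character(), marked = logical(),
                        hypo = logical(), bound = logical(),
                        de_direction = character(),
                        c_responsive = logical(), l_responsive = logical(),
                        gxl = logical(), stringsAsFactors = FALSE)
    return(list(annotation = gr, truth = truth))
  }
  with_seed(cfg$seed, {
    # apportion genes to chromosomes by length (largest remainder)
    quota <- cfg$n_genes * genome / sum(genome)
    n_per <- floor(quota)
    left <- cfg$n_genes - sum(n_per)
    if (left > 0) {
      extra <- order(quota - n_per, decreasing = TRUE)[seq_len(left)]
      n_per[extra] <- n_per[extra] + 1
    }
    chrom <- character(0); gstart <- integer(0); gend <- integer(0)
    for (ci in seq_along(genome)) {
      n_c <- n_per[ci]
      if (n_c == 0) next
      L <- genome[ci]
      lens <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2],
                     n_c, replace = TRUE)
      gaps <- sample(cfg$intergenic_gap_range[1]:cfg$intergenic_gap_range[2],
                     n_c, replace = TRUE)
      starts <- .edge_margin + cumsum(gaps) + cumsum(c(0L, lens[-n_c]))
      ends <- starts + lens - 1L
      if (ends[n_c] > L - .edge_margin)
        stop(sprintf(
          "cannot place %d genes on %s (length %d): need up to %d bp",
          n_c, names(genome)[ci], L, ends[n_c] + .edge_margin))
      chrom <- c(chrom, rep(names(genome)[ci], n_c))
      gstart <- c(gstart, starts); gend <- c(gend, ends)
    }
    ids <- sprintf("g%04d", seq_len(cfg$n_genes))
    gr <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(gstart, gend),
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE))
    names(gr) <- ids
    gr$gene_id <- ids
    gr <- set_genome(gr, genome)

    marked <- as.logical(rbinom(cfg$n_genes, 1, cfg$frac_marked))
    hypo <- marked & as.logical(rbinom(cfg$n_genes, 1, cfg$frac_hypo))
    bound <- hypo & as.logical(rbinom(cfg$n_genes, 1, cfg$frac_bound))
    de <- ifelse(hypo, "down",
                 ifelse(as.logical(rbinom(cfg$n_genes, 1, cfg$frac_up)),
                        "up", "none"))
    truth <- data.frame(
      gene_id = ids, marked = marked, hypo = hypo, bound = bound,
      de_direction = de,
      c_responsive = as.logical(rbinom(cfg$n_genes, 1, cfg$frac_c)),
      l_responsive = as.logical(rbinom(cfg$n_genes, 1, cfg$frac_l)),
      gxl = as.logical(rbinom(cfg$n_genes, 1, cfg$frac_gxl)),
      stringsAsFactors = FALSE)
    list(annotation = gr, truth = truth)
  })
}

# Per-base signal weight over a gene body, transcript-oriented 5'->3':
# linear 1.5 at the TSS tapering to 0.75 at the TTS, normalized to mean 1,
# then (mutant, hypo genes) attenuated over the 3' portion.
.body_weights <- function(width, attenuate = FALSE, attenuation = 1,
                          from = 0.4) {
  w <- seq(1.5, 0.75, length.out = width)
  w <- w / mean(w)
  if (attenuate) {
    i0 <- floor(from * width) + 1L
    if (i0 <= width) w[i0:width] <- w[i0:width] * attenuation
  }
  w
}

#' Simulate a ChIP or input fragment library
#'
#' Draws a fragment library of expected size `config$library_size` (actual
#' size Poisson-distributed). `input` places fragment midpoints uniformly
#' over the genome. `chip_mark` adds, on top of that uniform background,
#' `enrichment_fold`-weighted fragment density over marked gene bodies with
#' a 5'-weighted linear profile; for `genotype = "mut"` the density over the
#' 3' portion of hypomethylated gene bodies is multiplied by
#' `three_prime_attenuation`. `chip_binding` adds uniform-density peaks over
#' enzyme-bound gene bodies only. Fragments are fixed-length and strandless.
#'
#' @param annotation gene `GRanges` from [build_annotation()].
#' @param truth matching truth data.frame.
#' @param genotype `"WT"` or `"mut"`.
#' @param library_kind `"chip_mark"`, `"input"`, or `"chip_binding"`.
#' @param config the [synthetic_config()].
#' @param seed integer seed for this library (defaults to `config$seed`).
#' @return a fragment `GRanges` with seqlengths set.
#' @export
simulate_chip_fragments <- function(annotation, truth,
                                    genotype = c("WT", "mut"),
                                    library_kind = c("chip_mark", "input",
                                                     "chip_binding"),
                                    config, seed = config$seed) {
  genotype <- match.arg(genotype)
  library_kind <- match.arg(library_kind)
  cfg <- validate_synthetic_config(config)
  if (length(annotation) != nrow(truth) ||
      (length(annotation) &&
       !identical(names(annotation), truth$gene_id)))
    stop("annotation and truth are inconsistent")
  genome <- cfg$chrom_lengths
  fl <- cfg$fragment_length

  sig_genes <- switch(library_kind,
    input = integer(0),
    chip_mark = which(truth$marked),
    chip_binding = which(truth$bound))

  with_seed(seed, {
    widths <- GenomicRanges::width(annotation)
    wlist <- vector("list", length(sig_genes))
    mass <- numeric(length(sig_genes))
    for (j in seq_along(sig_genes)) {
      g <- sig_genes[j]
      if (library_kind == "chip_mark") {
        att <- genotype == "mut" && truth$hypo[g]
        wv <- .body_weights(widths[g], attenuate = att,
                            attenuation = cfg$three_prime_attenuation,
                            from = cfg$attenuation_from)
      } else {
        wv <- rep(1, widths[g])
      }
      wlist[[j]] <- wv
      mass[j] <- (cfg$enrichment_fold - 1) * sum(wv)
    }

    n_total <- rpois(1, cfg$library_size)
    masses <- c(background = sum(genome), mass)
    alloc <- as.vector(rmultinom(1, n_total, masses))
    n_bg <- alloc[1]

    # background midpoints: chromosome by length, position uniform
    chr_idx <- sample.int(length(genome), n_bg, replace = TRUE,
                          prob = genome)
    mid_chrom <- names(genome)[chr_idx]
    mid_pos <- floor(runif(n_bg) * genome[chr_idx]) + 1L

    # signal midpoints per gene, 5'-weighted within the body
    for (j in seq_along(sig_genes)) {
      n_g <- alloc[j + 1]
      if (n_g == 0) next
      g <- sig_genes[j]
      idx <- sample.int(widths[g], n_g, replace = TRUE, prob = wlist[[j]])
      pos <- if (as.character(GenomicRanges::strand(annotation)[g]) == "-")
        GenomicRanges::end(annotation)[g] - idx + 1L
      else
        GenomicRanges::start(annotation)[g] + idx - 1L
      mid_chrom <- c(mid_chrom, rep(as.character(
        GenomicRanges::seqnames(annotation)[g]), n_g))
      mid_pos <- c(mid_pos, pos)
    }

    st <- mid_pos - fl %/% 2L
    en <- st + fl - 1L
    lens <- unname(genome[mid_chrom])
    st <- pmax(st, 1L)
    en <- pmin(en, lens)
    gr <- GenomicRanges::GRanges(mid_chrom, IRanges::IRanges(st, en),
                                 strand = "*")
    set_genome(gr, genome)
  })
}

#' Simulate the factorial expression matrix
#'
#' Builds a balanced 2x2x2 (genotype x carbon x light) design with
#' `n_reps` replicates per cell. On the log2 scale each value is the gene's
#' baseline plus its assigned effects — the genotype effect for genes with a
#' `de_direction` (sign flipped for `up` genes), the carbon/light effects for
#' responsive genes in treated samples, the interaction effect in the
#' (mutant, light+) cells for interaction genes — plus Gaussian noise. The
#' matrix is returned on the linear scale, as microarray summaries are, so
#' the low-expression cutoff can be exercised downstream.
#'
#' @param truth truth data.frame from [build_annotation()].
#' @param config the [synthetic_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `values` (genes x samples linear-scale matrix) and
#'   `design` (data.frame: sample, genotype, carbon, light, rep).
#' @export
simulate_expression <- function(truth, config, seed = config$seed) {
  cfg <- validate_synthetic_config(config)
  if (cfg$n_reps < 2) stop("n_reps must be >= 2 for the factorial design")
  design <- expand.grid(rep = seq_len(cfg$n_reps),
                        light = c("-", "+"), carbon = c("-", "+"),
                        genotype = c("WT", "mut"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("genotype", "carbon", "light", "rep")]
  design$sample <- sprintf("%s_C%s_L%s_r%d", design$genotype,
                           design$carbon, design$light, design$rep)
  design <- design[, c("sample", "genotype", "carbon", "light", "rep")]

  n_g <- nrow(truth); n_s <- nrow(design)
  eff <- cfg$effect_log2
  with_seed(seed, {
    baseline <- rnorm(n_g, cfg$expr_baseline_log2_mean,
                      cfg$expr_baseline_log2_sd)
    g_eff <- ifelse(truth$de_direction == "down", eff[["G"]],
                    ifelse(truth$de_direction == "up", -eff[["G"]], 0))
    is_mut <- design$genotype == "mut"
    is_cp <- design$carbon == "+"
    is_lp <- design$light == "+"
    logv <- matrix(baseline, n_g, n_s)
    logv <- logv + outer(g_eff, as.numeric(is_mut))
    logv <- logv + outer(ifelse(truth$c_responsive, eff[["C"]], 0),
                         as.numeric(is_cp))
    logv <- logv + outer(ifelse(truth$l_responsive, eff[["L"]], 0),
                         as.numeric(is_lp))
    logv <- logv + outer(ifelse(truth$gxl, eff[["GxL"]], 0),
                         as.numeric(is_mut & is_lp))
    if (cfg$noise_log2_sd > 0)
      logv <- logv + matrix(rnorm(n_g * n_s, 0, cfg$noise_log2_sd), n_g, n_s)
    values <- 2^logv
    dimnames(values) <- list(truth$gene_id, design$sample)
    list(values = values, design = design)
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [build_annotation()], then
#' [simulate_chip_fragments()] for every library in the study design —
#' per genotype and condition, `n_chip_reps` mark-ChIP replicates plus one
#' input, and one enzyme-binding ChIP library overall — and
#' [simulate_expression()]. Library seeds are derived deterministically
#' from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param conditions character vector of condition labels included in the
#'   fragment design (marks are simulated independently of condition).
#' @param n_chip_reps mark-ChIP replicates per genotype/condition.
#' @return list with `annotation`, `truth`, `fragments` (named list of
#'   fragment `GRanges`), `fragment_design` (data.frame), `expression`.
#' @export
simulate_study <- function(config, conditions = "CpLp", n_chip_reps = 2) {
  cfg <- validate_synthetic_config(config)
  ann <- build_annotation(cfg)
  frag_design <- expand.grid(
    rep = seq_len(n_chip_reps), library_kind = "chip_mark",
    condition = conditions, genotype = c("WT", "mut"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  inputs <- expand.grid(
    rep = 1L, library_kind = "input",
    condition = conditions, genotype = c("WT", "mut"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  binding <- data.frame(rep = 1L, library_kind = "chip_binding",
                        condition = conditions[1], genotype = "WT",
                        stringsAsFactors = FALSE)
  frag_design <- rbind(frag_design, inputs, binding)
  frag_design <- frag_design[, c("genotype", "condition", "library_kind",
                                 "rep")]
  frag_design$name <- sprintf("%s_%s_%s_rep%d", frag_design$genotype,
                              frag_design$condition,
                              frag_design$library_kind, frag_design$rep)
  fragments <- vector("list", nrow(frag_design))
  names(fragments) <- frag_design$name
  for (i in seq_len(nrow(frag_design))) {
    fragments[[i]] <- simulate_chip_fragments(
      ann$annotation, ann$truth,
      genotype = frag_design$genotype[i],
      library_kind = frag_design$library_kind[i],
      config = cfg,
      seed = (cfg$seed + i * 7919L) %% .Machine$integer.max)
  }
  expr <- simulate_expression(ann$truth, cfg,
                              seed = (cfg$seed + 104729L) %%
                                .Machine$integer.max)
  list(annotation = ann$annotation, truth = ann$truth,
       fragments = fragments, fragment_design = frag_design,
       expression = expr)
}
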