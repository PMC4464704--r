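test_that("annotation layout respects the config and its invariants", {
  empty <- build_annotation(tiny_cfg(n_genes = 0))
  expect_length(empty$annotation, 0)
  expect_equal(nrow(empty$truth), 0)

  all_marked <- build_annotation(tiny_cfg(frac_marked = 1, seed = 3))
  expect_true(all(all_marked$truth$marked))

  ann <- build_annotation(tiny_cfg(seed = 5))
  gr <- ann$annotation
  # non-overlapping, coordinate-ordered, inside the chromosome
  expect_true(all(diff(GenomicRanges::start(gr)) > 0))
  expect_true(all(GenomicRanges::start(gr)[-1] >
                    GenomicRanges::end(gr)[-length(gr)]))
  expect_true(all(GenomicRanges::end(gr) <=
                    tiny_cfg()$chrom_lengths["chrA"]))
  # truth label implications
  expect_true(all(ann$truth$marked[ann$truth$hypo]))
  expect_true(all(ann$truth$hypo[ann$truth$bound]))
  expect_setequal(ann$truth$gene_id, names(gr))
  # determinism
  ann2 <- build_annotation(tiny_cfg(seed = 5))
  expect_identical(ann$truth, ann2$truth)
  expect_identical(GenomicRanges::start(gr),
                   GenomicRanges::start(ann2$annotation))

  expect_error(build_annotation(
    synthetic_config(n_genes = 500, chrom_lengths = c(c1 = 1e5))),
    "cannot place")
})

test_that("truth fractions fall in binomial 99% bounds at n = 500", {
  cfg <- synthetic_config(n_genes = 500, frac_hypo = 0.4, seed = 11)
  ann <- build_annotation(cfg)
  n_marked <- sum(ann$truth$marked)
  n_hypo <- sum(ann$truth$hypo)
  # oracle: central 99% binomial interval at the realized number of draws
  lo <- qbinom(0.005, n_marked, 0.4)
  hi <- qbinom(0.995, n_marked, 0.4)
  expect_gte(n_hypo, lo)
  expect_lte(n_hypo, hi)
  n_mk_lo <- qbinom(0.005, 500, cfg$frac_marked)
  n_mk_hi <- qbinom(0.995, 500, cfg$frac_marked)
  expect_gte(n_marked, n_mk_lo)
  expect_lte(n_marked, n_mk_hi)
})

test_that("fragment libraries have the configured size and background", {
  cfg <- synthetic_config(n_genes = 50, chrom_lengths = c(chr1 = 1e6),
                          library_size = 1e5, seed = 21)
  ann <- build_annotation(cfg)
  inp <- simulate_chip_fragments(ann$annotation, ann$truth, "WT", "input",
                                 cfg, seed = 22)
  # library size within 4 * sqrt(lambda) of the target
  expect_lt(abs(length(inp) - cfg$library_size), 4 * sqrt(cfg$library_size))
  # closed-form background coverage expectation: lib * frag_len / genome
  cov <- compute_coverage(inp, cfg$chrom_lengths)
  obs_mean <- sum(as.numeric(S4Vectors::runValue(cov$cov$chr1)) *
                    S4Vectors::runLength(cov$cov$chr1)) / 1e6
  expected <- length(inp) * cfg$fragment_length / 1e6
  se <- sqrt(length(inp)) * cfg$fragment_length / 1e6
  expect_lt(abs(obs_mean - expected), 3 * se)
  # determinism per seed
  inp2 <- simulate_chip_fragments(ann$annotation, ann$truth, "WT", "input",
                                  cfg, seed = 22)
  expect_identical(GenomicRanges::start(inp), GenomicRanges::start(inp2))
})

test_that("enrichment_fold = 1 leaves ChIP indistinguishable from input", {
  cfg <- synthetic_config(n_genes = 50, chrom_lengths = c(chr1 = 1e6),
                          library_size = 1e5, enrichment_fold = 1,
                          seed = 31)
  ann <- build_annotation(cfg)
  chip <- simulate_chip_fragments(ann$annotation, ann$truth, "WT",
                                  "chip_mark", cfg, seed = 32)
  inp <- simulate_chip_fragments(ann$annotation, ann$truth, "WT", "input",
                                 cfg, seed = 33)
  mean_cov <- function(fr) length(fr) * cfg$fragment_length / 1e6
  expect_lt(abs(mean_cov(chip) / mean_cov(inp) - 1), 0.05)
  # and per-gene-body density matches too (ratio of midpoint counts)
  in_bodies <- function(fr) sum(GenomicRanges::countOverlaps(
    ann$annotation, fr, ignore.strand = TRUE))
  expect_lt(abs(in_bodies(chip) / in_bodies(inp) - 1), 0.1)
})

test_that("complete 3' attenuation reduces mutant coverage to background", {
  cfg <- synthetic_config(n_genes = 60, chrom_lengths = c(chr1 = 1.2e6),
                          library_size = 1e5, three_prime_attenuation = 0,
                          seed = 41)
  ann <- build_annotation(cfg)
  chip <- simulate_chip_fragments(ann$annotation, ann$truth, "mut",
                                  "chip_mark", cfg, seed = 42)
  cov <- compute_coverage(chip, cfg$chrom_lengths)
  hypo <- ann$annotation[ann$truth$hypo]
  # 3' 60% of each body in transcript orientation, trimmed by one fragment
  # length at its 5' edge (fixed-length fragments bleed half a fragment
  # across the attenuation boundary)
  w <- GenomicRanges::width(hypo)
  plus <- as.character(GenomicRanges::strand(hypo)) == "+"
  reg_start <- ifelse(plus,
    GenomicRanges::start(hypo) + floor(0.4 * w) + cfg$fragment_length,
    GenomicRanges::start(hypo))
  reg_end <- ifelse(plus, GenomicRanges::end(hypo),
    GenomicRanges::end(hypo) - floor(0.4 * w) - cfg$fragment_length)
  tot <- 0; bp <- 0
  for (i in seq_along(hypo)) {
    v <- IRanges::Views(cov$cov$chr1, reg_start[i], reg_end[i])
    tot <- tot + sum(IRanges::viewSums(v))
    bp <- bp + reg_end[i] - reg_start[i] + 1
  }
  obs <- tot / bp
  # empirical background: intergenic space one fragment length away from
  # any gene body; same library, so library-composition effects cancel
  margin <- GenomicRanges::resize(
    GenomicRanges::granges(ann$annotation),
    GenomicRanges::width(ann$annotation) + 2L * cfg$fragment_length,
    fix = "center")
  inter <- GenomicRanges::gaps(GenomicRanges::reduce(margin,
                                                     ignore.strand = TRUE))
  inter <- inter[GenomicRanges::strand(inter) == "*" &
                   GenomicRanges::width(inter) > 0]
  bg_tot <- sum(vapply(seq_along(inter), function(i)
    sum(IRanges::viewSums(IRanges::Views(
      cov$cov$chr1, GenomicRanges::start(inter)[i],
      GenomicRanges::end(inter)[i]))), numeric(1)))
  bg_bp <- sum(GenomicRanges::width(inter))
  bg <- bg_tot / bg_bp
  # Poisson SE oracle: SE of a regional mean ~ sqrt(n_frags) * len / bp
  se_reg <- sqrt(obs * bp / cfg$fragment_length) * cfg$fragment_length / bp
  se_bg <- sqrt(bg * bg_bp / cfg$fragment_length) *
    cfg$fragment_length / bg_bp
  expect_lt(abs(obs - bg), 3 * sqrt(se_reg^2 + se_bg^2))
})

test_that("expression matrix realizes the factorial construction", {
  cfg0 <- tiny_cfg(noise_log2_sd = 0,
                   effect_log2 = c(G = 0, C = 0, L = 0, GxL = 0),
                   seed = 51)
  ann <- build_annotation(cfg0)
  ex <- simulate_expression(ann$truth, cfg0, seed = 52)
  # noiseless null: every gene constant across all samples
  expect_equal(max(apply(ex$values, 1, function(r) diff(range(r)))), 0)

  cfg1 <- tiny_cfg(noise_log2_sd = 0, frac_marked = 1, frac_hypo = 1,
                   effect_log2 = c(G = -2, C = 1, L = 1, GxL = 0.5),
                   seed = 53)
  ann1 <- build_annotation(cfg1)
  ex1 <- simulate_expression(ann1$truth, cfg1, seed = 54)
  down <- which(ann1$truth$de_direction == "down")[1]
  mut <- ex1$design$genotype == "mut"
  expect_equal(mean(ex1$values[down, mut]) * 4,
               mean(ex1$values[down, !mut]))
  # balanced design: 8 cells x n_reps
  expect_equal(nrow(ex1$design), 8 * cfg1$n_reps)
  expect_true(all(table(ex1$design$genotype, ex1$design$carbon,
                        ex1$design$light) == cfg1$n_reps))
})

test_that("fixtures round-trip losslessly and the manifest covers the design", {
  cfg <- tiny_cfg(library_size = 2e3, seed = 61)
  study <- simulate_study(cfg, conditions = c("plain", "treated"))
  outdir <- withr::local_tempdir()
  manifest <- write_fixtures(study$annotation, study$truth,
                             study$fragments, study$expression, outdir)

  # one BED per (genotype, condition, library_kind, replicate) design cell
  expect_equal(sum(manifest$kind == "fragments"),
               nrow(study$fragment_design))
  expect_setequal(manifest$name[manifest$kind == "fragments"],
                  study$fragment_design$name)

  ann2 <- read_annotation(file.path(outdir, "annotation.gff3"),
                          genome = cfg$chrom_lengths)
  expect_identical(names(ann2), names(study$annotation))
  expect_identical(GenomicRanges::start(ann2),
                   GenomicRanges::start(study$annotation))
  expect_identical(GenomicRanges::end(ann2),
                   GenomicRanges::end(study$annotation))
  expect_identical(as.character(GenomicRanges::strand(ann2)),
                   as.character(GenomicRanges::strand(study$annotation)))

  tr2 <- read_truth(file.path(outdir, "truth.tsv"))
  expect_identical(tr2, study$truth)

  fr_name <- manifest$name[manifest$kind == "fragments"][1]
  fr2 <- read_fragments(manifest$path[manifest$name == fr_name][1],
                        genome = cfg$chrom_lengths)
  fr1 <- study$fragments[[fr_name]]
  expect_identical(GenomicRanges::start(GenomicRanges::sort(fr2)),
                   GenomicRanges::start(GenomicRanges::sort(fr1)))

  ex2 <- read_expression(file.path(outdir, "expression.tsv"),
                         file.path(outdir, "expression_design.tsv"))
  expect_equal(ex2$values, study$expression$values, tolerance = 1e-8)
  expect_identical(ex2$design$sample, study$expression$design$sample)
})

test_that("BED output is 0-based half-open on disk", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  gr <- epimark:::set_genome(gr, c(chr1 = 1000))
  f <- withr::local_tempfile(fileext = ".bed")
  rtracklayer::export(gr, f, format = "bed")
  fields <- strsplit(readLines(f)[1], "\t")[[1]]
  expect_identical(fields[2], "0")
  expect_identical(fields[3], "100")
})
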