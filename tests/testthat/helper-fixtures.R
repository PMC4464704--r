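# Shared fixture builders; everything is generated in code at test time.

tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 60, chrom_lengths = c(chrA = 6e5),
         gene_length_range = c(800, 2000),
         intergenic_gap_range = c(600, 1500),
         library_size = 3e4),
    list(...))
  do.call(synthetic_config, args)
}

# uniform-value coverage track over a toy genome, no fragments involved
flat_track <- function(genome, value, rpm = TRUE) {
  cov <- methods::as(lapply(genome, function(L)
    S4Vectors::Rle(value, L)), "SimpleRleList")
  structure(list(cov = cov, library_size = NA_integer_, rpm = rpm,
                 rpm_factor = NA_real_), class = "coverage_track")
}

# coverage track from an explicit per-base numeric vector (single chrom)
vector_track <- function(v, chrom = "chrA") {
  cov <- methods::as(stats::setNames(list(S4Vectors::Rle(v)), chrom),
                     "SimpleRleList")
  structure(list(cov = cov, library_size = NA_integer_, rpm = TRUE,
                 rpm_factor = NA_real_), class = "coverage_track")
}

random_islands <- function(n, genome_len = 1e6, chrom = "chrA",
                           width_range = c(200, 2000)) {
  st <- sample.int(genome_len - width_range[2], n, replace = TRUE)
  wd <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, st + wd - 1))
  gr$p_value <- runif(n)
  gr$fdr <- p.adjust(gr$p_value, "BH")
  gr
}

uniform_fragments <- function(n, genome_len = 1e6, chrom = "chr1",
                              frag_len = 200L) {
  st <- sample.int(genome_len - frag_len, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(st, st + frag_len - 1L))
  epimark:::set_genome(gr, stats::setNames(genome_len, chrom))
}
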