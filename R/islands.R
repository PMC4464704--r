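#' Parameters for island calling
#'
#' Window-cluster calling of broad histone-mark enrichment: fixed
#' `window_bp` windows are scored against the genome-wide background rate
#' (scaled by the effective genome factor, the mappable fraction), eligible
#' windows are clustered across gaps of up to `gap_bp` into islands, and
#' islands are tested against the input library with Benjamini-Hochberg
#' control. Defaults are the standard broad-mark settings: 200 bp windows
#' and gaps, effective genome factor 0.9, redundancy threshold 1, island
#' FDR < 0.01 with ChIP/input enrichment > 2.
#'
#' @param window_bp window size (bp).
#' @param gap_bp maximum ineligible gap bridged within an island; must be a
#'   multiple of `window_bp`.
#' @param effective_genome_factor mappable fraction of the genome used for
#'   the background rate.
#' @param redundancy_threshold maximum identical fragments retained by
#'   [deduplicate_fragments()].
#' @param window_p upper-tail Poisson p-value below which a window is
#'   eligible.
#' @param island_fdr BH threshold for retained islands.
#' @param min_enrichment minimum ChIP/input enrichment for retained islands.
#' @return list of class `island_params`.
#' @export
island_params <- function(window_bp = 200, gap_bp = 200,
                          effective_genome_factor = 0.9,
                          redundancy_threshold = 1,
                          window_p = 0.05, island_fdr = 0.01,
                          min_enrichment = 2) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (gap_bp %% window_bp != 0) stop("gap_bp must be a multiple of window_bp")
  if (effective_genome_factor <= 0 || effective_genome_factor > 1)
    stop("effective_genome_factor must be in (0, 1]")
  if (redundancy_threshold < 1) stop("redundancy_threshold must be >= 1")
  structure(list(window_bp = as.integer(window_bp),
                 gap_bp = as.integer(gap_bp),
                 effective_genome_factor = effective_genome_factor,
                 redundancy_threshold = as.integer(redundancy_threshold),
                 window_p = window_p, island_fdr = island_fdr,
                 min_enrichment = min_enrichment),
            class = "island_params")
}

#' Remove clonal (PCR-duplicate) fragments
#'
#' Retains at most `redundancy_threshold` fragments per identical
#' (chromosome, start, end, strand) key; the surplus is presumed PCR
#' amplification. The result does not depend on input order.
#'
#' @param fragments fragment `GRanges`.
#' @param redundancy_threshold maximum copies retained per position.
#' @return deduplicated fragment `GRanges`, coordinate-sorted.
#' @export
deduplicate_fragments <- function(fragments, redundancy_threshold = 1) {
  if (redundancy_threshold < 1) stop("redundancy_threshold must be >= 1")
  gr <- GenomicRanges::sort(fragments)
  key <- paste(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr),
               as.character(GenomicRanges::strand(gr)), sep = "\r")
  runs <- rle(key)
  occ <- sequence(runs$lengths)
  gr[occ <= redundancy_threshold]
}

#' Per-base fragment coverage
#'
#' Each fragment increments every base it covers; optional RPM scaling
#' multiplies by 1e6 / library size (library size = number of fragments).
#'
#' @param fragments deduplicated fragment `GRanges`.
#' @param genome named chromosome lengths.
#' @param rpm scale to reads-per-million?
#' @return list of class `coverage_track`: `cov` (an `RleList`),
#'   `library_size`, `rpm`, `rpm_factor`.
#' @export
compute_coverage <- function(fragments, genome, rpm = FALSE) {
  genome <- check_genome(genome)
  bad <- !(as.character(GenomicRanges::seqnames(fragments)) %in%
             names(genome))
  if (any(bad)) stop("fragments on chromosomes absent from genome")
  lens <- genome[as.character(GenomicRanges::seqnames(fragments))]
  if (any(GenomicRanges::start(fragments) < 1) ||
      any(GenomicRanges::end(fragments) > lens))
    stop("fragment outside chromosome bounds")
  fr <- set_genome(fragments, genome)
  cov <- GenomicRanges::coverage(fr, width = as.list(genome))
  n <- length(fragments)
  fac <- if (n > 0) 1e6 / n else NA_real_
  if (rpm) cov <- cov * fac
  structure(list(cov = cov, library_size = n, rpm = rpm, rpm_factor = fac),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d fragments over %d chromosome(s)%s\n",
              x$library_size, length(x$cov),
              if (x$rpm) ", RPM-scaled" else ""))
  invisible(x)
}

# window index of each fragment midpoint; windows tile [1, nwin*w]
.window_counts <- function(fragments, chrom, nwin, w) {
  fr <- fragments[as.character(GenomicRanges::seqnames(fragments)) == chrom]
  if (!length(fr)) return(integer(nwin))
  mid <- (GenomicRanges::start(fr) + GenomicRanges::end(fr)) %/% 2L
  widx <- (mid - 1L) %/% w + 1L
  widx <- widx[widx >= 1L & widx <= nwin]
  tabulate(widx, nbins = nwin)
}

# midpoint count of fragments within [start, end] on given chromosomes
.region_counts <- function(fragments, chrom, start, end) {
  mid <- (GenomicRanges::start(fragments) +
            GenomicRanges::end(fragments)) %/% 2L
  mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(fragments),
                                 IRanges::IRanges(mid, mid))
  regions <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  GenomicRanges::countOverlaps(regions, mids)
}

#' Call enriched islands against an input library
#'
#' Tiles each chromosome into non-overlapping `window_bp` windows and counts
#' ChIP fragment midpoints per window. A window is eligible when its count
#' is improbably high under the genome-wide Poisson background rate
#' `lambda_w = library_size * window_bp / (effective_genome_factor * genome
#' length)` (upper-tail p < `window_p`). Maximal runs of eligible windows,
#' bridging ineligible gaps up to `gap_bp`, form candidate islands. Each
#' island is then tested by an upper-tail Poisson comparison of its ChIP
#' count against the larger of the library-size-scaled input count and the
#' background expectation, BH-adjusted across islands; islands with
#' `fdr < island_fdr` and ChIP/input enrichment `> min_enrichment` are
#' retained.
#'
#' @param chip deduplicated ChIP fragment `GRanges`.
#' @param input deduplicated input fragment `GRanges`, or `NULL` to test
#'   against the genomic background alone.
#' @param genome named chromosome lengths.
#' @param params an [island_params()].
#' @param keep_all return all candidate islands (with a `retained` flag)
#'   instead of retained islands only?
#' @return island `GRanges`, coordinate-sorted and window-aligned, with
#'   columns `chip_count`, `input_count`, `enrichment`, `p_value`, `fdr`
#'   (and `retained` when `keep_all = TRUE`).
#' @export
call_islands <- function(chip, input = NULL, genome,
                         params = island_params(), keep_all = FALSE) {
  genome <- check_genome(genome)
  if (length(chip) == 0) stop("empty chip library")
  w <- params$window_bp
  gap_win <- params$gap_bp %/% w
  lib_chip <- length(chip)
  lib_input <- if (is.null(input)) NA_integer_ else length(input)
  lambda_w <- lib_chip * w /
    (params$effective_genome_factor * sum(genome))
  # smallest count k with P(X >= k) < window_p
  k0 <- qpois(1 - params$window_p, lambda_w)
  while (ppois(k0 - 1, lambda_w, lower.tail = FALSE) >= params$window_p)
    k0 <- k0 + 1L

  out <- list()
  for (chrom in names(genome)) {
    nwin <- as.integer(genome[chrom] %/% w)
    if (nwin == 0) next
    counts <- .window_counts(chip, chrom, nwin, w)
    elig <- which(counts >= k0)
    if (!length(elig)) next
    grp <- cumsum(c(1L, diff(elig) > gap_win + 1L))
    first <- tapply(elig, grp, min)
    last <- tapply(elig, grp, max)
    isl_start <- (first - 1L) * w + 1L
    isl_end <- last * w
    chip_count <- vapply(seq_along(first), function(i)
      sum(counts[first[i]:last[i]]), numeric(1))
    out[[chrom]] <- data.frame(
      chrom = chrom, start = isl_start, end = isl_end,
      n_windows = as.integer(last - first + 1L),
      chip_count = chip_count, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      chip_count = numeric(0), input_count = numeric(0),
      enrichment = numeric(0), p_value = numeric(0), fdr = numeric(0))
    return(set_genome(gr, genome))
  }
  tab <- do.call(rbind, out)

  if (is.null(input)) {
    tab$input_count <- NA_real_
    expected <- lambda_w * tab$n_windows
    tab$enrichment <- tab$chip_count / expected
  } else {
    tab$input_count <- .region_counts(input, tab$chrom, tab$start, tab$end)
    expected <- pmax(tab$input_count * lib_chip / lib_input,
                     lambda_w * tab$n_windows)
    # pseudocount 0.5 guards the ratio only; the test uses raw counts
    tab$enrichment <- ((tab$chip_count + 0.5) / lib_chip) /
      ((tab$input_count + 0.5) / lib_input)
  }
  tab$p_value <- ppois(tab$chip_count - 1, expected, lower.tail = FALSE)
  tab$fdr <- p.adjust(tab$p_value, method = "BH")
  tab$retained <- tab$fdr < params$island_fdr &
    tab$enrichment > params$min_enrichment

  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start, tab$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    tab[, c("chip_count", "input_count", "enrichment", "p_value", "fdr",
            "retained")])
  gr <- set_genome(gr, genome)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!keep_all) {
    gr <- gr[gr$retained]
    gr$retained <- NULL
  }
  gr
}

#' Call differential islands between two ChIP libraries
#'
#' Candidate regions are the disjoint atoms of the union of islands called
#' in either library (against its input when given, else against the
#' genomic background): where the two libraries' islands differ in extent —
#' the signature of a positional mark loss — the differing stretch is
#' tested on its own rather than averaged into the full island. Each
#' region's raw fragment counts in the two libraries are
#' compared by the exact conditional two-sided test of two Poisson rates
#' with the library sizes as exposures ([stats::poisson.test()]), BH
#' adjusted across regions. The fold change is the larger over the smaller
#' RPM with a 0.5 pseudocount on both counts; a region is significant iff
#' `fdr < fdr_cutoff` and `fold_change > fc_cutoff`.
#'
#' @param chip_a,chip_b deduplicated ChIP fragment `GRanges`.
#' @param genome named chromosome lengths.
#' @param params an [island_params()] used for candidate calling.
#' @param fc_cutoff fold-change threshold (default 2; use 1.3 for mild
#'   treatment contrasts).
#' @param fdr_cutoff BH threshold (default 0.05).
#' @param input_a,input_b optional matching input libraries.
#' @return candidate-region `GRanges` with columns `count_a`, `count_b`,
#'   `rpm_a`, `rpm_b`, `fold_change`, `direction` (`"a_up"`/`"b_up"`),
#'   `p_value`, `fdr`, `significant`.
#' @export
call_differential_islands <- function(chip_a, chip_b, genome,
                                      params = island_params(),
                                      fc_cutoff = 2, fdr_cutoff = 0.05,
                                      input_a = NULL, input_b = NULL) {
  genome <- check_genome(genome)
  isl_a <- call_islands(chip_a, input_a, genome, params)
  isl_b <- call_islands(chip_b, input_b, genome, params)
  cand <- GenomicRanges::disjoin(c(GenomicRanges::granges(isl_a),
                                   GenomicRanges::granges(isl_b)))
  lib_a <- length(chip_a); lib_b <- length(chip_b)
  if (!length(cand)) {
    S4Vectors::mcols(cand) <- S4Vectors::DataFrame(
      count_a = numeric(0), count_b = numeric(0), rpm_a = numeric(0),
      rpm_b = numeric(0), fold_change = numeric(0),
      direction = character(0), p_value = numeric(0), fdr = numeric(0),
      significant = logical(0))
    return(cand)
  }
  chroms <- as.character(GenomicRanges::seqnames(cand))
  count_a <- .region_counts(chip_a, chroms, GenomicRanges::start(cand),
                            GenomicRanges::end(cand))
  count_b <- .region_counts(chip_b, chroms, GenomicRanges::start(cand),
                            GenomicRanges::end(cand))
  rpm_a <- (count_a + 0.5) / lib_a * 1e6
  rpm_b <- (count_b + 0.5) / lib_b * 1e6
  fc <- pmax(rpm_a, rpm_b) / pmin(rpm_a, rpm_b)
  direction <- ifelse(rpm_a >= rpm_b, "a_up", "b_up")
  p <- vapply(seq_along(count_a), function(i)
    poisson.test(c(count_a[i], count_b[i]), c(lib_a, lib_b))$p.value,
    numeric(1))
  fdr <- p.adjust(p, method = "BH")
  S4Vectors::mcols(cand) <- S4Vectors::DataFrame(
    count_a = count_a, count_b = count_b, rpm_a = rpm_a, rpm_b = rpm_b,
    fold_change = fc, direction = direction, p_value = p, fdr = fdr,
    significant = fdr < fdr_cutoff & fc > fc_cutoff)
  GenomicRanges::sort(cand, ignore.strand = TRUE)
}

#' Annotate islands (or differential islands) to genes
#'
#' A gene receives an island's status when they overlap by at least
#' `min_overlap_bp`. For plain islands every overlapped gene is `marked`
#' and the rest `unmarked`. For differential islands (recognized by a
#' `direction` column; only significant regions are used) genes overlapped
#' by `a_up` regions get `labels[["a_up"]]`, by `b_up` regions
#' `labels[["b_up"]]`, by both directions `ambiguous` (excluded from
#' downstream sets), and the rest `unchanged`.
#'
#' @param islands island or differential-island `GRanges`.
#' @param annotation gene `GRanges` (names = gene ids).
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @param labels status labels for the two directions of a differential
#'   contrast; the defaults fit a (wild-type, mutant) = (a, b) contrast.
#' @return data.frame with columns `gene_id`, `status`, covering every
#'   annotated gene.
#' @export
annotate_islands_to_genes <- function(islands, annotation,
                                      min_overlap_bp = 1,
                                      labels = c(a_up = "hypomethylated",
                                                 b_up = "hypermethylated")) {
  status <- rep("unmarked", length(annotation))
  diff_mode <- "direction" %in% names(S4Vectors::mcols(islands))
  if (diff_mode) {
    status <- rep("unchanged", length(annotation))
    sig <- islands[islands$significant]
    hit_a <- GenomicRanges::countOverlaps(
      annotation, sig[sig$direction == "a_up"],
      minoverlap = min_overlap_bp, ignore.strand = TRUE) > 0
    hit_b <- GenomicRanges::countOverlaps(
      annotation, sig[sig$direction == "b_up"],
      minoverlap = min_overlap_bp, ignore.strand = TRUE) > 0
    status[hit_a] <- labels[["a_up"]]
    status[hit_b] <- labels[["b_up"]]
    status[hit_a & hit_b] <- "ambiguous"
  } else {
    hit <- GenomicRanges::countOverlaps(
      annotation, islands, minoverlap = min_overlap_bp,
      ignore.strand = TRUE) > 0
    status[hit] <- "marked"
  }
  data.frame(gene_id = names(annotation), status = status,
             stringsAsFactors = FALSE)
}
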