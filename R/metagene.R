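#' Binning scheme for metagene profiles
#'
#' The gene body is scaled into `body_bins` near-equal intervals and each
#' flank of `flank_bp` is split into `flank_bins` fixed-width bins, giving
#' a 60-bin profile under the defaults (10 upstream + 40 body + 10
#' downstream, flank bins of 50 bp).
#'
#' @param body_bins number of scaled gene-body bins.
#' @param flank_bp flank width (bp) on each side.
#' @param flank_bins bins per flank; must divide `flank_bp`.
#' @return list of class `bin_scheme`.
#' @export
bin_scheme <- function(body_bins = 40, flank_bp = 500, flank_bins = 10) {
  if (body_bins <= 0 || flank_bp <= 0 || flank_bins <= 0)
    stop("all scheme fields must be positive")
  if (flank_bp %% flank_bins != 0)
    stop("flank_bp must be divisible by flank_bins")
  structure(list(body_bins = as.integer(body_bins),
                 flank_bp = as.integer(flank_bp),
                 flank_bins = as.integer(flank_bins)),
            class = "bin_scheme")
}

#' Positional profile of one gene
#'
#' Computes the mean per-base coverage in each bin of the scheme. The body
#' is split left-to-right into `body_bins` intervals, the first
#' `width %% body_bins` of which receive one extra base; for minus-strand
#' genes the complete vector is then reversed, so index 1 is always the
#' 5'-most bin and the minus-strand profile is the exact reversal of the
#' plus-strand one. Flanks are fixed `flank_bp` windows immediately outside
#' the body, binned at `flank_bp / flank_bins` bp.
#'
#' @param gene a length-1 `GRanges`.
#' @param coverage a `coverage_track` (RPM-scaled for the published usage).
#' @param scheme a [bin_scheme()].
#' @return numeric vector of length `2 * flank_bins + body_bins`, or `NULL`
#'   when the gene body is shorter than `body_bins` or a flank leaves the
#'   chromosome (such genes are skipped and counted by callers).
#' @export
gene_bin_profile <- function(gene, coverage, scheme = bin_scheme()) {
  chrom <- as.character(GenomicRanges::seqnames(gene))
  if (!chrom %in% names(coverage$cov))
    stop("gene outside coverage track: ", chrom)
  rle <- coverage$cov[[chrom]]
  s <- GenomicRanges::start(gene); e <- GenomicRanges::end(gene)
  L <- e - s + 1L
  nb <- scheme$body_bins
  fb <- scheme$flank_bins
  fw <- scheme$flank_bp %/% fb
  if (L < nb) return(NULL)
  if (s - scheme$flank_bp < 1L || e + scheme$flank_bp > length(rle))
    return(NULL)

  base <- L %/% nb; r <- L %% nb
  widths <- rep.int(base, nb)
  if (r > 0) widths[seq_len(r)] <- widths[seq_len(r)] + 1L
  body_starts <- s + cumsum(c(0L, widths[-nb]))
  body_ends <- body_starts + widths - 1L

  up_starts <- s - scheme$flank_bp + (seq_len(fb) - 1L) * fw
  down_starts <- e + 1L + (seq_len(fb) - 1L) * fw
  starts <- c(up_starts, body_starts, down_starts)
  ends <- c(up_starts + fw - 1L, body_ends, down_starts + fw - 1L)

  v <- IRanges::viewMeans(IRanges::Views(rle, start = starts, end = ends))
  v <- as.numeric(v)
  if (as.character(GenomicRanges::strand(gene)) == "-") v <- rev(v)
  v
}

#' Positional profiles for a set of genes
#'
#' @param annotation gene `GRanges` (names = gene ids).
#' @param coverage a `coverage_track`.
#' @param scheme a [bin_scheme()].
#' @return matrix (genes x bins); genes skipped for length or flank reasons
#'   are dropped and listed in the `"skipped"` attribute.
#' @export
metagene_matrix <- function(annotation, coverage, scheme = bin_scheme()) {
  nbin <- 2L * scheme$flank_bins + scheme$body_bins
  profs <- lapply(seq_along(annotation), function(i)
    gene_bin_profile(annotation[i], coverage, scheme))
  keep <- !vapply(profs, is.null, logical(1))
  m <- do.call(rbind, profs[keep])
  if (is.null(m)) m <- matrix(numeric(0), 0, nbin)
  rownames(m) <- names(annotation)[keep]
  attr(m, "skipped") <- names(annotation)[!keep]
  m
}

#' Aggregate per-gene profiles into a metagene profile
#'
#' Per-bin median over the requested gene set, as used for plotting the
#' positional mark distribution across all significantly marked genes.
#'
#' @param profiles matrix from [metagene_matrix()].
#' @param gene_set character vector of gene ids (must be profiled).
#' @return list of class `metagene_profile`: `profile` (numeric, one value
#'   per bin), `n_genes`, `normalization_factor`.
#' @export
aggregate_profiles <- function(profiles, gene_set = rownames(profiles)) {
  gene_set <- intersect(gene_set, rownames(profiles))
  if (!length(gene_set)) stop("empty gene set")
  sub <- profiles[gene_set, , drop = FALSE]
  structure(list(profile = apply(sub, 2, median),
                 n_genes = length(gene_set),
                 normalization_factor = 1),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(
    "metagene_profile: %d bins over %d genes (normalization factor %.4g)\n",
    length(x$profile), x$n_genes, x$normalization_factor))
  invisible(x)
}

# mean per-base coverage over a set of gene bodies
.gene_body_mean <- function(coverage, annotation, gene_set) {
  genes <- annotation[intersect(gene_set, names(annotation))]
  if (!length(genes)) stop("no genes to normalize over")
  tot <- 0; bp <- 0
  for (chrom in unique(as.character(GenomicRanges::seqnames(genes)))) {
    g <- genes[as.character(GenomicRanges::seqnames(genes)) == chrom]
    v <- IRanges::Views(coverage$cov[[chrom]],
                        start = GenomicRanges::start(g),
                        end = GenomicRanges::end(g))
    tot <- tot + sum(IRanges::viewSums(v))
    bp <- bp + sum(GenomicRanges::width(g))
  }
  tot / bp
}

#' Cross-sample normalization of metagene profiles
#'
#' When the mark landscape differs globally between two samples (for
#' example a methyltransferase mutant retains far fewer marked genes), the
#' RPM scale alone misstates the comparison: the same sequencing depth is
#' spread over a different amount of marked chromatin. Each profile is
#' therefore divided by its own sample's mean RPM coverage over that
#' sample's marked gene bodies, putting the gene-body-mean signal of each
#' sample at 1 in expectation.
#'
#' @param profile_a,profile_b `metagene_profile` objects.
#' @param coverage_a,coverage_b matching RPM `coverage_track`s.
#' @param annotation gene `GRanges`.
#' @param gene_set_a,gene_set_b each sample's marked-gene ids.
#' @param mode `"marked_body_mean"` (default) divides each profile by its
#'   sample's mean coverage over that sample's marked gene bodies;
#'   `"genome_mean"` divides by the sample's whole-genome mean coverage.
#' @return list with normalized `profile_a` and `profile_b`.
#' @export
normalize_profiles_between_samples <- function(profile_a, profile_b,
                                               coverage_a, coverage_b,
                                               annotation,
                                               gene_set_a, gene_set_b,
                                               mode = c("marked_body_mean",
                                                        "genome_mean")) {
  mode <- match.arg(mode)
  if (mode == "marked_body_mean") {
    fa <- .gene_body_mean(coverage_a, annotation, gene_set_a)
    fb <- .gene_body_mean(coverage_b, annotation, gene_set_b)
  } else {
    gmean <- function(cv) sum(vapply(cv$cov, function(r)
      sum(as.numeric(S4Vectors::runValue(r)) *
            as.numeric(S4Vectors::runLength(r))), numeric(1))) /
      sum(vapply(cv$cov, length, numeric(1)))
    fa <- gmean(coverage_a); fb <- gmean(coverage_b)
  }
  if (fa <= 0 || fb <= 0) stop("zero mean coverage over marked bodies")
  norm <- function(p, f) {
    p$profile <- p$profile / f
    p$normalization_factor <- p$normalization_factor / f
    p
  }
  list(profile_a = norm(profile_a, fa), profile_b = norm(profile_b, fb))
}

#' Fraction of body signal in the 3' half
#'
#' Quantifies a 5'/3' shift of the positional profile as the share of
#' gene-body signal falling in the 3' half of the body bins; a flat profile
#' gives 0.5 and a 3' loss of the mark drives the value down.
#'
#' @param profile a `metagene_profile` (or plain numeric bin vector).
#' @param scheme the [bin_scheme()] the profile was built with.
#' @return fraction in `[0, 1]`.
#' @export
three_prime_fraction <- function(profile, scheme = bin_scheme()) {
  v <- if (inherits(profile, "metagene_profile")) profile$profile
       else as.numeric(profile)
  nb <- scheme$body_bins; fb <- scheme$flank_bins
  if (length(v) != 2L * fb + nb)
    stop("profile length does not match scheme")
  body <- v[(fb + 1L):(fb + nb)]
  tot <- sum(body)
  if (tot <= 0) stop("all-zero gene body")
  sum(body[(nb %/% 2L + 1L):nb]) / tot
}
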