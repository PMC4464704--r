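#' Write a synthetic study to disk as standard text formats
#'
#' Writes the gene annotation as GFF3 (1-based closed), each fragment
#' library as BED (0-based half-open starts, as the format requires), the
#' expression matrix and its sample-design sidecar as TSV, and the truth
#' table as TSV. Everything round-trips losslessly through the matching
#' `read_*` functions.
#'
#' @param annotation gene `GRanges` (names = gene ids).
#' @param truth truth data.frame (or `NULL` to skip).
#' @param fragment_sets named list of fragment `GRanges`.
#' @param expression list with `values` and `design` as produced by
#'   [simulate_expression()] (or `NULL` to skip).
#' @param outdir output directory, created if needed.
#' @return invisibly, a manifest data.frame with columns `kind`, `name`,
#'   `path`.
#' @export
write_fixtures <- function(annotation, truth = NULL, fragment_sets = list(),
                           expression = NULL, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  manifest <- data.frame(kind = character(), name = character(),
                         path = character(), stringsAsFactors = FALSE)
  add <- function(kind, name, path) {
    manifest <<- rbind(manifest, data.frame(
      kind = kind, name = name, path = path, stringsAsFactors = FALSE))
  }

  gff <- file.path(outdir, "annotation.gff3")
  ann <- annotation
  S4Vectors::mcols(ann) <- NULL
  ann$type <- "gene"
  ann$ID <- names(annotation)
  tryCatch(rtracklayer::export(ann, gff, format = "gff3"),
           error = function(e) stop("writing ", gff, ": ",
                                    conditionMessage(e)))
  add("annotation", "annotation", gff)

  if (!is.null(truth)) {
    tp <- file.path(outdir, "truth.tsv")
    write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
    add("truth", "truth", tp)
  }

  if (length(fragment_sets)) {
    fdir <- file.path(outdir, "fragments")
    dir.create(fdir, showWarnings = FALSE)
    for (nm in names(fragment_sets)) {
      bp <- file.path(fdir, paste0(nm, ".bed"))
      tryCatch(rtracklayer::export(fragment_sets[[nm]], bp, format = "bed"),
               error = function(e) stop("writing ", bp, ": ",
                                        conditionMessage(e)))
      add("fragments", nm, bp)
    }
  }

  if (!is.null(expression)) {
    ep <- file.path(outdir, "expression.tsv")
    df <- data.frame(gene_id = rownames(expression$values),
                     expression$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
    add("expression", "expression", ep)
    dp <- file.path(outdir, "expression_design.tsv")
    write.table(expression$design, dp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    add("design", "expression_design", dp)
  }
  invisible(manifest)
}

#' Read a gene annotation from GFF3
#'
#' @param path GFF3 file with gene features (`ID` attribute = gene id).
#' @param genome optional named chromosome lengths applied to the result.
#' @return a `GRanges` with names and a `gene_id` column, coordinate-sorted.
#' @export
read_annotation <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == "gene"]
  ids <- as.character(gr$ID)
  S4Vectors::mcols(gr) <- NULL
  names(gr) <- ids
  gr$gene_id <- ids
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (!is.null(genome)) gr <- set_genome(gr, genome)
  gr
}

#' Read a fragment library from BED
#'
#' @param path BED file of mapped fragments.
#' @param genome optional named chromosome lengths applied to the result.
#' @return a fragment `GRanges`.
#' @export
read_fragments <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  S4Vectors::mcols(gr) <- NULL
  if (!is.null(genome)) gr <- set_genome(gr, genome)
  gr
}

#' Read an expression matrix and its design sidecar
#'
#' @param values_path TSV with a `gene_id` column followed by one column
#'   per sample (linear scale).
#' @param design_path TSV with columns sample, genotype, carbon, light, rep.
#' @return list with `values` (matrix) and `design` (data.frame).
#' @export
read_expression <- function(values_path, design_path) {
  df <- read.delim(values_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$gene_id
  design <- read.delim(design_path, stringsAsFactors = FALSE,
                       colClasses = c(rep("character", 4), "integer"))
  if (!identical(colnames(values), design$sample))
    stop("expression columns do not match design samples")
  list(values = values, design = design)
}

#' Read a ground-truth table
#'
#' @param path TSV written by [write_fixtures()].
#' @return data.frame of per-gene truth labels.
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
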