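#' Read a count matrix with lengths and sample sheet from TSV files
#'
#' Expects the three plain tab-separated tables written by
#' [write_dataset()]: `counts.tsv` (header `gene_id` + library ids,
#' integer cells), `lengths.tsv` (`gene_id`, `length_bp`) and
#' `samples.tsv` (`library_id`, `stage`, `replicate`). Duplicate gene
#' ids, non-integer or negative cells, unknown libraries and missing
#' lengths are rejected with messages naming the offender.
#'
#' @param counts_path,lengths_path,samples_path file paths.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, lengths_path, samples_path) {
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(raw)[1] != "gene_id") stop("first column must be gene_id")
  dup <- raw$gene_id[duplicated(raw$gene_id)]
  if (length(dup))
    stop("duplicate gene id(s) in ", counts_path, ": ",
         paste(unique(dup), collapse = ", "))
  mat <- as.matrix(raw[, -1, drop = FALSE])
  bad <- which(!is.finite(mat) | mat < 0 | mat != floor(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at gene '%s', library '%s' (row %d, column %d)",
                 raw$gene_id[bad[1, 1]], colnames(mat)[bad[1, 2]],
                 bad[1, 1], bad[1, 2] + 1L))
  rownames(mat) <- raw$gene_id

  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  lengths <- stats::setNames(len$length_bp, len$gene_id)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  samples$stage <- as.character(samples$stage)
  samples$replicate <- as.character(samples$replicate)
  count_matrix(mat, lengths, samples)
}

#' Read a trait table
#'
#' TSV with a `library_id` column followed by one numeric column per
#' trait (metabolite concentrations).
#'
#' @param path file path.
#' @return data.frame with library ids as rownames.
#' @export
read_traits <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(raw)[1] != "library_id") stop("first column must be library_id")
  traits <- raw[, -1, drop = FALSE]
  rownames(traits) <- raw$library_id
  if (any(!vapply(traits, is.numeric, logical(1))))
    stop("all trait columns must be numeric")
  traits
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Writes `counts.tsv`, `lengths.tsv`, `samples.tsv`, `traits.tsv` and
#' `truth.tsv` (gene_id, module_label) in the formats
#' [read_count_matrix()] and [read_traits()] consume.
#'
#' @param dataset from [simulate_dataset()].
#' @param outdir directory (created if absent).
#' @return invisibly, the vector of written paths.
#' @export
write_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cm <- dataset$counts
  paths <- c(
    write_tsv(data.frame(gene_id = rownames(cm$counts), cm$counts,
                         check.names = FALSE),
              file.path(outdir, "counts.tsv")),
    write_tsv(data.frame(gene_id = names(cm$lengths),
                         length_bp = unname(cm$lengths)),
              file.path(outdir, "lengths.tsv")),
    write_tsv(cm$samples, file.path(outdir, "samples.tsv")),
    write_tsv(data.frame(library_id = rownames(dataset$traits),
                         dataset$traits, check.names = FALSE),
              file.path(outdir, "traits.tsv")),
    write_tsv(data.frame(gene_id = names(dataset$truth$module_label_per_gene),
                         module_label = unname(dataset$truth$module_label_per_gene)),
              file.path(outdir, "truth.tsv")))
  invisible(paths)
}

#' Read a qPCR Ct table
#'
#' TSV with columns `gene_id`, `sample_id`, `ct_target`, `ct_reference`,
#' `is_calibrator` (0/1 or TRUE/FALSE).
#'
#' @param path file path.
#' @return data.frame ready for [ddct_relative_expression()].
#' @export
read_qpcr <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "sample_id", "ct_target", "ct_reference",
            "is_calibrator")
  if (!all(need %in% names(raw)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  raw$calibrator <- as.logical(raw$is_calibrator)
  raw
}
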