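#' Gene-level count matrix with lengths and sample design
#'
#' Bundles an integer fragment-count matrix (genes x libraries) with
#' per-gene transcript lengths and the sample sheet describing which
#' ripening stage and biological replicate each library belongs to.
#' This is the input container for every downstream stage.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   libraries in columns (colnames = library ids). All cells must be
#'   non-negative integers.
#' @param lengths named numeric vector of transcript lengths in bp, one
#'   entry per gene in `counts`.
#' @param samples data.frame with columns `library_id`, `stage`,
#'   `replicate`; one row per library of `counts`.
#' @return an object of class `count_matrix`: a list with elements
#'   `counts`, `lengths`, `samples`.
#' @examples
#' cm <- count_matrix(
#'   counts  = matrix(c(10L, 0L, 5L, 7L), 2, 2,
#'                    dimnames = list(c("g1", "g2"), c("L1", "L2"))),
#'   lengths = c(g1 = 1000, g2 = 500),
#'   samples = data.frame(library_id = c("L1", "L2"),
#'                        stage = c("S1", "S2"), replicate = c("A", "A")))
#' library_totals(cm)
#' @export
count_matrix <- function(counts, lengths, samples) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and library ids as colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at gene '%s', library '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"

  need <- c("library_id", "stage", "replicate")
  if (!all(need %in% names(samples)))
    stop("samples sheet needs columns: ", paste(need, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  unknown <- setdiff(colnames(counts), samples$library_id)
  if (length(unknown))
    stop("library not in sample sheet: ", paste(unknown, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$library_id), , drop = FALSE]
  rownames(samples) <- NULL

  missing_len <- setdiff(rownames(counts), names(lengths))
  if (length(missing_len))
    stop("missing length for gene(s): ",
         paste(utils::head(missing_len, 5), collapse = ", "))
  lengths <- lengths[rownames(counts)]
  if (any(!is.finite(lengths) | lengths <= 0))
    stop("gene lengths must be positive and finite")

  structure(list(counts = counts, lengths = lengths, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d libraries (%d stages x %d replicates)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$stage)),
              max(table(x$samples$stage))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Total mapped fragments per library
#'
#' Column sums of the count matrix; the `N` totals used both by the
#' two-library exact test and by FPKM normalization.
#'
#' @param cm a [count_matrix()].
#' @return named numeric vector of per-library totals.
#' @export
library_totals <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  colSums(cm$counts)
}

#' Ripening stages in sheet order
#'
#' @param cm a [count_matrix()].
#' @return character vector of stage labels in order of first appearance.
#' @export
stages <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  unique(cm$samples$stage)
}

# libraries belonging to one stage, in sheet order
stage_libraries <- function(cm, stage) {
  libs <- cm$samples$library_id[cm$samples$stage == stage]
  if (!length(libs)) stop("stage not present in sample sheet: ", stage)
  libs
}
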