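#' Relative expression by the delta-delta-Ct method
#'
#' Classic qPCR relative quantification against a reference gene and a
#' calibrator sample, assuming a doubling per cycle:
#' \deqn{\Delta Ct_s = Ct_{target,s} - Ct_{reference,s}, \quad
#'   \Delta\Delta Ct_s = \Delta Ct_s - \Delta Ct_{calibrator}, \quad
#'   RE_s = 2^{-\Delta\Delta Ct_s}.}
#' Rows sharing a (`gene_id`, `sample_id`) pair are treated as technical
#' replicates and their Ct values are averaged before the deltas. The
#' calibrator sample's relative expression is exactly 1.
#'
#' @param records data.frame with columns `sample_id`, `ct_target`,
#'   `ct_reference`, `calibrator` (logical; exactly one calibrator
#'   sample per gene) and optionally `gene_id` (a single unnamed gene is
#'   assumed absent).
#' @return data.frame `gene_id`, `sample_id`, `delta_ct`,
#'   `delta_delta_ct`, `rel_expr`.
#' @examples
#' ddct_relative_expression(data.frame(
#'   sample_id = c("S1", "S3"), ct_target = c(24, 20),
#'   ct_reference = c(15, 15), calibrator = c(TRUE, FALSE)))
#' @export
ddct_relative_expression <- function(records) {
  need <- c("sample_id", "ct_target", "ct_reference", "calibrator")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (!"gene_id" %in% names(records)) records$gene_id <- "gene"
  ct <- c(records$ct_target, records$ct_reference)
  if (any(!is.finite(ct) | ct <= 0 | ct >= 50))
    stop("Ct values must lie in (0, 50)")

  out <- lapply(split(records, records$gene_id), function(g) {
    # average technical replicates per sample
    agg <- stats::aggregate(g[c("ct_target", "ct_reference", "calibrator")],
                            by = list(sample_id = g$sample_id),
                            FUN = function(v) if (is.logical(v)) any(v)
                                              else mean(v))
    ncal <- sum(agg$calibrator)
    if (ncal == 0) stop("no calibrator sample for gene ", g$gene_id[1])
    if (ncal > 1) stop("more than one calibrator sample for gene ",
                       g$gene_id[1])
    dct <- agg$ct_target - agg$ct_reference
    ddct <- dct - dct[agg$calibrator]
    re <- 2^(-ddct)
    re[agg$calibrator] <- 1                 # exact, no rounding residue
    data.frame(gene_id = g$gene_id[1], sample_id = agg$sample_id,
               delta_ct = dct, delta_delta_ct = ddct, rel_expr = re,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
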