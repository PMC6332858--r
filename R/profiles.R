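#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `1e9 * count / (library_total * length_bp)`.
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of FPKM, same dimnames as the counts.
#' @examples
#' cm <- count_matrix(
#'   matrix(c(100L, 0L), 1, 2, dimnames = list("g1", c("L1", "L2"))),
#'   c(g1 = 1000),
#'   data.frame(library_id = c("L1", "L2"), stage = "S1",
#'              replicate = c("A", "B")))
#' compute_fpkm(cm)   # 1e9 * 100 / (100 * 1000) = 1e6 ... totals are colSums
#' @export
compute_fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- library_totals(cm)
  if (any(totals <= 0))
    stop("library with zero total fragments: ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  if (any(cm$lengths <= 0)) stop("zero-length gene")
  sweep(1e9 * cm$counts / cm$lengths, 2, totals, "/")
}

# sign pattern of one comparison: +/0/- as integer, 0 when not a DEG
profile_sign <- function(de) ifelse(de$is_deg, sign(de$log2ratio), 0L)

#' Four-group ripening expression-profile classification
#'
#' Assigns each gene a trajectory group from the signs of its two
#' consecutive stage comparisons (stage1 to stage2, stage2 to stage3):
#' group I = up-regulated, II = up then down, III = down-regulated,
#' IV = down then up. A comparison contributes a sign only when the gene
#' was a DEG there; genes significant in neither comparison are
#' `excluded`, as are genes whose largest change exceeds the fold cap
#' (default 32-fold, i.e. |log2 ratio| > 5). Genes significant in one
#' comparison only fold into the monotone groups I/III by default
#' (`single_interval = "monotone"`); set `single_interval = "excluded"`
#' to drop them instead.
#'
#' @param de_12,de_23 data.frames from [run_pairwise_de()] covering the
#'   same genes: stage1 vs stage2 and stage2 vs stage3.
#' @param fold_cap_log2 exclusion cap in log2 units (default 5);
#'   `Inf` disables it.
#' @param single_interval how to treat one-sided significance patterns.
#' @return data.frame with `gene_id`, `group` (factor with levels
#'   I, II, III, IV, excluded), `sign_12`, `sign_23`, `log2ratio_12`,
#'   `log2ratio_23`.
#' @export
classify_profiles <- function(de_12, de_23, fold_cap_log2 = 5,
                              single_interval = c("monotone", "excluded")) {
  single_interval <- match.arg(single_interval)
  if (!setequal(de_12$gene_id, de_23$gene_id))
    stop("the two comparisons must cover the same genes")
  de_23 <- de_23[match(de_12$gene_id, de_23$gene_id), , drop = FALSE]

  s12 <- profile_sign(de_12)
  s23 <- profile_sign(de_23)
  key <- paste(s12, s23)
  group <- rep("excluded", length(key))
  group[key %in% c("1 1")] <- "I"
  group[key == "1 -1"] <- "II"
  group[key %in% c("-1 -1")] <- "III"
  group[key == "-1 1"] <- "IV"
  one_sided <- key %in% c("1 0", "0 1", "-1 0", "0 -1")
  if (single_interval == "monotone") {
    group[key %in% c("1 0", "0 1")] <- "I"
    group[key %in% c("-1 0", "0 -1")] <- "III"
  }
  capped <- pmax(abs(de_12$log2ratio), abs(de_23$log2ratio)) > fold_cap_log2
  group[capped] <- "excluded"

  data.frame(gene_id = de_12$gene_id,
             group = factor(group, levels = c("I", "II", "III", "IV",
                                              "excluded")),
             sign_12 = s12, sign_23 = s23,
             log2ratio_12 = de_12$log2ratio,
             log2ratio_23 = de_23$log2ratio,
             stringsAsFactors = FALSE)
}

# published bin edges for the two display scales
.bin_edges <- list(
  fig3  = c(0, 0.1, 0.7, 2, 4, 8, 20, 100, 1000, 12500),
  fig56 = c(0, 1, 2, 4, 8, 16, 32, 64, 128, 256, 512, 1024, Inf)
)

#' Expression magnitude bin of an FPKM value
#'
#' Maps FPKM onto the discrete color scales used for profile display:
#' `"fig3"` is the 9-bin scale (0-0.1, 0.1-0.7, 0.7-2, 2-4, 4-8, 8-20,
#' 20-100, 100-1000, 1000-12500), `"fig56"` the 12-bin scale (0-1, 1-2,
#' 2-4, ..., 512-1024, >1024). Intervals are half-open `[lo, hi)`; the
#' top `fig3` bin is closed above at 12500 while the top `fig56` bin is
#' unbounded.
#'
#' @param fpkm non-negative numeric (vectorized).
#' @param scheme `"fig3"` or `"fig56"`.
#' @return integer bin index (1-based); NA with a warning for `fig3`
#'   values above 12500.
#' @export
bin_expression <- function(fpkm, scheme = c("fig3", "fig56")) {
  scheme <- match.arg(scheme)
  if (any(fpkm < 0)) stop("FPKM must be non-negative")
  edges <- .bin_edges[[scheme]]
  idx <- findInterval(fpkm, edges, rightmost.closed = (scheme == "fig3"))
  if (scheme == "fig3" && any(fpkm > edges[length(edges)])) {
    warning("FPKM above the top fig3 bin edge (12500); returning NA")
    idx[fpkm > edges[length(edges)]] <- NA_integer_
  }
  as.integer(idx)
}
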