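#' Pearson correlation with a t-based two-sided p-value
#'
#' The standard correlation test: `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' against Student's t with `n - 2` degrees of freedom, two-sided.
#' `r = +-1` returns `p = 0`. Equivalent to the regularized incomplete
#' beta tail `I_{1-r^2}((n-2)/2, 1/2)`, which the test-suite uses as the
#' independent oracle.
#'
#' @param u,v numeric sample vectors of equal length `n >= 4`, each with
#'   nonzero variance.
#' @return list with elements `r`, `p`, `n`.
#' @examples
#' correlation_test(1:9, c(2, 1, 4, 3, 6, 5, 8, 7, 9))
#' @export
correlation_test <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  n <- length(u)
  if (n < 4) stop("need at least 4 samples")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) stop("zero variance input")
  r <- stats::cor(u, v)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Module-trait association matrix
#'
#' Pearson correlation of every module eigengene with every trait
#' column, with the per-cell t-test p-value. No multiplicity correction
#' is applied across the grid (each cell is reported as tested); pass
#' the `p` matrix through [bh_adjust()] if a corrected view is wanted.
#'
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @param traits data.frame or matrix, libraries x traits, with
#'   rownames matching (and ordered as) the eigengene rows.
#' @return list of class `module_trait` with matrices `r` and `p`
#'   (modules x traits) and the sample count `n`.
#' @export
module_trait_matrix <- function(eigengenes, traits) {
  traits <- as.matrix(traits)
  if (nrow(traits) != nrow(eigengenes) ||
      (!is.null(rownames(traits)) && !is.null(rownames(eigengenes)) &&
       !identical(rownames(traits), rownames(eigengenes))))
    stop("traits and eigengenes must share identically ordered libraries")
  nm <- ncol(eigengenes)
  nt <- ncol(traits)
  r <- p <- matrix(NA_real_, nm, nt,
                   dimnames = list(colnames(eigengenes), colnames(traits)))
  for (i in seq_len(nm)) for (j in seq_len(nt)) {
    ct <- correlation_test(eigengenes[, i], traits[, j])
    r[i, j] <- ct$r
    p[i, j] <- ct$p
  }
  structure(list(r = r, p = p, n = nrow(eigengenes)), class = "module_trait")
}

#' @export
print.module_trait <- function(x, digits = 2, ...) {
  cat(sprintf("module_trait: %d modules x %d traits (n = %d)\n",
              nrow(x$r), ncol(x$r), x$n))
  show <- matrix(sprintf("%.*f (p=%.1g)", digits, x$r, x$p),
                 nrow(x$r), dimnames = dimnames(x$r))
  print(show, quote = FALSE)
  invisible(x)
}

#' Modules significantly associated with any trait
#'
#' @param mt a `module_trait` object.
#' @param p_threshold strict per-cell p-value cutoff (default 0.001).
#' @return integer module numbers whose best trait p-value is below the
#'   cutoff.
#' @export
significant_modules <- function(mt, p_threshold = 0.001) {
  stopifnot(inherits(mt, "module_trait"))
  if (!nrow(mt$p)) return(integer(0))
  hit <- apply(mt$p, 1, min) < p_threshold
  as.integer(sub("^ME", "", rownames(mt$p)[hit]))
}

#' Select candidate genes by gene-trait correlation
#'
#' Within the trait-associated modules, correlates each gene's
#' expression (by default `log2(FPKM + 1)`) with every trait and keeps
#' genes whose best absolute correlation is strictly greater than
#' `r_threshold` (default 0.91).
#'
#' @param fpkm FPKM matrix genes x libraries.
#' @param traits libraries x traits table (rows ordered as the FPKM
#'   columns).
#' @param partition a `module_partition`.
#' @param modules integer module numbers to search (e.g. from
#'   [significant_modules()]).
#' @param r_threshold strict cutoff on `|r|` (default 0.91).
#' @param log_transform correlate on `log2(FPKM + 1)` (default) or raw
#'   FPKM.
#' @return data.frame `gene_id`, `module`, `best_trait`, `gene_trait_r`
#'   for the selected genes, ordered by decreasing `|r|`.
#' @export
select_candidate_genes <- function(fpkm, traits, partition, modules,
                                   r_threshold = 0.91, log_transform = TRUE) {
  stopifnot(inherits(partition, "module_partition"))
  if (!length(modules)) stop("empty module list")
  traits <- as.matrix(traits)
  labels <- partition$labels[rownames(fpkm)]
  genes <- names(labels)[labels %in% modules]
  if (!length(genes))
    return(data.frame(gene_id = character(0), module = integer(0),
                      best_trait = character(0), gene_trait_r = numeric(0)))
  expr <- fpkm[genes, , drop = FALSE]
  if (log_transform) expr <- log2(expr + 1)
  keep <- apply(expr, 1, stats::sd) > 0
  expr <- expr[keep, , drop = FALSE]
  r <- stats::cor(t(expr), traits)          # genes x traits
  best <- max.col(abs(r), ties.method = "first")
  best_r <- r[cbind(seq_len(nrow(r)), best)]
  out <- data.frame(gene_id = rownames(expr),
                    module = unname(labels[rownames(expr)]),
                    best_trait = colnames(traits)[best],
                    gene_trait_r = unname(best_r),
                    stringsAsFactors = FALSE)
  out <- out[abs(out$gene_trait_r) > r_threshold, , drop = FALSE]
  out <- out[order(-abs(out$gene_trait_r), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intramodular hub genes
#'
#' Ranks module members by module membership and connectivity: `kME` is
#' the correlation of a gene's expression with its own module eigengene;
#' intramodular connectivity is the gene's summed adjacency to the other
#' members of its module. Hubs are genes with `kME >= kme_threshold`,
#' at most `top_k_per_module` per module, taken in order of decreasing
#' intramodular connectivity (ties broken by gene id, so the hub set
#' does not depend on input order).
#'
#' @param expr expression matrix genes x samples used for the network.
#' @param eigengenes from [module_eigengenes()].
#' @param partition a `module_partition`.
#' @param adjacency from [soft_adjacency()], same genes as `expr`.
#' @param kme_threshold inclusive kME cutoff (default 0.9).
#' @param top_k_per_module maximum hubs per module (default 5).
#' @return data.frame `gene_id`, `module`, `kME`, `intramodular_k`,
#'   `is_hub` covering all module members.
#' @export
identify_hubs <- function(expr, eigengenes, partition, adjacency,
                          kme_threshold = 0.9, top_k_per_module = 5) {
  stopifnot(inherits(partition, "module_partition"))
  labels <- partition$labels[rownames(expr)]
  genes <- names(labels)[labels > 0]
  genes <- sort(genes)                       # order-independent output
  if (!length(genes))
    return(data.frame(gene_id = character(0), module = integer(0),
                      kME = numeric(0), intramodular_k = numeric(0),
                      is_hub = logical(0)))
  out <- data.frame(gene_id = genes, module = unname(labels[genes]),
                    kME = NA_real_, intramodular_k = NA_real_,
                    is_hub = FALSE, stringsAsFactors = FALSE)
  for (m in sort(unique(out$module))) {
    gm <- out$gene_id[out$module == m]
    me <- eigengenes[, paste0("ME", m)]
    out$kME[out$module == m] <-
      as.numeric(stats::cor(t(expr[gm, , drop = FALSE]), me))
    a <- adjacency[gm, gm, drop = FALSE]
    out$intramodular_k[out$module == m] <- rowSums(a) - diag(a)
    idx <- which(out$module == m & out$kME >= kme_threshold)
    if (length(idx)) {
      ord <- idx[order(-out$intramodular_k[idx], out$gene_id[idx])]
      out$is_hub[utils::head(ord, top_k_per_module)] <- TRUE
    }
  }
  out
}

#' Export weighted network edges for Cytoscape
#'
#' Writes the undirected edge list of a gene subset above a weight
#' threshold, either as a 3-column TSV (`source`, `target`, `weight`)
#' or in SIF dialect (`source coexp target`). Each unordered pair
#' appears once, source < target lexicographically, no self-edges.
#'
#' @param mat adjacency or TOM matrix with gene dimnames.
#' @param genes subset of genes to export (default: all).
#' @param weight_threshold inclusive minimum edge weight, in \[0, 1\].
#' @param format `"tsv"` (default) or `"sif"`.
#' @param file optional path; when given the edge list is also written
#'   there.
#' @return data.frame `source`, `target`, `weight` (weight omitted from
#'   the SIF file but kept in the returned frame).
#' @export
export_network_edges <- function(mat, genes = rownames(mat),
                                 weight_threshold = 0.1,
                                 format = c("tsv", "sif"), file = NULL) {
  format <- match.arg(format)
  if (weight_threshold < 0 || weight_threshold > 1)
    stop("weight_threshold must lie in [0, 1]")
  missing <- setdiff(genes, rownames(mat))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(utils::head(missing, 5),
                                          collapse = ", "))
  genes <- sort(genes)
  m <- mat[genes, genes, drop = FALSE]
  idx <- which(upper.tri(m) & m >= weight_threshold, arr.ind = TRUE)
  edges <- data.frame(source = genes[idx[, 1]], target = genes[idx[, 2]],
                      weight = m[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(file)) {
    if (format == "sif") {
      writeLines(sprintf("%s coexp %s", edges$source, edges$target), file)
    } else {
      utils::write.table(edges, file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  edges
}
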