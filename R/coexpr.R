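#' Filter genes for network construction
#'
#' Keeps genes whose mean FPKM across all libraries is strictly greater
#' than `min_mean` (default 1) and whose expression is not constant
#' (zero-variance genes have no defined correlation and are dropped).
#'
#' @param fpkm numeric FPKM matrix, genes x libraries.
#' @param min_mean strict lower bound on the mean FPKM (default 1).
#' @return character vector of retained gene ids (possibly empty).
#' @export
filter_expressed <- function(fpkm, min_mean = 1) {
  stopifnot(is.matrix(fpkm))
  keep <- rowMeans(fpkm) > min_mean & apply(fpkm, 1, stats::sd) > 0
  rownames(fpkm)[keep]
}

#' Soft-thresholded unsigned adjacency
#'
#' Unsigned weighted-network adjacency: `a_ij = |cor(g_i, g_j)|^beta`
#' (Pearson), diagonal fixed at 1. With `signed = TRUE` the signed
#' variant `((1 + cor)/2)^beta` is used instead; the unsigned form is
#' the default throughout the pipeline.
#'
#' @param expr numeric matrix, genes x samples (typically
#'   `log2(FPKM + 1)` of the filtered genes).
#' @param beta soft power (default 16).
#' @param signed use the signed transform instead of `|cor|^beta`.
#' @return symmetric adjacency matrix in \[0, 1\] with unit diagonal and
#'   attribute `beta`.
#' @export
soft_adjacency <- function(expr, beta = 16, signed = FALSE) {
  if (beta <= 0) stop("beta must be positive")
  if (ncol(expr) < 4) stop("need at least 4 samples")
  v <- apply(expr, 1, stats::sd)
  if (any(v == 0)) stop("zero-variance gene(s): ",
                        paste(utils::head(rownames(expr)[v == 0], 5),
                              collapse = ", "))
  r <- stats::cor(t(expr))
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  a <- (a + t(a)) / 2           # exact symmetry despite rounding
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Topological overlap similarity
#'
#' Unsigned topological overlap matrix of a weighted network:
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
#'   \quad l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}}
#' with connectivity \eqn{k_i = \sum_{j \ne i} a_{ij}}; the diagonal is
#' set to 1. High overlap marks gene pairs that are both directly
#' connected and share neighbors; `1 - TOM` is the clustering
#' dissimilarity used by [detect_modules()].
#'
#' @param adj adjacency from [soft_adjacency()] (symmetric, unit
#'   diagonal, entries in \[0, 1\]).
#' @return symmetric TOM matrix with attribute `connectivity`.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-12)) stop("adjacency must be symmetric")
  if (any(adj < 0) || any(adj > 1 + 1e-12)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(adj) - diag(adj)
  # (A %*% A)_ij counts u = i and u = j (each contributing a_ij since diag = 1)
  l <- adj %*% adj - 2 * adj
  diag(l) <- 0
  kmin <- outer(k, k, pmin)
  tom <- (l + adj) / (kmin + 1 - adj)
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  attr(tom, "connectivity") <- k
  tom
}

#' Detect co-expression modules by hierarchical clustering of 1 - TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`, cut statically at `cut_quantile` times the maximum merge
#' height. Clusters smaller than `min_module_size` are left unassigned
#' (label 0, the conventional "grey" role); surviving modules are
#' renumbered 1, 2, ... by decreasing size.
#'
#' A static cut is a deliberate simplification of the dynamic tree-cut
#' used by the automatic blockwise constructors. Its known weakness is
#' stem absorption: genes that attach to a dense branch one by one just
#' below the cut, without being interconnected themselves — chance
#' correlates of the module's profile, frequent at small sample
#' numbers. Branch-shape-aware cutting rejects these; to recover that
#' behavior, pass the soft `adjacency` and each cluster is pruned to
#' its core: genes whose intramodular connectivity (summed adjacency to
#' the rest of the cluster) falls below `stem_k_fraction` of the
#' cluster median are unassigned. At soft power 16 core members and
#' stem genes typically differ in intramodular connectivity by an order
#' of magnitude, so the default fraction sits in a wide gap.
#'
#' @param tom matrix from [tom_similarity()].
#' @param min_module_size smallest cluster kept as a module (default 30).
#' @param cut_quantile fraction of the maximum merge height at which the
#'   tree is cut (default 0.99).
#' @param adjacency optional matrix from [soft_adjacency()]; enables
#'   stem pruning.
#' @param stem_k_fraction core-membership threshold as a fraction of
#'   the cluster's median intramodular connectivity (default 0.4).
#' @return object of class `module_partition`: list with `labels`
#'   (named integer vector, 0 = unassigned), `min_module_size`,
#'   `cut_height` and the `hclust` tree.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_quantile = 0.99,
                           adjacency = NULL, stem_k_fraction = 0.4) {
  n <- nrow(tom)
  ids <- rownames(tom)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all genes left unassigned")
    labels <- stats::setNames(rep(0L, n), ids)
    return(structure(list(labels = labels, min_module_size = min_module_size,
                          cut_height = NA_real_, tree = NULL),
                     class = "module_partition"))
  }
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  # exact ties can leave heights non-monotone by ~1e-16; cutree rejects that
  if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
  h <- cut_quantile * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  if (!is.null(adjacency)) raw <- prune_stems(raw, adjacency, stem_k_fraction)
  labels <- prune_and_rank(raw, min_module_size)
  names(labels) <- ids
  structure(list(labels = labels, min_module_size = min_module_size,
                 cut_height = h, tree = tree),
            class = "module_partition")
}

# unassign cluster members whose intramodular connectivity is below
# frac * cluster median (stem genes attached by the static cut)
prune_stems <- function(raw, adjacency, frac) {
  for (cl in unique(raw[raw > 0])) {
    members <- which(raw == cl)
    if (length(members) < 3) next
    a <- adjacency[members, members, drop = FALSE]
    kin <- rowSums(a) - diag(a)
    med <- stats::median(kin)
    if (med > 0) raw[members[kin < frac * med]] <- 0L
  }
  raw
}

# drop clusters below min size to 0 and renumber the rest by decreasing
# size (ties by original cluster index, so the result is deterministic)
prune_and_rank <- function(raw, min_module_size) {
  sizes <- table(raw[raw > 0])
  keep <- names(sizes)[sizes >= min_module_size]
  out <- rep(0L, length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (m in seq_along(ord)) out[raw == as.integer(ord[m])] <- m
  }
  out
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- table(x$labels[x$labels > 0])
  cat(sprintf("module_partition: %d modules over %d genes (%d unassigned)\n",
              length(tab), length(x$labels), sum(x$labels == 0)))
  if (length(tab)) print(tab)
  invisible(x)
}

#' Module eigengenes
#'
#' For each module, genes are standardized across samples and the module
#' eigengene is the first right-singular vector of the standardized
#' genes x samples block: the unit-norm sample profile that explains the
#' largest share of the module's expression variance. Its sign is
#' oriented so that its correlation with the module's mean standardized
#' profile is non-negative.
#'
#' @param expr numeric matrix genes x samples used for the network.
#' @param partition a `module_partition`.
#' @return numeric matrix samples x modules (columns `ME1`, `ME2`, ...),
#'   with attribute `var_explained` (first squared singular value over
#'   the total). Zero-module partitions give a 0-column matrix.
#' @export
module_eigengenes <- function(expr, partition) {
  stopifnot(inherits(partition, "module_partition"))
  labels <- partition$labels[rownames(expr)]
  mods <- sort(unique(labels[labels > 0]))
  me <- matrix(numeric(0), nrow = ncol(expr), ncol = 0,
               dimnames = list(colnames(expr), NULL))
  ve <- numeric(0)
  for (m in mods) {
    block <- expr[names(labels)[labels == m], , drop = FALSE]
    if (nrow(block) < 2) stop("module ", m, " has fewer than 2 genes")
    sds <- apply(block, 1, stats::sd)
    if (any(sds == 0)) stop("zero-variance gene in module ", m)
    z <- (block - rowMeans(block)) / sds
    sv <- svd(z)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    me <- cbind(me, e)
    ve <- c(ve, sv$d[1]^2 / sum(sv$d^2))
  }
  colnames(me) <- if (length(mods)) paste0("ME", mods) else character(0)
  attr(me, "var_explained") <- stats::setNames(ve, colnames(me))
  me
}

#' Merge modules with similar eigengenes
#'
#' Modules whose eigengenes are highly correlated are merged: modules
#' are clustered (average linkage) on the dissimilarity
#' `1 - cor(eigengene_a, eigengene_b)`, clusters below
#' `merge_cut_height` are fused, eigengenes are recomputed, and the
#' procedure iterates to a fixed point. Merged modules are renumbered by
#' decreasing size.
#'
#' @param expr the expression matrix the partition was built from.
#' @param partition a `module_partition`.
#' @param merge_cut_height eigengene dissimilarity below which modules
#'   merge (default 0.25, i.e. correlation above 0.75).
#' @param max_iter safety bound on merge rounds.
#' @return a `module_partition` with merged, renumbered labels.
#' @export
merge_modules <- function(expr, partition, merge_cut_height = 0.25,
                          max_iter = 20) {
  stopifnot(inherits(partition, "module_partition"))
  labels <- partition$labels
  for (it in seq_len(max_iter)) {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    me <- module_eigengenes(expr, replace_labels(partition, labels))
    d <- 1 - stats::cor(me)
    tree <- stats::hclust(stats::as.dist(d), method = "average")
    if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
    grp <- stats::cutree(tree, h = merge_cut_height)
    if (max(grp) == length(mods)) break      # nothing merged
    new <- labels
    for (g in unique(grp)) {
      members <- mods[grp == g]
      new[labels %in% members] <- min(members)
    }
    sizes <- table(new[new > 0])
    ord <- as.integer(names(sizes)[order(-sizes, as.integer(names(sizes)))])
    relab <- stats::setNames(seq_along(ord), ord)
    new[new > 0] <- relab[as.character(new[new > 0])]
    if (identical(unname(new), unname(labels))) break
    labels <- new
  }
  replace_labels(partition, labels)
}

replace_labels <- function(partition, labels) {
  partition$labels <- labels
  partition
}
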