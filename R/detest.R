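#' Exact two-library differential expression test
#'
#' The classical digital-expression test for comparing one gene between two
#' sequencing libraries without replicates. Fragment counts are modelled as
#' Poisson; conditioning on the observed count `x` in library 1, the
#' probability of seeing `i` fragments in library 2 given equal underlying
#' expression is
#'
#' \deqn{p(i \mid x) = \left(\frac{N_2}{N_1}\right)^i
#'   \frac{(x+i)!}{x!\, i!\, (1 + N_2/N_1)^{x+i+1}}}
#'
#' where `N1`, `N2` are the total fragment counts of the two libraries.
#' The Poisson mean itself (the gene's true transcript abundance) is a
#' latent quantity marginalized out by this conditioning and is never
#' estimated. The terms form a negative-binomial mass function in `i`
#' (size `x + 1`, success probability `N1/(N1+N2)`), which is what the
#' tail-sum oracle in the test-suite exploits.
#'
#' `ac_term()` evaluates a single term; all factorials go through
#' `lgamma()` so large counts cannot overflow.
#'
#' @param i non-negative integer (vectorized): hypothetical count in
#'   library 2.
#' @param x non-negative integer: observed count in library 1.
#' @param ratio positive real: `N2/N1`.
#' @return probability mass in (0, 1).
#' @seealso [ac_pvalue()] for the two-sided test built on these terms.
#' @examples
#' ac_term(0, 0, 1)        # 1/2
#' ac_term(1, 5, 1)        # choose(6,1)/2^7 = 0.046875
#' sum(ac_term(0:200, 5, 1))  # terms sum to 1
#' @export
ac_term <- function(i, x, ratio) {
  if (any(i < 0) || any(x < 0)) stop("i and x must be non-negative")
  if (!is.finite(ratio) || ratio <= 0) stop("ratio must be positive")
  exp(ac_log_term(i, x, ratio))
}

# log of ac_term, vectorized over i (and x if same length)
ac_log_term <- function(i, x, ratio) {
  i * log(ratio) + lgamma(x + i + 1) - lgamma(x + 1) - lgamma(i + 1) -
    (x + i + 1) * log1p(ratio)
}

# lower tail S = sum_{i=0}^{y} p(i|x). The mass is concentrated around
# the negative-binomial mean (x+1)*ratio; for very large y only a window
# of +-60 sd around the mean is evaluated (mass outside is below 1e-300).
# Summation relies on base sum()'s extended-precision accumulator.
ac_lower_tail <- function(x, y, ratio) {
  if (y < 0) return(0)
  lo <- 0
  hi <- y
  if (hi > 1e5) {
    mu <- (x + 1) * ratio
    s <- sqrt((x + 1) * ratio * (1 + ratio))
    lo <- max(0, floor(mu - 60 * s))
    hi <- min(y, ceiling(mu + 60 * s))
    if (hi < lo) {                       # y far below the bulk: S ~ 0
      lo <- max(0, y - 1000)
      hi <- y
    }
  }
  sum(exp(ac_log_term(lo:hi, x, ratio)))
}

# upper tail sum_{i=y+1}^{inf} p(i|x), summed directly so that small
# tails keep full relative precision (2*(1 - S) would cancel); the sum
# is extended in blocks until the boundary term is negligible
ac_upper_tail <- function(x, y, ratio) {
  mu <- (x + 1) * ratio
  s <- sqrt((x + 1) * ratio * (1 + ratio))
  lo <- y + 1
  hi <- ceiling(max(lo + 200, mu + 60 * s))
  tot <- 0
  for (block in 1:50) {
    tot <- tot + sum(exp(ac_log_term(lo:hi, x, ratio)))
    if (exp(ac_log_term(hi, x, ratio)) < tot * 1e-18 + 1e-320) break
    lo <- hi + 1
    hi <- hi + ceiling(10 * s) + 200
  }
  tot
}

#' Two-sided p-value of the exact two-library test
#'
#' Computes \eqn{S = \sum_{i=0}^{y} p(i \mid x)} and returns `2*S` when
#' `S <= 0.5`, otherwise `2*(1 - S)`; the result is clamped into (0, 1].
#' The `1 - S` branch is evaluated by summing the upper-tail terms
#' directly, so small p-values keep full relative precision on either
#' branch. The statistic is symmetric: swapping `(x, N1)` with
#' `(y, N2)` gives the same p-value.
#'
#' @param x,y non-negative integer counts of the gene in library 1 and 2
#'   (vectorized; recycled to common length).
#' @param N1,N2 positive totals of fragments in library 1 and 2.
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' ac_pvalue(0, 0, 1e6, 1e6)    # 1
#' ac_pvalue(5, 1, 1e6, 1e6)    # 1/8
#' ac_pvalue(2, 0, 100, 200)    # 2/27
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  if (N1 <= 0 || N2 <= 0) stop("library totals N1, N2 must be positive")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(x != floor(x)) || any(y != floor(y)))
    stop("counts must be integers")
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  ratio <- N2 / N1
  vapply(seq_len(n), function(k) {
    S <- ac_lower_tail(x[k], y[k], ratio)
    pv <- if (S <= 0.5) 2 * S else 2 * ac_upper_tail(x[k], y[k], ratio)
    min(max(pv, .Machine$double.xmin), 1)
  }, numeric(1))
}

#' Multiple-testing adjustment for the DE screen
#'
#' Benjamini-Hochberg step-up false-discovery-rate adjustment (the
#' default), with a Bonferroni alternative. Thin wrapper over
#' [stats::p.adjust()] that enforces the (0, 1] input contract.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = method)
}

#' Log2 expression ratio with additive pseudo-expression
#'
#' @param fpkm_a,fpkm_b non-negative FPKM of the earlier and later stage.
#' @param epsilon positive pseudo-FPKM added to both sides so that zeros
#'   are well-defined; default 0.01.
#' @return `log2((fpkm_b + epsilon) / (fpkm_a + epsilon))` — oriented
#'   later stage over earlier stage.
#' @export
log2_ratio <- function(fpkm_a, fpkm_b, epsilon = 0.01) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (any(fpkm_a < 0) || any(fpkm_b < 0)) stop("FPKM must be non-negative")
  log2((fpkm_b + epsilon) / (fpkm_a + epsilon))
}

#' Pairwise differential-expression screen between two ripening stages
#'
#' Pools replicate libraries within each stage by summation (so the
#' `N1`/`N2` totals keep their total-fragments meaning), runs the exact
#' two-library test per gene, adjusts over all genes of the comparison,
#' and flags DEGs with the screen `fdr < fdr_threshold` (strict) and
#' `|log2 ratio| >= min_abs_log2` (inclusive). A non-default
#' `replicate_mode = "median_pairs"` instead tests every replicate pair
#' across the two stages and takes the per-gene median p-value.
#'
#' @param cm a [count_matrix()].
#' @param stage_a,stage_b stage labels; the ratio is oriented
#'   `stage_b` over `stage_a` (later over earlier).
#' @param fdr_threshold strict FDR cutoff (default 0.001).
#' @param min_abs_log2 inclusive fold-change cutoff in log2 units
#'   (default 1, i.e. two-fold).
#' @param epsilon pseudo-FPKM for the ratio, see [log2_ratio()].
#' @param adjust_method passed to [bh_adjust()].
#' @param replicate_mode `"pool"` (default) or `"median_pairs"`.
#' @return data.frame with columns `gene_id`, `x`, `y`, `N1`, `N2`,
#'   `pvalue`, `fdr`, `log2ratio`, `is_deg`.
#' @export
run_pairwise_de <- function(cm, stage_a, stage_b,
                            fdr_threshold = 0.001, min_abs_log2 = 1,
                            epsilon = 0.01, adjust_method = "BH",
                            replicate_mode = c("pool", "median_pairs")) {
  stopifnot(inherits(cm, "count_matrix"))
  replicate_mode <- match.arg(replicate_mode)
  if (!nrow(cm$counts)) stop("empty gene set")
  libs_a <- stage_libraries(cm, stage_a)
  libs_b <- stage_libraries(cm, stage_b)

  x <- rowSums(cm$counts[, libs_a, drop = FALSE])
  y <- rowSums(cm$counts[, libs_b, drop = FALSE])
  totals <- library_totals(cm)
  N1 <- sum(totals[libs_a])
  N2 <- sum(totals[libs_b])
  if (N1 <= 0 || N2 <= 0) stop("a stage has zero total fragments")

  if (replicate_mode == "pool") {
    pvalue <- ac_pvalue(x, y, N1, N2)
  } else {
    pairs <- expand.grid(a = libs_a, b = libs_b, stringsAsFactors = FALSE)
    pv <- sapply(seq_len(nrow(pairs)), function(k) {
      ac_pvalue(cm$counts[, pairs$a[k]], cm$counts[, pairs$b[k]],
                totals[[pairs$a[k]]], totals[[pairs$b[k]]])
    })
    pvalue <- apply(matrix(pv, nrow = nrow(cm$counts)), 1, stats::median)
  }

  fdr <- bh_adjust(pvalue, method = adjust_method)
  fpkm_a <- 1e9 * x / (N1 * cm$lengths)
  fpkm_b <- 1e9 * y / (N2 * cm$lengths)
  l2r <- log2_ratio(fpkm_a, fpkm_b, epsilon)
  data.frame(gene_id = rownames(cm$counts),
             x = unname(x), y = unname(y), N1 = N1, N2 = N2,
             pvalue = unname(pvalue), fdr = unname(fdr),
             log2ratio = unname(l2r),
             is_deg = unname(fdr < fdr_threshold & abs(l2r) >= min_abs_log2),
             stringsAsFactors = FALSE)
}
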