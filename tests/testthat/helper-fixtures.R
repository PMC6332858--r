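# shared fixtures and independent oracles for the test-suite

# tiny count_matrix with one library per stage and equal gene lengths;
# `filler` pads each library to a fixed total
toy_count_matrix <- function(counts_by_stage, total = NULL, length_bp = 1000) {
  mat <- do.call(cbind, counts_by_stage)
  colnames(mat) <- paste0("L", seq_along(counts_by_stage))
  rownames(mat) <- sprintf("g%d", seq_len(nrow(mat)))
  if (!is.null(total)) {
    filler <- total - colSums(mat)
    stopifnot(all(filler >= 0))
    mat <- rbind(mat, filler = filler)
    rownames(mat)[nrow(mat)] <- "filler"
  }
  storage.mode(mat) <- "integer"
  count_matrix(mat,
               stats::setNames(rep(length_bp, nrow(mat)), rownames(mat)),
               data.frame(library_id = colnames(mat),
                          stage = names(counts_by_stage),
                          replicate = "A",
                          stringsAsFactors = FALSE))
}

# lower tail of the conditional test via R's independent negative
# binomial distribution function (the terms are NB(size = x+1,
# prob = N1/(N1+N2)) masses)
nb_oracle_pvalue <- function(x, y, N1, N2) {
  S <- stats::pnbinom(y, size = x + 1, prob = N1 / (N1 + N2))
  if (S <= 0.5) 2 * S else 2 * (1 - S)
}

# incomplete-beta form of the two-sided Pearson correlation p-value
beta_oracle_pvalue <- function(r, n) {
  stats::pbeta(1 - r^2, (n - 2) / 2, 1 / 2)
}

# pair of vectors of length n whose Pearson correlation is exactly r,
# built from an orthonormalized basis
vectors_with_cor <- function(r, n) {
  z1 <- seq_len(n) - mean(seq_len(n))
  z1 <- z1 / sqrt(sum(z1^2))
  raw <- seq_len(n)^2
  z2 <- raw - mean(raw) - sum(raw * z1) * z1
  z2 <- z2 / sqrt(sum(z2^2))
  list(u = z1, v = r * z1 + sqrt(1 - r^2) * z2)
}

# module_partition with given labels, bypassing detection
manual_partition <- function(labels, min_module_size = 2) {
  structure(list(labels = labels, min_module_size = min_module_size,
                 cut_height = NA_real_, tree = NULL),
            class = "module_partition")
}

# exact rational-arithmetic oracle for the two-library test, evaluated
# with Python's fractions module; returns p-values for the full
# (ratio, x, y) grid in row-major loop order
exact_rational_pvalues <- function(xs, ys, ratios_num_den) {
  script <- paste(
    "from fractions import Fraction",
    sprintf("ratios = [%s]",
            paste(sprintf("Fraction(%d, %d)", ratios_num_den[, 1],
                          ratios_num_den[, 2]), collapse = ", ")),
    sprintf("xs = %s", paste0("[", paste(xs, collapse = ","), "]")),
    sprintf("ys = %s", paste0("[", paste(ys, collapse = ","), "]")),
    "out = []",
    "for r in ratios:",
    "    for x in xs:",
    "        t0 = Fraction(1) / (1 + r) ** (x + 1)",
    "        for y in ys:",
    "            t = t0",
    "            S = t",
    "            for i in range(1, y + 1):",
    "                t = t * r * Fraction(x + i, i) / (1 + r)",
    "                S += t",
    "            p = 2 * S if S <= Fraction(1, 2) else 2 * (1 - S)",
    "            out.append(float(p))",
    "print('\\n'.join(repr(v) for v in out))",
    sep = "\n")
  out <- system2("python", "-", stdout = TRUE, input = script)
  as.numeric(out)
}
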