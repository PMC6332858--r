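test_that("expression filter applies the strict mean and variance rules", {
  fp <- rbind(constant5 = rep(5, 6),      # mean > 1 but zero variance
              mean_one = c(0.5, 1.5, 0.5, 1.5, 0.5, 1.5),   # mean exactly 1
              keeper = c(2, 3, 2, 3, 2, 3),
              low = rep(0.2, 6) + (1:6) / 100)
  colnames(fp) <- paste0("L", 1:6)
  expect_identical(filter_expressed(fp), "keeper")
  expect_length(filter_expressed(fp[c("low"), , drop = FALSE]), 0)
})

test_that("unsigned adjacency matches closed forms", {
  s <- c(1, 1, -1, -1)
  t <- c(1, -1, 1, -1)
  expr <- rbind(g1 = s, g2 = s + sqrt(3) * t,   # cor(g1, g2) = 0.5 exactly
                g3 = -2 * s + 1,                # cor(g1, g3) = -1
                g4 = 3 * s + 5)                 # cor(g1, g4) = +1
  colnames(expr) <- paste0("L", 1:4)
  a <- soft_adjacency(expr, beta = 16)
  expect_equal(a["g1", "g2"], 0.5^16)
  expect_equal(0.5^16, 1.52587890625e-05)
  expect_equal(a["g1", "g3"], 1)
  expect_equal(a["g1", "g4"], 1)
  expect_equal(diag(a), setNames(rep(1, 4), rownames(expr)))
  a1 <- soft_adjacency(expr, beta = 1)
  expect_equal(unname(a1["g1", "g2"]), 0.5)
  expect_error(soft_adjacency(expr, beta = 0), "positive")
  expect_error(soft_adjacency(rbind(expr, flat = rep(2, 4))), "zero-variance")
})

const_adjacency <- function(n, a) {
  m <- matrix(a, n, n, dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  diag(m) <- 1
  m
}

test_that("topological overlap matches constant-graph closed forms", {
  # complete graph with constant off-diagonal a:
  # TOM = ((n-2)a^2 + a) / ((n-2)a + 1)
  for (n in c(3, 4, 7)) {
    for (a in c(0.1, 0.5, 1)) {
      tom <- tom_similarity(const_adjacency(n, a))
      expected <- ((n - 2) * a^2 + a) / ((n - 2) * a + 1)
      off <- tom[upper.tri(tom)]
      expect_equal(off, rep(expected, length(off)), tolerance = 1e-10)
    }
  }
  expect_equal(unname(tom_similarity(const_adjacency(4, 0.5))[1, 2]), 0.5,
               tolerance = 1e-12)
  expect_equal(unname(tom_similarity(const_adjacency(3, 1))[1, 2]), 1,
               tolerance = 1e-12)
  tom0 <- tom_similarity(const_adjacency(5, 0))
  expect_equal(tom0[upper.tri(tom0)], rep(0, 10))
})

test_that("topological overlap equals the brute-force triple loop", {
  set.seed(11)
  for (rep in 1:3) {
    expr <- matrix(rnorm(12 * 8), 12, 8,
                   dimnames = list(paste0("g", 1:12), paste0("L", 1:8)))
    adj <- soft_adjacency(expr, beta = 6)
    tom <- tom_similarity(adj)
    n <- nrow(adj)
    ref <- diag(n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + adj[i, u] * adj[u, j]
      ki <- sum(adj[i, -i])
      kj <- sum(adj[j, -j])
      ref[i, j] <- (l + adj[i, j]) / (min(ki, kj) + 1 - adj[i, j])
    }
    expect_equal(unname(tom), unname(ref), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(isSymmetric(unname(tom)))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  expect_error(tom_similarity(matrix(c(1, 0.2, 0.4, 1), 2, 2)), "symmetric")
})

block_tom <- function(sizes, within = 0.8, between = 0.05) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  m <- matrix(between, n, n,
              dimnames = list(paste0("g", 1:n), paste0("g", 1:n)))
  for (b in seq_along(sizes)) m[lab == b, lab == b] <- within
  diag(m) <- 1
  m
}

test_that("planted blocks are detected as modules", {
  tom <- block_tom(c(50, 50))
  part <- detect_modules(tom, min_module_size = 30)
  expect_equal(max(part$labels), 2)
  expect_equal(unname(part$labels[1:50]), rep(part$labels[[1]], 50))
  expect_equal(unname(part$labels[51:100]), rep(part$labels[[51]], 50))
  expect_false(part$labels[[1]] == part$labels[[51]])
})

test_that("small gene sets are left unassigned with a warning", {
  tom <- block_tom(c(10, 10))
  expect_warning(part <- detect_modules(tom, min_module_size = 30),
                 "unassigned")
  expect_true(all(part$labels == 0))
})

test_that("gene order does not change the detected partition", {
  set.seed(3)
  tom <- block_tom(c(40, 35, 30), within = 0.7, between = 0.02)
  part <- detect_modules(tom, min_module_size = 30)
  perm <- sample(nrow(tom))
  part_p <- detect_modules(tom[perm, perm], min_module_size = 30)
  # same partition up to label names: cross-table has one nonzero per row
  tab <- table(part$labels[rownames(tom)], part_p$labels[rownames(tom)])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("stem pruning drops weakly attached genes but keeps the core", {
  tom <- block_tom(c(50, 41))
  adj <- block_tom(c(50, 41), within = 0.4, between = 0.001)
  # gene 91: attached to block 2 in the tree but nearly disconnected
  tom <- cbind(rbind(tom, stem = c(rep(0.05, 50), rep(0.45, 41))),
               stem = c(rep(0.05, 50), rep(0.45, 41), 1))
  adj <- cbind(rbind(adj, stem = c(rep(0.001, 50), rep(0.02, 41))),
               stem = c(rep(0.001, 50), rep(0.02, 41), 1))
  rownames(tom)[92] <- colnames(tom)[92] <- "stem"
  rownames(adj)[92] <- colnames(adj)[92] <- "stem"
  plain <- detect_modules(tom, min_module_size = 30)
  pruned <- detect_modules(tom, min_module_size = 30, adjacency = adj)
  expect_gt(plain$labels[["stem"]], 0)
  expect_equal(pruned$labels[["stem"]], 0L)
  expect_true(all(pruned$labels[1:91] > 0))
})

latent_profiles <- function() {
  s <- c(1, 1, 1, 0, 0, 0, -1, -1, -1) * sqrt(2 / 3)
  t <- c(1, -1, 0, 1, -1, 0, 1, -1, 0)
  list(s = s, t = t)
}

test_that("eigengene of a rank-1 module is the common profile", {
  lp <- latent_profiles()
  expr <- rbind(g1 = 2 * lp$s + 1, g2 = 0.5 * lp$s - 3, g3 = 7 * lp$s)
  colnames(expr) <- paste0("L", 1:9)
  part <- manual_partition(setNames(c(1L, 1L, 1L), rownames(expr)))
  me <- module_eigengenes(expr, part)
  expect_equal(attr(me, "var_explained")[["ME1"]], 1)
  expect_equal(sum(me[, "ME1"]^2), 1)               # unit norm
  zs <- lp$s / sqrt(sum((lp$s - mean(lp$s))^2))     # standardized direction
  expect_equal(abs(cor(me[, "ME1"], lp$s)), 1, tolerance = 1e-9)
  expect_gte(cor(me[, "ME1"], lp$s), 0)             # sign-oriented upward
})

test_that("eigengene is invariant to duplicating a member profile", {
  lp <- latent_profiles()
  expr <- rbind(g1 = 2 * lp$s + 1, g2 = 0.5 * lp$s - 3, g3 = 7 * lp$s)
  colnames(expr) <- paste0("L", 1:9)
  me1 <- module_eigengenes(expr, manual_partition(
    setNames(rep(1L, 3), rownames(expr))))
  expr2 <- rbind(expr, g4 = 0.5 * lp$s - 3)
  me2 <- module_eigengenes(expr2, manual_partition(
    setNames(rep(1L, 4), rownames(expr2))))
  expect_equal(me1[, "ME1"], me2[, "ME1"], tolerance = 1e-9)
})

test_that("negating every member leaves the eigengene aligned with the mean", {
  set.seed(5)
  lp <- latent_profiles()
  expr <- t(sapply(1:6, function(i) lp$s + rnorm(9, 0, 0.3)))
  dimnames(expr) <- list(paste0("g", 1:6), paste0("L", 1:9))
  part <- manual_partition(setNames(rep(1L, 6), rownames(expr)))
  for (e in list(expr, -expr)) {
    me <- module_eigengenes(e, part)
    z <- t(scale(t(e)))
    expect_gte(cor(me[, "ME1"], colMeans(z)), 0)
  }
})

test_that("no single gene explains more module variance than the eigengene", {
  set.seed(9)
  expr <- matrix(rnorm(8 * 9), 8, 9,
                 dimnames = list(paste0("g", 1:8), paste0("L", 1:9)))
  part <- manual_partition(setNames(rep(1L, 8), rownames(expr)))
  me <- module_eigengenes(expr, part)
  z <- t(scale(t(expr)))
  total <- sum(z^2)
  for (g in seq_len(nrow(z))) {
    u <- z[g, ] / sqrt(sum(z[g, ]^2))
    expect_lte(sum((z %*% u)^2) / total,
               attr(me, "var_explained")[["ME1"]] + 1e-12)
  }
})

test_that("modules with identical eigengenes merge; dissimilar ones do not", {
  lp <- latent_profiles()
  mk <- function(base, lab, n = 4) {
    e <- t(sapply(seq_len(n), function(i) (i + 1) * base + i))
    dimnames(e) <- list(paste0(lab, seq_len(n)), paste0("L", 1:9))
    e
  }
  # two modules on the same latent -> merged into one
  expr <- rbind(mk(lp$s, "a"), mk(lp$s, "b"))
  part <- manual_partition(setNames(rep(c(1L, 2L), each = 4),
                                    rownames(expr)))
  merged <- merge_modules(expr, part)
  expect_equal(max(merged$labels), 1)

  # eigengene correlation 0.5 -> dissimilarity 0.5 > 0.25 -> untouched
  s_hat <- lp$s / sqrt(sum(lp$s^2))
  t_hat <- lp$t / sqrt(sum(lp$t^2))
  half <- 0.5 * s_hat + sqrt(0.75) * t_hat   # cor(s, half) = 0.5 exactly
  expr2 <- rbind(mk(lp$s, "a"), mk(half, "b"))
  part2 <- manual_partition(setNames(rep(c(1L, 2L), each = 4),
                                     rownames(expr2)))
  kept <- merge_modules(expr2, part2)
  expect_equal(max(kept$labels), 2)

  # idempotence
  again <- merge_modules(expr2, kept)
  expect_identical(again$labels, kept$labels)
})
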