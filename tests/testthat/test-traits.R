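test_that("correlation test matches the incomplete-beta oracle on a grid", {
  for (n in c(4, 6, 9, 15, 30)) {
    for (r in c(-0.99, -0.97, -0.5, -0.1, 0.1, 0.62, 0.95, 0.99)) {
      vv <- vectors_with_cor(r, n)
      ct <- correlation_test(vv$u, vv$v)
      expect_equal(ct$r, r, tolerance = 1e-12)
      expect_equal(ct$p, beta_oracle_pvalue(r, n), tolerance = 1e-10)
    }
  }
})

test_that("correlation test handles the degenerate ends", {
  u <- c(2, 1, 4, 3, 6, 5, 8, 7, 9)
  self <- correlation_test(u, u)
  expect_equal(self$r, 1)
  expect_equal(self$p, 0)
  orth <- vectors_with_cor(0, 9)
  expect_equal(correlation_test(orth$u, orth$v)$p, 1)
  expect_error(correlation_test(u, rep(1, 9)), "variance")
  expect_error(correlation_test(u, 1:5), "mismatch")
  expect_error(correlation_test(1:3, 3:1), "at least 4")
})

test_that("r = -0.97 with nine libraries gives p of 1e-5 at one digit", {
  vv <- vectors_with_cor(-0.97, 9)
  p <- correlation_test(vv$u, vv$v)$p
  expect_equal(signif(p, 1), 1e-5)
  expect_equal(p, 1.4946e-5, tolerance = 1e-4)
})

test_that("module-trait matrix correlates every eigengene with every trait", {
  set.seed(21)
  me <- matrix(rnorm(27), 9, 3, dimnames = list(paste0("L", 1:9),
                                                paste0("ME", 1:3)))
  traits <- data.frame(t1 = me[, 1], t2 = rnorm(9), row.names = paste0("L", 1:9))
  mt <- module_trait_matrix(me, traits)
  expect_equal(mt$r["ME1", "t1"], 1)
  expect_equal(mt$p["ME1", "t1"], 0)
  expect_equal(mt$n, 9)
  for (i in 1:3) for (j in 1:2)
    expect_equal(mt$p[i, j],
                 beta_oracle_pvalue(mt$r[i, j], 9), tolerance = 1e-10)
  expect_error(module_trait_matrix(me, traits[c(2:9, 1), ]), "ordered")
})

test_that("permuted traits rarely reach high module correlations", {
  set.seed(8)
  ds <- simulate_dataset(synthetic_config(seed = 8))
  res <- suppressMessages(run_pipeline(pipeline_config(seed = 8),
                                       counts = ds$counts,
                                       traits = ds$traits))
  me <- res$network$eigengenes
  tr <- ds$traits$sucrose
  hits <- 0
  nperm <- 1000
  for (k in seq_len(nperm)) {
    rmax <- max(abs(cor(me, sample(tr))))
    if (rmax > 0.8) hits <- hits + 1
  }
  expect_lt(hits / nperm, 0.05)
})

test_that("candidate selection honors the strict r threshold and module scope", {
  trait <- c(3, 10, 22, 38, 55, 80, 95, 110, 124)
  # genes expressed along the trait's own standardized direction
  z1 <- (trait - mean(trait)) / sqrt(sum((trait - mean(trait))^2))
  raw <- seq_len(9)^2
  z2 <- raw - mean(raw) - sum(raw * z1) * z1
  z2 <- z2 / sqrt(sum(z2^2))
  g_perfect <- z1
  g_at91 <- 0.91 * z1 + sqrt(1 - 0.91^2) * z2
  g_at95 <- 0.95 * z1 + sqrt(1 - 0.95^2) * z2
  g_outside <- z1 + 0.001 * z2
  fpkm <- rbind(g_perfect = g_perfect, g_at91 = g_at91,
                g_at95 = g_at95, g_outside = g_outside) + 2
  colnames(fpkm) <- paste0("L", 1:9)
  part <- manual_partition(setNames(c(1L, 1L, 1L, 2L), rownames(fpkm)))
  traits <- data.frame(sucrose = trait, row.names = colnames(fpkm))

  cand <- select_candidate_genes(fpkm, traits, part, modules = 1,
                                 log_transform = FALSE)
  expect_true("g_perfect" %in% cand$gene_id)
  expect_true("g_at95" %in% cand$gene_id)
  expect_false("g_at91" %in% cand$gene_id)      # strict >
  expect_false("g_outside" %in% cand$gene_id)   # outside module scope
  expect_equal(unique(cand$best_trait), "sucrose")
  expect_error(select_candidate_genes(fpkm, traits, part, modules = integer(0)),
               "empty")
})

test_that("raising the candidate threshold never adds genes", {
  set.seed(33)
  ds <- simulate_dataset(synthetic_config(seed = 33))
  res <- suppressMessages(run_pipeline(pipeline_config(seed = 33),
                                       counts = ds$counts,
                                       traits = ds$traits))
  part <- res$network$partition
  fp <- res$fpkm[rownames(res$network$expr), ]
  prev <- NULL
  for (thr in c(0.5, 0.7, 0.91, 0.97, 0.999)) {
    sel <- select_candidate_genes(fp, ds$traits, part,
                                  res$significant_modules, r_threshold = thr)
    if (!is.null(prev)) expect_true(all(sel$gene_id %in% prev))
    prev <- sel$gene_id
  }
})

test_that("hub selection rewards module membership and connectivity", {
  lp_s <- c(1, 1, 1, 0, 0, 0, -1, -1, -1)
  set.seed(14)
  expr <- rbind(
    hub = lp_s,                                  # the latent itself
    t(sapply(1:6, function(i) lp_s + rnorm(9, 0, 0.5))))
  rownames(expr) <- c("hub", paste0("m", 1:6))
  colnames(expr) <- paste0("L", 1:9)
  part <- manual_partition(setNames(rep(1L, 7), rownames(expr)))
  adj <- soft_adjacency(expr, beta = 6)
  me <- module_eigengenes(expr, part)
  hubs <- identify_hubs(expr, me, part, adj, kme_threshold = 0.8,
                        top_k_per_module = 2)
  expect_equal(nrow(hubs), 7)
  expect_equal(sum(hubs$is_hub), 2)
  expect_true(hubs$is_hub[hubs$gene_id == "hub"])
  expect_gt(hubs$kME[hubs$gene_id == "hub"], 0.99)

  # an unreachable kME threshold yields no hubs
  none <- identify_hubs(expr, me, part, adj, kme_threshold = 0.99999)
  expect_equal(sum(none$is_hub), 0)

  # input order does not change the hub set
  perm <- sample(nrow(expr))
  hubs_p <- identify_hubs(expr[perm, ], me, part, adj,
                          kme_threshold = 0.8, top_k_per_module = 2)
  expect_identical(hubs_p$gene_id[hubs_p$is_hub],
                   hubs$gene_id[hubs$is_hub])
})

test_that("edge export filters, orders and deduplicates", {
  # weights: ab = 0.5, ac = 0.2, bc = 0.05 (rows/cols deliberately unsorted)
  m <- matrix(c(1, 0.5, 0.05,
                0.5, 1, 0.2,
                0.05, 0.2, 1), 3, 3,
              dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  e <- export_network_edges(m, weight_threshold = 0.1)
  expect_equal(nrow(e), 2)
  expect_equal(e$source, c("a", "a"))
  expect_equal(e$target, c("b", "c"))
  expect_true(all(e$source < e$target))
  expect_equal(sort(e$weight), c(0.2, 0.5))

  none <- export_network_edges(m, weight_threshold = 1.0)
  expect_equal(nrow(none), 0)

  sif <- tempfile(fileext = ".sif")
  export_network_edges(m, weight_threshold = 0.1, format = "sif", file = sif)
  expect_equal(readLines(sif), c("a coexp b", "a coexp c"))

  expect_error(export_network_edges(m, weight_threshold = 1.5), "\\[0, 1\\]")
  expect_error(export_network_edges(m, genes = c("a", "zz"),
                                    weight_threshold = 0.1), "zz")

  set.seed(2)
  expr <- matrix(rnorm(80), 10, 8,
                 dimnames = list(paste0("g", 1:10), paste0("L", 1:8)))
  big <- export_network_edges(soft_adjacency(expr, beta = 2),
                              weight_threshold = 0)
  expect_equal(nrow(big), choose(10, 2))
  expect_false(any(duplicated(paste(big$source, big$target))))
  expect_false(any(big$source == big$target))
})
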