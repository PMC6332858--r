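#' Pipeline configuration
#'
#' Collects every stage threshold in one validated object. The defaults
#' are the analysis parameters of the ripening study: FDR < 0.001 and
#' |log2 ratio| >= 1 for the DEG screen, a 32-fold profile cap
#' (log2 cap 5), mean FPKM > 1 for the network filter, soft power 16,
#' minimum module size 30, merge cut height 0.25, gene-trait candidate
#' threshold r > 0.91, and hub kME >= 0.9.
#'
#' @param counts_path,lengths_path,samples_path,traits_path optional
#'   input file paths (unused when in-memory objects are passed to
#'   [run_pipeline()]).
#' @param fdr_threshold,min_abs_log2 DEG screen thresholds.
#' @param fold_cap_log2 profile-classification fold cap (log2 units).
#' @param min_mean_fpkm strict network filter on mean FPKM.
#' @param beta soft power of the unsigned adjacency.
#' @param min_module_size,merge_cut_height,cut_quantile module
#'   detection/merging parameters.
#' @param module_p_threshold per-cell p cutoff defining trait-associated
#'   modules.
#' @param r_threshold strict gene-trait candidate cutoff.
#' @param kme_threshold,top_k_per_module hub selection parameters.
#' @param edge_weight_threshold minimum adjacency weight exported to the
#'   edge list.
#' @param seed master seed (used when simulating, recorded always).
#' @param outdir optional output directory; when set every intermediate
#'   table plus a JSON manifest is written there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, lengths_path = NULL,
                            samples_path = NULL, traits_path = NULL,
                            fdr_threshold = 0.001, min_abs_log2 = 1,
                            fold_cap_log2 = 5, min_mean_fpkm = 1,
                            beta = 16, min_module_size = 30,
                            merge_cut_height = 0.25, cut_quantile = 0.99,
                            module_p_threshold = 0.001, r_threshold = 0.91,
                            kme_threshold = 0.9, top_k_per_module = 5,
                            edge_weight_threshold = 0.1,
                            seed = 1, outdir = NULL) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(fdr_threshold > 0, fdr_threshold < 1, min_abs_log2 >= 0,
              fold_cap_log2 > 0, min_mean_fpkm >= 0, beta > 0,
              min_module_size >= 1, merge_cut_height >= 0,
              merge_cut_height <= 1, cut_quantile > 0, cut_quantile <= 1,
              module_p_threshold > 0, r_threshold >= 0, r_threshold <= 1,
              kme_threshold >= 0, kme_threshold <= 1,
              top_k_per_module >= 1, edge_weight_threshold >= 0,
              edge_weight_threshold <= 1)
  })
  structure(cfg, class = "pipeline_config")
}

pipeline_stage <- function(name, manifest_env, expr) {
  message(sprintf("[%s] start", name))
  res <- tryCatch(expr, error = function(e) {
    man <- manifest_env$manifest
    if (!is.null(manifest_env$outdir)) {
      jsonlite::write_json(man,
                           file.path(manifest_env$outdir,
                                     "manifest.partial.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done", name))
  res
}

#' Run the full analysis pipeline
#'
#' Executes the study's stage order on a count matrix and trait table:
#' pairwise DEG screens between consecutive and outer stages, four-group
#' profile classification, FPKM filtering, unsigned network
#' construction (adjacency, TOM, module detection, eigengenes, module
#' merging), module-trait association, candidate-gene and hub selection,
#' and edge-list export. With `outdir` set, all intermediate tables are
#' written as TSV along with a JSON manifest recording the package
#' version, parameters, seed and per-stage row counts. For a fixed input
#' and config the run is deterministic.
#'
#' @param config a [pipeline_config()].
#' @param counts a [count_matrix()]; when NULL, read from the config
#'   paths.
#' @param traits libraries x traits table (rownames = library ids);
#'   when NULL, read from `config$traits_path`.
#' @return list with elements `de` (list of three data.frames),
#'   `profiles`, `fpkm`, `network` (adjacency, tom, partition,
#'   eigengenes), `module_trait`, `significant_modules`, `candidates`,
#'   `hubs`, `edges`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), counts = NULL,
                         traits = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(counts))
    counts <- read_count_matrix(config$counts_path, config$lengths_path,
                                config$samples_path)
  if (is.null(traits)) traits <- read_traits(config$traits_path)
  traits <- traits[counts$samples$library_id, , drop = FALSE]

  env <- new.env()
  env$outdir <- config$outdir
  if (!is.null(config$outdir))
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  env$manifest <- list(
    package = "flavornet",
    version = as.character(utils::packageVersion("flavornet")),
    seed = config$seed,
    parameters = config[!(names(config) %in%
                            c("counts_path", "lengths_path", "samples_path",
                              "traits_path", "outdir"))],
    stages = list(), files = character(0))
  note <- function(stage, n, file = NULL, obj = NULL) {
    env$manifest$stages[[stage]] <- n
    if (!is.null(file) && !is.null(config$outdir)) {
      path <- file.path(config$outdir, file)
      if (is.function(obj)) obj(path) else write_tsv(obj, path)
      env$manifest$files <- c(env$manifest$files, file)
    }
  }

  st <- stages(counts)
  if (length(st) < 3) stop("pipeline expects three ripening stages")
  pairs <- list(c(st[1], st[2]), c(st[2], st[3]), c(st[1], st[3]))

  de <- pipeline_stage("detest", env, {
    res <- lapply(pairs, function(p)
      run_pairwise_de(counts, p[1], p[2],
                      fdr_threshold = config$fdr_threshold,
                      min_abs_log2 = config$min_abs_log2))
    names(res) <- vapply(pairs, function(p) paste0(p[1], "_vs_", p[2]), "")
    for (nm in names(res))
      note(paste0("de_", nm), sum(res[[nm]]$is_deg),
           paste0("de_", nm, ".tsv"), res[[nm]])
    res
  })

  profiles <- pipeline_stage("profiles", env, {
    pr <- classify_profiles(de[[1]], de[[2]],
                            fold_cap_log2 = config$fold_cap_log2)
    note("profiles", sum(pr$group != "excluded"), "profiles.tsv", pr)
    pr
  })

  fpkm <- pipeline_stage("fpkm", env, {
    fp <- compute_fpkm(counts)
    note("fpkm", nrow(fp), "fpkm.tsv",
         data.frame(gene_id = rownames(fp), fp, check.names = FALSE))
    fp
  })

  network <- pipeline_stage("network", env, {
    keep <- filter_expressed(fpkm, config$min_mean_fpkm)
    if (!length(keep))
      stop("no gene passes the expression filter (mean FPKM > ",
           config$min_mean_fpkm, ")")
    expr <- log2(fpkm[keep, , drop = FALSE] + 1)
    adj <- soft_adjacency(expr, beta = config$beta)
    tom <- tom_similarity(adj)
    part <- detect_modules(tom, min_module_size = config$min_module_size,
                           cut_quantile = config$cut_quantile,
                           adjacency = adj)
    if (any(part$labels > 0))
      part <- merge_modules(expr, part,
                            merge_cut_height = config$merge_cut_height)
    me <- module_eigengenes(expr, part)
    note("network_filter", length(keep))
    note("modules", max(part$labels), "modules.tsv",
         data.frame(gene_id = names(part$labels),
                    module = unname(part$labels)))
    note("eigengenes", ncol(me), "eigengenes.tsv",
         data.frame(library_id = rownames(me), me, check.names = FALSE))
    list(expr = expr, adjacency = adj, tom = tom, partition = part,
         eigengenes = me)
  })

  if (max(network$partition$labels) == 0)
    warning("no module passed min_module_size; ",
            "trait association and candidate selection are empty")

  mt <- pipeline_stage("trait_assoc", env, {
    if (!ncol(network$eigengenes)) {
      m <- structure(list(r = matrix(numeric(0), 0, ncol(traits),
                                     dimnames = list(NULL, colnames(traits))),
                          p = matrix(numeric(0), 0, ncol(traits),
                                     dimnames = list(NULL, colnames(traits))),
                          n = nrow(traits)), class = "module_trait")
    } else {
      m <- module_trait_matrix(network$eigengenes, traits)
    }
    note("module_trait", nrow(m$r), "module_trait_r.tsv",
         data.frame(module = rownames(m$r), m$r, check.names = FALSE))
    if (!is.null(config$outdir)) {
      write_tsv(data.frame(module = rownames(m$p), m$p, check.names = FALSE),
                file.path(config$outdir, "module_trait_p.tsv"))
      env$manifest$files <- c(env$manifest$files, "module_trait_p.tsv")
    }
    m
  })

  sig <- significant_modules(mt, config$module_p_threshold)

  candidates <- pipeline_stage("candidates", env, {
    cand <- if (length(sig)) {
      select_candidate_genes(fpkm[rownames(network$expr), , drop = FALSE],
                             traits, network$partition, sig,
                             r_threshold = config$r_threshold)
    } else {
      data.frame(gene_id = character(0), module = integer(0),
                 best_trait = character(0), gene_trait_r = numeric(0))
    }
    note("candidates", nrow(cand), "candidates.tsv", cand)
    cand
  })

  hubs <- pipeline_stage("hubs", env, {
    h <- if (ncol(network$eigengenes)) {
      identify_hubs(network$expr, network$eigengenes, network$partition,
                    network$adjacency, kme_threshold = config$kme_threshold,
                    top_k_per_module = config$top_k_per_module)
    } else {
      data.frame(gene_id = character(0), module = integer(0),
                 kME = numeric(0), intramodular_k = numeric(0),
                 is_hub = logical(0))
    }
    note("hubs", sum(h$is_hub), "hubs.tsv", h)
    h
  })

  edges <- pipeline_stage("edges", env, {
    sel <- if (nrow(candidates)) candidates$gene_id
           else rownames(network$adjacency)
    e <- export_network_edges(network$adjacency, sel,
                              weight_threshold = config$edge_weight_threshold)
    note("edges", nrow(e), "edges.tsv", e)
    e
  })

  env$manifest$timestamp <- format(Sys.time(), tz = "UTC")
  if (!is.null(config$outdir)) {
    jsonlite::write_json(env$manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    env$manifest$files <- c(env$manifest$files, "manifest.json")
  }

  list(de = de, profiles = profiles, fpkm = fpkm, network = network,
       module_trait = mt, significant_modules = sig,
       candidates = candidates, hubs = hubs, edges = edges,
       manifest = env$manifest)
}
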