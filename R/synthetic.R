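#' Configuration of the synthetic ripening dataset
#'
#' Describes a seeded benchmark dataset with the statistical structure
#' the pipeline assumes: a 3-stage x 3-replicate library design, planted
#' co-expression modules whose log2-expression follows stage-level
#' trajectories (monotone rise and two transient dip/decline shapes),
#' negative binomial counts, and metabolite-like trait vectors linearly
#' coupled to the module latents.
#'
#' Defaults emulate the ripening study design: 580 genes of which
#' 3 x 60 belong to planted modules, stage trajectories spanning 3 log2
#' units, replicate jitter of 0.15 log2 units, and four traits shaped
#' like the published metabolite trajectories — sucrose rising
#' 3.04 to 124.35 mg/g, malic acid falling 35.10 to 8.4 mg/g, plus
#' beta-ionone and gamma-decalactone (ug/g) rising with ripening.
#' Metabolites that fall during ripening couple to the rising module
#' with a negative slope. The three default trajectories (monotone
#' rise, up-then-down, down-then-up) are pairwise 60 degrees apart in
#' the centered-profile plane (pairwise |correlation| = 0.5): an
#' unsigned network cannot distinguish a shape from its mirror image,
#' so planted modules must be non-collinear under absolute correlation
#' to be separable at all. Their direction vectors additionally sum to
#' zero, so the stage-dependent shift the modules impose on library
#' totals — which FPKM normalization would otherwise propagate into
#' every gene as a spurious common component — cancels to first order.
#'
#' @param n_genes total number of genes.
#' @param module_sizes sizes of the planted modules (must sum to at most
#'   `n_genes`); remaining genes are unstructured background.
#' @param stage_profiles list of per-module numeric vectors of length
#'   `n_stages`: stage-level log2-expression offsets.
#' @param n_stages,n_reps design dimensions (defaults 3 x 3).
#' @param baseline_log2_fpkm_range interval the per-gene baseline
#'   log2-FPKM is drawn from.
#' @param replicate_jitter_sd sd (log2 units) of the per-library jitter
#'   added to the stage-level latent.
#' @param nb_dispersion negative-binomial dispersion (reciprocal of the
#'   size parameter); 0 gives Poisson counts.
#' @param library_size_range interval of per-library total fragment
#'   targets.
#' @param gene_length_range interval of transcript lengths (bp).
#' @param trait_loadings data.frame with columns `trait`, `module`,
#'   `slope`, `intercept`, `noise_sd`: each trait is
#'   `intercept + slope * latent_module + N(0, noise_sd)`, floored at 0.
#' @param seed integer master seed; split internally into independent
#'   substreams for ground truth, counts and traits.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 580,
                             module_sizes = c(60, 60, 60),
                             stage_profiles = list(c(0, 1.5, 3),
                                                   c(1.5, 3, 0),
                                                   c(3, 0, 1.5)),
                             n_stages = 3, n_reps = 3,
                             baseline_log2_fpkm_range = c(2, 8),
                             replicate_jitter_sd = 0.15,
                             nb_dispersion = 0.05,
                             library_size_range = c(8e6, 12e6),
                             gene_length_range = c(500, 3000),
                             trait_loadings = default_trait_loadings(),
                             seed = 1) {
  cfg <- list(n_genes = n_genes, module_sizes = module_sizes,
              stage_profiles = stage_profiles, n_stages = n_stages,
              n_reps = n_reps,
              baseline_log2_fpkm_range = baseline_log2_fpkm_range,
              replicate_jitter_sd = replicate_jitter_sd,
              nb_dispersion = nb_dispersion,
              library_size_range = library_size_range,
              gene_length_range = gene_length_range,
              trait_loadings = trait_loadings, seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_genes < 1) stop("n_genes must be positive")
  if (any(cfg$module_sizes < 1)) stop("module sizes must be positive")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("sum(module_sizes) exceeds n_genes")
  if (length(cfg$stage_profiles) != length(cfg$module_sizes))
    stop("one stage profile per module is required")
  if (any(lengths(cfg$stage_profiles) != cfg$n_stages))
    stop("each stage profile must have n_stages values")
  if (cfg$n_stages * cfg$n_reps < 4)
    stop("need at least 4 libraries (n_stages * n_reps)")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  for (rng in list(cfg$baseline_log2_fpkm_range, cfg$library_size_range,
                   cfg$gene_length_range))
    if (length(rng) != 2 || diff(rng) <= 0)
      stop("ranges must be non-degenerate intervals (lo < hi)")
  tl <- cfg$trait_loadings
  need <- c("trait", "module", "slope", "intercept", "noise_sd")
  if (!all(need %in% names(tl)))
    stop("trait_loadings needs columns: ", paste(need, collapse = ", "))
  if (any(tl$module < 1 | tl$module > length(cfg$module_sizes)))
    stop("trait loading references unknown module index")
  invisible(cfg)
}

#' Default metabolite-like trait loadings
#'
#' Four traits coupled to the planted modules. Intercepts are the
#' stage-trajectory midpoints, so with the default (mean-centered)
#' latents the noiseless trait trajectories run 3.04 to 124.35 mg/g
#' (sucrose, rising with module 1), 35.10 to 8.4 mg/g (malic acid,
#' falling: module 1 with negative slope), 0.05 to 2.45 ug/g
#' (beta-ionone, rising) and 0.1 to 6.1 ug/g (gamma-decalactone, on
#' module 2). Noise sds are a few percent of each trait's range, the
#' regime in which module-trait correlations at n = 9 reach the
#' published |r| ~ 0.95 magnitude.
#'
#' @return data.frame with columns `trait`, `module`, `slope`,
#'   `intercept`, `noise_sd`.
#' @export
default_trait_loadings <- function() {
  data.frame(
    trait = c("sucrose", "malic_acid", "beta_ionone", "gamma_decalactone"),
    module = c(1L, 1L, 1L, 2L),
    slope = c((124.35 - 3.04) / 3, -(35.10 - 8.4) / 3, 2.4 / 3, 6.0 / 3),
    intercept = c((124.35 + 3.04) / 2, (35.10 + 8.4) / 2,
                  (0.05 + 2.45) / 2, (0.1 + 6.1) / 2),
    noise_sd = c(5, 1.5, 0.1, 0.25),
    stringsAsFactors = FALSE
  )
}

# independent, reproducible substreams from one master seed
substream_seed <- function(seed, name) {
  offset <- c(truth = 101L, counts = 211L, traits = 307L, null = 401L)
  (abs(as.integer(seed)) %% 2000000L) * 1000L + offset[[name]]
}

#' Planted ground truth of a synthetic dataset
#'
#' Assigns the first `module_sizes[1]` genes to module 1, the next block
#' to module 2, and so on; remaining genes are background (label 0).
#' Builds one latent value per library and module: the module's
#' stage-profile value for the library's stage plus Normal replicate
#' jitter, then mean-centered across libraries. Also records, per trait,
#' the attenuation-corrected correlation the trait generator will aim
#' for: `slope * sd(latent) / sqrt(slope^2 var(latent) + noise_sd^2)`
#' with the slope's sign.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_truth` with `module_label_per_gene`
#'   (named integer vector), `latent_per_module` (libraries x modules
#'   matrix), `trait_true_correlation` (named numeric) and the design
#'   (`samples` data.frame).
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "truth"))

  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  labels <- rep(0L, config$n_genes)
  at <- 1L
  for (m in seq_along(config$module_sizes)) {
    labels[at:(at + config$module_sizes[m] - 1L)] <- m
    at <- at + config$module_sizes[m]
  }
  names(labels) <- gene_ids

  stage_names <- paste0("S", seq_len(config$n_stages))
  samples <- data.frame(
    library_id = paste0(rep(stage_names, each = config$n_reps), "_",
                        rep(LETTERS[seq_len(config$n_reps)],
                            config$n_stages)),
    stage = rep(stage_names, each = config$n_reps),
    replicate = rep(LETTERS[seq_len(config$n_reps)], config$n_stages),
    stringsAsFactors = FALSE)

  n_lib <- nrow(samples)
  latents <- sapply(seq_along(config$module_sizes), function(m) {
    v <- config$stage_profiles[[m]][match(samples$stage, stage_names)] +
      stats::rnorm(n_lib, 0, config$replicate_jitter_sd)
    v - mean(v)
  })
  latents <- matrix(latents, nrow = n_lib,
                    dimnames = list(samples$library_id,
                                    paste0("M", seq_along(config$module_sizes))))

  tl <- config$trait_loadings
  vlat <- apply(latents, 2, stats::var)[tl$module]
  rho <- sign(tl$slope) * sqrt(tl$slope^2 * vlat /
                                 (tl$slope^2 * vlat + tl$noise_sd^2))
  rho[tl$slope == 0] <- 0

  structure(list(module_label_per_gene = labels,
                 latent_per_module = latents,
                 trait_true_correlation = stats::setNames(rho, tl$trait),
                 samples = samples),
            class = "synthetic_truth")
}

#' Simulate a count matrix from planted ground truth
#'
#' For a gene in module m, the expected FPKM in library s is
#' `2^(baseline_g + latent_m(s))`; background genes use the baseline
#' alone. Counts are drawn negative-binomially with mean
#' `FPKM * length_bp * library_size / 1e9` and dispersion
#' `nb_dispersion` (Poisson at dispersion 0). Gene lengths, baselines
#' and library-size targets are drawn uniformly from their configured
#' ranges.
#'
#' @param truth from [make_ground_truth()].
#' @param config the same [synthetic_config()].
#' @return a [count_matrix()]; the drawn library-size targets are kept
#'   in `attr(, "target_library_sizes")` (realized totals are the
#'   column sums).
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "counts"))

  gene_ids <- names(truth$module_label_per_gene)
  n_gene <- length(gene_ids)
  n_lib <- nrow(truth$samples)

  lengths <- stats::setNames(
    round(stats::runif(n_gene, config$gene_length_range[1],
                       config$gene_length_range[2])), gene_ids)
  baseline <- stats::runif(n_gene, config$baseline_log2_fpkm_range[1],
                           config$baseline_log2_fpkm_range[2])
  lib_sizes <- round(stats::runif(n_lib, config$library_size_range[1],
                                  config$library_size_range[2]))

  offsets <- matrix(0, n_gene, n_lib)
  inmod <- truth$module_label_per_gene > 0
  offsets[inmod, ] <- truth$latent_per_module[, truth$module_label_per_gene[inmod],
                                              drop = FALSE] |> t()
  fpkm_mean <- 2^(baseline + offsets)
  mu <- fpkm_mean * lengths * rep(lib_sizes, each = n_gene) / 1e9

  counts <- if (config$nb_dispersion == 0) {
    stats::rpois(length(mu), lambda = mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  }
  counts <- matrix(as.integer(counts), n_gene, n_lib,
                   dimnames = list(gene_ids, truth$samples$library_id))
  cm <- count_matrix(counts, lengths, truth$samples)
  attr(cm, "target_library_sizes") <- stats::setNames(lib_sizes,
                                                      truth$samples$library_id)
  cm
}

#' Simulate metabolite trait vectors coupled to module latents
#'
#' Each trait is `intercept + slope * latent_module + N(0, noise_sd)`,
#' floored at 0 (concentrations are non-negative).
#'
#' @param truth from [make_ground_truth()].
#' @param config the same [synthetic_config()].
#' @return data.frame libraries x traits with library ids as rownames.
#' @export
simulate_traits <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, "traits"))
  tl <- config$trait_loadings
  n_lib <- nrow(truth$latent_per_module)
  vals <- sapply(seq_len(nrow(tl)), function(k) {
    lat <- truth$latent_per_module[, tl$module[k]]
    pmax(0, tl$intercept[k] + tl$slope[k] * lat +
           stats::rnorm(n_lib, 0, tl$noise_sd[k]))
  })
  traits <- as.data.frame(matrix(vals, nrow = n_lib))
  names(traits) <- tl$trait
  rownames(traits) <- rownames(truth$latent_per_module)
  traits
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: ground truth, counts and traits from one config.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with elements `counts`
#'   (a [count_matrix()]), `traits` and `truth`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  truth <- make_ground_truth(config)
  counts <- simulate_counts(truth, config)
  traits <- simulate_traits(truth, config)
  structure(list(counts = counts, traits = traits, truth = truth),
            class = "synthetic_dataset")
}

#' Simulate a null two-library pair with equal true expression
#'
#' Draws gene-level relative abundances once (gamma weights, shared by
#' both libraries) and then independent Poisson counts with totals close
#' to `N1` and `N2`. Because the true abundances are identical, every
#' positive test call is a false positive — the fixture for type-I-error
#' calibration of [ac_pvalue()].
#'
#' @param n_genes number of genes.
#' @param N1,N2 target library totals.
#' @param seed integer seed.
#' @return list with integer vectors `x`, `y` and the nominal totals
#'   `N1`, `N2`.
#' @export
simulate_null_pair <- function(n_genes, N1, N2, seed = 1) {
  if (N1 <= 0 || N2 <= 0) stop("N1 and N2 must be positive")
  set.seed(substream_seed(seed, "null"))
  w <- stats::rgamma(n_genes, shape = 1, rate = 1)
  p <- w / sum(w)
  list(x = stats::rpois(n_genes, p * N1),
       y = stats::rpois(n_genes, p * N2),
       N1 = N1, N2 = N2)
}
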