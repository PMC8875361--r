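#' Simulation configuration
#'
#' Bundles the generator parameters. Per-gene baseline means are drawn from a
#' log-normal law with median 200 (meanlog = log(200), sdlog = 1 by default);
#' counts are negative binomial with variance `mu + alpha * mu^2`; per-sample
#' library-size factors are drawn uniformly on \[0.7, 1.4\]. The seed fully
#' determines the output.
#'
#' @param n_genes Number of genes (positive integer).
#' @param n_replicates Biological replicates per (strain, condition) cell
#'   (default 3, the study design).
#' @param mean_meanlog,mean_sdlog Log-normal parameters of the per-gene
#'   baseline mean.
#' @param dispersion NB dispersion alpha, a single nonnegative value or one
#'   per gene; `0` gives Poisson counts.
#' @param sf_range Length-2 range of the uniform size-factor law.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes, n_replicates = 3L,
                       mean_meanlog = log(200), mean_sdlog = 1,
                       dispersion = 0.05, sf_range = c(0.7, 1.4),
                       seed = 1L) {
  stopifnot(length(n_genes) == 1L, n_genes >= 1, n_replicates >= 1,
            mean_sdlog >= 0, all(dispersion >= 0),
            length(sf_range) == 2L, all(sf_range > 0),
            sf_range[2] >= sf_range[1])
  if (n_genes != round(n_genes) || n_replicates != round(n_replicates))
    stop("n_genes and n_replicates must be integers")
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog,
                 dispersion = dispersion, sf_range = sf_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a mutant-panel count matrix with planted regulon structure
#'
#' Draws a gene-by-sample matrix of negative-binomial counts for every
#' combination of genotype, condition and replicate. The mean of gene i in
#' sample s is `mu_i * expression_multiplier(i, genotype_s, condition_s) *
#' sizefactor_s`, so the planted sigma-factor dependencies appear exactly in
#' the strains that lack the governing factor(s). Identical configuration and
#' truth give bit-identical output.
#'
#' @param config A [sim_config()].
#' @param genotypes Named list of genotypes (default [genotype_panel()]).
#' @param conditions Character vector of condition labels
#'   (default [study_conditions()]).
#' @param truth Planted effects, see [planted_effects()]; default none.
#' @return List with `counts` (integer matrix, genes x samples), `samples`
#'   (data frame: sample_id, strain, condition, replicate) and `truth`
#'   (list: `mu`, `alpha`, `size_factors`, `effects`).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, seed = 7))
#' dim(sim$counts)  # 50 x 45
#' @export
simulate_counts <- function(config,
                            genotypes = genotype_panel(),
                            conditions = study_conditions(),
                            truth = planted_effects(NULL)) {
  stopifnot(inherits(config, "sim_config"))
  truth <- planted_effects(truth)
  n_truth_genes <- length(unique(truth$gene_id))
  if (config$n_genes < n_truth_genes)
    stop("n_genes (", config$n_genes, ") smaller than number of distinct planted genes (",
         n_truth_genes, ")")
  if (is.null(names(genotypes)) || any(names(genotypes) == ""))
    stop("genotypes must be a named list")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
  # planted genes occupy the first rows so their ids are stable across runs
  if (n_truth_genes > 0L) {
    planted <- unique(truth$gene_id)
    gene_ids[seq_along(planted)] <- planted
  }
  mu <- stats::rlnorm(config$n_genes, meanlog = config$mean_meanlog,
                      sdlog = config$mean_sdlog)
  names(mu) <- gene_ids
  alpha <- rep_len(config$dispersion, config$n_genes)
  names(alpha) <- gene_ids

  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         condition = conditions,
                         strain = names(genotypes),
                         stringsAsFactors = FALSE)[, c("strain", "condition", "replicate")]
  samples$sample_id <- paste(samples$strain, samples$condition,
                             paste0("r", samples$replicate), sep = "_")
  samples <- samples[, c("sample_id", "strain", "condition", "replicate")]
  n_samp <- nrow(samples)
  sf <- stats::runif(n_samp, config$sf_range[1], config$sf_range[2])
  names(sf) <- samples$sample_id

  # multiplier matrix: genes x (genotype, condition) cells, applied per sample
  mult <- matrix(1, nrow = config$n_genes, ncol = n_samp,
                 dimnames = list(gene_ids, samples$sample_id))
  if (nrow(truth) > 0L) {
    for (k in seq_len(nrow(truth))) {
      g <- truth$gene_id[k]
      for (s in seq_len(n_samp)) {
        mult[g, s] <- expression_multiplier(g, samples$strain[s],
                                            samples$condition[s], truth)
      }
    }
  }

  mean_mat <- (mu * mult) * rep(sf, each = config$n_genes)
  counts <- matrix(0L, nrow = config$n_genes, ncol = n_samp,
                   dimnames = list(gene_ids, samples$sample_id))
  pois <- alpha == 0
  if (any(pois)) {
    counts[pois, ] <- stats::rpois(sum(pois) * n_samp, lambda = mean_mat[pois, ])
  }
  if (any(!pois)) {
    counts[!pois, ] <- stats::rnbinom(sum(!pois) * n_samp,
                                      mu = mean_mat[!pois, ],
                                      size = 1 / alpha[!pois])
  }
  storage.mode(counts) <- "integer"

  list(counts = counts, samples = samples,
       truth = list(mu = mu, alpha = alpha, size_factors = sf, effects = truth))
}

#' Default planted-truth panel for validation runs
#'
#' Plants `n_per_class` genes for each of the six recoverable classes
#' (SigB/SigD/SigCorE, each activated and repressed) in one condition, giving
#' a truth table whose recovery exercises every assignment rule.
#'
#' @param n_per_class Genes per class.
#' @param condition Condition carrying the effects (default "heat").
#' @param effect_log2 Planted log2 effect size (default 2, i.e. four-fold).
#' @return A [planted_effects()] data frame of `6 * n_per_class` rows.
#' @export
default_truth <- function(n_per_class = 100L, condition = "heat",
                          effect_log2 = 2) {
  classes <- expand.grid(sigma = c("B", "D", "CorE"),
                         direction = c("activated", "repressed"),
                         stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(classes)), function(k) {
    data.frame(
      gene_id = sprintf("planted_%s_%s_%03d", classes$sigma[k],
                        substr(classes$direction[k], 1, 3), seq_len(n_per_class)),
      sigma = classes$sigma[k], condition = condition,
      direction = classes$direction[k], effect_log2 = effect_log2,
      stringsAsFactors = FALSE)
  }))
  planted_effects(rows)
}
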