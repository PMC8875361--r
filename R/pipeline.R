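#' Read and validate a pipeline configuration
#'
#' A single YAML file drives the command-style entry points. Recognized
#' top-level keys: `paths` (counts, samples, exclusions, truth, out_dir),
#' `thresholds` (fdr_threshold, lfc_threshold), `simulation`
#' (n_genes, n_replicates, dispersion, mean_meanlog, mean_sdlog, sf_range,
#' effect_log2, n_per_class, planted_condition) and `seed`. All randomness
#' flows from the one seed.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg$thresholds <- utils::modifyList(
    list(fdr_threshold = 0.05, lfc_threshold = 1),
    as.list(cfg$thresholds))
  ft <- cfg$thresholds$fdr_threshold
  lt <- cfg$thresholds$lfc_threshold
  if (!is.numeric(ft) || ft <= 0 || ft >= 1) stop("fdr_threshold must be in (0,1)")
  if (!is.numeric(lt) || lt < 0) stop("lfc_threshold must be >= 0")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$paths <- as.list(cfg$paths)
  structure(cfg, class = "pipeline_config")
}

.log_msg <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  message(msg)
  if (!is.null(log_path)) cat(msg, "\n", file = log_path, append = TRUE)
}

#' Simulate a study-shaped dataset to disk
#'
#' Writes `counts.tsv`, `samples.tsv` and `truth.tsv` for a synthetic
#' five-strain, three-condition, three-replicate experiment with planted
#' regulon effects, plus a `run_log.txt` recording the seed and parameters.
#'
#' @param config A [pipeline_config()] (its `simulation` block and `seed`
#'   are used; outputs go to `paths$out_dir`).
#' @return Named character vector of the files written, invisibly.
#' @export
cmd_simulate <- function(config) {
  config <- pipeline_config(config)
  out_dir <- config$paths$out_dir
  if (is.null(out_dir)) stop("config paths$out_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  cat("", file = log_path)

  sim_block <- as.list(config$simulation)
  n_per_class <- if (is.null(sim_block$n_per_class)) 100L else sim_block$n_per_class
  effect_log2 <- if (is.null(sim_block$effect_log2)) 2 else sim_block$effect_log2
  planted_condition <- if (is.null(sim_block$planted_condition)) "heat" else
    sim_block$planted_condition
  cfg_args <- sim_block[intersect(names(sim_block),
                                  c("n_genes", "n_replicates", "mean_meanlog",
                                    "mean_sdlog", "dispersion", "sf_range"))]
  if (is.null(cfg_args$n_genes)) cfg_args$n_genes <- 3000L
  cfg_args$seed <- config$seed
  sc <- do.call(sim_config, cfg_args)

  truth <- if (n_per_class > 0) {
    default_truth(n_per_class, condition = planted_condition,
                  effect_log2 = effect_log2)
  } else planted_effects(NULL)
  sim <- simulate_counts(sc, truth = truth)

  files <- c(counts = file.path(out_dir, "counts.tsv"),
             samples = file.path(out_dir, "samples.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_counts(sim$counts, files["counts"])
  write_sample_table(sim$samples, files["samples"])
  write_truth(sim$truth$effects, files["truth"])
  .log_msg(log_path, "simulate: seed=", config$seed,
           " n_genes=", sc$n_genes, " n_replicates=", sc$n_replicates,
           " dispersion=", paste(unique(sc$dispersion), collapse = ","),
           " planted=", nrow(truth), " (", n_per_class, "/class in ",
           planted_condition, ", effect_log2=", effect_log2, ")")
  invisible(files)
}

#' Run the full analysis from files on disk
#'
#' Reads counts and the sample table named in the config, applies any
#' exclusion list, fits the regulon model and writes every product: one TSV
#' per contrast, per-condition status tables, the combined regulon
#' assignments, the cross-condition overlap report and per-condition
#' heat-map matrices of candidate genes. The run log records gene counts at
#' each filtering step.
#'
#' @param config A [pipeline_config()]; requires `paths$counts`,
#'   `paths$samples`, `paths$out_dir`.
#' @return The fitted `sigreg_fit`, invisibly.
#' @export
cmd_analyze <- function(config) {
  config <- pipeline_config(config)
  p <- config$paths
  for (key in c("counts", "samples", "out_dir")) {
    if (is.null(p[[key]])) stop("config paths$", key, " is required")
  }
  if (!file.exists(p$counts)) stop("counts file not found: ", p$counts)
  if (!file.exists(p$samples)) stop("samples file not found: ", p$samples)
  if (!dir.exists(p$out_dir)) dir.create(p$out_dir, recursive = TRUE)
  log_path <- file.path(p$out_dir, "run_log.txt")
  cat("", file = log_path)

  counts <- read_counts(p$counts)
  samples <- read_sample_table(p$samples, counts)
  .log_msg(log_path, "analyze: ", nrow(counts), " genes x ",
           ncol(counts), " samples read")
  exclusions <- NULL
  if (!is.null(p$exclusions) && file.exists(p$exclusions)) {
    exclusions <- utils::read.delim(p$exclusions, sep = "\t",
                                    stringsAsFactors = FALSE)
    .log_msg(log_path, "analyze: exclusion list with ",
             nrow(exclusions), " entries")
  }

  fit <- fit_sigma_regulons(counts, samples,
                            fdr_threshold = config$thresholds$fdr_threshold,
                            lfc_threshold = config$thresholds$lfc_threshold,
                            exclusions = exclusions,
                            sigma_genes = config$sigma_genes)
  .log_msg(log_path, "analyze: ", length(fit$dispersions),
           " genes after exclusions; ", length(fit$contrasts), " contrasts")

  write_contrasts(fit$contrasts, p$out_dir)
  for (cond in names(fit$status)) {
    for (strain in names(fit$status[[cond]])) {
      utils::write.table(fit$status[[cond]][[strain]],
                         file.path(p$out_dir, paste0("status_", strain, "_",
                                                     cond, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cand <- fit$assignments$gene_id[fit$assignments$condition == cond]
    .log_msg(log_path, "analyze: condition ", cond, ": ",
             length(cand), " candidate genes")
    strains <- names(fit$status[[cond]])
    tabs <- stats::setNames(
      lapply(strains, function(s) fit$contrasts[[paste0(s, "_vs_CS_", cond)]]),
      strains)
    write_heatmap_matrix(heatmap_matrix(tabs, cand),
                         file.path(p$out_dir, paste0("heatmap_", cond, ".tsv")))
  }
  utils::write.table(fit$assignments,
                     file.path(p$out_dir, "regulon_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fit$overlap)) {
    utils::write.table(fit$overlap,
                       file.path(p$out_dir, "regulon_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .log_msg(log_path, "analyze: ",
           sum(!is.na(fit$assignments$label) & fit$assignments$label != "none"),
           " genes assigned a label")
  invisible(fit)
}

#' Evaluate regulon recovery against a planted truth
#'
#' Compares pipeline assignments with the simulator's truth table. A planted
#' gene counts as recovered when it receives its planted label in its
#' planted condition with the planted direction (an "activated" target is
#' expected `down` — targets fall when the governing factor is deleted —
#' and a "repressed" target `up`). The false-assignment rate is the fraction
#' of unplanted genes that receive any regulon label (SigB, SigD, SigCorE or
#' shared) in that condition.
#'
#' @param truth Planted-effects data frame or TSV path from [cmd_simulate()].
#' @param assignments Assignment data frame (or `regulon_assignments.tsv`
#'   path) from [cmd_analyze()] / [fit_sigma_regulons()].
#' @param all_genes Character vector of all analyzed gene ids (needed for
#'   the false-assignment denominator); defaults to the union of truth and
#'   assignment genes.
#' @return Data frame of per-class sensitivity plus rows `overall`
#'   (sensitivity across classes) and `false_assignment`
#'   (`rate` = mislabeled unplanted fraction).
#' @export
cmd_evaluate <- function(truth, assignments, all_genes = NULL) {
  if (is.character(truth) && length(truth) == 1L) truth <- read_truth(truth)
  truth <- planted_effects(truth)
  if (is.character(assignments) && length(assignments) == 1L) {
    assignments <- utils::read.delim(assignments, sep = "\t",
                                     stringsAsFactors = FALSE)
  }
  known <- c("SigB", "SigD", "SigCorE", "shared", "none")
  bad <- setdiff(stats::na.omit(unique(assignments$label)), known)
  if (length(bad))
    stop("unknown label(s) in assignments: ", paste(bad, collapse = ", "))

  truth$expected_label <- c(B = "SigB", D = "SigD", CorE = "SigCorE")[truth$sigma]
  truth$expected_direction <- c(activated = "down", repressed = "up")[truth$direction]

  key <- function(g, cond) paste(g, cond, sep = "\r")
  asg_key <- key(assignments$gene_id, assignments$condition)
  idx <- match(key(truth$gene_id, truth$condition), asg_key)
  got_label <- assignments$label[idx]
  got_dir <- assignments$direction[idx]
  hit <- !is.na(got_label) & got_label == truth$expected_label &
    got_dir == truth$expected_direction

  cls <- paste(truth$expected_label, truth$expected_direction, sep = "_")
  per_class <- do.call(rbind, lapply(split(hit, cls), function(h) {
    data.frame(n_planted = length(h), n_recovered = sum(h),
               rate = sum(h) / length(h))
  }))
  per_class <- data.frame(class = rownames(per_class), per_class,
                          row.names = NULL, stringsAsFactors = FALSE)

  if (is.null(all_genes))
    all_genes <- union(truth$gene_id, assignments$gene_id)
  unplanted <- setdiff(all_genes, truth$gene_id)
  labeled <- assignments$gene_id[!is.na(assignments$label) &
                                   assignments$label != "none"]
  n_false <- length(intersect(unplanted, labeled))
  rbind(per_class,
        data.frame(class = "overall", n_planted = length(hit),
                   n_recovered = sum(hit), rate = mean(hit)),
        data.frame(class = "false_assignment", n_planted = length(unplanted),
                   n_recovered = n_false,
                   rate = if (length(unplanted)) n_false / length(unplanted) else 0))
}
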