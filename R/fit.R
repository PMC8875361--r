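#' Fit the sigma-factor regulon model to a mutant-panel count matrix
#'
#' The package's central fitting function. Runs the complete analysis on a
#' gene-by-sample count matrix from the five-strain panel (CS control plus
#' dsigB, dsigD, dsigBCE, dsigCDE): median-of-ratios normalization,
#' method-of-moments dispersion, per-condition negative-binomial Wald
#' contrasts of every mutant against CS, three-level status calls, the
#' combinatorial regulon-assignment rules, the control strain's own
#' stress-response annotation, and (with two or more conditions) the
#' cross-condition regulon comparison.
#'
#' @param counts Nonnegative integer matrix, genes x samples.
#' @param samples Design data frame: `sample_id`, `strain`, `condition`,
#'   `replicate`. Strain labels must include `CS`; mutants follow the
#'   panel naming of [genotype_panel()].
#' @param fdr_threshold FDR significance threshold (default 0.05).
#' @param lfc_threshold Two-fold gate in log2 units (default 1).
#' @param exclusions Optional gene ids removed before the analysis
#'   (e.g. rRNA operons), see [apply_exclusions()].
#' @param sigma_genes Optional named vector mapping sigma-factor letters to
#'   locus tags, see [sigma_gene_masks()]; each strain's deleted factors are
#'   masked from its status calls.
#' @return Object of class `sigreg_fit`: a list with components `contrasts`
#'   (all Wald tables), `status` (per condition, per strain), `assignments`
#'   (combined data frame: gene_id, condition, label, direction,
#'   cs_response), `overlap` (cross-condition comparison or NULL),
#'   `size_factors`, `dispersions`, `thresholds`, `samples`.
#' @seealso [summary.sigreg_fit()], [coef.sigreg_fit()], [plot.sigreg_fit()]
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 60, seed = 3),
#'                        truth = default_truth(2, effect_log2 = 3))
#' fit <- fit_sigma_regulons(sim$counts, sim$samples)
#' summary(fit)
#' @export
fit_sigma_regulons <- function(counts, samples, fdr_threshold = 0.05,
                               lfc_threshold = 1, exclusions = NULL,
                               sigma_genes = NULL) {
  if (!is.null(exclusions)) counts <- apply_exclusions(counts, exclusions)
  validate_design(counts, samples)
  contrasts <- run_all_contrasts(counts, samples)
  masks <- if (!is.null(sigma_genes)) sigma_gene_masks(sigma_genes) else NULL

  conditions <- unique(samples$condition)
  mutants <- intersect(.mutant_strains(), unique(samples$strain))
  status <- list()
  assignments <- list()
  for (cond in conditions) {
    st <- list()
    for (strain in mutants) {
      nm <- paste0(strain, "_vs_CS_", cond)
      st[[strain]] <- call_status(contrasts[[nm]], fdr_threshold,
                                  lfc_threshold,
                                  mask_genes = masks[[strain]])
    }
    status[[cond]] <- st
    asg <- assign_regulons(st, cond)
    cs_nm <- paste0("CS_", cond, "_vs_standard")
    if (cond != "standard" && cs_nm %in% names(contrasts)) {
      asg <- annotate_cs_response(asg, contrasts[[cs_nm]], fdr_threshold)
    } else {
      asg$cs_response <- rep("unknown", nrow(asg))
    }
    assignments[[cond]] <- asg
  }
  assignments <- do.call(rbind, assignments)
  rownames(assignments) <- NULL

  overlap <- NULL
  if (length(conditions) >= 2L && nrow(assignments) > 0L &&
      length(unique(assignments$condition)) >= 2L) {
    overlap <- compare_conditions(assignments)
  }

  structure(list(contrasts = contrasts, status = status,
                 assignments = assignments, overlap = overlap,
                 size_factors = attr(contrasts, "size_factors"),
                 dispersions = attr(contrasts, "dispersions"),
                 thresholds = c(fdr = fdr_threshold, lfc = lfc_threshold),
                 samples = samples),
            class = "sigreg_fit")
}

#' @export
print.sigreg_fit <- function(x, ...) {
  cat("Sigma-factor regulon fit\n")
  cat("  design: ", length(unique(x$samples$strain)), " strains x ",
      length(unique(x$samples$condition)), " conditions, ",
      nrow(x$samples), " samples, ",
      length(x$dispersions), " genes\n", sep = "")
  cat("  thresholds: FDR < ", x$thresholds["fdr"], ", |log2FC| >= ",
      x$thresholds["lfc"], "\n", sep = "")
  cat("  contrasts: ", length(x$contrasts), "\n", sep = "")
  asg <- x$assignments
  real <- asg[!is.na(asg$label) & asg$label != "none", , drop = FALSE]
  cat("  assigned genes (label != none): ", nrow(real), "\n", sep = "")
  invisible(x)
}

#' Summarize a sigma-factor regulon fit
#'
#' Tabulates regulon sizes per condition, label and direction.
#'
#' @param object A `sigreg_fit`.
#' @param ... Unused.
#' @return Data frame: `condition`, `label`, `direction`, `n_genes`
#'   (class `summary.sigreg_fit`).
#' @export
summary.sigreg_fit <- function(object, ...) {
  asg <- object$assignments
  asg <- asg[!is.na(asg$label), , drop = FALSE]
  if (nrow(asg) == 0L) {
    out <- data.frame(condition = character(), label = character(),
                      direction = character(), n_genes = integer())
  } else {
    tab <- stats::aggregate(list(n_genes = asg$gene_id),
                            by = list(condition = asg$condition,
                                      label = asg$label,
                                      direction = asg$direction),
                            FUN = length)
    out <- tab[order(tab$condition, tab$label, tab$direction), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("summary.sigreg_fit", "data.frame")
  out
}

#' @export
print.summary.sigreg_fit <- function(x, ...) {
  cat("Regulon sizes by condition:\n")
  print.data.frame(x)
  invisible(x)
}

#' Log2 fold-change coefficients of a regulon fit
#'
#' @param object A `sigreg_fit`.
#' @param ... Unused.
#' @return Numeric matrix, genes x contrasts, of Wald log2 fold changes.
#' @export
coef.sigreg_fit <- function(object, ...) {
  genes <- object$contrasts[[1]]$gene_id
  m <- vapply(object$contrasts, function(tab) tab$log2fc[match(genes, tab$gene_id)],
              numeric(length(genes)))
  matrix(m, nrow = length(genes),
         dimnames = list(genes, names(object$contrasts)))
}

#' Heat-map plot of regulon genes
#'
#' Draws a base-graphics log2 fold-change heat map (genes x mutant strains)
#' for one condition, restricted to assigned regulon genes by default.
#'
#' @param x A `sigreg_fit`.
#' @param condition Condition to plot (default: first with assignments).
#' @param genes Gene subset (default: genes with a label other than "none").
#' @param ... Passed to [graphics::image()].
#' @return The plotted matrix, invisibly.
#' @export
plot.sigreg_fit <- function(x, condition = NULL, genes = NULL, ...) {
  asg <- x$assignments
  if (is.null(condition)) {
    with_hits <- unique(asg$condition[!is.na(asg$label) & asg$label != "none"])
    condition <- if (length(with_hits)) with_hits[1] else unique(asg$condition)[1]
  }
  if (is.null(genes)) {
    genes <- asg$gene_id[asg$condition == condition &
                           !is.na(asg$label) & asg$label != "none"]
  }
  strains <- intersect(.mutant_strains(), unique(x$samples$strain))
  tabs <- stats::setNames(
    lapply(strains, function(s) x$contrasts[[paste0(s, "_vs_CS_", condition)]]),
    strains)
  m <- heatmap_matrix(tabs, genes)
  if (nrow(m) == 0L) {
    warning("no genes to plot for condition '", condition, "'")
    return(invisible(m))
  }
  lim <- max(abs(m), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(51)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = pal, zlim = c(-lim, lim), axes = FALSE,
                  xlab = "", ylab = "",
                  main = paste0("log2 fold change vs CS (", condition, ")"), ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.6)
  invisible(m)
}
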