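#' Call per-gene differential-expression status for one mutant strain
#'
#' Converts a contrast table into the three-level status used by the regulon
#' rules: `UP` when `fdr < fdr_threshold` and `log2fc > 0`, `DOWN` when
#' `fdr < fdr_threshold` and `log2fc < 0`, otherwise `NS`. `twofold` records
#' whether the call is also at least two-fold
#' (`|log2fc| >= lfc_threshold` and significant). Genes named in
#' `mask_genes` — the sigma-factor genes deleted in this strain — get a
#' masked (NA) status so they never enter the rules for that strain.
#'
#' @param result Contrast table from [nb_wald_test()] for one mutant strain
#'   vs CS in one condition.
#' @param fdr_threshold Significance threshold on FDR (default 0.05).
#' @param lfc_threshold Two-fold gate on |log2fc| (default 1).
#' @param mask_genes Gene ids to mask (deleted sigma factors).
#' @return Data frame: `gene_id`, `status` ("UP"/"DOWN"/"NS" or NA when
#'   masked), `twofold` (logical, NA when masked).
#' @export
call_status <- function(result, fdr_threshold = 0.05, lfc_threshold = 1,
                        mask_genes = NULL) {
  stopifnot(all(c("gene_id", "log2fc", "fdr") %in% names(result)))
  if (fdr_threshold <= 0 || fdr_threshold >= 1) stop("fdr_threshold must be in (0,1)")
  if (lfc_threshold < 0) stop("lfc_threshold must be >= 0")
  sig <- !is.na(result$fdr) & result$fdr < fdr_threshold
  status <- rep("NS", nrow(result))
  status[sig & result$log2fc > 0] <- "UP"
  status[sig & result$log2fc < 0] <- "DOWN"
  twofold <- status != "NS" & abs(result$log2fc) >= lfc_threshold
  if (!is.null(mask_genes)) {
    masked <- result$gene_id %in% mask_genes
    status[masked] <- NA_character_
    twofold[masked] <- NA
  }
  data.frame(gene_id = result$gene_id, status = status, twofold = twofold,
             stringsAsFactors = FALSE)
}

#' Genes eligible for regulon analysis
#'
#' The candidate gate: a gene enters regulon assignment when it shows a
#' significant at-least-two-fold change (`twofold = TRUE`) in at least one of
#' the four mutant strains. Inside the rules themselves, sub-two-fold but
#' significant calls still count.
#'
#' @param statuses Named list of [call_status()] tables, one per mutant
#'   strain (`dsigB`, `dsigD`, `dsigBCE`, `dsigCDE`).
#' @return Character vector of candidate gene ids (order of first table).
#' @export
candidate_genes <- function(statuses) {
  .check_status_set(statuses)
  if (nrow(statuses[[1]]) == 0L) return(character(0))
  hit <- Reduce(`|`, lapply(statuses, function(s)
    !is.na(s$twofold) & s$twofold))
  statuses[[1]]$gene_id[hit]
}

.check_status_set <- function(statuses) {
  need <- .mutant_strains()
  miss <- setdiff(need, names(statuses))
  if (length(miss))
    stop("missing status table(s) for strain(s): ", paste(miss, collapse = ", "))
  ids <- lapply(statuses[need], function(s) s$gene_id)
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    stop("status tables disagree on gene ids/order")
  invisible(TRUE)
}

#' Assign one gene's regulon label from its four-strain status pattern
#'
#' The combinatorial rules that define the regulons operationally:
#' \describe{
#'   \item{SigB}{down-regulated in both dsigB and dsigBCE with dsigD
#'     unchanged and dsigCDE unchanged or up-regulated (the mirrored pattern
#'     gives SigB/up, with down-regulation in dsigCDE allowed).}
#'   \item{SigD}{down-regulated in both dsigD and dsigCDE with dsigB
#'     unchanged and dsigBCE unchanged or up-regulated (mirrored for up).}
#'   \item{SigCorE}{same-direction significant change in both triple
#'     inactivation strains with both single mutants unchanged — the panel
#'     cannot separate SigC from SigE.}
#'   \item{shared}{any other pattern with at least two regulated strains
#'     (a reporting category, not a regulon).}
#'   \item{none}{everything else.}
#' }
#'
#' @param status_B,status_D,status_BCE,status_CDE Status in dsigB, dsigD,
#'   dsigBCE, dsigCDE: each "UP", "DOWN", "NS", or NA when masked.
#' @return List with `label` (one of SigB/SigD/SigCorE/shared/none, or NA
#'   when unclassifiable), `direction` ("up"/"down"/"mixed"/"na"), and
#'   `unclassifiable` (TRUE when a masked status blocks the rules).
#' @examples
#' assign_regulon("DOWN", "NS", "DOWN", "NS")$label   # "SigB"
#' assign_regulon("NS", "DOWN", "UP", "DOWN")$label   # "SigD"
#' @export
assign_regulon <- function(status_B, status_D, status_BCE, status_CDE) {
  s <- c(status_B, status_D, status_BCE, status_CDE)
  if (anyNA(s)) {
    return(list(label = NA_character_, direction = NA_character_,
                unclassifiable = TRUE))
  }
  if (!all(s %in% c("UP", "DOWN", "NS")))
    stop("statuses must be UP, DOWN or NS (or NA when masked)")
  lab <- .regulon_label(s[1], s[2], s[3], s[4])
  list(label = lab$label, direction = lab$direction, unclassifiable = FALSE)
}

.regulon_label <- function(b, d, bce, cde) {
  if (b == "DOWN" && bce == "DOWN" && d == "NS" && cde %in% c("NS", "UP"))
    return(list(label = "SigB", direction = "down"))
  if (b == "UP" && bce == "UP" && d == "NS" && cde %in% c("NS", "DOWN"))
    return(list(label = "SigB", direction = "up"))
  if (d == "DOWN" && cde == "DOWN" && b == "NS" && bce %in% c("NS", "UP"))
    return(list(label = "SigD", direction = "down"))
  if (d == "UP" && cde == "UP" && b == "NS" && bce %in% c("NS", "DOWN"))
    return(list(label = "SigD", direction = "up"))
  if (bce == "DOWN" && cde == "DOWN" && b == "NS" && d == "NS")
    return(list(label = "SigCorE", direction = "down"))
  if (bce == "UP" && cde == "UP" && b == "NS" && d == "NS")
    return(list(label = "SigCorE", direction = "up"))
  reg <- c(b, d, bce, cde)
  reg <- reg[reg != "NS"]
  if (length(reg) >= 2L) {
    dir <- if (all(reg == "UP")) "up" else if (all(reg == "DOWN")) "down" else "mixed"
    return(list(label = "shared", direction = dir))
  }
  list(label = "none", direction = "na")
}

#' Assign regulon labels to every candidate gene in one condition
#'
#' Applies the candidate gate and [assign_regulon()] across a set of status
#' tables for the four mutant strains.
#'
#' @param statuses Named list of [call_status()] tables for `dsigB`,
#'   `dsigD`, `dsigBCE`, `dsigCDE`.
#' @param condition Condition label recorded in the output.
#' @return Data frame: `gene_id`, `condition`, `label`, `direction`,
#'   `unclassifiable` — one row per candidate gene.
#' @export
assign_regulons <- function(statuses, condition) {
  .check_status_set(statuses)
  cand <- candidate_genes(statuses)
  if (length(cand) == 0L) {
    return(data.frame(gene_id = character(), condition = character(),
                      label = character(), direction = character(),
                      unclassifiable = logical(), stringsAsFactors = FALSE))
  }
  idx <- match(cand, statuses[["dsigB"]]$gene_id)
  res <- lapply(idx, function(i) {
    assign_regulon(statuses[["dsigB"]]$status[i], statuses[["dsigD"]]$status[i],
                   statuses[["dsigBCE"]]$status[i], statuses[["dsigCDE"]]$status[i])
  })
  data.frame(gene_id = cand, condition = condition,
             label = vapply(res, function(r) r$label, character(1)),
             direction = vapply(res, function(r) r$direction, character(1)),
             unclassifiable = vapply(res, function(r) r$unclassifiable, logical(1)),
             stringsAsFactors = FALSE)
}

#' Compare regulon membership across conditions
#'
#' For every regulon label, reports which conditions each member gene was
#' assigned in, making intersections and set differences directly readable
#' (a gene with `conditions = "heat,highlight"` belongs to the regulon under
#' both treatments).
#'
#' @param assignments Either one combined assignment data frame (with a
#'   `condition` column) or a list of per-condition frames from
#'   [assign_regulons()].
#' @return Data frame: `label`, `gene_id`, `conditions` (comma-joined sorted
#'   labels), `n_conditions`.
#' @export
compare_conditions <- function(assignments) {
  if (is.data.frame(assignments)) {
    comb <- assignments
  } else {
    comb <- do.call(rbind, assignments)
  }
  if (length(unique(comb$condition)) < 2L)
    stop("need assignments for at least two conditions")
  comb <- comb[!is.na(comb$label) & !comb$label %in% c("none"), , drop = FALSE]
  if (nrow(comb) == 0L) {
    return(data.frame(label = character(), gene_id = character(),
                      conditions = character(), n_conditions = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- split(comb$condition, paste(comb$label, comb$gene_id, sep = "\r"))
  parts <- strsplit(names(key), "\r", fixed = TRUE)
  out <- data.frame(
    label = vapply(parts, `[`, character(1), 1L),
    gene_id = vapply(parts, `[`, character(1), 2L),
    conditions = vapply(key, function(x) paste(sort(unique(x)), collapse = ","),
                        character(1)),
    n_conditions = vapply(key, function(x) length(unique(x)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$label, -out$n_conditions, out$gene_id), , drop = FALSE]
}

#' Annotate regulon genes with the control strain's own stress response
#'
#' Adds `cs_response`: how each regulon gene behaved when the control strain
#' under stress was compared with the control strain under standard growth —
#' `up`/`down` by the same FDR-and-sign rule as [call_status()] but with no
#' fold-change gate, `ns` otherwise, `unknown` when the CS table is missing.
#'
#' @param assignments Assignment data frame for one condition.
#' @param cs_stress_result CS stress-vs-standard contrast table for that
#'   condition, or `NULL`.
#' @param fdr_threshold Significance threshold (default 0.05).
#' @return `assignments` with a `cs_response` column appended.
#' @export
annotate_cs_response <- function(assignments, cs_stress_result,
                                 fdr_threshold = 0.05) {
  if (is.null(cs_stress_result)) {
    warning("CS stress-vs-standard table missing; cs_response set to 'unknown'")
    assignments$cs_response <- rep("unknown", nrow(assignments))
    return(assignments)
  }
  idx <- match(assignments$gene_id, cs_stress_result$gene_id)
  fdr <- cs_stress_result$fdr[idx]
  lfc <- cs_stress_result$log2fc[idx]
  resp <- rep("ns", nrow(assignments))
  sig <- !is.na(fdr) & fdr < fdr_threshold
  resp[sig & lfc > 0] <- "up"
  resp[sig & lfc < 0] <- "down"
  resp[is.na(idx)] <- "unknown"
  assignments$cs_response <- resp
  assignments
}

#' Log2 fold-change matrix for heat-map export
#'
#' Assembles a genes x strains matrix of log2 fold changes from the four
#' mutant-vs-CS tables of one condition, in the given gene order. Masked or
#' missing entries are NA and are written literally as "NA" by
#' [write_heatmap_matrix()].
#'
#' @param contrasts Named list of contrast tables (names = strain labels).
#' @param genes Gene subset, a subset of the tables' genes.
#' @param mask Optional named list: strain -> gene ids to blank out.
#' @return Numeric matrix, `length(genes)` x `length(contrasts)`.
#' @export
heatmap_matrix <- function(contrasts, genes, mask = NULL) {
  if (length(genes) == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = length(contrasts),
                  dimnames = list(NULL, names(contrasts))))
  all_genes <- unique(unlist(lapply(contrasts, function(x) x$gene_id)))
  unknown <- setdiff(genes, all_genes)
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  m <- vapply(contrasts, function(tab) tab$log2fc[match(genes, tab$gene_id)],
              numeric(length(genes)))
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, names(contrasts)))
  if (!is.null(mask)) {
    for (strain in intersect(names(mask), colnames(m))) {
      m[rownames(m) %in% mask[[strain]], strain] <- NA_real_
    }
  }
  m
}

#' @rdname heatmap_matrix
#' @param m Matrix from [heatmap_matrix()].
#' @param path Output TSV path.
#' @export
write_heatmap_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Sigma-factor gene masking per deletion strain
#'
#' Given the locus tags of the four group 2 sigma-factor genes, returns for
#' each mutant strain the genes deleted in it — these are masked from its
#' status calls because a deleted gene's "expression change" is a genotype
#' artifact, not regulation.
#'
#' @param sigma_genes Named character vector/list mapping factor letters
#'   ("B","C","D","E") to gene ids, e.g.
#'   `c(B = "sll0306", C = "sll0184", D = "sll2012", E = "sll1689")`.
#' @return Named list: strain -> gene ids to mask.
#' @export
sigma_gene_masks <- function(sigma_genes) {
  sigma_genes <- unlist(sigma_genes)
  panel <- genotype_panel()
  masks <- lapply(panel, function(funct) {
    deleted <- setdiff(c("B", "C", "D", "E"), funct)
    unname(sigma_genes[intersect(deleted, names(sigma_genes))])
  })
  masks[.mutant_strains()]
}
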