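#' Canonical strain panel of the sigma-factor study
#'
#' The five genotypes of the *Synechocystis* sp. PCC 6803 group 2 sigma-factor
#' deletion panel: the glucose-tolerant control strain (CS) carrying all four
#' group 2 factors, the single mutants dsigB and dsigD, and the two triple
#' inactivation strains dsigBCE (SigD is the only functional group 2 factor)
#' and dsigCDE (SigB is the only functional group 2 factor).
#'
#' @return Named list mapping strain label to the character vector of its
#'   functional group 2 sigma factors (subset of `c("B","C","D","E")`).
#' @examples
#' genotype_panel()$dsigBCE  # "D"
#' @export
genotype_panel <- function() {
  list(
    CS      = c("B", "C", "D", "E"),
    dsigB   = c("C", "D", "E"),
    dsigD   = c("B", "C", "E"),
    dsigBCE = c("D"),
    dsigCDE = c("B")
  )
}

#' Growth conditions of the study design
#'
#' Labels for the three transcriptome conditions: standard growth, 1 h at
#' 42 degrees C ("heat"), and 1 h at PPFD 750 umol photons m-2 s-1
#' ("highlight"). The physical metadata are descriptive only and never enter
#' any computation.
#'
#' @return Character vector of the three condition labels.
#' @export
study_conditions <- function() c("standard", "heat", "highlight")

.stress_conditions <- function() c("heat", "highlight")

.mutant_strains <- function() c("dsigB", "dsigD", "dsigBCE", "dsigCDE")

#' Expression multiplier implied by a planted regulon effect
#'
#' Encodes the sigma-factor dependency model used by the count simulator.
#' A planted effect for sigma "B" (resp. "D") applies in a genotype lacking
#' factor B (resp. D); an effect for "CorE" applies only when the genotype
#' lacks *both* C and E, because the strain panel cannot separate the SigC
#' and SigE regulons. When an effect applies, an "activated" target's mean
#' is multiplied by `2^-effect_log2` (the factor normally activates the
#' gene, so its targets drop when it is missing) and a "repressed" target's
#' mean by `2^+effect_log2`.
#'
#' @param gene_id Gene label.
#' @param genotype Strain label, a name of [genotype_panel()], or a character
#'   vector of functional sigma factors.
#' @param condition Condition label.
#' @param truth Data frame of planted effects as returned by
#'   [planted_effects()] (columns `gene_id`, `sigma`, `condition`,
#'   `direction`, `effect_log2`).
#' @return A single positive multiplier; 1.0 when no effect matches.
#' @examples
#' tr <- planted_effects(data.frame(gene_id = "g1", sigma = "B",
#'   condition = "heat", direction = "activated", effect_log2 = 2))
#' expression_multiplier("g1", "dsigB", "heat", tr)    # 0.25
#' expression_multiplier("g1", "dsigCDE", "heat", tr)  # 1 (retains SigB)
#' @export
expression_multiplier <- function(gene_id, genotype, condition, truth) {
  sig <- .functional_sigmas(genotype)
  hit <- truth[truth$gene_id == gene_id & truth$condition == condition, , drop = FALSE]
  if (nrow(hit) == 0L) return(1.0)
  if (nrow(hit) > 1L) {
    stop("conflicting duplicate effects for gene '", gene_id,
         "' in condition '", condition, "'")
  }
  applies <- switch(hit$sigma,
    B    = !("B" %in% sig),
    D    = !("D" %in% sig),
    CorE = !("C" %in% sig) && !("E" %in% sig),
    stop("unknown sigma label '", hit$sigma, "'")
  )
  if (!applies) return(1.0)
  if (hit$direction == "activated") 2^(-hit$effect_log2) else 2^(hit$effect_log2)
}

.functional_sigmas <- function(genotype) {
  if (length(genotype) == 1L && genotype %in% names(genotype_panel())) {
    return(genotype_panel()[[genotype]])
  }
  if (all(genotype %in% c("B", "C", "D", "E")) && length(genotype) >= 1L) {
    return(genotype)
  }
  stop("unknown genotype label: ", paste(genotype, collapse = ","))
}

#' Validate a table of planted regulon effects
#'
#' Checks and returns the truth table the simulator plants into its counts.
#' Each row declares that one gene, in one condition, depends on one sigma
#' factor (or the indistinguishable C/E pair) with a positive log2 effect
#' size and a direction: "activated" targets decrease when the factor is
#' missing, "repressed" targets increase.
#'
#' @param effects Data frame with columns `gene_id`, `sigma` (one of
#'   "B", "D", "CorE"), `condition`, `direction` ("activated"/"repressed"),
#'   `effect_log2` (positive).
#' @return The validated data frame (character columns, numeric effect).
#' @export
planted_effects <- function(effects) {
  if (is.null(effects) || nrow(effects) == 0L) {
    return(data.frame(gene_id = character(), sigma = character(),
                      condition = character(), direction = character(),
                      effect_log2 = numeric(), stringsAsFactors = FALSE))
  }
  need <- c("gene_id", "sigma", "condition", "direction", "effect_log2")
  miss <- setdiff(need, names(effects))
  if (length(miss)) stop("planted effects lack columns: ", paste(miss, collapse = ", "))
  effects <- effects[, need]
  for (col in need[1:4]) effects[[col]] <- as.character(effects[[col]])
  effects$effect_log2 <- as.numeric(effects$effect_log2)
  if (any(!effects$sigma %in% c("B", "D", "CorE")))
    stop("sigma must be one of B, D, CorE")
  if (any(!effects$direction %in% c("activated", "repressed")))
    stop("direction must be 'activated' or 'repressed'")
  if (any(!is.finite(effects$effect_log2)) || any(effects$effect_log2 <= 0))
    stop("effect_log2 must be strictly positive")
  key <- paste(effects$gene_id, effects$condition)
  if (anyDuplicated(key))
    stop("a gene may carry at most one effect per condition; duplicated: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  effects
}
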