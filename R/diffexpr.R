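#' Median-of-ratios size factors
#'
#' Library-size normalization in the style standard for count-based RNA-seq:
#' the reference profile is the per-gene geometric mean across samples,
#' restricted to genes with no zero count; each sample's size factor is the
#' median of its ratios to that reference.
#'
#' @param counts Nonnegative integer matrix, genes x samples.
#' @return Named numeric vector of positive per-sample size factors.
#' @examples
#' m <- rbind(g1 = c(a = 100L, b = 200L), g2 = c(a = 50L, b = 100L))
#' size_factors(m)  # ~0.7071, ~1.4142
#' @export
size_factors <- function(counts) {
  .check_counts(counts)
  ref <- rowSums(counts == 0L) == 0L
  if (!any(ref))
    stop("no gene is zero-free across all samples; cannot form the ",
         "median-of-ratios reference (pseudo-reference fallback is disabled)")
  sub <- counts[ref, , drop = FALSE]
  geomean <- exp(rowMeans(log(sub)))
  sf <- apply(sub / geomean, 2, stats::median)
  names(sf) <- colnames(counts)
  sf
}

#' Method-of-moments dispersion estimates
#'
#' Per-gene NB dispersion alpha (variance `mu + alpha * mu^2`) estimated on
#' size-factor-normalized counts, pooling the within-group variance across
#' all (strain, condition) replicate groups:
#' `alpha = max(alpha_floor, (pooled_var - pooled_mean) / pooled_mean^2)`.
#' Counts at or below the Poisson limit hit the floor.
#'
#' @param counts Count matrix.
#' @param samples Design data frame (`sample_id`, `strain`, `condition`).
#' @param sf Size factors; computed from `counts` when `NULL`.
#' @param alpha_floor Lower bound on alpha (default 1e-8, numerical
#'   stability at the Poisson limit).
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, samples, sf = NULL,
                                alpha_floor = 1e-8) {
  validate_design(counts, samples)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts[, samples$sample_id, drop = FALSE], 2,
                sf[samples$sample_id], "/")
  grp <- paste(samples$strain, samples$condition, sep = ":")
  sizes <- table(grp)
  if (any(sizes < 2L))
    stop("group(s) with < 2 replicates: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  ss <- numeric(nrow(norm))
  df <- 0L
  for (g in unique(grp)) {
    cols <- which(grp == g)
    x <- norm[, cols, drop = FALSE]
    ss <- ss + rowSums((x - rowMeans(x))^2)
    df <- df + length(cols) - 1L
  }
  v <- ss / df
  m <- rowMeans(norm)
  alpha <- ifelse(m > 0, (v - m) / m^2, 0)
  alpha <- pmax(alpha_floor, alpha)
  names(alpha) <- rownames(counts)
  alpha
}

# Maximum-likelihood fit of one NB group mean on the log scale, vectorized
# over genes. Each row of y shares beta: y_ij ~ NB(mu = sf_j * exp(beta_i),
# size = 1/alpha_i). Rows whose counts are all zero are held at the
# continuity value beta = log(0.5 / sum(sf)). Returns beta, observed
# information at the optimum, and the all-zero indicator.
.nb_group_fit <- function(y, sf, alpha, max_iter = 100L, tol = 1e-10) {
  tot <- rowSums(y)
  zero <- tot == 0
  beta <- log(pmax(tot, 0.5) / sum(sf))
  active <- which(!zero)
  for (iter in seq_len(max_iter)) {
    if (length(active) == 0L) break
    mu <- exp(beta[active]) %o% sf
    amu <- 1 + alpha[active] * mu
    u <- rowSums((y[active, , drop = FALSE] - mu) / amu)
    info <- rowSums(mu / amu)
    delta <- pmin(pmax(u / info, -5), 5)
    beta[active] <- beta[active] + delta
    active <- active[abs(delta) >= tol]
  }
  mu <- exp(beta) %o% sf
  amu <- 1 + alpha * mu
  obs_info <- rowSums(mu * (1 + alpha * y) / amu^2)
  list(beta = beta, obs_info = obs_info, zero = zero)
}

#' Two-group negative-binomial Wald test
#'
#' Fits, per gene, a two-group NB model with known dispersion and sample
#' offsets `log(sf)`; the reported `log2fc` is the estimated test-over-
#' reference log2 ratio, its standard error comes from the observed
#' information of the fit, and `p` is the two-sided normal tail of
#' `wald = log2fc / se`. No fold-change shrinkage is applied.
#'
#' Genes with all-zero counts in both groups are flagged `"untestable"`
#' (`log2fc = 0`, `p = 1`) and excluded from FDR adjustment. A gene with all
#' zeros in exactly one group is flagged `"zero_group"`: the empty group's
#' count total is replaced by 0.5 (continuity correction) and the fold
#' change is capped at +/-10 log2 units.
#'
#' @param counts Count matrix (columns = samples of the two groups).
#' @param group Factor over the columns with exactly two levels, reference
#'   level first.
#' @param sf Size factors for these columns.
#' @param dispersions Per-gene alpha (named or in row order).
#' @param contrast_name Label stored in the result's `contrast` attribute.
#' @return Data frame (one row per gene): `gene_id`, `base_mean`, `log2fc`,
#'   `se`, `wald`, `p`, `fdr`, `flag`.
#' @export
nb_wald_test <- function(counts, group, sf, dispersions,
                         contrast_name = NULL) {
  .check_counts(counts)
  group <- as.factor(group)
  if (nlevels(group) != 2L || length(group) != ncol(counts))
    stop("group must be a two-level factor over the columns of counts")
  if (min(table(group)) < 2L)
    stop("each contrast group needs >= 2 replicates")
  if (!is.null(names(dispersions))) dispersions <- dispersions[rownames(counts)]
  alpha <- pmax(as.numeric(dispersions), 1e-12)
  if (length(alpha) != nrow(counts)) stop("one dispersion per gene required")
  if (!is.null(names(sf))) sf <- sf[colnames(counts)]

  ref_cols <- group == levels(group)[1]
  fit_ref <- .nb_group_fit(counts[, ref_cols, drop = FALSE], sf[ref_cols], alpha)
  fit_tst <- .nb_group_fit(counts[, !ref_cols, drop = FALSE], sf[!ref_cols], alpha)

  ln2 <- log(2)
  log2fc <- (fit_tst$beta - fit_ref$beta) / ln2
  se <- sqrt(1 / fit_tst$obs_info + 1 / fit_ref$obs_info) / ln2

  flag <- rep("", nrow(counts))
  both_zero <- fit_tst$zero & fit_ref$zero
  one_zero <- xor(fit_tst$zero, fit_ref$zero)
  flag[one_zero] <- "zero_group"
  flag[both_zero] <- "untestable"
  log2fc[one_zero] <- pmin(pmax(log2fc[one_zero], -10), 10)

  wald <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(wald))
  log2fc[both_zero] <- 0
  se[both_zero] <- NA_real_
  wald[both_zero] <- NA_real_
  p[both_zero] <- 1

  base_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  fdr <- rep(NA_real_, nrow(counts))
  testable <- !both_zero
  if (any(testable)) fdr[testable] <- bh_adjust(p[testable])

  out <- data.frame(gene_id = rownames(counts), base_mean = base_mean,
                    log2fc = log2fc, se = se, wald = wald, p = p, fdr = fdr,
                    flag = flag, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast_name
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply by `m / rank`, take
#' the cumulative minimum from the largest rank down, cap at 1, and return
#' in the input order. Untestable genes must be excluded by the caller
#' before adjustment.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  adj[ro]
}

#' Run every contrast of the mutant-panel design
#'
#' For each condition, tests every mutant strain against the control strain
#' CS in the same condition; additionally, for every stress condition (any
#' condition other than `"standard"`) tests CS under stress against CS under
#' standard growth, which supports the control-strain stress-response
#' annotation of regulon genes. Size factors are computed once on the full
#' matrix and dispersions pooled across all replicate groups; FDR is
#' adjusted within each contrast table separately.
#'
#' @param counts Count matrix covering the full design.
#' @param samples Design data frame.
#' @param sf,dispersions Optional precomputed normalization/dispersion;
#'   derived from the data when `NULL`.
#' @return Named list of [nb_wald_test()] tables: `<strain>_vs_CS_<condition>`
#'   for every mutant, plus `CS_<condition>_vs_standard` for stress
#'   conditions. Attributes `size_factors` and `dispersions` carry the
#'   shared estimates.
#' @export
run_all_contrasts <- function(counts, samples, sf = NULL, dispersions = NULL) {
  validate_design(counts, samples)
  if (!"CS" %in% samples$strain) stop("design lacks the control strain CS")
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(counts, samples, sf)

  conditions <- unique(samples$condition)
  for (cond in conditions) {
    if (!any(samples$strain == "CS" & samples$condition == cond))
      stop("control strain CS missing in condition '", cond, "'")
  }

  one <- function(test_ids, ref_ids, name) {
    ids <- c(ref_ids, test_ids)
    grp <- factor(rep(c("ref", "test"), c(length(ref_ids), length(test_ids))),
                  levels = c("ref", "test"))
    nb_wald_test(counts[, ids, drop = FALSE], grp, sf[ids], dispersions,
                 contrast_name = name)
  }
  sample_ids <- function(strain, cond)
    samples$sample_id[samples$strain == strain & samples$condition == cond]

  out <- list()
  for (cond in conditions) {
    for (strain in setdiff(unique(samples$strain[samples$condition == cond]), "CS")) {
      nm <- paste0(strain, "_vs_CS_", cond)
      out[[nm]] <- one(sample_ids(strain, cond), sample_ids("CS", cond), nm)
    }
  }
  if ("standard" %in% conditions) {
    for (cond in setdiff(conditions, "standard")) {
      nm <- paste0("CS_", cond, "_vs_standard")
      out[[nm]] <- one(sample_ids("CS", cond), sample_ids("CS", "standard"), nm)
    }
  }
  attr(out, "size_factors") <- sf
  attr(out, "dispersions") <- dispersions
  out
}

#' Write contrast tables as TSV
#'
#' One file per contrast, named after the contrast (e.g.
#' `dsigB_vs_CS_heat.tsv`), columns `gene_id`, `base_mean`, `log2fc`, `se`,
#' `wald`, `p`, `fdr`, `flag`.
#'
#' @param contrasts Named list from [run_all_contrasts()].
#' @param dir Output directory (created if missing).
#' @return Paths written, invisibly.
#' @export
write_contrasts <- function(contrasts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(contrasts)) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(contrasts[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
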