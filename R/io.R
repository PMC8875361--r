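#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a tab-separated file whose header starts with `gene_id` followed by
#' sample ids, one row per gene. Values must be nonnegative integers; row and
#' column order are preserved from the file.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix with gene ids as rownames, sample ids as colnames.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(tab) < 2L) stop("count file needs a gene_id column plus >= 1 sample")
  gene_ids <- tab[[1]]
  sample_ids <- colnames(tab)[-1]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(tab[-1], as.numeric, numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(gene_ids, sample_ids))
  bad <- which(is.na(vals) | vals < 0 | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-integer or negative count at gene '", gene_ids[bad[1, 1]],
         "', sample '", sample_ids[bad[1, 2]], "' in ", path)
  }
  storage.mode(vals) <- "integer"
  vals
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_counts()]: tab separator, UTF-8, no quoting, header cell
#' fixed to `gene_id`. `write_counts(read_counts(f))` reproduces `f` modulo
#' line endings.
#'
#' @param counts Integer matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  .check_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_counts <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must be a matrix with gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  invisible(TRUE)
}

#' Read or write the sample design table
#'
#' The design TSV has columns `sample_id`, `strain`, `condition`, `replicate`.
#' [read_sample_table()] validates against a count matrix when one is given:
#' every sample column must appear exactly once and every (strain, condition)
#' cell needs at least two replicates for the differential-expression stage.
#'
#' @param path TSV path.
#' @param counts Optional count matrix to validate against.
#' @return Data frame with the four design columns.
#' @export
read_sample_table <- function(path, counts = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "strain", "condition", "replicate")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  tab <- tab[, need]
  tab$replicate <- as.integer(tab$replicate)
  if (!is.null(counts)) validate_design(counts, tab)
  tab
}

#' @rdname read_sample_table
#' @param samples Design data frame.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a count matrix against its design
#'
#' @param counts Count matrix.
#' @param samples Design data frame (`sample_id`, `strain`, `condition`,
#'   `replicate`).
#' @return `TRUE` invisibly; errors describe the violation.
#' @export
validate_design <- function(counts, samples) {
  .check_counts(counts)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in design")
  missing_s <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_s))
    stop("samples in counts but not in design: ", paste(missing_s, collapse = ", "))
  extra_s <- setdiff(samples$sample_id, colnames(counts))
  if (length(extra_s))
    stop("samples in design but not in counts: ", paste(extra_s, collapse = ", "))
  reps <- table(paste(samples$strain, samples$condition, sep = ":"))
  if (any(reps < 2L))
    stop("groups with < 2 replicates: ",
         paste(names(reps)[reps < 2L], collapse = ", "))
  invisible(TRUE)
}

#' Remove excluded genes from a count matrix
#'
#' Drops the listed genes (e.g. rRNA operons) before the analysis. Genes
#' absent from the matrix are counted and reported with a warning, never
#' fatal; the per-strain masking of deleted sigma-factor genes is applied at
#' the regulon stage instead. Idempotent.
#'
#' @param counts Count matrix.
#' @param exclude Character vector of gene ids to drop (or a data frame with
#'   a `gene_id` column, as read from an exclusion-list TSV).
#' @return The reduced count matrix; attribute `n_removed` records how many
#'   genes were dropped.
#' @export
apply_exclusions <- function(counts, exclude) {
  .check_counts(counts)
  if (is.data.frame(exclude)) exclude <- exclude$gene_id
  exclude <- unique(as.character(exclude))
  if (length(exclude) == 0L) {
    attr(counts, "n_removed") <- 0L
    return(counts)
  }
  present <- intersect(exclude, rownames(counts))
  absent <- setdiff(exclude, rownames(counts))
  if (length(absent))
    warning(length(absent), " excluded gene(s) not present in matrix: ",
            paste(utils::head(absent, 5), collapse = ", "))
  if (length(present) == nrow(counts))
    stop("exclusion list would remove all genes")
  out <- counts[setdiff(rownames(counts), present), , drop = FALSE]
  attr(out, "n_removed") <- length(present)
  out
}

#' Read or write a planted-truth table
#'
#' TSV with columns `gene_id`, `sigma`, `condition`, `direction`,
#' `effect_log2`, matching [planted_effects()].
#'
#' @param path TSV path.
#' @return Validated planted-effects data frame.
#' @export
read_truth <- function(path) {
  planted_effects(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname read_truth
#' @param truth Planted-effects data frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(planted_effects(truth), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
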