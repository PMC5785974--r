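#' Convert FPKM to TPM
#'
#' `TPM_i = FPKM_i / sum(FPKM) * 1e6`; the output always sums to one million.
#'
#' @param fpkm Non-negative numeric vector with positive sum.
#' @return TPM vector of the same length.
#' @examples
#' tpm_from_fpkm(c(1, 3, 6))
#' @export
tpm_from_fpkm <- function(fpkm) {
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  s <- sum(fpkm)
  if (s <= 0) stop("FPKM vector sums to zero; TPM undefined")
  fpkm / s * 1e6
}

#' Apply the per-cell RNA content correction
#'
#' Cells sorted into the low-mitochondria fraction contain less total RNA per
#' cell; their TPM values are multiplied by a correction factor (0.34 in the
#' reference protocol, as quantified by poly(A) RNA-FISH) so that abundances
#' are comparable per cell across conditions.
#'
#' @param tpm Numeric abundance vector.
#' @param factor Positive multiplicative factor (default 0.34).
#' @return Corrected vector with attribute `unit = "per-cell-corrected TPM"`.
#' @export
apply_percell_correction <- function(tpm, factor = 0.34) {
  if (factor <= 0) stop("correction factor must be positive")
  structure(tpm * factor, unit = "per-cell-corrected TPM")
}

#' Estimate the expression detection threshold
#'
#' Selects every gene with exactly one zero and one non-zero value across the
#' two conditions, collects the non-zero member of each such pair, and
#' returns the median of that collection (mid-point convention for even
#' counts).
#'
#' @param expr_low,expr_high Equal-length non-negative abundance vectors.
#' @return The detection threshold.
#' @examples
#' detection_threshold(c(0, 2, 1, 0), c(4, 0, 3, 0))  # selected {4, 2} -> 3
#' @export
detection_threshold <- function(expr_low, expr_high) {
  if (length(expr_low) != length(expr_high)) {
    stop("condition vectors must have equal length")
  }
  sel <- xor(expr_low == 0, expr_high == 0)
  if (!any(sel)) stop("no genes with one zero and one non-zero value; threshold undefined")
  nonzero <- pmax(expr_low, expr_high)[sel]
  median(nonzero)
}

#' Discard undetected genes and floor values at the detection threshold
#'
#' Genes whose expression is below the threshold in both conditions are
#' discarded; remaining values below the threshold are replaced by it.
#'
#' @param table Data frame with columns `gene_id`, `low`, `high`.
#' @param tau Positive detection threshold.
#' @return The filtered, floored table.
#' @export
floor_at_threshold <- function(table, tau) {
  stopifnot(all(c("gene_id", "low", "high") %in% names(table)), tau > 0)
  keep <- !(table$low < tau & table$high < tau)
  out <- table[keep, , drop = FALSE]
  out$low <- pmax(out$low, tau)
  out$high <- pmax(out$high, tau)
  rownames(out) <- NULL
  out
}

#' Per-gene fold change against the genome-wide band
#'
#' Computes `log2(high/low)` for each gene of interest together with the
#' genome-wide mean and standard deviation of the same quantity over all
#' retained genes, the reference band against which gene-set fold changes
#' are displayed. Inputs must already be corrected and floored, so no zero
#' division can occur.
#'
#' @param table Floored expression table (`gene_id`, `low`, `high`).
#' @param gene_set Character vector of gene ids to report individually.
#' @return List with `genes` (data frame `gene_id`, `log2_fc`),
#'   `genome_mean`, `genome_sd`, `n_genes`.
#' @export
foldchange_vs_genome <- function(table, gene_set) {
  stopifnot(all(c("gene_id", "low", "high") %in% names(table)))
  if (any(table$low <= 0)) stop("table must be floored (strictly positive)")
  lfc <- log2(table$high / table$low)
  idx <- match(gene_set, table$gene_id)
  if (anyNA(idx)) stop("gene_set members missing from table: ",
                       paste(gene_set[is.na(idx)], collapse = ", "))
  list(
    genes = data.frame(gene_id = gene_set, log2_fc = lfc[idx],
                       stringsAsFactors = FALSE),
    genome_mean = mean(lfc),
    genome_sd = sd(lfc),
    n_genes = nrow(table)
  )
}

#' Read / write two-condition expression tables as TSV
#'
#' Plain TSV with columns `gene_id`, `low`, `high`.
#'
#' @param path File path.
#' @return For `read_expression_tsv`, a data frame.
#' @export
read_expression_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_expression_tsv
#' @param table Expression data frame.
#' @export
write_expression_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
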