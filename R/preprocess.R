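#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the common distribution given by the
#' across-column mean of the order statistics. Ties are resolved by
#' averaging the averaged order statistics over tied ranks. Row and column
#' labels are unchanged; within-column rank order is preserved.
#'
#' @param matrix Numeric log2 expression matrix, probes x samples.
#' @return The normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(matrix) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 2L) {
    stop("quantile normalization needs at least 2 samples")
  }
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Empirical-Bayes batch-effect correction (ComBat)
#'
#' Removes additive and multiplicative per-batch effects from a log2
#' expression matrix while preserving biological group differences. Probes
#' are standardized with respect to mean expression and treatment effect,
#' per-batch location/scale parameters are shrunk by empirical Bayes
#' (nonparametric by default, as a kernel-weighted posterior; parametric
#' normal/inverse-gamma as a fast option), batch effects are subtracted and
#' divided out, and the data are back-transformed.
#'
#' A single batch is a no-op (the input is returned unchanged). Batches of
#' size one and batch labels perfectly confounded with the biological groups
#' make the effects unidentifiable and raise an error.
#'
#' @param matrix Numeric log2 expression matrix.
#' @param design Sample design data.frame covering the matrix columns; the
#'   \code{batch} column defines batches and the biological group is the
#'   interaction of role, compound and concentration (preserved as treatment
#'   effect).
#' @param mode \code{"nonparametric"} (default) or \code{"parametric"}.
#' @return Corrected matrix, same dimnames.
#' @export
combat_correct <- function(matrix, design, mode = c("nonparametric", "parametric")) {
  mode <- match.arg(mode)
  validate_expression_matrix(matrix)
  design <- validate_sample_design(design, matrix)
  design <- design[match(colnames(matrix), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) {
    stop("design must cover every sample column of the matrix")
  }
  batch <- factor(design$batch)
  if (nlevels(batch) < 2L) {
    message("combat_correct: single batch, nothing to correct")
    return(matrix)
  }
  if (any(table(batch) < 2L)) stop("every batch needs at least 2 samples")
  group <- interaction(design$role,
                       ifelse(is.na(design$compound), "", design$compound),
                       ifelse(is.na(design$concentration), "", design$concentration),
                       drop = TRUE)
  mod <- NULL
  if (nlevels(group) > 1L) {
    mod <- stats::model.matrix(~group)
    full <- cbind(stats::model.matrix(~batch), mod[, -1L, drop = FALSE])
    if (qr(full)$rank < ncol(full)) {
      stop("batch is confounded with the biological groups; effects are unidentifiable")
    }
  }
  # probes without residual variance cannot be standardized; pass through
  resid_sd <- .residual_sd(matrix, batch, group)
  fixed <- resid_sd <= .Machine$double.eps^0.5
  if (any(fixed)) {
    warning(sum(fixed), " probe(s) with zero residual variance passed through uncorrected")
  }
  work <- matrix[!fixed, , drop = FALSE]
  corrected <- suppressMessages(
    sva::ComBat(dat = work, batch = batch, mod = mod,
                par.prior = (mode == "parametric"))
  )
  out <- matrix
  out[!fixed, ] <- corrected
  out
}

.residual_sd <- function(matrix, batch, group) {
  cells <- interaction(batch, group, drop = TRUE)
  centered <- matrix
  for (lv in levels(cells)) {
    idx <- cells == lv
    centered[, idx] <- matrix[, idx, drop = FALSE] - rowMeans(matrix[, idx, drop = FALSE])
  }
  apply(centered, 1L, stats::sd)
}
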