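#' Gene weight: log2 fold-change scaled by log1.1 intensity
#'
#' The elementary DDPP quantity for one gene in one patient: the log2
#' fold-change of tumor over patient-matched normal tissue, multiplied by the
#' logarithm to base 1.1 of the expression intensity in a designated tissue.
#' The intensity factor up-weights fold-changes seen at high absolute
#' expression.
#'
#' @param t tumor intensity (linear scale, > 0).
#' @param n normal-tissue intensity (linear scale, > 0).
#' @param i intensity used for the log1.1 factor (tumor or normal, > 0;
#'   values > 1 give a positive factor). Vectors are recycled elementwise.
#' @return numeric vector of weights, \code{log2(t/n) * log(i, base = 1.1)}.
#' @examples
#' gene_weight(8, 2, 1.1)    # 2 * 1 = 2
#' gene_weight(2, 8, 1.1^3)  # -2 * 3 = -6
#' @export
gene_weight <- function(t, n, i) {
  if (!is.numeric(t) || !is.numeric(n) || !is.numeric(i))
    stop("intensities must be numeric")
  if (any(t <= 0) || any(n <= 0) || any(i <= 0))
    stop("intensities must be strictly positive")
  log2(t / n) * log(i, base = 1.1)
}

#' Per-gene weight matrix for a paired cohort
#'
#' Applies [gene_weight()] to every gene x patient cell of a paired
#' expression object, with the log1.1 intensity taken from either the tumor
#' or the normal tissue.
#'
#' @param expr a [paired_expression] object.
#' @param source tissue supplying the intensity factor, `"tumor"` or
#'   `"normal"`.
#' @return an object of class `"gene_weight_matrix"`: a list with elements
#'   `weights` (genes x patients matrix), `source`, `gene_ids`,
#'   `patient_ids`.
#' @export
gene_weight_matrix <- function(expr, source = c("tumor", "normal")) {
  source <- match.arg(source)
  stopifnot(inherits(expr, "paired_expression"))
  i <- if (source == "tumor") expr$tumor else expr$normal
  w <- log2(expr$tumor / expr$normal) * log(i, base = 1.1)
  if (any(!is.finite(w)))
    stop("non-finite gene weights; intensities must be positive and finite")
  structure(
    list(weights = w, source = source,
         gene_ids = rownames(w), patient_ids = colnames(w)),
    class = "gene_weight_matrix"
  )
}

#' @export
print.gene_weight_matrix <- function(x, ...) {
  cat("Gene weight matrix:", nrow(x$weights), "genes x",
      ncol(x$weights), "patients; intensity source:", x$source, "\n")
  invisible(x)
}

#' Pearson correlation with a two-sided p-value
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return list with elements `r` and `p` (two-sided, from the t
#'   distribution with n - 2 degrees of freedom, floored at 1e-300).
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Pearson correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = max(ct$p.value, 1e-300))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of BH q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || length(p) < 1) stop("p must be a non-empty numeric vector")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Aggregate gene weights over a gene set
#'
#' Collapses the weights of a gene set into one value per patient using the
#' median, mean, or sum — the three aggregation modes used by DDPP
#' correlators.
#'
#' @param weights a `"gene_weight_matrix"` or a genes x patients matrix with
#'   rownames.
#' @param gene_set character vector of gene ids (non-empty, all present).
#' @param mode `"median"`, `"mean"`, or `"sum"`.
#' @return named numeric vector, one aggregate per patient.
#' @export
aggregate_weights <- function(weights, gene_set, mode = c("median", "mean", "sum")) {
  mode <- match.arg(mode)
  w <- if (inherits(weights, "gene_weight_matrix")) weights$weights else weights
  if (length(gene_set) < 1) stop("gene_set must be non-empty")
  missing <- setdiff(gene_set, rownames(w))
  if (length(missing) > 0)
    stop("unknown gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
  sub <- w[gene_set, , drop = FALSE]
  switch(mode,
    median = apply(sub, 2, stats::median),
    mean   = colMeans(sub),
    sum    = colSums(sub)
  )
}
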