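#' High/low call for one gene in normal tissue
#'
#' Splits the patients into high and low expressors of a gene by exact k = 2
#' clustering of the log2 normal-tissue intensities; the cluster with the
#' larger mean is `high`. The separation between the two clusters is
#' summarized by a pooled-variance (Student's) t-test.
#'
#' @param normal_expr named per-patient vector of positive linear-scale
#'   intensities in normal tissue (>= 2 distinct values).
#' @param gene_id label carried into the result.
#' @return object of class `"immune_gene_call"`: `gene_id`, `calls` (factor
#'   low/high named by patient), `cluster_means` (log2 scale),
#'   `t`, `p`.
#' @export
call_gene_high_low <- function(normal_expr, gene_id = NA_character_) {
  if (any(normal_expr <= 0)) stop("intensities must be positive")
  v <- log2(normal_expr)
  km <- kmeans2_1d(as.numeric(v))
  calls <- factor(ifelse(km$labels == 2L, "high", "low"),
                  levels = c("low", "high"))
  names(calls) <- names(normal_expr)
  sep <- cluster_separation_test(as.numeric(v), calls)
  structure(list(gene_id = gene_id, calls = calls,
                 cluster_means = km$centers, t = sep$t, p = sep$p),
            class = "immune_gene_call")
}

#' @export
print.immune_gene_call <- function(x, ...) {
  cat(sprintf("Immune gene call [%s]: %d high / %d low (cluster means %.2f / %.2f log2; t = %.2f, p = %.3g)\n",
              x$gene_id, sum(x$calls == "high"), sum(x$calls == "low"),
              x$cluster_means[2], x$cluster_means[1], x$t, x$p))
  invisible(x)
}

#' Pooled-variance t-test between two clusters
#'
#' Two-sample Student's t-test (equal variances, two-sided) between the
#' values of two label groups, each of size >= 2. Degenerate inputs where
#' both groups are constant with equal means return t = 0, p = 1.
#'
#' @param values numeric vector.
#' @param labels two-level factor/vector parallel to `values`.
#' @return list with `t` and `p`.
#' @export
cluster_separation_test <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) stop("labels must have exactly 2 levels")
  split_v <- split(values, droplevels(labels))
  if (any(lengths(split_v) < 2)) stop("both label groups must have size >= 2")
  a <- split_v[[1]]; b <- split_v[[2]]
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Rank candidate checkpoint genes by cluster separation
#'
#' Calls each candidate gene high/low in normal tissue and orders the genes
#' by the significance of the high-versus-low separation (ascending p, ties
#' by gene id) — the screen that singles out strongly bimodal checkpoint
#' genes.
#'
#' @param expr a [paired_expression] object.
#' @param candidate_genes character vector of gene ids; absent candidates
#'   are skipped with a warning.
#' @return data.frame (`gene_id`, `t`, `p`, `mean_low`, `mean_high`) in
#'   ascending-p order, with the per-gene call objects in the `"calls"`
#'   attribute.
#' @export
rank_checkpoint_genes <- function(expr, candidate_genes) {
  stopifnot(inherits(expr, "paired_expression"))
  missing <- setdiff(candidate_genes, expr$gene_ids)
  if (length(missing) > 0)
    warning("candidate gene(s) absent, skipped: ", paste(missing, collapse = ", "))
  present <- intersect(candidate_genes, expr$gene_ids)
  calls <- lapply(present, function(g)
    call_gene_high_low(expr$normal[g, ], gene_id = g))
  names(calls) <- present
  out <- data.frame(
    gene_id = present,
    t = vapply(calls, function(cl) cl$t, numeric(1)),
    p = vapply(calls, function(cl) cl$p, numeric(1)),
    mean_low = vapply(calls, function(cl) cl$cluster_means[1], numeric(1)),
    mean_high = vapply(calls, function(cl) cl$cluster_means[2], numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "calls") <- calls
  out
}

#' Combine three checkpoint calls into tolerant/competent/other
#'
#' A patient is immune-`tolerant` when all three checkpoint genes are called
#' high in normal tissue (co-overexpression of CTLA-4, PD-L1 and ICOS), and
#' immune-`competent` under the configurable favorable rule (default:
#' CTLA-4 low with PD-L1 and ICOS high); every other combination is
#' `other`. Patients lacking any call are excluded with a reason.
#'
#' @param calls list of three `"immune_gene_call"` objects, in CTLA-4,
#'   PD-L1, ICOS role order.
#' @param competent_rule character vector of `"low"`/`"high"` per gene
#'   defining the competent combination.
#' @return object of class `"immune_status_table"`: data.frame with one
#'   call column per gene and a `status` factor
#'   (tolerant/competent/other), plus an `"excluded"` attribute.
#' @export
assign_combined_status <- function(calls,
                                   competent_rule = c("low", "high", "high")) {
  if (length(calls) != 3) stop("exactly three gene calls are required")
  if (length(competent_rule) != 3 || !all(competent_rule %in% c("low", "high")))
    stop("competent_rule must be three 'low'/'high' tokens")
  gene_ids <- vapply(calls, function(cl) cl$gene_id, character(1))
  pats <- Reduce(union, lapply(calls, function(cl) names(cl$calls)))
  call_mat <- vapply(calls, function(cl) as.character(cl$calls[pats]),
                     character(length(pats)))
  if (length(pats) == 1) call_mat <- matrix(call_mat, nrow = 1)
  colnames(call_mat) <- gene_ids
  rownames(call_mat) <- pats
  complete <- stats::complete.cases(call_mat)
  excluded <- data.frame(patient_id = pats[!complete],
                         reason = rep("missing immune gene call", sum(!complete)),
                         stringsAsFactors = FALSE)
  call_mat <- call_mat[complete, , drop = FALSE]
  status <- rep("other", nrow(call_mat))
  status[rowSums(call_mat == "high") == 3] <- "tolerant"
  status[apply(call_mat, 1, function(r) all(r == competent_rule))] <- "competent"
  out <- data.frame(patient_id = rownames(call_mat), call_mat,
                    status = factor(status,
                                    levels = c("tolerant", "competent", "other")),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  structure(out, excluded = excluded,
            class = c("immune_status_table", class(out)))
}

#' Immune-checkpoint status of normal lung tissue
#'
#' Top-level classifier: calls each of the three checkpoint genes high/low
#' in normal tissue (exact k = 2 clustering of log2 intensities) and
#' combines the calls into the immune-tolerant / immune-competent / other
#' label used by the combined DDPP-immune stratification.
#'
#' @param expr a [paired_expression] object.
#' @param genes three gene ids in CTLA-4, PD-L1, ICOS role order.
#' @param competent_rule see [assign_combined_status()].
#' @return object of class `"immune_status"`: list with `table` (the
#'   [assign_combined_status()] result), `gene_tests` (the
#'   [rank_checkpoint_genes()] ranking), and `genes`.
#' @export
immune_status <- function(expr, genes = c("CTLA4", "PDL1", "ICOS"),
                          competent_rule = c("low", "high", "high")) {
  if (length(genes) != 3) stop("exactly three checkpoint genes are required")
  missing <- setdiff(genes, expr$gene_ids)
  if (length(missing) > 0)
    stop("checkpoint gene(s) absent from expression: ",
         paste(missing, collapse = ", "))
  ranking <- rank_checkpoint_genes(expr, genes)
  calls <- attr(ranking, "calls")[genes]
  tab <- assign_combined_status(calls, competent_rule = competent_rule)
  structure(list(table = tab, gene_tests = ranking, genes = genes,
                 competent_rule = competent_rule),
            class = "immune_status")
}

#' @export
print.immune_status <- function(x, ...) {
  counts <- table(x$table$status)
  cat("Normal-tissue immune status (", paste(x$genes, collapse = ", "), "):\n",
      sep = "")
  cat(sprintf("  tolerant %d, competent %d, other %d\n",
              counts[["tolerant"]], counts[["competent"]], counts[["other"]]))
  invisible(x)
}

#' @export
summary.immune_status <- function(object, ...) {
  list(status_counts = table(object$table$status),
       gene_tests = object$gene_tests,
       excluded = attr(object$table, "excluded"))
}
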