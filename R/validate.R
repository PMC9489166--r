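#' Random-gene-set specificity null
#'
#' The specificity design: repeatedly draw random gene sets of a fixed size
#' from the whole transcriptome, build a correlator for each (fixed
#' aggregation: mean of tumor-source weights, no mode search — searching
#' would inflate the null), and record the fit p-value against the group's
#' DFS. Significance is assessed by BH correction across the iterations at
#' 0.05: on data with no planted signal, no random set should survive.
#'
#' @param weights a [gene_weight_matrix()] (tumor source) for the cohort.
#' @param clinical validated clinical table.
#' @param patients patient ids of the group under test.
#' @param set_size number of genes per random set (default 10).
#' @param n_iter number of random sets.
#' @param seed integer seed.
#' @return object of class `"specificity_result"`: list with `n_iter`,
#'   `set_size`, `p_values`, `q_values`, `n_significant`, `seed`.
#' @export
random_set_specificity <- function(weights, clinical, patients, set_size = 10,
                                   n_iter = 1000, seed = 1) {
  stopifnot(inherits(weights, "gene_weight_matrix"))
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (set_size > length(weights$gene_ids))
    stop("set_size exceeds the gene universe")
  clin <- as.data.frame(clinical)
  y <- clin$dfs_months[match(patients, clin$patient_id)]
  if (any(is.na(y))) stop("patients missing from clinical table")
  w <- weights$weights[, patients, drop = FALSE]
  set.seed(as.integer(seed))
  p_values <- vapply(seq_len(n_iter), function(i) {
    genes <- sample(rownames(w), set_size)
    agg <- colMeans(w[genes, , drop = FALSE])
    if (stats::sd(agg) == 0) return(1)
    fit_correlator(agg, y)$fit_p
  }, numeric(1))
  q <- bh_fdr(p_values)
  structure(list(n_iter = n_iter, set_size = set_size, p_values = p_values,
                 q_values = q, n_significant = sum(q < 0.05),
                 seed = as.integer(seed)),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("Random-set specificity: %d sets of %d genes; %d significant after BH at 0.05 (min p = %.3g)\n",
              x$n_iter, x$set_size, x$n_significant, min(x$p_values)))
  invisible(x)
}

#' Bootstrap stability of a group signature
#'
#' The replicate design: repeatedly split a group into a random training
#' set and a held-out set, rerun the full correlator selection on the
#' training patients, predict the held-out DFS, and compare the selected
#' gene set with the correlator selected on the whole group. Stability is
#' the fraction of iterations whose selected gene set is identical (set
#' equality) to the full-group set; predictive performance is the pooled
#' Pearson correlation between predicted and observed held-out DFS.
#'
#' @param expr a [paired_expression] object.
#' @param clinical validated clinical table.
#' @param patients patient ids of the group.
#' @param train_size training-set size (default 18; must be < group size).
#' @param n_iter number of resampling iterations.
#' @param seed integer seed.
#' @param k_min,k_max,fdr passed to [select_predictor()].
#' @return object of class `"stability_result"`: list with `n_iter`,
#'   `train_size`, `selected_sets`, `failed_iterations`,
#'   `identical_fraction`, `full_gene_set`, `predicted`, `observed`,
#'   `pooled_r`, `pooled_p`, `seed`. Iterations whose training set yields
#'   no correlator count as unstable and contribute NA predictions (never
#'   dropped silently).
#' @export
bootstrap_stability <- function(expr, clinical, patients, train_size = 18,
                                n_iter = 200, seed = 1, k_min = 3, k_max = 20,
                                fdr = 0.05) {
  if (train_size >= length(patients))
    stop("train_size must be smaller than the group size")
  if (n_iter < 1) stop("n_iter must be >= 1")
  wt <- gene_weight_matrix(expr, "tumor")
  wn <- gene_weight_matrix(expr, "normal")
  clin <- as.data.frame(clinical)
  dfs_of <- function(ids) clin$dfs_months[match(ids, clin$patient_id)]
  full <- select_predictor(wt, wn, clinical, patients, group = "full",
                           k_min = k_min, k_max = k_max, fdr = fdr)
  wlist <- list(tumor = wt, normal = wn)
  set.seed(as.integer(seed))
  held_n <- length(patients) - train_size
  selected_sets <- vector("list", n_iter)
  failed <- logical(n_iter)
  predicted <- observed <- matrix(NA_real_, nrow = n_iter, ncol = held_n)
  for (i in seq_len(n_iter)) {
    train <- sample(patients, train_size)
    test <- setdiff(patients, train)
    cor_i <- tryCatch(
      select_predictor(wt, wn, clinical, train, group = "train", k_min = k_min,
                       k_max = k_max, fdr = fdr),
      error = function(e) NULL)
    observed[i, ] <- dfs_of(test)
    if (is.null(cor_i)) {
      failed[i] <- TRUE
      selected_sets[[i]] <- character(0)
      next
    }
    selected_sets[[i]] <- cor_i$gene_ids
    agg <- aggregate_weights(wlist[[cor_i$intensity_source]],
                             cor_i$gene_ids, cor_i$aggregation)[test]
    predicted[i, ] <- cor_i$intercept + cor_i$slope * agg
  }
  identical_set <- vapply(selected_sets, function(s)
    length(s) > 0 && setequal(s, full$gene_ids), logical(1))
  ok <- !is.na(predicted)
  if (sum(ok) >= 3 && stats::sd(predicted[ok]) > 0 && stats::sd(observed[ok]) > 0) {
    pw <- pearson_with_p(predicted[ok], observed[ok])
    pooled_r <- pw$r; pooled_p <- pw$p
  } else {
    pooled_r <- NA_real_; pooled_p <- NA_real_
  }
  structure(list(n_iter = n_iter, train_size = train_size,
                 selected_sets = selected_sets, failed_iterations = sum(failed),
                 identical_fraction = mean(identical_set),
                 full_gene_set = full$gene_ids,
                 predicted = as.vector(t(predicted)),
                 observed = as.vector(t(observed)),
                 pooled_r = pooled_r, pooled_p = pooled_p,
                 seed = as.integer(seed)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Bootstrap stability: %d iterations (train %d); identical-set fraction %.3f; pooled r = %.4f (p = %.3g)\n",
              x$n_iter, x$train_size, x$identical_fraction,
              x$pooled_r, x$pooled_p))
  if (x$failed_iterations > 0)
    cat("  ", x$failed_iterations, "iteration(s) yielded no correlator (counted as unstable)\n")
  invisible(x)
}
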