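#' Screen genes against disease-free survival within a group
#'
#' Pearson-correlates every gene's weight with DFS over the patients of one
#' histology-by-treatment group, with BH q-values across genes.
#' Constant-weight genes are excluded (recorded in the `"flagged"`
#' attribute).
#'
#' @param weights a [gene_weight_matrix()] object.
#' @param clinical validated clinical table.
#' @param patients character vector of patient ids forming the group
#'   (length >= 4).
#' @return data.frame with columns `gene_id`, `r`, `p`, `q`, `rank`
#'   (rank 1 = smallest p).
#' @export
screen_genes <- function(weights, clinical, patients) {
  stopifnot(inherits(weights, "gene_weight_matrix"))
  clinical <- as.data.frame(clinical)
  if (length(patients) < 4)
    stop("group has fewer than 4 patients; per-group correlator unavailable")
  if (!all(patients %in% weights$patient_ids))
    stop("patients missing from weight matrix")
  y <- clinical$dfs_months[match(patients, clinical$patient_id)]
  if (any(is.na(y))) stop("patients missing from clinical table")
  w <- weights$weights[, patients, drop = FALSE]
  n <- length(y)
  constant <- matrixStats_rowSds0(w)
  flagged <- rownames(w)[constant]
  w <- w[!constant, , drop = FALSE]
  if (nrow(w) == 0) stop("no non-constant genes to screen")
  r <- as.vector(stats::cor(t(w), y))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- pmax(2 * stats::pt(-abs(tstat), df = n - 2), 1e-300)
  out <- data.frame(gene_id = rownames(w), r = r, p = p, q = bh_fdr(p),
                    rank = rank(p, ties.method = "first"),
                    stringsAsFactors = FALSE)
  attr(out, "flagged") <- flagged
  attr(out, "n_patients") <- n
  out
}

# rows with zero variance, without forming a genes x genes matrix
matrixStats_rowSds0 <- function(w) {
  mu <- rowMeans(w)
  rowSums((w - mu)^2) == 0
}

#' Ordinary least-squares link from an aggregate to DFS
#'
#' Fits DFS (months) on a per-patient weight aggregate; the fitted line is a
#' group's correlator. `fit_r`/`fit_p` are the Pearson correlation and its
#' two-sided p-value (`fit_p` is `NA` for n = 2, where the line merely
#' interpolates).
#'
#' @param aggregate numeric per-patient aggregate (non-constant, length >= 2).
#' @param dfs numeric DFS in months, same length.
#' @return list with `slope`, `intercept`, `fit_r`, `fit_p`, `n`.
#' @export
fit_correlator <- function(aggregate, dfs) {
  n <- length(aggregate)
  if (n != length(dfs)) stop("aggregate and dfs must have equal length")
  if (n < 2) stop("need at least 2 patients")
  if (stats::sd(aggregate) == 0) stop("constant aggregate: correlator undefined")
  xb <- mean(aggregate); yb <- mean(dfs)
  slope <- sum((aggregate - xb) * (dfs - yb)) / sum((aggregate - xb)^2)
  intercept <- yb - slope * xb
  if (stats::sd(dfs) == 0) {
    r <- 0; p <- 1
  } else {
    r <- stats::cor(aggregate, dfs)
    p <- if (n >= 3) {
      t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
      max(2 * stats::pt(-abs(t), df = n - 2), 1e-300)
    } else NA_real_
  }
  list(slope = slope, intercept = intercept, fit_r = r, fit_p = p, n = n)
}

#' Select the optimal correlator for one group
#'
#' Searches intensity source (tumor, normal) x aggregation mode (median,
#' mean, sum) x signature size k over genes gated at BH q < `fdr` and taken
#' in ascending screening-p order, and returns the combination maximizing
#' the absolute fit correlation |r| between aggregate and DFS. |r| values
#' within 1e-12 are treated as tied; ties break deterministically to the
#' smaller k, then mode order median < mean < sum, then tumor before normal.
#'
#' @param weights_t,weights_n [gene_weight_matrix()] objects for the tumor
#'   and normal intensity sources.
#' @param clinical validated clinical table.
#' @param patients patient ids of the group.
#' @param group group key (carried into the result).
#' @param k_min,k_max bounds of the signature-size scan.
#' @param fdr BH q-value gate for candidate genes.
#' @param modes,sources subsets of the search space, in tie-break order.
#' @return object of class `"ddpp_correlator"`: gene set, aggregation mode,
#'   intensity source, slope/intercept (months per aggregate unit),
#'   fit_r/fit_p, n_patients.
#' @export
select_predictor <- function(weights_t, weights_n, clinical, patients,
                             group = NA_character_, k_min = 3, k_max = 20,
                             fdr = 0.05,
                             modes = c("median", "mean", "sum"),
                             sources = c("tumor", "normal")) {
  modes <- match.arg(modes, several.ok = TRUE)
  sources <- match.arg(sources, several.ok = TRUE)
  wlist <- list(tumor = weights_t, normal = weights_n)
  y <- as.data.frame(clinical)
  y <- y$dfs_months[match(patients, y$patient_id)]
  best <- NULL
  for (src in sources) {
    wobj <- wlist[[src]]
    if (is.null(wobj)) next
    scr <- screen_genes(wobj, clinical, patients)
    sig <- scr[scr$q < fdr, , drop = FALSE]
    if (nrow(sig) < k_min) next
    sig <- sig[order(sig$p, -abs(sig$r), sig$gene_id), , drop = FALSE]
    for (k in seq(k_min, min(k_max, nrow(sig)))) {
      genes <- sig$gene_id[seq_len(k)]
      for (mode in modes) {
        agg <- aggregate_weights(wobj, genes, mode)[patients]
        if (stats::sd(agg) == 0) next
        fit <- fit_correlator(agg, y)
        cand <- list(genes = genes, mode = mode, source = src, fit = fit,
                     key = c(-round(abs(fit$fit_r), 12), k,
                             match(mode, c("median", "mean", "sum")),
                             match(src, c("tumor", "normal"))))
        if (is.null(best) || lex_less(cand$key, best$key)) best <- cand
      }
    }
  }
  if (is.null(best))
    stop("no significant correlator for group ", group,
         " (no gene set passes q < ", fdr, " with k >= ", k_min, ")")
  structure(
    list(group = group, gene_ids = best$genes, aggregation = best$mode,
         intensity_source = best$source, slope = best$fit$slope,
         intercept = best$fit$intercept, fit_r = best$fit$fit_r,
         fit_p = best$fit$fit_p, n_patients = best$fit$n),
    class = "ddpp_correlator"
  )
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.ddpp_correlator <- function(x, ...) {
  cat(sprintf("DDPP correlator [%s]: %d genes, %s of %s-source weights\n",
              x$group, length(x$gene_ids), x$aggregation, x$intensity_source))
  cat(sprintf("  DFS = %.4g + %.4g x aggregate  (r = %.4f, p = %.3g, n = %d)\n",
              x$intercept, x$slope, x$fit_r, x$fit_p, x$n_patients))
  invisible(x)
}

#' Score patients with their group correlators
#'
#' The DDPP score of a patient is the predicted DFS in months from the
#' patient's group correlator: intercept + slope x aggregate of the
#' correlator's gene weights. Patients in groups without a fitted correlator
#' are listed as excluded, never silently dropped.
#'
#' @param correlators named list of `"ddpp_correlator"` objects, keyed by
#'   group.
#' @param weights_t,weights_n weight matrices for the two intensity sources.
#' @param clinical validated clinical table.
#' @return list with `scores` (data.frame patient_id, group, score) and
#'   `excluded` (data.frame patient_id, reason).
#' @export
score_patients <- function(correlators, weights_t, weights_n, clinical) {
  clin <- as.data.frame(clinical)
  keys <- group_key(clin$histology, clin$chemo)
  wlist <- list(tumor = weights_t, normal = weights_n)
  scores <- excluded <- NULL
  for (g in unique(keys)) {
    pats <- clin$patient_id[keys == g]
    cor_g <- correlators[[g]]
    if (is.null(cor_g)) {
      excluded <- rbind(excluded, data.frame(
        patient_id = pats, reason = paste0("no correlator for group ", g),
        stringsAsFactors = FALSE))
      next
    }
    agg <- aggregate_weights(wlist[[cor_g$intensity_source]],
                             cor_g$gene_ids, cor_g$aggregation)[pats]
    scores <- rbind(scores, data.frame(
      patient_id = pats, group = g,
      score = unname(cor_g$intercept + cor_g$slope * agg),
      stringsAsFactors = FALSE))
  }
  if (is.null(scores))
    scores <- data.frame(patient_id = character(0), group = character(0),
                         score = numeric(0), stringsAsFactors = FALSE)
  if (is.null(excluded))
    excluded <- data.frame(patient_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  list(scores = scores, excluded = excluded)
}

#' Stratify DDPP scores into high/low risk classes
#'
#' Pools the scores of all scored patients and cuts them with the exact 1-D
#' k = 2 clustering; the cluster with the higher center is labeled `high`
#' (longer predicted DFS, lower risk).
#'
#' @param scores named numeric vector of DDPP scores (>= 2 patients).
#' @return object of class `"ddpp_classes"`: data.frame (`patient_id`,
#'   `score`, `class`) with attributes `threshold` and `centers`.
#' @export
classify_ddpp <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scored patients")
  km <- kmeans2_1d(as.numeric(scores))
  out <- data.frame(
    patient_id = if (is.null(names(scores))) as.character(seq_along(scores))
                 else names(scores),
    score = as.numeric(scores),
    class = factor(ifelse(km$labels == 2L, "high", "low"),
                   levels = c("low", "high")),
    stringsAsFactors = FALSE
  )
  structure(out, threshold = km$threshold, centers = km$centers,
            class = c("ddpp_classes", class(out)))
}

#' Fit the DDPP model to a paired-expression cohort
#'
#' The main fitting function. For each histology-by-treatment group it
#' screens all gene weights (log2 tumor/normal fold-change x log1.1
#' intensity) against DFS, selects the |r|-maximizing correlator
#' ([select_predictor()]), scores every patient with the group correlator
#' (predicted DFS in months), and stratifies the pooled scores into
#' high/low classes by exact k = 2 clustering.
#'
#' @param expr a [paired_expression] object.
#' @param clinical clinical table (coerced through [cohort_clinical()]).
#' @param k_min,k_max signature-size scan bounds.
#' @param fdr BH q-value gate for the per-group gene screen.
#' @param modes,sources search space for aggregation mode and intensity
#'   source.
#' @param group_by `"histology_chemo"` (the six-group design) or
#'   `"histology"` (pooled treatment arms; demonstrates the degraded
#'   predictor obtained without treatment separation).
#' @param min_group_size groups below this size are not fitted (recorded in
#'   the per-group failure list).
#' @return object of class `"ddpp"` with components `correlators` (named
#'   list), `failed_groups` (named character reasons), `scores` (patient_id,
#'   group, score, class), `threshold`, `centers`, `excluded`, `clinical`,
#'   and the call. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' cfg <- synth_config(n_genes = 300,
#'                     group_sizes = c("AC:NC" = 12, "SCC:NC" = 10),
#'                     signature_sizes = c("AC:NC" = 5, "SCC:NC" = 4),
#'                     noise_sd = 0, immune_tolerant_count = 4,
#'                     missing_stage_count = 0, seed = 7)
#' coh <- generate_cohort(cfg)
#' fit <- ddpp(coh$expression, coh$clinical, k_max = 8)
#' summary(fit)
#' @export
ddpp <- function(expr, clinical, k_min = 3, k_max = 20, fdr = 0.05,
                 modes = c("median", "mean", "sum"),
                 sources = c("tumor", "normal"),
                 group_by = c("histology_chemo", "histology"),
                 min_group_size = 4) {
  group_by <- match.arg(group_by)
  stopifnot(inherits(expr, "paired_expression"))
  if (!inherits(clinical, "cohort_clinical")) clinical <- cohort_clinical(clinical)
  missing_pat <- setdiff(clinical$patient_id, expr$patient_ids)
  if (length(missing_pat) > 0)
    stop("clinical patients absent from expression: ",
         paste(utils::head(missing_pat, 5), collapse = ", "))
  wt <- gene_weight_matrix(expr, "tumor")
  wn <- gene_weight_matrix(expr, "normal")
  groups <- if (group_by == "histology_chemo") {
    suppressWarnings(partition_groups(clinical))
  } else {
    split(clinical$patient_id, clinical$histology)
  }
  correlators <- list()
  failed <- character(0)
  for (g in names(groups)) {
    pats <- groups[[g]]
    if (length(pats) == 0) next
    if (length(pats) < min_group_size) {
      failed[g] <- sprintf("group size %d < %d", length(pats), min_group_size)
      next
    }
    res <- tryCatch(
      select_predictor(wt, wn, clinical, pats, group = g, k_min = k_min,
                       k_max = k_max, fdr = fdr, modes = modes,
                       sources = sources),
      error = function(e) conditionMessage(e))
    if (inherits(res, "ddpp_correlator")) correlators[[g]] <- res
    else failed[g] <- res
  }
  sc <- score_patients(correlators, wt, wn, clinical)
  scores <- sc$scores
  threshold <- centers <- NULL
  if (nrow(scores) >= 2 && length(unique(scores$score)) >= 2) {
    cls <- classify_ddpp(stats::setNames(scores$score, scores$patient_id))
    scores$class <- cls$class
    threshold <- attr(cls, "threshold")
    centers <- attr(cls, "centers")
  } else {
    scores$class <- factor(rep(NA_character_, nrow(scores)),
                           levels = c("low", "high"))
  }
  structure(
    list(correlators = correlators, failed_groups = failed, scores = scores,
         threshold = threshold, centers = centers, excluded = sc$excluded,
         clinical = clinical, group_by = group_by,
         settings = list(k_min = k_min, k_max = k_max, fdr = fdr,
                         modes = modes, sources = sources),
         call = match.call()),
    class = "ddpp"
  )
}

#' @export
print.ddpp <- function(x, ...) {
  cat("DDPP fit:", length(x$correlators), "group correlator(s),",
      nrow(x$scores), "patients scored\n")
  if (!is.null(x$threshold))
    cat(sprintf("  high/low threshold: %.3f months (%d high, %d low)\n",
                x$threshold, sum(x$scores$class == "high", na.rm = TRUE),
                sum(x$scores$class == "low", na.rm = TRUE)))
  if (length(x$failed_groups) > 0)
    cat("  unfitted groups:", paste(names(x$failed_groups), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ddpp <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$correlators, function(cor_g) {
    data.frame(group = cor_g$group, n = cor_g$n_patients,
               n_genes = length(cor_g$gene_ids), mode = cor_g$aggregation,
               source = cor_g$intensity_source, slope = cor_g$slope,
               intercept = cor_g$intercept, fit_r = cor_g$fit_r,
               fit_p = cor_g$fit_p, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(correlator_table = tab,
                 n_high = sum(object$scores$class == "high", na.rm = TRUE),
                 n_low = sum(object$scores$class == "low", na.rm = TRUE),
                 threshold = object$threshold, centers = object$centers,
                 failed_groups = object$failed_groups,
                 n_excluded = nrow(object$excluded)),
            class = "summary.ddpp")
}

#' @export
print.summary.ddpp <- function(x, ...) {
  cat("Per-group DDPP correlators:\n")
  print(x$correlator_table, digits = 4)
  if (!is.null(x$threshold))
    cat(sprintf("\nRisk classes: %d high, %d low; threshold %.3f months (centers %.3f / %.3f)\n",
                x$n_high, x$n_low, x$threshold, x$centers[1], x$centers[2]))
  if (length(x$failed_groups) > 0) {
    cat("Unfitted groups:\n")
    for (g in names(x$failed_groups))
      cat("  ", g, ": ", x$failed_groups[[g]], "\n", sep = "")
  }
  if (x$n_excluded > 0) cat(x$n_excluded, "patient(s) excluded from scoring\n")
  invisible(x)
}

#' @export
coef.ddpp <- function(object, ...) {
  t(vapply(object$correlators,
           function(cor_g) c(intercept = cor_g$intercept, slope = cor_g$slope),
           numeric(2)))
}

#' Predict DDPP scores for a cohort
#'
#' Applies the fitted per-group correlators to (new) paired-expression data:
#' each patient's score is the predicted DFS from the correlator of the
#' patient's group.
#'
#' @param object a fitted `"ddpp"` model.
#' @param expr new [paired_expression] (omit for fitted scores).
#' @param clinical clinical table for the new patients.
#' @param ... unused.
#' @return data.frame `patient_id`, `group`, `score`; patients whose group
#'   has no correlator are absent (see the `"excluded"` attribute).
#' @export
predict.ddpp <- function(object, expr = NULL, clinical = NULL, ...) {
  if (is.null(expr)) return(object$scores)
  if (is.null(clinical)) stop("clinical table required with new expression data")
  if (!inherits(clinical, "cohort_clinical")) clinical <- cohort_clinical(clinical)
  wt <- gene_weight_matrix(expr, "tumor")
  wn <- gene_weight_matrix(expr, "normal")
  sc <- score_patients(object$correlators, wt, wn, clinical)
  structure(sc$scores, excluded = sc$excluded)
}

#' @export
fitted.ddpp <- function(object, ...) {
  stats::setNames(object$scores$score, object$scores$patient_id)
}

#' @export
residuals.ddpp <- function(object, ...) {
  obs <- object$clinical$dfs_months[match(object$scores$patient_id,
                                          object$clinical$patient_id)]
  stats::setNames(obs - object$scores$score, object$scores$patient_id)
}

#' Predicted-versus-observed DFS plot
#'
#' @param x a fitted `"ddpp"` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ddpp <- function(x, ...) {
  obs <- x$clinical$dfs_months[match(x$scores$patient_id, x$clinical$patient_id)]
  grp <- factor(x$scores$group)
  graphics::plot(x$scores$score, obs, col = as.integer(grp), pch = 19,
                 xlab = "DDPP score (predicted DFS, months)",
                 ylab = "Observed DFS (months)", ...)
  graphics::abline(0, 1, lty = 2)
  if (!is.null(x$threshold)) graphics::abline(v = x$threshold, lty = 3)
  graphics::legend("topleft", legend = levels(grp), col = seq_along(levels(grp)),
                   pch = 19, cex = 0.8, bty = "n")
  invisible(x)
}
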