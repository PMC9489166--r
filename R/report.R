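#' Write a pipeline report to disk
#'
#' Serializes a `"ddpp_report"` as a machine-readable bundle:
#' `report.json` (config echo, cohort summary, correlators, thresholds,
#' log-rank p-values, Cox tables, validation summaries, exclusions, log),
#' plus flat tables `scores.tsv`, `immune_status.tsv`, `km_curves.tsv`,
#' `cox_forest.tsv` and `correlators.json`.
#'
#' @param report a `"ddpp_report"` from [run_ddpp_pipeline()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ddpp_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!is.null(report$fit)) {
    utils::write.table(report$fit$scores, file.path(dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(lapply(report$fit$correlators, unclass),
                         file.path(dir, "correlators.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$immune))
    utils::write.table(report$immune$table, file.path(dir, "immune_status.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$km_suite) && length(report$km_suite$comparisons) > 0) {
    curves <- do.call(rbind, lapply(report$km_suite$comparisons, function(cmp) {
      do.call(rbind, lapply(names(cmp$km), function(arm) {
        k <- as.data.frame(cmp$km[[arm]])
        cbind(comparison = cmp$name, arm = arm, k)
      }))
    }))
    utils::write.table(curves, file.path(dir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$cox$forest))
    utils::write.table(report$cox$forest, file.path(dir, "cox_forest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# plain-list view of the report for JSON serialization (drops matrices and
# model internals, keeps every reported statistic)
report_to_list <- function(report) {
  fit <- report$fit
  km <- report$km_suite
  cox <- report$cox
  val <- report$validation
  list(
    seed = report$seed,
    config = report$config,
    cohort = lapply(report$cohort, function(x)
      if (inherits(x, "table")) as.list(stats::setNames(as.integer(x), names(x))) else x),
    correlators = if (!is.null(fit)) lapply(fit$correlators, function(cor_g)
      list(group = cor_g$group, gene_ids = cor_g$gene_ids,
           aggregation = cor_g$aggregation,
           intensity_source = cor_g$intensity_source, slope = cor_g$slope,
           intercept = cor_g$intercept, fit_r = cor_g$fit_r,
           fit_p = cor_g$fit_p, n_patients = cor_g$n_patients)),
    failed_groups = if (!is.null(fit)) as.list(fit$failed_groups),
    ddpp = if (!is.null(fit)) list(
      threshold = fit$threshold, centers = fit$centers,
      n_high = sum(fit$scores$class == "high", na.rm = TRUE),
      n_low = sum(fit$scores$class == "low", na.rm = TRUE),
      scores = fit$scores),
    immune = if (!is.null(report$immune)) list(
      genes = report$immune$genes,
      status_counts = as.list(table(report$immune$table$status)),
      gene_tests = report$immune$gene_tests,
      table = report$immune$table),
    km_comparisons = if (!is.null(km)) lapply(km$comparisons, function(cmp)
      list(name = cmp$name, arms = as.list(cmp$arms),
           medians = as.list(cmp$medians),
           logrank = list(chisq = cmp$logrank$chisq, df = cmp$logrank$df,
                          p = cmp$logrank$p))),
    km_skipped = if (!is.null(km)) as.list(km$skipped),
    cox = if (!is.null(cox)) list(
      univariate = lapply(cox$univariate, cox_to_list),
      multivariate = cox_to_list(cox$multivariate),
      forest = cox$forest),
    validation = if (!is.null(val)) list(
      specificity = if (!is.null(val$specificity)) list(
        n_iter = val$specificity$n_iter, set_size = val$specificity$set_size,
        n_significant = val$specificity$n_significant,
        min_p = min(val$specificity$p_values), seed = val$specificity$seed),
      bootstrap = if (!is.null(val$bootstrap)) list(
        n_iter = val$bootstrap$n_iter, train_size = val$bootstrap$train_size,
        identical_fraction = val$bootstrap$identical_fraction,
        failed_iterations = val$bootstrap$failed_iterations,
        pooled_r = val$bootstrap$pooled_r, pooled_p = val$bootstrap$pooled_p,
        seed = val$bootstrap$seed)),
    excluded = report$excluded,
    errors = report$errors,
    log = report$log
  )
}

cox_to_list <- function(fit) {
  if (!inherits(fit, "ddpp_cox")) return(list(error = fit))
  list(table = fit$table, loglik = fit$loglik, aic = fit$aic,
       converged = fit$converged, n = fit$n, n_events = fit$n_events,
       reference = as.list(fit$reference))
}
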