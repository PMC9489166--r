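#' Configuration for an end-to-end pipeline run
#'
#' Either a synthetic-cohort configuration or input data (in-memory objects
#' or file paths) must be supplied, together with the analysis settings and
#' a single seed from which all randomness flows.
#'
#' @param synth optional [synth_config()]; its seed is overridden by `seed`.
#' @param expr optional [paired_expression] or path to an expression TSV.
#' @param clinical optional clinical table or path to a clinical CSV.
#' @param immune_genes three checkpoint gene ids (CTLA-4, PD-L1, ICOS roles).
#' @param competent_rule favorable immune combination, see
#'   [assign_combined_status()].
#' @param k_min,k_max,fdr correlator-selection settings.
#' @param validation optional list with elements `specificity` and/or
#'   `bootstrap`, each a list of arguments (`group`, `set_size`/`train_size`,
#'   `n_iter`).
#' @param seed integer master seed.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synth = NULL, expr = NULL, clinical = NULL,
                            immune_genes = c("CTLA4", "PDL1", "ICOS"),
                            competent_rule = c("low", "high", "high"),
                            k_min = 3, k_max = 20, fdr = 0.05,
                            validation = NULL, seed = 1L) {
  if (is.null(synth) && (is.null(expr) || is.null(clinical)))
    stop("either a synth_config or both expression and clinical inputs are required")
  if (!is.null(synth)) {
    stopifnot(inherits(synth, "synth_config"))
    synth$seed <- as.integer(seed)
  }
  structure(list(synth = synth, expr = expr, clinical = clinical,
                 immune_genes = immune_genes, competent_rule = competent_rule,
                 k_min = k_min, k_max = k_max, fdr = fdr,
                 validation = validation, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full DDPP analysis pipeline
#'
#' Orchestrates: cohort acquisition (synthetic generation or file/objects)
#' -> group partition -> per-group correlator selection -> DDPP scoring and
#' high/low stratification -> normal-tissue immune status -> the stratified
#' Kaplan-Meier/log-rank comparison suite -> univariate and multivariate
#' Cox models -> optional specificity/bootstrap validation. Each stage is
#' logged with a timestamp; a stage failure is recorded under the stage
#' name and the partial report is still returned.
#'
#' @param config a [pipeline_config()] object.
#' @return object of class `"ddpp_report"` — see [write_report()] for the
#'   serialized layout. The report accounts for every patient as scored or
#'   excluded-with-reason.
#' @export
run_ddpp_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  logbuf <- character(0)
  logmsg <- function(...) {
    line <- paste0(...)
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), line)
    logbuf <<- c(logbuf, line)
  }
  errors <- list()
  stage <- function(name, code) {
    logmsg("stage ", name, " started")
    out <- tryCatch(code, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      logmsg("stage ", name, " FAILED: ", conditionMessage(e))
      NULL
    })
    if (!name %in% names(errors)) logmsg("stage ", name, " done")
    out
  }

  truth <- NULL
  if (!is.null(config$synth)) {
    coh <- stage("simulate", generate_cohort(config$synth))
    if (is.null(coh)) stop("cohort simulation failed: ", errors$simulate)
    expr <- coh$expression; clinical <- coh$clinical; truth <- coh$truth
  } else {
    expr <- stage("read_expression",
                  if (inherits(config$expr, "paired_expression")) config$expr
                  else read_expression(config$expr))
    clinical <- stage("read_clinical",
                      if (is.character(config$clinical)) read_clinical(config$clinical)
                      else cohort_clinical(config$clinical))
    if (is.null(expr) || is.null(clinical))
      stop("input loading failed: ", paste(unlist(errors), collapse = "; "))
  }

  fit <- stage("fit_ddpp",
               ddpp(expr, clinical, k_min = config$k_min, k_max = config$k_max,
                    fdr = config$fdr))
  imm <- stage("immune_status",
               immune_status(expr, genes = config$immune_genes,
                             competent_rule = config$competent_rule))
  km_suite <- if (!is.null(fit))
    stage("stratified_km", stratified_km_suite(fit$scores, imm, clinical))
  cox <- if (!is.null(fit))
    stage("cox_models", pipeline_cox(fit$scores, imm, clinical))

  validation <- NULL
  if (!is.null(config$validation)) {
    validation <- list()
    groups <- suppressWarnings(partition_groups(clinical))
    vs <- config$validation$specificity
    if (!is.null(vs)) {
      validation$specificity <- stage("validate_specificity", {
        wt <- gene_weight_matrix(expr, "tumor")
        do.call(random_set_specificity, c(
          list(weights = wt, clinical = clinical,
               patients = groups[[vs$group %||% "AC:NC"]],
               seed = config$seed + 1L),
          vs[setdiff(names(vs), "group")]))
      })
    }
    vb <- config$validation$bootstrap
    if (!is.null(vb)) {
      validation$bootstrap <- stage("validate_bootstrap", {
        do.call(bootstrap_stability, c(
          list(expr = expr, clinical = clinical,
               patients = groups[[vb$group %||% "AC:NC"]],
               seed = config$seed + 2L, k_min = config$k_min,
               k_max = config$k_max, fdr = config$fdr),
          vb[setdiff(names(vb), "group")]))
      })
    }
  }

  excluded <- if (!is.null(fit)) fit$excluded else
    data.frame(patient_id = clinical$patient_id,
               reason = "DDPP fit failed", stringsAsFactors = FALSE)
  report <- structure(
    list(seed = config$seed,
         config = config_echo(config),
         cohort = list(
           n_patients = nrow(clinical),
           group_sizes = vapply(suppressWarnings(partition_groups(clinical)),
                                length, integer(1)),
           n_chemo = sum(clinical$chemo),
           n_surgery_only = sum(!clinical$chemo),
           histology_counts = table(clinical$histology),
           n_full_clinical = sum(clinical$stage != "undetermined"),
           n_undetermined_stage = sum(clinical$stage == "undetermined")),
         fit = fit, immune = imm, km_suite = km_suite, cox = cox,
         validation = validation, truth = truth, excluded = excluded,
         errors = errors, log = logbuf),
    class = "ddpp_report")
  logmsg("pipeline finished with ", length(errors), " stage error(s)")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_echo <- function(config) {
  list(immune_genes = config$immune_genes,
       competent_rule = config$competent_rule,
       k_min = config$k_min, k_max = config$k_max, fdr = config$fdr,
       seed = config$seed,
       synthetic = !is.null(config$synth),
       synth = if (!is.null(config$synth))
         config$synth[c("n_genes", "group_sizes", "signature_sizes",
                        "noise_sd", "dfs_range_months", "seed")])
}

#' @export
print.ddpp_report <- function(x, ...) {
  cat("DDPP pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  cohort:", x$cohort$n_patients, "patients;",
      x$cohort$n_full_clinical, "with full clinical data\n")
  if (!is.null(x$fit))
    cat("  correlators:", length(x$fit$correlators), "fitted;",
        nrow(x$fit$scores), "patients scored\n")
  if (!is.null(x$km_suite))
    cat("  KM comparisons:", length(x$km_suite$comparisons), "produced,",
        length(x$km_suite$skipped), "skipped\n")
  if (length(x$errors) > 0)
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Stratified Kaplan-Meier comparison suite
#'
#' Produces the standard panel of DFS comparisons: TNM stage splits (1+2 vs
#' 3+4; 1 vs >1), DDPP high vs low (overall and within stages 1+2),
#' chemotherapy vs none within stage 1+2 for each DDPP class, the three
#' single-gene immune splits, the CTLA-4 split within PD-L1-high, within
#' ICOS-high, and within PD-L1+ICOS-high, and the three-arm combination of
#' DDPP class with immune status (DDPP-low tolerant vs DDPP-high competent
#' vs all other combinations). Patients with undetermined stage are
#' excluded from stage-stratified comparisons only. Comparisons with an
#' empty arm are skipped with a warning and recorded.
#'
#' @param scores data.frame with `patient_id`, `class` (from a `"ddpp"`
#'   fit).
#' @param immune an `"immune_status"` object (or NULL to skip immune
#'   comparisons).
#' @param clinical validated clinical table.
#' @return list with `comparisons` (named list; each has `name`, `arms`
#'   (per-arm n), `km` (per-arm [km_estimate()] curves), `medians`,
#'   `logrank`) and `skipped` (named reasons).
#' @export
stratified_km_suite <- function(scores, immune, clinical) {
  clin <- as.data.frame(clinical)
  comparisons <- list()
  skipped <- character(0)

  arm_of <- function(ids, label) {
    if (length(ids) == 0) return(NULL)
    data.frame(patient_id = ids, arm = label, stringsAsFactors = FALSE)
  }
  add <- function(name, ...) {
    arms <- Filter(Negate(is.null), list(...))
    if (length(arms) < 2) {
      skipped[[name]] <<- "fewer than 2 non-empty arms"
      warning("comparison ", name, " skipped: fewer than 2 non-empty arms")
      return(invisible(NULL))
    }
    dat <- do.call(rbind, arms)
    idx <- match(dat$patient_id, clin$patient_id)
    times <- clin$dfs_months[idx]; events <- clin$event[idx]
    lr <- tryCatch(logrank_test(times, events, dat$arm),
                   error = function(e) conditionMessage(e))
    if (is.character(lr)) {
      skipped[[name]] <<- lr
      warning("comparison ", name, " skipped: ", lr)
      return(invisible(NULL))
    }
    km <- lapply(split(seq_len(nrow(dat)), dat$arm), function(i)
      km_estimate(times[i], events[i]))
    comparisons[[name]] <<- list(
      name = name,
      arms = vapply(split(dat$patient_id, dat$arm), length, integer(1)),
      km = km,
      medians = vapply(km, function(k) attr(k, "median"), numeric(1)),
      logrank = lr)
    invisible(NULL)
  }

  staged <- clin[clin$stage != "undetermined", ]
  early <- staged$patient_id[staged$stage %in% c("1", "2")]
  late <- staged$patient_id[staged$stage %in% c("3", "4")]
  add("stage_1_2_vs_3_4",
      arm_of(early, "stage 1+2"), arm_of(late, "stage 3+4"))
  add("stage_1_vs_above",
      arm_of(staged$patient_id[staged$stage == "1"], "stage 1"),
      arm_of(staged$patient_id[staged$stage != "1"], "stage >1"))

  has_class <- !is.na(scores$class)
  hi <- scores$patient_id[has_class & scores$class == "high"]
  lo <- scores$patient_id[has_class & scores$class == "low"]
  add("ddpp_high_vs_low", arm_of(hi, "DDPP high"), arm_of(lo, "DDPP low"))
  add("ddpp_within_stage_1_2",
      arm_of(intersect(hi, early), "DDPP high"),
      arm_of(intersect(lo, early), "DDPP low"))
  chemo_ids <- clin$patient_id[clin$chemo]
  nc_ids <- clin$patient_id[!clin$chemo]
  add("chemo_within_stage_1_2_ddpp_low",
      arm_of(intersect(intersect(lo, early), nc_ids), "NC"),
      arm_of(intersect(intersect(lo, early), chemo_ids), "chemo"))
  add("chemo_within_stage_1_2_ddpp_high",
      arm_of(intersect(intersect(hi, early), nc_ids), "NC"),
      arm_of(intersect(intersect(hi, early), chemo_ids), "chemo"))

  if (!is.null(immune)) {
    tab <- immune$table
    genes <- immune$genes
    gh <- lapply(genes, function(g) tab$patient_id[tab[[g]] == "high"])
    gl <- lapply(genes, function(g) tab$patient_id[tab[[g]] == "low"])
    names(gh) <- names(gl) <- genes
    for (g in genes)
      add(paste0(g, "_high_vs_low"),
          arm_of(gh[[g]], paste(g, "high")), arm_of(gl[[g]], paste(g, "low")))
    ctla4 <- genes[1]; pdl1 <- genes[2]; icos <- genes[3]
    add(paste0(ctla4, "_within_", pdl1, "_high"),
        arm_of(intersect(gl[[ctla4]], gh[[pdl1]]), paste(ctla4, "low")),
        arm_of(intersect(gh[[ctla4]], gh[[pdl1]]), paste(ctla4, "high")))
    add(paste0(ctla4, "_within_", icos, "_high"),
        arm_of(intersect(gl[[ctla4]], gh[[icos]]), paste(ctla4, "low")),
        arm_of(intersect(gh[[ctla4]], gh[[icos]]), paste(ctla4, "high")))
    both_high <- intersect(gh[[pdl1]], gh[[icos]])
    add("triple_immune",
        arm_of(intersect(gl[[ctla4]], both_high), "tolerogenic absent"),
        arm_of(intersect(gh[[ctla4]], both_high), "tolerant"))
    tolerant <- tab$patient_id[tab$status == "tolerant"]
    competent <- tab$patient_id[tab$status == "competent"]
    called <- tab$patient_id
    arm1 <- intersect(lo, tolerant)
    arm2 <- intersect(hi, competent)
    scored_called <- intersect(scores$patient_id[has_class], called)
    arm3 <- setdiff(scored_called, c(arm1, arm2))
    add("ddpp_immune_3arm",
        arm_of(arm1, "DDPP low + tolerant"),
        arm_of(arm2, "DDPP high + competent"),
        arm_of(arm3, "other combinations"))
  }
  list(comparisons = comparisons, skipped = skipped)
}

# univariate + multivariate Cox models on stage group, histology, DDPP
# class and immune status; fitted on patients with the relevant covariates
pipeline_cox <- function(scores, immune, clinical) {
  clin <- as.data.frame(clinical)
  dat <- data.frame(patient_id = clin$patient_id,
                    time = clin$dfs_months, event = clin$event,
                    stringsAsFactors = FALSE)
  dat$stage_group <- factor(ifelse(clin$stage %in% c("1", "2"), "1+2",
                            ifelse(clin$stage %in% c("3", "4"), "3+4", NA)),
                            levels = c("1+2", "3+4"))
  dat$histology <- clin$histology
  idx <- match(dat$patient_id, scores$patient_id)
  dat$ddpp <- factor(as.character(scores$class[idx]), levels = c("high", "low"))
  if (!is.null(immune)) {
    jdx <- match(dat$patient_id, immune$table$patient_id)
    dat$immune <- factor(as.character(immune$table$status[jdx]),
                         levels = c("competent", "tolerant", "other"))
  }
  covars <- intersect(c("stage_group", "histology", "ddpp", "immune"), names(dat))
  fit_one <- function(cols) {
    keep <- stats::complete.cases(dat[cols])
    tryCatch(cox_fit(dat[keep, cols, drop = FALSE],
                     dat$time[keep], dat$event[keep]),
             error = function(e) conditionMessage(e))
  }
  univariate <- lapply(covars, function(v) fit_one(v))
  names(univariate) <- covars
  multivariate <- fit_one(covars)
  ok_uni <- Filter(function(f) inherits(f, "ddpp_cox") && f$converged, univariate)
  forest <- tryCatch({
    fits <- ok_uni
    if (inherits(multivariate, "ddpp_cox") && multivariate$converged)
      fits <- c(fits, list(multivariate = multivariate))
    if (length(fits) > 0) build_forest_table(fits) else NULL
  }, error = function(e) NULL)
  list(univariate = univariate, multivariate = multivariate, forest = forest)
}
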