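#' Kaplan-Meier curve for one arm
#'
#' Product-limit estimator of the DFS distribution. The median is the
#' smallest time at which the survival probability drops to 0.5 or below
#' (NA when the curve never reaches 0.5).
#'
#' @param times positive event/censoring times (months).
#' @param events logical (or 0/1) recurrence indicators.
#' @return object of class `"km_curve"`: data.frame (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`) with attributes `median` and `n`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1) stop("empty input")
  if (any(times <= 0)) stop("times must be positive")
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  med <- if (any(curve$surv <= 0.5)) min(curve$time[curve$surv <= 0.5]) else NA_real_
  structure(curve, median = med, n = length(times),
            class = c("km_curve", class(curve)))
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", attr(x, "n"), "| median =",
      if (is.na(attr(x, "median"))) "not reached" else
        sprintf("%.1f months", attr(x, "median")), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Log-rank test across survival groups
#'
#' Standard log-rank chi-square comparison of two or more survival
#' distributions (hypergeometric variance at each distinct event time),
#' with `groups - 1` degrees of freedom.
#'
#' @param times positive times.
#' @param events logical recurrence indicators (>= 1 event overall).
#' @param group factor/vector of group labels (every level non-empty).
#' @return object of class `"logrank_test"`: list with `chisq`, `df`, `p`,
#'   `observed`, `expected`, `n` (per group).
#' @export
logrank_test <- function(times, events, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least 2 non-empty groups")
  if (any(table(group) == 0)) stop("a group has zero patients")
  events <- as.logical(events)
  if (sum(events) < 1) stop("need at least one event overall")
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1
  p <- stats::pchisq(sd_fit$chisq, df = df, lower.tail = FALSE)
  structure(list(chisq = unname(sd_fit$chisq), df = df, p = p,
                 observed = stats::setNames(as.numeric(sd_fit$obs), levels(group)),
                 expected = stats::setNames(as.numeric(sd_fit$exp), levels(group)),
                 n = table(group)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.3f on %d df, p = %.3g\n",
              x$chisq, x$df, x$p))
  print(data.frame(n = as.integer(x$n), observed = x$observed,
                   expected = x$expected))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood Cox regression (Efron tie handling) with Wald
#' confidence intervals and p-values per coefficient. Categorical covariates
#' are expanded against their first factor level as reference.
#'
#' @param covariates data.frame of covariates (numeric, logical or factor);
#'   no covariate may be constant.
#' @param times positive times.
#' @param events logical recurrence indicators; the number of events must be
#'   at least the number of covariate columns.
#' @return object of class `"ddpp_cox"`: list with `table` (term, hr,
#'   ci_lower, ci_upper, p), `loglik`, `aic`, `converged`, `n`, `n_events`,
#'   `reference` (named reference levels of factor covariates).
#' @export
cox_fit <- function(covariates, times, events) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 1) stop("need at least one covariate")
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.character(v)) covariates[[nm]] <- v <- factor(v)
    if (is.factor(v)) v <- droplevels(v)
    if (length(unique(stats::na.omit(v))) < 2)
      stop("constant covariate: ", nm)
    if (is.factor(covariates[[nm]])) covariates[[nm]] <- droplevels(covariates[[nm]])
  }
  events <- as.logical(events)
  if (sum(events) < ncol(covariates))
    stop("fewer events than covariates")
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fit <- survival::coxph(
    stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", names(covariates)), collapse = " + "))),
    data = dat, ties = "efron")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- !any(is.na(beta)) && all(is.finite(se)) &&
    fit$iter < 20 && all(abs(beta) < 15)
  z <- beta / se
  tab <- data.frame(
    term = names(beta),
    hr = exp(beta),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  loglik <- fit$loglik[length(fit$loglik)]
  refs <- vapply(covariates, function(v)
    if (is.factor(v)) levels(v)[1] else NA_character_, character(1))
  structure(list(table = tab, loglik = loglik,
                 aic = 2 * length(beta) - 2 * loglik,
                 converged = converged, n = length(times),
                 n_events = sum(events), reference = refs[!is.na(refs)],
                 coxph = fit),
            class = "ddpp_cox")
}

#' @export
print.ddpp_cox <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d, loglik = %.3f, AIC = %.2f%s\n",
              x$n, x$n_events, x$loglik, x$aic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$table, digits = 4)
  if (length(x$reference) > 0)
    cat("Reference levels:",
        paste(names(x$reference), x$reference, sep = " = ", collapse = "; "), "\n")
  invisible(x)
}

#' Tidy forest-plot table from Cox fits
#'
#' Stacks one or more converged Cox fits into the tidy rows a forest plot
#' consumes, with reference-level annotations for categorical covariates
#' and conventional significance markers (* < 0.05, ** < 0.01,
#' *** < 0.001).
#'
#' @param fits a single `"ddpp_cox"` fit or a (optionally named) list of
#'   them.
#' @return data.frame with columns `model`, `term`, `hr`, `ci_lower`,
#'   `ci_upper`, `p`, `signif`, `reference`.
#' @export
build_forest_table <- function(fits) {
  if (inherits(fits, "ddpp_cox")) fits <- list(model = fits)
  if (length(fits) < 1) stop("need at least one fit")
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  conv <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(conv)) stop("no converged fit to tabulate")
  rows <- lapply(names(fits)[conv], function(nm) {
    f <- fits[[nm]]
    tab <- f$table
    tab$model <- nm
    tab$signif <- cut(tab$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                      labels = c("***", "**", "*", ""))
    tab$reference <- ""
    for (cov in names(f$reference)) {
      hit <- startsWith(tab$term, cov)
      tab$reference[hit] <- paste0("ref: ", cov, " = ", f$reference[[cov]])
    }
    tab[, c("model", "term", "hr", "ci_lower", "ci_upper", "p", "signif",
            "reference")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
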