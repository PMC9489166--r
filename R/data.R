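#' Paired tumor/normal expression container
#'
#' Holds linear-scale expression intensities for tumor and patient-matched
#' normal tissue over a shared gene and patient index.
#'
#' @param tumor,normal numeric genes x patients matrices with identical
#'   dimnames; all values strictly positive, no missing entries.
#' @return object of class `"paired_expression"`: list with `tumor`,
#'   `normal`, `gene_ids`, `patient_ids`.
#' @export
paired_expression <- function(tumor, normal) {
  if (!is.matrix(tumor) || !is.matrix(normal))
    stop("tumor and normal must be matrices")
  if (is.null(rownames(tumor)) || is.null(colnames(tumor)))
    stop("matrices must carry gene rownames and patient colnames")
  if (!identical(dim(tumor), dim(normal)) ||
      !identical(rownames(tumor), rownames(normal)) ||
      !identical(colnames(tumor), colnames(normal)))
    stop("tumor and normal must share identical gene and patient indices")
  if (anyDuplicated(rownames(tumor)))
    stop("duplicate gene id: ", rownames(tumor)[anyDuplicated(rownames(tumor))])
  if (any(is.na(tumor)) || any(is.na(normal)))
    stop("missing intensities are not allowed")
  if (any(tumor <= 0) || any(normal <= 0))
    stop("all intensities must be strictly positive")
  structure(
    list(tumor = tumor, normal = normal,
         gene_ids = rownames(tumor), patient_ids = colnames(tumor)),
    class = "paired_expression"
  )
}

#' @export
print.paired_expression <- function(x, ...) {
  cat("Paired tumor/normal expression:", length(x$gene_ids), "genes x",
      length(x$patient_ids), "patients\n")
  invisible(x)
}

HISTOLOGIES <- c("AC", "SCC", "LCC")
STAGE_LEVELS <- c("1", "2", "3", "4", "undetermined")
GROUP_KEYS <- c("AC:NC", "AC:CT", "SCC:NC", "SCC:CT", "LCC:NC", "LCC:CT")

#' Validate a per-patient clinical table
#'
#' Coerces and checks the clinical covariates the pipeline uses: histology
#' (AC/SCC/LCC), TNM stage (1-4 or undetermined), adjuvant-chemotherapy flag,
#' disease-free survival in months, and the recurrence-event flag.
#'
#' @param x data.frame with columns `patient_id`, `histology`, `stage`,
#'   `chemo`, `dfs_months`, `event`.
#' @return validated data.frame (class `"cohort_clinical"` prepended) with
#'   `histology` and `stage` as factors, `chemo`/`event` logical,
#'   `dfs_months` numeric.
#' @export
cohort_clinical <- function(x) {
  required <- c("patient_id", "histology", "stage", "chemo", "dfs_months", "event")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  x <- as.data.frame(x)[required]
  x$patient_id <- as.character(x$patient_id)
  if (anyDuplicated(x$patient_id))
    stop("duplicate patient_id in clinical table")
  hist <- toupper(trimws(as.character(x$histology)))
  bad <- setdiff(unique(hist), HISTOLOGIES)
  if (length(bad) > 0)
    stop("unknown histology token(s): ", paste(bad, collapse = ", "))
  x$histology <- factor(hist, levels = HISTOLOGIES)
  stage <- trimws(as.character(x$stage))
  stage[!(stage %in% c("1", "2", "3", "4"))] <- "undetermined"
  x$stage <- factor(stage, levels = STAGE_LEVELS)
  x$chemo <- parse_flag(x$chemo, yes = c("1", "TRUE", "T", "CT", "YES"),
                        no = c("0", "FALSE", "F", "NC", "NO"), what = "chemo")
  x$event <- parse_flag(x$event, yes = c("1", "TRUE", "T", "YES"),
                        no = c("0", "FALSE", "F", "NO"), what = "event")
  x$dfs_months <- as.numeric(x$dfs_months)
  if (any(is.na(x$dfs_months)) || any(x$dfs_months <= 0))
    stop("dfs_months must be positive for every patient")
  class(x) <- c("cohort_clinical", class(x))
  x
}

parse_flag <- function(v, yes, no, what) {
  tok <- toupper(trimws(as.character(v)))
  out <- rep(NA, length(tok))
  out[tok %in% yes] <- TRUE
  out[tok %in% no] <- FALSE
  if (any(is.na(out)))
    stop("unparseable ", what, " value(s): ",
         paste(unique(tok[is.na(out)]), collapse = ", "))
  out
}

group_key <- function(histology, chemo) {
  paste0(as.character(histology), ":", ifelse(chemo, "CT", "NC"))
}

#' Partition a cohort into the six histology-by-treatment groups
#'
#' Every patient with non-missing histology and chemotherapy flag is assigned
#' to exactly one of AC:NC, AC:CT, SCC:NC, SCC:CT, LCC:NC, LCC:CT. Empty
#' groups are permitted but flagged with a warning.
#'
#' @param clinical validated clinical table (see [cohort_clinical()]).
#' @return named list of patient-id vectors, one entry per group key.
#' @export
partition_groups <- function(clinical) {
  clinical <- as.data.frame(clinical)
  keys <- group_key(clinical$histology, clinical$chemo)
  out <- lapply(GROUP_KEYS, function(k) clinical$patient_id[keys == k])
  names(out) <- GROUP_KEYS
  empty <- GROUP_KEYS[lengths(out) == 0]
  if (length(empty) > 0)
    warning("empty group(s): ", paste(empty, collapse = ", "))
  out
}
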