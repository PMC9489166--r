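#' Read a paired expression TSV
#'
#' The file has one gene per row: a first column of gene ids followed by one
#' column per sample, named `<patient>_T` (tumor) or `<patient>_N` (normal).
#' Patients possessing both tissue columns are retained; patients with only
#' one tissue are dropped with a warning.
#'
#' @param path path to a tab-separated file.
#' @return a [paired_expression] object.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a gene column plus sample columns")
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[anyDuplicated(gene_ids)])
  samples <- names(df)[-1]
  tissue <- sub("^.*_", "", samples)
  patient <- sub("_[TN]$", "", samples)
  if (!all(tissue %in% c("T", "N")))
    stop("sample columns must be named <patient>_T or <patient>_N; offending: ",
         paste(samples[!tissue %in% c("T", "N")], collapse = ", "))
  paired <- intersect(patient[tissue == "T"], patient[tissue == "N"])
  unpaired <- setdiff(unique(patient), paired)
  if (length(unpaired) > 0)
    warning("dropping patient(s) missing one tissue: ",
            paste(unpaired, collapse = ", "))
  if (length(paired) == 0) stop("no patient has both tumor and normal columns")
  get_mat <- function(suffix) {
    cols <- paste0(paired, suffix)
    m <- as.matrix(df[, cols, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(df[cols], is.numeric, logical(1)))
      stop("non-numeric intensities in sample ", cols[bad[1]])
    }
    nonpos <- which(m <= 0 | is.na(m), arr.ind = TRUE)
    if (nrow(nonpos) > 0)
      stop("non-positive or missing intensity for gene ",
           gene_ids[nonpos[1, 1]], ", sample ", cols[nonpos[1, 2]])
    dimnames(m) <- list(gene_ids, paired)
    m
  }
  paired_expression(get_mat("_T"), get_mat("_N"))
}

#' Write a paired expression TSV
#'
#' Inverse of [read_expression()]: columns `gene_id`, then `<patient>_T` and
#' `<patient>_N` for each patient.
#'
#' @param expr a [paired_expression] object.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "paired_expression"))
  cols <- list(gene_id = expr$gene_ids)
  for (p in expr$patient_ids) {
    cols[[paste0(p, "_T")]] <- expr$tumor[, p]
    cols[[paste0(p, "_N")]] <- expr$normal[, p]
  }
  utils::write.table(as.data.frame(cols, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical CSV
#'
#' Expects columns `patient_id`, `histology`, `stage`, `chemo`,
#' `dfs_months`, `event`. Stage tokens outside 1-4 (e.g. "NA") become
#' `undetermined`; chemo accepts 0/1, true/false, NC/CT.
#'
#' @param path path to a comma-separated file.
#' @return validated clinical table (see [cohort_clinical()]).
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  cohort_clinical(df)
}

#' Write a clinical CSV
#'
#' @param clinical validated clinical table.
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  df <- as.data.frame(clinical)
  df$chemo <- ifelse(df$chemo, "CT", "NC")
  df$event <- as.integer(df$event)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
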