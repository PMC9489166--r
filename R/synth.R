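#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every parameter of the synthetic NSCLC cohort: the
#' six histology-by-treatment group sizes, per-group planted signature sizes
#' and linear DFS links, the DFS range, noise levels, the background
#' intensity range, and the immune-checkpoint mixture design.
#'
#' Defaults emulate the study design the pipeline targets: 123 patients in
#' groups of 24/33/32/18/6/10 (AC:NC, AC:CT, SCC:NC, SCC:CT, LCC:NC,
#' LCC:CT), ~19,500 genes, DFS uniform on 3-92 months, signature sizes
#' 10/10/15/7/5/10 with the LCC:NC signature weighted by normal-tissue
#' intensity and all others by tumor intensity, three bimodal
#' immune-checkpoint genes in normal tissue, 28 planted immune-tolerant
#' patients among those with full clinical data, and 3 patients with
#' undetermined TNM stage.
#'
#' @param n_genes total number of genes (immune genes included).
#' @param group_sizes named integer vector over the six group keys.
#' @param signature_sizes named integer vector: planted signature size per
#'   group (0 = no signature).
#' @param signature_sources named character vector per group, `"tumor"` or
#'   `"normal"`: which tissue's intensity enters the planted weights.
#' @param link_slope,link_intercept per-group linear link, DFS =
#'   intercept + slope x mean planted-gene weight (months). Scalars are
#'   recycled over groups.
#' @param dfs_range_months length-2 positive vector, min < max.
#' @param noise_sd residual SD of the per-gene weight around its DFS link.
#'   The default keeps the planted signal FDR-detectable even in the
#'   smallest (n = 6) group, so the default cohort yields all six group
#'   correlators; raise it to stress-test selection and stability.
#' @param dispersion_sd SD of the within-signature gene-to-gene dispersion;
#'   it sums to zero across the signature for every patient, so the
#'   signature-mean weight stays an exact affine function of DFS when
#'   `noise_sd = 0` while individual genes and strict subsets are imperfect.
#' @param intensity_log2_range background log2-intensity bounds (positive).
#' @param immune_genes gene ids of the immune-checkpoint genes (order
#'   matters: the combined-status rules refer to the first gene (CTLA-4
#'   role) versus the remaining two (PD-L1, ICOS roles)).
#' @param immune_high_fraction named fractions: marginal probability of the
#'   high component for non-planted patients.
#' @param immune_mixture low/high component means and common SD on the log2
#'   scale (default separation 8 SD).
#' @param immune_tolerant_count exact number of planted all-high
#'   (immune-tolerant) patients among patients with determined stage.
#' @param missing_stage_count patients assigned stage `undetermined`.
#' @param stage_prob sampling weights of stages 1-4.
#' @param censor_fraction fraction of patients with a censored DFS
#'   (`event = FALSE`); default 0 (every patient relapses, as in a cohort
#'   followed until the last recurrence).
#' @param seed integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return validated object of class `"synth_config"`.
#' @export
synth_config <- function(n_genes = 19500,
                         group_sizes = c("AC:NC" = 24, "AC:CT" = 33,
                                         "SCC:NC" = 32, "SCC:CT" = 18,
                                         "LCC:NC" = 6, "LCC:CT" = 10),
                         signature_sizes = c("AC:NC" = 10, "AC:CT" = 10,
                                             "SCC:NC" = 15, "SCC:CT" = 7,
                                             "LCC:NC" = 5, "LCC:CT" = 10),
                         signature_sources = c("AC:NC" = "tumor", "AC:CT" = "tumor",
                                               "SCC:NC" = "tumor", "SCC:CT" = "tumor",
                                               "LCC:NC" = "normal", "LCC:CT" = "tumor"),
                         link_slope = 5, link_intercept = 47.5,
                         dfs_range_months = c(3, 92),
                         noise_sd = 0.15, dispersion_sd = 0.05,
                         intensity_log2_range = c(5, 14),
                         immune_genes = c("CTLA4", "PDL1", "ICOS"),
                         immune_high_fraction = c(CTLA4 = 0.5, PDL1 = 0.5, ICOS = 0.5),
                         immune_mixture = c(low_mean = 6, high_mean = 10, sd = 0.5),
                         immune_tolerant_count = 28,
                         missing_stage_count = 3,
                         stage_prob = c(56, 27, 32, 5),
                         censor_fraction = 0,
                         seed = 1L) {
  if (n_genes < 1) stop("n_genes must be positive")
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% GROUP_KEYS))
    stop("group_sizes must be named with histology:treatment keys among ",
         paste(GROUP_KEYS, collapse = ", "))
  if (any(group_sizes < 0)) stop("group sizes must be non-negative")
  if (sum(group_sizes) < 1) stop("cohort must contain at least one patient")
  unknown <- setdiff(names(signature_sizes), names(group_sizes))
  if (length(unknown) > 0)
    stop("signature_sizes references unknown group(s): ",
         paste(unknown, collapse = ", "))
  if (any(signature_sizes < 0)) stop("signature sizes must be non-negative")
  if (length(dfs_range_months) != 2 || dfs_range_months[1] <= 0 ||
      dfs_range_months[1] >= dfs_range_months[2])
    stop("dfs_range_months must satisfy 0 < min < max")
  if (noise_sd < 0 || dispersion_sd < 0) stop("noise/dispersion SDs must be >= 0")
  if (length(intensity_log2_range) != 2 || intensity_log2_range[1] <= 0 ||
      intensity_log2_range[1] >= intensity_log2_range[2])
    stop("intensity_log2_range must satisfy 0 < lo < hi")
  groups <- names(group_sizes)
  sig <- stats::setNames(rep(0L, length(groups)), groups)
  sig[names(signature_sizes)] <- as.integer(signature_sizes)
  src <- stats::setNames(rep("tumor", length(groups)), groups)
  src[names(signature_sources)] <- signature_sources
  if (!all(src %in% c("tumor", "normal")))
    stop("signature_sources entries must be 'tumor' or 'normal'")
  slope <- rep_len(link_slope, length(groups)); names(slope) <- groups
  if (!is.null(names(link_slope))) slope[names(link_slope)] <- link_slope
  if (any(slope == 0)) stop("link_slope must be non-zero")
  icept <- rep_len(link_intercept, length(groups)); names(icept) <- groups
  if (!is.null(names(link_intercept))) icept[names(link_intercept)] <- link_intercept
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("censor_fraction must lie in [0, 1)")
  if (immune_tolerant_count < 0 || missing_stage_count < 0)
    stop("counts must be non-negative")
  if (immune_tolerant_count > sum(group_sizes) - missing_stage_count)
    stop("immune_tolerant_count exceeds the number of fully documented patients")
  structure(
    list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
         signature_sizes = sig, signature_sources = src,
         link_slope = slope, link_intercept = icept,
         dfs_range_months = dfs_range_months, noise_sd = noise_sd,
         dispersion_sd = dispersion_sd,
         intensity_log2_range = intensity_log2_range,
         immune_genes = immune_genes,
         immune_high_fraction = immune_high_fraction,
         immune_mixture = immune_mixture,
         immune_tolerant_count = as.integer(immune_tolerant_count),
         missing_stage_count = as.integer(missing_stage_count),
         stage_prob = stage_prob, censor_fraction = censor_fraction,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic paired-expression cohort with planted signatures
#'
#' Draws a cohort with the statistical structure the DDPP analysis assumes:
#' per-group gene signatures whose mean weight is linearly linked to DFS,
#' an exchangeable background transcriptome, and bimodal immune-checkpoint
#' expression in normal tissue with a planted tolerant subgroup. Ground
#' truth is returned for parameter-recovery tests.
#'
#' @param config a [synth_config()] object.
#' @return list with elements `expression` ([paired_expression]), `clinical`
#'   (validated clinical table), and `truth`: planted gene sets, per-group
#'   link slope/intercept (on the signature-mean scale) and intensity
#'   source, per-patient immune membership, and the planted tolerant ids.
#' @export
generate_cohort <- function(config) {
  generate_impl(config, plant = TRUE)
}

#' Generate a null cohort with no planted signatures
#'
#' Identical machinery to [generate_cohort()] but every gene weight is
#' statistically independent of DFS — the null reference for the
#' random-gene-set specificity design.
#'
#' @param config a [synth_config()] object.
#' @return list with elements `expression` and `clinical`.
#' @export
generate_null_cohort <- function(config) {
  out <- generate_impl(config, plant = FALSE)
  out[c("expression", "clinical")]
}

generate_impl <- function(config, plant) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  sizes <- config$group_sizes[config$group_sizes > 0]
  n_pat <- sum(sizes)
  patient_ids <- sprintf("P%03d", seq_len(n_pat))
  group <- rep(names(sizes), sizes)

  immune <- config$immune_genes
  has_immune <- config$n_genes >= length(immune) && length(immune) > 0
  n_bg <- config$n_genes - if (has_immune) length(immune) else 0L
  gene_ids <- c(if (has_immune) immune, sprintf("G%05d", seq_len(n_bg)))

  dfs <- stats::runif(n_pat, config$dfs_range_months[1], config$dfs_range_months[2])
  event <- stats::runif(n_pat) >= config$censor_fraction
  stage <- sample(c("1", "2", "3", "4"), n_pat, replace = TRUE,
                  prob = config$stage_prob)
  if (config$missing_stage_count > 0)
    stage[sample.int(n_pat, config$missing_stage_count)] <- "undetermined"

  rng <- config$intensity_log2_range
  log2t <- matrix(stats::runif(config$n_genes * n_pat, rng[1], rng[2]),
                  nrow = config$n_genes, dimnames = list(gene_ids, patient_ids))
  log2n <- matrix(stats::runif(config$n_genes * n_pat, rng[1], rng[2]),
                  nrow = config$n_genes, dimnames = list(gene_ids, patient_ids))

  planted <- list()
  if (plant) {
    pool <- setdiff(gene_ids, if (has_immune) immune else character(0))
    sig <- config$signature_sizes[names(sizes)]
    need <- sum(sig)
    if (need > length(pool))
      stop("not enough genes to plant all signatures: need ", need,
           " of ", length(pool))
    chosen <- sample(pool, need)
    offset <- 0L
    log2_11 <- log2(1.1)
    for (g in names(sizes)) {
      s <- sig[[g]]
      if (s == 0) next
      genes <- chosen[offset + seq_len(s)]
      offset <- offset + s
      pats <- patient_ids[group == g]
      m <- length(pats)
      target <- (dfs[match(pats, patient_ids)] - config$link_intercept[[g]]) /
        config$link_slope[[g]]
      disp <- matrix(0, nrow = s, ncol = m)
      if (s > 1) {
        disp[seq_len(s - 1), ] <- stats::rnorm((s - 1) * m, 0, config$dispersion_sd)
        disp[s, ] <- -colSums(disp[seq_len(s - 1), , drop = FALSE])
      }
      noise <- matrix(stats::rnorm(s * m, 0, config$noise_sd), nrow = s)
      w <- matrix(target, nrow = s, ncol = m, byrow = TRUE) + disp + noise
      if (config$signature_sources[[g]] == "tumor") {
        l2i <- log2t[genes, pats, drop = FALSE]
        log2n[genes, pats] <- l2i - w * log2_11 / l2i
      } else {
        l2i <- log2n[genes, pats, drop = FALSE]
        log2t[genes, pats] <- l2i + w * log2_11 / l2i
      }
      planted[[g]] <- genes
    }
  }

  membership <- NULL
  if (has_immune) {
    staged <- patient_ids[stage != "undetermined"]
    tolerant_ids <- sample(staged, config$immune_tolerant_count)
    frac <- config$immune_high_fraction[immune]
    combos <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), length(immune))))
    colnames(combos) <- immune
    all_high <- rowSums(combos) == length(immune)
    probs <- apply(combos, 1, function(h) prod(ifelse(h, frac, 1 - frac)))
    probs[all_high] <- 0  # tolerant membership is planted exactly, not sampled
    others <- setdiff(patient_ids, tolerant_ids)
    pick <- sample.int(nrow(combos), length(others), replace = TRUE,
                       prob = probs / sum(probs))
    high <- matrix(TRUE, nrow = length(immune), ncol = n_pat,
                   dimnames = list(immune, patient_ids))
    high[, others] <- t(combos[pick, , drop = FALSE])
    mix <- config$immune_mixture
    mu <- ifelse(high, mix[["high_mean"]], mix[["low_mean"]])
    log2n[immune, ] <- mu + stats::rnorm(length(mu), 0, mix[["sd"]])
    membership <- immune_membership_from_calls(high)
  }

  clinical <- cohort_clinical(data.frame(
    patient_id = patient_ids,
    histology = sub(":.*$", "", group),
    stage = stage,
    chemo = ifelse(grepl(":CT$", group), "CT", "NC"),
    dfs_months = dfs,
    event = ifelse(event, 1, 0),
    stringsAsFactors = FALSE
  ))
  expr <- paired_expression(2^log2t, 2^log2n)

  truth <- list(
    planted_genes = planted,
    link_slope = config$link_slope[names(planted)],
    link_intercept = config$link_intercept[names(planted)],
    planted_source = config$signature_sources[names(planted)],
    immune_membership = membership,
    immune_high = if (has_immune) high else NULL,
    tolerant_ids = if (has_immune) sort(tolerant_ids) else character(0),
    seed = config$seed
  )
  list(expression = expr, clinical = clinical, truth = truth)
}

# combined tolerant/competent/other label from a genes x patients logical
# matrix of high calls (rows ordered CTLA-4 role first, then PD-L1, ICOS)
immune_membership_from_calls <- function(high) {
  status <- rep("other", ncol(high))
  status[colSums(high) == nrow(high)] <- "tolerant"
  status[!high[1, ] & colSums(high[-1, , drop = FALSE]) == nrow(high) - 1] <- "competent"
  stats::setNames(status, colnames(high))
}
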