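make_weight_obj <- function(w, source = "tumor") {
  structure(list(weights = w, source = source, gene_ids = rownames(w),
                 patient_ids = colnames(w)), class = "gene_weight_matrix")
}

simple_clinical <- function(ids, dfs) {
  cohort_clinical(data.frame(patient_id = ids, histology = "AC", stage = "1",
                             chemo = "NC", dfs_months = dfs, event = 1))
}

test_that("screening finds planted genes and rejects small groups", {
  coh <- generate_cohort(tiny_config(noise_sd = 0))
  cl <- coh$clinical
  g <- "AC:NC"
  pats <- cl$patient_id[cl$histology == "AC" & !cl$chemo]
  w <- gene_weight_matrix(coh$expression, "tumor")
  scr <- screen_genes(w, cl, pats)
  planted <- coh$truth$planted_genes[[g]]
  expect_true(all(scr$q[scr$gene_id %in% planted] < 0.05))
  # planted genes occupy the top ranks
  expect_setequal(scr$gene_id[scr$rank <= length(planted)], planted)
  expect_error(screen_genes(w, cl, pats[1:3]), "fewer than 4")
})

test_that("correlator fit is exact on collinear data and interpolates two points", {
  fit <- fit_correlator(c(1, 2, 3), c(5, 7, 9))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 3)
  expect_equal(fit$fit_r, 1)
  two <- fit_correlator(c(1, 3), c(10, 20))
  expect_equal(two$slope, 5)
  expect_equal(two$intercept, 5)
  expect_true(is.na(two$fit_p))
  expect_error(fit_correlator(c(2, 2, 2), 1:3), "constant")
})

test_that("predictor selection recovers planted signatures exactly without noise", {
  coh <- generate_cohort(tiny_config(noise_sd = 0))
  cl <- coh$clinical
  wt <- gene_weight_matrix(coh$expression, "tumor")
  wn <- gene_weight_matrix(coh$expression, "normal")
  for (g in names(coh$truth$planted_genes)) {
    pats <- cl$patient_id[paste0(cl$histology, ":",
                                 ifelse(cl$chemo, "CT", "NC")) == g]
    cor_g <- select_predictor(wt, wn, cl, pats, group = g)
    expect_setequal(cor_g$gene_ids, coh$truth$planted_genes[[g]])
    expect_equal(cor_g$intensity_source, coh$truth$planted_source[[g]])
    expect_gt(abs(cor_g$fit_r), 1 - 1e-12)
    expect_equal(cor_g$slope, coh$truth$link_slope[[g]], tolerance = 1e-8)
    expect_equal(cor_g$intercept, coh$truth$link_intercept[[g]], tolerance = 1e-8)
  }
})

test_that("selection errors on a null group with no significant genes", {
  nc <- generate_null_cohort(reduced_config(n_genes = 1500, seed = 8))
  cl <- nc$clinical
  pats <- cl$patient_id[cl$histology == "AC" & !cl$chemo]
  wt <- gene_weight_matrix(nc$expression, "tumor")
  wn <- gene_weight_matrix(nc$expression, "normal")
  expect_error(select_predictor(wt, wn, cl, pats, group = "AC:NC"),
               "no significant correlator")
})

test_that("exactly tied candidates resolve to the smallest k and mode order", {
  # four genes each a perfect affine image of DFS: every prefix ties at |r| = 1
  ids <- paste0("P", 1:8)
  dfs <- c(10, 25, 33, 41, 52, 60, 75, 88)
  w <- rbind(
    g1 = dfs, g2 = 2 * dfs + 1, g3 = 0.5 * dfs - 3, g4 = 3 * dfs,
    matrix(c(5, 3, 8, 1, 9, 2, 7, 4,
             2, 9, 4, 6, 1, 8, 3, 5), nrow = 2, byrow = TRUE,
           dimnames = list(c("n1", "n2"), NULL)))
  colnames(w) <- ids
  cl <- simple_clinical(ids, dfs)
  cor_g <- select_predictor(make_weight_obj(w), NULL, cl, ids,
                            sources = "tumor", k_min = 3, k_max = 4)
  expect_length(cor_g$gene_ids, 3)
  expect_equal(cor_g$aggregation, "median")
  expect_gt(abs(cor_g$fit_r), 1 - 1e-12)
})

test_that("scoring uses the group correlator and lists unscorable patients", {
  coh <- generate_cohort(tiny_config(noise_sd = 0))
  cl <- coh$clinical
  wt <- gene_weight_matrix(coh$expression, "tumor")
  wn <- gene_weight_matrix(coh$expression, "normal")
  pats <- cl$patient_id[cl$histology == "AC" & !cl$chemo]
  correlators <- list("AC:NC" = select_predictor(wt, wn, cl, pats, group = "AC:NC"))
  sc <- score_patients(correlators, wt, wn, cl)
  # noiseless limit: the score equals the true DFS for the fitted group
  obs <- cl$dfs_months[match(sc$scores$patient_id, cl$patient_id)]
  expect_equal(sc$scores$score, obs, tolerance = 1e-8)
  expect_setequal(sc$scores$patient_id, pats)
  expect_setequal(sc$excluded$patient_id, setdiff(cl$patient_id, pats))
  expect_match(sc$excluded$reason[1], "no correlator")
})

test_that("adding a constant to one group's DFS shifts its scores by that constant", {
  coh <- generate_cohort(tiny_config(noise_sd = 0.5, seed = 19))
  cl <- coh$clinical
  fit1 <- ddpp(coh$expression, cl, k_max = 8)
  shift <- 7
  cl2 <- cl
  idx <- cl2$histology == "AC" & !cl2$chemo
  cl2$dfs_months[idx] <- cl2$dfs_months[idx] + shift
  fit2 <- ddpp(coh$expression, cl2, k_max = 8)
  # same genes selected, so OLS re-centering moves scores by exactly the shift
  expect_setequal(fit2$correlators[["AC:NC"]]$gene_ids,
                  fit1$correlators[["AC:NC"]]$gene_ids)
  s1 <- fit1$scores[fit1$scores$group == "AC:NC", ]
  s2 <- fit2$scores[fit2$scores$group == "AC:NC", ]
  expect_equal(s2$score[match(s1$patient_id, s2$patient_id)],
               s1$score + shift, tolerance = 1e-6)
})

test_that("ddpp model object supports the standard methods", {
  coh <- generate_cohort(tiny_config(noise_sd = 0))
  fit <- ddpp(coh$expression, coh$clinical, k_max = 8)
  expect_s3_class(fit, "ddpp")
  expect_length(fit$correlators, 2)
  expect_equal(nrow(fit$scores), nrow(coh$clinical))

  cf <- coef(fit)
  expect_equal(dim(cf), c(2L, 2L))
  expect_equal(unname(cf[, "slope"]), c(5, 5), tolerance = 1e-8)

  obs <- coh$clinical$dfs_months[match(fit$scores$patient_id,
                                       coh$clinical$patient_id)]
  expect_equal(unname(fitted(fit)[fit$scores$patient_id]),
               fit$scores$score)
  expect_equal(unname(residuals(fit)), obs - fit$scores$score)

  # predict on the same cohort reproduces the fitted scores
  pred <- predict(fit, coh$expression, coh$clinical)
  expect_equal(pred$score[match(fit$scores$patient_id, pred$patient_id)],
               fit$scores$score)
  expect_output(print(fit), "DDPP fit")
  expect_output(print(summary(fit)), "correlators")
  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
})

test_that("pooled treatment arms degrade the predictor on treatment-linked signals", {
  # groups share histology but have different planted links, so pooling
  # treatment arms cannot fit both exactly
  cfg <- synth_config(n_genes = 400,
                      group_sizes = c("AC:NC" = 14, "AC:CT" = 14),
                      signature_sizes = c("AC:NC" = 5, "AC:CT" = 5),
                      link_intercept = c("AC:NC" = 20, "AC:CT" = 70),
                      noise_sd = 0, immune_tolerant_count = 5,
                      missing_stage_count = 0, seed = 23)
  coh <- generate_cohort(cfg)
  split_fit <- ddpp(coh$expression, coh$clinical, k_max = 8)
  pooled <- ddpp(coh$expression, coh$clinical, k_max = 8,
                 group_by = "histology")
  expect_gt(abs(split_fit$correlators[["AC:NC"]]$fit_r), 1 - 1e-10)
  pooled_cor <- pooled$correlators[["AC"]]
  expect_true(is.null(pooled_cor) || abs(pooled_cor$fit_r) < 0.9)
})
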