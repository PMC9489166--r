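test_that("default design constants are reproduced at reduced gene count", {
  coh <- generate_cohort(reduced_config(n_genes = 500, seed = 9))
  cl <- coh$clinical
  expect_equal(nrow(cl), 123)
  expect_equal(vapply(suppressWarnings(partition_groups(cl)), length, integer(1)),
               c("AC:NC" = 24L, "AC:CT" = 33L, "SCC:NC" = 32L,
                 "SCC:CT" = 18L, "LCC:NC" = 6L, "LCC:CT" = 10L))
  expect_equal(sum(cl$chemo), 61)
  expect_equal(sum(!cl$chemo), 62)
  expect_equal(as.integer(table(cl$histology)), c(57L, 50L, 16L))
  expect_equal(sum(cl$stage != "undetermined"), 120)
  expect_length(coh$truth$tolerant_ids, 28)
})

test_that("intensities and DFS respect their bounds and events default to observed", {
  coh <- generate_cohort(tiny_config(noise_sd = 1))
  expect_true(all(coh$expression$tumor > 1))
  expect_true(all(coh$expression$normal > 1))
  expect_true(all(coh$clinical$dfs_months >= 3 & coh$clinical$dfs_months <= 92))
  expect_true(all(coh$clinical$event))
})

test_that("censoring option marks the requested fraction of patients", {
  cfg <- reduced_config(n_genes = 200, censor_fraction = 0.3, seed = 21)
  coh <- generate_cohort(cfg)
  frac <- mean(!coh$clinical$event)
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.45)
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- tiny_config(noise_sd = 0.5, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression$tumor, b$expression$tumor)
  expect_identical(a$expression$normal, b$expression$normal)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
})

test_that("noiseless planted aggregate is an exact affine function of DFS", {
  coh <- generate_cohort(tiny_config(noise_sd = 0))
  cl <- coh$clinical
  for (g in names(coh$truth$planted_genes)) {
    src <- coh$truth$planted_source[[g]]
    w <- gene_weight_matrix(coh$expression, src)
    pats <- cl$patient_id[paste0(cl$histology, ":", ifelse(cl$chemo, "CT", "NC")) == g]
    agg <- aggregate_weights(w, coh$truth$planted_genes[[g]], "mean")[pats]
    dfs <- cl$dfs_months[match(pats, cl$patient_id)]
    expect_gt(abs(cor(agg, dfs)), 1 - 1e-12)
  }
})

test_that("planted tolerant count equals the all-high membership count", {
  coh <- generate_cohort(reduced_config(n_genes = 200, seed = 13))
  high <- coh$truth$immune_high
  all_high <- colnames(high)[colSums(high) == nrow(high)]
  expect_setequal(all_high, coh$truth$tolerant_ids)
  expect_length(all_high, 28)
  # membership labels partition the cohort
  expect_setequal(names(coh$truth$immune_membership), coh$clinical$patient_id)
  expect_true(all(coh$truth$immune_membership %in%
                    c("tolerant", "competent", "other")))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(signature_sizes = c(BOGUS = 5)), "unknown group")
  expect_error(synth_config(dfs_range_months = c(0, 92)), "min")
  expect_error(synth_config(dfs_range_months = c(10, 5)), "min")
  expect_error(synth_config(noise_sd = -1), ">= 0")
  expect_error(synth_config(group_sizes = c("AC:NC" = 0)), "at least one patient")
  expect_error(synth_config(immune_tolerant_count = 500), "exceeds")
})

test_that("null cohort p-values are uniform and weights carry no DFS signal", {
  cfg <- reduced_config(n_genes = 2000, seed = 31)
  nc <- generate_null_cohort(cfg)
  cl <- nc$clinical
  pats <- cl$patient_id[paste0(cl$histology, ":", ifelse(cl$chemo, "CT", "NC")) == "AC:NC"]
  scr <- screen_genes(gene_weight_matrix(nc$expression, "tumor"), cl, pats)
  ks <- suppressWarnings(ks.test(scr$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sum(scr$q < 0.05), 0)
})

test_that("single-gene null cohort is valid and generation is seed-stable", {
  cfg <- synth_config(n_genes = 1, group_sizes = c("AC:NC" = 5),
                      signature_sizes = c("AC:NC" = 0),
                      immune_tolerant_count = 0, missing_stage_count = 0,
                      seed = 3)
  a <- generate_null_cohort(cfg)
  b <- generate_null_cohort(cfg)
  expect_equal(dim(a$expression$tumor), c(1L, 5L))
  expect_identical(a$expression$tumor, b$expression$tumor)
  expect_identical(a$clinical, b$clinical)
})
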