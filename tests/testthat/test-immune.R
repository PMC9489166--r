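test_that("high/low calls split an obvious bimodal vector", {
  v <- setNames(c(1, 1, 100, 100), paste0("P", 1:4))
  call <- call_gene_high_low(v, "X")
  expect_equal(as.character(call$calls), c("low", "low", "high", "high"))
  # order invariance
  call2 <- call_gene_high_low(v[c(3, 1, 4, 2)], "X")
  expect_equal(as.character(call2$calls[names(v)]), as.character(call$calls))
  # positive rescaling preserves the calls
  call3 <- call_gene_high_low(v * 7.5, "X")
  expect_equal(as.character(call3$calls), as.character(call$calls))
  expect_error(call_gene_high_low(setNames(rep(2, 4), paste0("P", 1:4))),
               "distinct")
})

test_that("cluster separation matches the pooled-variance formula", {
  # generic case, hand-computed Student's t with pooled variance
  vals <- c(1, 2, 5, 7); labs <- c("L", "L", "H", "H")
  sp2 <- (var(c(1, 2)) + var(c(5, 7))) / 2
  t_hand <- (mean(c(5, 7)) - mean(c(1, 2))) / sqrt(sp2 * (1 / 2 + 1 / 2))
  got <- cluster_separation_test(vals, labs)
  expect_equal(abs(got$t), abs(t_hand))
  expect_equal(got$p, 2 * pt(-abs(t_hand), df = 2))

  # equal means give t = 0, p = 1
  flat <- cluster_separation_test(c(1, 2, 1, 2), c("L", "L", "H", "H"))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)

  # zero pooled variance with distinct means: the formula's limit
  deg <- cluster_separation_test(c(0, 0, 1, 1), c("L", "L", "H", "H"))
  expect_true(is.infinite(deg$t))
  expect_equal(deg$p, 0)

  expect_error(cluster_separation_test(1:3, c("L", "L", "H")), "size >= 2")
})

test_that("planted bimodal checkpoint genes are recovered and rank first", {
  coh <- generate_cohort(reduced_config(n_genes = 60, seed = 37))
  st <- immune_status(coh$expression)
  truth_high <- coh$truth$immune_high
  for (g in st$genes) {
    calls <- attr(st$gene_tests, "calls")[[g]]$calls
    expect_equal(unname(calls == "high"),
                 unname(truth_high[g, names(calls)]))
    expect_lt(attr(st$gene_tests, "calls")[[g]]$p, 1e-10)
  }
  # combined labels match the planted membership exactly
  membership <- coh$truth$immune_membership[st$table$patient_id]
  expect_equal(as.character(st$table$status), unname(membership))
  expect_equal(sum(st$table$status == "tolerant"), 28)

  # the bimodal checkpoint genes outrank unimodal background genes
  bg <- setdiff(coh$expression$gene_ids, st$genes)[1:2]
  rk <- rank_checkpoint_genes(coh$expression, c(bg, st$genes))
  expect_setequal(rk$gene_id[1:3], st$genes)
})

test_that("candidate handling covers singletons, empties and missing genes", {
  coh <- generate_cohort(tiny_config(n_genes = 20))
  one <- rank_checkpoint_genes(coh$expression, "CTLA4")
  expect_equal(nrow(one), 1L)
  none <- rank_checkpoint_genes(coh$expression, character(0))
  expect_equal(nrow(none), 0L)
  expect_warning(rk <- rank_checkpoint_genes(coh$expression, c("CTLA4", "NOPE")),
                 "NOPE")
  expect_equal(rk$gene_id, "CTLA4")
})

test_that("combined status implements the tolerant and competent rules", {
  mk_call <- function(gene, states) {
    structure(list(gene_id = gene,
                   calls = factor(states, levels = c("low", "high")) |>
                     setNames(paste0("P", seq_along(states))),
                   cluster_means = c(1, 5), t = 10, p = 1e-6),
              class = "immune_gene_call")
  }
  calls <- list(mk_call("CTLA4", c("high", "low", "low", "high")),
                mk_call("PDL1",  c("high", "high", "low", "low")),
                mk_call("ICOS",  c("high", "high", "low", "high")))
  st <- assign_combined_status(calls)
  expect_equal(as.character(st$status), c("tolerant", "competent", "other", "other"))
  # the three labels partition the called patients
  expect_equal(sum(table(st$status)), nrow(st))

  # a patient lacking one call is excluded with a reason
  calls2 <- calls
  calls2[[3]]$calls <- calls2[[3]]$calls[1:3]
  st2 <- assign_combined_status(calls2)
  expect_equal(nrow(st2), 3L)
  expect_equal(attr(st2, "excluded")$patient_id, "P4")

  # the competent rule is configurable
  st3 <- assign_combined_status(calls, competent_rule = c("high", "low", "high"))
  expect_equal(as.character(st3$status), c("tolerant", "other", "other", "competent"))
})
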