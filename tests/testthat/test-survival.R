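test_that("Kaplan-Meier estimator matches hand product-limit values", {
  km <- km_estimate(c(5, 10), c(TRUE, FALSE))
  expect_equal(km$surv[km$time == 5], 0.5)
  expect_equal(attr(km, "median"), 5)

  cens <- km_estimate(c(4, 8, 12), c(FALSE, FALSE, FALSE))
  expect_true(all(cens$surv == 1))
  expect_true(is.na(attr(cens, "median")))

  four <- km_estimate(1:4, rep(TRUE, 4))
  expect_equal(four$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(attr(four, "median"), 2)
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(11)
  t <- sample(1:50, 20, replace = TRUE)
  km <- km_estimate(t, rep(TRUE, 20))
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp)
})

test_that("log-rank statistic matches the hand observed-expected formula", {
  t1 <- c(1, 2, 3); t2 <- c(10, 11, 12)
  times <- c(t1, t2); events <- rep(TRUE, 6)
  grp <- rep(c("A", "B"), each = 3)
  # hand evaluation: at each distinct event time sum O - E and the
  # hypergeometric variance for group A
  o_minus_e <- 0; v <- 0
  for (u in sort(unique(times))) {
    at_risk <- times >= u
    d <- sum(times == u & events)
    n <- sum(at_risk); n1 <- sum(at_risk & grp == "A")
    o_minus_e <- o_minus_e + sum(times == u & events & grp == "A") - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  hand_chisq <- o_minus_e^2 / v
  lr <- logrank_test(times, events, grp)
  expect_equal(lr$chisq, hand_chisq, tolerance = 1e-10)
  expect_equal(lr$df, 1)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-10)

  # label swap leaves the statistic unchanged
  lr2 <- logrank_test(times, events, rev(grp))
  expect_equal(lr2$chisq, lr$chisq)
})

test_that("identical groups give a null log-rank and three groups give df 2", {
  times <- c(3, 6, 9, 3, 6, 9); events <- rep(TRUE, 6)
  lr <- logrank_test(times, events, rep(c("A", "B"), each = 3))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-10)

  lr3 <- logrank_test(c(times, 20, 30), c(events, TRUE, TRUE),
                      c(rep(c("A", "B"), each = 3), "C", "C"))
  expect_equal(lr3$df, 2)

  expect_error(logrank_test(times, rep(FALSE, 6), rep(c("A", "B"), each = 3)),
               "one event")
  expect_error(logrank_test(times, events, rep("A", 6)), "2 non-empty groups")
})

test_that("Cox coefficient matches grid-search partial-likelihood maximization", {
  # 6 patients, no ties, one binary covariate
  times <- c(1, 3, 5, 7, 9, 11)
  events <- rep(TRUE, 6)
  x <- c(1, 1, 0, 1, 0, 0)
  fit <- cox_fit(data.frame(x = x), times, events)
  # independent oracle: literal partial log-likelihood on the exact risk sets
  pll <- function(beta) {
    sum(vapply(which(events), function(i) {
      risk <- times >= times[i]
      beta * x[i] - log(sum(exp(beta * x[risk])))
    }, numeric(1)))
  }
  grid <- seq(-5, 5, by = 1e-3)
  beta_grid <- grid[which.max(vapply(grid, pll, numeric(1)))]
  expect_lt(abs(log(fit$table$hr) - beta_grid), 1e-3 + 1e-4)
  # improvement over the null coefficient and AIC identity
  expect_gte(pll(log(fit$table$hr)), pll(0))
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
  expect_true(fit$converged)
})

test_that("shorter event times in the coded group give HR above one", {
  times <- c(2, 3, 4, 5, 30, 35, 40, 45)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  # groups fully separated in time: the coefficient diverges but its sign
  # (HR above one for the early-relapse group) is stable
  fit <- suppressWarnings(cox_fit(data.frame(risk = x), times, rep(TRUE, 8)))
  expect_gt(fit$table$hr, 1)
})

test_that("Cox p-values are approximately uniform under the null", {
  set.seed(29)
  p <- replicate(200, {
    n <- 40
    times <- rexp(n)
    x <- rbinom(n, 1, 0.5)
    cox_fit(data.frame(x = x), times, rep(TRUE, n))$table$p
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("Cox input validation and the forest table behave", {
  times <- c(2, 3, 4, 5, 30, 35, 40, 45)
  expect_error(cox_fit(data.frame(x = rep(1, 8)), times, rep(TRUE, 8)),
               "constant covariate")
  expect_error(cox_fit(data.frame(x = rbinom(8, 1, 0.5), y = rnorm(8),
                                  z = rnorm(8)),
                       times, c(TRUE, TRUE, rep(FALSE, 6))),
               "fewer events")

  # overlapping event times so the partial likelihood has a finite optimum
  t_mix <- c(2, 3, 8, 5, 30, 7, 40, 6)
  one <- cox_fit(data.frame(risk = c(1, 0, 1, 0, 1, 0, 0, 1)), t_mix,
                 rep(TRUE, 8))
  ft1 <- build_forest_table(one)
  expect_equal(nrow(ft1), 1L)
  expect_true(all(ft1$hr > 0))

  grp <- factor(rep(c("a", "b", "c"), times = c(3, 3, 2)))
  fit3 <- cox_fit(data.frame(grp = grp), t_mix, rep(TRUE, 8))
  ft3 <- build_forest_table(list(levels = fit3))
  expect_equal(nrow(ft3), 2L)
  expect_true(all(grepl("ref: grp = a", ft3$reference)))
})
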