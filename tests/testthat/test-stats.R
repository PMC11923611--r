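test_that("beta-binomial reduces to the binomial as overdispersion vanishes", {
  x <- 0:20
  d0 <- dbetabinom(x, 20, 0.3, rho = 1e-9)
  expect_lt(max(abs(d0 - dbinom(x, 20, 0.3))), 1e-6)
  expect_equal(sum(dbetabinom(x, 20, 0.3, rho = 0.2)), 1, tolerance = 1e-12)

  set.seed(19)
  draws <- rbetabinom(4000, 50, 0.4, rho = 0.1)
  expect_lt(abs(mean(draws) - 20), 0.5)
  expect_gt(var(draws), 50 * 0.4 * 0.6)  # overdispersed beyond binomial
})

test_that("pearson_with_t reproduces the analytic t and brute force", {
  # an exactly planted correlation of 0.69 over 86 individuals gives the
  # textbook t of 8.7 on 84 df
  n <- 86
  e1 <- scale(sin(seq_len(n)))[, 1]
  e2 <- residuals(lm(scale(cos(seq_len(n) * 2))[, 1] ~ e1))
  e2 <- e2 / sd(e2)
  y <- 0.69 * e1 + sqrt(1 - 0.69^2) * e2
  res <- pearson_with_t(e1, y)
  expect_equal(res$r, 0.69, tolerance = 1e-6)
  expect_equal(res$df, 84)
  expect_equal(round(res$t, 1), 8.7)
  expect_lt(res$p, 0.01)

  set.seed(20)
  x <- rnorm(30); z <- rnorm(30)
  res2 <- pearson_with_t(x, z)
  r <- cor(x, z)
  expect_equal(res2$t, r * sqrt(28 / (1 - r^2)), tolerance = 1e-12)
  expect_error(pearson_with_t(x, rep(1, 30)), "variance")
})

test_that("repeatability spans its extremes and rejects degenerate input", {
  ids <- rep(sprintf("I%02d", 1:10), each = 5)
  vals <- rep(rnorm(10), each = 5)
  # residual variance sits on the boundary here, so the optimizer warns
  r1 <- suppressWarnings(repeatability(vals, ids))
  expect_gt(r1$r_rpt, 0.99)
  expect_lt(r1$p, 0.001)

  set.seed(22)
  r0 <- suppressWarnings(
    repeatability(rnorm(200), rep(sprintf("I%02d", 1:20), each = 10)))
  expect_lt(r0$r_rpt, 0.1)
  expect_error(repeatability(rnorm(5), c("a", "b", "c", "d", "e")),
               "at least 2")
})

test_that("planted full-population contrasts are recovered with Table-style output", {
  pop <- make_population(population_config(seed = 42))
  agg <- aggregate_budgets(simulate_budgets(pop, seed = 42))
  fe <- fit_glmm(agg, "excavate")
  co <- fe$coefficients
  expect_true(fe$converged)
  expect_lt(co$beta[co$term == "statusbreeder"], 0)
  expect_lt(co$beta[grepl(":", co$term)], 0)
  expect_equal(co$z, co$beta / co$se, tolerance = 1e-9)
  expect_true(all(co$se > 0))
  expect_true(fe$r2_marginal >= 0 && fe$r2_marginal <= 1)

  fr <- fit_glmm(agg, "rest")
  expect_gt(fr$coefficients$beta[fr$coefficients$term == "statusbreeder"], 0)
  fo <- fit_glmm(agg, "odba")
  expect_lt(fo$coefficients$beta[fo$coefficients$term == "statusbreeder"], 0)
  expect_equal(fo$family, "gamma-log")

  # breeding females eat vertically less often than everyone else
  fv <- fit_glmm(agg, "vertical_eat", fixed = ~ status + sex)
  expect_lt(fv$coefficients$beta[fv$coefficients$term == "statusbreeder"], 0)

  expect_error(fit_glmm(agg[agg$group_id %in% unique(agg$group_id)[1:2], ],
                        "excavate"), "3 groups")
})

test_that("task correlations detect planted association and its absence", {
  set.seed(25)
  n <- 60
  d <- data.frame(
    individual_id = sprintf("I%02d", 1:n),
    group_id = rep(sprintf("G%02d", 1:6), each = 10),
    n_total = rep(5000, n)
  )
  base <- plogis(rnorm(n, qlogis(0.08), 0.4))
  d$n_excavate <- rbinom(n, d$n_total, base)
  # food carrying tracks excavation (positive planted association)
  d$n_food_carry <- rbinom(n, d$n_total, plogis(qlogis(base) + rnorm(n, 0, 0.1)))
  # walk-around is independent
  d$n_walk_around <- rbinom(n, d$n_total, plogis(rnorm(n, qlogis(0.05), 0.4)))
  tc <- task_correlations(d)
  ec <- tc[tc$response == "excavate" & tc$predictor == "food_carry", ]
  expect_gt(ec$beta, 0)
  expect_lt(ec$p, 0.01)
  # latent-scale marginal R2 keeps the logit residual variance pi^2/3 in
  # the denominator, so even a tight association stays numerically small
  ew <- tc[tc$response == "excavate" & tc$predictor == "walk_around", ]
  expect_gt(ec$r2_marginal, 2 * max(ew$r2_marginal, 1e-3))
  expect_lt(ew$r2_marginal, 0.05)
  expect_gt(ew$p, 0.05)
  expect_error(task_correlations(d[1:5, ]), "at least 10")
})

test_that("Grubbs screening flags a single gross outlier", {
  set.seed(26)
  x <- c(rnorm(30), 8)
  fl <- grubbs_outliers(x)
  expect_true(fl[31])
  expect_lt(sum(fl), 3)
  expect_false(any(grubbs_outliers(rnorm(30, sd = 0.5))[1:5]))
})
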