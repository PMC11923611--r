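caps <- function(id, m1, m2, gap, sex = "F") {
  data.frame(individual_id = id,
             date = as.Date("2019-01-01") + c(0, gap),
             mass_g = c(m1, m2), sex = sex, stringsAsFactors = FALSE)
}

test_that("growth-pair eligibility filters match the selection rules", {
  cc <- rbind(
    caps("ok", 70, 95, 120),        # eligible
    caps("heavy", 95, 120, 120),    # first mass >= 90 g
    caps("short", 70, 80, 60),      # gap below 3 months
    caps("long", 70, 120, 300),     # gap above 8 months
    caps("edge_lo", 70, 90, 91),    # inclusive lower gap bound
    caps("edge_hi", 70, 120, 244),  # inclusive upper gap bound
    data.frame(individual_id = "once", date = as.Date("2019-01-01"),
               mass_g = 50, sex = "M")
  )
  pairs <- select_growth_pairs(cc)
  expect_setequal(pairs$individual_id, c("ok", "edge_lo", "edge_hi"))
  ex <- attr(pairs, "excluded")
  expect_equal(ex$reason[ex$individual_id == "heavy"], "first_mass")
  expect_equal(ex$reason[ex$individual_id == "short"], "gap")
  expect_equal(ex$reason[ex$individual_id == "long"], "gap")
  expect_equal(ex$reason[ex$individual_id == "once"], "single_capture")
  # every individual is either kept or reason-coded
  expect_equal(nrow(pairs) + nrow(ex), 7)
})

test_that("the growth surface recovers a known smooth and centres residuals", {
  set.seed(15)
  n <- 200
  truth <- function(m, sex, gap) {
    40 * exp(-((m - 40) / 30)^2) + 5 * (sex == "M") + 0.05 * gap
  }
  pairs <- data.frame(
    individual_id = sprintf("I%03d", 1:n),
    first_mass = runif(n, 20, 85),
    gap_days = sample(91:244, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE)
  )
  pairs$second_mass <- pairs$first_mass +
    truth(pairs$first_mass, pairs$sex, pairs$gap_days) + rnorm(n, 0, 2)
  surf <- fit_growth_surface(pairs)
  pred <- predict(surf, pairs)
  expect_lt(sqrt(mean((pred - truth(pairs$first_mass, pairs$sex,
                                    pairs$gap_days))^2)), 2)
  gi <- growth_index(pairs, surf)
  expect_lt(abs(mean(gi$growth_index_g)), 0.5)
  for (sx in c("F", "M")) {
    expect_lt(abs(mean(gi$growth_index_g[pairs$sex == sx])), 0.7)
  }

  # a pair lying on the surface scores ~0; 10 g above scores ~+10
  p0 <- pairs[1, ]
  p0$second_mass <- p0$first_mass + pred[1]
  expect_lt(abs(growth_index(p0, surf)$growth_index_g), 1e-9)
  p10 <- p0; p10$second_mass <- p10$second_mass + 10
  expect_lt(abs(growth_index(p10, surf)$growth_index_g - 10), 1e-9)

  # out-of-range first mass is flagged as extrapolated
  px <- pairs[1, ]; px$first_mass <- 5
  expect_true(growth_index(px, surf)$extrapolated)

  # constant growth: flat surface, all residuals near zero
  flat <- pairs
  flat$second_mass <- flat$first_mass + 25
  surff <- fit_growth_surface(flat)
  expect_lt(max(abs(growth_index(flat, surff)$growth_index_g)), 1e-6)

  expect_error(fit_growth_surface(pairs[1:10, ]), "at least 20")
})

test_that("growth index ranks planted fast and slow growers", {
  pop <- make_population(population_config(seed = 23))
  pairs <- select_growth_pairs(pop$captures)
  expect_gte(nrow(pairs), 30)
  surf <- fit_growth_surface(pairs)
  gi <- growth_index(pairs, surf)
  mult <- pop$individuals$growth_mult[
    match(gi$individual_id, pop$individuals$individual_id)]
  rho <- cor(gi$growth_index_g, mult, method = "spearman")
  expect_gt(rho, 0.8)
})
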