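test_that("synthetic populations have the study's social structure", {
  pop <- make_population(population_config(seed = 1))
  ind <- pop$individuals
  expect_equal(length(unique(ind$group_id)), 11)
  for (g in split(ind, ind$group_id)) {
    expect_equal(sum(g$status == "breeder" & g$sex == "F"), 1)
    expect_equal(sum(g$status == "breeder" & g$sex == "M"), 1)
    expect_equal(unique(g$group_size), nrow(g))
  }
  expect_true(all(ind$age_months >= 4))  # collaring threshold analogue
  expect_equal(nrow(pop$captures), 2 * nrow(ind))

  pop2 <- make_population(population_config(seed = 1))
  expect_identical(pop, pop2)

  expect_error(make_population(population_config(group_sizes = c(5, 1))),
               "infeasible")
})

test_that("schedules tile the deployment and hit planted time shares", {
  pop <- make_population(population_config(mini = TRUE, seed = 2))
  meta <- pop$individuals[pop$individuals$status == "non-breeder", ][1, ]

  model <- schedule_model()
  sch <- simulate_schedule(meta, model, days = 2, seed = 3)
  expect_equal(sch$start_s[1], 0)
  expect_equal(max(sch$end_s), 2 * 86400)
  expect_equal(sch$start_s[-1], sch$end_s[-nrow(sch)], tolerance = 1e-9)
  expect_true(all(sch$end_s > sch$start_s))
  expect_true(all(sch$behaviour %in% behaviour_vocabulary()))

  # with individual/day noise off, a 17-day realized excavate share sits
  # within 0.01 of the planted 8% target for the baseline individual
  quiet <- model
  quiet$sd_individual <- 0; quiet$sd_day <- 0
  base <- meta
  # age chosen where the centred age term vanishes, so the linear
  # predictor sits exactly at the 8% baseline
  base$sex <- "F"; base$age_months <- 14 + sqrt(121.33)
  base$growth_mult <- 0
  base$group_size <- 9.5   # population-mean group size
  sch17 <- simulate_schedule(base, quiet, days = 17, seed = 4,
                             group_size_center = 9.5)
  dur <- sch17$end_s - sch17$start_s
  exc <- map_to_categories(sch17$behaviour) == "excavate"
  expect_lt(abs(sum(dur[exc]) / sum(dur) - 0.08), 0.01)

  # planted breeder contrast: same covariates, large group
  br <- base; br$status <- "breeder"; br$group_size <- 16
  nb <- base; nb$group_size <- 16
  shr <- function(m, seed) {
    s <- simulate_schedule(m, quiet, days = 10, seed = seed,
                           group_size_center = 9.5)
    d <- s$end_s - s$start_s
    sum(d[map_to_categories(s$behaviour) == "excavate"]) / sum(d)
  }
  expect_lt(shr(br, 5), shr(nb, 5))
})

test_that("synthesized signal geometry matches the posture model", {
  sig <- signal_model()
  # noiseless rest with zero dynamic amplitude: constant gravity vector
  quiet_sig <- sig
  quiet_sig$amp[quiet_sig$behaviour == "rest"] <- 0
  quiet_sig$noise[quiet_sig$behaviour == "rest"] <- 0
  iv <- data.frame(start_s = 0, end_s = 10, behaviour = "rest")
  s <- synthesize_acc(iv, quiet_sig, 25, seed = 6)
  vm <- sqrt(rowSums(s$xyz^2))
  expect_equal(vm, rep(9.8, 250), tolerance = 1e-9)

  # vertical eating pitches above 60 degrees: mean z below the cutoff in
  # at least 99% of windows; horizontal eating stays above it
  iv <- data.frame(start_s = seq(0, 990, 10), end_s = seq(10, 1000, 10),
                   behaviour = "eat")
  sv <- synthesize_acc(iv, sig, 25, seed = 7, p_vertical = 1)
  wv <- segment_windows(sv, 2)
  expect_gte(mean(is_vertical(wv)), 0.99)
  sh <- synthesize_acc(iv, sig, 25, seed = 8, p_vertical = 0)
  expect_lte(mean(is_vertical(segment_windows(sh, 2))), 0.01)
})

test_that("generated schedules label at least 90% of 2 s windows", {
  pop <- make_population(population_config(mini = TRUE, seed = 9))
  sch <- simulate_schedule(pop$individuals[1, ], schedule_model(),
                           days = 1, seed = 10)
  # windows over the day; labels need full single-behaviour coverage
  w <- segment_windows(acc_series(matrix(0, 86400 * 25, 3), rate_hz = 25), 2)
  lab <- attach_labels(w, sch)
  expect_gte(mean(!is.na(lab$windows$label)), 0.9)
})

test_that("budget-level simulation carries the planted vertical-eating gap", {
  pop <- make_population(population_config(seed = 11))
  agg <- aggregate_budgets(simulate_budgets(pop, seed = 11))
  bf <- agg$status == "breeder" & agg$sex == "F"
  expect_lt(mean(agg$n_vertical_eat[bf] / agg$n_eat[bf]),
            mean(agg$n_vertical_eat[!bf] / agg$n_eat[!bf]))
  expect_true(all(agg$n_excavate <= agg$n_total))
  expect_true(all(agg$odba > 0))
})

test_that("the mini dataset writes a complete, reloadable fixture", {
  out <- file.path(tempdir(), "digwork_mini")
  res <- generate_dataset(out, population_config(mini = TRUE, seed = 12),
                          acc_seconds = 60)
  expect_true(file.exists(res$truth_path))
  expect_true(all(file.exists(res$label_paths)))
  expect_true(all(file.exists(res$acc_paths)))

  truth <- jsonlite::read_json(res$truth_path)
  expect_equal(truth$planted$coef_excavate$status, -0.542)
  expect_equal(truth$planted$coef_excavate$interaction, -0.066)

  series <- read_acc(res$acc_paths[1], rate_hz = 25)[[1]]
  expect_equal(n_samples(series), 60 * 25)
  labs <- read_labels(res$label_paths[1])
  expect_gt(nrow(labs), 10)
  bud <- read.csv(file.path(out, "budgets.csv"))
  expect_true(all(c("prop_excavate", "n_total", "mean_odba") %in% names(bud)))
  unlink(out, recursive = TRUE)
})
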