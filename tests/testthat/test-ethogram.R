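pred_df <- function(categories, id = "a", window_s = 2,
                    behaviour = NULL) {
  d <- data.frame(
    individual_id = id,
    start_s = (seq_along(categories) - 1) * window_s,
    category = categories,
    stringsAsFactors = FALSE
  )
  if (!is.null(behaviour)) d$behaviour <- behaviour
  d
}

test_that("bouts are maximal runs whose concatenation conserves time", {
  b <- build_bouts(pred_df(c("rest", "rest", "excavate")))
  expect_equal(nrow(b), 2)
  expect_equal(b$end_s - b$start_s, c(4, 2))
  expect_equal(b$n_windows, c(2, 1))

  alt <- build_bouts(pred_df(rep(c("rest", "move"), 5)))
  expect_equal(nrow(alt), 10)

  set.seed(6)
  cats <- sample(c("rest", "excavate", "move", "other"), 200, replace = TRUE)
  b <- build_bouts(pred_df(cats))
  expect_equal(sum(b$end_s - b$start_s), 200 * 2)
  expect_equal(sum(b$n_windows), 200)

  bad <- pred_df(c("rest", "rest"))
  bad$start_s <- c(2, 0)
  expect_error(build_bouts(bad), "time-ordered")
})

test_that("walk-around respects the 5 s bout and 60 s excavation guards", {
  # helper: n_pre rest windows, optionally one excavate window at a given
  # start, more rest, then a movement bout of n_move windows
  seq_case <- function(exc_at, n_move, total_pre = 40) {
    cats <- rep("rest", total_pre)
    if (!is.na(exc_at)) cats[exc_at / 2 + 1] <- "excavate"
    pred_df(c(cats, rep("move", n_move), "rest"))
  }

  # 4 s movement bout: too short, excluded
  p <- seq_case(NA, 2)
  expect_false(any(walk_around_windows(p)))
  # 6 s bout (> 5 s) with clean history: included
  p <- seq_case(NA, 3)
  expect_equal(sum(walk_around_windows(p)), 3)
  # 8 s bout with an excavate window 30 s before the bout start: excluded
  p <- seq_case(80 - 30, 4)   # bout starts at 80 s
  expect_false(any(walk_around_windows(p)))
  # last excavate window 61 s before bout start: outside the guard, included
  p <- seq_case(80 - 61, 4)
  expect_equal(sum(walk_around_windows(p)), 4)
  # exactly 60 s before: inside the half-open guard interval, excluded
  p <- seq_case(80 - 60, 4)
  expect_false(any(walk_around_windows(p)))

  # walk-around windows are movement windows; removing excavation makes
  # every long movement bout walk-around
  set.seed(8)
  cats <- sample(c("rest", "move", "other"), 300, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
  p <- pred_df(cats)
  wa <- walk_around_windows(p)
  expect_true(all(p$category[wa] == "move"))
  b <- build_bouts(p)
  long_move <- sum(b$n_windows[b$category == "move" &
                                 (b$end_s - b$start_s) > 5])
  expect_equal(sum(wa), long_move)

  # food-carry windows are dropped from walk-around when flagged
  p2 <- pred_df(c(rep("rest", 5), rep("move", 4)),
                behaviour = c(rep("rest", 5), "run", "food-carry",
                              "run", "run"))
  wa2 <- walk_around_windows(p2)
  expect_equal(sum(wa2), 3)
  expect_false(wa2[7])
})

test_that("vertical-eating proportion handles edge cases", {
  expect_equal(vertical_eating_proportion(c(2, 2, 2), rep("eat", 3)), 1)
  expect_equal(vertical_eating_proportion(c(2, 9), rep("eat", 2)), 0.5)
  expect_equal(vertical_eating_proportion(4.9, "eat"), 0)  # strict cutoff
  expect_true(is.na(vertical_eating_proportion(c(2, 9), rep("dig", 2))))
})

test_that("daily budgets normalise, count and flag incomplete days", {
  p <- pred_df(rep("rest", 100))
  b <- daily_time_budget(p)
  expect_equal(b$prop_rest, 1)
  expect_equal(b$prop_excavate + b$prop_move + b$prop_other, 0)
  expect_true(b$incomplete)

  set.seed(10)
  cats <- sample(c("rest", "excavate", "move", "other"), 500, replace = TRUE)
  p <- pred_df(cats)
  p$odba <- rgamma(500, 10)
  b <- daily_time_budget(p)
  expect_equal(b$prop_rest + b$prop_excavate + b$prop_move + b$prop_other,
               1, tolerance = 1e-9)
  expect_equal(b$n_excavate, sum(cats == "excavate"))
  expect_equal(b$n_total, 500)
  expect_equal(b$mean_odba, mean(p$odba))

  # proportions are permutation-invariant within a day
  p2 <- p; p2$category <- sample(p2$category)
  expect_equal(daily_time_budget(p2)$prop_rest, b$prop_rest)

  # windows on different days split into different rows
  p3 <- pred_df(rep("rest", 4))
  p3$start_s <- c(0, 2, 86400, 86402)
  b3 <- daily_time_budget(p3)
  expect_equal(b3$day, c(1, 2))
  expect_equal(b3$n_total, c(2, 2))

  # a planted 8% excavation rate is recovered within binomial error
  set.seed(13)
  n <- 43200
  cats <- ifelse(runif(n) < 0.08, "excavate", "rest")
  b4 <- daily_time_budget(pred_df(cats))
  expect_lt(abs(b4$prop_excavate - 0.08), 4 * sqrt(0.08 * 0.92 / n))
})
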