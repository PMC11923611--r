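test_that("running mean matches a brute-force windowed mean", {
  expect_equal(running_mean(rep(3, 7)), rep(3, 7))
  expect_equal(running_mean(c(0, 10), k = 10), c(5, 5))
  expect_error(running_mean(1:5, k = 0), "k")

  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(sample(5:80, 1))
    k <- sample(2:12, 1)
    brute <- vapply(seq_along(x), function(i) {
      lo <- max(1, i - floor(k / 2))
      hi <- min(length(x), i + k - floor(k / 2) - 1)
      mean(x[lo:hi])
    }, numeric(1))
    expect_equal(running_mean(x, k), brute, tolerance = 1e-12)
  }
})

test_that("ODBA is zero for constant signal, offset-invariant and degree-1", {
  w <- make_windows(matrix(rep(c(0, 0, 9.8), each = 50), ncol = 3))
  expect_equal(odba(w), 0)

  xyz <- random_window(31)
  base <- odba(make_windows(xyz))
  shifted <- odba(make_windows(xyz + rep(c(5, -3, 100), each = 50)))
  expect_lt(abs(base - shifted), 1e-9)

  # doubling the zero-mean dynamic part doubles ODBA
  set.seed(32)
  dyn <- matrix(rnorm(150), 50, 3)
  dyn <- sweep(dyn, 2, colMeans(dyn))
  grav <- rep(c(0, 0, 9.8), each = 50)
  o1 <- odba(make_windows(matrix(grav, ncol = 3) + dyn))
  o2 <- odba(make_windows(matrix(grav, ncol = 3) + 2 * dyn))
  expect_equal(o2, 2 * o1, tolerance = 1e-10)

  # sine of known amplitude against the naive re-implementation
  t <- (0:49) / 25
  xyz <- cbind(3 * sin(2 * pi * 2 * t), 0 * t, 9.8 + 0 * t)
  expect_equal(odba(make_windows(xyz)), odba_brute(xyz), tolerance = 1e-10)

  # per-sample-mean scaling divides by the window size
  expect_equal(odba(make_windows(xyz), odba_scale = "per_sample_mean"),
               odba_brute(xyz) / 50, tolerance = 1e-10)
})

test_that("mean z reflects posture and the vertical cutoff is strict", {
  w <- make_windows(matrix(rep(c(0, 0, 9.8), each = 50), ncol = 3))
  expect_equal(mean_z(w), 9.8)

  # pitched 60 degrees from horizontal: z carries half gravity
  th <- 60 * pi / 180
  w60 <- make_windows(cbind(rep(9.8 * sin(th), 50), rep(0, 50),
                            rep(9.8 * cos(th), 50)))
  expect_equal(mean_z(w60), 4.9, tolerance = 1e-12)

  set.seed(5)
  xyz <- random_window(5)
  expect_equal(mean_z(make_windows(xyz)), mean(xyz[, 3]), tolerance = 1e-12)

  mkz <- function(z) make_windows(cbind(rep(0, 50), rep(0, 50), rep(z, 50)))
  expect_true(is_vertical(mkz(2.0)))
  expect_false(is_vertical(mkz(4.9)))   # boundary: strictly less-than
  expect_false(is_vertical(mkz(9.8)))
})

test_that("feature extraction is deterministic, complete and offset-robust", {
  xyz <- random_window(77)
  w <- make_windows(xyz)
  f1 <- extract_features(w)
  f2 <- extract_features(w)
  expect_identical(f1, f2)
  expect_equal(ncol(f1), 50)
  expect_identical(colnames(f1), feature_names())
  expect_true(all(is.finite(f1)))

  # constant window: dispersion and dynamic features vanish,
  # location features equal the constants
  fc <- extract_features(make_windows(matrix(rep(c(1, 2, 9.8), each = 50),
                                             ncol = 3)))
  expect_equal(unname(fc[1, "x_mean"]), 1)
  expect_equal(unname(fc[1, "z_q50"]), 9.8)
  zero_feats <- c("x_sd", "x_range", "x_skew", "x_mad1", "x_zc",
                  "y_sd", "z_sd", "odba", "vm_sd", "vm_iqr")
  expect_lt(max(abs(fc[1, zero_feats])), 1e-9)

  # axis offsets leave every dynamic-component feature untouched
  f3 <- extract_features(make_windows(xyz + rep(c(2, -1, 3), each = 50)))
  dyn_feats <- c(t(outer(c("x", "y", "z"),
                         c("sd", "range", "skew", "kurt", "mad1", "zc",
                           "domfreq"), paste, sep = "_")),
                 "cor_xy", "cor_xz", "cor_yz",
                 "odba", "odba_x", "odba_y", "odba_z")
  expect_equal(f1[1, dyn_feats], f3[1, dyn_feats], tolerance = 1e-9)
})

test_that("synthetic resting ODBA is stochastically below digging ODBA", {
  sig <- signal_model()
  iv <- data.frame(start_s = c(0, 1000), end_s = c(1000, 2000),
                   behaviour = c("rest", "dig"))
  s <- synthesize_acc(iv, sig, 25, seed = 8)
  w <- attach_labels(segment_windows(s, 2), iv)$windows
  o <- odba(w)
  rest <- o[w$label == "rest" & !is.na(w$label)][1:500]
  dig <- o[w$label == "dig" & !is.na(w$label)][1:500]
  wt <- wilcox.test(rest, dig, alternative = "less")
  expect_lt(wt$p.value, 0.01)
})
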