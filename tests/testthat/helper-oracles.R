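# Deterministic sample set used for the dip reference-value comparison.
# The matching reference dips in dip_reference_values.csv were computed by
# direct linear-programming minimisation of the sup-norm distance over
# piecewise-linear unimodal CDFs (tools/dip_oracle.py), independently of
# the package implementation.
dip_reference_cases <- function() {
  set.seed(20240917)
  cases <- vector("list", 100)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    cases[[i]] <- switch(i %% 5 + 1,
      rnorm(n),
      c(rnorm(ceiling(n / 2), -2.5, 0.4), rnorm(floor(n / 2), 2.5, 0.4)),
      round(runif(n), 1),
      rexp(n),
      round(rnorm(n) * 4) / 2)
  }
  cases
}

# Naive re-implementation of the ODBA formula for oracle comparisons.
odba_brute <- function(xyz, k = 10) {
  total <- 0
  for (ax in 1:3) {
    v <- xyz[, ax]
    n <- length(v)
    for (i in seq_len(n)) {
      lo <- max(1, i - floor(k / 2))
      hi <- min(n, i + k - floor(k / 2) - 1)
      total <- total + abs(v[i] - mean(v[lo:hi]))
    }
  }
  total
}
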