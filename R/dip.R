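#' Hartigan's dip statistic
#'
#' Minimal sup-norm distance between the empirical CDF of a sample and
#' the class of unimodal CDFs (convex left of the mode, concave right of
#' it, at most one atom at the mode). Computed by the classical iterative
#' greatest-convex-minorant / least-concave-majorant algorithm: the
#' candidate modal interval is shrunk to where the gap between the two
#' hulls is largest, while the deviations of the empirical CDF from the
#' convex minorant (left of the modal interval) and the concave majorant
#' (right of it) accumulate into the statistic. The dip is at least
#' 1/(2n) for any sample of size n, with equality for perfectly
#' "uniform-like" samples, and is invariant under affine transforms of
#' the data; large values indicate more than one mode.
#'
#' @param x numeric vector, length >= 2, finite values.
#' @return the dip statistic D (a number in `[1/(2n), 0.25]`).
#' @examples
#' dip_statistic(c(0, 1))            # 0.25, the two-point maximum
#' dip_statistic(seq_len(20))        # 1/40, the lower bound
#' @export
dip_statistic <- function(x) {
  if (length(x) < 2) stop("need at least 2 observations")
  if (!all(is.finite(x))) stop("x must be finite")
  x <- sort(x)
  n <- length(x)
  if (x[1] == x[n]) return(1 / (2 * n))  # degenerate: floor at the bound

  # collapse ties into knots; corner values of the empirical CDF per knot
  u <- unique(x)
  cum <- cumsum(tabulate(match(x, u))) / n
  if (length(u) < length(x)) {
    # tied samples: atoms interact with the modal interval in ways the
    # fast hull iteration does not track; use the exact mode-enumeration
    return(max(1 / (2 * n), dip_exact_knots(u, cum)))
  }
  x <- u
  lowc <- c(0, cum[-length(cum)])  # F just below each knot
  uppc <- cum                      # F at/above each knot
  k <- length(x)

  # lower convex hull touch indices of points (x[i], lowc[i]) over idx
  lower_hull <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2) {
        a <- h[length(h) - 1]; b <- h[length(h)]
        # drop b if it lies on/above segment a--i
        if ((lowc[b] - lowc[a]) * (x[i] - x[a]) >=
            (lowc[i] - lowc[a]) * (x[b] - x[a])) h <- h[-length(h)] else break
      }
      h <- c(h, i)
    }
    h
  }
  upper_hull <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2) {
        a <- h[length(h) - 1]; b <- h[length(h)]
        if ((uppc[b] - uppc[a]) * (x[i] - x[a]) <=
            (uppc[i] - uppc[a]) * (x[b] - x[a])) h <- h[-length(h)] else break
      }
      h <- c(h, i)
    }
    h
  }
  interp <- function(hx, hy, xv) {
    if (length(hx) == 1) return(rep(hy, length(xv)))
    stats::approx(hx, hy, xout = xv, ties = "ordered")$y
  }

  atom <- uppc - lowc
  low <- 1L; high <- k
  d_half <- 1 / (2 * n)
  repeat {
    if (high - low <= 1L) {
      # terminal modal interval: the mode absorbs the larger end atom,
      # the other end must still be crossed continuously
      if (high > low) d_half <- max(d_half, min(atom[low], atom[high]) / 2)
      break
    }
    idx <- low:high
    g <- lower_hull(idx)   # gcm touch indices
    l <- upper_hull(idx)   # lcm touch indices
    gx <- x[g]; gy <- lowc[g]
    lx <- x[l]; ly <- uppc[l]

    # largest gap between the concave majorant and convex minorant curves;
    # piecewise linear, so the max sits at a hull vertex of either curve
    gap_at_g <- interp(lx, ly, gx) - gy
    gap_at_l <- ly - interp(gx, gy, lx)
    d <- max(gap_at_g, gap_at_l)
    if (d <= 2 * d_half) break

    if (max(gap_at_g) >= max(gap_at_l)) {
      vi <- g[which.max(gap_at_g)]
      # lcm segment spanning the argmax vertex
      seg <- findInterval(x[vi], lx, rightmost.closed = TRUE)
      new_low <- vi
      new_high <- l[min(seg + 1L, length(l))]
    } else {
      vi <- l[which.max(gap_at_l)]
      seg <- findInterval(x[vi], gx, rightmost.closed = TRUE)
      new_low <- g[max(seg, 1L)]
      new_high <- vi
    }
    if (new_low < low) new_low <- low
    if (new_high > high) new_high <- high

    # deviations of the empirical CDF outside the new modal interval:
    # F rises above the convex minorant left of it, and drops below the
    # concave majorant right of it; the modal endpoints contribute only
    # their outer corner (an atom at the mode is admissible)
    dl <- max(0, lowc[new_low] - interp(gx, gy, x[new_low]))
    if (new_low > low) {
      li <- low:(new_low - 1L)
      dl <- max(dl, uppc[li] - interp(gx, gy, x[li]))
    }
    dr <- max(0, interp(lx, ly, x[new_high]) - uppc[new_high])
    if (new_high < high) {
      ri <- (new_high + 1L):high
      dr <- max(dr, interp(lx, ly, x[ri]) - lowc[ri])
    }
    d_half <- max(d_half, dl / 2, dr / 2)

    if (new_low == low && new_high == high) {
      if (high > low) d_half <- max(d_half, min(atom[low], atom[high]) / 2)
      break
    }
    low <- new_low; high <- new_high
  }
  d_half
}

#' Bootstrap dip test for unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution. The null distribution of the dip is obtained by
#' bootstrap from the uniform(0,1) distribution — the classical
#' calibration, which is asymptotically the least favourable unimodal
#' null — and the p-value is the fraction of bootstrap dips at least as
#' large as the observed one.
#'
#' @param x numeric sample, length >= 4.
#' @param n_boot number of bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap draws.
#' @param null_dips optional precomputed numeric vector of null dip values
#'   for this sample size (e.g. from [dip_null_distribution()]); when
#'   supplied, `n_boot` and `seed` are ignored.
#' @return list with elements `D` (dip statistic), `p` (bootstrap
#'   p-value), `n` (sample size) and `n_boot`.
#' @export
dip_test <- function(x, n_boot = 2000, seed = 1, null_dips = NULL) {
  if (length(x) < 4) stop("need at least 4 observations")
  D <- dip_statistic(x)
  if (is.null(null_dips)) {
    null_dips <- dip_null_distribution(length(x), n_boot, seed)
  }
  p <- mean(null_dips >= D - 1e-12)
  list(D = D, p = p, n = length(x), n_boot = length(null_dips))
}

#' Null distribution of the dip for a given sample size
#'
#' Dip statistics of `n_boot` uniform(0,1) samples of size `n`. Computing
#' this once and passing it to [dip_test()] via `null_dips` avoids
#' re-simulating the null when many samples of the same size are tested.
#'
#' @param n sample size.
#' @param n_boot number of replicates.
#' @param seed integer seed.
#' @return numeric vector of length `n_boot`.
#' @export
dip_null_distribution <- function(n, n_boot = 2000, seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vapply(seq_len(n_boot), function(i) dip_statistic(stats::runif(n)),
         numeric(1))
}

# --- exact dip for samples with tied values -------------------------------
#
# Minimal t such that some unimodal CDF stays within t of the empirical
# CDF, found by bisection over t with an exact feasibility check per mode
# placement. A unimodal CDF is convex left of its mode and concave right
# of it, continuous except for at most one atom at the mode. With the
# mode at knot m, the left branch must pass through bands
# [c_j - t, c_{j-1} + t] at knots j < m and end in the left-limit band at
# u_m; the right branch starts in [c_m - t, c_m + t] at u_m. Branch
# feasibility is a convex-minorant test, and the junction (left limit <=
# mode value) uses the extremal branch values at the mode, obtained from
# the two-point support-line certificates
#   f(u_p) >= A_i + (A_i - B_j) (u_p - u_i) / (u_i - u_j),  j < i < p,
# which are exact for the minimal end value of a convex nondecreasing
# function within bands (and, mirrored, the maximal start value of a
# concave one).

# greatest convex minorant values of points (u, y) at the knots u
gcm_values <- function(u, y) {
  h <- integer(0)
  for (i in seq_along(u)) {
    while (length(h) >= 2) {
      a <- h[length(h) - 1]; b <- h[length(h)]
      if ((y[b] - y[a]) * (u[i] - u[a]) >= (y[i] - y[a]) * (u[b] - u[a])) {
        h <- h[-length(h)]
      } else break
    }
    h <- c(h, i)
  }
  if (length(h) == 1) return(y)
  stats::approx(u[h], y[h], xout = u, ties = "ordered")$y
}

# minimal achievable end value of a convex nondecreasing function within
# [A, B] at knots u (assumes the chain is feasible)
convex_min_end <- function(u, A, B) {
  p <- length(u)
  best <- A[p]
  if (p >= 3) {
    for (i in 2:(p - 1)) {
      j <- 1:(i - 1)
      v <- A[i] + (A[i] - B[j]) * (u[p] - u[i]) / (u[i] - u[j])
      v <- v[A[i] > B[j]]
      if (length(v)) best <- max(best, v)
    }
  }
  best
}

dip_feasible_mode <- function(u, cl, cu, t, m) {
  k <- length(u)
  # left: knots 1..m-1 plus the left limit at u_m
  if (m > 1) {
    li <- 1:(m - 1)
    A <- pmax(cu[li] - t, 0)
    B <- pmin(cl[li] + t, 1)
    A <- c(A, max(cl[m] - t, 0))
    B <- c(B, min(cl[m] + t, 1))
    if (any(A > B + 1e-14)) return(FALSE)
    ul <- u[1:m]
    g <- gcm_values(ul, B)
    if (any(g < A - 1e-12)) return(FALSE)
    lmin <- convex_min_end(ul, A, B)
  } else lmin <- 0
  # right: knots m..k, atom allowed at the mode knot
  ri <- m:k
  A <- pmax(cu[ri] - t, 0)
  B <- pmin(c(cu[m], cl[ri[-1]]) + t, 1)
  if (any(A > B + 1e-14)) return(FALSE)
  ur <- u[ri]
  # concave side: mirror into a convex problem
  Ar <- rev(-B); Br <- rev(-A); um <- rev(-ur)
  g <- gcm_values(um, Br)
  if (any(g < Ar - 1e-12)) return(FALSE)
  rmax <- -convex_min_end(um, Ar, Br)
  lmin <= rmax + 1e-12
}

dip_exact_knots <- function(u, cum) {
  k <- length(u)
  cl <- c(0, cum[-k])   # F just below each knot
  cu <- cum             # F at each knot
  feasible <- function(t) {
    for (m in 1:k) if (dip_feasible_mode(u, cl, cu, t, m)) return(TRUE)
    FALSE
  }
  lo <- 0; hi <- 0.5
  for (it in 1:50) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  hi
}
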