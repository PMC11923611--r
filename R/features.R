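#' Centred running mean
#'
#' Running average of `k` points used in the dynamic-acceleration
#' calculation. With the default even `k = 10` the window spans offsets
#' -5..+4 around each point and is truncated at the series edges, so the
#' output always has the same length as the input.
#'
#' @param signal numeric vector.
#' @param k window size in samples (default 10).
#' @return numeric vector of the same length.
#' @export
running_mean <- function(signal, k = 10) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) stop("k must be >= 1")
  n <- length(signal)
  if (n < 1) stop("signal must have length >= 1")
  left <- floor(k / 2)
  right <- k - left - 1
  idx <- seq_len(n)
  lo <- pmax(1L, idx - left)
  hi <- pmin(n, idx + right)
  cs <- c(0, cumsum(signal))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Per-axis matrix of window samples: samples-per-window x n_windows.
window_axis_matrix <- function(windows, axis) {
  series <- attr(windows, "series")
  spw <- windows$n_samples[1]
  idx <- outer(0:(spw - 1L), windows$first_sample, "+")
  matrix(series$xyz[idx, axis], nrow = spw)
}

# Columnwise running-mean deviation sums: ODBA contribution of one axis.
# Columns are centred first so constant signals cancel exactly.
axis_odba <- function(M, k) {
  n <- nrow(M)
  M <- M - rep(colMeans(M), each = n)
  left <- floor(k / 2); right <- k - left - 1
  idx <- seq_len(n)
  lo <- pmax(1L, idx - left)
  hi <- pmin(n, idx + right)
  cs <- rbind(0, apply(M, 2, cumsum))
  rm <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  colSums(abs(M - rm))
}

#' Overall dynamic body acceleration per window
#'
#' ODBA for each 2 s window: each axis is high-pass filtered by
#' subtracting a running average of `k` points (computed within the
#' window), and the absolute deviations are summed across samples and the
#' three axes. ODBA is zero for any constant signal and invariant to
#' adding a constant offset to any axis. `odba_scale = "per_sample_mean"`
#' divides by the number of samples; only relative comparisons are used
#' downstream, so conclusions do not depend on this choice.
#'
#' @param windows an `acc_windows` object.
#' @param k running-mean length in samples (default 10).
#' @param odba_scale `"sum"` (default) or `"per_sample_mean"`.
#' @return non-negative numeric vector, one ODBA value per window.
#' @export
odba <- function(windows, k = 10, odba_scale = c("sum", "per_sample_mean")) {
  stopifnot(inherits(windows, "acc_windows"))
  odba_scale <- match.arg(odba_scale)
  if (nrow(windows) == 0) return(numeric(0))
  spw <- windows$n_samples[1]
  if (spw < 2) stop("windows must contain at least 2 samples")
  if (spw < k) stop("windows must contain at least k samples")
  v <- axis_odba(window_axis_matrix(windows, 1), k) +
    axis_odba(window_axis_matrix(windows, 2), k) +
    axis_odba(window_axis_matrix(windows, 3), k)
  if (odba_scale == "per_sample_mean") v <- v / spw
  v
}

#' Mean z-axis acceleration per window
#'
#' The window mean of the dorso-ventral (z) axis reflects body posture: a
#' horizontal animal carries the full gravity component on z
#' (about 9.8 m s^-2), a pitched-up posture reduces it by the cosine of
#' the pitch angle.
#'
#' @param windows an `acc_windows` object.
#' @return numeric vector of mean z values, one per window.
#' @export
mean_z <- function(windows) {
  stopifnot(inherits(windows, "acc_windows"))
  if (nrow(windows) == 0) return(numeric(0))
  if (windows$n_samples[1] < 1) stop("empty windows")
  colMeans(window_axis_matrix(windows, 3))
}

#' Vertical-posture test per window
#'
#' TRUE where the mean z-axis acceleration is strictly below `cutoff`.
#' The default cutoff of 4.9 m s^-2 is half standard gravity, the value
#' that discriminates eating upright against an in-ground tuber (pitch
#' above 60 degrees) from eating detached food items in a horizontal
#' posture. A window with mean z exactly at the cutoff is not vertical.
#'
#' @param windows an `acc_windows` object.
#' @param cutoff posture threshold in m s^-2 (default 4.9).
#' @return logical vector, one value per window.
#' @export
is_vertical <- function(windows, cutoff = 4.9) {
  mean_z(windows) < cutoff
}

#' Names of the 50 window features
#'
#' Fixed, ordered names of the feature vector computed by
#' [extract_features()]: per axis (x, y, z) mean, standard deviation, min,
#' max, range, skewness, excess kurtosis, 25th/50th/75th percentiles, mean
#' absolute first difference, zero-crossing count of the mean-subtracted
#' signal and dominant-frequency power fraction (39); the three pairwise
#' axis correlations; and whole-window ODBA, its per-axis components,
#' vector-magnitude mean, SD and inter-quartile range, and the tilt angle
#' of the mean acceleration vector from the z axis (8). Dispersion and
#' dynamic features are invariant to constant per-axis offsets.
#'
#' @return character vector of length 50.
#' @export
feature_names <- function() {
  per_axis <- c("mean", "sd", "min", "max", "range", "skew", "kurt",
                "q25", "q50", "q75", "mad1", "zc", "domfreq")
  c(as.vector(t(outer(c("x", "y", "z"), per_axis, paste, sep = "_"))),
    "cor_xy", "cor_xz", "cor_yz",
    "odba", "odba_x", "odba_y", "odba_z",
    "vm_mean", "vm_sd", "tilt", "vm_iqr")
}

axis_feature_block <- function(M) {
  spw <- nrow(M)
  mu <- colMeans(M)
  Mc <- M - rep(mu, each = spw)
  m2 <- colMeans(Mc^2)
  sdv <- sqrt(m2 * spw / (spw - 1))
  mn <- apply(M, 2, min)
  mx <- apply(M, 2, max)
  skew <- ifelse(m2 > 0, colMeans(Mc^3) / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, colMeans(Mc^4) / m2^2 - 3, 0)
  qs <- apply(M, 2, stats::quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  mad1 <- colMeans(abs(M[-1, , drop = FALSE] - M[-spw, , drop = FALSE]))
  pos <- Mc > 0
  zc <- colSums(pos[-1, , drop = FALSE] != pos[-spw, , drop = FALSE])
  pw <- Mod(stats::mvfft(Mc))^2
  pw <- pw[2:(floor(spw / 2) + 1), , drop = FALSE]
  tot <- colSums(pw)
  domfreq <- ifelse(tot > 0, apply(pw, 2, max) / ifelse(tot > 0, tot, 1), 0)
  rbind(mu, sdv, mn, mx, mx - mn, skew, kurt, qs, mad1, zc, domfreq)
}

#' Extract the 50-feature vector for every window
#'
#' Deterministic, finite feature matrix used to train and apply the
#' behaviour classifier; see [feature_names()] for the feature set.
#'
#' @param windows an `acc_windows` object.
#' @param k running-mean length used for the ODBA features (default 10).
#' @return numeric matrix, one row per window, 50 named columns.
#' @export
extract_features <- function(windows, k = 10) {
  stopifnot(inherits(windows, "acc_windows"))
  nm <- feature_names()
  if (nrow(windows) == 0) {
    return(matrix(numeric(0), ncol = 50, dimnames = list(NULL, nm)))
  }
  spw <- windows$n_samples[1]
  X <- window_axis_matrix(windows, 1)
  Y <- window_axis_matrix(windows, 2)
  Z <- window_axis_matrix(windows, 3)
  blocks <- rbind(axis_feature_block(X), axis_feature_block(Y),
                  axis_feature_block(Z))

  cor_pair <- function(A, B) {
    Ac <- A - rep(colMeans(A), each = spw)
    Bc <- B - rep(colMeans(B), each = spw)
    den <- sqrt(colSums(Ac^2) * colSums(Bc^2))
    ifelse(den > 0, colSums(Ac * Bc) / ifelse(den > 0, den, 1), 0)
  }
  ox <- axis_odba(X, k); oy <- axis_odba(Y, k); oz <- axis_odba(Z, k)
  VM <- sqrt(X^2 + Y^2 + Z^2)
  vm_mu <- colMeans(VM)
  vm_sd <- sqrt(colMeans((VM - rep(vm_mu, each = spw))^2) * spw / (spw - 1))
  vq <- apply(VM, 2, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  mvec_norm <- sqrt(colMeans(X)^2 + colMeans(Y)^2 + colMeans(Z)^2)
  tilt <- ifelse(mvec_norm > 0,
                 acos(pmin(1, pmax(-1, colMeans(Z) / ifelse(mvec_norm > 0, mvec_norm, 1)))),
                 0)
  out <- t(rbind(blocks,
                 cor_pair(X, Y), cor_pair(X, Z), cor_pair(Y, Z),
                 ox + oy + oz, ox, oy, oz,
                 vm_mu, vm_sd, tilt, vq[2, ] - vq[1, ]))
  dimnames(out) <- list(NULL, nm)
  if (!all(is.finite(out))) stop("non-finite feature values computed")
  out
}
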