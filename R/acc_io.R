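#' Construct a tri-axial acceleration series
#'
#' An `acc_series` holds one individual's uniformly sampled tri-axial
#' acceleration stream: an n x 3 matrix of x, y, z values in m s^-2 plus
#' the sampling rate. Loggers of the kind emulated here record continuously
#' at 25 Hz on three perpendicular axes; timestamps are carried as seconds
#' from the series start, calendar time only matters at I/O.
#'
#' @param xyz numeric matrix with three columns (x, y, z), one row per
#'   sample. All values must be finite.
#' @param individual_id character scalar identifying the deployment.
#' @param rate_hz sampling rate in Hz (default 25).
#' @param start_time optional start time (numeric seconds or POSIXct),
#'   stored as metadata only.
#' @return object of class `acc_series`.
#' @export
acc_series <- function(xyz, individual_id = "ind", rate_hz = 25,
                       start_time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have exactly three columns (x, y, z)")
  if (nrow(xyz) > 0 && !all(is.finite(xyz))) {
    bad <- which(!apply(is.finite(xyz), 1, all))
    stop("non-finite acceleration values at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0) {
    stop("rate_hz must be a single positive number")
  }
  colnames(xyz) <- c("x", "y", "z")
  structure(
    list(individual_id = as.character(individual_id),
         rate_hz = rate_hz, start_time = start_time, xyz = xyz),
    class = "acc_series"
  )
}

#' @export
print.acc_series <- function(x, ...) {
  cat(sprintf("<acc_series> %s: %d samples at %g Hz (%.1f s)\n",
              x$individual_id, nrow(x$xyz), x$rate_hz,
              nrow(x$xyz) / x$rate_hz))
  invisible(x)
}

#' Number of samples and duration of a series
#' @param series an `acc_series`.
#' @return `n_samples()`: integer count; `duration_s()`: seconds.
#' @export
n_samples <- function(series) nrow(series$xyz)

#' @rdname n_samples
#' @export
duration_s <- function(series) nrow(series$xyz) / series$rate_hz

#' Read logger acceleration CSV
#'
#' Reads a CSV with header `timestamp,x,y,z` (timestamps either numeric
#' seconds or ISO-8601 strings; accelerations in m s^-2). Timestamps must
#' be monotone. Recording gaps larger than `gap_tol` sample intervals are
#' treated as logger dropout: the stream is split at each such gap and one
#' `acc_series` is returned per contiguous segment (smaller irregularities
#' are treated as timestamp jitter and ignored).
#'
#' @param path file path.
#' @param rate_hz nominal sampling rate in Hz (default 25).
#' @param individual_id id attached to the returned series; defaults to the
#'   file name without extension.
#' @param gap_tol gap tolerance in sample intervals before splitting
#'   (default 2).
#' @return a list of `acc_series`, one per contiguous segment.
#' @export
read_acc <- function(path, rate_hz = 25, individual_id = NULL, gap_tol = 2) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "x", "y", "z")
  if (!all(need %in% names(dat))) {
    stop("acceleration CSV must have columns: ", paste(need, collapse = ","),
         " (missing: ", paste(setdiff(need, names(dat)), collapse = ","), ")")
  }
  if (is.null(individual_id)) {
    individual_id <- sub("\\.[^.]*$", "", basename(path))
  }
  ts <- dat$timestamp
  if (!is.numeric(ts)) {
    tt <- as.POSIXct(ts, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(tt)) stop("unparseable timestamps in ", path)
    ts <- as.numeric(tt)
  }
  if (nrow(dat) > 1 && any(diff(ts) < 0)) {
    stop("timestamps must be monotone non-decreasing")
  }
  xyz <- as.matrix(dat[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    bad <- which(!apply(is.finite(xyz), 1, all))
    stop("non-finite acceleration values at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  dt <- 1 / rate_hz
  breaks <- which(diff(ts) > gap_tol * dt)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, nrow(dat))
  if (length(breaks) > 0) {
    message(sprintf("%s: %d recording gap(s) > %g sample intervals; split into %d segments",
                    individual_id, length(breaks), gap_tol, length(starts)))
  }
  lapply(seq_along(starts), function(i) {
    acc_series(xyz[starts[i]:ends[i], , drop = FALSE],
               individual_id = individual_id, rate_hz = rate_hz,
               start_time = ts[starts[i]])
  })
}

#' Write an acceleration series to CSV
#'
#' Inverse of [read_acc()]: writes `timestamp,x,y,z` with numeric-second
#' timestamps at the series sampling rate. Read-back is sample-exact.
#'
#' @param series an `acc_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_acc <- function(series, path) {
  n <- n_samples(series)
  t0 <- if (inherits(series$start_time, "POSIXct")) {
    as.numeric(series$start_time)
  } else {
    as.numeric(series$start_time)
  }
  out <- data.frame(
    timestamp = t0 + (seq_len(n) - 1) / series$rate_hz,
    x = series$xyz[, 1], y = series$xyz[, 2], z = series$xyz[, 3]
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write behaviour-label interval files
#'
#' Label CSVs have the header `start_s,end_s,behaviour`, with times in
#' seconds from the start of the matching acceleration series and
#' behaviours drawn from [behaviour_vocabulary()].
#'
#' @param path file path.
#' @param vocabulary allowed behaviour names.
#' @return data.frame with columns `start_s`, `end_s`, `behaviour`.
#' @export
read_labels <- function(path, vocabulary = behaviour_vocabulary()) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "behaviour")
  if (!all(need %in% names(dat))) {
    stop("label CSV must have columns: ", paste(need, collapse = ","))
  }
  validate_intervals(dat, vocabulary)
  dat
}

#' @rdname read_labels
#' @param intervals data.frame of labelled intervals.
#' @export
write_labels <- function(intervals, path) {
  utils::write.csv(intervals[, c("start_s", "end_s", "behaviour")], path,
                   row.names = FALSE)
  invisible(path)
}

validate_intervals <- function(intervals, vocabulary = behaviour_vocabulary()) {
  if (any(intervals$end_s <= intervals$start_s)) {
    stop("intervals must satisfy end_s > start_s")
  }
  bad <- setdiff(unique(intervals$behaviour), vocabulary)
  if (length(bad) > 0) {
    stop("behaviours outside the vocabulary: ", paste(bad, collapse = ", "))
  }
  o <- order(intervals$start_s)
  s <- intervals$start_s[o]; e <- intervals$end_s[o]
  if (length(s) > 1 && any(s[-1] < e[-length(e)] - 1e-9)) {
    stop("labelled intervals overlap")
  }
  invisible(intervals)
}

#' Segment a series into fixed-length windows
#'
#' Cuts the stream into contiguous, non-overlapping windows of
#' `window_s` seconds aligned to the series start; at 25 Hz and 2 s this is
#' 50 samples per axis per window. A trailing partial window is discarded.
#'
#' @param series an `acc_series`.
#' @param window_s window length in seconds (default 2).
#' @return an `acc_windows` object: a data.frame with one row per window
#'   (`individual_id`, `index`, `start_s`, `first_sample`, `n_samples`,
#'   `label`, `predicted`) carrying the parent series and window length as
#'   attributes. `index` is 1-based.
#' @export
segment_windows <- function(series, window_s = 2) {
  stopifnot(inherits(series, "acc_series"))
  if (window_s <= 0) stop("window_s must be positive")
  spw <- round(series$rate_hz * window_s)
  if (spw < 2) stop("window holds fewer than 2 samples at this rate")
  n_win <- floor(n_samples(series) / spw)
  tab <- data.frame(
    individual_id = rep(series$individual_id, n_win),
    index = seq_len(n_win),
    start_s = (seq_len(n_win) - 1) * window_s,
    first_sample = (seq_len(n_win) - 1L) * spw + 1L,
    n_samples = rep(spw, n_win),
    label = rep(NA_character_, n_win),
    predicted = rep(NA_character_, n_win),
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("acc_windows", "data.frame"),
            series = series, window_s = window_s)
}

#' Extract the raw samples of one window
#' @param windows an `acc_windows` object.
#' @param i window row number.
#' @return numeric matrix (samples x 3).
#' @export
window_samples <- function(windows, i) {
  series <- attr(windows, "series")
  f <- windows$first_sample[i]
  series$xyz[f:(f + windows$n_samples[i] - 1L), , drop = FALSE]
}

#' Attach ground-truth behaviour labels to windows
#'
#' A window is labelled if and only if a single behaviour interval fully
#' covers it, so each training segment contains one behaviour only.
#' Intervals shorter than the window length can never cover a window; they
#' are tallied as omitted (in the source study about 6% of labelled
#' behaviours were too short and dropped the same way).
#'
#' @param windows an `acc_windows` object from [segment_windows()].
#' @param intervals data.frame of labelled intervals
#'   (`start_s`, `end_s`, `behaviour`), non-overlapping.
#' @param vocabulary allowed behaviour names.
#' @return list with elements `windows` (the input with `label` filled
#'   where covered) and `omitted` (count of intervals shorter than the
#'   window length).
#' @export
attach_labels <- function(windows, intervals,
                          vocabulary = behaviour_vocabulary()) {
  stopifnot(inherits(windows, "acc_windows"))
  validate_intervals(intervals, vocabulary)
  window_s <- attr(windows, "window_s")
  omitted <- sum(intervals$end_s - intervals$start_s < window_s)
  w_start <- windows$start_s
  w_end <- windows$start_s + window_s
  lab <- windows$label
  for (j in seq_len(nrow(intervals))) {
    covered <- w_start >= intervals$start_s[j] - 1e-9 &
      w_end <= intervals$end_s[j] + 1e-9
    lab[covered] <- intervals$behaviour[j]
  }
  windows$label <- lab
  list(windows = windows, omitted = omitted)
}
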