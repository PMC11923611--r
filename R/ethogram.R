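#' Collapse per-window predictions into behaviour bouts
#'
#' A bout is a maximal run of consecutive windows of one individual with
#' the same category. Concatenating the bouts reconstructs the window
#' sequence exactly.
#'
#' @param predictions data.frame with columns `individual_id`, `start_s`
#'   and `category`, time-ordered within each individual.
#' @param window_s window length in seconds (default 2).
#' @return data.frame with columns `individual_id`, `category`, `start_s`,
#'   `end_s`, `n_windows`.
#' @export
build_bouts <- function(predictions, window_s = 2) {
  need <- c("individual_id", "start_s", "category")
  if (!all(need %in% names(predictions))) {
    stop("predictions must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(predictions, predictions$individual_id), function(p) {
    if (is.unsorted(p$start_s, strictly = TRUE)) {
      stop("windows of individual ", p$individual_id[1],
           " are not time-ordered")
    }
    r <- rle(p$category)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    data.frame(
      individual_id = p$individual_id[1],
      category = r$values,
      start_s = p$start_s[starts],
      end_s = p$start_s[ends] + window_s,
      n_windows = r$lengths,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Identify walk-around windows
#'
#' Walk-around is locomotion unrelated to excavation and may reflect
#' tunnel patrolling: windows inside movement bouts strictly longer than
#' `min_bout_s` whose preceding `lookback_s` seconds (the half-open
#' interval before the bout start) contain no excavate-category window.
#' Excavating work sequences routinely involve short runs back to the
#' digging point, which this definition removes. Bouts are built at
#' category level (run, walk and food-carry fused); with
#' `exclude_food_carry = TRUE` (default) windows whose behaviour is
#' food-carry are dropped from the returned set, since food carrying is
#' scored as its own task.
#'
#' @param predictions data.frame with columns `individual_id`, `start_s`,
#'   `category` (and `behaviour` if `exclude_food_carry`), time-ordered
#'   within individual.
#' @param window_s window length in seconds (default 2).
#' @param min_bout_s minimum bout duration in seconds, exclusive
#'   (default 5; with 2 s windows the shortest qualifying bout is 6 s).
#' @param lookback_s excavation-free guard interval before the bout start
#'   in seconds (default 60).
#' @param exclude_food_carry drop food-carry windows from the result.
#' @return logical vector along the rows of `predictions`: TRUE for
#'   walk-around windows.
#' @export
walk_around_windows <- function(predictions, window_s = 2, min_bout_s = 5,
                                lookback_s = 60, exclude_food_carry = TRUE) {
  is_wa <- rep(FALSE, nrow(predictions))
  for (id in unique(predictions$individual_id)) {
    rows <- which(predictions$individual_id == id)
    p <- predictions[rows, ]
    bouts <- build_bouts(p, window_s)
    exc_starts <- p$start_s[p$category == "excavate"]
    mv <- bouts[bouts$category == "move" &
                  (bouts$end_s - bouts$start_s) > min_bout_s, , drop = FALSE]
    for (b in seq_len(nrow(mv))) {
      s0 <- mv$start_s[b]
      if (any(exc_starts >= s0 - lookback_s & exc_starts < s0)) next
      sel <- p$start_s >= s0 & p$start_s < mv$end_s[b]
      is_wa[rows[sel]] <- TRUE
    }
  }
  if (exclude_food_carry && "behaviour" %in% names(predictions)) {
    is_wa[predictions$behaviour == "food-carry"] <- FALSE
  }
  is_wa
}

#' Proportion of eating done in a vertical posture
#'
#' Among windows classified as eating, the fraction whose mean z-axis
#' acceleration is strictly below the posture cutoff. Eating upright
#' against an in-ground tuber pitches the body more than 60 degrees, so
#' vertical eating indicates feeding directly from tubers rather than on
#' detached pieces (which may come from the group's food store). With no
#' eating windows the proportion is undefined and `NA` is returned.
#'
#' @param mean_z numeric vector of window mean z values (m s^-2).
#' @param behaviour character vector of window behaviours.
#' @param cutoff posture threshold (default 4.9 m s^-2).
#' @return proportion in `[0, 1]`, or `NA_real_` if nothing was eaten.
#' @export
vertical_eating_proportion <- function(mean_z, behaviour, cutoff = 4.9) {
  stopifnot(length(mean_z) == length(behaviour))
  eat <- behaviour == "eat"
  if (!any(eat)) return(NA_real_)
  mean(mean_z[eat] < cutoff)
}

#' Per-individual-day behavioural time budgets
#'
#' One row per individual and calendar day: the proportions of windows in
#' each of the four categories, the excavate/total window counts used by
#' the proportion mixed models, mean ODBA, and (when behaviour and
#' posture columns are present) the vertical-eating proportion. Days with
#' fewer than half the expected number of windows are flagged incomplete;
#' they are kept, and can be filtered by the caller.
#'
#' @param predictions data.frame with columns `individual_id`, `start_s`,
#'   `category`; optionally `odba`, `behaviour` and `mean_z`.
#' @param window_s window length in seconds (default 2).
#' @param day_s seconds per day (default 86400).
#' @return data.frame with columns `individual_id`, `day`, `prop_rest`,
#'   `prop_excavate`, `prop_move`, `prop_other`, `n_excavate`, `n_total`,
#'   `mean_odba`, `prop_vertical_eat`, `incomplete`.
#' @export
daily_time_budget <- function(predictions, window_s = 2, day_s = 86400) {
  need <- c("individual_id", "start_s", "category")
  if (!all(need %in% names(predictions))) {
    stop("predictions must have columns: ", paste(need, collapse = ", "))
  }
  day <- floor(predictions$start_s / day_s) + 1L
  key <- interaction(predictions$individual_id, day, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(predictions)), key), function(i) {
    p <- predictions[i, ]
    n <- nrow(p)
    props <- vapply(category_levels(),
                    function(cl) mean(p$category == cl), numeric(1))
    data.frame(
      individual_id = p$individual_id[1],
      day = floor(p$start_s[1] / day_s) + 1L,
      prop_rest = props[["rest"]],
      prop_excavate = props[["excavate"]],
      prop_move = props[["move"]],
      prop_other = props[["other"]],
      n_excavate = sum(p$category == "excavate"),
      n_total = n,
      mean_odba = if ("odba" %in% names(p)) mean(p$odba) else NA_real_,
      prop_vertical_eat = if (all(c("behaviour", "mean_z") %in% names(p))) {
        vertical_eating_proportion(p$mean_z, p$behaviour)
      } else NA_real_,
      incomplete = n < 0.5 * day_s / window_s,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$individual_id, out$day), ]
  rownames(out) <- NULL
  out
}
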