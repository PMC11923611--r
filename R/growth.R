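#' Select capture pairs eligible for the growth index
#'
#' From longitudinal capture records, takes each individual's first two
#' captures and keeps the pair only if the first body mass is below
#' 90 g (roughly below one year of age, so growth is still informative)
#' and the second capture falls 3 to 8 months after the first. Months
#' are concretised as 91-244 days inclusive.
#'
#' @param captures data.frame with columns `individual_id`, `date`
#'   (Date or ISO string), `mass_g`, `sex`.
#' @param max_first_mass first-mass eligibility threshold in g
#'   (default 90, strict).
#' @param gap_days_range allowed days between the two captures
#'   (default `c(91, 244)`, inclusive).
#' @return data.frame with columns `individual_id`, `first_mass`,
#'   `second_mass`, `gap_days`, `sex`; excluded individuals are recorded
#'   in the `excluded` attribute with a reason code (`single_capture`,
#'   `first_mass`, `gap`).
#' @export
select_growth_pairs <- function(captures, max_first_mass = 90,
                                gap_days_range = c(91, 244)) {
  captures$date <- as.Date(captures$date)
  if (any(captures$mass_g <= 0)) stop("body masses must be positive")
  keep <- list(); excl <- list()
  for (id in unique(captures$individual_id)) {
    cc <- captures[captures$individual_id == id, ]
    cc <- cc[order(cc$date), ]
    if (nrow(cc) < 2) {
      excl[[id]] <- "single_capture"
      next
    }
    gap <- as.numeric(cc$date[2] - cc$date[1])
    if (cc$mass_g[1] >= max_first_mass) {
      excl[[id]] <- "first_mass"
    } else if (gap < gap_days_range[1] || gap > gap_days_range[2]) {
      excl[[id]] <- "gap"
    } else {
      keep[[id]] <- data.frame(
        individual_id = id, first_mass = cc$mass_g[1],
        second_mass = cc$mass_g[2], gap_days = gap, sex = cc$sex[1],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(keep)) do.call(rbind, keep) else
    data.frame(individual_id = character(0), first_mass = numeric(0),
               second_mass = numeric(0), gap_days = numeric(0),
               sex = character(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(
    individual_id = names(excl),
    reason = unlist(excl, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  out
}

#' Fit the population growth surface
#'
#' Models mass gain (second minus first mass) with a generalized additive
#' model: a sex-specific penalized cubic regression spline over the first
#' mass — growth rates change nonlinearly over ontogeny — plus linear sex
#' and capture-gap terms. Smoothness is selected by generalized
#' cross-validation.
#'
#' @param pairs data.frame from [select_growth_pairs()].
#' @param k basis dimension of each sex's smooth (default 5).
#' @return object of class `growth_surface` wrapping the fitted
#'   [mgcv::gam()] model and the observed first-mass range.
#' @export
fit_growth_surface <- function(pairs, k = 5) {
  if (nrow(pairs) < 20) stop("need at least 20 growth pairs to fit")
  d <- data.frame(
    growth = pairs$second_mass - pairs$first_mass,
    first_mass = pairs$first_mass,
    gap_days = pairs$gap_days,
    sex = factor(pairs$sex)
  )
  model <- mgcv::gam(
    growth ~ s(first_mass, by = sex, k = k, bs = "cr") + sex + gap_days,
    data = d, method = "GCV.Cp"
  )
  structure(
    list(model = model, range_first_mass = range(d$first_mass),
         sex_levels = levels(d$sex)),
    class = "growth_surface"
  )
}

#' @export
predict.growth_surface <- function(object, pairs, ...) {
  fm <- pmin(pmax(pairs$first_mass, object$range_first_mass[1]),
             object$range_first_mass[2])
  nd <- data.frame(first_mass = fm, gap_days = pairs$gap_days,
                   sex = factor(pairs$sex, levels = object$sex_levels))
  as.numeric(mgcv::predict.gam(object$model, newdata = nd))
}

#' Individual growth index
#'
#' Residual of each individual's observed mass gain from the fitted
#' population growth surface: positive values mark individuals growing
#' faster than the population average for their starting mass, sex and
#' capture gap. Pairs whose first mass lies outside the fitted range are
#' predicted at the range boundary and flagged.
#'
#' @param pairs data.frame from [select_growth_pairs()].
#' @param surface a `growth_surface` from [fit_growth_surface()].
#' @return data.frame with columns `individual_id`, `growth_index_g` and
#'   `extrapolated`.
#' @export
growth_index <- function(pairs, surface) {
  pred <- predict(surface, pairs)
  data.frame(
    individual_id = pairs$individual_id,
    growth_index_g = (pairs$second_mass - pairs$first_mass) - pred,
    extrapolated = pairs$first_mass < surface$range_first_mass[1] |
      pairs$first_mass > surface$range_first_mass[2],
    stringsAsFactors = FALSE
  )
}
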