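#' Configuration of a synthetic study population
#'
#' Defaults emulate the field study the package is built around: 11
#' social groups averaging nine members, one breeding pair per group,
#' collar deployments of on average 17 days (SD 3.9) recorded at 25 Hz.
#' The `mini` profile (4 groups, 5 collared individuals each, 2 days) is
#' a fast end-to-end profile for tests and examples.
#'
#' @param n_groups number of groups.
#' @param group_size_mean mean group size (sizes are 3 + Poisson).
#' @param group_sizes optional fixed vector of group sizes.
#' @param collared_per_group number of collared individuals per group
#'   (`NULL` collars every eligible member; breeders are always
#'   collared).
#' @param deployment_days_mean,deployment_days_sd deployment length
#'   distribution in days.
#' @param rate_hz logger sampling rate.
#' @param seed root seed; all randomness derives from it.
#' @param mini logical: use the small fast profile.
#' @return list of configuration values.
#' @export
population_config <- function(n_groups = 11, group_size_mean = 9,
                              group_sizes = NULL, collared_per_group = NULL,
                              deployment_days_mean = 17,
                              deployment_days_sd = 3.9,
                              rate_hz = 25, seed = 1, mini = FALSE) {
  if (mini) {
    n_groups <- 4
    group_sizes <- c(4, 8, 14, 18)
    collared_per_group <- 5
    deployment_days_mean <- 2
    deployment_days_sd <- 0
  }
  list(n_groups = n_groups, group_size_mean = group_size_mean,
       group_sizes = group_sizes, collared_per_group = collared_per_group,
       deployment_days_mean = deployment_days_mean,
       deployment_days_sd = deployment_days_sd,
       rate_hz = rate_hz, seed = seed, mini = mini)
}

#' Planted behavioural effect structure of the generator
#'
#' The semi-Markov schedule generator drives each individual's time
#' shares from linear predictors on the logit scale (for the excavate
#' and rest categories) and the log scale (for ODBA). The planted
#' coefficient defaults are the field study's fitted contrasts: breeders
#' excavate less and rest more than non-breeders, increasingly so in
#' larger groups (negative status x group-size interaction for
#' excavating), males excavate less than females, excavating has a
#' hump-shaped age profile peaking around 14 months, and faster-growing
#' individuals excavate more. Group-size enters centred. Noise standard
#' deviations (individual, day, group) are calibrated so that a
#' full-sized population reproduces the field study's coefficient
#' standard errors and a daily repeatability of roughly 0.37.
#'
#' @param p_excavate baseline excavate time share of a non-breeding
#'   female at mean group size and peak age (default 0.08).
#' @param p_rest baseline resting share (default 0.55).
#' @param odba_mean baseline mean ODBA per 2 s window, m s^-2.
#' @return list describing the schedule model; see the vignette for the
#'   meaning of every component.
#' @export
schedule_model <- function(p_excavate = 0.08, p_rest = 0.55,
                           odba_mean = 40) {
  behaviours <- behaviour_vocabulary()
  dwell_mean <- c(rest = 90, dig = 25, sweep = 15, `back-kick` = 10,
                  run = 8, walk = 12, `food-carry` = 10, eat = 40,
                  groom = 20, gnaw = 15, `dust-bathe` = 12, rear = 6,
                  sniff = 6, scratch = 8)[behaviours]
  bout_weight <- c(rest = 0.30, dig = 0.07, sweep = 0.06,
                   `back-kick` = 0.03, run = 0.09, walk = 0.09,
                   `food-carry` = 0.04, eat = 0.08, groom = 0.06,
                   gnaw = 0.04, `dust-bathe` = 0.02, rear = 0.04,
                   sniff = 0.05, scratch = 0.03)[behaviours]
  list(
    behaviours = behaviours,
    dwell_meanlog = log(dwell_mean) - 0.5 * 0.6^2,  # mean of LN = dwell_mean
    dwell_sdlog = stats::setNames(rep(0.6, length(behaviours)), behaviours),
    bout_weight = bout_weight / sum(bout_weight),
    coef_excavate = c(intercept = stats::qlogis(p_excavate),
                      status = -0.542, group_size = -0.005,
                      interaction = -0.066, sex_male = -0.139,
                      age_quad = -0.002, growth = 0.15),
    coef_rest = c(intercept = stats::qlogis(p_rest), status = 0.324,
                  group_size = 0.011, interaction = 0.018,
                  sex_male = 0.181),
    coef_odba = c(intercept = log(odba_mean), status = -0.274,
                  group_size = -0.007, interaction = -0.020,
                  sex_male = -0.100),
    sd_individual = 0.22, sd_day = 0.485, sd_group = 0.10,
    sd_individual_odba = 0.14, sd_group_odba = 0.05, odba_shape = 60,
    p_vertical_eat = c(breeding_female = 0.35, other = 0.55),
    eat_share = 0.06, age_peak_months = 14
  )
}

#' Per-behaviour signal model for raw acceleration synthesis
#'
#' Each behaviour is generated as a static gravity component set by the
#' body pitch (z carries 9.8 cos(pitch)), a band-limited oscillatory
#' dynamic component, and Gaussian sensor noise. Resting has the
#' smallest dynamic amplitude and excavating the largest, so ODBA orders
#' the states as it does in real loggers; vertical eating uses a pitch
#' above 60 degrees so its mean z falls below the 4.9 m s^-2 posture
#' cutoff, horizontal eating stays well above it.
#'
#' @return data.frame with one row per behaviour: `pitch_deg`, dynamic
#'   amplitude `amp`, frequency `freq_hz`, noise SD `noise`, and axis
#'   weights `wx`, `wy`, `wz`.
#' @export
signal_model <- function() {
  data.frame(
    behaviour = behaviour_vocabulary(),
    pitch_deg = c(10, 30, 20, 15, 5, 5, 8, 20, 25, 35, 50, 70, 40, 20),
    amp       = c(0.15, 6, 4.5, 5.5, 3.5, 1.8, 2.6, 1.2, 2, 1.5, 3, 0.8,
                  0.5, 2.8),
    freq_hz   = c(0.5, 3.2, 2.4, 1.6, 4, 1.8, 2.2, 1.2, 3, 4.5, 1.4, 0.8,
                  1, 3.6),
    noise     = c(0.1, 1, 0.9, 1.1, 0.7, 0.5, 0.8, 0.4, 0.5, 0.4, 1.2,
                  0.4, 0.25, 0.6),
    wx = c(0.5, 1.0, 0.3, 0.5, 0.2, 0.3, 0.6, 0.5, 0.8, 0.3, 0.9, 0.2,
           0.4, 0.3),
    wy = c(0.5, 0.3, 1.0, 0.4, 0.3, 0.2, 0.7, 0.4, 0.3, 0.8, 0.4, 0.3,
           0.8, 0.9),
    wz = c(0.7, 0.6, 0.4, 1.0, 1.0, 1.0, 0.4, 0.8, 0.4, 0.4, 0.3, 0.9,
           0.3, 0.5),
    vertical_pitch_deg = c(rep(NA, 7), 75, rep(NA, 6)),
    horizontal_pitch_deg = c(rep(NA, 7), 20, rep(NA, 6)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic study population
#'
#' Builds groups with one breeding pair each plus non-breeding helpers of
#' both sexes, true ages, latent growth multipliers, deployment lengths,
#' and longitudinal capture records consistent with a logistic population
#' growth curve. Only individuals past four months of age (the 60 g
#' collaring threshold in mass terms) are collared.
#'
#' @param config list from [population_config()].
#' @return list with `individuals` (metadata of collared individuals) and
#'   `captures` (two capture records per individual for the growth
#'   module).
#' @export
make_population <- function(config = population_config()) {
  set.seed(config$seed)
  sizes <- config$group_sizes
  if (is.null(sizes)) {
    # overdispersed sizes: natural groups range from pairs to ~20 members
    sizes <- pmin(2 + stats::rnbinom(config$n_groups, size = 2.5,
                                     mu = config$group_size_mean - 2), 22)
  }
  if (any(sizes < 2)) stop("group sizes below 2 are infeasible")
  rows <- list()
  for (g in seq_len(config$n_groups)) {
    n <- sizes[g]
    status <- c("breeder", "breeder", rep("non-breeder", n - 2))
    sex <- c("F", "M", sample(c("F", "M"), n - 2, replace = TRUE,
                              prob = c(0.45, 0.55)))
    age <- c(stats::runif(2, 36, 84), stats::runif(n - 2, 4, 36))
    rows[[g]] <- data.frame(
      individual_id = sprintf("G%02d_I%02d", g, seq_len(n)),
      group_id = sprintf("G%02d", g),
      status = status, sex = sex,
      age_months = age,
      group_size = n,
      growth_mult = stats::rnorm(n),
      stringsAsFactors = FALSE
    )
  }
  ind <- do.call(rbind, rows)
  ind$deployment_days <- pmax(1, round(stats::rnorm(
    nrow(ind), config$deployment_days_mean, config$deployment_days_sd)))
  # collaring: breeders always; helpers sampled if a per-group cap is set
  keep <- unlist(lapply(split(seq_len(nrow(ind)), ind$group_id), function(i) {
    br <- i[ind$status[i] == "breeder"]
    nb <- i[ind$status[i] != "breeder"]
    cap <- config$collared_per_group
    if (is.null(cap)) c(br, nb) else c(br, nb[seq_len(max(0, cap - length(br)))])
  }))
  collared <- ind[sort(keep), ]
  rownames(collared) <- NULL

  # logistic growth curve: mass (g) as a function of age in months.
  # First captures happen young (the population is trapped twice a year,
  # so most animals enter the records as juveniles); occasional late
  # first captures and out-of-range recapture gaps yield the realistic
  # share of pairs the growth-index filters exclude.
  curve_mass <- function(age_m) 150 / (1 + exp(-(age_m - 8) / 5))
  nc <- nrow(collared)
  cap_age <- pmin(collared$age_months, stats::runif(nc, 4, 13))
  late <- stats::runif(nc) < 0.12
  cap_age[late] <- collared$age_months[late]
  gap <- sample(80:260, nc, replace = TRUE)
  first_mass <- curve_mass(cap_age) * (1 + 0.05 * stats::rnorm(nc))
  gain <- (curve_mass(cap_age + gap / 30.4) - curve_mass(cap_age)) *
    (1 + 0.25 * collared$growth_mult) + 2 * stats::rnorm(nc)
  t0 <- as.Date("2018-09-01")
  captures <- rbind(
    data.frame(individual_id = collared$individual_id, date = t0,
               mass_g = round(pmax(first_mass, 8), 1), sex = collared$sex,
               stringsAsFactors = FALSE),
    data.frame(individual_id = collared$individual_id, date = t0 + gap,
               mass_g = round(pmax(first_mass + gain, 9), 1),
               sex = collared$sex, stringsAsFactors = FALSE)
  )
  list(individuals = collared, captures = captures)
}

# Linear predictors of one individual's behavioural targets.
individual_targets <- function(meta, model, group_size_center,
                               group_effects = NULL) {
  is_b <- as.numeric(meta$status == "breeder")
  is_m <- as.numeric(meta$sex == "M")
  gs <- meta$group_size - group_size_center
  ce <- model$coef_excavate
  # the age hump applies within non-breeders (breeders are uniformly old)
  # and is centred over the helper age distribution (uniform 4-36 months)
  # so that it does not shift the planted status contrast
  age_dev <- (meta$age_months - model$age_peak_months)^2 - 121.33
  eta_exc <- ce[["intercept"]] + ce[["status"]] * is_b +
    ce[["group_size"]] * gs + ce[["interaction"]] * is_b * gs +
    ce[["sex_male"]] * is_m +
    ce[["age_quad"]] * age_dev * (1 - is_b) +
    ce[["growth"]] * meta$growth_mult
  cr <- model$coef_rest
  eta_rest <- cr[["intercept"]] + cr[["status"]] * is_b +
    cr[["group_size"]] * gs + cr[["interaction"]] * is_b * gs +
    cr[["sex_male"]] * is_m
  co <- model$coef_odba
  eta_odba <- co[["intercept"]] + co[["status"]] * is_b +
    co[["group_size"]] * gs + co[["interaction"]] * is_b * gs +
    co[["sex_male"]] * is_m
  if (!is.null(group_effects)) {
    eta_exc <- eta_exc + group_effects$exc[meta$group_id]
    eta_rest <- eta_rest + group_effects$rest[meta$group_id]
    eta_odba <- eta_odba + group_effects$odba[meta$group_id]
  }
  list(exc = unname(eta_exc), rest = unname(eta_rest),
       odba = unname(eta_odba))
}

#' Simulate one individual's behaviour schedule
#'
#' Semi-Markov generation: bouts are drawn with log-normal dwell times
#' and state probabilities tilted so that the long-run time share of the
#' excavate and rest categories matches the individual's planted
#' targets; remaining categories share the residual time in their base
#' proportions. Each day receives its own logit-scale perturbation, so
#' daily time budgets show realistic between-day variation and
#' within-individual repeatability.
#'
#' @param meta one-row data.frame of individual metadata (as produced by
#'   [make_population()]).
#' @param model list from [schedule_model()].
#' @param days number of deployment days.
#' @param seed integer seed for this individual's stream.
#' @param group_size_center centring constant for group size (the
#'   population mean).
#' @param day_s seconds per day.
#' @return data.frame of labelled intervals (`start_s`, `end_s`,
#'   `behaviour`) tiling the deployment without gaps or overlaps.
#' @export
simulate_schedule <- function(meta, model, days = meta$deployment_days,
                              seed = 1, group_size_center = 9,
                              day_s = 86400) {
  set.seed(seed)
  eta <- individual_targets(meta, model, group_size_center)
  eta_exc <- eta$exc + stats::rnorm(1, 0, model$sd_individual)
  eta_rest <- eta$rest + stats::rnorm(1, 0, model$sd_individual)
  beh <- model$behaviours
  cats <- map_to_categories(beh)
  mean_dwell <- exp(model$dwell_meanlog + model$dwell_sdlog^2 / 2)
  tshare <- model$bout_weight * mean_dwell  # unnormalised base time shares

  out <- vector("list", days)
  for (d in seq_len(days)) {
    p_exc <- stats::plogis(eta_exc + stats::rnorm(1, 0, model$sd_day))
    p_rest <- stats::plogis(eta_rest + stats::rnorm(1, 0, model$sd_day))
    if (p_exc + p_rest > 0.95) {  # keep room for the remaining categories
      sc <- 0.95 / (p_exc + p_rest)
      p_exc <- p_exc * sc; p_rest <- p_rest * sc
    }
    p_oth <- 1 - p_exc - p_rest
    w <- model$bout_weight
    t_exc <- sum(tshare[cats == "excavate"])
    t_rest <- sum(tshare[cats == "rest"])
    t_oth <- sum(tshare) - t_exc - t_rest
    z <- t_oth / p_oth
    w[cats == "excavate"] <- w[cats == "excavate"] * p_exc * z / t_exc
    w[cats == "rest"] <- w[cats == "rest"] * p_rest * z / t_rest
    w <- w / sum(w)
    n_draw <- ceiling(day_s / sum(w * mean_dwell) * 1.6) + 20
    st <- sample(seq_along(beh), n_draw, replace = TRUE, prob = w)
    dw <- stats::rlnorm(n_draw, model$dwell_meanlog[st],
                        model$dwell_sdlog[st])
    ends <- cumsum(dw)
    while (ends[length(ends)] < day_s) {  # top up in the rare short case
      st2 <- sample(seq_along(beh), 50, replace = TRUE, prob = w)
      dw2 <- stats::rlnorm(50, model$dwell_meanlog[st2],
                           model$dwell_sdlog[st2])
      st <- c(st, st2); dw <- c(dw, dw2); ends <- cumsum(dw)
    }
    last <- which(ends >= day_s)[1]
    st <- st[1:last]; ends <- ends[1:last]; ends[last] <- day_s
    out[[d]] <- data.frame(
      start_s = (d - 1) * day_s + c(0, ends[-last]),
      end_s = (d - 1) * day_s + ends,
      behaviour = beh[st], stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Synthesize a raw tri-axial acceleration stream from a schedule
#'
#' Per-sample signal: gravity components from the behaviour's posture
#' (plus a per-bout pitch jitter), a sinusoidal dynamic component with
#' per-bout amplitude jitter and random phase, and Gaussian noise.
#' Behaviour boundaries are aligned to samples. Eat intervals draw an
#' upright or horizontal posture with the supplied probability.
#'
#' @param intervals data.frame of labelled intervals from
#'   [simulate_schedule()] (or hand-built).
#' @param sig data.frame from [signal_model()].
#' @param rate_hz sampling rate.
#' @param seed integer seed.
#' @param p_vertical probability that an eat interval is upright.
#' @param individual_id id stored in the returned series.
#' @param amp_mult,pitch_offset per-individual signal idiosyncrasy:
#'   amplitude multiplier and pitch offset in degrees.
#' @return an `acc_series`; the matching sample-aligned intervals are in
#'   attribute `intervals`.
#' @export
synthesize_acc <- function(intervals, sig = signal_model(), rate_hz = 25,
                           seed = 1, p_vertical = 0.55,
                           individual_id = "sim", amp_mult = 1,
                           pitch_offset = 0) {
  set.seed(seed)
  g <- 9.8
  n_int <- nrow(intervals)
  row <- match(intervals$behaviour, sig$behaviour)
  if (anyNA(row)) stop("intervals contain behaviours outside the vocabulary")
  # sample-aligned boundaries
  s0 <- round(intervals$start_s * rate_hz)
  s1 <- round(intervals$end_s * rate_hz)
  n_total <- s1[n_int] - s0[1]
  xyz <- matrix(0, n_total, 3)
  pitch <- sig$pitch_deg[row] + pitch_offset
  vert <- !is.na(sig$vertical_pitch_deg[row])
  if (any(vert)) {
    up <- stats::runif(sum(vert)) < p_vertical
    pitch[vert] <- ifelse(up, sig$vertical_pitch_deg[row[vert]],
                          sig$horizontal_pitch_deg[row[vert]]) + pitch_offset
  }
  for (i in seq_len(n_int)) {
    ns <- s1[i] - s0[i]
    if (ns <= 0) next
    t <- (seq_len(ns) - 1) / rate_hz
    r <- row[i]
    th <- pitch[i] * pi / 180
    a <- sig$amp[r] * amp_mult * exp(stats::rnorm(1, 0, 0.15))
    ph <- stats::runif(3, 0, 2 * pi)
    f <- sig$freq_hz[r] * exp(stats::rnorm(1, 0, 0.08))
    idx <- (s0[i] - s0[1]) + seq_len(ns)
    xyz[idx, 1] <- g * sin(th) + a * sig$wx[r] * sin(2 * pi * f * t + ph[1]) +
      stats::rnorm(ns, 0, sig$noise[r])
    xyz[idx, 2] <- a * sig$wy[r] * sin(2 * pi * f * t + ph[2]) +
      stats::rnorm(ns, 0, sig$noise[r])
    xyz[idx, 3] <- g * cos(th) + a * sig$wz[r] * sin(2 * pi * f * t + ph[3]) +
      stats::rnorm(ns, 0, sig$noise[r])
  }
  series <- acc_series(xyz, individual_id = individual_id, rate_hz = rate_hz,
                       start_time = intervals$start_s[1])
  attr(series, "intervals") <- data.frame(
    start_s = s0 / rate_hz - s0[1] / rate_hz,
    end_s = s1 / rate_hz - s0[1] / rate_hz,
    behaviour = intervals$behaviour, stringsAsFactors = FALSE
  )
  series
}

#' Budget-level simulation of a study dataset
#'
#' Draws per-individual-day window counts and ODBA directly from the
#' planted linear predictors — the same generative model the schedule
#' simulator targets, expressed at the time-budget level where the
#' mixed-model analyses operate. Used for statistical
#' parameter-recovery experiments where synthesizing raw 25 Hz signal
#' would add nothing but runtime.
#'
#' @param population list from [make_population()].
#' @param model list from [schedule_model()].
#' @param seed integer seed.
#' @param windows_per_day classified 2 s windows per day (default 43200).
#' @return data.frame of daily budgets (columns as
#'   [daily_time_budget()]) plus the metadata columns of the population.
#' @export
simulate_budgets <- function(population, model = schedule_model(), seed = 1,
                             windows_per_day = 43200) {
  set.seed(seed)
  ind <- population$individuals
  gids <- unique(ind$group_id)
  geff <- list(
    exc = stats::setNames(stats::rnorm(length(gids), 0, model$sd_group), gids),
    rest = stats::setNames(stats::rnorm(length(gids), 0, model$sd_group), gids),
    odba = stats::setNames(stats::rnorm(length(gids), 0, model$sd_group_odba),
                           gids)
  )
  eta <- individual_targets(ind, model, mean(ind$group_size), geff)
  n <- nrow(ind)
  e_ind <- stats::rnorm(n, 0, model$sd_individual)
  r_ind <- stats::rnorm(n, 0, model$sd_individual)
  o_ind <- stats::rnorm(n, 0, model$sd_individual_odba)
  p_vert <- ifelse(ind$status == "breeder" & ind$sex == "F",
                   model$p_vertical_eat[["breeding_female"]],
                   model$p_vertical_eat[["other"]])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    nd <- ind$deployment_days[i]
    de <- stats::rnorm(nd, 0, model$sd_day)
    dr <- stats::rnorm(nd, 0, model$sd_day)
    pe <- stats::plogis(eta$exc[i] + e_ind[i] + de)
    pr <- stats::plogis(eta$rest[i] + r_ind[i] + dr)
    n_exc <- stats::rbinom(nd, windows_per_day, pe)
    n_rest <- stats::rbinom(nd, pmax(windows_per_day - n_exc, 0),
                            pmin(pr / pmax(1 - pe, 1e-9), 1))
    rem <- pmax(windows_per_day - n_exc - n_rest, 0)
    n_eat <- stats::rbinom(nd, rem, pmin(model$eat_share * windows_per_day /
                                           pmax(rem, 1), 1))
    n_vert <- stats::rbinom(nd, n_eat, p_vert[i])
    n_move <- stats::rbinom(nd, rem, 0.3)
    mu <- exp(eta$odba[i] + o_ind[i])
    odba_day <- stats::rgamma(nd, shape = model$odba_shape,
                              rate = model$odba_shape / mu)
    out[[i]] <- data.frame(
      individual_id = ind$individual_id[i], day = seq_len(nd),
      prop_rest = n_rest / windows_per_day,
      prop_excavate = n_exc / windows_per_day,
      prop_move = n_move / windows_per_day,
      prop_other = 1 - (n_rest + n_exc + n_move) / windows_per_day,
      n_excavate = n_exc, n_rest = n_rest, n_move = n_move,
      n_eat = n_eat, n_vertical_eat = n_vert,
      n_total = windows_per_day, mean_odba = odba_day,
      stringsAsFactors = FALSE
    )
  }
  budgets <- do.call(rbind, out)
  merge(budgets, ind, by = "individual_id", sort = FALSE)
}

#' Aggregate daily budgets to one row per individual
#'
#' Window counts are summed and ODBA averaged over days, giving the
#' per-individual table the breeder/non-breeder mixed models are fitted
#' on.
#'
#' @param budgets data.frame from [simulate_budgets()] (or
#'   [daily_time_budget()] merged with metadata).
#' @return data.frame with one row per individual.
#' @export
aggregate_budgets <- function(budgets) {
  sp <- split(budgets, budgets$individual_id)
  out <- lapply(sp, function(b) {
    data.frame(
      individual_id = b$individual_id[1],
      group_id = b$group_id[1], status = b$status[1], sex = b$sex[1],
      group_size = b$group_size[1], age_months = b$age_months[1],
      growth_mult = b$growth_mult[1],
      n_excavate = sum(b$n_excavate), n_rest = sum(b$n_rest),
      n_eat = sum(b$n_eat), n_vertical_eat = sum(b$n_vertical_eat),
      n_total = sum(b$n_total), odba = mean(b$mean_odba),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Windows with ground-truth labels for classifier development
#'
#' Builds a multi-individual training set: for each synthetic individual
#' and behaviour, a signal excerpt long enough for the requested number
#' of 2 s windows is synthesized (with per-individual amplitude and
#' posture idiosyncrasies), segmented and labelled.
#'
#' @param n_individuals number of synthetic individuals.
#' @param windows_per_class labelled windows per behaviour per
#'   individual.
#' @param seed integer seed.
#' @param rate_hz sampling rate.
#' @param window_s window length (s).
#' @return list with `features` (matrix), `labels`, `individual_id`,
#'   `mean_z`, `odba` vectors across all labelled windows.
#' @export
simulate_training_windows <- function(n_individuals = 12,
                                      windows_per_class = 25, seed = 1,
                                      rate_hz = 25, window_s = 2) {
  sig <- signal_model()
  beh <- behaviour_vocabulary()
  feats <- list(); labs <- list(); ids <- list(); mz <- list(); ob <- list()
  for (i in seq_len(n_individuals)) {
    set.seed(seed * 1000 + i)
    amp_mult <- exp(stats::rnorm(1, 0, 0.2))
    pitch_off <- stats::rnorm(1, 0, 4)
    # one long interval per behaviour, shuffled, with a pad to drop edges
    len <- windows_per_class * window_s + 2 * window_s
    ord <- sample(beh)
    intervals <- data.frame(
      start_s = (seq_along(ord) - 1) * len,
      end_s = seq_along(ord) * len,
      behaviour = ord, stringsAsFactors = FALSE
    )
    series <- synthesize_acc(intervals, sig, rate_hz,
                             seed = seed * 1000 + i,
                             individual_id = sprintf("S%02d", i),
                             amp_mult = amp_mult, pitch_offset = pitch_off)
    w <- segment_windows(series, window_s)
    lab <- attach_labels(w, intervals)$windows
    keep <- !is.na(lab$label)
    # drop the first/last window of each behaviour block to avoid edges
    block <- findInterval(lab$start_s, intervals$start_s)
    first_last <- lab$start_s < intervals$start_s[block] + window_s |
      lab$start_s >= intervals$end_s[block] - 2 * window_s
    keep <- keep & !first_last
    wk <- lab[keep, ]
    attr(wk, "series") <- series; attr(wk, "window_s") <- window_s
    class(wk) <- c("acc_windows", "data.frame")
    feats[[i]] <- extract_features(wk)
    labs[[i]] <- wk$label
    ids[[i]] <- rep(sprintf("S%02d", i), nrow(wk))
    mz[[i]] <- mean_z(wk)
    ob[[i]] <- odba(wk)
  }
  list(features = do.call(rbind, feats), labels = unlist(labs),
       individual_id = unlist(ids), mean_z = unlist(mz),
       odba = unlist(ob))
}

#' Write a complete synthetic dataset to disk
#'
#' Produces the file layout a field campaign would: per-individual
#' behaviour-interval CSVs and raw acceleration CSV excerpts, individual
#' metadata and capture CSVs, a daily-budget CSV derived from the
#' schedules, and a `truth.json` recording every planted parameter for
#' parameter-recovery tests. Raw 25 Hz signal is written only for the
#' first `acc_seconds` of each deployment: full-deployment raw files are
#' enormous and carry no information the schedules do not.
#'
#' @param out_dir output directory (created if needed).
#' @param config list from [population_config()].
#' @param model list from [schedule_model()].
#' @param acc_seconds seconds of raw signal to write per individual.
#' @return invisibly, a list of the written paths and the in-memory
#'   tables.
#' @export
generate_dataset <- function(out_dir, config = population_config(),
                             model = schedule_model(), acc_seconds = 300) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- make_population(config)
  sig <- signal_model()
  gsc <- mean(pop$individuals$group_size)
  label_paths <- character(0); acc_paths <- character(0)
  for (i in seq_len(nrow(pop$individuals))) {
    meta <- pop$individuals[i, ]
    sched <- simulate_schedule(meta, model, days = meta$deployment_days,
                               seed = config$seed * 10000 + i,
                               group_size_center = gsc)
    lp <- file.path(out_dir, paste0(meta$individual_id, "_labels.csv"))
    write_labels(sched, lp)
    label_paths <- c(label_paths, lp)
    cut <- sched[sched$start_s < acc_seconds, ]
    cut$end_s <- pmin(cut$end_s, acc_seconds)
    p_vert <- if (meta$status == "breeder" && meta$sex == "F") {
      model$p_vertical_eat[["breeding_female"]]
    } else model$p_vertical_eat[["other"]]
    series <- synthesize_acc(cut, sig, config$rate_hz,
                             seed = config$seed * 10000 + i,
                             p_vertical = p_vert,
                             individual_id = meta$individual_id)
    ap <- file.path(out_dir, paste0(meta$individual_id, "_acc.csv"))
    write_acc(series, ap)
    acc_paths <- c(acc_paths, ap)
  }
  budgets <- simulate_budgets(pop, model, seed = config$seed)
  utils::write.csv(pop$individuals,
                   file.path(out_dir, "individuals.csv"), row.names = FALSE)
  utils::write.csv(pop$captures,
                   file.path(out_dir, "captures.csv"), row.names = FALSE)
  utils::write.csv(budgets, file.path(out_dir, "budgets.csv"),
                   row.names = FALSE)
  truth <- list(config = config[setdiff(names(config), "group_sizes")],
                planted = lapply(
                  model[c("coef_excavate", "coef_rest", "coef_odba",
                          "p_vertical_eat", "sd_individual", "sd_day",
                          "sd_group")],
                  function(v) if (length(v) > 1) as.list(v) else v))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    dir = out_dir, label_paths = label_paths, acc_paths = acc_paths,
    population = pop, budgets = budgets,
    truth_path = file.path(out_dir, "truth.json")
  ))
}
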