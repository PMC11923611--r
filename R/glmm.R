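#' Mixed models for workload metrics
#'
#' Fits the comparison of behavioural metrics across individuals with a
#' group-level random intercept, using the error structure appropriate to
#' each response: a gamma GLMM with log link for ODBA (a positive,
#' right-skewed activity measure) and beta-binomial GLMMs with logit link
#' for proportions of time (excavating, resting, vertical eating), which
#' absorb the strong overdispersion of per-individual window counts.
#' The default fixed structure is breeding status, centred group size,
#' their interaction — breeder/helper contrasts are expected to widen as
#' more helpers are available — and sex. Estimation is maximum
#' likelihood with a Laplace approximation (glmmTMB).
#'
#' @param data data.frame with one row per individual: columns used by
#'   `fixed`, a `group_id` column, and the response columns — `odba` for
#'   the gamma model, or a numerator/denominator count pair for the
#'   proportion models (`n_excavate`/`n_total`, `n_rest`/`n_total`,
#'   `n_vertical_eat`/`n_eat`).
#' @param response one of `"odba"`, `"excavate"`, `"rest"`,
#'   `"vertical_eat"`.
#' @param fixed right-hand-side formula of fixed effects; group size is
#'   centred to its mean beforehand when a `group_size` column is
#'   present.
#' @param group name of the grouping column for the random intercept.
#' @param REML use restricted maximum likelihood (default FALSE). REML
#'   counteracts the downward bias of variance components — and hence of
#'   coefficient standard errors — when the number of groups is small.
#' @return object of class `glmm_fit`: list with `coefficients` (term,
#'   beta, se, z, p), `family`, `var_group` (random-intercept variance),
#'   `r2_marginal`, `converged`, and the underlying `model`.
#' @export
fit_glmm <- function(data, response = c("odba", "excavate", "rest",
                                        "vertical_eat"),
                     fixed = ~ status * group_size_c + sex,
                     group = "group_id", REML = FALSE) {
  response <- match.arg(response)
  if (length(unique(data[[group]])) < 3) {
    stop("need at least 3 groups for a group random intercept")
  }
  if ("group_size" %in% names(data) && !("group_size_c" %in% names(data))) {
    data$group_size_c <- data$group_size - mean(data$group_size)
  }
  if ("status" %in% names(data) && !is.factor(data$status)) {
    # report the breeder contrast against the non-breeder baseline
    data$status <- factor(data$status,
                          levels = c("non-breeder", "breeder"))
  }
  lhs <- switch(response,
    odba = "odba",
    excavate = "cbind(n_excavate, n_total - n_excavate)",
    rest = "cbind(n_rest, n_total - n_rest)",
    vertical_eat = "cbind(n_vertical_eat, n_eat - n_vertical_eat)"
  )
  fam <- if (response == "odba") {
    stats::Gamma(link = "log")
  } else {
    glmmTMB::betabinomial(link = "logit")
  }
  form <- stats::as.formula(paste(
    lhs, "~", paste(deparse(fixed[[2]]), collapse = ""),
    "+ (1 |", group, ")"
  ))
  model <- glmmTMB::glmmTMB(form, data = data, family = fam, REML = REML)
  converged <- isTRUE(model$sdr$pdHess) &&
    is.finite(as.numeric(stats::logLik(model)))
  if (!converged) {
    warning("GLMM did not converge cleanly; coefficients are flagged")
  }
  sm <- summary(model)$coefficients$cond
  coefs <- data.frame(
    term = rownames(sm), beta = sm[, 1], se = sm[, 2],
    z = sm[, 3], p = sm[, 4], row.names = NULL,
    stringsAsFactors = FALSE
  )
  vg <- glmmTMB::VarCorr(model)$cond[[group]]
  var_group <- if (is.null(vg)) 0 else as.numeric(vg[1, 1])
  structure(
    list(coefficients = coefs, family = if (response == "odba")
      "gamma-log" else "beta-binomial-logit",
      var_group = var_group,
      r2_marginal = r2_marginal_glmm(model, var_group),
      converged = converged, response = response, model = model),
    class = "glmm_fit"
  )
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %s (%s)%s\n", x$response, x$family,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients, digits = 3)
  cat(sprintf("group variance %.4f, marginal R2 %.3f\n",
              x$var_group, x$r2_marginal))
  invisible(x)
}

# Variance-partition (latent-scale) marginal R2: fixed-effect variance
# over fixed + random + distribution-specific variance. Logit-link
# proportions use pi^2/3; the gamma log link uses trigamma(shape).
r2_marginal_glmm <- function(model, var_group) {
  X <- stats::model.matrix(model)
  beta <- glmmTMB::fixef(model)$cond
  eta <- as.numeric(X %*% beta)
  var_f <- stats::var(eta)
  fam <- stats::family(model)$family
  var_d <- if (grepl("Gamma", fam, ignore.case = TRUE)) {
    trigamma(1 / glmmTMB::sigma(model)^2)
  } else {
    pi^2 / 3
  }
  var_f / (var_f + var_group + var_d)
}

#' Pairwise task associations among cooperative behaviours
#'
#' Task specialization would show up as negative associations between an
#' individual's contributions to different cooperative tasks. For each
#' dyad of behaviours, the first behaviour's window counts are modelled
#' by a beta-binomial GLMM on the other behaviour's proportion with a
#' group random intercept; the association is reported as the marginal R2
#' and the predictor's p-value. Optionally, observations flagged by
#' Grubbs's outlier test on either proportion are refitted without.
#'
#' @param data data.frame with one row per individual: count columns
#'   `n_<behaviour>` for each behaviour, `n_total`, and `group_id`.
#' @param behaviours behaviours to cross (default excavate, food_carry,
#'   walk_around).
#' @param screen_outliers also report each dyad refitted without
#'   Grubbs-flagged outliers.
#' @return data.frame with one row per dyad (and per outlier screen):
#'   `response`, `predictor`, `r2_marginal`, `beta`, `p`, `n`,
#'   `outliers_removed`.
#' @export
task_correlations <- function(data,
                              behaviours = c("excavate", "food_carry",
                                             "walk_around"),
                              screen_outliers = FALSE) {
  if (nrow(data) < 10) stop("need at least 10 individuals")
  pairs <- utils::combn(behaviours, 2, simplify = FALSE)
  one <- function(resp, pred, rows, removed) {
    d <- data[rows, ]
    d$y <- d[[paste0("n_", resp)]]
    d$x <- d[[paste0("n_", pred)]] / d$n_total
    if (stats::sd(d$x) == 0) {
      return(data.frame(response = resp, predictor = pred,
                        r2_marginal = NA_real_, beta = NA_real_,
                        p = NA_real_, n = nrow(d),
                        outliers_removed = removed))
    }
    m <- glmmTMB::glmmTMB(cbind(y, n_total - y) ~ x + (1 | group_id),
                          data = d, family = glmmTMB::betabinomial())
    sm <- summary(m)$coefficients$cond
    vg <- glmmTMB::VarCorr(m)$cond$group_id
    data.frame(
      response = resp, predictor = pred,
      r2_marginal = r2_marginal_glmm(m, as.numeric(vg[1, 1])),
      beta = sm["x", 1], p = sm["x", 4], n = nrow(d),
      outliers_removed = removed
    )
  }
  out <- list()
  for (pr in pairs) {
    out[[length(out) + 1]] <- one(pr[1], pr[2], seq_len(nrow(data)), 0L)
    if (screen_outliers) {
      p1 <- data[[paste0("n_", pr[1])]] / data$n_total
      p2 <- data[[paste0("n_", pr[2])]] / data$n_total
      drop <- grubbs_outliers(p1) | grubbs_outliers(p2)
      if (any(drop)) {
        out[[length(out) + 1]] <- one(pr[1], pr[2], which(!drop),
                                      sum(drop))
      }
    }
  }
  do.call(rbind, out)
}

#' Grubbs's test for outliers
#'
#' Iteratively flags the most extreme observation while
#' `max |x - mean| / sd` exceeds the Grubbs critical value at level
#' `alpha`.
#'
#' @param x numeric vector.
#' @param alpha significance level (default 0.05).
#' @return logical vector marking outliers.
#' @export
grubbs_outliers <- function(x, alpha = 0.05) {
  out <- rep(FALSE, length(x))
  repeat {
    idx <- which(!out)
    n <- length(idx)
    if (n < 3) break
    v <- x[idx]
    g <- abs(v - mean(v)) / stats::sd(v)
    tcrit <- stats::qt(1 - alpha / (2 * n), n - 2)
    gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    i <- which.max(g)
    if (g[i] > gcrit) out[idx[i]] <- TRUE else break
  }
  out
}

#' Pearson correlation with its t statistic
#'
#' @param x,y numeric vectors of equal length (>= 3) with non-zero
#'   variance.
#' @return list with `r`, `t` (`r * sqrt(df / (1 - r^2))`), `df`
#'   (`n - 2`) and the two-sided `p`.
#' @export
pearson_with_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  r <- stats::cor(x, y)
  df <- length(x) - 2
  t <- r * sqrt(df / (1 - r^2))
  list(r = r, t = t, df = df,
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Beta-binomial density and random draws
#'
#' Parameterised by the mean probability `prob` and the intra-class
#' overdispersion `rho` in `[0, 1)`: draws are binomial with a
#' Beta-distributed success probability with mean `prob` and variance
#' `rho * prob * (1 - prob)`. As `rho` tends to 0 the distribution
#' reduces to the binomial.
#'
#' @param x count value(s).
#' @param size number of trials.
#' @param prob mean success probability.
#' @param rho overdispersion (default 0 gives the binomial).
#' @param log return log density.
#' @return `dbetabinom()`: (log) density; `rbetabinom()`: random counts.
#' @export
dbetabinom <- function(x, size, prob, rho = 0, log = FALSE) {
  if (rho <= 0) return(stats::dbinom(x, size, prob, log = log))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  ll <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  if (log) ll else exp(ll)
}

#' @rdname dbetabinom
#' @param n number of draws.
#' @export
rbetabinom <- function(n, size, prob, rho = 0) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}
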