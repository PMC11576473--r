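#' Estimate within-day and between-day variance components
#'
#' Fits an intercept-only binomial generalized linear mixed model on the logit
#' scale with two independent Normal random intercepts: one for testing day
#' (between-day) and one per tube observation (within-day). The tube effect is
#' an observation-level random intercept — tube labels have no identity across
#' days, so "tubes within a testing day" is a per-tube effect. The marginal
#' likelihood is maximized with the Laplace approximation via
#' \code{lme4::glmer}. Estimates on the zero boundary are reported as 0
#' (a boundary/singular fit is a legitimate outcome, not an error).
#'
#' @param obs A data frame of tube observations spanning at least 2 days, with
#'   at least 2 tubes on some day. The `arm` column is ignored; pass data from
#'   a single treatment (mixed-arm data would confound arm with day).
#' @return An object of class `variance_components`: a list with
#'   `within_day_sd`, `between_day_sd`, the corresponding variances, the
#'   achieved `log_likelihood`, `n_tubes`, `n_days`, and the fitted model in
#'   `fit`.
#' @examples
#' set.seed(1)
#' obs <- simulate_variability_data(30, 6, variance = variance_assumptions(0.25, 0.6))
#' estimate_variance_components(obs)
#' @export
estimate_variance_components <- function(obs) {
  validate_tube_observations(obs)
  n_days <- length(unique(obs$day_id))
  if (n_days < 2) {
    stop("between-day SD is undefined with a single testing day; ",
         "at least 2 days are required", call. = FALSE)
  }
  if (max(table(obs$day_id)) < 2) {
    stop("at least one day must have 2 or more tubes", call. = FALSE)
  }

  dat <- data.frame(
    dead = obs$n_dead,
    alive = obs$n_exposed - obs$n_dead,
    day = factor(obs$day_id),
    tube_obs = factor(seq_len(nrow(obs)))
  )

  # A constant death proportion carries no excess variation at all: both
  # components sit on the zero boundary and the likelihood is that of the
  # intercept-only binomial model.
  if (length(unique(dat$dead / (dat$dead + dat$alive))) == 1) {
    null_fit <- stats::glm(cbind(dead, alive) ~ 1, data = dat,
                           family = stats::binomial())
    return(structure(
      list(within_day_sd = 0, between_day_sd = 0,
           within_day_variance = 0, between_day_variance = 0,
           log_likelihood = as.numeric(stats::logLik(null_fit)),
           n_tubes = nrow(obs), n_days = n_days, fit = null_fit),
      class = "variance_components"
    ))
  }
  warnings_seen <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(cbind(dead, alive) ~ 1 + (1 | day) + (1 | tube_obs),
                  data = dat, family = stats::binomial()),
      error = function(e) {
        stop("variance-component model failed to fit: ", conditionMessage(e),
             call. = FALSE)
      }
    ),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  conv_fail <- grepl("failed to converge", warnings_seen, ignore.case = TRUE)
  if (any(conv_fail)) {
    stop("variance-component model did not converge: ",
         paste(warnings_seen[conv_fail], collapse = "; "), call. = FALSE)
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  within_sd <- vc$sdcor[vc$grp == "tube_obs"]
  between_sd <- vc$sdcor[vc$grp == "day"]

  structure(
    list(
      within_day_sd = within_sd,
      between_day_sd = between_sd,
      within_day_variance = within_sd^2,
      between_day_variance = between_sd^2,
      log_likelihood = as.numeric(stats::logLik(fit)),
      n_tubes = nrow(obs),
      n_days = n_days,
      fit = fit
    ),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Logit-scale variance components (%d tubes over %d days):\n",
              x$n_tubes, x$n_days))
  cat(sprintf("  within-day  SD %.3f (variance %.3f)\n",
              x$within_day_sd, x$within_day_variance))
  cat(sprintf("  between-day SD %.3f (variance %.3f)\n",
              x$between_day_sd, x$between_day_variance))
  cat(sprintf("  log-likelihood %.2f\n", x$log_likelihood))
  invisible(x)
}

#' Coefficients of variation of tube mortality
#'
#' The per-day CoV (intra-assay precision) is the SD of that day's tube-level
#' mortality proportions divided by their mean; it needs at least 2 tubes on
#' the day and is reported as `NA` otherwise. The overall CoV (inter-assay
#' precision) is, by default, the SD of the daily mean mortalities divided by
#' the grand mean of the daily means; `overall = "pooled"` instead pools all
#' tubes regardless of day.
#'
#' @param obs A data frame of tube observations.
#' @param overall `"daily_means"` (default) or `"pooled"`.
#' @return An object of class `cov_summary`: a list with `per_day` (data frame
#'   of day, n tubes, mean mortality, CoV) and `overall`.
#' @examples
#' obs <- tube_observations(day_id = c(1, 1, 2, 2), tube_id = letters[1:4],
#'                          arm = NA, n_exposed = 10, n_dead = c(3, 5, 5, 7))
#' coefficient_of_variation(obs)$overall  # sd(c(.4,.6)) / .5
#' @export
coefficient_of_variation <- function(obs,
                                     overall = c("daily_means", "pooled")) {
  validate_tube_observations(obs)
  overall <- match.arg(overall)
  prop <- obs$n_dead / obs$n_exposed

  days <- sort(unique(obs$day_id))
  per_day <- do.call(rbind, lapply(days, function(d) {
    p <- prop[obs$day_id == d]
    m <- mean(p)
    cov <- if (length(p) < 2) {
      NA_real_
    } else if (m == 0) {
      stop("per-day CoV undefined: mean mortality is 0 on day ", d,
           call. = FALSE)
    } else {
      stats::sd(p) / m
    }
    data.frame(day_id = d, n_tubes = length(p), mean_mortality = m, cov = cov)
  }))

  if (length(days) < 2) {
    stop("overall CoV requires at least 2 testing days", call. = FALSE)
  }
  vals <- if (overall == "daily_means") per_day$mean_mortality else prop
  grand <- mean(vals)
  if (grand == 0) stop("overall CoV undefined: mean mortality is 0",
                       call. = FALSE)
  structure(
    list(per_day = per_day, overall = stats::sd(vals) / grand,
         overall_method = overall),
    class = "cov_summary"
  )
}

#' @export
print.cov_summary <- function(x, ...) {
  cat(sprintf("Overall CoV (%s): %.3f over %d days\n", x$overall_method,
              x$overall, nrow(x$per_day)))
  print(x$per_day, row.names = FALSE)
  invisible(x)
}

#' Conditional R-squared of a binomial-logit mixed model
#'
#' The proportion of latent-scale variance explained by fixed plus random
#' effects, using the theoretical logistic residual variance \eqn{\pi^2/3}:
#' \deqn{R^2_c = \frac{\sigma^2_f + \sum_k \sigma^2_k}
#'                    {\sigma^2_f + \sum_k \sigma^2_k + \pi^2/3}.}
#'
#' @param fixed_effect_variance Variance of the linear predictor due to fixed
#'   effects (>= 0).
#' @param random_effect_variances Numeric vector of random-effect variances
#'   (each >= 0).
#' @return A proportion in \eqn{[0, 1)}.
#' @examples
#' conditional_r_squared(0, c(1.529, 0.123))
#' @export
conditional_r_squared <- function(fixed_effect_variance,
                                  random_effect_variances = numeric(0)) {
  .check_nonneg(fixed_effect_variance, "fixed_effect_variance")
  if (length(random_effect_variances) > 0 &&
      (any(!is.finite(random_effect_variances)) ||
       any(random_effect_variances < 0))) {
    stop("`random_effect_variances` must all be non-negative", call. = FALSE)
  }
  explained <- fixed_effect_variance + sum(random_effect_variances)
  explained / (explained + pi^2 / 3)
}

#' Variability report for a tube-level dataset
#'
#' Bundles the variance components, their conditional R-squared (intercept-only
#' model, so the explained variance is entirely from the random effects) and
#' the CoV table into a JSON-serializable list, optionally written to file.
#'
#' @param obs A data frame of tube observations.
#' @param path Optional path to write the report as JSON.
#' @return The report list, invisibly if `path` is given.
#' @export
variance_report <- function(obs, path = NULL) {
  comp <- estimate_variance_components(obs)
  cov <- coefficient_of_variation(obs)
  report <- list(
    n_tubes = comp$n_tubes,
    n_days = comp$n_days,
    within_day_sd = comp$within_day_sd,
    between_day_sd = comp$between_day_sd,
    within_day_variance = comp$within_day_variance,
    between_day_variance = comp$between_day_variance,
    log_likelihood = comp$log_likelihood,
    conditional_r_squared = conditional_r_squared(
      0, c(comp$within_day_variance, comp$between_day_variance)),
    overall_cov = cov$overall,
    per_day_cov = cov$per_day
  )
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
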