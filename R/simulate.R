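#' Spread tubes over testing days
#'
#' Tubes are allocated to days as evenly as possible, with remainder tubes
#' going to the earliest days (5 tubes over 2 days gives 3 + 2). Both arms use
#' the same allocation.
#'
#' @param tubes_per_arm Number of tubes per arm.
#' @param days Number of testing days (<= `tubes_per_arm`).
#' @return Integer vector of length `days`: tubes run on each day.
#' @examples
#' day_allocation(5, 2)
#' day_allocation(10, 3)
#' @export
day_allocation <- function(tubes_per_arm, days) {
  tubes_per_arm <- .check_count(tubes_per_arm, "tubes_per_arm")
  days <- .check_count(days, "days")
  if (days > tubes_per_arm) {
    stop("`days` cannot exceed `tubes_per_arm`", call. = FALSE)
  }
  counts <- rep(tubes_per_arm %/% days, days)
  rem <- tubes_per_arm %% days
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  as.integer(counts)
}

#' Simulate the number of dead mosquitoes in one tube
#'
#' One tube's 24-hour death count follows a logit-normal binomial model:
#' \deqn{\mathrm{logit}(p) = \mathrm{logit}(m) + \delta + \varepsilon, \quad
#'       \varepsilon \sim N(0, \sigma_w^2), \quad
#'       X \sim \mathrm{Binomial}(n, p)}
#' where \eqn{m} is the arm's mortality, \eqn{\delta} a (given) day effect and
#' \eqn{\sigma_w} the within-day, tube-to-tube logit SD. Degenerate
#' mortalities 0 and 1 give deterministic counts 0 and `n_exposed`: random
#' effects cannot move a degenerate probability, and no random numbers are
#' consumed.
#'
#' @param arm_mortality Arm-level mortality proportion in \eqn{[0, 1]}.
#' @param day_effect Logit-scale day effect (a real number, default 0).
#' @param within_day_sd Logit-scale SD of the per-tube effect (>= 0).
#' @param n_exposed Mosquitoes exposed in the tube (>= 1).
#' @return A single integer death count in `[0, n_exposed]`.
#' @examples
#' set.seed(1)
#' simulate_tube_count(0.9, within_day_sd = 0.25)
#' simulate_tube_count(1.0, within_day_sd = 0.25)  # always 25
#' @export
simulate_tube_count <- function(arm_mortality, day_effect = 0,
                                within_day_sd = 0, n_exposed = 25L) {
  .check_proportion(arm_mortality, "arm_mortality")
  .check_nonneg(within_day_sd, "within_day_sd")
  n_exposed <- .check_count(n_exposed, "n_exposed")
  if (length(day_effect) != 1 || !is.finite(day_effect)) {
    stop("`day_effect` must be a single finite number", call. = FALSE)
  }
  if (arm_mortality == 0) return(0L)
  if (arm_mortality == 1) return(n_exposed)
  eps <- if (within_day_sd > 0) stats::rnorm(1, 0, within_day_sd) else 0
  p <- stats::plogis(stats::qlogis(arm_mortality) + day_effect + eps)
  stats::rbinom(1, n_exposed, p)
}

#' Simulate one two-arm tube bioassay dataset
#'
#' Generates tube-level death counts for a full experiment under the
#' hierarchical logit-normal binomial model. Each testing day draws a
#' logit-scale day effect \eqn{\delta_d \sim N(0, \sigma_b^2)}; each tube adds
#' an independent \eqn{N(0, \sigma_w^2)} effect. For a single-day design the
#' day effect is fixed at 0: running everything on one day removes between-day
#' variability from the comparison.
#'
#' By default the day effects of the two arms are drawn independently
#' (`day_effects = "independent"`). This is the configuration under which
#' splitting an assay over several days costs power, as observed in practice:
#' each arm's realized day-to-day deviations then perturb the estimated
#' mortality contrast. With `day_effects = "shared"` both arms receive the
#' identical day effect (arms run side-by-side and affected identically),
#' which largely cancels in the two-arm comparison.
#'
#' @param design An [assay_design()].
#' @param effect An [effect_spec()].
#' @param variance A [variance_assumptions()].
#' @param day_effects `"independent"` (default) or `"shared"`: whether the two
#'   arms draw separate day effects or share one per day.
#' @return A data frame of tube observations (columns `day_id`, `tube_id`,
#'   `arm`, `n_exposed`, `n_dead`) with `2 * tubes_per_arm` rows.
#' @examples
#' set.seed(1)
#' simulate_dataset(assay_design(4), effect_spec(0.9, 0.1),
#'                  variance_assumptions(0.25, 0.60))
#' @export
simulate_dataset <- function(design, effect, variance = variance_assumptions(),
                             day_effects = c("independent", "shared")) {
  .check_class(design, "assay_design", "assay_design")
  .check_class(effect, "effect_spec", "effect_spec")
  .check_class(variance, "variance_assumptions", "variance_assumptions")
  day_effects <- match.arg(day_effects)

  D <- design$days
  counts <- day_allocation(design$tubes_per_arm, D)
  day_of_tube <- rep.int(seq_len(D), counts)

  draw_delta <- function() {
    if (D > 1L && variance$between_day_sd > 0) {
      stats::rnorm(D, 0, variance$between_day_sd)
    } else {
      rep(0, D)
    }
  }
  delta_ref <- draw_delta()
  delta_trt <- if (day_effects == "shared") delta_ref else draw_delta()

  one_arm <- function(arm, mortality, delta) {
    n <- design$mosquitoes_per_tube
    Tt <- design$tubes_per_arm
    if (mortality == 0) {
      dead <- rep(0L, Tt)
    } else if (mortality == 1) {
      dead <- rep(n, Tt)
    } else {
      eps <- if (variance$within_day_sd > 0) {
        stats::rnorm(Tt, 0, variance$within_day_sd)
      } else {
        rep(0, Tt)
      }
      p <- stats::plogis(stats::qlogis(mortality) + delta[day_of_tube] + eps)
      dead <- stats::rbinom(Tt, n, p)
    }
    data.frame(
      day_id = day_of_tube,
      tube_id = sprintf("%s_d%d_t%02d", substr(arm, 1, 3), day_of_tube,
                        seq_len(Tt)),
      arm = arm,
      n_exposed = n,
      n_dead = dead,
      stringsAsFactors = FALSE
    )
  }

  obs <- rbind(
    one_arm("reference", effect$reference_mortality, delta_ref),
    one_arm("treatment",
            effect$reference_mortality + effect$mortality_difference,
            delta_trt)
  )
  rownames(obs) <- NULL
  obs
}

#' Simulate single-arm variability-study data
#'
#' Emulates an observational variability study: one treatment run repeatedly
#' over many days, the setting in which the within- and between-day variance
#' components are estimated. Each day draws its own logit-scale effect
#' \eqn{N(0, \sigma_b^2)} (here day effects are always drawn, since day-to-day
#' variation is the object of study), and each tube an independent
#' \eqn{N(0, \sigma_w^2)} effect.
#'
#' @param days Number of testing days.
#' @param tubes_per_day Tubes run per day.
#' @param mosquitoes_per_tube Mosquitoes per tube (default 25).
#' @param mortality Median tube mortality (in (0, 1)).
#' @param variance A [variance_assumptions()].
#' @return A data frame of tube observations with `arm = NA`.
#' @examples
#' set.seed(1)
#' head(simulate_variability_data(5, 4, variance = variance_assumptions(0.35, 1.24)))
#' @export
simulate_variability_data <- function(days, tubes_per_day,
                                      mosquitoes_per_tube = 25L,
                                      mortality = 0.5,
                                      variance = variance_assumptions()) {
  days <- .check_count(days, "days")
  tubes_per_day <- .check_count(tubes_per_day, "tubes_per_day")
  mosquitoes_per_tube <- .check_count(mosquitoes_per_tube, "mosquitoes_per_tube")
  .check_proportion(mortality, "mortality")
  if (mortality %in% c(0, 1)) {
    stop("`mortality` must lie strictly between 0 and 1", call. = FALSE)
  }
  .check_class(variance, "variance_assumptions", "variance_assumptions")

  n_tubes <- days * tubes_per_day
  day_id <- rep(seq_len(days), each = tubes_per_day)
  delta <- if (variance$between_day_sd > 0) {
    stats::rnorm(days, 0, variance$between_day_sd)
  } else {
    rep(0, days)
  }
  eps <- if (variance$within_day_sd > 0) {
    stats::rnorm(n_tubes, 0, variance$within_day_sd)
  } else {
    rep(0, n_tubes)
  }
  p <- stats::plogis(stats::qlogis(mortality) + delta[day_id] + eps)
  data.frame(
    day_id = day_id,
    tube_id = sprintf("d%03d_t%02d", day_id,
                      rep(seq_len(tubes_per_day), times = days)),
    arm = NA_character_,
    n_exposed = mosquitoes_per_tube,
    n_dead = stats::rbinom(n_tubes, mosquitoes_per_tube, p),
    stringsAsFactors = FALSE
  )
}

#' Write tube observations to a CSV file
#'
#' Writes the standard five columns (`day_id`, `tube_id`, `arm`, `n_exposed`,
#' `n_dead`) plus any extra pass-through columns, with a header row.
#'
#' @param obs A data frame of tube observations.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_tube_csv()] for the inverse operation.
#' @export
write_tube_csv <- function(obs, path) {
  validate_tube_observations(obs)
  core <- c("day_id", "tube_id", "arm", "n_exposed", "n_dead")
  obs <- obs[, c(core, setdiff(names(obs), core)), drop = FALSE]
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Vectorized engine behind estimate_power(): per-replicate arm death totals.
# Same data-generating process as simulate_dataset(), drawn replicate-wise in
# matrices (days x replicates day effects, tubes x replicates tube effects).
.simulate_arm_totals <- function(design, effect, variance, replicates,
                                 day_effects = "independent") {
  Tt <- design$tubes_per_arm
  D <- design$days
  n <- design$mosquitoes_per_tube
  day_of_tube <- rep.int(seq_len(D), day_allocation(Tt, D))

  draw_delta <- function() {
    if (D > 1L && variance$between_day_sd > 0) {
      matrix(stats::rnorm(D * replicates, 0, variance$between_day_sd),
             D, replicates)
    } else {
      matrix(0, D, replicates)
    }
  }
  delta_ref <- draw_delta()
  delta_trt <- if (day_effects == "shared") delta_ref else draw_delta()

  arm_totals <- function(mortality, delta) {
    if (mortality == 0) return(rep(0L, replicates))
    if (mortality == 1) return(rep(Tt * n, replicates))
    eta <- stats::qlogis(mortality) + delta[day_of_tube, , drop = FALSE]
    if (variance$within_day_sd > 0) {
      eta <- eta + matrix(stats::rnorm(Tt * replicates, 0, variance$within_day_sd),
                          Tt, replicates)
    }
    dead <- matrix(stats::rbinom(Tt * replicates, n, stats::plogis(eta)),
                   Tt, replicates)
    colSums(dead)
  }

  list(
    reference = arm_totals(effect$reference_mortality, delta_ref),
    treatment = arm_totals(effect$reference_mortality + effect$mortality_difference,
                           delta_trt),
    n_per_arm = Tt * n
  )
}
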