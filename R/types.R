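#' Describe the layout of a two-arm tube bioassay
#'
#' An assay design fixes how many tubes each treatment arm uses, over how many
#' testing days the tubes are spread, and how many mosquitoes go into each
#' tube. Tubes are allocated to days as evenly as possible (see
#' [day_allocation()]), identically for both arms.
#'
#' @param tubes_per_arm Number of tubes per treatment arm (>= 1).
#' @param days Number of testing days (>= 1, <= `tubes_per_arm`).
#' @param mosquitoes_per_tube Mosquitoes exposed per tube (>= 1); the WHO
#'   standard is 25.
#'
#' @return An object of class `assay_design`.
#' @examples
#' assay_design(4)                # the standard 4x4 single-day design
#' assay_design(10, days = 2)
#' @export
assay_design <- function(tubes_per_arm, days = 1L, mosquitoes_per_tube = 25L) {
  tubes_per_arm <- .check_count(tubes_per_arm, "tubes_per_arm")
  days <- .check_count(days, "days")
  mosquitoes_per_tube <- .check_count(mosquitoes_per_tube, "mosquitoes_per_tube")
  if (days > tubes_per_arm) {
    stop("`days` (", days, ") cannot exceed `tubes_per_arm` (", tubes_per_arm,
         "): there cannot be more day groups than tubes per arm", call. = FALSE)
  }
  structure(
    list(tubes_per_arm = tubes_per_arm, days = days,
         mosquitoes_per_tube = mosquitoes_per_tube),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("Assay design: %d tubes/arm x %d mosquitoes/tube over %d day%s\n",
              x$tubes_per_arm, x$mosquitoes_per_tube, x$days,
              if (x$days > 1) "s" else ""))
  invisible(x)
}

#' Specify arm mortalities via a reference level and a difference
#'
#' The reference arm (pyrethroid-only) has mortality `reference_mortality`;
#' the treatment arm (pyrethroid-PBO) has mortality
#' `reference_mortality + mortality_difference`. Mortalities are interpreted
#' as the back-transform of the logit-scale mean of the tube-level
#' distribution (i.e. the median tube mortality).
#'
#' @param reference_mortality Mortality proportion of the reference arm, in
#'   \eqn{[0, 1]}.
#' @param mortality_difference Added mortality in the treatment arm, in
#'   \eqn{[0, 1 - reference\_mortality]}.
#'
#' @return An object of class `effect_spec`.
#' @examples
#' effect_spec(0.90, 0.10)  # 90% vs 100%: the WHO synergism threshold case
#' @export
effect_spec <- function(reference_mortality, mortality_difference = 0) {
  .check_proportion(reference_mortality, "reference_mortality")
  .check_proportion(mortality_difference, "mortality_difference")
  if (reference_mortality + mortality_difference > 1 + 1e-12) {
    stop("reference_mortality + mortality_difference must not exceed 1 (got ",
         reference_mortality + mortality_difference, ")", call. = FALSE)
  }
  structure(
    list(reference_mortality = reference_mortality,
         mortality_difference = mortality_difference),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  cat(sprintf("Effect: reference %.1f%% vs treatment %.1f%% (difference %.1f pp)\n",
              100 * x$reference_mortality,
              100 * (x$reference_mortality + x$mortality_difference),
              100 * x$mortality_difference))
  invisible(x)
}

#' Logit-scale variability assumptions for the simulator
#'
#' Both standard deviations are on the logit scale, as estimated by a binomial
#' mixed model with a tube-within-day random intercept (`within_day_sd`) and a
#' testing-day random intercept (`between_day_sd`). The defaults are the
#' values observed for a pyrethroid-resistant strain, the relevant setting for
#' synergism assays.
#'
#' @param within_day_sd Logit-scale SD of per-tube random effects (>= 0).
#' @param between_day_sd Logit-scale SD of per-day random effects (>= 0).
#'
#' @return An object of class `variance_assumptions`.
#' @examples
#' variance_assumptions()            # resistant-strain defaults
#' variance_assumptions(0.35, 1.24)  # a much noisier, susceptible-strain level
#' @export
variance_assumptions <- function(within_day_sd = 0.25, between_day_sd = 0.60) {
  .check_nonneg(within_day_sd, "within_day_sd")
  .check_nonneg(between_day_sd, "between_day_sd")
  structure(
    list(within_day_sd = within_day_sd, between_day_sd = between_day_sd),
    class = "variance_assumptions"
  )
}

#' @export
print.variance_assumptions <- function(x, ...) {
  cat(sprintf("Logit-scale SDs: within-day %.3g, between-day %.3g\n",
              x$within_day_sd, x$between_day_sd))
  invisible(x)
}

#' Assemble and validate a table of tube observations
#'
#' The unit of observation throughout the package is one tube: the day it was
#' run, its identifier, which arm it belongs to, how many mosquitoes were
#' exposed and how many were dead at 24 hours.
#'
#' @param day_id Integer day index (1, 2, ...).
#' @param tube_id Character tube identifier (opaque).
#' @param arm `"reference"`, `"treatment"`, or `NA` for single-arm
#'   variability data.
#' @param n_exposed Mosquitoes exposed per tube (>= 1).
#' @param n_dead Mosquitoes dead at 24 h (0 <= `n_dead` <= `n_exposed`).
#'
#' @return A validated `data.frame` with the five columns above.
#' @examples
#' tube_observations(day_id = c(1, 1), tube_id = c("a", "b"),
#'                   arm = c("reference", "treatment"),
#'                   n_exposed = 25, n_dead = c(20, 25))
#' @export
tube_observations <- function(day_id, tube_id, arm, n_exposed, n_dead) {
  obs <- data.frame(
    day_id = as.integer(day_id),
    tube_id = as.character(tube_id),
    arm = as.character(arm),
    n_exposed = as.integer(n_exposed),
    n_dead = as.integer(n_dead),
    stringsAsFactors = FALSE
  )
  validate_tube_observations(obs)
}

#' Validate a table of tube observations
#'
#' Checks the tube-level invariants: required columns present, counts
#' non-negative integers, `n_dead <= n_exposed`, `n_exposed >= 1`, and `arm`
#' (when given) one of `"reference"`/`"treatment"`.
#'
#' @param obs A data frame of tube observations.
#' @param context Label used in error messages (e.g. a file name).
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_tube_observations <- function(obs, context = "tube observations") {
  required <- c("day_id", "tube_id", "arm", "n_exposed", "n_dead")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0) {
    stop(context, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(obs) == 0) {
    stop(context, ": no observations", call. = FALSE)
  }
  bad <- which(!is.finite(obs$n_exposed) | obs$n_exposed < 1)
  if (length(bad) > 0) {
    stop(context, ": n_exposed must be a positive integer (row ", bad[1], ")",
         call. = FALSE)
  }
  bad <- which(!is.finite(obs$n_dead) | obs$n_dead < 0 | obs$n_dead > obs$n_exposed)
  if (length(bad) > 0) {
    stop(context, ": n_dead must lie in [0, n_exposed] (row ", bad[1], ": ",
         obs$n_dead[bad[1]], "/", obs$n_exposed[bad[1]], ")", call. = FALSE)
  }
  known_arm <- is.na(obs$arm) | obs$arm %in% c("reference", "treatment")
  if (!all(known_arm)) {
    stop(context, ": arm must be 'reference', 'treatment' or NA (row ",
         which(!known_arm)[1], ")", call. = FALSE)
  }
  invisible(obs)
}

# ---- shared validators ----

.check_count <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != as.integer(x)) {
    stop("`", name, "` must be a single positive integer", call. = FALSE)
  }
  as.integer(x)
}

.check_proportion <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single proportion in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0) {
    stop("`", name, "` must be a single non-negative number", call. = FALSE)
  }
  invisible(x)
}

.check_class <- function(x, cls, ctor) {
  if (!inherits(x, cls)) {
    stop("expected an object created by `", ctor, "()`", call. = FALSE)
  }
  invisible(x)
}
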