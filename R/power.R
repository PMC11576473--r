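# Stable per-cell seed derived from a base seed and a cell index, kept inside
# the 32-bit integer range so set.seed() accepts it.
.derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) %% 2147483647 + 104729 * as.numeric(index)) %%
               2147483646) + 1L
}

#' Monte-Carlo power of a two-arm tube bioassay
#'
#' Simulates `replicates` complete experiments under the hierarchical
#' logit-normal binomial model, scores each with the two-arm binomial GLM
#' likelihood-ratio test, and reports the proportion of replicates with
#' p-value below `alpha`, together with its Monte-Carlo standard error
#' \eqn{\sqrt{\hat\pi(1-\hat\pi)/R}}.
#'
#' @param design An [assay_design()].
#' @param effect An [effect_spec()].
#' @param variance A [variance_assumptions()].
#' @param alpha Significance level (default 0.05, two-sided via the
#'   chi-square(1) tail).
#' @param replicates Number of simulated experiments (default 10000).
#' @param seed Optional integer seed; when given the estimate is reproducible
#'   bit-for-bit.
#' @param day_effects Passed to the simulator; see [simulate_dataset()].
#' @return An object of class `power_estimate`: a list with `power`,
#'   `mc_standard_error`, and the inputs.
#' @examples
#' estimate_power(assay_design(4), effect_spec(0.90, 0.10),
#'                variance_assumptions(0.25, 0), replicates = 2000, seed = 1)
#' @export
estimate_power <- function(design, effect, variance = variance_assumptions(),
                           alpha = 0.05, replicates = 10000L, seed = NULL,
                           day_effects = c("independent", "shared")) {
  .check_class(design, "assay_design", "assay_design")
  .check_class(effect, "effect_spec", "effect_spec")
  .check_class(variance, "variance_assumptions", "variance_assumptions")
  day_effects <- match.arg(day_effects)
  replicates <- .check_count(replicates, "replicates")
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  tot <- .simulate_arm_totals(design, effect, variance, replicates, day_effects)
  stat <- .lrt_stat(tot$reference, tot$n_per_arm, tot$treatment, tot$n_per_arm)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  power <- mean(p < alpha)

  structure(
    list(design = design, effect = effect, variance = variance,
         alpha = alpha, replicates = replicates, power = power,
         mc_standard_error = sqrt(power * (1 - power) / replicates),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         day_effects = day_effects),
    class = "power_estimate"
  )
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Estimated power: %.4f (MC SE %.4f, %d replicates, alpha %.3g)\n",
              x$power, x$mc_standard_error, x$replicates, x$alpha))
  print(x$design); print(x$effect); print(x$variance)
  invisible(x)
}

#' Define a grid of power-simulation scenarios
#'
#' The defaults reproduce the standard scenario grid: mortality differences 0
#' to 50% in 2.5% steps, 4-10 tubes per arm, 1-5 testing days, within-day
#' logit SDs 0.15-0.35 and between-day logit SDs 0.40-0.80, with 10,000
#' replicates per combination.
#'
#' @param differences Mortality differences to assess (evenly spaced grid).
#' @param tubes_per_arm Tube counts per arm.
#' @param days Numbers of testing days.
#' @param within_day_sds Within-day logit-scale SDs.
#' @param between_day_sds Between-day logit-scale SDs.
#' @param reference_mortality Reference-arm mortality (default 0.50, the point
#'   of maximum uncertainty).
#' @param alpha Significance level.
#' @param replicates Replicates per combination.
#' @param base_seed Base seed; each combination derives its own seed from it,
#'   so any grid cell is reproducible in isolation.
#' @return An object of class `simulation_grid`.
#' @export
simulation_grid <- function(differences = seq(0, 0.50, by = 0.025),
                            tubes_per_arm = 4:10,
                            days = 1:5,
                            within_day_sds = c(0.15, 0.20, 0.25, 0.30, 0.35),
                            between_day_sds = c(0.40, 0.50, 0.60, 0.70, 0.80),
                            reference_mortality = 0.5,
                            alpha = 0.05,
                            replicates = 10000L,
                            base_seed = 1L) {
  stopifnot(length(differences) > 0, length(tubes_per_arm) > 0,
            length(days) > 0, length(within_day_sds) > 0,
            length(between_day_sds) > 0)
  .check_proportion(reference_mortality, "reference_mortality")
  for (d in differences) .check_proportion(d, "differences")
  for (s in c(within_day_sds, between_day_sds)) .check_nonneg(s, "sd values")
  if (length(differences) > 1) {
    steps <- diff(sort(differences))
    if (max(steps) - min(steps) > 1e-9) {
      stop("`differences` must lie on an evenly spaced grid", call. = FALSE)
    }
  }
  structure(
    list(differences = differences, tubes_per_arm = as.integer(tubes_per_arm),
         days = as.integer(days), within_day_sds = within_day_sds,
         between_day_sds = between_day_sds,
         reference_mortality = reference_mortality, alpha = alpha,
         replicates = .check_count(replicates, "replicates"),
         base_seed = as.integer(base_seed)),
    class = "simulation_grid"
  )
}

#' Enumerate the parameter combinations of a simulation grid
#'
#' @param grid A [simulation_grid()].
#' @return A data frame with one row per Cartesian combination
#'   (difference x tubes x days x within-day SD x between-day SD), its cell
#'   index and derived seed.
#' @examples
#' nrow(grid_combinations(simulation_grid()))  # 21 * 7 * 5 * 5 * 5 = 18375
#' @export
grid_combinations <- function(grid) {
  .check_class(grid, "simulation_grid", "simulation_grid")
  combos <- expand.grid(
    difference = grid$differences,
    tubes_per_arm = grid$tubes_per_arm,
    days = grid$days,
    within_day_sd = grid$within_day_sds,
    between_day_sd = grid$between_day_sds,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  combos$reference_mortality <- grid$reference_mortality
  combos$cell <- seq_len(nrow(combos))
  combos$seed <- .derive_seed(grid$base_seed, combos$cell)
  combos
}

#' Evaluate a power grid
#'
#' Runs [estimate_power()] for every combination in the grid (or a subset of
#' cells, supporting chunked evaluation). Combinations whose day count exceeds
#' the tube count, or whose mortalities exceed 1, are invalid designs and get
#' `NA` power with a logged warning.
#'
#' @param grid A [simulation_grid()].
#' @param cells Optional integer vector of cell indices to evaluate (for
#'   chunked or resumed runs); default all.
#' @param day_effects Passed to the simulator; see [simulate_dataset()].
#' @param progress Print a progress line every 100 cells.
#' @return A data frame with the combination columns plus `power`,
#'   `mc_standard_error`, `replicates`, `alpha`.
#' @export
power_grid <- function(grid, cells = NULL,
                       day_effects = c("independent", "shared"),
                       progress = FALSE) {
  day_effects <- match.arg(day_effects)
  combos <- grid_combinations(grid)
  if (!is.null(cells)) {
    if (!all(cells %in% combos$cell)) {
      stop("`cells` must be valid cell indices of this grid", call. = FALSE)
    }
    combos <- combos[combos$cell %in% cells, , drop = FALSE]
  }
  combos$power <- NA_real_
  combos$mc_standard_error <- NA_real_
  combos$replicates <- grid$replicates
  combos$alpha <- grid$alpha
  for (i in seq_len(nrow(combos))) {
    row <- combos[i, ]
    if (row$days > row$tubes_per_arm ||
        row$reference_mortality + row$difference > 1 + 1e-12) {
      warning("skipping invalid combination at cell ", row$cell, call. = FALSE)
      next
    }
    pe <- estimate_power(
      assay_design(row$tubes_per_arm, row$days),
      effect_spec(row$reference_mortality, row$difference),
      variance_assumptions(row$within_day_sd, row$between_day_sd),
      alpha = grid$alpha, replicates = grid$replicates,
      seed = row$seed, day_effects = day_effects
    )
    combos$power[i] <- pe$power
    combos$mc_standard_error[i] <- pe$mc_standard_error
    if (progress && i %% 100 == 0) {
      message("power_grid: ", i, "/", nrow(combos), " cells done")
    }
  }
  rownames(combos) <- NULL
  combos
}

#' Minimum detectable mortality difference at a target power
#'
#' Scans the mortality-difference grid from small to large, estimating the
#' power of each difference by Monte-Carlo simulation, and returns the first
#' grid value whose estimated power reaches the target (the first-crossing
#' rule, equivalent to reading a power curve against a horizontal target
#' line). Differences that would push the treatment arm past 100% mortality
#' are dropped from the scan with a warning. The scan stops at the first
#' crossing; the evaluated part of the power curve is returned.
#'
#' @param design An [assay_design()].
#' @param variance A [variance_assumptions()].
#' @param reference_mortality Reference-arm mortality (default 0.50, the
#'   worst-case point of maximum uncertainty).
#' @param power_target Target power (default 0.80).
#' @param alpha Significance level.
#' @param replicates Replicates per grid point.
#' @param differences Difference grid (default 0 to 0.50 by 0.025).
#' @param seed Optional base seed; each grid point derives its own seed.
#' @param day_effects Passed to the simulator; see [simulate_dataset()].
#' @return An object of class `mdd_result`: a list with `mdd` (the smallest
#'   qualifying difference, or `NA` if none within the grid), `achievable`,
#'   and `curve` (a data frame of evaluated differences and powers).
#' @examples
#' min_detectable_difference(assay_design(4), variance_assumptions(0.25, 0),
#'                           replicates = 1000, seed = 1)
#' @export
min_detectable_difference <- function(design, variance = variance_assumptions(),
                                      reference_mortality = 0.5,
                                      power_target = 0.80, alpha = 0.05,
                                      replicates = 10000L,
                                      differences = seq(0, 0.50, by = 0.025),
                                      seed = NULL,
                                      day_effects = c("independent", "shared")) {
  .check_class(design, "assay_design", "assay_design")
  .check_class(variance, "variance_assumptions", "variance_assumptions")
  .check_proportion(reference_mortality, "reference_mortality")
  if (power_target < 0 || power_target > 1) {
    stop("`power_target` must be in [0, 1]", call. = FALSE)
  }
  day_effects <- match.arg(day_effects)
  differences <- sort(differences)
  ok <- reference_mortality + differences <= 1 + 1e-12
  if (!all(ok)) {
    warning("scan truncated at a difference of ", 1 - reference_mortality,
            ": larger differences would exceed 100% treatment mortality",
            call. = FALSE)
    differences <- differences[ok]
  }

  curve <- data.frame(difference = numeric(0), power = numeric(0),
                      mc_standard_error = numeric(0), seed = integer(0))
  mdd <- NA_real_
  for (i in seq_along(differences)) {
    d <- differences[i]
    cell_seed <- if (is.null(seed)) NULL else .derive_seed(seed, i)
    pe <- estimate_power(design, effect_spec(reference_mortality, d), variance,
                         alpha = alpha, replicates = replicates,
                         seed = cell_seed, day_effects = day_effects)
    curve[nrow(curve) + 1L, ] <- list(d, pe$power, pe$mc_standard_error,
                                      if (is.null(cell_seed)) NA_integer_ else cell_seed)
    if (pe$power >= power_target) {
      mdd <- d
      break
    }
  }

  structure(
    list(mdd = mdd, achievable = !is.na(mdd), power_target = power_target,
         design = design, variance = variance,
         reference_mortality = reference_mortality, alpha = alpha,
         replicates = replicates, curve = curve, day_effects = day_effects),
    class = "mdd_result"
  )
}

#' @export
print.mdd_result <- function(x, ...) {
  if (x$achievable) {
    cat(sprintf("Minimum detectable difference at %.0f%% power: %.1f%% (reference %.0f%%)\n",
                100 * x$power_target, 100 * x$mdd, 100 * x$reference_mortality))
  } else {
    cat(sprintf("No difference within the grid reaches %.0f%% power (reference %.0f%%)\n",
                100 * x$power_target, 100 * x$reference_mortality))
  }
  invisible(x)
}

#' Minimum tubes per arm needed to detect a given difference
#'
#' Scans an ascending range of tubes-per-arm values and returns the smallest
#' one whose Monte-Carlo power for the given mortality difference reaches the
#' target, or a not-achievable result if none does (mirroring effects so small
#' that the required sample size falls outside the assessed range). Candidates
#' smaller than the number of days are skipped with a warning.
#'
#' @param difference Mortality difference to detect.
#' @param variance A [variance_assumptions()].
#' @param reference_mortality Reference-arm mortality (default 0.50).
#' @param days Number of testing days.
#' @param power_target Target power (default 0.80).
#' @param tubes_range Ascending candidate tube counts (default 4:10).
#' @param alpha Significance level.
#' @param replicates Replicates per candidate.
#' @param mosquitoes_per_tube Mosquitoes per tube (default 25).
#' @param seed Optional base seed.
#' @param day_effects Passed to the simulator; see [simulate_dataset()].
#' @return An object of class `min_tubes_result`: a list with `min_tubes`
#'   (`NA` when not achievable within the range), `achievable`, and `curve`.
#' @examples
#' min_tubes_for_difference(0.5, variance_assumptions(0.25, 0),
#'                          replicates = 500, seed = 1)
#' @export
min_tubes_for_difference <- function(difference,
                                     variance = variance_assumptions(),
                                     reference_mortality = 0.5, days = 1L,
                                     power_target = 0.80, tubes_range = 4:10,
                                     alpha = 0.05, replicates = 10000L,
                                     mosquitoes_per_tube = 25L, seed = NULL,
                                     day_effects = c("independent", "shared")) {
  .check_proportion(difference, "difference")
  .check_proportion(reference_mortality, "reference_mortality")
  if (length(tubes_range) == 0 || is.unsorted(tubes_range)) {
    stop("`tubes_range` must be a nonempty ascending integer vector",
         call. = FALSE)
  }
  day_effects <- match.arg(day_effects)

  curve <- data.frame(tubes_per_arm = integer(0), power = numeric(0),
                      mc_standard_error = numeric(0))
  min_tubes <- NA_integer_
  for (i in seq_along(tubes_range)) {
    tt <- tubes_range[i]
    if (tt < days) {
      warning("skipping ", tt, " tubes/arm: fewer tubes than testing days",
              call. = FALSE)
      next
    }
    cell_seed <- if (is.null(seed)) NULL else .derive_seed(seed, i)
    pe <- estimate_power(assay_design(tt, days, mosquitoes_per_tube),
                         effect_spec(reference_mortality, difference),
                         variance, alpha = alpha, replicates = replicates,
                         seed = cell_seed, day_effects = day_effects)
    curve[nrow(curve) + 1L, ] <- list(as.integer(tt), pe$power,
                                      pe$mc_standard_error)
    if (pe$power >= power_target) {
      min_tubes <- as.integer(tt)
      break
    }
  }

  structure(
    list(min_tubes = min_tubes, achievable = !is.na(min_tubes),
         power_target = power_target, difference = difference,
         reference_mortality = reference_mortality, days = days,
         alpha = alpha, replicates = replicates, curve = curve,
         day_effects = day_effects),
    class = "min_tubes_result"
  )
}

#' @export
print.min_tubes_result <- function(x, ...) {
  if (x$achievable) {
    cat(sprintf("Minimum tubes/arm to detect a %.1f%% difference at %.0f%% power: %d\n",
                100 * x$difference, 100 * x$power_target, x$min_tubes))
  } else {
    cat(sprintf("A %.1f%% difference is not achievable at %.0f%% power within the assessed range\n",
                100 * x$difference, 100 * x$power_target))
  }
  invisible(x)
}

.grid_columns <- c("difference", "tubes_per_arm", "days", "within_day_sd",
                   "between_day_sd", "reference_mortality", "cell", "seed",
                   "power", "mc_standard_error", "replicates", "alpha")

#' Save or load a precomputed power-grid cache
#'
#' The cache is a plain CSV of grid rows plus a JSON sidecar (same path with a
#' `.json` extension) recording the column schema, the row count and the
#' package version, so a cache can be validated when reloaded. The round trip
#' is lossless, including seeds and replicate counts.
#'
#' @param grid_table A data frame produced by [power_grid()].
#' @param path CSV file path.
#' @return `save_grid()` returns `path` invisibly; `load_grid()` returns the
#'   grid table.
#' @export
save_grid <- function(grid_table, path) {
  missing_cols <- setdiff(.grid_columns, names(grid_table))
  if (length(missing_cols) > 0) {
    stop("grid table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(grid_table[, .grid_columns], path, row.names = FALSE,
                   quote = FALSE)
  meta <- list(
    format = "tubepower_power_grid",
    columns = .grid_columns,
    rows = nrow(grid_table),
    package_version = as.character(utils::packageVersion("tubepower"))
  )
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_grid
#' @export
load_grid <- function(path) {
  if (!file.exists(path)) stop("no such grid cache: ", path, call. = FALSE)
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed grid cache '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing_cols <- setdiff(.grid_columns, names(tab))
  if (length(missing_cols) > 0) {
    stop("malformed grid cache '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cc in setdiff(.grid_columns, c("power", "mc_standard_error"))) {
    bad <- which(is.na(tab[[cc]]))
    if (length(bad) > 0) {
      stop("malformed grid cache '", path, "': missing value in column '", cc,
           "' at row ", bad[1], call. = FALSE)
    }
  }
  tab
}

#' Look up one combination in a power-grid cache
#'
#' Exact lookup only: a combination absent from the cache raises a condition
#' of class `tubepower_not_precomputed` rather than interpolating.
#'
#' @param grid_table A grid table from [power_grid()] or [load_grid()].
#' @param difference,tubes_per_arm,days,within_day_sd,between_day_sd
#'   Combination to look up.
#' @return The matching one-row data frame.
#' @export
grid_lookup <- function(grid_table, difference, tubes_per_arm, days,
                        within_day_sd, between_day_sd) {
  hit <- abs(grid_table$difference - difference) < 1e-9 &
    grid_table$tubes_per_arm == tubes_per_arm &
    grid_table$days == days &
    abs(grid_table$within_day_sd - within_day_sd) < 1e-9 &
    abs(grid_table$between_day_sd - between_day_sd) < 1e-9
  if (!any(hit)) {
    stop(structure(
      class = c("tubepower_not_precomputed", "error", "condition"),
      list(message = sprintf(
        paste0("combination not precomputed in this grid cache: difference %g,",
               " %d tubes/arm, %d day(s), within-day SD %g, between-day SD %g"),
        difference, tubes_per_arm, days, within_day_sd, between_day_sd),
        call = NULL)
    ))
  }
  grid_table[which(hit)[1], , drop = FALSE]
}
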