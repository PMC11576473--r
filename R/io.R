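#' Describe how a tube-level CSV maps onto tube observations
#'
#' Deposited bioassay files vary in their column headers, so the reader is
#' driven by an explicit mapping from source columns to the fields of a tube
#' observation. Columns not mentioned in the mapping (weights, temperature,
#' humidity, ...) are preserved as pass-through metadata.
#'
#' @param date Source column holding the testing date (or day label).
#' @param tube Source column holding the tube identifier.
#' @param arm Source column holding the treatment arm, or `NULL` for
#'   single-arm variability data.
#' @param exposed Source column holding the number of mosquitoes exposed.
#' @param dead Source column holding the number dead at 24 h.
#' @param date_format Optional `strptime` format for parsing dates; when
#'   `NULL`, ISO dates are tried and non-date values fall back to their
#'   natural (numeric or lexical) order.
#' @return An object of class `column_mapping`.
#' @export
column_mapping <- function(date = "date", tube = "tube_id", arm = NULL,
                           exposed = "n_exposed", dead = "n_dead",
                           date_format = NULL) {
  cols <- c(date = date, tube = tube, exposed = exposed, dead = dead,
            if (!is.null(arm)) c(arm = arm))
  if (anyDuplicated(cols)) {
    stop("mapped source columns must be distinct", call. = FALSE)
  }
  structure(list(date = date, tube = tube, arm = arm, exposed = exposed,
                 dead = dead, date_format = date_format),
            class = "column_mapping")
}

# Order distinct date values chronologically: explicit format first, then ISO
# dates, then numeric order, then lexical order.
.day_order <- function(values, date_format) {
  u <- unique(values)
  if (!is.null(date_format)) {
    d <- as.Date(as.character(u), format = date_format)
    if (anyNA(d)) {
      stop("date column has values not matching format '", date_format, "'",
           call. = FALSE)
    }
    return(u[order(d)])
  }
  d <- tryCatch(suppressWarnings(as.Date(as.character(u))),
                error = function(e) rep(as.Date(NA), length(u)))
  if (!anyNA(d)) return(u[order(d)])
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) return(u[order(num)])
  sort(u)
}

#' Read tube-level bioassay data from a CSV file
#'
#' Reads a delimited file (UTF-8, header row required) and returns one tube
#' observation per row. `day_id` is assigned by the distinct date values in
#' chronological order (1 = earliest). Rows violating the tube invariants
#' (e.g. more dead than exposed) are rejected with a message naming the
#' offending row; unmapped columns are carried along unchanged.
#'
#' @param path CSV file path.
#' @param mapping A [column_mapping()].
#' @return A validated data frame of tube observations; the original date
#'   value is kept in a `date` column.
#' @seealso [write_tube_csv()]; read its output back with
#'   `column_mapping(date = "day_id", arm = "arm")`.
#' @export
read_tube_csv <- function(path, mapping = column_mapping()) {
  .check_class(mapping, "column_mapping", "column_mapping")
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("could not parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0) stop("'", path, "' contains no data rows", call. = FALSE)

  needed <- c(mapping$date, mapping$tube, mapping$exposed, mapping$dead,
              mapping$arm)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("'", path, "' is missing mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  exposed <- suppressWarnings(as.integer(raw[[mapping$exposed]]))
  dead <- suppressWarnings(as.integer(raw[[mapping$dead]]))
  bad <- which(is.na(exposed) | is.na(dead) | exposed < 1 | dead < 0 |
                 dead > exposed)
  if (length(bad) > 0) {
    r <- bad[1]
    stop("'", path, "' row ", r, ": invalid counts (exposed = ",
         raw[[mapping$exposed]][r], ", dead = ", raw[[mapping$dead]][r],
         "); need 0 <= dead <= exposed and exposed >= 1", call. = FALSE)
  }

  date_values <- raw[[mapping$date]]
  day_levels <- .day_order(date_values, mapping$date_format)
  day_id <- match(date_values, day_levels)

  arm <- if (is.null(mapping$arm)) {
    NA_character_
  } else {
    a <- tolower(trimws(as.character(raw[[mapping$arm]])))
    bad_arm <- which(!a %in% c("reference", "treatment"))
    if (length(bad_arm) > 0) {
      stop("'", path, "' row ", bad_arm[1],
           ": arm must be 'reference' or 'treatment' (got '",
           raw[[mapping$arm]][bad_arm[1]], "')", call. = FALSE)
    }
    a
  }

  obs <- data.frame(
    day_id = as.integer(day_id),
    tube_id = as.character(raw[[mapping$tube]]),
    arm = arm,
    n_exposed = exposed,
    n_dead = dead,
    date = as.character(date_values),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(raw), needed)
  if (length(extra) > 0) obs <- cbind(obs, raw[, extra, drop = FALSE])
  validate_tube_observations(obs, context = path)
  obs
}
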