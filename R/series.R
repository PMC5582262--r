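#' Longitudinal measurement series
#'
#' Validated container for subject- or group-level longitudinal
#' measurements: GFR, plasma volume, mass gains and 1,5-AG
#' concentrations by gestational week.
#'
#' @name series
NULL

.SERIES_GROUPS <- c("normal", "gdm_dm")
.SERIES_VARIABLES <- c("gfr", "plasma_volume", "plasma_mass_gain",
                       "total_mass_gain", "ag")
.SERIES_COLS <- c("subject_id", "group", "week", "variable", "value", "sd")

#' Construct a longitudinal series
#'
#' One row per record: `subject_id` (text), `group` (`normal` or
#' `gdm_dm`), `week` (gestational weeks, 0--42), `variable` (one of
#' `gfr`, `plasma_volume`, `plasma_mass_gain`, `total_mass_gain`, `ag`),
#' `value` (in the variable's unit: mL/min, mL, kg, kg, ug/mL), and an
#' optional non-negative `sd`.
#'
#' Validation enforces: no duplicate (subject_id, week, variable);
#' strictly positive values for `gfr`, `plasma_volume` and `ag`; and
#' `total_mass_gain >= plasma_mass_gain` where both are present at a
#' pregnant week.
#'
#' @param records data.frame with the columns above (`sd` optional)
#' @return object of class `longitudinal_series`
#' @export
longitudinal_series <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"sd" %in% names(records)) records$sd <- NA_real_
  missing_cols <- setdiff(.SERIES_COLS, names(records))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[, .SERIES_COLS]
  records$subject_id <- as.character(records$subject_id)
  records$group <- as.character(records$group)
  records$variable <- as.character(records$variable)
  records$week <- as.numeric(records$week)
  records$value <- as.numeric(records$value)
  records$sd <- as.numeric(records$sd)

  bad_group <- which(!records$group %in% .SERIES_GROUPS)
  if (length(bad_group)) {
    stop(sprintf("row %d: unknown group '%s'", bad_group[1],
                 records$group[bad_group[1]]), call. = FALSE)
  }
  bad_var <- which(!records$variable %in% .SERIES_VARIABLES)
  if (length(bad_var)) {
    stop(sprintf("row %d: unknown variable '%s'", bad_var[1],
                 records$variable[bad_var[1]]), call. = FALSE)
  }
  check_week(records$week)
  key <- paste(records$subject_id, records$week, records$variable, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("row %d: duplicate (subject_id, week, variable) record",
                 dup[1]), call. = FALSE)
  }
  pos_var <- records$variable %in% c("gfr", "plasma_volume", "ag")
  bad_val <- which(pos_var & records$value <= 0)
  if (length(bad_val)) {
    stop(sprintf("row %d: %s value must be strictly positive", bad_val[1],
                 records$variable[bad_val[1]]), call. = FALSE)
  }
  bad_sd <- which(!is.na(records$sd) & records$sd < 0)
  if (length(bad_sd)) {
    stop(sprintf("row %d: sd must be non-negative", bad_sd[1]), call. = FALSE)
  }
  pm <- records[records$variable == "plasma_mass_gain" & records$week > 0, ]
  tm <- records[records$variable == "total_mass_gain" & records$week > 0, ]
  m <- match(paste(pm$subject_id, pm$week), paste(tm$subject_id, tm$week))
  m_ok <- !is.na(m)
  if (any(m_ok) && any(tm$value[m[m_ok]] < pm$value[m_ok])) {
    stop("total_mass_gain < plasma_mass_gain for a (subject, week) pair",
         call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records), class = "longitudinal_series")
}

#' @export
print.longitudinal_series <- function(x, ...) {
  r <- x$records
  cat(sprintf("Longitudinal series: %d records, %d subjects, weeks %g-%g\n",
              nrow(r), length(unique(r$subject_id)),
              min(r$week), max(r$week)))
  tab <- table(r$variable, r$group)
  print(tab)
  invisible(x)
}

#' Number of records in a series
#' @param x a [longitudinal_series()]
#' @return integer record count
#' @export
n_records <- function(x) {
  stopifnot(inherits(x, "longitudinal_series"))
  nrow(x$records)
}

#' Per-week group means
#'
#' Arithmetic mean and sample SD per (group, week, variable) — the
#' observed-means table consumed by [calibrate()]. With a single record
#' in a cell the SD is `NA`.
#'
#' @param data a [longitudinal_series()]
#' @return data.frame with columns group, week, variable, mean, sd, n
#' @export
group_means <- function(data) {
  stopifnot(inherits(data, "longitudinal_series"))
  r <- data$records
  agg <- stats::aggregate(value ~ group + week + variable, data = r,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(group = agg$group, week = agg$week,
                    variable = agg$variable,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]))
  out <- out[order(out$group, out$variable, out$week), ]
  rownames(out) <- NULL
  out
}
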