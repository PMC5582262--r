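#' Tabular and configuration I/O
#'
#' CSV readers/writers for longitudinal series and trajectories, JSON
#' writers for fit results, flat key-value configuration for curve
#' parameters (JSON or YAML), and run manifests. All floats are written
#' with 12 significant digits; read-back reproduces the written object
#' to that precision.
#'
#' @name io
NULL

fmt_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 12, format = "g"))
}

#' Read a longitudinal series from CSV
#'
#' Expected header: `subject_id,group,week,variable,value,sd` (UTF-8;
#' blank `sd` allowed). Validation errors name the offending row.
#'
#' @param path CSV file path
#' @return a [longitudinal_series()]; row order preserved
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  missing_cols <- setdiff(setdiff(.SERIES_COLS, "sd"), names(df))
  if (length(missing_cols)) {
    stop("CSV header missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("sd" %in% names(df)) df$sd <- suppressWarnings(as.numeric(df$sd))
  longitudinal_series(df)
}

#' Write a longitudinal series to CSV
#'
#' @param data a [longitudinal_series()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_series <- function(data, path) {
  stopifnot(inherits(data, "longitudinal_series"))
  r <- data$records
  out <- data.frame(subject_id = r$subject_id, group = r$group,
                    week = fmt_num(r$week), variable = r$variable,
                    value = fmt_num(r$value), sd = fmt_num(r$sd))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a calibration result to JSON
#'
#' Serialises estimates, sse, evaluation count, convergence flag and an
#' echo of the fit specification (variant, free/fixed split, bounds,
#' init, tolerance, reabsorption model).
#'
#' @param fit a [calibrate()] result
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  payload <- list(
    estimates = fit$estimates, sse = fit$sse, n_eval = fit$n_eval,
    converged = fit$converged,
    spec = list(variant = fit$spec$variant, free = as.list(fit$spec$free),
                fixed = fit$spec$fixed, bounds = fit$spec$bounds,
                init = fit$spec$init, tol = fit$spec$tol,
                reabs_model = fit$spec$reabs_model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a calibration result from JSON
#'
#' @param path JSON path written by [write_fit()]
#' @return a `fit_result`
#' @export
read_fit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- fit_spec(variant = j$spec$variant,
                   free = unlist(j$spec$free) %||% character(0),
                   fixed = lapply(j$spec$fixed, as.numeric),
                   bounds = lapply(j$spec$bounds,
                                   function(b) as.numeric(unlist(b))),
                   init = lapply(j$spec$init, as.numeric),
                   tol = j$spec$tol, reabs_model = j$spec$reabs_model)
  structure(list(estimates = lapply(j$estimates, as.numeric),
                 sse = j$sse, n_eval = as.integer(j$n_eval),
                 converged = isTRUE(j$converged), spec = spec),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

kinetic_params_to_list <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  list(k_i = p$k_i, glucose = p$glucose,
       curves = curve_config_list(p$curves),
       reabs = unclass(p$reabs), reabs_model = p$reabs_model,
       r_const = p$r_const, stickle_intercept = p$stickle_intercept)
}

kinetic_params_from_list <- function(x) {
  kinetic_params(k_i = x$k_i, glucose = x$glucose,
                 curves = curve_config_from_list(x$curves),
                 reabs = do.call(reabsorption_params,
                                 lapply(x$reabs, as.numeric)),
                 reabs_model = x$reabs_model,
                 r_const = x$r_const, stickle_intercept = x$stickle_intercept)
}

#' Write a trajectory to CSV with a JSON parameter sidecar
#'
#' CSV columns (fixed order): `week,concentration_ug_per_ml`. The full
#' kinetic parameter set used is written next to it as `<path>.params.json`
#' and round-trips exactly through [read_trajectory()].
#'
#' @param traj an [trajectory()] result
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ag_trajectory"))
  out <- data.frame(week = fmt_num(traj$weeks),
                    concentration_ug_per_ml = fmt_num(traj$concentration))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(kinetic_params_to_list(traj$params),
                       paste0(path, ".params.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a trajectory and its parameter sidecar
#'
#' @param path CSV path written by [write_trajectory()]
#' @return an `ag_trajectory`
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".params.json")
  if (!file.exists(sidecar)) stop("missing parameter sidecar: ", sidecar,
                                  call. = FALSE)
  p <- kinetic_params_from_list(jsonlite::read_json(sidecar,
                                                    simplifyVector = FALSE))
  structure(list(weeks = df$week,
                 concentration = df$concentration_ug_per_ml, params = p),
            class = "ag_trajectory")
}

curve_config_list <- function(curves) {
  stopifnot(inherits(curves, "physio_curve_set"))
  g <- curves$gfr; v <- curves$plasma_volume; f <- curves$fpm
  list("gfr.a2" = g$a2, "gfr.a1" = g$a1, "gfr.a0" = g$a0,
       "pv.num" = v$num, "pv.d0" = v$d0, "pv.d1" = v$d1,
       "pv.rate" = v$rate, "pv.t_mid" = v$t_mid, "pv.offset" = v$offset,
       "pv.sign" = v$sign,
       "fpm.slope" = f$slope, "fpm.intercept" = f$intercept)
}

curve_config_from_list <- function(x) {
  x <- lapply(x, as.numeric)
  physio_curve_set(
    gfr = gfr_quadratic(a2 = x[["gfr.a2"]], a1 = x[["gfr.a1"]],
                        a0 = x[["gfr.a0"]]),
    plasma_volume = plasma_volume_sigmoid(
      num = x[["pv.num"]], d0 = x[["pv.d0"]], d1 = x[["pv.d1"]],
      rate = x[["pv.rate"]], t_mid = x[["pv.t_mid"]],
      offset = x[["pv.offset"]], sign = x[["pv.sign"]]),
    fpm = fpm_line(slope = x[["fpm.slope"]],
                   intercept = x[["fpm.intercept"]]))
}

#' Write curve parameters as flat key-value configuration
#'
#' Keys: `gfr.a2, gfr.a1, gfr.a0, pv.num, pv.d0, pv.d1, pv.rate,
#' pv.t_mid, pv.offset, pv.sign, fpm.slope, fpm.intercept`. Format is
#' chosen by extension: `.json` or `.yaml`/`.yml`.
#'
#' @param curves a [physio_curve_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_curve_config <- function(curves, path) {
  cfg <- curve_config_list(curves)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path, precision = 12)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read curve parameters from flat key-value configuration
#'
#' @param path `.json` or `.yaml`/`.yml` file written by
#'   [write_curve_config()] (missing keys fall back to defaults)
#' @return a [physio_curve_set()]
#' @export
read_curve_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported config extension: ", ext, call. = FALSE)
  }
  defaults <- curve_config_list(physio_curve_set())
  curve_config_from_list(utils::modifyList(defaults, cfg))
}

#' Run manifest
#'
#' Records what produced a set of outputs: a free-text command label,
#' MD5 digests of the input files, the seed (if any), the package
#' version and a timestamp. Digests are recomputable from the inputs,
#' so identical manifests imply identical inputs.
#'
#' @param command text label of the operation
#' @param inputs character vector of input file paths
#' @param seed integer seed or `NULL`
#' @return list of class `run_manifest`
#' @export
run_manifest <- function(command, inputs = character(0), seed = NULL) {
  digests <- if (length(inputs)) {
    missing_in <- inputs[!file.exists(inputs)]
    if (length(missing_in)) {
      stop("manifest input not found: ", missing_in[1], call. = FALSE)
    }
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  structure(list(command = command, input_digests = digests, seed = seed,
                 version = as.character(utils::packageVersion("gestag")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' Write a run manifest to JSON
#'
#' @param manifest a [run_manifest()]
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
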