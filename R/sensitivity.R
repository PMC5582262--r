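#' One-at-a-time parameter sweeps
#'
#' Sweeps a single parameter — the input rate k_i, a constant
#' reabsorption fraction, or the mean maximal glucose — across a list of
#' values, holding everything else at a base parameter set, and returns
#' one steady-state trajectory per value.
#'
#' @name sensitivity
NULL

.SWEEP_PARAMS <- c("k_i", "r_const", "glucose")

#' Sweep specification
#'
#' @param parameter one of `"k_i"`, `"r_const"`, `"glucose"`; sweeping
#'   `r_const` overrides the reabsorption model with a constant
#' @param values non-empty, strictly increasing values to sweep
#'   (`r_const` values must lie in (0, 1))
#' @param base base [kinetic_params()]
#' @param weeks gestational week grid, default every 2 weeks from 6 to 38
#' @return object of class `sweep_spec`
#' @export
sweep_spec <- function(parameter = c("k_i", "r_const", "glucose"),
                       values, base = kinetic_params(),
                       weeks = seq(6, 38, by = 2)) {
  parameter <- match.arg(parameter)
  if (length(values) == 0) stop("values must be non-empty", call. = FALSE)
  if (is.unsorted(values, strictly = TRUE)) {
    stop("values must be strictly increasing", call. = FALSE)
  }
  if (parameter == "r_const" && any(values <= 0 | values >= 1)) {
    stop("r_const values must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(inherits(base, "kinetic_params"))
  structure(list(parameter = parameter, values = values, base = base,
                 weeks = weeks), class = "sweep_spec")
}

#' Default sweep value grids
#'
#' k_i 2--5 mg/day, constant r 0.995--0.9984, glucose 5--11 mM: the
#' ranges spanning normal and diabetic pregnancy.
#'
#' @param parameter sweep parameter name
#' @return numeric value grid
#' @export
default_sweep_values <- function(parameter = c("k_i", "r_const", "glucose")) {
  parameter <- match.arg(parameter)
  switch(parameter,
         k_i = c(2, 3, 4, 5),
         r_const = c(0.995, 0.998, 0.9984),
         glucose = c(5, 7.4, 9, 11))
}

set_swept <- function(base, parameter, value) {
  if (parameter == "k_i") {
    base$k_i <- value
    if (is.null(base$r_const)) base else base
  } else if (parameter == "r_const") {
    base$r_const <- value
    base
  } else {
    base$glucose <- value
    base
  }
}

#' Run a one-at-a-time sweep
#'
#' One trajectory per swept value; output order matches the input
#' values. A value whose reabsorption fraction leaves (0, 1) yields an
#' error entry and the sweep continues.
#'
#' @param spec a [sweep_spec()]
#' @return object of class `sweep_result`: list of entries, each with
#'   `value` and either `trajectory` or `error` (message)
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  entries <- lapply(spec$values, function(v) {
    p <- set_swept(spec$base, spec$parameter, v)
    tryCatch(list(value = v, trajectory = trajectory(spec$weeks, p)),
             error = function(e) list(value = v,
                                      error = conditionMessage(e)))
  })
  structure(list(parameter = spec$parameter, entries = entries,
                 weeks = spec$weeks), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  ok <- vapply(x$entries, function(e) is.null(e$error), logical(1))
  cat(sprintf("Sweep over %s: %d values (%d ok, %d failed), %d weeks\n",
              x$parameter, length(x$entries), sum(ok), sum(!ok),
              length(x$weeks)))
  invisible(x)
}

#' Long-format table of a sweep
#'
#' Lossless flattening: one row per (parameter value, week).
#' Error entries are dropped (they carry no concentrations).
#'
#' @param result a [run_sweep()] result
#' @return data.frame with columns parameter, value, week,
#'   concentration_ug_per_ml
#' @export
tabulate_sweep <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  ok <- Filter(function(e) is.null(e$error), result$entries)
  if (length(ok) == 0) {
    stop("no successful sweep entries to tabulate", call. = FALSE)
  }
  do.call(rbind, lapply(ok, function(e) {
    data.frame(parameter = result$parameter, value = e$value,
               week = e$trajectory$weeks,
               concentration_ug_per_ml = e$trajectory$concentration)
  }))
}
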