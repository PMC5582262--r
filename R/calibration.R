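#' Least-squares calibration to longitudinal 1,5-AG means
#'
#' Fits the steady-state model to week-binned group-mean 1,5-AG data by
#' derivative-free simplex minimisation of the unweighted sum of squared
#' errors, reproducing the model-variant workflow: an unfitted
#' "adjusted" evaluation, a best fit with time-constant reabsorption,
#' and a best fit with gestation-dependent reabsorption, each for
#' normal and diabetic pregnancy.
#'
#' @name calibration
NULL

.FIT_PARAMS <- c("k_i", "a", "b", "c", "glucose")

.VARIANTS <- c("normal_adjusted", "normal_bestfit", "normal_bestfit_rtime",
               "diabetic_adjusted", "diabetic_bestfit",
               "diabetic_bestfit_rtime")

.DEFAULT_BOUNDS <- list(k_i = c(0.1, 50), a = c(0.9, 0.99999),
                        b = c(0, 0.01), glucose = c(1, 30), c = c(0, 0.01))

#' Calibration specification
#'
#' Splits the five model parameters (`k_i`, `a`, `b`, `c`, `glucose`)
#' into a free set (optimised) and a fixed map; carries per-parameter
#' bounds, the initial point, the objective termination tolerance and
#' the reabsorption model the variant uses.
#'
#' @param variant one of the six variant names (see [variant_defaults()])
#' @param free character vector of free parameter names
#' @param fixed named list of values for the remaining parameters
#' @param bounds named list of c(lo, hi) per parameter
#' @param init named list of starting values (must cover `free`)
#' @param tol function-value termination tolerance (> 0)
#' @param reabs_model `"gestational"` or `"stickle"` (see [kinetic_params()])
#' @return object of class `fit_spec`
#' @export
fit_spec <- function(variant, free, fixed, bounds = .DEFAULT_BOUNDS,
                     init = NULL, tol = 1e-5,
                     reabs_model = c("gestational", "stickle")) {
  variant <- match.arg(variant, .VARIANTS)
  reabs_model <- match.arg(reabs_model)
  free <- as.character(free)
  stopifnot(all(free %in% .FIT_PARAMS), all(names(fixed) %in% .FIT_PARAMS))
  if (length(intersect(free, names(fixed)))) {
    stop("free and fixed parameter sets overlap", call. = FALSE)
  }
  if (!setequal(c(free, names(fixed)), .FIT_PARAMS)) {
    stop("free + fixed must cover exactly: ",
         paste(.FIT_PARAMS, collapse = ", "), call. = FALSE)
  }
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (is.null(init)) init <- fixed
  for (nm in free) {
    if (is.null(init[[nm]])) {
      stop("init missing for free parameter ", nm, call. = FALSE)
    }
    bd <- bounds[[nm]]
    if (init[[nm]] < bd[1] || init[[nm]] > bd[2]) {
      stop("init for ", nm, " outside its bounds", call. = FALSE)
    }
  }
  structure(list(variant = variant, free = free, fixed = fixed,
                 bounds = bounds, init = init, tol = tol,
                 reabs_model = reabs_model),
            class = "fit_spec")
}

#' Default calibration specifications per model variant
#'
#' * `normal_adjusted`: nothing free; k_i = 5, a = 0.9984, b = 0
#'   (the unfitted evaluation at nominal constants).
#' * `normal_bestfit`: free k_i and a, with b = 0.
#' * `normal_bestfit_rtime`: free k_i, a and the post-week-25 decline b.
#' * `diabetic_adjusted`: nothing free; k_i = 5, glucose = 8.9 mM,
#'   glucose-only reabsorption.
#' * `diabetic_bestfit`: free k_i and glucose, glucose-only reabsorption.
#' * `diabetic_bestfit_rtime`: k_i fixed at 5, free a, b and glucose,
#'   glucose sensitivity c fixed at 0.0026 per mM.
#'
#' Tolerance 1e-5 throughout. `c` and `glucose` enter the gestational
#' model only as the product c * glucose, so they are never both free.
#'
#' @param variant one of the six variant names
#' @return a [fit_spec()]
#' @export
variant_defaults <- function(variant) {
  variant <- match.arg(variant, .VARIANTS)
  switch(variant,
    normal_adjusted = fit_spec(variant, free = character(0),
      fixed = list(k_i = 5, a = 0.9984, b = 0, c = 0.0026, glucose = 5)),
    normal_bestfit = fit_spec(variant, free = c("k_i", "a"),
      fixed = list(b = 0, c = 0.0026, glucose = 5),
      init = list(k_i = 5, a = 0.9984, b = 0, c = 0.0026, glucose = 5)),
    normal_bestfit_rtime = fit_spec(variant, free = c("k_i", "a", "b"),
      fixed = list(c = 0.0026, glucose = 5),
      init = list(k_i = 5, a = 0.9984, b = 1e-4, c = 0.0026, glucose = 5)),
    diabetic_adjusted = fit_spec(variant, free = character(0),
      fixed = list(k_i = 5, a = 0.9984, b = 0, c = 0.0026, glucose = 8.9),
      reabs_model = "stickle"),
    diabetic_bestfit = fit_spec(variant, free = c("k_i", "glucose"),
      fixed = list(a = 0.9984, b = 0, c = 0.0026),
      init = list(k_i = 5, a = 0.9984, b = 0, c = 0.0026, glucose = 8.9),
      reabs_model = "stickle"),
    diabetic_bestfit_rtime = fit_spec(variant,
      free = c("a", "b", "glucose"),
      fixed = list(k_i = 5, c = 0.0026),
      init = list(k_i = 5, a = 0.9984, b = 1e-4, c = 0.0026, glucose = 8.9)))
}

params_from_estimates <- function(est, spec, base_curves = physio_curve_set()) {
  kinetic_params(
    k_i = est$k_i, glucose = est$glucose, curves = base_curves,
    reabs = reabsorption_params(a = est$a, b = est$b, c = est$c),
    reabs_model = spec$reabs_model)
}

#' Sum of squared errors of a trajectory against observed means
#'
#' Unweighted sum over observed weeks of (predicted - mean)^2; every
#' observed week must lie on the trajectory grid.
#'
#' @param predicted an [trajectory()] result
#' @param observed data.frame of group means with `week` and `mean`
#'   columns (as produced by [group_means()], restricted to `ag`)
#' @return SSE in (ug/mL)^2
#' @export
sse <- function(predicted, observed) {
  stopifnot(inherits(predicted, "ag_trajectory"), is.data.frame(observed))
  if (nrow(observed) == 0) stop("empty observation set", call. = FALSE)
  pred <- trajectory_at(predicted, observed$week)
  sum((pred - observed$mean)^2)
}

observed_ag_means <- function(data, group = NULL) {
  if (inherits(data, "longitudinal_series")) {
    gm <- group_means(data)
    gm <- gm[gm$variable == "ag", , drop = FALSE]
    if (!is.null(group)) gm <- gm[gm$group == group, , drop = FALSE]
    if (length(unique(gm$group)) > 1) {
      stop("series contains several groups; pass `group` to select one",
           call. = FALSE)
    }
    obs <- gm[, c("week", "mean"), drop = FALSE]
  } else {
    stopifnot(is.data.frame(data), all(c("week", "mean") %in% names(data)))
    obs <- data[, c("week", "mean")]
  }
  obs <- obs[order(obs$week), ]
  if (nrow(obs) == 0) stop("no 1,5-AG observations", call. = FALSE)
  rownames(obs) <- NULL
  obs
}

# fminsearchbnd-style bounded transform: u unconstrained -> x in [lo, hi]
bound_tx <- function(u, lo, hi) lo + (hi - lo) * (sin(u) + 1) / 2
bound_tx_inv <- function(x, lo, hi) {
  z <- 2 * (x - lo) / (hi - lo) - 1
  asin(pmin(1, pmax(-1, z)))
}

#' Calibrate a model variant to observed 1,5-AG means
#'
#' Minimises [sse()] over the free parameters of `spec` by Nelder--Mead
#' simplex ([pracma::nelder_mead()]) from `spec$init`, with bounds
#' enforced by a sine transform. Deterministic given data and spec, and
#' invariant to the row order of the input.
#'
#' @param data a [longitudinal_series()] of `ag` records (group means are
#'   formed internally), or a data.frame with `week` and `mean` columns
#' @param spec a [fit_spec()]
#' @param curves the [physio_curve_set()] held fixed during fitting
#' @param group group to fit when `data` is a multi-group series
#' @return object of class `fit_result`: named `estimates` for all five
#'   parameters, `sse`, `n_eval`, `converged`, and the `spec` used
#' @export
calibrate <- function(data, spec, curves = physio_curve_set(), group = NULL) {
  stopifnot(inherits(spec, "fit_spec"))
  if (all(c("c", "glucose") %in% spec$free)) {
    stop(paste("c and glucose are not jointly identifiable (they enter",
               "only as the product c * glucose); fix one of them"),
         call. = FALSE)
  }
  obs <- observed_ag_means(data, group)
  if (nrow(obs) < length(spec$free) + 1) {
    stop("need at least |free| + 1 distinct observed weeks", call. = FALSE)
  }
  weeks <- obs$week

  est0 <- spec$fixed
  est0[spec$free] <- spec$init[spec$free]
  objective_at <- function(est) {
    p <- params_from_estimates(est, spec, curves)
    sse(trajectory(weeks, p), obs)
  }

  if (length(spec$free) == 0) {
    val <- objective_at(est0)
    return(structure(list(estimates = est0[.FIT_PARAMS], sse = val,
                          n_eval = 1L, converged = TRUE, spec = spec),
                     class = "fit_result"))
  }

  lo <- vapply(spec$free, function(nm) spec$bounds[[nm]][1], numeric(1))
  hi <- vapply(spec$free, function(nm) spec$bounds[[nm]][2], numeric(1))
  u0 <- bound_tx_inv(unlist(spec$init[spec$free]), lo, hi)

  n_eval <- 0L
  fn <- function(u) {
    n_eval <<- n_eval + 1L
    est <- est0
    est[spec$free] <- as.list(bound_tx(u, lo, hi))
    tryCatch(objective_at(est), error = function(e) 1e12)
  }
  opt <- if (length(spec$free) == 1) {
    # 1-D simplex degenerates; golden-section/parabolic search instead
    o <- stats::optimize(fn, lower = bound_tx_inv(lo, lo, hi),
                         upper = bound_tx_inv(hi, lo, hi), tol = 1e-10)
    list(xmin = o$minimum, fmin = o$objective, count = n_eval)
  } else {
    pracma::nelder_mead(fn, u0, tol = spec$tol, maxfeval = 20000)
  }
  est <- est0
  est[spec$free] <- as.list(bound_tx(opt$xmin, lo, hi))
  final_sse <- opt$fmin
  init_sse <- objective_at(est0)
  # tie-break: if the initialization is already optimal to numerical noise,
  # keep it (the objective can have exactly flat directions; see vignette)
  if (init_sse <= final_sse * (1 + 1e-9) + 1e-15) {
    est <- est0
    final_sse <- init_sse
  }
  converged <- is.finite(final_sse) && final_sse <= init_sse + spec$tol &&
    opt$count < 20000
  structure(list(estimates = est[.FIT_PARAMS], sse = final_sse,
                 n_eval = n_eval, converged = converged, spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Calibration (%s): sse = %.6g (ug/mL)^2, %d evaluations%s\n",
              x$spec$variant, x$sse, x$n_eval,
              if (x$converged) "" else " [NOT CONVERGED]"))
  free <- x$spec$free
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-8s %.6g%s\n", nm, x$estimates[[nm]],
                if (nm %in% free) "  (fitted)" else "  (fixed)"))
  }
  invisible(x)
}
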