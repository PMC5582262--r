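#' Two-compartment 1,5-AG mass balance
#'
#' Renal reabsorption models, the fast-time mass-balance ODE, and the
#' steady-state plasma 1,5-AG concentration across gestation.
#'
#' Mass balance: plasma 1,5-AG (concentration C, mg/mL) is fed at rate
#' f(t) * k_i / V(t) — the dietary/endogenous input k_i (mg/day)
#' partitioned into plasma by the fractional plasma mass f(t) and diluted
#' by plasma volume V(t) (mL) — and cleared at rate
#' GFR(t) * C / V(t) * (1 - r), where GFR is converted to mL/day and r is
#' the tubular reabsorption fraction. At normoglycemia r is ~0.9984 and
#' nearly all filtered 1,5-AG returns to plasma; glucose above ~7.4 mM
#' competitively depresses r, and after week 25 of gestation r may
#' decline linearly with time.
#'
#' At the fixed point the plasma volume cancels:
#' C = f(t) * k_i / (GFR_day(t) * (1 - r)).
#'
#' @name ag_kinetics
NULL

MIN_PER_DAY <- 1440

#' Piecewise reabsorption-fraction parameters
#'
#' r(t, G) = a - b * (t - t_break) * \[t > t_break\] - c * G * \[G > g_threshold\].
#' The glucose threshold point itself takes the constant branch.
#'
#' @param a baseline reabsorption fraction, in (0, 1)
#' @param b post-breakpoint decline rate (per week, >= 0)
#' @param c glucose sensitivity (per mM, >= 0)
#' @param g_threshold glucose threshold (mM, > 0)
#' @param t_break breakpoint week, in (0, 42)
#' @return object of class `reabsorption_params`
#' @export
reabsorption_params <- function(a = 0.9984, b = 0, c = 0.0026,
                                g_threshold = 7.4, t_break = 25) {
  if (a <= 0 || a >= 1) stop("a must lie in (0, 1)", call. = FALSE)
  if (b < 0) stop("b must be >= 0", call. = FALSE)
  if (c < 0) stop("c must be >= 0", call. = FALSE)
  if (g_threshold <= 0) stop("g_threshold must be positive", call. = FALSE)
  if (t_break <= 0 || t_break >= 42) stop("t_break must lie in (0, 42)", call. = FALSE)
  structure(list(a = a, b = b, c = c, g_threshold = g_threshold,
                 t_break = t_break), class = "reabsorption_params")
}

check_reabsorption <- function(r) {
  if (any(r <= 0 | r >= 1)) {
    stop("invalid reabsorption fraction: outside (0, 1)", call. = FALSE)
  }
  r
}

#' Glucose-only reabsorption fraction
#'
#' The piecewise glucose model: constant `baseline` below the threshold
#' (the threshold point included), and the falling line
#' `-slope * glucose + intercept` above it. Defaults are the published
#' constants (baseline 0.9984; the alternative printed baseline 0.998 is
#' available by argument).
#'
#' @param glucose plasma glucose (mM, > 0); vectorised
#' @param slope line slope magnitude (per mM)
#' @param intercept line intercept (unitless)
#' @param baseline constant normoglycemic fraction
#' @param threshold glucose threshold (mM)
#' @return reabsorption fraction in (0, 1)
#' @export
reabsorption_stickle <- function(glucose, slope = 0.0026, intercept = 1.018,
                                 baseline = 0.9984, threshold = 7.4) {
  if (any(glucose <= 0)) stop("glucose must be positive", call. = FALSE)
  r <- ifelse(glucose <= threshold, baseline, -slope * glucose + intercept)
  check_reabsorption(r)
}

#' Gestation- and glucose-dependent reabsorption fraction
#'
#' r = a - b * (week - t_break) after the breakpoint, minus c * glucose
#' when glucose exceeds the threshold; continuous in week at the
#' breakpoint and piecewise linear.
#'
#' @param week gestational week(s)
#' @param glucose plasma glucose (mM, > 0)
#' @param p a [reabsorption_params()]
#' @return reabsorption fraction in (0, 1)
#' @export
reabsorption_gestational <- function(week, glucose, p = reabsorption_params()) {
  stopifnot(inherits(p, "reabsorption_params"))
  check_week(week)
  if (any(glucose <= 0)) stop("glucose must be positive", call. = FALSE)
  r <- p$a -
    ifelse(week > p$t_break, p$b * (week - p$t_break), 0) -
    ifelse(glucose > p$g_threshold, p$c * glucose, 0)
  check_reabsorption(r)
}

#' Full kinetic parameter set
#'
#' @param k_i 1,5-AG input rate (mg/day, > 0); nominal 5
#' @param glucose mean maximal plasma glucose (mM, > 0); 5 for normal
#'   pregnancy (any value below the 7.4 mM threshold behaves identically),
#'   8.9 representative for untreated GDM/DM
#' @param curves a [physio_curve_set()]
#' @param reabs a [reabsorption_params()]
#' @param reabs_model `"gestational"` for the time-dependent model or
#'   `"stickle"` for the glucose-only model (with `stickle_intercept`
#'   as the upper-branch intercept and `reabs$a` as the baseline)
#' @param r_const optional constant reabsorption override in (0, 1);
#'   when set it bypasses the reabsorption model entirely (used by
#'   direct-r parameter sweeps)
#' @param stickle_intercept upper-branch intercept for `"stickle"` mode
#' @return object of class `kinetic_params`
#' @export
kinetic_params <- function(k_i = 5, glucose = 5,
                           curves = physio_curve_set(),
                           reabs = reabsorption_params(),
                           reabs_model = c("gestational", "stickle"),
                           r_const = NULL,
                           stickle_intercept = 1.018) {
  if (k_i <= 0) stop("k_i must be positive", call. = FALSE)
  if (glucose <= 0) stop("glucose must be positive", call. = FALSE)
  stopifnot(inherits(curves, "physio_curve_set"),
            inherits(reabs, "reabsorption_params"))
  reabs_model <- match.arg(reabs_model)
  if (!is.null(r_const)) check_reabsorption(r_const)
  structure(list(k_i = k_i, glucose = glucose, curves = curves,
                 reabs = reabs, reabs_model = reabs_model,
                 r_const = r_const, stickle_intercept = stickle_intercept),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("1,5-AG kinetic parameters\n")
  cat(sprintf("  k_i: %g mg/day   [G]: %g mM   reabsorption: %s\n",
              x$k_i, x$glucose,
              if (!is.null(x$r_const)) sprintf("constant r = %g", x$r_const)
              else x$reabs_model))
  if (is.null(x$r_const)) {
    cat(sprintf("  r params: a=%g b=%g c=%g threshold=%g mM break=%g wk\n",
                x$reabs$a, x$reabs$b, x$reabs$c, x$reabs$g_threshold,
                x$reabs$t_break))
  }
  invisible(x)
}

#' Effective reabsorption fraction for a parameter set
#'
#' Dispatches to the constant override, the glucose-only model, or the
#' gestational model according to the parameter set.
#'
#' @param week gestational week(s)
#' @param p a [kinetic_params()]
#' @return reabsorption fraction in (0, 1)
#' @export
reabsorption_at <- function(week, p) {
  stopifnot(inherits(p, "kinetic_params"))
  check_week(week)
  if (!is.null(p$r_const)) {
    return(rep(p$r_const, length(week)))
  }
  if (p$reabs_model == "stickle") {
    rep(reabsorption_stickle(p$glucose, slope = p$reabs$c,
                             intercept = p$stickle_intercept,
                             baseline = p$reabs$a,
                             threshold = p$reabs$g_threshold),
        length(week))
  } else {
    reabsorption_gestational(week, p$glucose, p$reabs)
  }
}

#' Fast-time derivative of plasma 1,5-AG
#'
#' Right-hand side of the mass balance at a frozen gestational week:
#' input f * k_i / V minus clearance GFR_day * C / V * (1 - r), with
#' GFR converted from mL/min to mL/day.
#'
#' @param concentration plasma 1,5-AG (mg/mL, >= 0)
#' @param week gestational week (scalar)
#' @param p a [kinetic_params()]
#' @return dC/dt in mg/mL per day
#' @export
dC_dt <- function(concentration, week, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(concentration < 0)) stop("concentration must be >= 0", call. = FALSE)
  f <- eval_fpm(p$curves$fpm, week)
  v <- eval_plasma_volume(p$curves$plasma_volume, week)
  gfr_day <- eval_gfr(p$curves$gfr, week) * MIN_PER_DAY
  r <- reabsorption_at(week, p)
  f * p$k_i / v - gfr_day * concentration / v * (1 - r)
}

#' Closed-form steady-state 1,5-AG concentration
#'
#' Fixed point of the mass balance; plasma volume cancels:
#' C = 1000 * f(week) * k_i / (GFR_day(week) * (1 - r)), reported in
#' ug/mL (the unit of the clinical 1,5-AG data).
#'
#' @param week gestational week(s)
#' @param p a [kinetic_params()]
#' @return steady-state concentration in ug/mL (vectorised over `week`)
#' @export
steady_state_closed_form <- function(week, p) {
  stopifnot(inherits(p, "kinetic_params"))
  f <- eval_fpm(p$curves$fpm, week)
  gfr_day <- eval_gfr(p$curves$gfr, week) * MIN_PER_DAY
  r <- reabsorption_at(week, p)
  if (any(1 - r < 1e-9)) {
    stop("clearance vanishes: reabsorption fraction too close to 1",
         call. = FALSE)
  }
  1000 * f * p$k_i / (gfr_day * (1 - r))
}

#' Steady state by ODE integration
#'
#' Integrates the fast-time mass balance ([dC_dt()]) at a frozen
#' gestational week with [deSolve::ode()] (lsoda) until the relative
#' derivative |dC/dt| / C falls below the declaration threshold, then
#' returns the concentration in ug/mL. Used as an independent check on
#' [steady_state_closed_form()]; the two agree to the requested
#' tolerance regardless of the initial condition.
#'
#' @param week gestational week (scalar)
#' @param p a [kinetic_params()]
#' @param init initial plasma concentration (mg/mL, >= 0)
#' @param tol relative agreement requested against the fixed point
#' @param horizon fast-time integration horizon (days)
#' @param declare relative-derivative threshold declaring steady state
#' @return steady-state concentration in ug/mL
#' @export
steady_state_by_integration <- function(week, p, init = 0, tol = 1e-8,
                                        horizon = 365, declare = 1e-9) {
  stopifnot(inherits(p, "kinetic_params"), length(week) == 1)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  thr <- min(declare, tol)
  rhs <- function(t, y, parms) list(dC_dt(y, week, p))
  chunk <- 30
  t0 <- 0
  y <- init
  if (y > 0 && abs(dC_dt(y, week, p)) / y < thr) {
    return(1000 * y)
  }
  while (t0 < horizon) {
    t1 <- min(t0 + chunk, horizon)
    sol <- deSolve::ode(y = c(C = y), times = c(t0, t1), func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-14)
    y <- unname(sol[nrow(sol), "C"])
    if (y > 0 && abs(dC_dt(y, week, p)) / y < thr) {
      return(1000 * y)
    }
    t0 <- t1
  }
  stop("steady state not reached within integration horizon", call. = FALSE)
}

#' Steady-state trajectory across gestation
#'
#' Evaluates the closed-form steady state on an ordered week grid.
#'
#' @param weeks non-empty, sorted gestational week grid
#' @param p a [kinetic_params()]
#' @return object of class `ag_trajectory`: list with `weeks`,
#'   `concentration` (ug/mL) and the `params` used
#' @export
trajectory <- function(weeks, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (length(weeks) == 0) stop("empty week grid", call. = FALSE)
  if (is.unsorted(weeks, strictly = FALSE)) {
    stop("week grid must be sorted", call. = FALSE)
  }
  conc <- steady_state_closed_form(weeks, p)
  structure(list(weeks = weeks, concentration = conc, params = p),
            class = "ag_trajectory")
}

#' @export
print.ag_trajectory <- function(x, ...) {
  cat(sprintf("1,5-AG steady-state trajectory: %d weeks (%g-%g), %0.2f-%0.2f ug/mL\n",
              length(x$weeks), min(x$weeks), max(x$weeks),
              min(x$concentration), max(x$concentration)))
  invisible(x)
}

#' Trajectory concentration at given weeks
#'
#' @param traj an [trajectory()] result
#' @param weeks weeks to extract; must be on the grid
#' @return concentrations in ug/mL
#' @export
trajectory_at <- function(traj, weeks) {
  stopifnot(inherits(traj, "ag_trajectory"))
  idx <- match(weeks, traj$weeks)
  if (any(is.na(idx))) stop("requested week not on trajectory grid", call. = FALSE)
  traj$concentration[idx]
}
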