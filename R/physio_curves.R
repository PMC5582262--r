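#' Gestational physiology curves
#'
#' Constructors and evaluators for the three fitted gestational
#' physiological parameter curves used by the 1,5-AG kinetic model:
#' a quadratic glomerular filtration rate (GFR), a sigmoidal plasma
#' volume, and a linear fractional plasma mass. Gestational time is
#' measured in weeks since conception; week 0 is the pre-pregnancy
#' baseline and the supported range is 0--42 weeks.
#'
#' @name physio_curves
NULL

.WEEK_MIN <- 0
.WEEK_MAX <- 42

check_week <- function(week) {
  if (!is.numeric(week) || any(!is.finite(week))) {
    stop("gestational week must be finite numeric", call. = FALSE)
  }
  if (any(week < .WEEK_MIN | week > .WEEK_MAX)) {
    stop(sprintf("gestational week outside supported range [%g, %g]",
                 .WEEK_MIN, .WEEK_MAX), call. = FALSE)
  }
  invisible(week)
}

#' Quadratic GFR curve
#'
#' GFR(t) = a2 t^2 + a1 t + a0 in mL/min, t in gestational weeks.
#' Defaults are the fitted coefficients for normal pregnancy.
#'
#' @param a2 quadratic coefficient (mL/min per week^2)
#' @param a1 linear coefficient (mL/min per week)
#' @param a0 intercept, the pre-pregnancy GFR (mL/min); must be positive
#' @return object of class `gfr_quadratic`
#' @export
gfr_quadratic <- function(a2 = -0.077, a1 = 4.17, a0 = 99.04) {
  stopifnot(is.numeric(a2), is.numeric(a1), is.numeric(a0))
  if (a0 <= 0) stop("a0 (week-0 GFR) must be positive", call. = FALSE)
  structure(list(a2 = a2, a1 = a1, a0 = a0), class = "gfr_quadratic")
}

#' Sigmoidal plasma-volume curve
#'
#' V(t) = num / (d0 + d1 * exp(sign * rate * (t - t_mid))) + offset, in mL.
#' `sign` is an explicit convention flag: +1 is the printed form of the
#' fitted curve (which decreases with gestation); -1 gives the rising
#' orientation matching the underlying cohort data. Steady-state 1,5-AG
#' is invariant to this choice because plasma volume cancels there.
#'
#' @param num numerator (mL)
#' @param d0 denominator constant (> 0)
#' @param d1 denominator amplitude (> 0)
#' @param rate exponential rate (per week)
#' @param t_mid centering week
#' @param offset baseline volume (mL, > 0)
#' @param sign exponent sign convention, +1 (printed) or -1
#' @return object of class `plasma_volume_sigmoid`
#' @export
plasma_volume_sigmoid <- function(num = 796.2, d0 = 0.62, d1 = 4.4,
                                  rate = 0.21, t_mid = 9.2, offset = 2378,
                                  sign = 1) {
  if (d0 <= 0 || d1 <= 0) stop("d0 and d1 must be positive", call. = FALSE)
  if (offset <= 0) stop("offset must be positive", call. = FALSE)
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1", call. = FALSE)
  structure(list(num = num, d0 = d0, d1 = d1, rate = rate,
                 t_mid = t_mid, offset = offset, sign = sign),
            class = "plasma_volume_sigmoid")
}

#' Linear fractional-plasma-mass curve
#'
#' f(t) = slope * t + intercept: the fraction of body-mass gain during
#' pregnancy attributable to plasma gain, used to partition 1,5-AG input
#' into the plasma compartment. Must evaluate inside (0, 1].
#'
#' @param slope per-week change (1/week)
#' @param intercept fraction at week 0 (unitless)
#' @return object of class `fpm_line`
#' @export
fpm_line <- function(slope = -0.006, intercept = 0.32) {
  structure(list(slope = slope, intercept = intercept), class = "fpm_line")
}

#' Bundle of the three gestational physiology curves
#'
#' @param gfr a [gfr_quadratic()]
#' @param plasma_volume a [plasma_volume_sigmoid()]
#' @param fpm an [fpm_line()]
#' @return object of class `physio_curve_set`
#' @export
physio_curve_set <- function(gfr = gfr_quadratic(),
                             plasma_volume = plasma_volume_sigmoid(),
                             fpm = fpm_line()) {
  stopifnot(inherits(gfr, "gfr_quadratic"),
            inherits(plasma_volume, "plasma_volume_sigmoid"),
            inherits(fpm, "fpm_line"))
  structure(list(gfr = gfr, plasma_volume = plasma_volume, fpm = fpm),
            class = "physio_curve_set")
}

#' @export
print.physio_curve_set <- function(x, ...) {
  cat("Gestational physiology curve set\n")
  cat(sprintf("  GFR (mL/min):          %.4g t^2 + %.4g t + %.4g\n",
              x$gfr$a2, x$gfr$a1, x$gfr$a0))
  cat(sprintf("  Plasma volume (mL):    %.4g/(%.3g + %.3g exp(%+d*%.3g (t - %.3g))) + %.4g\n",
              x$plasma_volume$num, x$plasma_volume$d0, x$plasma_volume$d1,
              x$plasma_volume$sign, x$plasma_volume$rate,
              x$plasma_volume$t_mid, x$plasma_volume$offset))
  cat(sprintf("  Fractional plasma mass: %.4g t + %.4g\n",
              x$fpm$slope, x$fpm$intercept))
  invisible(x)
}

#' Evaluate the GFR curve
#'
#' @param curve a [gfr_quadratic()]
#' @param week gestational week(s) in \[0, 42\]
#' @return GFR in mL/min (vectorised over `week`)
#' @export
eval_gfr <- function(curve, week) {
  stopifnot(inherits(curve, "gfr_quadratic"))
  check_week(week)
  g <- curve$a2 * week^2 + curve$a1 * week + curve$a0
  if (any(g <= 0)) {
    stop("degenerate GFR curve: non-positive value in supported week range",
         call. = FALSE)
  }
  g
}

#' Peak of the GFR curve
#'
#' Vertex of the quadratic (requires a downward parabola, a2 < 0) and the
#' fold-increase of peak GFR over the week-0 value.
#'
#' @param curve a [gfr_quadratic()]
#' @return list with `peak_week` (weeks) and `fold_increase` (unitless)
#' @export
gfr_peak <- function(curve) {
  stopifnot(inherits(curve, "gfr_quadratic"))
  if (curve$a2 >= 0) {
    stop("no interior maximum: quadratic coefficient must be negative",
         call. = FALSE)
  }
  peak_week <- -curve$a1 / (2 * curve$a2)
  list(peak_week = peak_week,
       fold_increase = eval_gfr(curve, peak_week) / eval_gfr(curve, 0))
}

#' Evaluate the plasma-volume curve
#'
#' @param curve a [plasma_volume_sigmoid()]
#' @param week gestational week(s)
#' @return plasma volume in mL (vectorised over `week`)
#' @export
eval_plasma_volume <- function(curve, week) {
  stopifnot(inherits(curve, "plasma_volume_sigmoid"))
  check_week(week)
  denom <- curve$d0 + curve$d1 * exp(curve$sign * curve$rate * (week - curve$t_mid))
  v <- curve$num / denom + curve$offset
  if (any(v <= 0)) {
    stop("non-physiological plasma volume (<= 0)", call. = FALSE)
  }
  v
}

#' Fractional plasma mass from mass gains
#'
#' Ratio of plasma-mass gain to total body-mass gain since conception.
#' Undefined at week 0, where both gains are zero.
#'
#' @param delta_plasma_mass plasma-mass gain (kg)
#' @param delta_total_mass total body-mass gain (kg); must be positive
#' @return fraction (unitless)
#' @export
compute_fpm <- function(delta_plasma_mass, delta_total_mass) {
  if (any(delta_total_mass <= 0)) {
    stop("total mass gain must be positive (fraction undefined at baseline)",
         call. = FALSE)
  }
  delta_plasma_mass / delta_total_mass
}

#' Evaluate the fractional-plasma-mass line
#'
#' @param line an [fpm_line()]
#' @param week gestational week(s)
#' @return fraction in (0, 1] (vectorised over `week`)
#' @export
eval_fpm <- function(line, week) {
  stopifnot(inherits(line, "fpm_line"))
  check_week(week)
  f <- line$slope * week + line$intercept
  if (any(f <= 0 | f > 1)) {
    stop("fractional plasma mass outside (0, 1]: non-physiological",
         call. = FALSE)
  }
  f
}

#' Coefficient of determination
#'
#' Standard R^2 = 1 - SS_res / SS_tot.
#'
#' @param observed numeric vector
#' @param predicted numeric vector, same length
#' @return unitless R^2 (can be negative for fits worse than the mean)
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("zero total variance: R^2 undefined", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

series_subset <- function(data, variable, group = NULL) {
  stopifnot(inherits(data, "longitudinal_series"))
  d <- data$records
  d <- d[d$variable == variable, , drop = FALSE]
  if (!is.null(group)) d <- d[d$group == group, , drop = FALSE]
  d
}

#' Fit the quadratic GFR curve
#'
#' Ordinary least squares on all `gfr` records, solved in closed form
#' (normal equations via the QR decomposition in [stats::lm.fit()]).
#'
#' @param data a [longitudinal_series()] containing `gfr` records
#' @return list with `curve` (a [gfr_quadratic()]) and `r2`
#' @export
fit_gfr_quadratic <- function(data) {
  d <- series_subset(data, "gfr")
  if (length(unique(d$week)) < 3) {
    stop("underdetermined: need gfr records at >= 3 distinct weeks",
         call. = FALSE)
  }
  X <- cbind(1, d$week, d$week^2)
  beta <- stats::lm.fit(X, d$value)$coefficients
  beta[is.na(beta)] <- 0
  curve <- gfr_quadratic(a2 = unname(beta[3]), a1 = unname(beta[2]),
                         a0 = unname(beta[1]))
  pred <- drop(X %*% c(curve$a0, curve$a1, curve$a2))
  r2 <- if (stats::var(d$value) == 0) 1 else r_squared(d$value, pred)
  list(curve = curve, r2 = r2)
}

#' Fit the sigmoidal plasma-volume curve
#'
#' Nonlinear least squares (Levenberg--Marquardt, [minpack.lm::nlsLM()])
#' from the supplied initialization; at least six distinct visit weeks
#' are required. The sigmoid as written carries two exactly redundant
#' degrees of freedom (num, d0, d1 share a common scale, and t_mid can
#' be absorbed into d1), so the fit profiles them out by holding d0 and
#' t_mid at their initialization and optimizing the four identifiable
#' parameters (num, d1, rate, offset); the returned curve is reported in
#' the full six-parameter form.
#'
#' @param data a [longitudinal_series()] containing `plasma_volume` records
#' @param init starting [plasma_volume_sigmoid()]; its `sign` is kept fixed
#' @return list with `curve`, `r2` and `n_iter`
#' @export
fit_plasma_volume_sigmoid <- function(data, init = plasma_volume_sigmoid()) {
  stopifnot(inherits(init, "plasma_volume_sigmoid"))
  d <- series_subset(data, "plasma_volume")
  if (length(unique(d$week)) < 6) {
    stop("underdetermined: need plasma_volume records at >= 6 distinct weeks",
         call. = FALSE)
  }
  sgn <- init$sign
  d0 <- init$d0
  t_mid <- init$t_mid
  df <- data.frame(week = d$week, value = d$value)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ num / (d0 + d1 * exp(sgn * rate * (week - t_mid))) + offset,
      data = df,
      start = init[c("num", "d1", "rate", "offset")],
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13,
                                           ptol = 1e-13)),
    error = function(e) {
      stop("plasma-volume sigmoid fit failed: ", conditionMessage(e),
           call. = FALSE)
    })
  est <- as.list(stats::coef(fit))
  curve <- plasma_volume_sigmoid(num = est$num, d0 = d0, d1 = est$d1,
                                 rate = est$rate, t_mid = t_mid,
                                 offset = est$offset, sign = sgn)
  r2 <- r_squared(d$value, eval_plasma_volume(curve, d$week))
  list(curve = curve, r2 = r2, n_iter = fit$convInfo$finIter)
}

#' Fit the fractional-plasma-mass line
#'
#' Forms per-week fractions from paired `plasma_mass_gain` and
#' `total_mass_gain` records via [compute_fpm()] (week 0 always excluded:
#' the ratio is 0/0 there), then fits an ordinary least-squares line.
#'
#' @param data a [longitudinal_series()] with both mass-gain variables
#' @return list with `line` (an [fpm_line()]) and `r2`
#' @export
fit_fpm_line <- function(data) {
  pm <- series_subset(data, "plasma_mass_gain")
  tm <- series_subset(data, "total_mass_gain")
  key <- function(d) paste(d$subject_id, d$week, sep = "\r")
  m <- match(key(pm), key(tm))
  ok <- !is.na(m) & pm$week > 0
  if (!any(ok)) stop("no paired mass-gain records at pregnant weeks", call. = FALSE)
  week <- pm$week[ok]
  frac <- compute_fpm(pm$value[ok], tm$value[m[ok]])
  if (length(unique(week)) < 2) {
    stop("underdetermined: need paired mass gains at >= 2 pregnant weeks",
         call. = FALSE)
  }
  beta <- stats::lm.fit(cbind(1, week), frac)$coefficients
  line <- fpm_line(slope = unname(beta[2]), intercept = unname(beta[1]))
  pred <- line$slope * week + line$intercept
  r2 <- if (stats::var(frac) == 0) 1 else r_squared(frac, pred)
  list(line = line, r2 = r2)
}
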