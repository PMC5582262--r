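# Shared fixtures: generating parameter sets and observed-mean tables
# built in code (no stored data).

truth_normal_rtime <- function() {
  kinetic_params(k_i = 5.16, glucose = 5,
                 reabs = reabsorption_params(a = 0.99825, b = 5.78e-5))
}

truth_diabetic_rtime <- function(c = 0.0026) {
  kinetic_params(k_i = 5, glucose = 9.5,
                 reabs = reabsorption_params(a = 0.997, b = 5.78e-5, c = c))
}

obs_means <- function(p, weeks = seq(6, 38, by = 2)) {
  data.frame(week = weeks, mean = steady_state_closed_form(weeks, p))
}

demo_series <- function() {
  longitudinal_series(data.frame(
    subject_id = c("s1", "s1", "s2", "s2", "s3"),
    group = c("normal", "normal", "normal", "gdm_dm", "gdm_dm"),
    week = c(0, 16, 16, 20, 20),
    variable = c("gfr", "gfr", "gfr", "ag", "ag"),
    value = c(99, 150, 160, 10, 14),
    sd = c(NA, NA, 5, NA, NA)))
}
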