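#' Analysis pipeline configuration
#'
#' Bundles the knobs shared by the estimation and covariate stages: the
#' rolling-window setting, window stride, the minimum number of forecasts a
#' window must contain per condition, the lower bound on the influence weight
#' alpha, the reference group for the confirmation-bias dummy, and tie /
#' fallback rules.
#'
#' @param window_setting Length rule for the trailing estimation window:
#'   `"weekly"` (7 days), `"quarter_duration"` (a quarter of the question's
#'   lifetime, rounded up) or `"max_of_both"` (the default; the longer of the
#'   two, which keeps short questions on weekly windows and long sparse
#'   questions on quarter windows).
#' @param stride Days between successive window end points (default 7, i.e.
#'   non-overlapping weekly steps for the default setting on short questions).
#' @param min_forecasts Minimum forecasts per condition (and per skill stratum
#'   when stratified) for a window to be used; windows below are discarded.
#' @param eps Lower bound for the influence weight alpha.  The model's
#'   likelihood is singular at alpha = 0 (the treatment variance
#'   `alpha^2 sigma^2` collapses), so estimation is over `[eps, 1]`.
#' @param confirm_reference Which condition's mean forecast anchors the
#'   confirmation-bias dummy: `"treatment"` (default) or `"control"`.
#' @param var_type `"sample"` (n-1 denominator, default) or `"population"`
#'   variance for the uncertainty covariate.
#' @param skill_method Normalization used by [skill_split()]:
#'   `"zscore"`, `"rank"` or `"raw"`.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return A list of class `"hf_config"`.
#' @export
#' @examples
#' pipeline_config(window_setting = "weekly", stride = 7)
pipeline_config <- function(window_setting = c("max_of_both", "weekly",
                                               "quarter_duration"),
                            stride = 7L,
                            min_forecasts = 4L,
                            eps = 0.01,
                            confirm_reference = c("treatment", "control"),
                            var_type = c("sample", "population"),
                            skill_method = c("zscore", "rank", "raw"),
                            seed = NULL) {
  window_setting <- match.arg(window_setting)
  confirm_reference <- match.arg(confirm_reference)
  var_type <- match.arg(var_type)
  skill_method <- match.arg(skill_method)
  stride <- as.integer(stride)
  if (!is.finite(eps) || eps <= 0) {
    abort("`eps` must be > 0: the likelihood is undefined at alpha = 0.",
          class = "hf_config_error")
  }
  if (stride < 1L) {
    abort("`stride` must be at least 1 day.", class = "hf_config_error")
  }
  if (min_forecasts < 1L) {
    abort("`min_forecasts` must be positive.", class = "hf_config_error")
  }
  structure(
    list(window_setting = window_setting, stride = stride,
         min_forecasts = as.integer(min_forecasts), eps = eps,
         confirm_reference = confirm_reference, var_type = var_type,
         skill_method = skill_method, seed = seed),
    class = "hf_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys are arguments of
#'   [pipeline_config()].
#' @return A list of class `"hf_config"`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration keys: ", paste(unknown, collapse = ", ")),
          class = "hf_config_error")
  }
  do.call(pipeline_config, vals)
}

#' @export
print.hf_config <- function(x, ...) {
  cat("<hybridcast pipeline config>\n")
  cat("  window:", x$window_setting, "| stride:", x$stride, "d",
      "| min forecasts:", x$min_forecasts, "\n")
  cat("  alpha bounds: [", x$eps, ", 1] | confirming ref:",
      x$confirm_reference, "\n")
  invisible(x)
}

#' Synthetic tournament configuration
#'
#' Defines the study conditions emulated by [simulate_tournament()]: a pool of
#' ordinal questions whose answer bins are cut from recent history of a daily
#' series, a control condition forecasting from a drifting group prior, a
#' treatment condition combining that prior with a daily machine forecast
#' through the DeGroot rule `y = alpha * x + (1 - alpha) * m`, and a set of
#' machine-free skill-assessment questions.
#'
#' @param n_questions Number of machine-paired questions.
#' @param n_users Users per condition.
#' @param activity Daily probability that an active user forecasts an open
#'   question (Bernoulli schedule; real arrival patterns are unknown).
#' @param duration_mean,duration_sd,duration_min,duration_max Question
#'   durations are drawn from Normal(53, 33) days, redrawn until inside
#'   `[duration_min, duration_max]`; a weekly window must fit, hence the
#'   7-day floor.
#' @param n_options_range Candidate numbers of answer options (2 to 5).
#' @param n_independent_questions Machine-free questions used only for the
#'   skill split (126 by default).
#' @param tournament_days Length of the tournament calendar.
#' @param pre_history_days Days of historical series available before a
#'   question opens (what the machine model is first fit on).
#' @param prior_start_range,prior_end_range Ranges for the control group's
#'   mean probability on the (eventual) correct option at open and at close;
#'   the group prior drifts linearly between the two, emulating priors that
#'   sharpen toward the truth as evidence accrues.
#' @param sigma_prior Standard deviation of individual priors around the group
#'   mean, on the correct-option probability scale.
#' @param alpha True influence-weight process: either
#'   `list(type = "constant", value = a)` with `a` in (0, 1], or
#'   `list(type = "linear", beta0 =, beta =, noise_sd =)` where `beta` is a
#'   named vector of planted coefficients applied to per-question standard
#'   normal planted covariates.
#' @param machine Machine-forecaster settings:
#'   `list(type = "arima", noise_frac =, bias_sd =, max_p =, max_q =)` fits
#'   an ARIMA to a copy of the truth series corrupted by observation noise
#'   (`noise_frac` times the series' local scale) and an optional persistent
#'   per-question offset (`bias_sd`); the order search uses a compact
#'   `p, q <= 2` grid by default since the pre-open histories are short.
#'   `list(type = "oracle")` gives a perfect machine that always reports the
#'   resolved option with certainty.
#' @param skill_range Range of users' latent accuracy on skill questions.
#' @param skill_sd Forecast noise around latent accuracy on skill questions.
#' @param seed Integer seed; the same seed reproduces the tournament
#'   bit-identically.
#'
#' @return A list of class `"hf_sim_config"`.
#' @export
tournament_config <- function(n_questions = 50L,
                              n_users = 30L,
                              activity = 0.5,
                              duration_mean = 53,
                              duration_sd = 33,
                              duration_min = 7L,
                              duration_max = 160L,
                              n_options_range = 2:5,
                              n_independent_questions = 126L,
                              tournament_days = 210L,
                              pre_history_days = 45L,
                              prior_start_range = c(0.35, 0.55),
                              prior_end_range = c(0.60, 0.85),
                              sigma_prior = 0.1,
                              alpha = list(type = "constant", value = 0.86),
                              machine = list(type = "arima", noise_frac = 0.2,
                                             bias_sd = 0),
                              skill_range = c(0.5, 0.9),
                              skill_sd = 0.15,
                              seed = 1L) {
  if (!is.list(alpha) || is.null(alpha$type)) {
    abort("`alpha` must be a list with a `type` field.", class = "hf_config_error")
  }
  if (alpha$type == "constant") {
    if (is.null(alpha$value) || alpha$value <= 0 || alpha$value > 1) {
      abort("Constant alpha must lie in (0, 1].", class = "hf_config_error")
    }
  } else if (alpha$type == "linear") {
    if (is.null(alpha$beta0) || is.null(alpha$beta)) {
      abort("Linear alpha process needs `beta0` and a named `beta` vector.",
            class = "hf_config_error")
    }
    alpha$noise_sd <- alpha$noise_sd %||% 0.05
  } else {
    abort("`alpha$type` must be 'constant' or 'linear'.",
          class = "hf_config_error")
  }
  if (sigma_prior < 0) {
    abort("`sigma_prior` must be >= 0.", class = "hf_config_error")
  }
  if (!machine$type %in% c("arima", "oracle")) {
    abort("`machine$type` must be 'arima' or 'oracle'.",
          class = "hf_config_error")
  }
  if (machine$type == "arima") {
    machine$noise_frac <- machine$noise_frac %||% 0.2
    machine$bias_sd <- machine$bias_sd %||% 0
    machine$max_p <- machine$max_p %||% 2L
    machine$max_q <- machine$max_q %||% 2L
  }
  if (duration_min < 7L) {
    abort("`duration_min` must be >= 7 days so a weekly window fits.",
          class = "hf_config_error")
  }
  structure(
    list(n_questions = as.integer(n_questions), n_users = as.integer(n_users),
         activity = activity, duration_mean = duration_mean,
         duration_sd = duration_sd, duration_min = as.integer(duration_min),
         duration_max = as.integer(duration_max),
         n_options_range = as.integer(n_options_range),
         n_independent_questions = as.integer(n_independent_questions),
         tournament_days = as.integer(tournament_days),
         pre_history_days = as.integer(pre_history_days),
         prior_start_range = prior_start_range,
         prior_end_range = prior_end_range,
         sigma_prior = sigma_prior, alpha = alpha, machine = machine,
         skill_range = skill_range, skill_sd = skill_sd,
         seed = as.integer(seed)),
    class = "hf_sim_config"
  )
}

#' @export
print.hf_sim_config <- function(x, ...) {
  cat("<hybridcast tournament config>\n")
  cat("  questions:", x$n_questions, "| users/condition:", x$n_users,
      "| activity:", x$activity, "\n")
  cat("  alpha process:", x$alpha$type,
      if (x$alpha$type == "constant") paste0("(", x$alpha$value, ")") else "",
      "| machine:", x$machine$type, "| seed:", x$seed, "\n")
  invisible(x)
}
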