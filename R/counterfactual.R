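# Counterfactual framework: predict influence weights from a fitted
# regression, transform realized control forecasts into simulated treatment
# forecasts through the DeGroot combination, and sweep one regression
# coefficient at a time to measure each cognitive factor's impact on
# accuracy, stratified by machine helpfulness.

# Vectorized per-forecast Brier over a padded probability matrix.
score_rows <- function(pm, n_opt, resolved, ordinal) {
  vapply(seq_len(nrow(pm)), function(i) {
    p <- pm[i, seq_len(n_opt[i])]
    if (ordinal[i]) brier_ordinal(p, resolved[i])
    else brier_density(p, resolved[i])
  }, numeric(1))
}

#' Per-question Brier scores
#'
#' Mean per-forecast Brier score by question (ordinal variant on ordinal
#' questions) -- the accuracy summary the counterfactual sweeps compare.
#'
#' @param forecasts Forecast tibble.
#' @param questions Question tibble (resolved questions are scored).
#' @return A tibble `question_id, brier`.
#' @export
per_question_brier <- function(forecasts, questions) {
  scored <- score_forecasts(forecasts, questions)
  scored %>%
    group_by(.data$question_id) %>%
    summarise(brier = mean(.data$score), .groups = "drop")
}

#' Simulate exposing the control group to the machine
#'
#' Maps every realized control forecast `x` to the treatment forecast the
#' model predicts it would have become,
#' `y = alpha * x + (1 - alpha) * m`, componentwise with the machine
#' forecast of the same day (nearest earlier day if missing, logged).  The
#' mapping is deterministic -- it transforms the realized priors rather than
#' redrawing them -- so sweep comparisons carry no Monte-Carlo noise.
#' Forecasts not covered by any (question, window, stratum) in `alphas` are
#' dropped (reported via a message).
#'
#' @param control_forecasts Control-condition forecast tibble.
#' @param machine_forecasts Daily machine forecasts.
#' @param alphas Tibble `question_id, window_start, window_end, stratum,
#'   alpha` (use stratum `"all"` for unstratified weights).
#' @param questions Question tibble.
#' @param skill_labels Optional `user_id, stratum`; required when `alphas`
#'   is skill-stratified.
#' @return A forecast tibble with `condition = "simulated"`.
#' @export
simulate_exposure <- function(control_forecasts, machine_forecasts, alphas,
                              questions, skill_labels = NULL) {
  prep <- prepare_exposure(control_forecasts, machine_forecasts, alphas,
                           questions, skill_labels)
  apply_exposure(prep, prep$alpha)
}

# Resolve, once, which covariate/alpha row and which machine forecast each
# control forecast maps to; sweeps then only change the alpha values.
prepare_exposure <- function(control_forecasts, machine_forecasts, alphas,
                             questions, skill_labels = NULL) {
  fc <- dplyr::filter(control_forecasts, .data$condition == "control")
  if ("stratum" %in% names(alphas) &&
      any(alphas$stratum != "all")) {
    if (is.null(skill_labels)) {
      abort("`alphas` is skill-stratified; supply `skill_labels`.",
            class = "hf_counterfactual_error")
    }
    fc <- dplyr::inner_join(fc,
                            dplyr::select(skill_labels, "user_id", "stratum"),
                            by = "user_id")
  } else {
    fc$stratum <- "all"
  }
  al <- alphas
  if (!"stratum" %in% names(al)) al$stratum <- "all"
  # window containing the forecast's day, per question and stratum
  row_id <- integer(nrow(fc))
  for (k in seq_len(nrow(fc))) {
    cand <- which(al$question_id == fc$question_id[k] &
                    al$stratum == fc$stratum[k] &
                    al$window_start <= fc$timestamp[k] &
                    al$window_end >= fc$timestamp[k])
    row_id[k] <- if (length(cand) == 0) NA_integer_ else cand[which.min(al$window_end[cand])]
  }
  keep <- !is.na(row_id)
  if (any(!keep)) {
    inform(paste0(sum(!keep), " control forecast(s) fell outside all",
                  " estimation windows and were dropped."))
  }
  fc <- fc[keep, ]
  row_id <- row_id[keep]

  qinfo <- dplyr::select(questions, "question_id", "n_options",
                         "resolved_option", "is_ordinal")
  fc <- dplyr::inner_join(fc, qinfo, by = "question_id")
  x_pm <- prob_matrix(fc)
  m_pm <- matrix(NA_real_, nrow(fc), 5)
  mkey <- paste(machine_forecasts$question_id, machine_forecasts$date)
  j <- match(paste(fc$question_id, fc$timestamp), mkey)
  fallback <- which(is.na(j))
  if (length(fallback) > 0) {
    inform(paste0(length(fallback),
                  " forecast(s) had no same-day machine forecast; nearest earlier day used."))
    for (k in fallback) {
      earlier <- which(machine_forecasts$question_id == fc$question_id[k] &
                         machine_forecasts$date <= fc$timestamp[k])
      if (length(earlier) > 0) j[k] <- max(earlier)
    }
  }
  keep <- !is.na(j)
  fc <- fc[keep, ]; j <- j[keep]; row_id <- row_id[keep]
  x_pm <- x_pm[keep, , drop = FALSE]
  m_pm <- prob_matrix(machine_forecasts)[j, , drop = FALSE]
  list(fc = fc, x = x_pm, m = m_pm, alpha_row = row_id,
       alpha = al$alpha[row_id])
}

apply_exposure <- function(prep, alpha_per_forecast) {
  a <- alpha_per_forecast
  y <- a * prep$x + (1 - a) * prep$m
  out <- prep$fc
  out[PROB_COLS] <- as_tibble(y)
  out$condition <- "simulated"
  dplyr::select(out, -"n_options", -"resolved_option", -"is_ordinal",
                -"stratum")
}

#' Sweep one regression coefficient and measure the accuracy impact
#'
#' For each value on a grid around the learned coefficient, replaces that
#' single coefficient in the fitted influence regression, re-predicts the
#' influence weights for every (question, window, stratum) covariate row,
#' re-simulates exposing the control group to the machine with those
#' weights, and scores the simulated forecasts.  Reported per question as
#' the percent change in Brier score against the learned-coefficient
#' baseline (positive = less accurate), summarized by median and
#' interquartile range within machine-quality strata: questions whose
#' machine outperformed more than half the control users
#' (mean helpfulness > 0.5) versus the rest.  Stratum membership is fixed by
#' the unmodified helpfulness values throughout the sweep.
#'
#' @param fit An `"influence_fit"` (Model 1 recommended: the Eq.-style
#'   main-effects model).
#' @param covariates Covariate rows the fit was trained on (original scale).
#' @param control_forecasts,machine_forecasts,questions Tournament tables.
#' @param coef_name Name of the coefficient to sweep (as in
#'   `tidy(fit)$term`).
#' @param grid Grid of coefficient values; defaults to the learned value
#'   plus/minus 3 standard errors in 13 steps (always includes the learned
#'   value).
#' @param skill_labels Optional `user_id, stratum` for stratified weights.
#' @param eps Lower clamp for predicted alphas.
#' @return A tibble of class `"hf_sweep"`: one row per (coefficient value,
#'   machine-quality stratum) with the median, quartiles and question count
#'   of the percent Brier change; attributes `coef_name`, `learned`, `se`.
#' @export
sweep_coefficient <- function(fit, covariates, control_forecasts,
                              machine_forecasts, questions, coef_name,
                              grid = NULL, skill_labels = NULL, eps = 0.01) {
  beta <- coef(fit$fit)
  if (!coef_name %in% names(beta)) {
    abort(paste0("Coefficient '", coef_name, "' is not in the fit (",
                 paste(names(beta), collapse = ", "), ")."),
          class = "hf_counterfactual_error")
  }
  se <- sqrt(diag(fit$vcov))[coef_name]
  learned <- beta[coef_name]
  if (is.null(grid)) {
    grid <- learned + se * seq(-3, 3, length.out = 13)
  }
  if (!any(abs(grid - learned) < 1e-12)) grid <- sort(c(grid, learned))

  quality <- covariates %>%
    group_by(.data$question_id) %>%
    summarise(helpfulness = mean(.data$helpfulness), .groups = "drop") %>%
    mutate(quality = ifelse(.data$helpfulness > 0.5, "high", "low"))

  al_frame <- tibble(question_id = covariates$question_id,
                     window_start = covariates$window_start,
                     window_end = covariates$window_end,
                     stratum = covariates$skill,
                     alpha = NA_real_)
  prep <- prepare_exposure(control_forecasts, machine_forecasts, al_frame,
                           questions, skill_labels)

  brier_for <- function(beta_vec) {
    a_rows <- predict_alpha(fit, covariates, eps = eps,
                            coef_override = beta_vec)
    sim <- apply_exposure(prep, a_rows[prep$alpha_row])
    qinfo <- prep$fc
    pm <- prob_matrix(sim)
    s <- score_rows(pm, qinfo$n_options, qinfo$resolved_option,
                    qinfo$is_ordinal)
    tibble(question_id = sim$question_id, s = s) %>%
      group_by(.data$question_id) %>%
      summarise(brier = mean(.data$s), .groups = "drop")
  }

  base <- brier_for(beta)
  out <- purrr::map(grid, function(g) {
    b <- beta; b[coef_name] <- g
    cur <- brier_for(b)
    chg <- dplyr::inner_join(base, cur, by = "question_id",
                             suffix = c("_base", "_new")) %>%
      mutate(pct = 100 * (.data$brier_new - .data$brier_base) /
               .data$brier_base) %>%
      dplyr::inner_join(quality, by = "question_id")
    chg %>%
      group_by(.data$quality) %>%
      summarise(median = median(.data$pct),
                q25 = stats::quantile(.data$pct, 0.25, names = FALSE),
                q75 = stats::quantile(.data$pct, 0.75, names = FALSE),
                n_questions = dplyr::n(), .groups = "drop") %>%
      mutate(coefficient = coef_name, value = g, .before = 1)
  }) %>% bind_rows()
  for (q in c("high", "low")) {
    if (!q %in% out$quality) {
      warn(paste0("No questions in the '", q, "'-quality machine stratum."))
    }
  }
  structure(out, class = c("hf_sweep", class(out)),
            coef_name = coef_name, learned = unname(learned),
            se = unname(se))
}
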