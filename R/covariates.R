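# The cognitive covariates attached to each influence estimate: uncertainty,
# difficulty, confirmation, machine helpfulness, question lifetime, distance
# between machine and priors, and machine reputation.

#' Confirmation-bias dummy
#'
#' The reference forecast's nearest simplex vertex (the one-hot forecast it
#' leans toward; ties go to the lowest option index) is its "extreme".  The
#' machine forecast is *confirming* when it is at least as close to that
#' extreme as the reference itself.
#'
#' @param m Machine probability vector.
#' @param p Reference probability vector (mean forecast of the configured
#'   reference group).
#' @return `1L` if confirming, else `0L`.
#' @export
#' @examples
#' confirming(c(0.9, 0.1), c(0.6, 0.4))  # more extreme in p's direction: 1
#' confirming(c(0.4, 0.6), c(0.6, 0.4))  # pulls the other way: 0
confirming <- function(m, p) {
  if (length(m) != length(p)) {
    abort("`m` and `p` must be simplex vectors of the same length.",
          class = "hf_covariate_error")
  }
  ties <- sum(p == max(p)) > 1
  if (ties) inform("Uniform/tied reference forecast: extreme vertex taken at the lowest option index.")
  x <- one_hot(which.max(p), length(p))
  as.integer(sqrt(sum((x - m)^2)) <= sqrt(sum((x - p)^2)))
}

#' Machine helpfulness
#'
#' Fraction of control users whose Brier score is strictly worse (greater)
#' than the machine's; ties count one half, so the measure is an unbiased
#' quantile of the machine within the human accuracy distribution.
#'
#' @param user_briers Per-user Brier scores of the control group.
#' @param machine_brier The machine's Brier score on the same window.
#' @return A value in `[0, 1]`.
#' @export
helpfulness <- function(user_briers, machine_brier) {
  if (length(user_briers) == 0) {
    abort("Need at least one scored control user.",
          class = "hf_covariate_error")
  }
  (sum(user_briers > machine_brier) +
     0.5 * sum(user_briers == machine_brier)) / length(user_briers)
}

#' Question lifetime at a window's end
#'
#' Fraction of the question's open period elapsed by the window end.
#'
#' @param window_end Window end date.
#' @param t_open,t_close Question open/close dates.
#' @return A value in `[0, 1]`.
#' @export
lifetime <- function(window_end, t_open, t_close) {
  as.numeric(window_end - t_open) / as.numeric(t_close - t_open)
}

#' Cumulative-probability distance between two forecasts
#'
#' Euclidean distance between the cumulative probability vectors, the
#' ordinal-aware discrepancy used for the distance covariate.
#'
#' @param m,p Probability vectors over the same ordered options.
#' @return Nonnegative distance.
#' @export
#' @examples
#' distance_cumulative(c(0.9, 0.1), c(0.6, 0.4))  # 0.3
distance_cumulative <- function(m, p) {
  if (length(m) != length(p)) {
    abort("`m` and `p` must have the same length.",
          class = "hf_covariate_error")
  }
  sqrt(sum((cumsum(m) - cumsum(p))^2))
}

#' Forecast-set uncertainty
#'
#' Mean of the per-option variances (the average diagonal of the forecasts'
#' covariance matrix) across a set of full probability vectors.
#'
#' @param pm Matrix of probability vectors (rows = forecasts).
#' @param var_type `"sample"` (n-1) or `"population"` (n) variance.
#' @return Nonnegative scalar.
#' @export
uncertainty <- function(pm, var_type = c("sample", "population")) {
  var_type <- match.arg(var_type)
  if (is.null(dim(pm)) || nrow(pm) < 2) {
    abort("Need at least 2 forecasts to measure uncertainty.",
          class = "hf_covariate_error")
  }
  v <- apply(pm, 2, var)
  if (var_type == "population") v <- v * (nrow(pm) - 1) / nrow(pm)
  mean(v)
}

#' Machine reputation at each question's open
#'
#' Negative mean machine Brier score over the machine-paired questions that
#' had resolved by the time the question opened (no look-ahead).  Questions
#' opening before any machine track record exists are imputed with the
#' tournament-wide mean and flagged.
#'
#' @param questions Question tibble.
#' @param machine_forecasts Daily machine-forecast tibble.
#' @return A tibble `question_id, reputation, reputation_imputed`.
#' @export
machine_reputation <- function(questions, machine_forecasts) {
  qs <- dplyr::filter(questions, .data$has_machine,
                      !is.na(.data$resolved_option))
  briers <- machine_question_briers(machine_forecasts, qs)
  global <- mean(briers$machine_brier)
  purrr::map(seq_len(nrow(qs)), function(i) {
    prior_qs <- dplyr::filter(qs, .data$t_close <= qs$t_open[i])
    hist <- dplyr::semi_join(briers, prior_qs, by = "question_id")
    if (nrow(hist) == 0) {
      tibble(question_id = qs$question_id[i], reputation = -global,
             reputation_imputed = TRUE)
    } else {
      tibble(question_id = qs$question_id[i],
             reputation = -mean(hist$machine_brier),
             reputation_imputed = FALSE)
    }
  }) %>% bind_rows()
}

# Time-averaged Brier of the machine's daily forecasts, per question
# (ordinal variant on ordinal questions).
machine_question_briers <- function(machine_forecasts, questions) {
  qs <- dplyr::filter(questions, !is.na(.data$resolved_option))
  df <- dplyr::inner_join(machine_forecasts,
                          dplyr::select(qs, "question_id", "n_options",
                                        "resolved_option", "is_ordinal"),
                          by = "question_id")
  pm <- prob_matrix(df)
  df$s <- vapply(seq_len(nrow(df)), function(i) {
    question_variant_score(pm[i, seq_len(df$n_options[i])],
                           df$resolved_option[i], df$is_ordinal[i])
  }, numeric(1))
  df %>%
    group_by(.data$question_id) %>%
    summarise(machine_brier = mean(.data$s), .groups = "drop")
}

#' Assemble the covariate table for the influence regressions
#'
#' For every influence estimate (question, window, skill stratum) computes
#' the regression predictors: `uncertainty` and `difficulty` from the
#' window's control forecasts, the `confirming` dummy between the window's
#' mean machine forecast and the mean forecast of the configured reference
#' group, `helpfulness` of the machine against the control users,
#' `lifetime`, the cumulative-probability `distance` between machine and
#' control forecasts, and the question-level machine `reputation`.  When the
#' estimates are stratified by skill, the control and reference forecasts
#' are restricted to the stratum, matching the stratum-specific prior.
#'
#' @param estimates Output of [estimate_influence()].
#' @param forecasts,questions,machine_forecasts Tournament tables.
#' @param config A [pipeline_config()] (reference group, variance type).
#' @param skill_labels Optional `user_id, stratum` tibble; required when the
#'   estimates are skill-stratified.
#' @return A tibble with one row per (question, window, stratum):
#'   identifiers, `skill`, the response `alpha`, and the covariates.
#' @export
build_covariates <- function(estimates, forecasts, questions,
                             machine_forecasts,
                             config = pipeline_config(),
                             skill_labels = NULL) {
  qs <- dplyr::filter(questions, .data$has_machine,
                      !is.na(.data$resolved_option))
  scored <- score_forecasts(dplyr::semi_join(forecasts, qs,
                                             by = "question_id"), qs)
  if (is.null(skill_labels)) {
    scored$stratum <- "all"
  } else {
    scored <- dplyr::inner_join(scored,
                                dplyr::select(skill_labels, "user_id",
                                              "stratum"),
                                by = "user_id")
  }
  mach <- dplyr::inner_join(machine_forecasts,
                            dplyr::select(qs, "question_id", "n_options",
                                          "resolved_option", "is_ordinal"),
                            by = "question_id")
  mach_pm <- prob_matrix(mach)
  mach$s <- vapply(seq_len(nrow(mach)), function(i) {
    question_variant_score(mach_pm[i, seq_len(mach$n_options[i])],
                           mach$resolved_option[i], mach$is_ordinal[i])
  }, numeric(1))
  rep_tbl <- machine_reputation(questions, machine_forecasts)

  rows <- purrr::map(seq_len(nrow(estimates)), function(i) {
    est <- estimates[i, ]
    q <- dplyr::filter(qs, .data$question_id == est$question_id)
    n_opt <- q$n_options
    in_win <- function(df, datecol) {
      dplyr::filter(df, .data$question_id == est$question_id,
                    .data[[datecol]] >= est$window_start,
                    .data[[datecol]] <= est$window_end)
    }
    ctrl <- in_win(scored, "timestamp") %>%
      dplyr::filter(.data$condition == "control",
                    .data$stratum == est$stratum)
    ref_cond <- config$confirm_reference
    ref <- in_win(scored, "timestamp") %>%
      dplyr::filter(.data$condition == ref_cond,
                    .data$stratum == est$stratum)
    mw <- in_win(mach, "date")
    if (nrow(ctrl) < 2 || nrow(mw) == 0 || nrow(ref) == 0) return(NULL)

    ctrl_pm <- prob_matrix(ctrl)[, seq_len(n_opt), drop = FALSE]
    mw_pm <- prob_matrix(mw)[, seq_len(n_opt), drop = FALSE]
    m_mean <- colMeans(mw_pm)
    m_mean <- m_mean / sum(m_mean)
    ref_mean <- colMeans(prob_matrix(ref)[, seq_len(n_opt), drop = FALSE])
    ref_mean <- ref_mean / sum(ref_mean)

    per_user <- ctrl %>%
      group_by(.data$user_id) %>%
      summarise(b = mean(.data$score), .groups = "drop")
    machine_window_brier <- mean(mw$s)

    same_day <- match(ctrl$timestamp, mw$date)
    dists <- vapply(seq_len(nrow(ctrl)), function(k) {
      j <- same_day[k]
      if (is.na(j)) {
        earlier <- which(mw$date <= ctrl$timestamp[k])
        if (length(earlier) == 0) return(NA_real_)
        j <- max(earlier)
      }
      distance_cumulative(mw_pm[j, ], ctrl_pm[k, ])
    }, numeric(1))

    tibble(
      question_id = est$question_id, window_start = est$window_start,
      window_end = est$window_end, skill = est$stratum, alpha = est$alpha,
      uncertainty = uncertainty(ctrl_pm, config$var_type),
      difficulty = mean(ctrl$score),
      confirming = confirming(m_mean, ref_mean),
      helpfulness = helpfulness(per_user$b, machine_window_brier),
      lifetime = lifetime(est$window_end, q$t_open, q$t_close),
      distance = mean(dists, na.rm = TRUE)
    )
  }) %>% bind_rows()
  if (nrow(rows) == 0) {
    abort("No covariate rows could be built (windows too sparse?).",
          class = "hf_covariate_error")
  }
  left_join(rows, rep_tbl, by = "question_id")
}
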