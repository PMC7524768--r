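# Influence-weight estimation: binary projection onto the correct option,
# rolling trailing windows, plug-in priors from the control group, and
# bounded maximum-likelihood estimation of the weight alpha that treatment
# forecasters place on their prior beliefs (1 - alpha on the machine).

#' Project forecasts onto the correct option
#'
#' Multi-option forecasts are collapsed to the probability assigned to the
#' resolved (correct) option; the incorrect options' mass is implicit.  This
#' is what makes the model's k-dimensional likelihood univariate, and it is
#' only possible retrospectively, after resolution.
#'
#' @param probs A probability vector or matrix (rows = forecasts).
#' @param resolved_option 1-based index of the correct option.
#' @return Numeric vector of correct-option probabilities.
#' @export
#' @examples
#' project_binary(c(0.2, 0.3, 0.5), 3)
project_binary <- function(probs, resolved_option) {
  if (is.na(resolved_option)) {
    abort("Question is unresolved: binary projection requires the correct option.",
          class = "hf_influence_error")
  }
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (resolved_option < 1 || resolved_option > ncol(probs)) {
    abort("`resolved_option` out of range.", class = "hf_influence_error")
  }
  unname(probs[, resolved_option])
}

# Add a p_correct column to a forecast-like table (forecasts or machine).
add_projection <- function(df, questions) {
  qres <- dplyr::select(questions, "question_id", "n_options",
                        "resolved_option")
  if (any(is.na(qres$resolved_option))) {
    qres <- dplyr::filter(qres, !is.na(.data$resolved_option))
  }
  out <- dplyr::inner_join(df, qres, by = "question_id")
  pm <- prob_matrix(out)
  out$p_correct <- pm[cbind(seq_len(nrow(out)), out$resolved_option)]
  dplyr::select(out, -"n_options", -"resolved_option")
}

#' Window length implied by a setting
#'
#' `"weekly"` is 7 days, `"quarter_duration"` is a quarter of the question's
#' duration rounded up, `"max_of_both"` the maximum of the two.
#'
#' @param duration Question duration in days.
#' @param setting One of `"weekly"`, `"quarter_duration"`, `"max_of_both"`.
#' @return Window length in days.
#' @export
window_length <- function(duration,
                          setting = c("max_of_both", "weekly",
                                      "quarter_duration")) {
  setting <- match.arg(setting)
  switch(setting,
         weekly = 7L,
         quarter_duration = as.integer(ceiling(duration / 4)),
         max_of_both = max(7L, as.integer(ceiling(duration / 4))))
}

#' Build trailing estimation windows for a question
#'
#' Trailing (end-inclusive) windows of the setting's length, with end points
#' advanced by `stride` days from the first full window to the question's
#' last open day.  A question shorter than the window length gets a single
#' full-span window.  Forecast-count filtering happens at estimation time.
#'
#' @param question One-row question tibble (`question_id, t_open, t_close`).
#' @param setting Window-length rule, see [window_length()].
#' @param stride Days between successive window ends.
#' @return A tibble `question_id, start, end, setting`.
#' @export
build_windows <- function(question,
                          setting = c("max_of_both", "weekly",
                                      "quarter_duration"),
                          stride = 7L) {
  setting <- match.arg(setting)
  duration <- as.integer(question$t_close - question$t_open)
  last_open <- question$t_close - 1L
  L <- window_length(duration, setting)
  if (duration < L) {
    ends <- last_open
    starts <- question$t_open
  } else {
    ends <- seq(question$t_open + L - 1L, last_open, by = stride)
    if (tail(ends, 1) != last_open) ends <- c(ends, last_open)
    starts <- ends - L + 1L
  }
  tibble(question_id = question$question_id, start = starts, end = ends,
         setting = setting)
}

#' Plug-in prior from control projections in a window
#'
#' Sample mean and unbiased sample variance of the control group's
#' correct-option probabilities; the variance is floored at 1e-6 with a
#' degeneracy flag so the likelihood stays finite when all control forecasts
#' coincide.
#'
#' @param p_correct Numeric vector of control correct-option probabilities.
#' @return A list `mu, sigma2, n_control, degenerate`.
#' @export
#' @examples
#' estimate_prior(c(0.2, 0.4, 0.6, 0.8))
estimate_prior <- function(p_correct) {
  n <- length(p_correct)
  if (n < 2) {
    abort("Need at least 2 control projections for a prior.",
          class = "hf_influence_error")
  }
  mu <- mean(p_correct)
  s2 <- var(p_correct)
  degenerate <- s2 < 1e-6
  list(mu = mu, sigma2 = max(s2, 1e-6), n_control = n,
       degenerate = degenerate)
}

#' Log-likelihood of the influence weight
#'
#' Under the DeGroot-with-normal-priors model, a treatment forecast paired
#' with the machine forecast current on its day is
#' `Y ~ Normal(alpha * mu + (1 - alpha) * m, alpha^2 * sigma2)`.  After the
#' binary collapse the density is univariate, and the log-likelihood of the
#' window's treatment projections is the sum of the corresponding normal
#' log-densities.  Vectorized over `alpha`.
#'
#' @param alpha Influence weight(s) in (0, 1]; the density is singular at 0.
#' @param y Treatment correct-option probabilities.
#' @param m Machine correct-option probabilities, same length as `y` (each
#'   forecast paired with its own day's machine forecast).
#' @param mu,sigma2 Plug-in prior mean and variance from [estimate_prior()].
#' @return Log-likelihood value(s).
#' @export
alpha_loglik <- function(alpha, y, m, mu, sigma2) {
  if (any(alpha <= 0)) {
    abort("`alpha` must be > 0: the model variance alpha^2*sigma2 collapses at 0.",
          class = "hf_influence_error")
  }
  if (length(y) != length(m)) {
    abort("`y` and `m` must be paired (same length).",
          class = "hf_influence_error")
  }
  vapply(alpha, function(a) {
    sum(dnorm(y, mean = a * mu + (1 - a) * m, sd = a * sqrt(sigma2),
              log = TRUE))
  }, numeric(1))
}

#' Maximum-likelihood influence weight for one window
#'
#' Maximizes [alpha_loglik()] over `[eps, 1]`: a coarse grid locates the
#' basin, golden-section/parabolic search ([stats::optimize()]) refines it,
#' and the bounds are checked explicitly so boundary solutions (e.g.
#' treatment glued to the machine) are found.  If the optimizer fails, a
#' 0.001-step grid search is used with a warning.
#'
#' @inheritParams alpha_loglik
#' @param eps Lower bound for alpha (default 0.01).
#' @return A list `alpha, loglik, n_treatment`.
#' @export
estimate_alpha <- function(y, m, mu, sigma2, eps = 0.01) {
  f <- function(a) alpha_loglik(a, y, m, mu, sigma2)
  res <- tryCatch({
    coarse <- seq(eps, 1, by = 0.005)
    ll <- f(coarse)
    a0 <- coarse[which.max(ll)]
    lo <- max(eps, a0 - 0.01)
    hi <- min(1, a0 + 0.01)
    opt <- optimize(f, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
    cand_a <- c(opt$maximum, eps, 1, a0)
    cand_ll <- c(opt$objective, ll[1], ll[length(ll)], max(ll))
    best <- which.max(cand_ll)
    list(alpha = cand_a[best], loglik = cand_ll[best])
  }, error = function(e) {
    warn(paste0("Optimizer failed (", conditionMessage(e),
                "); falling back to grid search."))
    grid <- seq(eps, 1, by = 0.001)
    ll <- f(grid)
    list(alpha = grid[which.max(ll)], loglik = max(ll))
  })
  res$n_treatment <- length(y)
  res
}

#' Estimate influence weights across a tournament
#'
#' The full estimation pipeline: for every resolved machine-paired question,
#' build trailing windows, project forecasts onto the correct option, form
#' the plug-in prior from the window's control forecasts, pair each treatment
#' forecast with its day's machine forecast, and maximize the likelihood for
#' alpha.  Windows with fewer than `config$min_forecasts` forecasts in either
#' condition (within the stratum, when stratified) are discarded.  When
#' `skill_labels` is supplied (see [skill_split()]) both the prior and the
#' treatment forecasts are restricted to each skill stratum, giving one
#' estimate per (question, window, stratum).
#'
#' @param forecasts,questions,machine_forecasts Tournament tables.
#' @param config A [pipeline_config()].
#' @param skill_labels Optional tibble `user_id, stratum` from
#'   [skill_split()]; `NULL` estimates a single population stratum `"all"`.
#' @return A tibble of influence estimates: one row per retained
#'   (question, window, stratum) with `alpha`, the log-likelihood, counts,
#'   and the plug-in prior used.
#' @export
estimate_influence <- function(forecasts, questions, machine_forecasts,
                               config = pipeline_config(),
                               skill_labels = NULL) {
  qs <- dplyr::filter(questions, .data$has_machine,
                      !is.na(.data$resolved_option))
  if (nrow(qs) == 0) {
    abort("No resolved machine-paired questions to estimate on.",
          class = "hf_influence_error")
  }
  fc <- add_projection(dplyr::semi_join(forecasts, qs, by = "question_id"), qs)
  mach <- add_projection(machine_forecasts, qs) %>%
    dplyr::select("question_id", "date", m = "p_correct")
  if (is.null(skill_labels)) {
    fc$stratum <- "all"
  } else {
    fc <- dplyr::inner_join(fc,
                            dplyr::select(skill_labels, "user_id", "stratum"),
                            by = "user_id")
  }
  fc <- dplyr::left_join(fc, mach, by = c("question_id", "timestamp" = "date"))

  out <- purrr::map(seq_len(nrow(qs)), function(i) {
    qrow <- qs[i, ]
    wins <- build_windows(qrow, config$window_setting, config$stride)
    # plain vectors: the window loop is the hot path
    qsel <- fc$question_id == qrow$question_id
    ts <- fc$timestamp[qsel]; cond <- fc$condition[qsel]
    strat <- fc$stratum[qsel]; pc <- fc$p_correct[qsel]; mm <- fc$m[qsel]
    purrr::map(seq_len(nrow(wins)), function(w) {
      inw <- ts >= wins$start[w] & ts <= wins$end[w]
      purrr::map(unique(strat[inw]), function(s) {
        ss <- inw & strat == s
        ctrl_pc <- pc[ss & cond == "control"]
        tsel <- ss & cond == "treatment" & !is.na(mm)
        trt_pc <- pc[tsel]; trt_m <- mm[tsel]
        if (length(ctrl_pc) < config$min_forecasts ||
            length(trt_pc) < config$min_forecasts) {
          return(NULL)
        }
        prior <- estimate_prior(ctrl_pc)
        est <- estimate_alpha(trt_pc, trt_m, prior$mu, prior$sigma2,
                              eps = config$eps)
        tibble(question_id = qrow$question_id, window_start = wins$start[w],
               window_end = wins$end[w], setting = wins$setting[w],
               stratum = s, alpha = est$alpha, loglik = est$loglik,
               n_treatment = est$n_treatment, n_control = prior$n_control,
               mu = prior$mu, sigma2 = prior$sigma2,
               prior_degenerate = prior$degenerate)
      }) %>% bind_rows()
    }) %>% bind_rows()
  }) %>% bind_rows()
  if (nrow(out) == 0) {
    warn("No window met the minimum forecast-count requirement.")
  }
  out
}

#' Compare forecast variances between conditions
#'
#' The model implies that exposing forecasters to the machine shrinks the
#' forecast variance: `Var(treatment) = alpha^2 * Var(control)`.  Per
#' question, this computes the mean within-day variance of the
#' correct-option probability for each condition (within-day, so the drift
#' of the group prior does not masquerade as dispersion), then compares the
#' per-question variances between conditions with a two-sample t-test.
#'
#' @param forecasts,questions Tournament tables (resolved, machine-paired
#'   questions are used).
#' @param min_per_day Minimum forecasts per condition-day for that day's
#'   variance to count (default 2).
#' @return A list of class `"hf_variance_comparison"`: per-condition mean
#'   variances, their ratio with a delta-method standard error, the t-test
#'   p-value, and the per-question table.
#' @export
compare_condition_variances <- function(forecasts, questions,
                                        min_per_day = 2L) {
  qs <- dplyr::filter(questions, .data$has_machine,
                      !is.na(.data$resolved_option))
  if (nrow(qs) < 2) {
    abort("Need at least 2 resolved questions to compare variances.",
          class = "hf_influence_error")
  }
  fc <- add_projection(dplyr::semi_join(forecasts, qs, by = "question_id"), qs)
  per_day <- fc %>%
    group_by(.data$question_id, .data$condition, .data$timestamp) %>%
    summarise(v = if (dplyr::n() >= min_per_day) var(.data$p_correct)
              else NA_real_,
              .groups = "drop")
  per_q <- per_day %>%
    dplyr::filter(!is.na(.data$v)) %>%
    group_by(.data$question_id, .data$condition) %>%
    summarise(mean_var = mean(.data$v), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_var") %>%
    dplyr::filter(!is.na(.data$control), !is.na(.data$treatment))
  if (nrow(per_q) < 2) {
    abort("Fewer than 2 questions have within-day variances in both conditions.",
          class = "hf_influence_error")
  }
  mC <- mean(per_q$control); mT <- mean(per_q$treatment)
  nq <- nrow(per_q)
  vC <- var(per_q$control) / nq; vT <- var(per_q$treatment) / nq
  ratio <- mT / mC
  se_ratio <- sqrt(vT / mC^2 + mT^2 * vC / mC^4)
  tt <- if (isTRUE(all.equal(per_q$control, per_q$treatment))) {
    list(p.value = 1)  # identical data: no difference by construction
  } else {
    t.test(per_q$treatment, per_q$control)
  }
  structure(
    list(mean_var_control = mC, mean_var_treatment = mT, ratio = ratio,
         se_ratio = se_ratio, p_value = tt$p.value, n_questions = nq,
         per_question = per_q),
    class = "hf_variance_comparison"
  )
}

#' @export
print.hf_variance_comparison <- function(x, ...) {
  cat("<condition variance comparison> (", x$n_questions, "questions )\n")
  cat(sprintf("  mean within-day var: control %.4f, treatment %.4f (ratio %.3f +/- %.3f)\n",
              x$mean_var_control, x$mean_var_treatment, x$ratio, x$se_ratio))
  cat(sprintf("  two-sample t-test p = %.3g\n", x$p_value))
  invisible(x)
}
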