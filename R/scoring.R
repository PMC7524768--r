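# Brier scoring (density and ordinal variants) and the skill split.

check_probs_arg <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (nrow(probs) == 0) {
    abort("Empty forecast series cannot be scored.", class = "hf_scoring_error")
  }
  ok <- apply(probs, 1, is_simplex)
  if (!all(ok)) {
    abort("Forecast probabilities must lie on the simplex (sum to 1).",
          class = "hf_scoring_error")
  }
  probs
}

#' Density Brier score
#'
#' The multi-category Brier score `sum_i (p_i - o_i)^2` against the one-hot
#' outcome, time-averaged over the rows when `probs` is a matrix of daily
#' forecasts.  Ranges over `[0, 2]`; 0 iff every forecast puts all mass on the
#' correct option.
#'
#' @param probs A probability vector, or a matrix with one forecast per row.
#' @param outcome 1-based index of the correct option.
#' @return A single nonnegative score.
#' @export
#' @examples
#' brier_density(c(0.8, 0.2), 1)
brier_density <- function(probs, outcome) {
  probs <- check_probs_arg(probs)
  n <- ncol(probs)
  if (outcome < 1 || outcome > n) {
    abort("`outcome` must index one of the answer options.",
          class = "hf_scoring_error")
  }
  o <- one_hot(outcome, n)
  mean(rowSums(sweep(probs, 2, o)^2))
}

#' Ordinal (cumulative) Brier score
#'
#' For questions with ordered answer options a miss into a neighbouring bin
#' should cost less than a miss far away.  This variant scores the cumulative
#' probability vector against the cumulative one-hot outcome:
#' `sum_i (P_i - O_i)^2` with `P = cumsum(p)`, `O = cumsum(o)` (the last
#' component always contributes 0).  Time-averaged over rows as in
#' [brier_density()].  Ranges over `[0, n_options - 1]`; for binary questions
#' it equals the density score divided by two.
#'
#' @inheritParams brier_density
#' @param is_ordinal Assertion that the question's options are ordered; pass
#'   `FALSE` to get an informative error directing you to [brier_density()].
#' @return A single nonnegative score.
#' @export
#' @examples
#' brier_ordinal(c(0.2, 0.3, 0.5), 1)
brier_ordinal <- function(probs, outcome, is_ordinal = TRUE) {
  if (!isTRUE(is_ordinal)) {
    abort("Ordinal Brier is only defined for ordered options; use brier_density() for categorical questions.",
          class = "hf_scoring_error")
  }
  probs <- check_probs_arg(probs)
  n <- ncol(probs)
  if (outcome < 1 || outcome > n) {
    abort("`outcome` must index one of the answer options.",
          class = "hf_scoring_error")
  }
  P <- t(apply(probs, 1, cumsum))
  if (n == 1) P <- matrix(P, ncol = 1)
  O <- cumsum(one_hot(outcome, n))
  mean(rowSums(sweep(P, 2, O)^2))
}

# Per-forecast score with the convention used throughout: ordinal variant for
# ordinal questions, density otherwise.
question_variant_score <- function(probs, outcome, is_ordinal) {
  if (isTRUE(is_ordinal)) brier_ordinal(probs, outcome)
  else brier_density(probs, outcome)
}

#' Score every forecast of resolved questions
#'
#' Adds a per-forecast Brier score to a forecast table, using the cumulative
#' (ordinal) variant for ordinal questions and the density variant otherwise
#' (or a forced variant).
#'
#' @param forecasts Forecast tibble (see [read_forecasts()]).
#' @param questions Question tibble; only resolved questions are scored.
#' @param variant `"auto"` (default), `"density"`, or `"ordinal"`.
#' @return The forecasts of resolved questions with a `score` column.
#' @export
score_forecasts <- function(forecasts, questions,
                            variant = c("auto", "density", "ordinal")) {
  variant <- match.arg(variant)
  qres <- dplyr::filter(questions, !is.na(.data$resolved_option))
  df <- dplyr::inner_join(
    forecasts,
    dplyr::select(qres, "question_id", "n_options", "resolved_option",
                  "is_ordinal"),
    by = "question_id"
  )
  if (nrow(df) == 0) {
    return(mutate(forecasts[0, ], score = numeric(0)))
  }
  pm <- prob_matrix(df)
  use_ordinal <- switch(variant,
    auto = df$is_ordinal,
    density = rep(FALSE, nrow(df)),
    ordinal = rep(TRUE, nrow(df))
  )
  score <- vapply(seq_len(nrow(df)), function(i) {
    p <- pm[i, seq_len(df$n_options[i])]
    if (use_ordinal[i]) brier_ordinal(p, df$resolved_option[i])
    else brier_density(p, df$resolved_option[i])
  }, numeric(1))
  df$score <- score
  dplyr::select(df, -"n_options", -"resolved_option", -"is_ordinal")
}

#' Split users into high and low skill
#'
#' Users are scored on the machine-free independent questions, their
#' per-question scores are normalized across users (z-scores by default, so
#' hard questions do not dominate), averaged per user, and the better half
#' (lower score is better) is labelled `"high"`.  Ties are broken
#' deterministically by `user_id`; with `n` users, `ceiling(n / 2)` are
#' labelled high.  Users without any resolved independent-question forecast
#' are excluded with a warning.
#'
#' @param forecasts Forecast tibble covering the independent questions.
#' @param questions Question tibble; rows with `has_machine == FALSE` and a
#'   resolved outcome define the skill-assessment set.
#' @param method Normalization of per-question scores: `"zscore"` (default),
#'   `"rank"` (fractional ranks in `[0, 1]`) or `"raw"`.
#' @return A tibble with `user_id`, `skill_score` (mean normalized score,
#'   lower is better) and `stratum` (`"high"`/`"low"`).
#' @export
skill_split <- function(forecasts, questions,
                        method = c("zscore", "rank", "raw")) {
  method <- match.arg(method)
  indep <- dplyr::filter(questions, !.data$has_machine,
                         !is.na(.data$resolved_option))
  if (nrow(indep) == 0) {
    abort("No resolved independent (machine-free) questions to assess skill on.",
          class = "hf_scoring_error")
  }
  scored <- score_forecasts(dplyr::semi_join(forecasts, indep,
                                             by = "question_id"),
                            indep)
  if (nrow(scored) == 0) {
    abort("No forecasts on the independent questions.",
          class = "hf_scoring_error")
  }
  dropped <- setdiff(unique(forecasts$user_id), unique(scored$user_id))
  if (length(dropped) > 0) {
    warn(paste0(length(dropped),
                " user(s) had no resolved independent-question forecast and were excluded from the skill split."))
  }
  per_uq <- scored %>%
    group_by(.data$user_id, .data$question_id) %>%
    summarise(score = mean(.data$score), .groups = "drop")
  normalized <- per_uq %>%
    group_by(.data$question_id) %>%
    mutate(norm = switch(method,
      zscore = if (sd(.data$score) > 0)
        (.data$score - mean(.data$score)) / sd(.data$score)
      else rep(0, dplyr::n()),
      rank = if (dplyr::n() > 1)
        (rank(.data$score) - 1) / (dplyr::n() - 1)
      else rep(0.5, dplyr::n()),
      raw = .data$score
    )) %>%
    ungroup()
  per_user <- normalized %>%
    group_by(.data$user_id) %>%
    summarise(skill_score = mean(.data$norm), .groups = "drop") %>%
    arrange(.data$skill_score, .data$user_id)
  n_high <- ceiling(nrow(per_user) / 2)
  per_user$stratum <- c(rep("high", n_high),
                        rep("low", nrow(per_user) - n_high))
  per_user
}
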