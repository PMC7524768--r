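# Shared fixtures, built in code and cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

# A small but complete tournament exercised by several test files.
demo_tournament <- function() {
  if (is.null(.fixture_env$demo)) {
    .fixture_env$demo <- simulate_tournament(tournament_config(
      n_questions = 8, n_users = 16, n_independent_questions = 40,
      seed = 42
    ))
  }
  .fixture_env$demo
}

demo_estimates <- function() {
  if (is.null(.fixture_env$demo_est)) {
    tour <- demo_tournament()
    .fixture_env$demo_est <- estimate_influence(
      tour$forecasts, tour$questions, tour$machine_forecasts,
      pipeline_config()
    )
  }
  .fixture_env$demo_est
}

demo_covariates <- function() {
  if (is.null(.fixture_env$demo_cov)) {
    tour <- demo_tournament()
    .fixture_env$demo_cov <- build_covariates(
      demo_estimates(), tour$forecasts, tour$questions,
      tour$machine_forecasts, pipeline_config()
    )
  }
  .fixture_env$demo_cov
}

# One-row question tibble for unit cases.
make_question <- function(question_id = "Q1", n_options = 2L,
                          t_open = as.Date("2018-01-01"), duration = 30L,
                          resolved_option = 1L, is_ordinal = TRUE,
                          has_machine = TRUE, edges = c(100)) {
  e <- rep(NA_real_, 4)
  e[seq_along(edges)] <- edges
  tibble::tibble(
    question_id = question_id, n_options = as.integer(n_options),
    t_open = t_open, t_close = t_open + duration,
    resolved_option = as.integer(resolved_option), is_ordinal = is_ordinal,
    has_machine = has_machine,
    edge1 = e[1], edge2 = e[2], edge3 = e[3], edge4 = e[4]
  )
}

# Forecast rows from a matrix/list of probability vectors.
make_forecasts <- function(probs, question_id = "Q1", user_id = NULL,
                           timestamp = as.Date("2018-01-05"),
                           condition = "control") {
  if (is.list(probs)) {
    n <- length(probs)
    pm <- matrix(NA_real_, n, 5)
    for (i in seq_len(n)) pm[i, seq_along(probs[[i]])] <- probs[[i]]
  } else {
    pm <- matrix(NA_real_, nrow(probs), 5)
    pm[, seq_len(ncol(probs))] <- probs
    n <- nrow(probs)
  }
  colnames(pm) <- paste0("p", 1:5)
  dplyr::bind_cols(
    tibble::tibble(
      user_id = user_id %||% sprintf("U%02d", seq_len(n)),
      question_id = question_id,
      timestamp = rep(timestamp, length.out = n),
      condition = rep(condition, length.out = n)
    ),
    tibble::as_tibble(pm)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
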