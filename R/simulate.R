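# Synthetic tournament generator.  Produces a full tournament -- questions
# with daily historical series, a machine forecaster, control forecasts drawn
# around a drifting group prior, treatment forecasts formed by the DeGroot
# combination with a planted influence weight, and machine-free skill
# questions -- so every downstream stage is testable without external data.

draw_duration <- function(cfg) {
  repeat {
    d <- round(rnorm(1, cfg$duration_mean, cfg$duration_sd))
    if (d >= cfg$duration_min && d <= cfg$duration_max) return(as.integer(d))
  }
}

# Daily AR(1)-with-drift level series around a random base level.
draw_series <- function(n_days, level, scale) {
  phi <- runif(1, 0.2, 0.6)
  innov <- as.numeric(stats::filter(rnorm(n_days, 0, scale), phi,
                                    method = "recursive"))
  drift <- rnorm(1, 0, scale / 4)
  level + cumsum(drift + innov)
}

question_edges <- function(recent, n_opt) {
  qs <- unname(stats::quantile(recent, (1:(n_opt - 1L)) / n_opt, type = 7))
  if (any(diff(qs) <= 1e-9) || length(qs) == 0) {
    rng <- range(recent)
    if (diff(rng) < 1e-9) rng <- rng + c(-1, 1)  # guard: flat history
    qs <- seq(rng[1], rng[2], length.out = n_opt + 1L)[2:n_opt]
  }
  qs
}

# Probability vectors from correct-option draws: mass pc on the resolved
# option, remainder spread uniformly over the others.
spread_probs <- function(pc, resolved, n_opt) {
  pm <- matrix((1 - pc) / (n_opt - 1L), nrow = length(pc), ncol = n_opt)
  pm[, resolved] <- pc
  pm
}

planted_alpha <- function(cfg, eps = 0.01) {
  a <- cfg$alpha
  if (a$type == "constant") {
    list(alpha = a$value, covs = NULL)
  } else {
    z <- setNames(rnorm(length(a$beta)), names(a$beta))
    val <- clamp(a$beta0 + sum(z * a$beta) + rnorm(1, 0, a$noise_sd), eps, 1)
    list(alpha = val, covs = as.list(z))
  }
}

#' Generate a synthetic hybrid forecasting tournament
#'
#' Emulates the study design the analysis pipeline assumes: each question has
#' a daily historical series (AR(1) increments with drift) whose quantiles
#' define 2-5 non-degenerate answer bins and whose value at `t_close`
#' resolves it; a machine forecaster (ARIMA fit on pre-open history, daily
#' rolling-origin forecasts discretized into the bins -- or a perfect
#' "oracle") serves the treatment condition; control users draw their
#' correct-option probability from `Normal(mu_t, sigma_prior^2)` clipped to
#' `[0.01, 0.99]` with `mu_t` drifting linearly toward the correct option;
#' treatment users draw an independent prior from the same distribution and
#' report the componentwise convex combination
#' `y = alpha * x + (1 - alpha) * m` with the planted influence weight; and a
#' set of machine-free categorical questions orders users by latent skill.
#'
#' The same seed reproduces the tournament bit-identically.
#'
#' @param config A [tournament_config()].
#' @return A list of class `"hf_tournament"` with tibbles `questions`,
#'   `forecasts`, `machine_forecasts`, `history` (the daily series each
#'   question is built on), and a `ground_truth` list holding the planted
#'   alpha per question, the prior-mean path, and users' latent skill.
#' @export
#' @examples
#' tour <- simulate_tournament(tournament_config(n_questions = 3, n_users = 6,
#'                                               n_independent_questions = 10))
#' tour$questions
simulate_tournament <- function(config = tournament_config()) {
  cfg <- config
  set.seed(cfg$seed)
  origin <- as.Date("2018-01-01")
  control_ids <- sprintf("C%03d", seq_len(cfg$n_users))
  treatment_ids <- sprintf("T%03d", seq_len(cfg$n_users))
  skill_tbl <- tibble(
    user_id = c(control_ids, treatment_ids),
    condition = rep(c("control", "treatment"), each = cfg$n_users),
    latent_skill = runif(2 * cfg$n_users, cfg$skill_range[1], cfg$skill_range[2])
  )

  questions <- vector("list", cfg$n_questions)
  history <- vector("list", cfg$n_questions)
  machine <- vector("list", cfg$n_questions)
  forecasts <- vector("list", cfg$n_questions)
  alpha_truth <- vector("list", cfg$n_questions)
  prior_paths <- vector("list", cfg$n_questions)

  for (q in seq_len(cfg$n_questions)) {
    qid <- sprintf("Q%03d", q)
    duration <- draw_duration(cfg)
    offset <- sample.int(cfg$tournament_days - duration + 1L, 1L) - 1L
    t_open <- origin + offset
    t_close <- t_open + duration
    dates <- seq(t_open - cfg$pre_history_days, t_close, by = "day")
    level <- runif(1, 50, 150)
    scale <- level * 0.01
    x <- draw_series(length(dates), level, scale)
    pre_idx <- which(dates < t_open)
    recent <- tail(x[pre_idx], 30)
    n_opt <- if (length(cfg$n_options_range) == 1) cfg$n_options_range else
      sample(cfg$n_options_range, 1)
    edges <- question_edges(recent, n_opt)
    resolved <- findInterval(x[length(x)], edges) + 1L

    qrow <- tibble(
      question_id = qid, n_options = n_opt, t_open = t_open,
      t_close = t_close, resolved_option = resolved, is_ordinal = TRUE,
      has_machine = TRUE,
      edge1 = edges[1] %|NA|% NA_real_,
      edge2 = if (n_opt > 2) edges[2] else NA_real_,
      edge3 = if (n_opt > 3) edges[3] else NA_real_,
      edge4 = if (n_opt > 4) edges[4] else NA_real_
    )
    questions[[q]] <- qrow
    history[[q]] <- tibble(question_id = qid, date = dates, value = x)

    if (cfg$machine$type == "oracle") {
      open_dates <- dates[dates >= t_open & dates < t_close]
      pm <- matrix(0, nrow = length(open_dates), ncol = n_opt)
      pm[, resolved] <- 1
      machine[[q]] <- dplyr::bind_cols(
        tibble(question_id = qid, date = open_dates),
        pack_probs(pm),
        tibble(point_estimate = x[length(x)], lo95 = x[length(x)],
               hi95 = x[length(x)])
      )
    } else {
      scale_ref <- sd(x[pre_idx])
      z <- x + rnorm(length(x), 0, cfg$machine$noise_frac * scale_ref) +
        rnorm(1, 0, cfg$machine$bias_sd * scale_ref)
      machine[[q]] <- machine_forecasts_for_question(z, dates, qrow,
                                                     max_p = cfg$machine$max_p,
                                                     max_q = cfg$machine$max_q)
    }

    p_start <- runif(1, cfg$prior_start_range[1], cfg$prior_start_range[2])
    p_end <- runif(1, cfg$prior_end_range[1], cfg$prior_end_range[2])
    open_dates <- seq(t_open, t_close - 1, by = "day")
    mu_path <- seq(p_start, p_end, length.out = duration)
    prior_paths[[q]] <- tibble(question_id = qid, date = open_dates,
                               mu = mu_path)
    ap <- planted_alpha(cfg)
    alpha_truth[[q]] <- tibble(question_id = qid, alpha_true = ap$alpha,
                               !!!(ap$covs %||% list()))

    mach_pm <- prob_matrix(machine[[q]])[, seq_len(n_opt), drop = FALSE]
    mach_dates <- machine[[q]]$date

    gen_condition <- function(ids, condition) {
      grid <- tidyr::expand_grid(user_id = ids, date = open_dates)
      grid <- grid[rbinom(nrow(grid), 1, cfg$activity) == 1, ]
      if (nrow(grid) == 0) return(NULL)
      day_idx <- as.integer(grid$date - t_open) + 1L
      pc <- clamp(rnorm(nrow(grid), mu_path[day_idx], cfg$sigma_prior),
                  0.01, 0.99)
      pm <- spread_probs(pc, resolved, n_opt)
      if (condition == "treatment") {
        midx <- match(grid$date, mach_dates)
        pm <- ap$alpha * pm + (1 - ap$alpha) * mach_pm[midx, , drop = FALSE]
      }
      dplyr::bind_cols(
        tibble(user_id = grid$user_id, question_id = qid,
               timestamp = grid$date, condition = condition),
        pack_probs(pm)
      )
    }
    forecasts[[q]] <- bind_rows(gen_condition(control_ids, "control"),
                                gen_condition(treatment_ids, "treatment"))
  }

  skill_q <- generate_skill_questions(cfg, skill_tbl, origin)

  out <- list(
    questions = bind_rows(bind_rows(questions), skill_q$questions),
    forecasts = bind_rows(bind_rows(forecasts), skill_q$forecasts),
    machine_forecasts = bind_rows(machine),
    history = bind_rows(history),
    ground_truth = list(alpha = bind_rows(alpha_truth),
                        prior_path = bind_rows(prior_paths),
                        user_skill = skill_tbl),
    config = cfg
  )
  class(out) <- "hf_tournament"
  out
}

# Machine-free categorical questions whose forecast accuracy orders users by
# latent skill; used only by the skill split.
generate_skill_questions <- function(cfg, skill_tbl, origin) {
  n <- cfg$n_independent_questions
  if (n == 0) {
    return(list(questions = NULL, forecasts = NULL))
  }
  qids <- sprintf("IQ%03d", seq_len(n))
  resolved <- sample(1:2, n, replace = TRUE)
  questions <- tibble(
    question_id = qids, n_options = 2L, t_open = origin,
    t_close = origin + 14L, resolved_option = resolved, is_ordinal = FALSE,
    has_machine = FALSE, edge1 = NA_real_, edge2 = NA_real_,
    edge3 = NA_real_, edge4 = NA_real_
  )
  grid <- tidyr::expand_grid(user_id = skill_tbl$user_id, question_id = qids)
  grid <- left_join(grid, skill_tbl, by = "user_id")
  grid <- left_join(grid,
                    tibble(question_id = qids, resolved = resolved),
                    by = "question_id")
  pc <- clamp(rnorm(nrow(grid), grid$latent_skill, cfg$skill_sd), 0.01, 0.99)
  pm <- matrix(NA_real_, nrow = nrow(grid), ncol = 2)
  pm[cbind(seq_len(nrow(grid)), grid$resolved)] <- pc
  pm[cbind(seq_len(nrow(grid)), 3L - grid$resolved)] <- 1 - pc
  forecasts <- dplyr::bind_cols(
    tibble(user_id = grid$user_id, question_id = grid$question_id,
           timestamp = origin + sample(0:13, nrow(grid), replace = TRUE),
           condition = grid$condition),
    pack_probs(pm)
  )
  list(questions = questions, forecasts = forecasts)
}

#' @export
print.hf_tournament <- function(x, ...) {
  nq <- sum(x$questions$has_machine)
  cat("<hybridcast synthetic tournament>\n")
  cat("  ", nq, "machine-paired questions,",
      nrow(x$questions) - nq, "independent skill questions\n")
  cat("  ", nrow(x$forecasts), "forecasts,",
      nrow(x$machine_forecasts), "daily machine forecasts\n")
  cat("   alpha process:", x$config$alpha$type, "| seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write a tournament's tables to a directory
#'
#' Writes `forecasts.csv`, `questions.csv`, `machine_forecasts.csv` and
#' `ground_truth.json` under `dir`.
#'
#' @param tournament An `"hf_tournament"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tournament <- function(tournament, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_forecasts(tournament$forecasts, file.path(dir, "forecasts.csv"))
  write_questions(tournament$questions, file.path(dir, "questions.csv"))
  write_machine_forecasts(tournament$machine_forecasts,
                          file.path(dir, "machine_forecasts.csv"))
  gt <- tournament$ground_truth
  gt$prior_path <- mutate(gt$prior_path, date = as.character(.data$date))
  write_results(gt, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
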