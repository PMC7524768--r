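# Synthetic tournament generator: determinism, invariants, planted structure.

test_that("the same seed reproduces the tournament bit-identically", {
  cfg <- tournament_config(n_questions = 3, n_users = 6,
                           n_independent_questions = 8, seed = 77)
  a <- simulate_tournament(cfg)
  b <- simulate_tournament(cfg)
  expect_identical(a$forecasts, b$forecasts)
  expect_identical(a$questions, b$questions)
  expect_identical(a$machine_forecasts, b$machine_forecasts)
  expect_identical(a$ground_truth$alpha, b$ground_truth$alpha)
})

test_that("generated questions respect the design invariants", {
  tour <- demo_tournament()
  qs <- tour$questions[tour$questions$has_machine, ]
  expect_true(all(qs$n_options >= 2 & qs$n_options <= 5))
  expect_true(all(qs$t_open < qs$t_close))
  expect_true(all(as.integer(qs$t_close - qs$t_open) >= 7))
  # resolution equals the bin containing the series value at close
  for (i in seq_len(nrow(qs))) {
    h <- tour$history[tour$history$question_id == qs$question_id[i], ]
    final <- h$value[h$date == qs$t_close[i]]
    edges <- as.numeric(qs[i, paste0("edge", seq_len(qs$n_options[i] - 1))])
    expect_equal(findInterval(final, edges) + 1L, qs$resolved_option[i])
  }
})

test_that("control forecasts track the drifting group prior", {
  tour <- demo_tournament()
  cfg <- tour$config
  fc <- tour$forecasts
  fc <- fc[fc$condition == "control" & grepl("^Q", fc$question_id), ]
  qs <- tour$questions
  pm <- as.matrix(fc[paste0("p", 1:5)])
  res <- qs$resolved_option[match(fc$question_id, qs$question_id)]
  pc <- pm[cbind(seq_len(nrow(fc)), res)]
  mu <- dplyr::inner_join(
    tibble::tibble(question_id = fc$question_id, date = fc$timestamp, pc = pc),
    tour$ground_truth$prior_path, by = c("question_id", "date")
  )
  dev <- mu$pc - mu$mu
  n <- nrow(mu)
  expect_lt(abs(mean(dev)), 3 * cfg$sigma_prior / sqrt(n))
})

test_that("clipping at the probability bounds is rare for mid-range priors", {
  cfg <- tournament_config(n_questions = 6, n_users = 25,
                           prior_start_range = c(0.2, 0.4),
                           prior_end_range = c(0.6, 0.8),
                           sigma_prior = 0.1,
                           n_independent_questions = 0, seed = 31)
  tour <- simulate_tournament(cfg)
  fc <- tour$forecasts[tour$forecasts$condition == "control", ]
  pm <- as.matrix(fc[paste0("p", 1:5)])
  res <- tour$questions$resolved_option[match(fc$question_id,
                                              tour$questions$question_id)]
  pc <- pm[cbind(seq_len(nrow(fc)), res)]
  expect_lt(mean(pc <= 0.01 | pc >= 0.99), 0.01)
})

test_that("zero prior variance collapses control forecasts onto the group mean", {
  cfg <- tournament_config(n_questions = 2, n_users = 5, sigma_prior = 0,
                           n_independent_questions = 0, seed = 5)
  tour <- simulate_tournament(cfg)
  fc <- tour$forecasts[tour$forecasts$condition == "control", ]
  pm <- as.matrix(fc[paste0("p", 1:5)])
  res <- tour$questions$resolved_option[match(fc$question_id,
                                              tour$questions$question_id)]
  pc <- pm[cbind(seq_len(nrow(fc)), res)]
  mu <- dplyr::inner_join(
    tibble::tibble(question_id = fc$question_id, date = fc$timestamp, pc = pc),
    tour$ground_truth$prior_path, by = c("question_id", "date")
  )
  expect_equal(mu$pc, mu$mu, tolerance = 1e-12)
})

test_that("treatment forecasts are the planted convex combination with the machine", {
  tour <- demo_tournament()
  a <- tour$ground_truth$alpha$alpha_true[1]
  trt <- tour$forecasts[tour$forecasts$condition == "treatment" &
                          grepl("^Q", tour$forecasts$question_id), ]
  mach <- tour$machine_forecasts
  key_t <- paste(trt$question_id, trt$timestamp)
  key_m <- paste(mach$question_id, mach$date)
  j <- match(key_t, key_m)
  expect_false(anyNA(j))
  pm_t <- as.matrix(trt[paste0("p", 1:5)])
  pm_m <- as.matrix(mach[paste0("p", 1:5)])[j, ]
  # invert the combination: x = (y - (1-a) m) / a must be a simplex point
  x <- (pm_t - (1 - a) * pm_m) / a
  sums <- rowSums(x, na.rm = TRUE)
  expect_equal(sums, rep(1, nrow(x)), tolerance = 1e-9)
  expect_true(all(x >= -1e-9, na.rm = TRUE))
  expect_true(all(pm_t >= -1e-12 & pm_t <= 1 + 1e-12, na.rm = TRUE))
})

test_that("skill questions are machine-free, counted exactly, and order users by skill", {
  tour <- demo_tournament()
  iq <- tour$questions[!tour$questions$has_machine, ]
  expect_equal(nrow(iq), 40)
  expect_true(all(!iq$has_machine))
  scored <- score_forecasts(
    tour$forecasts[grepl("^IQ", tour$forecasts$question_id), ], iq)
  per_user <- dplyr::summarise(dplyr::group_by(scored, user_id),
                               b = mean(score), .groups = "drop")
  joined <- dplyr::inner_join(per_user, tour$ground_truth$user_skill,
                              by = "user_id")
  expect_lt(cor(joined$b, joined$latent_skill), -0.7)
})

test_that("invalid generator settings are rejected at load", {
  expect_error(tournament_config(alpha = list(type = "constant", value = 0)),
               class = "hf_config_error")
  expect_error(tournament_config(alpha = list(type = "constant", value = 1.2)),
               class = "hf_config_error")
  expect_error(tournament_config(sigma_prior = -1), class = "hf_config_error")
  expect_error(tournament_config(machine = list(type = "wizard")),
               class = "hf_config_error")
  expect_error(tournament_config(duration_min = 3), class = "hf_config_error")
})

test_that("a tournament round-trips through its CSV files", {
  tour <- simulate_tournament(tournament_config(
    n_questions = 2, n_users = 4, n_independent_questions = 3, seed = 12))
  dir <- withr::local_tempdir()
  write_tournament(tour, dir)
  fc <- read_forecasts(file.path(dir, "forecasts.csv"))
  qs <- read_questions(file.path(dir, "questions.csv"))
  mf <- read_machine_forecasts(file.path(dir, "machine_forecasts.csv"))
  expect_equal(nrow(fc), nrow(tour$forecasts))
  expect_equal(qs$resolved_option, tour$questions$resolved_option)
  expect_equal(mf$p1, tour$machine_forecasts$p1, tolerance = 1e-12)
})
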