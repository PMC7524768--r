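# Binary projection, windows, priors, likelihood, and alpha estimation.

test_that("binary projection extracts the correct-option probability", {
  expect_equal(project_binary(c(0.2, 0.3, 0.5), 3), 0.5)
  expect_equal(project_binary(rep(0.25, 4), 2), 0.25)
  expect_equal(project_binary(c(0, 0, 1), 3), 1)
  expect_error(project_binary(c(0.5, 0.5), NA), class = "hf_influence_error")
  expect_error(project_binary(c(0.5, 0.5), 3), class = "hf_influence_error")
})

test_that("window lengths follow the three settings", {
  expect_equal(window_length(28, "quarter_duration"), 7L)
  expect_equal(window_length(12, "max_of_both"), 7L)
  expect_equal(window_length(60, "max_of_both"), 15L)
  expect_equal(window_length(60, "weekly"), 7L)
  expect_equal(window_length(30, "quarter_duration"), 8L)  # ceiling(30/4)
})

test_that("windows trail through the open period and short questions get one span", {
  q <- make_question(duration = 60L)
  w <- build_windows(q, "max_of_both", stride = 7L)
  expect_true(all(w$end - w$start + 1 == 15))
  expect_true(all(w$start >= q$t_open & w$end <= q$t_close - 1))
  expect_equal(max(w$end), q$t_close - 1)  # final window reaches the last open day

  q5 <- make_question(duration = 5L)
  w5 <- build_windows(q5, "weekly", stride = 7L)
  expect_equal(nrow(w5), 1)
  expect_equal(w5$start, q5$t_open)
  expect_equal(w5$end, q5$t_close - 1)
})

test_that("the plug-in prior is the sample mean and unbiased variance, floored when degenerate", {
  p <- estimate_prior(c(0.4, 0.6))
  expect_equal(p$mu, 0.5)
  expect_equal(p$sigma2, 0.02)
  p <- estimate_prior(c(0.2, 0.4, 0.6, 0.8))
  expect_equal(p$mu, 0.5)
  expect_equal(p$sigma2, 0.2 / 3, tolerance = 1e-12)
  p <- estimate_prior(rep(0.5, 6))
  expect_true(p$degenerate)
  expect_equal(p$sigma2, 1e-6)
  expect_error(estimate_prior(0.4), class = "hf_influence_error")
})

test_that("the log-likelihood matches the printed density formula", {
  # unit normal peak: alpha = 1, y = mu, sigma2 = 1/(2 pi) gives log density 0
  expect_equal(alpha_loglik(1, y = 0.5, m = 0.9, mu = 0.5,
                            sigma2 = 1 / (2 * pi)), 0, tolerance = 1e-12)
  # unimodality in y around the model mean
  ll_near <- alpha_loglik(0.8, y = 0.58, m = 0.9, mu = 0.5, sigma2 = 0.01)
  ll_far <- alpha_loglik(0.8, y = 0.75, m = 0.9, mu = 0.5, sigma2 = 0.01)
  expect_gt(ll_near, ll_far)  # model mean is 0.8*0.5 + 0.2*0.9 = 0.58
  expect_error(alpha_loglik(0, 0.5, 0.5, 0.5, 0.01),
               class = "hf_influence_error")
  expect_error(alpha_loglik(0.5, c(0.5, 0.6), 0.5, 0.5, 0.01),
               class = "hf_influence_error")

  # brute-force evaluation of the density product on random instances
  # (ranges keep the literal product representable in double precision)
  set.seed(33)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    y <- runif(n, 0.3, 0.7); m <- runif(n, 0.3, 0.7); mu <- runif(1, 0.4, 0.6)
    s2 <- runif(1, 0.01, 0.05); a <- runif(1, 0.3, 1)
    v <- y - a * mu - (1 - a) * m
    dens <- exp(-0.5 * v^2 / (a^2 * s2)) / sqrt(2 * pi * a^2 * s2)
    expect_equal(alpha_loglik(a, y, m, mu, s2), log(prod(dens)),
                 tolerance = 1e-9)
  }
})

test_that("alpha estimation recovers planted weights and boundary cases", {
  set.seed(34)
  mu <- 0.6; s2 <- 0.01; n <- 200
  # alpha* = 1: treatment indistinguishable from the prior
  y1 <- rnorm(n, mu, sqrt(s2))
  est <- estimate_alpha(y1, m = rep(0.9, n), mu = mu, sigma2 = s2)
  expect_gte(est$alpha, 0.95)
  # treatment glued to the machine: estimate collapses to the lower bound
  est0 <- estimate_alpha(rep(0.9, n), m = rep(0.9, n), mu = mu, sigma2 = s2)
  expect_equal(est0$alpha, 0.01, tolerance = 1e-6)
  # alpha* = 0.5 parameter recovery
  x <- rnorm(n, mu, sqrt(s2))
  y5 <- 0.5 * x + 0.5 * 0.9
  est5 <- estimate_alpha(y5, m = rep(0.9, n), mu = mu, sigma2 = s2)
  expect_gte(est5$alpha, 0.45)
  expect_lte(est5$alpha, 0.55)
})

test_that("the optimizer agrees with a fine grid search of the density formula", {
  set.seed(35)
  grid <- seq(0.01, 1, by = 0.001)
  for (i in 1:30) {
    n <- sample(8:60, 1)
    mu <- runif(1, 0.2, 0.8); s2 <- runif(1, 0.002, 0.03)
    a_true <- runif(1, 0.05, 1)
    m <- runif(n, 0.1, 0.9)
    y <- a_true * rnorm(n, mu, sqrt(s2)) + (1 - a_true) * m
    ll <- alpha_loglik(grid, y, m, mu, s2)
    a_grid <- grid[which.max(ll)]
    est <- estimate_alpha(y, m, mu, s2)
    expect_lte(abs(est$alpha - a_grid), 0.002)
  }
})

test_that("estimates are invariant to relabeling the incorrect options", {
  tour <- demo_tournament()
  est1 <- demo_estimates()
  fc <- tour$forecasts
  qs <- tour$questions
  # swap two incorrect-option columns on a >=3-option question
  qid <- qs$question_id[qs$has_machine & qs$n_options >= 3][1]
  q <- qs[qs$question_id == qid, ]
  wrong <- setdiff(seq_len(q$n_options), q$resolved_option)[1:2]
  sel <- fc$question_id == qid
  tmp <- fc[[paste0("p", wrong[1])]][sel]
  fc[[paste0("p", wrong[1])]][sel] <- fc[[paste0("p", wrong[2])]][sel]
  fc[[paste0("p", wrong[2])]][sel] <- tmp
  est2 <- estimate_influence(fc, qs, tour$machine_forecasts,
                             pipeline_config())
  expect_equal(est2$alpha, est1$alpha, tolerance = 1e-12)
})

test_that("windows below the minimum forecast count are discarded", {
  est <- demo_estimates()
  expect_true(all(est$n_treatment >= 4))
  expect_true(all(est$n_control >= 4))
  expect_true(all(est$alpha >= 0.01 & est$alpha <= 1))
})

test_that("identical condition data shows no variance difference", {
  tour <- demo_tournament()
  ctrl <- tour$forecasts[tour$forecasts$condition == "control" &
                           grepl("^Q", tour$forecasts$question_id), ]
  mirrored <- ctrl
  mirrored$condition <- "treatment"
  cmp <- compare_condition_variances(dplyr::bind_rows(ctrl, mirrored),
                                     tour$questions)
  expect_equal(cmp$ratio, 1)
  expect_equal(cmp$p_value, 1)
  expect_error(compare_condition_variances(ctrl, tour$questions[0, ]),
               class = "hf_influence_error")
})

test_that("skill stratification yields per-stratum estimates with stratum-specific priors", {
  tour <- demo_tournament()
  labels <- skill_split(tour$forecasts, tour$questions)
  est <- estimate_influence(tour$forecasts, tour$questions,
                            tour$machine_forecasts, pipeline_config(),
                            skill_labels = labels)
  expect_setequal(unique(est$stratum), c("high", "low"))
  both <- dplyr::count(est, question_id, window_start, stratum)
  expect_true(all(both$n == 1))
})
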