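# Standardization, cell-means fits, tidiers, and alpha prediction.

test_that("standardization gives exact z-scores and round-trips", {
  set.seed(41)
  tab <- simulate_covariate_table(n = 80)
  std <- standardize_covariates(tab)
  for (cl in c("uncertainty", "difficulty", "helpfulness", "lifetime",
               "distance", "reputation")) {
    expect_equal(mean(std[[cl]]), 0, tolerance = 1e-12)
    expect_equal(sd(std[[cl]]), 1, tolerance = 1e-12)
  }
  expect_identical(std$confirming, tab$confirming)  # dummies untouched
  expect_identical(std$alpha, tab$alpha)            # response untouched
  back <- destandardize_covariates(std)
  expect_equal(back$distance, tab$distance, tolerance = 1e-12)
  expect_equal(back$reputation, tab$reputation, tolerance = 1e-12)

  tab$lifetime <- 0.5
  expect_warning(std2 <- standardize_covariates(tab), "zero-variance")
  expect_false("lifetime" %in% names(std2))
})

test_that("a noiseless linear table is recovered exactly with R^2 = 1", {
  set.seed(42)
  tab <- simulate_covariate_table(n = 300, noise_sd = 0)
  beta <- attr(tab, "beta_true")
  fit <- fit_influence_model(tab, model = 1)
  est <- coef(fit$fit)
  expect_equal(est[names(beta)], beta, tolerance = 1e-8)
  g <- glance(fit)
  expect_equal(g$r.squared, 1, tolerance = 1e-12)
  expect_lte(g$adj.r.squared, g$r.squared)
  expect_equal(g$nobs, 300)
})

test_that("the three models carry the expected term structures", {
  set.seed(43)
  tab <- simulate_covariate_table(n = 200)
  t1 <- tidy(fit_influence_model(tab, model = 1))
  expect_setequal(t1$term,
                  c("skillhigh", "skilllow", "uncertainty", "difficulty",
                    "confirming", "helpfulness", "lifetime", "distance",
                    "reputation"))
  t2 <- tidy(fit_influence_model(tab, model = 2))
  expect_true(all(c("skillhigh:helpfulness", "skilllow:helpfulness",
                    "skillhigh:uncertainty", "skilllow:uncertainty",
                    "skillhigh:confirming", "skilllow:confirming")
                  %in% t2$term))
  # nested slopes replace those three mains in Model 2
  expect_false(any(c("helpfulness", "uncertainty", "confirming") %in% t2$term))
  t3 <- tidy(fit_influence_model(tab, model = 3))
  expect_true("confirming:distance" %in% t3$term)
  expect_equal(nrow(t3), nrow(t1) + 1)
  expect_true(all(t1$std.error > 0))
})

test_that("fits are invariant to row order and detect collinearity", {
  set.seed(44)
  tab <- simulate_covariate_table(n = 150)
  f1 <- fit_influence_model(tab, model = 1)
  f2 <- fit_influence_model(tab[sample(nrow(tab)), ], model = 1)
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-10)

  tab$helpfulness <- tab$distance  # perfectly collinear after z-scoring
  expect_error(fit_influence_model(tab, model = 1),
               class = "hf_regression_error")
})

test_that("skill cell means equal the stratum baselines when other effects vanish", {
  set.seed(45)
  beta <- c(skillhigh = 0.848, skilllow = 0.932, uncertainty = 0,
            difficulty = 0, confirming = 0, helpfulness = 0, lifetime = 0,
            distance = 0, reputation = 0)
  tab <- simulate_covariate_table(n = 200, beta = beta, noise_sd = 0)
  fit <- fit_influence_model(tab, model = 1)
  expect_equal(unname(coef(fit$fit)["skillhigh"]), 0.848, tolerance = 1e-10)
  expect_equal(unname(coef(fit$fit)["skilllow"]), 0.932, tolerance = 1e-10)
})

test_that("predict_alpha reproduces the linear predictor, clamps, and checks inputs", {
  set.seed(46)
  tab <- simulate_covariate_table(n = 120, noise_sd = 0.02)
  fit <- fit_influence_model(tab, model = 1)
  # a covariate row at the training means with confirming = 0 predicts the
  # stratum baseline
  row <- tab[1, ]
  for (i in seq_len(nrow(fit$scaling))) {
    row[[fit$scaling$term[i]]] <- fit$scaling$mean[i]
  }
  row$confirming <- 0L
  row$skill <- "high"
  expect_equal(predict_alpha(fit, row),
               unname(coef(fit$fit)["skillhigh"]), tolerance = 1e-9)

  # hand-computed dot product on a printed row
  row2 <- tibble::tibble(skill = "low", uncertainty = 0.025,
                         difficulty = 0.4, confirming = 1L,
                         helpfulness = 0.7, lifetime = 0.3, distance = 0.5,
                         reputation = -0.35)
  z <- function(v, term) {
    s <- fit$scaling
    (v - s$mean[s$term == term]) / s$sd[s$term == term]
  }
  b <- coef(fit$fit)
  expected <- b["skilllow"] + b["uncertainty"] * z(0.025, "uncertainty") +
    b["difficulty"] * z(0.4, "difficulty") + b["confirming"] +
    b["helpfulness"] * z(0.7, "helpfulness") +
    b["lifetime"] * z(0.3, "lifetime") + b["distance"] * z(0.5, "distance") +
    b["reputation"] * z(-0.35, "reputation")
  expect_equal(predict_alpha(fit, row2), min(max(unname(expected), 0.01), 1),
               tolerance = 1e-12)

  # clamping at both ends via coefficient overrides
  b_hi <- b; b_hi["skilllow"] <- 2
  expect_equal(predict_alpha(fit, row2, coef_override = b_hi), 1)
  b_lo <- b; b_lo["skilllow"] <- -2
  expect_equal(predict_alpha(fit, row2, coef_override = b_lo), 0.01)

  expect_error(predict_alpha(fit, dplyr::select(row2, -"distance")),
               class = "hf_regression_error")
})

test_that("cluster-robust standard errors are available", {
  skip_if_not_installed("sandwich")
  set.seed(47)
  tab <- simulate_covariate_table(n = 150)
  tab$question_id <- rep(sprintf("Q%02d", 1:30), each = 5)
  f_cl <- fit_influence_model(tab, model = 1, cluster = "question_id")
  f_cf <- fit_influence_model(tab, model = 1)
  expect_equal(coef(f_cl$fit), coef(f_cf$fit))
  expect_false(isTRUE(all.equal(tidy(f_cl)$std.error, tidy(f_cf)$std.error)))
})

test_that("regression on the full synthetic pipeline links alpha to its planted level", {
  tour <- demo_tournament()
  labels <- skill_split(tour$forecasts, tour$questions)
  est <- estimate_influence(tour$forecasts, tour$questions,
                            tour$machine_forecasts, pipeline_config(),
                            skill_labels = labels)
  cov <- build_covariates(est, tour$forecasts, tour$questions,
                          tour$machine_forecasts, pipeline_config(),
                          skill_labels = labels)
  fit <- fit_influence_model(cov, model = 1)
  b <- coef(fit$fit)
  # constant planted alpha = 0.86: both stratum baselines recover it closely
  expect_equal(unname(b["skillhigh"]), 0.86, tolerance = 0.06)
  expect_equal(unname(b["skilllow"]), 0.86, tolerance = 0.06)
})
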