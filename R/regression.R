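# Cell-means regressions of the influence weight on standardized cognitive
# covariates, mirroring the three-model structure of the cognitive analysis:
# Model 1 main effects, Model 2 skill interactions, Model 3 the
# distance x confirming interaction.

CONTINUOUS_COVARIATES <- c("uncertainty", "difficulty", "helpfulness",
                           "lifetime", "distance", "reputation")

#' Standardize continuous predictors
#'
#' Converts the continuous covariates to z-scores over the regression sample
#' (binary dummies `confirming` and `skill`, and the response `alpha`, are
#' left untouched), so coefficients read as the effect of a one-standard-
#' deviation change.  Zero-variance columns are dropped with a warning.  The
#' means and sds are attached as attribute `"hf_scaling"` so new data can be
#' placed on the same scale and the transform inverted.
#'
#' @param covariates Covariate tibble from [build_covariates()].
#' @param cols Columns to standardize (defaults to the continuous
#'   covariates present).
#' @return The tibble with standardized columns and a `"hf_scaling"`
#'   attribute (`term, mean, sd`).
#' @export
standardize_covariates <- function(covariates,
                                   cols = intersect(CONTINUOUS_COVARIATES,
                                                    names(covariates))) {
  if (nrow(covariates) < 2) {
    abort("Need at least 2 rows to standardize.", class = "hf_regression_error")
  }
  scaling <- tibble(term = character(0), mean = numeric(0), sd = numeric(0))
  for (cl in cols) {
    m <- mean(covariates[[cl]]); s <- sd(covariates[[cl]])
    if (!is.finite(s) || s == 0) {
      warn(paste0("Dropping zero-variance predictor '", cl, "'."))
      covariates[[cl]] <- NULL
      next
    }
    covariates[[cl]] <- (covariates[[cl]] - m) / s
    scaling <- bind_rows(scaling, tibble(term = cl, mean = m, sd = s))
  }
  attr(covariates, "hf_scaling") <- scaling
  covariates
}

#' Invert [standardize_covariates()]
#'
#' @param covariates A standardized tibble carrying the `"hf_scaling"`
#'   attribute.
#' @return The tibble on the original scale.
#' @export
destandardize_covariates <- function(covariates) {
  scaling <- attr(covariates, "hf_scaling")
  if (is.null(scaling)) {
    abort("No 'hf_scaling' attribute found.", class = "hf_regression_error")
  }
  for (i in seq_len(nrow(scaling))) {
    cl <- scaling$term[i]
    covariates[[cl]] <- covariates[[cl]] * scaling$sd[i] + scaling$mean[i]
  }
  attr(covariates, "hf_scaling") <- NULL
  covariates
}

model_formula <- function(model_id, strata, available) {
  base <- intersect(c("uncertainty", "difficulty", "confirming",
                      "helpfulness", "lifetime", "distance", "reputation"),
                    available)
  cellmeans <- length(strata) > 1
  lhs <- "alpha ~ "
  if (model_id == 2) {
    if (!cellmeans) {
      abort("Model 2's skill interactions need both skill strata.",
            class = "hf_regression_error")
    }
    # nested slopes: helpfulness, uncertainty and confirming get one slope
    # per skill stratum (no main effect), mirroring the skill cell means
    keep <- setdiff(base, c("helpfulness", "uncertainty", "confirming"))
    inter <- paste0("skill:", intersect(c("helpfulness", "uncertainty",
                                          "confirming"), available))
    rhs <- c("0", "skill", keep, inter)
  } else {
    rhs <- if (cellmeans) c("0", "skill", base) else base
    if (model_id == 3 && all(c("confirming", "distance") %in% available)) {
      rhs <- c(rhs, "confirming:distance")
    }
  }
  stats::as.formula(paste0(lhs, paste(rhs, collapse = " + ")))
}

#' Fit an influence-weight regression
#'
#' Ordinary least squares of the influence weight alpha on the standardized
#' covariates, with no global intercept: the two skill strata enter as
#' cell-mean indicator columns (`skill:high`, `skill:low`), so each stratum's
#' coefficient is its baseline influence level.  `model = 1` fits the main
#' effects; `model = 2` splits the helpfulness, uncertainty and confirming
#' slopes by skill stratum (nested slopes, one coefficient per stratum, in
#' place of those mains); `model = 3` adds the distance-by-confirming
#' interaction to the main-effects model.  Interactions are built from the
#' standardized mains.
#' Classical standard errors by default; pass `cluster` (a column name, e.g.
#' `"question_id"`) for cluster-robust errors.
#'
#' @param covariates Covariate tibble from [build_covariates()] (or
#'   [simulate_covariate_table()]); must contain `alpha`, `skill`,
#'   `confirming` and the continuous covariates.
#' @param model Model id: 1, 2 or 3.
#' @param standardize Standardize continuous predictors first (default TRUE;
#'   set FALSE if the table is already on the regression scale).
#' @param cluster Optional column name for cluster-robust standard errors
#'   (requires the sandwich package).
#' @return An object of class `"influence_fit"` supporting [tidy()],
#'   [glance()] and [predict_alpha()].
#' @export
fit_influence_model <- function(covariates, model = 1, standardize = TRUE,
                                cluster = NULL) {
  if (!model %in% 1:3) {
    abort("`model` must be 1, 2 or 3.", class = "hf_regression_error")
  }
  df <- covariates
  needed <- c("alpha", "skill", "confirming")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Covariate table misses: ",
                 paste(missing_cols, collapse = ", ")),
          class = "hf_regression_error")
  }
  if (standardize) df <- standardize_covariates(df)
  scaling <- attr(df, "hf_scaling") %||%
    tibble(term = character(0), mean = numeric(0), sd = numeric(0))
  strata <- sort(unique(as.character(df$skill)))
  df$skill <- factor(df$skill, levels = strata)
  form <- model_formula(model, strata, names(df))
  fit <- lm(form, data = df)
  if (anyNA(coef(fit))) {
    abort(paste0("Rank-deficient design; collinear term(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "hf_regression_error")
  }
  V <- if (!is.null(cluster)) {
    if (!requireNamespace("sandwich", quietly = TRUE)) {
      abort("Cluster-robust errors need the 'sandwich' package.",
            class = "hf_regression_error")
    }
    sandwich::vcovCL(fit, cluster = covariates[[cluster]])
  } else {
    vcov(fit)
  }
  structure(
    list(fit = fit, model_id = model, scaling = scaling, strata = strata,
         data = df, vcov = V, cluster = cluster),
    class = "influence_fit"
  )
}

#' @export
print.influence_fit <- function(x, ...) {
  cat("<influence regression> Model", x$model_id, "|",
      length(coef(x$fit)), "terms |", nrow(x$data), "observations\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy an influence regression
#'
#' @param x An `"influence_fit"`.
#' @param ... Unused.
#' @return A tibble `term, estimate, std.error, statistic, p.value` (standard
#'   errors from the fit's chosen covariance: classical or cluster-robust).
#' @method tidy influence_fit
#' @export
tidy.influence_fit <- function(x, ...) {
  est <- coef(x$fit)
  se <- sqrt(diag(x$vcov))
  stat <- est / se
  dfres <- x$fit$df.residual
  tibble(term = names(est), estimate = unname(est), std.error = unname(se),
         statistic = unname(stat),
         p.value = 2 * stats::pt(abs(stat), dfres, lower.tail = FALSE))
}

#' Model-level summary of an influence regression
#'
#' R-squared is computed about the response mean (the cell-means coding has
#' no global intercept, for which the default uncentered R-squared would be
#' misleadingly close to 1).
#'
#' @param x An `"influence_fit"`.
#' @param ... Unused.
#' @return A one-row tibble `r.squared, adj.r.squared, sigma, nobs, model`.
#' @method glance influence_fit
#' @export
glance.influence_fit <- function(x, ...) {
  y <- x$fit$model$alpha
  rss <- sum(residuals(x$fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  n <- length(y); p <- length(coef(x$fit))
  adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  tibble(r.squared = r2, adj.r.squared = adj,
         sigma = sqrt(rss / x$fit$df.residual), nobs = n,
         model = x$model_id)
}

#' Predict influence weights from a fitted regression
#'
#' Applies the fit's standardization to new covariate rows, evaluates the
#' linear predictor (optionally with an overridden coefficient vector, as the
#' counterfactual sweeps do) and clamps to `[eps, 1]`.
#'
#' @param fit An `"influence_fit"`.
#' @param newdata Covariate rows on the original (unstandardized) scale.
#' @param eps Lower clamp for alpha.
#' @param coef_override Optional named coefficient vector replacing the
#'   fitted one (must cover the fit's terms).
#' @return Numeric vector of predicted alphas in `[eps, 1]`.
#' @export
predict_alpha <- function(fit, newdata, eps = 0.01, coef_override = NULL) {
  df <- newdata
  for (i in seq_len(nrow(fit$scaling))) {
    cl <- fit$scaling$term[i]
    if (!cl %in% names(df)) {
      abort(paste0("Missing covariate '", cl, "' in newdata."),
            class = "hf_regression_error")
    }
    df[[cl]] <- (df[[cl]] - fit$scaling$mean[i]) / fit$scaling$sd[i]
  }
  df$skill <- factor(as.character(df$skill), levels = fit$strata)
  if (anyNA(df$skill)) {
    abort("newdata has skill strata unseen in the fit.",
          class = "hf_regression_error")
  }
  tt <- delete.response(terms(fit$fit))
  mm <- model.matrix(tt, data = df)
  beta <- coef_override %||% coef(fit$fit)
  if (!all(colnames(mm) %in% names(beta))) {
    abort("Coefficient vector does not cover the fit's terms.",
          class = "hf_regression_error")
  }
  unname(clamp(drop(mm %*% beta[colnames(mm)]), eps, 1))
}

#' Simulate a covariate table with planted regression coefficients
#'
#' Draws covariate rows with realistic raw scales and builds the response
#' `alpha` as an exact linear function of the *sample-standardized*
#' predictors plus optional Gaussian noise -- so a no-noise table is fitted
#' with R-squared exactly 1 and the planted coefficients are recovered
#' exactly, and a noisy table exercises standard-error calibration.  Default
#' coefficients are representative of reported influence regressions (strata
#' baselines near 0.85-0.93, small negative confirming / helpfulness /
#' distance / reputation effects).
#'
#' @param n Number of rows.
#' @param beta Named coefficients on the standardized scale; names must be
#'   `skillhigh, skilllow, uncertainty, difficulty, confirming, helpfulness,
#'   lifetime, distance, reputation`.
#' @param noise_sd Residual standard deviation.
#' @return A tibble with attribute `"beta_true"`.
#' @export
simulate_covariate_table <- function(n = 500,
                                     beta = c(skillhigh = 0.848,
                                              skilllow = 0.932,
                                              uncertainty = -0.011,
                                              difficulty = 0.021,
                                              confirming = -0.058,
                                              helpfulness = -0.031,
                                              lifetime = 0.002,
                                              distance = -0.060,
                                              reputation = -0.021),
                                     noise_sd = 0.05) {
  df <- tibble(
    question_id = sprintf("S%04d", seq_len(n)),
    skill = sample(c("high", "low"), n, replace = TRUE),
    uncertainty = abs(rnorm(n, 0.02, 0.01)),
    difficulty = abs(rnorm(n, 0.30, 0.15)),
    confirming = rbinom(n, 1, 0.5),
    helpfulness = runif(n),
    lifetime = runif(n),
    distance = abs(rnorm(n, 0.40, 0.20)),
    reputation = -abs(rnorm(n, 0.30, 0.10))
  )
  z <- function(x) (x - mean(x)) / sd(x)
  lin <- ifelse(df$skill == "high", beta["skillhigh"], beta["skilllow"]) +
    beta["uncertainty"] * z(df$uncertainty) +
    beta["difficulty"] * z(df$difficulty) +
    beta["confirming"] * df$confirming +
    beta["helpfulness"] * z(df$helpfulness) +
    beta["lifetime"] * z(df$lifetime) +
    beta["distance"] * z(df$distance) +
    beta["reputation"] * z(df$reputation)
  df$alpha <- as.numeric(lin) + rnorm(n, 0, noise_sd)
  attr(df, "beta_true") <- beta
  df
}
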