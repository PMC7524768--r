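# Daily probabilistic machine forecasts from historical series: automatic
# ARIMA order selection, rolling-origin forecasts with analytic variance
# growth, and discretization of the predictive normal into answer-option
# probabilities.

# KPSS level-stationarity statistic with a Bartlett-window long-run variance.
kpss_statistic <- function(x) {
  n <- length(x)
  e <- x - mean(x)
  s <- cumsum(e)
  l <- trunc(4 * (n / 100)^0.25)
  lrv <- sum(e^2) / n
  if (l > 0) {
    for (k in seq_len(l)) {
      w <- 1 - k / (l + 1)
      lrv <- lrv + 2 * w * sum(e[(k + 1):n] * e[1:(n - k)]) / n
    }
  }
  if (lrv <= 0) return(0)
  sum(s^2) / (n^2 * lrv)
}

# Order of differencing: smallest d whose differenced series passes the KPSS
# level-stationarity test at the 5% critical value (0.463).
select_d <- function(x, max_d = 2L) {
  for (d in 0:max_d) {
    w <- if (d == 0) x else diff(x, differences = d)
    if (sd(w) < 1e-10) return(d)
    if (kpss_statistic(w) < 0.463) return(d)
  }
  max_d
}

aicc_from_fit <- function(fit, n_eff) {
  k <- length(fit$coef) + 1  # + innovation variance
  aic <- fit$aic
  if (is.na(aic)) return(NA_real_)
  if (n_eff - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n_eff - k - 1)
}

#' Fit an automatically selected ARIMA model to a daily series
#'
#' The differencing order `d` is chosen by a KPSS level-stationarity test
#' (smallest `d <= max_d` whose differenced series is stationary at the 5%
#' level); `p` and `q` are then chosen by exhaustive corrected-AIC (AICc)
#' search over `p, q <= 3`, with candidates ordered by complexity so exact
#' criterion ties resolve to the smaller model.  `stats::arima` is the
#' fitting engine.  A (numerically) constant series yields a degenerate model
#' flagged `degenerate = TRUE` whose forecasts are the constant with zero
#' interval width.
#'
#' @param x Numeric series (daily observations, at least 10).
#' @param max_p,max_q,max_d Search-grid bounds.
#' @return An object of class `"series_model"`: order, coefficients,
#'   innovation variance, AICc, and the training series.
#' @export
fit_series_model <- function(x, max_p = 3L, max_q = 3L, max_d = 2L) {
  x <- as.numeric(x)
  if (length(x) < 10) {
    abort("Need at least 10 observations to fit a series model.",
          class = "hf_machine_error")
  }
  if (anyNA(x)) abort("Series contains NA.", class = "hf_machine_error")
  if (sd(x) < 1e-10) {
    return(structure(
      list(order = c(0L, 0L, 0L), coef = numeric(0), mean = x[1],
           sigma2 = 0, aicc = NA_real_, degenerate = TRUE, x = x),
      class = "series_model"))
  }
  d <- select_d(x, max_d)
  grid <- expand.grid(p = 0:max_p, q = 0:max_q)
  grid <- grid[order(grid$p + grid$q, grid$p), ]
  best <- NULL
  best_aicc <- Inf
  n_eff <- length(x) - d
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; q <- grid$q[i]
    fit <- tryCatch(
      suppressWarnings(arima(x, order = c(p, d, q),
                             include.mean = (d == 0), method = "CSS-ML")),
      error = function(e) NULL)
    if (is.null(fit)) next
    crit <- aicc_from_fit(fit, n_eff)
    if (is.finite(crit) && crit < best_aicc - 1e-9) {
      best <- fit
      best_aicc <- crit
      best_order <- c(p, d, q)
    }
  }
  if (is.null(best)) {
    abort("All candidate ARIMA fits failed.", class = "hf_machine_error")
  }
  mu <- if (d == 0) unname(coef(best)["intercept"]) else 0
  co <- coef(best)
  co <- co[setdiff(names(co), "intercept")]
  structure(
    list(order = as.integer(best_order), coef = co, mean = mu,
         sigma2 = best$sigma2, aicc = best_aicc, degenerate = FALSE, x = x),
    class = "series_model"
  )
}

#' @export
print.series_model <- function(x, ...) {
  cat("<series model> ARIMA(", paste(x$order, collapse = ","), ")",
      if (x$degenerate) " [degenerate: constant series]", "\n", sep = "")
  if (length(x$coef)) print(round(x$coef, 4))
  cat("  sigma2:", signif(x$sigma2, 4), " AICc:", signif(x$aicc, 6), "\n")
  invisible(x)
}

# psi-weights of the *integrated* model, used for analytic h-step forecast
# variance: var(h) = sigma2 * (1 + psi_1^2 + ... + psi_{h-1}^2).
integrated_psi <- function(model, h_max) {
  p <- model$order[1]; d <- model$order[2]; q <- model$order[3]
  phi <- if (p > 0) unname(model$coef[paste0("ar", 1:p)]) else numeric(0)
  theta <- if (q > 0) unname(model$coef[paste0("ma", 1:q)]) else numeric(0)
  ar_poly <- c(1, if (p > 0) -phi else NULL)
  if (d > 0) for (i in seq_len(d)) ar_poly <- poly_mult(ar_poly, c(1, -1))
  ar_star <- -ar_poly[-1]
  if (h_max < 1) return(numeric(0))
  ARMAtoMA(ar = ar_star, ma = theta, lag.max = h_max)
}

# One-step innovations of `x` under the fitted model, from a single
# fixed-coefficient Kalman pass (no re-optimization).
model_innovations <- function(model, x) {
  p <- model$order[1]; d <- model$order[2]; q <- model$order[3]
  w <- if (d == 0) x else diff(x, differences = d)
  if (p + q == 0) return(w - model$mean)
  fixed <- unname(model$coef)
  if (d == 0) fixed <- c(fixed, model$mean)
  fit <- suppressWarnings(arima(x, order = model$order,
                                include.mean = (d == 0),
                                fixed = fixed, transform.pars = FALSE))
  e <- as.numeric(residuals(fit))
  if (d > 0) e <- e[-seq_len(d)]
  e
}

#' Rolling-origin forecasts of a series' value at a fixed target date
#'
#' For each forecast origin (an index into `x`), computes the model's
#' `h`-step-ahead point forecast of the value at `target_idx` together with
#' its standard deviation from the analytic psi-weight variance growth, and
#' the 95% interval `point +/- 1.96 * sd`.  All origins are served from a
#' single filtering pass over the series, which is how the machine updates
#' its forecast daily as data accrues without refitting.
#'
#' @param model A `"series_model"`.
#' @param x The full observed series (must extend the training series).
#' @param origins Integer indices into `x`: the last observation available at
#'   each forecast time.
#' @param target_idx Integer index of the forecast target (resolution day).
#' @return A tibble with `origin, h, point, sd, lo95, hi95`.
#' @export
forecast_series <- function(model, x, origins, target_idx) {
  x <- as.numeric(x)
  if (any(origins >= target_idx + 1)) {
    abort("Forecast origins must precede or equal the target index.",
          class = "hf_machine_error")
  }
  hs <- target_idx - origins
  if (model$degenerate) {
    return(tibble(origin = origins, h = hs, point = x[origins], sd = 0,
                  lo95 = x[origins], hi95 = x[origins]))
  }
  p <- model$order[1]; d <- model$order[2]; q <- model$order[3]
  phi <- if (p > 0) unname(model$coef[paste0("ar", 1:p)]) else numeric(0)
  theta <- if (q > 0) unname(model$coef[paste0("ma", 1:q)]) else numeric(0)
  w <- if (d == 0) x else diff(x, differences = d)
  wc <- w - model$mean
  e <- model_innovations(model, x)
  h_max <- max(hs)
  psi <- integrated_psi(model, h_max)
  var_cum <- cumsum(c(1, psi^2))  # var(h) = sigma2 * var_cum[h]
  point <- numeric(length(origins))
  for (k in seq_along(origins)) {
    t <- origins[k]; h <- hs[k]
    if (h == 0) { point[k] <- x[t]; next }
    tw <- t - d
    fc <- numeric(h)
    for (j in seq_len(h)) {
      ar_part <- 0
      if (p > 0) for (i in seq_len(p)) {
        idx <- tw + j - i
        ar_part <- ar_part + phi[i] *
          (if (idx <= tw) wc[idx] else fc[idx - tw])
      }
      ma_part <- 0
      if (q > 0) for (i in seq_len(q)) {
        idx <- j - i
        if (idx <= 0) {
          eidx <- tw + idx
          if (eidx >= 1) ma_part <- ma_part + theta[i] * e[eidx]
        }
      }
      fc[j] <- ar_part + ma_part
    }
    w_hat <- fc + model$mean
    cur <- w_hat
    if (d > 0) for (kk in seq_len(d)) {
      prev <- if (d - kk == 0) x[1:t] else diff(x[1:t], differences = d - kk)
      cur <- cumsum(cur) + tail(prev, 1)
    }
    point[k] <- cur[h]
  }
  sdv <- sqrt(model$sigma2 * var_cum[pmax(hs, 1)])
  sdv[hs == 0] <- 0
  tibble(origin = origins, h = hs, point = point, sd = sdv,
         lo95 = point - 1.96 * sdv, hi95 = point + 1.96 * sdv)
}

#' Discretize a normal predictive distribution into answer-option bins
#'
#' Assigns each answer option the Normal(`point`, `sd`^2) probability mass
#' between its bin edges; the outer bins take the open tails.  With
#' `sd = 0` (a degenerate model) all mass goes to the bin containing the
#' point forecast.
#'
#' @param point Point forecast on the value scale.
#' @param sd Predictive standard deviation (> 0 unless `degenerate`).
#' @param option_edges Strictly increasing internal bin boundaries
#'   (`n_options - 1` values).
#' @param degenerate Set `TRUE` to allow `sd = 0`.
#' @return A probability vector of length `length(option_edges) + 1`.
#' @export
#' @examples
#' forecast_to_bins(100, 10, c(90, 110))
forecast_to_bins <- function(point, sd, option_edges, degenerate = FALSE) {
  if (is.unsorted(option_edges, strictly = TRUE)) {
    abort("`option_edges` must be strictly increasing.",
          class = "hf_machine_error")
  }
  n <- length(option_edges) + 1L
  if (sd <= 0) {
    if (!degenerate || sd < 0) {
      abort("`sd` must be > 0 (or set `degenerate = TRUE` for a point mass).",
            class = "hf_machine_error")
    }
    bin <- findInterval(point, option_edges) + 1L
    return(one_hot(bin, n))
  }
  cdf <- pnorm(option_edges, mean = point, sd = sd)
  probs <- diff(c(0, cdf, 1))
  probs / sum(probs)
}

#' Build the daily machine-forecast table for one question
#'
#' Fits the series model on the pre-open history, then produces one forecast
#' of the resolution-day value per open day (origin = that day's last
#' observation) and discretizes it into the question's answer options.
#'
#' @param values Numeric series covering pre-open history through `t_close`.
#' @param dates `Date` vector aligned with `values`.
#' @param question One-row question tibble (needs `question_id, t_open,
#'   t_close, n_options, edge1..edge4`).
#' @param max_p,max_q Order-search bounds passed to [fit_series_model()].
#' @return A machine-forecast tibble (see [read_machine_forecasts()]).
#' @export
machine_forecasts_for_question <- function(values, dates, question,
                                           max_p = 3L, max_q = 3L) {
  stopifnot(length(values) == length(dates))
  open_idx <- which(dates >= question$t_open & dates < question$t_close)
  pre_idx <- which(dates < question$t_open)
  close_idx <- which(dates == question$t_close)
  if (length(close_idx) != 1) {
    abort("Series must include the resolution day t_close.",
          class = "hf_machine_error")
  }
  model <- fit_series_model(values[pre_idx], max_p = max_p, max_q = max_q)
  fc <- forecast_series(model, values, origins = open_idx,
                        target_idx = close_idx)
  edges <- as.numeric(question[paste0("edge", seq_len(question$n_options - 1L))])
  pm <- t(vapply(seq_len(nrow(fc)), function(i) {
    forecast_to_bins(fc$point[i], fc$sd[i], edges,
                     degenerate = model$degenerate || fc$sd[i] == 0)
  }, numeric(question$n_options)))
  if (question$n_options == 1) pm <- matrix(pm, ncol = 1)
  dplyr::bind_cols(
    tibble(question_id = question$question_id, date = dates[open_idx]),
    pack_probs(pm),
    tibble(point_estimate = fc$point, lo95 = fc$lo95, hi95 = fc$hi95)
  )
}
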