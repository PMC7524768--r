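# Readers and writers for the tournament's tabular interchange formats.
# All tables are plain CSV with a fixed-width probability schema (p1..p5,
# blank beyond a question's number of options) so 2- to 5-option questions
# share one layout.  Reader/writer pairs are lossless round trips.

forecast_cols <- function() {
  readr::cols(
    user_id = readr::col_character(),
    question_id = readr::col_character(),
    timestamp = readr::col_date(),
    condition = readr::col_character(),
    p1 = readr::col_character(), p2 = readr::col_character(),
    p3 = readr::col_character(), p4 = readr::col_character(),
    p5 = readr::col_character()
  )
}

# Doubles are parsed via R's strtod (correctly rounded), so a write/read
# cycle reproduces them bit-for-bit.
reparse_doubles <- function(df, cols) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- as.numeric(df[[cl]])
  df
}

validate_prob_rows <- function(df, what = "forecast") {
  pm <- prob_matrix(df)
  n_opt <- rowSums(!is.na(pm))
  sums <- rowSums(pm, na.rm = TRUE)
  neg <- apply(pm, 1, function(r) any(r < 0, na.rm = TRUE))
  gap <- apply(is.na(pm), 1, function(r) {
    nn <- which(!r)
    length(nn) > 0 && max(nn) != length(nn)  # NA holes inside the prefix
  })
  bad <- which(neg | gap | n_opt < 2 | abs(sums - 1) > SIMPLEX_TOL)
  if (length(bad) > 0) {
    abort(
      paste0("Invalid ", what, " probabilities (not on the simplex within 1e-6) ",
             "in row(s): ", paste(head(bad, 20), collapse = ", "),
             if (length(bad) > 20) " ..."),
      class = "hf_validation_error", rows = bad
    )
  }
  # Renormalize tolerated drift so downstream code sees exact simplex
  # points; rows already at 1 within machine precision are left untouched
  # so write/read round trips are bit-exact.
  need <- abs(sums - 1) > 1e-12
  if (any(need)) {
    pm[need, ] <- sweep(pm[need, , drop = FALSE], 1, sums[need], "/")
    df[PROB_COLS] <- as_tibble(pm)
  }
  df
}

#' Read a forecast table
#'
#' Expects a CSV with columns `user_id, question_id, timestamp (ISO-8601 date),
#' condition (control|treatment), p1..p5`.  Rows whose probabilities are
#' negative, leave gaps in the `p1..p5` prefix, or deviate from summing to one
#' by more than 1e-6 are rejected with their row numbers; tolerated drift
#' below 1e-6 is renormalized.
#'
#' @param path CSV file path.
#' @return A tibble of validated forecasts.
#' @export
read_forecasts <- function(path) {
  df <- readr::read_csv(path, col_types = forecast_cols(), progress = FALSE)
  missing_cols <- setdiff(c("user_id", "question_id", "timestamp", "condition"),
                          names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Forecast file misses columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "hf_validation_error")
  }
  df <- reparse_doubles(df, PROB_COLS)
  bad_cond <- which(!df$condition %in% c("control", "treatment"))
  if (length(bad_cond) > 0) {
    abort(paste0("Unknown condition in row(s): ",
                 paste(head(bad_cond, 20), collapse = ", ")),
          class = "hf_validation_error", rows = bad_cond)
  }
  validate_prob_rows(df)
}

#' Write a forecast table
#'
#' @param forecasts A forecast tibble (see [read_forecasts()] for the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_forecasts <- function(forecasts, path) {
  readr::write_csv(full_precision(forecasts), path, progress = FALSE)
  invisible(path)
}

# Doubles rendered with 17 significant digits so reader/writer pairs are
# lossless bit-for-bit.
full_precision <- function(df) {
  for (cl in names(df)) {
    if (is.double(df[[cl]]) && !inherits(df[[cl]], "Date")) {
      df[[cl]] <- ifelse(is.na(df[[cl]]), NA_character_,
                         sprintf("%.17g", df[[cl]]))
    }
  }
  df
}

question_cols <- function() {
  readr::cols(
    question_id = readr::col_character(),
    n_options = readr::col_integer(),
    t_open = readr::col_date(), t_close = readr::col_date(),
    resolved_option = readr::col_integer(),
    is_ordinal = readr::col_logical(),
    has_machine = readr::col_logical(),
    edge1 = readr::col_character(), edge2 = readr::col_character(),
    edge3 = readr::col_character(), edge4 = readr::col_character()
  )
}

#' Read question metadata
#'
#' Columns: `question_id, n_options (2..5), t_open, t_close, resolved_option
#' (1-based, NA until resolution), is_ordinal, has_machine, edge1..edge4`
#' (ordered internal bin boundaries; `n_options - 1` of them, blank beyond).
#' A question counts as open on days `d` with `t_open <= d < t_close`.
#'
#' @param path CSV file path.
#' @return A tibble of validated questions.
#' @export
read_questions <- function(path) {
  df <- readr::read_csv(path, col_types = question_cols(), progress = FALSE)
  df <- reparse_doubles(df, paste0("edge", 1:4))
  validate_questions(df)
}

validate_questions <- function(df) {
  bad <- which(df$n_options < 2 | df$n_options > 5)
  if (length(bad) > 0) {
    abort(paste0("n_options outside 2..5 in row(s): ",
                 paste(head(bad, 20), collapse = ", ")),
          class = "hf_validation_error", rows = bad)
  }
  bad <- which(!(df$t_open < df$t_close))
  if (length(bad) > 0) {
    abort(paste0("t_open must precede t_close; row(s): ",
                 paste(head(bad, 20), collapse = ", ")),
          class = "hf_validation_error", rows = bad)
  }
  res <- df$resolved_option
  bad <- which(!is.na(res) & (res < 1 | res > df$n_options))
  if (length(bad) > 0) {
    abort(paste0("resolved_option out of range in row(s): ",
                 paste(head(bad, 20), collapse = ", ")),
          class = "hf_validation_error", rows = bad)
  }
  edge_mat <- as.matrix(df[paste0("edge", 1:4)])
  for (i in seq_len(nrow(df))) {
    if (!isTRUE(df$is_ordinal[i])) next  # categorical: labelled options, no numeric edges
    e <- edge_mat[i, seq_len(df$n_options[i] - 1L)]
    if (anyNA(e) || is.unsorted(e, strictly = TRUE)) {
      abort(paste0("Bin edges must be ", df$n_options[i] - 1L,
                   " strictly increasing values; row ", i),
            class = "hf_validation_error", rows = i)
    }
  }
  df
}

#' @rdname read_questions
#' @param questions A question tibble.
#' @export
write_questions <- function(questions, path) {
  readr::write_csv(full_precision(questions), path, progress = FALSE)
  invisible(path)
}

machine_cols <- function() {
  readr::cols(
    question_id = readr::col_character(),
    date = readr::col_date(),
    p1 = readr::col_character(), p2 = readr::col_character(),
    p3 = readr::col_character(), p4 = readr::col_character(),
    p5 = readr::col_character(),
    point_estimate = readr::col_character(),
    lo95 = readr::col_character(), hi95 = readr::col_character()
  )
}

#' Read daily machine forecasts
#'
#' Columns: `question_id, date, p1..p5` (simplex over the question's answer
#' options), `point_estimate, lo95, hi95` (the 95% prediction interval on the
#' value scale, `lo95 <= point_estimate <= hi95`).
#'
#' @param path CSV file path.
#' @return A tibble of validated machine forecasts.
#' @export
read_machine_forecasts <- function(path) {
  df <- readr::read_csv(path, col_types = machine_cols(), progress = FALSE)
  df <- reparse_doubles(df, c(PROB_COLS, "point_estimate", "lo95", "hi95"))
  bad <- which(!(df$lo95 <= df$point_estimate & df$point_estimate <= df$hi95))
  if (length(bad) > 0) {
    abort(paste0("Prediction interval must contain the point estimate; row(s): ",
                 paste(head(bad, 20), collapse = ", ")),
          class = "hf_validation_error", rows = bad)
  }
  validate_prob_rows(df, what = "machine forecast")
}

#' @rdname read_machine_forecasts
#' @param machine_forecasts A machine forecast tibble.
#' @export
write_machine_forecasts <- function(machine_forecasts, path) {
  readr::write_csv(full_precision(machine_forecasts), path, progress = FALSE)
  invisible(path)
}

#' Write pipeline results as JSON
#'
#' Serializes result objects (influence estimates, regression fits,
#' counterfactual summaries, or any list of tables/scalars) to JSON at full
#' double precision with stable field order.  Data frames round-trip through
#' [read_results()] losslessly.
#'
#' @param x Object to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  jsonlite::write_json(x, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
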