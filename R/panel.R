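#' Read a Google-Trends-style behavior index CSV
#'
#' The dialect matches Trends exports: optional leading metadata lines are
#' skipped until a header row whose first field is `Day` or `Week`, then rows
#' of `date,value`. Values are relative volumes in `[0, 100]` (the period
#' maximum is standardized to 100); the `"<1"` cell convention is mapped
#' to 0.5.
#'
#' @param path CSV file path.
#' @return A tibble with columns `period` (Date), `value` (numeric in
#'   `[0, 100]`), and attribute `granularity` (`"daily"` or `"weekly"`).
#' @export
read_trends_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("trends file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*\"?(Day|Week)\"?\\s*,", lines)[1]
  if (is.na(hdr)) abort("no 'Day,...' or 'Week,...' header found in trends file")
  granularity <- if (grepl("^\\s*\"?Day", lines[hdr])) "daily" else "weekly"
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) abort("trends file has a header but no data rows")

  fields <- strsplit(body, ",", fixed = TRUE)
  row_no <- hdr + seq_along(body)
  if (any(lengths(fields) < 2)) {
    abort(sprintf("trends row %d: expected 'date,value'",
                  row_no[lengths(fields) < 2][1]))
  }
  date_str <- trimws(vapply(fields, `[[`, "", 1L))
  val_str <- trimws(gsub("\"", "", vapply(fields, `[[`, "", 2L)))

  period <- as.Date(date_str, format = "%Y-%m-%d")
  if (anyNA(period)) {
    abort(sprintf("trends row %d: unparseable date '%s'",
                  row_no[is.na(period)][1], date_str[is.na(period)][1]))
  }
  value <- suppressWarnings(as.numeric(ifelse(val_str == "<1", "0.5", val_str)))
  if (anyNA(value)) {
    abort(sprintf("trends row %d: unparseable value '%s'",
                  row_no[is.na(value)][1], val_str[is.na(value)][1]))
  }
  bad <- value < 0 | value > 100
  if (any(bad)) {
    abort(sprintf("trends row %d: value %s outside [0, 100]",
                  row_no[bad][1], format(value[bad][1])))
  }
  if (anyDuplicated(period)) {
    abort(sprintf("trends row %d: duplicate period %s",
                  row_no[duplicated(period)][1],
                  format(period[duplicated(period)][1])))
  }
  out <- tibble::tibble(period = period, value = value) |>
    dplyr::arrange(.data$period)
  attr(out, "granularity") <- granularity
  out
}

#' Assemble the weekly analysis panel
#'
#' Aligns a weekly emotion series with the behavior index on the same 7-day
#' blocks. A daily behavior series is averaged (not summed) into the blocks —
#' the index is a relative volume, not a count. Every requested week must be
#' covered by both sources. Column order is fixed: behavior first, then the
#' emotions in lexicon order.
#'
#' @param emotions Output of [weekly_emotion_index()].
#' @param behavior Output of [read_trends_csv()], or any data frame with
#'   `period` and `value` columns (daily dates or week-start dates).
#' @param start_date First day of week 0.
#' @param n_weeks Number of weeks in the panel.
#' @return An `emovar_panel`: a tibble with `week`, `week_start`, `behavior`
#'   and one column per emotion, plus provenance attributes (`start_date`,
#'   `standardized`, `var_names`).
#' @export
assemble_weekly_panel <- function(emotions, behavior, start_date, n_weeks) {
  start_date <- as.Date(start_date)
  n_weeks <- as.integer(n_weeks)
  stopifnot(is.data.frame(emotions), is.data.frame(behavior), n_weeks >= 1)
  emo_names <- setdiff(names(emotions), c("week", "week_start", "n_days"))

  missing_emo <- setdiff(seq_len(n_weeks) - 1L, emotions$week)
  if (length(missing_emo)) {
    abort(sprintf("week %d missing in source 'emotions'", missing_emo[1]))
  }

  offset <- as.integer(behavior$period - start_date)
  keep <- offset >= 0L & offset < 7L * n_weeks
  bwk <- tibble::tibble(week = offset[keep] %/% 7L,
                        value = behavior$value[keep]) |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(behavior = mean(.data$value), .groups = "drop")
  missing_beh <- setdiff(seq_len(n_weeks) - 1L, bwk$week)
  if (length(missing_beh)) {
    abort(sprintf("week %d missing in source 'behavior'", missing_beh[1]))
  }

  panel <- emotions |>
    dplyr::filter(.data$week < n_weeks) |>
    dplyr::select("week", "week_start", dplyr::all_of(emo_names)) |>
    dplyr::inner_join(bwk, by = "week") |>
    dplyr::relocate("behavior", .after = "week_start") |>
    dplyr::arrange(.data$week)
  new_panel(panel, start_date = start_date, standardized = FALSE,
            var_names = c("behavior", emo_names))
}

new_panel <- function(df, start_date, standardized, var_names) {
  structure(
    tibble::new_tibble(df, class = "emovar_panel"),
    start_date = as.Date(start_date),
    standardized = standardized,
    var_names = var_names
  )
}

#' @export
print.emovar_panel <- function(x, ...) {
  cat(sprintf("<emovar_panel> T = %d weeks from %s%s; variables: %s\n",
              nrow(x), format(attr(x, "start_date")),
              if (isTRUE(attr(x, "standardized"))) " (standardized)" else "",
              paste(attr(x, "var_names"), collapse = ", ")))
  NextMethod()
}

panel_vars <- function(panel) {
  attr(panel, "var_names") %||%
    setdiff(names(panel), c("week", "week_start", "n_days"))
}

panel_matrix <- function(panel, vars = panel_vars(panel)) {
  as.matrix(as.data.frame(panel)[, vars, drop = FALSE])
}

#' Standardize the panel columns
#'
#' Centers each analysis column to mean 0 and scales it to sample standard
#' deviation 1 (denominator `T - 1`). Standardizing puts all variables on the
#' same scale, so an orthogonalized impulse response reads as the effect of a
#' one-standard-deviation shock.
#'
#' @param panel An `emovar_panel` (or data frame with the panel columns).
#' @return The standardized `emovar_panel` with the `standardized` attribute
#'   set; the applied centers and scales are stored in attributes `center`
#'   and `scale`.
#' @export
standardize_panel <- function(panel) {
  vars <- panel_vars(panel)
  stopifnot(nrow(panel) >= 2)
  X <- panel_matrix(panel, vars)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  if (any(sdev == 0)) {
    abort(sprintf("column '%s' is constant and cannot be standardized",
                  vars[sdev == 0][1]))
  }
  out <- panel
  for (j in seq_along(vars)) out[[vars[j]]] <- (X[, j] - mu[j]) / sdev[j]
  out <- new_panel(out, start_date = attr(panel, "start_date") %||% NA,
                   standardized = TRUE, var_names = vars)
  attr(out, "center") <- mu
  attr(out, "scale") <- sdev
  out
}

#' Pearson correlation between two panel columns
#'
#' Sample Pearson correlation with a two-sided t test:
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n - 2} degrees of freedom.
#'
#' @param panel Panel data frame.
#' @param col_a,col_b Column names.
#' @return One-row tibble: `col_a`, `col_b`, `r`, `t`, `df`, `p_value`, `n`.
#' @export
pearson_correlation <- function(panel, col_a, col_b) {
  stopifnot(col_a %in% names(panel), col_b %in% names(panel))
  x <- panel[[col_a]]
  y <- panel[[col_b]]
  n <- length(x)
  if (n < 3) abort("need at least 3 rows for a correlation test")
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance column in correlation")
  r <- cor(x, y)
  t_stat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- if (abs(r) >= 1) 0 else 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  tibble::tibble(col_a = col_a, col_b = col_b, r = r, t = t_stat,
                 df = n - 2L, p_value = p, n = as.integer(n))
}

#' Correlation screen of every emotion against behavior
#'
#' @param panel An `emovar_panel`.
#' @param behavior_col Name of the behavior column.
#' @return Tibble with one row per emotion: `emotion`, `r`, `p_value`, `n`.
#' @export
panel_correlations <- function(panel, behavior_col = "behavior") {
  vars <- setdiff(panel_vars(panel), behavior_col)
  purrr::map_dfr(vars, function(v) {
    res <- pearson_correlation(panel, v, behavior_col)
    tibble::tibble(emotion = v, r = res$r, p_value = res$p_value, n = res$n)
  })
}
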