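#' Configuration for the end-to-end pipeline
#'
#' @param documents Path to a JSON-lines/CSV documents file, or a documents
#'   data frame.
#' @param lexicon Path to a lexicon file, or an `emovar_lexicon`.
#' @param trends Path to a trends CSV, or a data frame with `period`/`value`.
#' @param start_date,n_weeks Weekly calendar (7-day blocks from
#'   `start_date`).
#' @param country,lang,from,to Optional document filters.
#' @param tz Timezone for date grouping.
#' @param standardize Standardize the panel before modelling (default TRUE;
#'   recorded in the provenance either way).
#' @param p Fixed lag order; if `NULL`, chosen by BIC over `1..p_max`.
#' @param p_max Largest candidate lag when selecting.
#' @param alpha Significance level for correlation/Granger decisions.
#' @param horizon IRF horizon in weeks.
#' @param ordering Cholesky ordering (default: panel column order).
#' @param boot Bootstrap replicates for IRF bands; 0 skips bands.
#' @param seed Master seed (required when `boot > 0`).
#' @param on_unstable `"abort"` or `"warn"` when the fitted VAR is unstable.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(documents, lexicon, trends,
                            start_date = "2020-01-21", n_weeks = 50,
                            country = NULL, lang = NULL, from = NULL,
                            to = NULL, tz = "UTC", standardize = TRUE,
                            p = NULL, p_max = 8, alpha = 0.05, horizon = 10,
                            ordering = NULL, boot = 1000, seed = NULL,
                            on_unstable = c("abort", "warn")) {
  on_unstable <- match.arg(on_unstable)
  if (n_weeks < p_max + 10) {
    abort(sprintf("n_weeks (%d) must be at least p_max + 10 (%d)",
                  as.integer(n_weeks), as.integer(p_max) + 10L))
  }
  if (is.null(seed) && boot > 0) {
    abort("a seed is required when bootstrap bands are requested")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes score -> daily index -> weekly index -> panel assembly ->
#' (standardize) -> correlation screen -> lag selection (or fixed lag) ->
#' VAR fit -> stability check -> Granger tests -> orthogonalized IRFs with
#' bootstrap bands, and collects everything into a report object.
#'
#' @param config A [pipeline_config()].
#' @return An `emovar_report` list: `descriptives` (per-emotion min/max/
#'   mean/SD of document scores), `daily`, `weekly`, `panel`,
#'   `correlations`, `lag_selection`, `p_used`, `model`, `stability`,
#'   `granger`, `irf`, `counts`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config

  lex <- stage("lexicon", {
    if (inherits(cfg$lexicon, "emovar_lexicon")) cfg$lexicon
    else read_lexicon(cfg$lexicon)
  })
  docs <- stage("documents", {
    if (is.data.frame(cfg$documents)) {
      d <- as_document_frame(cfg$documents, tz = cfg$tz)
      if (!is.null(cfg$country)) d <- d[!is.na(d$country_code) &
        toupper(d$country_code) == toupper(cfg$country), ]
      if (!is.null(cfg$lang)) d <- d[!is.na(d$lang) &
        tolower(d$lang) == tolower(cfg$lang), ]
      if (!is.null(cfg$from)) d <- d[d$date >= as.Date(cfg$from), ]
      if (!is.null(cfg$to)) d <- d[d$date <= as.Date(cfg$to), ]
      d
    } else {
      read_documents(cfg$documents, country = cfg$country, lang = cfg$lang,
                     from = cfg$from, to = cfg$to, tz = cfg$tz)
    }
  })
  scores <- stage("score", score_documents(docs, lex, tz = cfg$tz))
  daily <- stage("daily index", daily_emotion_index(scores, lex))
  weekly <- stage("weekly index",
                  weekly_emotion_index(daily, cfg$start_date, cfg$n_weeks))
  behavior <- stage("panel", {
    if (is.data.frame(cfg$trends)) cfg$trends else read_trends_csv(cfg$trends)
  })
  panel <- stage("panel", assemble_weekly_panel(weekly, behavior,
                                                cfg$start_date, cfg$n_weeks))
  if (isTRUE(cfg$standardize)) {
    panel <- stage("standardize", standardize_panel(panel))
  }
  correlations <- stage("correlations",
                        panel_correlations(panel) |>
                          dplyr::mutate(significant = .data$p_value < cfg$alpha))
  lag_sel <- NULL
  p_used <- cfg$p
  if (is.null(p_used)) {
    lag_sel <- stage("lag selection", select_lag(panel, cfg$p_max))
    p_used <- lag_sel$bic_order
  }
  model <- stage("fit", fit_var(panel, p_used))
  stability <- stage("stability", check_stability(model))
  if (!stability$is_stable) {
    msg <- sprintf("fitted VAR(%d) is unstable (max eigenvalue modulus %.4f)",
                   p_used, stability$max_modulus)
    if (cfg$on_unstable == "abort") abort(paste("pipeline stage 'stability' failed:", msg))
    warn(msg)
  }
  granger <- stage("granger", granger_matrix(panel, p_used, cfg$alpha))
  irf <- stage("irf", {
    ordering <- cfg$ordering %||% model$var_names
    if (cfg$boot > 0 && stability$is_stable) {
      bootstrap_irf_bands(panel, p_used, cfg$horizon, ordering = ordering,
                          B = cfg$boot, alpha = cfg$alpha, seed = cfg$seed)
    } else {
      orthogonalized_irf(model, cfg$horizon, ordering = ordering)
    }
  })

  emotions <- names(lex)
  descriptives <- scores |>
    tidyr::pivot_longer(dplyr::all_of(emotions), names_to = "emotion",
                        values_to = "score") |>
    dplyr::group_by(.data$emotion) |>
    dplyr::summarise(min = min(.data$score), max = max(.data$score),
                     mean = mean(.data$score), sd = sd(.data$score),
                     .groups = "drop")

  structure(list(
    descriptives = descriptives,
    daily = daily, weekly = weekly, panel = panel,
    correlations = correlations,
    lag_selection = lag_sel, p_used = p_used,
    model = model, stability = stability,
    granger = granger, irf = irf,
    counts = list(
      documents_in = nrow(docs),
      documents_scored = nrow(scores),
      documents_skipped = length(attr(scores, "skipped")),
      days = nrow(daily), weeks = nrow(panel)
    ),
    provenance = list(
      start_date = format(as.Date(cfg$start_date)),
      n_weeks = as.integer(cfg$n_weeks),
      tz = cfg$tz, standardized = isTRUE(cfg$standardize),
      alpha = cfg$alpha, horizon = as.integer(cfg$horizon),
      boot = as.integer(cfg$boot), seed = cfg$seed,
      ordering = irf$ordering
    )
  ), class = "emovar_report")
}

#' @export
print.emovar_report <- function(x, ...) {
  cat(sprintf("<emovar_report> %d weeks from %s; VAR(%d), %s\n",
              x$counts$weeks, x$provenance$start_date, x$p_used,
              if (x$stability$is_stable) "stable" else "UNSTABLE"))
  cat(sprintf("  documents: %d scored, %d skipped\n",
              x$counts$documents_scored, x$counts$documents_skipped))
  cat("\nCorrelation screen (emotion vs behavior):\n")
  print(x$correlations)
  cat("\nGranger causality tests:\n")
  print(x$granger)
  invisible(x)
}

#' Write a machine- and human-readable report
#'
#' Persists the report as `report.json` plus `report.md` (markdown tables for
#' the descriptive statistics, correlation screen, lag selection, stability,
#' and Granger sections), `panel.csv`, `daily_index.csv`, `irf.csv`, and —
#' when `plots = TRUE` — an IRF grid in `irf.pdf`.
#'
#' @param report An `emovar_report`.
#' @param out_dir Output directory (created if needed).
#' @param plots Also write the IRF plot grid.
#' @return Invisibly, the named vector of written paths.
#' @export
write_report <- function(report, out_dir, plots = FALSE) {
  stopifnot(inherits(report, "emovar_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    json = file.path(out_dir, "report.json"),
    md = file.path(out_dir, "report.md"),
    panel = file.path(out_dir, "panel.csv"),
    daily = file.path(out_dir, "daily_index.csv"),
    irf = file.path(out_dir, "irf.csv")
  )
  readr::write_csv(as.data.frame(report$panel), paths["panel"])
  readr::write_csv(report$daily, paths["daily"])
  readr::write_csv(tidy(report$irf), paths["irf"])

  payload <- list(
    descriptives = report$descriptives,
    correlations = report$correlations,
    lag_selection = if (!is.null(report$lag_selection))
      report$lag_selection$criteria,
    p_used = report$p_used,
    var = list(
      variables = report$model$var_names, p = report$model$p,
      intercept = report$model$intercept,
      A = lapply(report$model$A, function(m) unclass(as.data.frame(m))),
      Sigma = unclass(as.data.frame(report$model$Sigma)),
      T_effective = report$model$T_effective
    ),
    stability = list(moduli = report$stability$moduli,
                     is_stable = report$stability$is_stable),
    granger = report$granger,
    irf = list(shock = report$irf$shock, ordering = report$irf$ordering,
               H = report$irf$H, B = report$irf$B, seed = report$irf$seed,
               level = report$irf$level),
    counts = report$counts,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, paths["json"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "rows")

  md <- c(
    "# Emotion / preventive-behavior VAR report", "",
    sprintf("%d weeks from %s; VAR(%d); %s.", report$counts$weeks,
            report$provenance$start_date, report$p_used,
            if (report$stability$is_stable) "stable" else "unstable"),
    "", "## Descriptive statistics of document scores", "",
    md_table(report$descriptives),
    "", "## Correlation with the preventive-behavior index", "",
    md_table(report$correlations),
    if (!is.null(report$lag_selection)) c(
      "", "## Lag selection", "",
      md_table(report$lag_selection$criteria),
      sprintf("\nAIC selects p = %d; BIC selects p = %d.",
              report$lag_selection$aic_order, report$lag_selection$bic_order)
    ),
    "", "## Granger causality", "",
    md_table(dplyr::mutate(report$granger,
                           decision = ifelse(.data$reject, "reject", "accept")))
  )
  writeLines(unlist(md), paths["md"])

  if (plots) {
    paths <- c(paths, plot = file.path(out_dir, "irf.pdf"))
    grDevices::pdf(paths[["plot"]], width = 9, height = 8)
    print(autoplot(report$irf))
    grDevices::dev.off()
  }
  invisible(paths)
}

md_table <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 4, format = "g"))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
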