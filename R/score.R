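#' Score documents against an emotion lexicon
#'
#' Computes, for every document with at least one token, the linguistic score
#' of each emotion: the percentage of token positions matched by that
#' emotion's dictionary. Phrases are matched greedily on the token sequence
#' before single-token entries; one phrase match consumes its tokens and adds
#' a single word event to the numerator, while the denominator always counts
#' all tokens. A token position counts at most once per emotion, but may
#' count for several different emotions.
#'
#' Documents that tokenize to zero tokens (for example a bare URL) are
#' unscorable — the score denominator is undefined — so they are dropped and
#' reported in the `skipped` attribute of the result.
#'
#' @param docs Data frame with columns `id`, `timestamp` (or `created_at`;
#'   anything [base::as.Date()]-compatible or ISO / Twitter-style strings)
#'   and `text`.
#' @param lex An `emovar_lexicon`.
#' @param tz Named timezone used to reduce timestamps to calendar dates.
#' @return A tibble with columns `id`, `date`, `token_count` and one numeric
#'   column per emotion (scores in `[0, 100]`), one row per scorable
#'   document, in input order. Attribute `skipped` holds the ids of
#'   unscorable documents.
#' @examples
#' docs <- tibble::tibble(
#'   id = "1", timestamp = "2020-03-01", text = "Cry cry cry"
#' )
#' score_documents(docs, example_lexicon())
#' @export
score_documents <- function(docs, lex, tz = "UTC") {
  stopifnot(is.data.frame(docs), inherits(lex, "emovar_lexicon"))
  docs <- as_document_frame(docs, tz = tz)
  tokens <- tokenize(docs$text, lex)
  n_tok <- lengths(tokens)
  scorable <- n_tok >= 1L
  skipped <- docs$id[!scorable]

  out <- tibble::tibble(
    id = docs$id[scorable],
    date = docs$date[scorable],
    token_count = n_tok[scorable]
  )
  counts <- count_emotion_matches(tokens[scorable], lex)
  for (em in names(lex)) {
    out[[em]] <- if (nrow(out)) {
      unname(100 * counts[, em] / out$token_count)
    } else {
      numeric()
    }
  }
  attr(out, "skipped") <- skipped
  out
}

# matched word events per document x emotion; fast vectorized path with a
# sequential fallback for documents where a phrase might occur
count_emotion_matches <- function(tokens, lex) {
  n <- length(tokens)
  emotions <- names(lex)
  counts <- matrix(0L, n, length(emotions), dimnames = list(NULL, emotions))
  if (n == 0) return(counts)

  flat <- unlist(tokens, use.names = FALSE)
  doc_of <- rep.int(seq_len(n), lengths(tokens))
  uniq <- unique(flat)
  idx <- match(flat, uniq)

  for (em in emotions) {
    e <- lex[[em]]
    match_u <- uniq %in% c(e$words, e$emoticons)
    for (p in e$prefixes) match_u <- match_u | startsWith(uniq, p)
    matched <- match_u[idx]
    cnt <- integer(n)
    if (any(matched)) {
      tab <- rowsum(as.integer(matched), doc_of, reorder = FALSE)
      cnt[as.integer(rownames(tab))] <- tab[, 1]
    }
    if (length(e$phrases)) {
      first_words <- vapply(strsplit(e$phrases, "\\s+"), `[[`, "", 1L)
      cand_u <- uniq %in% first_words
      cand_docs <- unique(doc_of[cand_u[idx]])
      for (d in cand_docs) cnt[d] <- score_emotion_sequential(tokens[[d]], e)
    }
    counts[, em] <- cnt
  }
  counts
}

# greedy left-to-right scan: longest phrase first, else single-token match
score_emotion_sequential <- function(tk, entry) {
  phr <- strsplit(entry$phrases, "\\s+")
  phr <- phr[order(-lengths(phr))]
  single <- c(entry$words, entry$emoticons)
  nt <- length(tk)
  i <- 1L
  cnt <- 0L
  while (i <= nt) {
    advanced <- FALSE
    for (ph in phr) {
      L <- length(ph)
      if (i + L - 1L <= nt && identical(tk[i:(i + L - 1L)], ph)) {
        cnt <- cnt + 1L
        i <- i + L
        advanced <- TRUE
        break
      }
    }
    if (advanced) next
    if (tk[i] %in% single || any(startsWith(tk[i], entry$prefixes))) {
      cnt <- cnt + 1L
    }
    i <- i + 1L
  }
  cnt
}

as_document_frame <- function(docs, tz = "UTC") {
  nm <- names(docs)
  id <- docs[[intersect(c("id", "id_str"), nm)[1] %||% "id"]]
  ts_col <- intersect(c("timestamp", "created_at", "date"), nm)[1]
  text_col <- intersect(c("text", "full_text"), nm)[1]
  if (is.null(id) || is.na(ts_col) || is.na(text_col)) {
    abort("documents need columns id (or id_str), timestamp (or created_at/date), and text (or full_text)")
  }
  id <- as.character(id)
  if (any(!nzchar(id) | is.na(id))) abort("document ids must be nonempty")
  tibble::tibble(
    id = id,
    date = as_document_date(docs[[ts_col]], tz = tz),
    text = as.character(docs[[text_col]]),
    lang = as.character(docs[["lang"]] %||% rep(NA_character_, nrow(docs))),
    country_code = as.character(docs[["country_code"]] %||% rep(NA_character_, nrow(docs)))
  )
}

#' Daily base-rate-normalized emotion indices
#'
#' Groups scorable documents by calendar date and reports, per emotion, the
#' mean percent deviation of the document scores from the lexicon base rate:
#' \deqn{p_{md} = \frac{100}{|T_d|} \sum_{t \in T_d} \frac{p_m(t) - p_{Bm}}{p_{Bm}}}
#' where \eqn{T_d} is the set of that date's scorable documents. A day on
#' which every document scores exactly the base rate has index 0; a single
#' document at twice the base rate gives 100.
#'
#' @param docs Either raw documents (see [score_documents()]) or an already
#'   scored table (output of [score_documents()]).
#' @param lex The `emovar_lexicon` whose base rates normalize the index.
#' @param tz Timezone for date grouping when scoring raw documents.
#' @return Tibble with `date`, `n_documents`, and one index column per
#'   emotion; attribute `skipped` carries over unscorable document ids.
#' @export
daily_emotion_index <- function(docs, lex, tz = "UTC") {
  stopifnot(inherits(lex, "emovar_lexicon"))
  emotions <- names(lex)
  scores <- if (all(c("token_count", emotions) %in% names(docs)) &&
                "date" %in% names(docs)) {
    docs
  } else {
    score_documents(docs, lex, tz = tz)
  }
  if (nrow(scores) == 0) abort("no scorable documents: daily series is empty")
  pB <- base_rates(lex)
  out <- scores |>
    dplyr::group_by(date = .data$date) |>
    dplyr::summarise(
      n_documents = dplyr::n(),
      dplyr::across(dplyr::all_of(emotions),
                    ~ 100 * mean((.x - pB[[dplyr::cur_column()]]) /
                                   pB[[dplyr::cur_column()]])),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$date)
  attr(out, "skipped") <- attr(scores, "skipped")
  out
}

#' Weekly emotion indices from daily indices
#'
#' Averages daily indices over consecutive 7-day blocks anchored at
#' `start_date` (block `w` spans `start_date + 7w .. start_date + 7w + 6`).
#' These are calendar-anchored waves, not ISO weeks. A block's score is the
#' arithmetic mean of the daily indices available inside it; a block with no
#' covered day is an error.
#'
#' @param daily Output of [daily_emotion_index()].
#' @param start_date First day of week 0 (Date or string).
#' @param n_weeks Number of consecutive weekly blocks to emit; trailing days
#'   beyond the last block are dropped.
#' @return Tibble with `week` (0-based), `week_start`, `n_days` (day
#'   coverage) and one column per emotion.
#' @export
weekly_emotion_index <- function(daily, start_date, n_weeks) {
  start_date <- as.Date(start_date)
  n_weeks <- as.integer(n_weeks)
  stopifnot(is.data.frame(daily), n_weeks >= 1)
  emotions <- setdiff(names(daily), c("date", "n_documents"))
  offset <- as.integer(daily$date - start_date)
  keep <- offset >= 0L & offset < 7L * n_weeks
  d <- daily[keep, , drop = FALSE]
  wk <- offset[keep] %/% 7L

  out <- d |>
    dplyr::mutate(week = wk) |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      dplyr::across(dplyr::all_of(emotions), mean),
      .groups = "drop"
    )
  missing <- setdiff(seq_len(n_weeks) - 1L, out$week)
  if (length(missing)) {
    abort(sprintf("no daily data in week %s (weeks are 7-day blocks from %s)",
                  paste(missing, collapse = ", "), format(start_date)))
  }
  out |>
    dplyr::arrange(.data$week) |>
    dplyr::mutate(week_start = start_date + 7L * .data$week, .after = "week")
}

#' Read timestamped documents from JSON-lines or CSV
#'
#' JSON-lines files need one object per line with fields `id` (or `id_str`),
#' `created_at` (or `timestamp`), `text` (or `full_text`) and optional `lang`
#' and `country_code`; CSV files need the same headers.
#'
#' @param path Input file (`.jsonl`/`.ndjson`/`.json` or `.csv`).
#' @param country,lang Optional 2-letter filters (case-insensitive); rows
#'   with missing tags are dropped when a filter is set.
#' @param from,to Optional inclusive date bounds applied after timezone
#'   normalization.
#' @param tz Timezone for the date bounds.
#' @return Tibble with columns `id`, `date`, `text`, `lang`, `country_code`.
#' @export
read_documents <- function(path, country = NULL, lang = NULL,
                           from = NULL, to = NULL, tz = "UTC") {
  if (!file.exists(path)) abort(sprintf("documents file not found: %s", path))
  raw <- if (grepl("\\.(jsonl|ndjson|json)$", path, ignore.case = TRUE)) {
    jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  docs <- as_document_frame(raw, tz = tz)
  if (!is.null(country)) {
    docs <- docs[!is.na(docs$country_code) &
                   toupper(docs$country_code) == toupper(country), ]
  }
  if (!is.null(lang)) {
    docs <- docs[!is.na(docs$lang) & tolower(docs$lang) == tolower(lang), ]
  }
  if (!is.null(from)) docs <- docs[docs$date >= as.Date(from), ]
  if (!is.null(to)) docs <- docs[docs$date <= as.Date(to), ]
  docs
}
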