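#' Construct an emotion lexicon
#'
#' A lexicon maps each emotion to four classes of dictionary entries —
#' literal words, prefix wildcards (`"abhor*"` matches any token starting
#' with `abhor`), multi-word phrases, and emoticon symbols — plus a platform
#' base rate \eqn{p_{Bm}} (in percent units) used to normalize daily indices.
#'
#' Entries are lowercased on construction. A trailing `*` on a word entry
#' moves it to the prefix class, so word lists may be written in the usual
#' dictionary style (`"anger*"`, `"argue"`, ...). Duplicate entries within an
#' emotion are dropped.
#'
#' @param emotions Named list. Each element is a list with any of
#'   `words`, `prefixes`, `phrases`, `emoticons` (character vectors) and a
#'   required scalar `base_rate` (> 0, percent of tokens).
#' @return An object of class `emovar_lexicon`: a named list of emotion
#'   entries with canonicalized fields.
#' @examples
#' lex <- lexicon(list(
#'   anger = list(words = c("hate", "abhor*"), base_rate = 2),
#'   sadness = list(words = "cry", emoticons = ":(", base_rate = 2.5)
#' ))
#' names(lex)
#' @export
lexicon <- function(emotions) {
  if (!is.list(emotions) || length(emotions) == 0 || is.null(names(emotions)) ||
      any(!nzchar(names(emotions)))) {
    abort("lexicon: 'emotions' must be a nonempty named list")
  }
  if (anyDuplicated(names(emotions))) abort("lexicon: duplicate emotion names")
  known <- c("words", "prefixes", "phrases", "emoticons", "base_rate")
  out <- lapply(names(emotions), function(em) {
    spec <- emotions[[em]]
    bad <- setdiff(names(spec), known)
    if (length(bad)) {
      abort(sprintf("lexicon: unknown field '%s' for emotion '%s'", bad[1], em))
    }
    if (is.null(spec$base_rate)) {
      abort(sprintf("lexicon: missing base_rate for emotion '%s'", em))
    }
    base_rate <- as.numeric(spec$base_rate)
    if (length(base_rate) != 1 || !is.finite(base_rate) || base_rate <= 0) {
      abort(sprintf("lexicon: base_rate for '%s' must be a single value > 0", em))
    }
    words <- tolower(as.character(spec$words %||% character()))
    prefixes <- tolower(as.character(spec$prefixes %||% character()))
    phrases <- tolower(as.character(spec$phrases %||% character()))
    emoticons <- as.character(spec$emoticons %||% character())
    if (any(!nzchar(c(words, prefixes, phrases, emoticons)))) {
      abort(sprintf("lexicon: empty entry string in emotion '%s'", em))
    }
    # dictionary-style wildcard: trailing '*' marks a prefix pattern
    starred <- grepl("\\*$", words)
    prefixes <- c(prefixes, sub("\\*$", "", words[starred]))
    words <- words[!starred]
    prefixes <- sub("\\*$", "", prefixes)
    if (any(grepl("\\s", prefixes))) {
      abort(sprintf("lexicon: prefix pattern with whitespace in '%s'", em))
    }
    # multi-token entries in the word list are really phrases
    phrase_like <- grepl("\\s", words)
    phrases <- c(phrases, words[phrase_like])
    words <- words[!phrase_like]
    if (any(lengths(strsplit(phrases, "\\s+")) < 2)) {
      abort(sprintf("lexicon: phrase with fewer than 2 tokens in '%s'", em))
    }
    list(
      words = unique(words),
      prefixes = unique(prefixes),
      phrases = unique(phrases),
      emoticons = unique(emoticons),
      base_rate = base_rate
    )
  })
  names(out) <- names(emotions)
  structure(out, class = "emovar_lexicon")
}

#' Read an emotion lexicon from a JSON (or YAML) file
#'
#' The file holds `{"emotions": {"<name>": {"words": [...], "prefixes": [...],
#' "phrases": [...], "emoticons": [...], "base_rate": <percent>}, ...}}`.
#' A top-level named mapping without the `emotions` wrapper is also accepted.
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` lexicon file.
#' @return An `emovar_lexicon`.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) abort(sprintf("lexicon file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML lexica requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  emotions <- raw$emotions %||% raw
  lexicon(emotions)
}

#' Write a lexicon to JSON
#'
#' @param lex An `emovar_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "emovar_lexicon"))
  payload <- list(emotions = lapply(unclass(lex), function(e) {
    list(words = I(e$words), prefixes = I(e$prefixes), phrases = I(e$phrases),
         emoticons = I(e$emoticons), base_rate = e$base_rate)
  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Base rates of a lexicon
#'
#' @param lex An `emovar_lexicon`.
#' @return Named numeric vector of per-emotion base rates (percent).
#' @export
base_rates <- function(lex) {
  stopifnot(inherits(lex, "emovar_lexicon"))
  vapply(unclass(lex), `[[`, numeric(1), "base_rate")
}

#' @export
print.emovar_lexicon <- function(x, ...) {
  cat(sprintf("<emovar_lexicon> %d emotions\n", length(x)))
  for (em in names(x)) {
    e <- x[[em]]
    cat(sprintf(
      "  %s: %d words, %d prefixes, %d phrases, %d emoticons, base rate %.3g%%\n",
      em, length(e$words), length(e$prefixes), length(e$phrases),
      length(e$emoticons), e$base_rate))
  }
  invisible(x)
}

#' A compact anger/anxiety/sadness lexicon for examples and testing
#'
#' Covers the vocabulary used in the worked scoring examples (including
#' `piss*`, `hate`, `loathe*`, `fear`, `stressed`, `overwhelmed`, `cry`,
#' `":("`), a small set of further entries in the standard dictionary style,
#' and base rates matched to the synthetic reference corpus generated by
#' [synthesize_study()]. It is an open stand-in for proprietary word-count
#' dictionaries, not a reproduction of any of them.
#'
#' @return An `emovar_lexicon` with emotions anger, anxiety, sadness.
#' @export
example_lexicon <- function() {
  lexicon(list(
    anger = list(
      words = c("abhor*", "acrimon*", "affront*", "aggravat*", "anger*",
                "angr*", "annoy*", "argue", "argued", "arguing", "argument",
                "furious", "fury", "hate", "hated", "hates", "hating",
                "hostil*", "irritat*", "loathe*", "mad", "outrag*", "piss*",
                "rage", "resent*", "temper"),
      phrases = c("bad temper", "bent out of shape"),
      emoticons = c(">:("),
      base_rate = 2.0
    ),
    anxiety = list(
      words = c("afraid", "alarmed", "alarming*", "angst*", "antsy",
                "anxiet*", "anxious*", "apprehens*", "creep*", "daunt*",
                "disquiet*", "distraught*", "distress*", "dread", "eeri*",
                "fear", "feared", "fearful", "fears", "frantic*", "nervous*",
                "overwhelmed", "panic*", "scared", "stress*", "tense",
                "terrif*", "uneasy", "worried", "worry*"),
      emoticons = character(),
      base_rate = 3.0
    ),
    sadness = list(
      words = c("bawl*", "bereav*", "bittersweet*", "cheerless*",
                "crestfallen*", "cried", "cries", "cry", "crying", "deject*",
                "depress*", "despair*", "devastat*", "gloom*", "grief",
                "griev*", "heartbreak*", "hopeless*", "lonel*", "lost",
                "miserab*", "mourn*", "sad", "sadden*", "sadly", "sadness",
                "sob", "sobbed", "sobbing", "sorrow*", "tears", "weep*"),
      phrases = c("broken heart", "bummed out", "clinical depression"),
      emoticons = c(":(", "):", ":'("),
      base_rate = 2.5
    )
  ))
}
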