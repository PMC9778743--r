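# Emoticons recognized even when absent from the lexicon. Matched verbatim,
# before any lowercasing, longest first.
BUILTIN_EMOTICONS <- c(
  ">:(", ":'(", ":-)", ":-(", ";-)", ":)", ":(", "):", "(:", ";)",
  ":D", ":P", "<3"
)

#' Tokenize short texts
#'
#' Deterministic tweet-style tokenization used by the emotion scorer:
#' \enumerate{
#'   \item emoticon tokens are extracted first, verbatim, using the lexicon's
#'     emoticon entries plus a small built-in list (longest match wins);
#'   \item URLs and `@`-mentions are removed as non-lexical material;
#'   \item the leading `#` of hashtags is stripped (`#COVID19` becomes
#'     `covid19`);
#'   \item remaining text is lowercased;
#'   \item tokens are split on any character that is not a letter, digit, or
#'     internal apostrophe (`i'm` stays one token).
#' }
#'
#' @param text Character vector of raw texts.
#' @param lex Optional `emovar_lexicon`; its emoticon entries extend the
#'   built-in emoticon list.
#' @return A list of character vectors, one per input text (empty vector for
#'   texts with no tokens).
#' @examples
#' tokenize("Fear. Fear. Fear. #COVID19")[[1]]
#' tokenize("uhhhhhhhh ohhhhh :( :( :( :( #COVID19")[[1]]
#' @export
tokenize <- function(text, lex = NULL) {
  text <- as.character(text)
  n <- length(text)
  out <- vector("list", n)
  if (n == 0) return(out)
  text[is.na(text)] <- ""

  emoset <- BUILTIN_EMOTICONS
  if (!is.null(lex)) {
    stopifnot(inherits(lex, "emovar_lexicon"))
    emoset <- unique(c(unlist(lapply(unclass(lex), `[[`, "emoticons")), emoset))
  }
  emoset <- emoset[order(-nchar(emoset))]
  pat <- paste0("(", paste(escape_regex(emoset), collapse = "|"), ")")

  has_emo <- grepl(pat, text, perl = TRUE)
  if (any(!has_emo)) out[!has_emo] <- split_words(text[!has_emo])
  if (any(has_emo)) {
    marked <- gsub(pat, "\x01\\1\x01", text[has_emo], perl = TRUE)
    segs <- strsplit(marked, "\x01", fixed = TRUE)
    out[has_emo] <- lapply(segs, function(s) {
      is_emo <- s %in% emoset
      pieces <- vector("list", length(s))
      pieces[is_emo] <- as.list(s[is_emo])
      if (any(!is_emo)) pieces[!is_emo] <- split_words(s[!is_emo])
      unlist(pieces, use.names = FALSE) %||% character()
    })
  }
  out
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.<>=!:/-])", "\\\\\\1", x)

# steps 2-5 of the tokenizer, vectorized over texts. Regex passes touch
# only the strings that contain their trigger character, and edge
# apostrophes are stripped at the string level so no per-document cleanup
# loop is needed afterwards.
split_words <- function(x) {
  sel <- grepl("http", x, fixed = TRUE) | grepl("www.", x, fixed = TRUE) |
    grepl("@", x, fixed = TRUE)
  if (any(sel)) {
    x[sel] <- gsub("(https?://|www\\.)[^ \t\r\n]*|@[A-Za-z0-9_]+", " ",
                   x[sel], perl = TRUE)
  }
  sel <- grepl("#", x, fixed = TRUE)
  if (any(sel)) x[sel] <- gsub("#(?=[A-Za-z0-9])", "", x[sel], perl = TRUE)
  sel <- grepl("’", x, fixed = TRUE)
  if (any(sel)) x[sel] <- gsub("’", "'", x[sel], fixed = TRUE)
  x <- tolower(x)
  # apostrophes are word characters only between letters/digits
  sel <- grepl("'", x, fixed = TRUE)
  if (any(sel)) {
    x[sel] <- gsub("(?<![a-z0-9])'+|'+(?![a-z0-9])", " ", x[sel], perl = TRUE)
  }
  x <- gsub("^[^a-z0-9']+|[^a-z0-9']+$", "", x, perl = TRUE)
  toks <- strsplit(x, "[^a-z0-9']+", perl = TRUE)
  empty <- !nzchar(x)
  if (any(empty)) toks[empty] <- list(character(0))
  toks
}
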