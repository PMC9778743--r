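# internal helpers shared across modules

`%||%` <- rlang::`%||%`

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# coerce a timestamp-ish vector to Date under one named timezone; accepts
# Date, POSIXt, ISO strings and Twitter's created_at format. Only unique
# values are parsed, so million-document inputs with daily timestamps cost
# almost nothing.
as_document_date <- function(x, tz = "UTC") {
  if (inherits(x, "Date")) return(x)
  if (inherits(x, "POSIXt")) return(as.Date(x, tz = tz))
  x <- as.character(x)
  ux <- unique(x)
  out <- rep(as.Date(NA), length(ux))
  plain <- grepl("^\\d{4}-\\d{2}-\\d{2}$", ux)
  out[plain] <- as.Date(ux[plain], format = "%Y-%m-%d")
  rest <- !plain & !is.na(ux)
  if (any(rest)) {
    out[rest] <- suppressWarnings(as.Date(as.POSIXct(ux[rest], tz = tz,
      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                     "%Y-%m-%d")), tz = tz))
    twitter <- rest & is.na(out)
    if (any(twitter)) {
      # e.g. "Wed Jan 22 10:01:00 +0000 2020"
      old <- Sys.getlocale("LC_TIME"); on.exit(Sys.setlocale("LC_TIME", old))
      suppressWarnings(Sys.setlocale("LC_TIME", "C"))
      out[twitter] <- suppressWarnings(as.Date(as.POSIXct(
        ux[twitter], tz = tz, format = "%a %b %d %H:%M:%S %z %Y"), tz = tz))
    }
  }
  if (anyNA(out[!is.na(ux)])) {
    bad <- ux[is.na(out) & !is.na(ux)][1]
    abort(sprintf("unparseable timestamp: '%s'", bad))
  }
  out[match(x, ux)]
}

# deterministic child seeds derived from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
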