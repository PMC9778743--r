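#' Ground-truth specification for synthetic studies
#'
#' Bundles everything the generator needs: the latent weekly VAR (intercept,
#' lag matrices, innovation covariance) over the ordered variables
#' `behavior, anger, anxiety, sadness`, plus corpus parameters. The latent
#' variables live on a common unit-innovation scale, so coupling coefficients
#' read directly as standardized effects. When a study bundle is written, the
#' latent emotion components are multiplied by `emotion_scale` to give
#' percent-deviation index targets (a scaled value of 20 means "daily emotion
#' scores run 20% above the platform base rate"), and the latent behavior
#' component is affinely mapped into `[0, 100]` for the trends file; both
#' maps are recorded in the manifest and are undone by standardization, so
#' they leave the Granger/IRF structure intact.
#'
#' @param var_names Character vector of variable names (behavior first).
#' @param intercept Length-`K` intercept vector.
#' @param A List of `K x K` lag coefficient matrices.
#' @param Sigma `K x K` innovation covariance (positive definite).
#' @param T Number of weekly observations to emit.
#' @param burn_in Pre-sample steps dropped before recording.
#' @param docs_per_day,tokens_per_doc Corpus size parameters.
#' @param emotion_scale Multiplier from latent units to percent-deviation
#'   index targets.
#' @return An object of class `emovar_truth`.
#' @export
var_truth <- function(var_names, intercept, A, Sigma, T = 120L,
                      burn_in = 200L, docs_per_day = 500L,
                      tokens_per_doc = 20L, emotion_scale = 10) {
  K <- length(var_names)
  A <- lapply(A, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == K, ncol(m) == K)
    dimnames(m) <- list(var_names, var_names)
    m
  })
  Sigma <- as.matrix(Sigma)
  dimnames(Sigma) <- list(var_names, var_names)
  stopifnot(length(intercept) == K, nrow(Sigma) == K,
            docs_per_day >= 1, tokens_per_doc >= 1, T >= 1, burn_in >= 0)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("truth Sigma must be positive definite")
  truth <- structure(list(
    var_names = var_names, K = K, p = length(A),
    intercept = setNames(as.numeric(intercept), var_names),
    A = A, Sigma = Sigma,
    T = as.integer(T), burn_in = as.integer(burn_in),
    docs_per_day = as.integer(docs_per_day),
    tokens_per_doc = as.integer(tokens_per_doc),
    emotion_scale = as.numeric(emotion_scale)
  ), class = "emovar_truth")
  sr <- truth_spectral_radius(truth)
  if (sr >= 1) {
    abort(sprintf("truth VAR is unstable (spectral radius %.4f)", sr))
  }
  truth
}

truth_spectral_radius <- function(truth) {
  K <- truth$K
  p <- truth$p
  C <- matrix(0, K * p, K * p)
  C[seq_len(K), ] <- do.call(cbind, truth$A)
  if (p > 1) C[K + seq_len(K * (p - 1)), seq_len(K * (p - 1))] <- diag(K * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' @export
print.emovar_truth <- function(x, ...) {
  cat(sprintf("<emovar_truth> VAR(%d), K = %d (%s), T = %d, %d docs/day x %d tokens\n",
              x$p, x$K, paste(x$var_names, collapse = ", "), x$T,
              x$docs_per_day, x$tokens_per_doc))
  invisible(x)
}

#' Named ground-truth scenarios
#'
#' * `"null"` — no cross couplings: every variable is an independent AR(1).
#'   Used to check test calibration (no Granger causality anywhere).
#' * `"anxiety-driver"` — behavior loads on lagged anxiety with coefficient
#'   0.5; all sadness couplings are zero. Used for power/specificity checks.
#' * `"paper-like"` — a VAR(3) with bidirectional anger/anxiety-behavior
#'   couplings and an uncoupled sadness series, mimicking the qualitative
#'   structure reported for the US COVID-19 tweet study.
#'
#' All presets use unit innovation variances, so coupling coefficients are
#' standardized effects. With the default `emotion_scale = 10` the weekly
#' emotion index targets have a stationary spread of roughly 11-13 points —
#' deviations of this size keep every implied token-match probability
#' comfortably inside `(0, 1)` for the shipped base rates.
#'
#' @param scenario One of `"null"`, `"anxiety-driver"`, `"paper-like"`.
#' @param ... Overrides passed to [var_truth()] (e.g. `T`, `docs_per_day`).
#' @return An `emovar_truth`.
#' @export
var_truth_preset <- function(scenario = c("paper-like", "null",
                                          "anxiety-driver"), ...) {
  scenario <- match.arg(scenario)
  vn <- c("behavior", "anger", "anxiety", "sadness")
  base_diag <- c(0.5, 0.4, 0.45, 0.4)
  if (scenario == "null") {
    A <- list(diag(base_diag))
  } else if (scenario == "anxiety-driver") {
    A1 <- diag(base_diag)
    A1[1, 3] <- 0.5  # anxiety -> behavior
    A <- list(A1)
  } else {
    A1 <- diag(c(0.45, 0.35, 0.40, 0.35))
    A1[1, 3] <- 0.30   # anxiety -> behavior (positive, immediate)
    A1[1, 2] <- -0.08  # anger -> behavior (slightly negative)
    A2 <- diag(c(0.15, 0.10, 0.10, 0.10))
    A2[3, 1] <- -0.15  # behavior -> anxiety (negative, lagged)
    A3 <- diag(c(0.10, 0.05, 0.05, 0.05))
    A3[1, 2] <- -0.10
    A3[3, 1] <- -0.10
    A <- list(A1, A2, A3)
  }
  var_truth(vn, intercept = rep(0, 4), A = A, Sigma = diag(4), ...)
}

#' Simulate the latent weekly VAR path
#'
#' Draws `burn_in + T` steps of
#' \eqn{y_t = c + \sum_j A_j y_{t-j} + \varepsilon_t} with Gaussian
#' innovations of covariance `Sigma`, starting from the stationary mean, and
#' drops the burn-in.
#'
#' @param truth An `emovar_truth`.
#' @param T,burn_in Overrides of the truth's values.
#' @param seed Integer seed (required; the generator consumes no unseeded
#'   entropy).
#' @return Tibble with `week` (0-based) and one column per variable.
#' @export
simulate_var_series <- function(truth, T = truth$T, burn_in = truth$burn_in,
                                seed) {
  stopifnot(inherits(truth, "emovar_truth"))
  if (missing(seed)) abort("simulate_var_series requires a seed")
  K <- truth$K
  p <- truth$p
  n <- burn_in + T
  Asum <- Reduce(`+`, truth$A)
  mu <- solve(diag(K) - Asum, truth$intercept)
  U <- chol(truth$Sigma)
  Y <- withr::with_seed(seed, {
    eps <- matrix(rnorm(n * K), n, K) %*% U
    Y <- matrix(0, n + p, K)
    Y[seq_len(p), ] <- matrix(mu, p, K, byrow = TRUE)
    for (t in (p + 1):(n + p)) {
      acc <- truth$intercept + eps[t - p, ]
      for (j in seq_len(p)) acc <- acc + truth$A[[j]] %*% Y[t - j, ]
      Y[t, ] <- acc
    }
    Y
  })
  out <- Y[p + burn_in + seq_len(T), , drop = FALSE]
  colnames(out) <- truth$var_names
  dplyr::bind_cols(tibble::tibble(week = seq_len(T) - 1L),
                   tibble::as_tibble(out))
}

# a neutral filler vocabulary; entries are screened against the lexicon at
# generation time so filler tokens can never match an emotion
NEUTRAL_VOCAB <- c(
  "the", "and", "today", "people", "news", "update", "city", "home",
  "work", "school", "store", "weather", "morning", "evening", "coffee",
  "music", "game", "road", "water", "garden", "table", "window", "paper",
  "phone", "meeting", "market", "train", "river", "mountain", "summer",
  "winter", "yellow", "green", "quiet", "simple", "number", "letter",
  "orange", "planet", "bridge", "kitchen", "bottle", "picture", "pocket"
)

token_matches_lexicon <- function(tokens, entry) {
  hit <- tokens %in% c(entry$words, entry$emoticons)
  for (pr in entry$prefixes) hit <- hit | startsWith(tokens, pr)
  hit
}

#' Generate a tweet-like corpus whose daily indices follow given targets
#'
#' Inverts the daily-index definition: for target index \eqn{g_{md}} and base
#' rate \eqn{p_{Bm}}, each token of each document on date `d` is an
#' emotion-`m` word with probability
#' \eqn{q_{md} = (p_{Bm}/100)(1 + g_{md}/100)}, else a neutral filler word.
#' Emotion tokens are single literal words drawn from the lexicon (restricted
#' to words that match no other emotion), so per-document scores are exact
#' binomial proportions and the expected daily index equals the target.
#'
#' @param daily_targets Tibble with a `date` column and one target column per
#'   lexicon emotion (percent deviation from base rate).
#' @param lex An `emovar_lexicon`.
#' @param docs_per_day,tokens_per_doc Corpus size per date.
#' @param seed Integer seed.
#' @return Tibble of documents (`id`, `timestamp`, `text`, `lang`,
#'   `country_code`).
#' @export
corpus_from_emotion_series <- function(daily_targets, lex, docs_per_day,
                                       tokens_per_doc, seed) {
  stopifnot(inherits(lex, "emovar_lexicon"), is.data.frame(daily_targets))
  if (missing(seed)) abort("corpus generation requires a seed")
  emotions <- names(lex)
  if (!all(c("date", emotions) %in% names(daily_targets))) {
    abort("daily_targets needs a 'date' column and one column per lexicon emotion")
  }
  pB <- base_rates(lex)
  n_days <- nrow(daily_targets)
  targets <- as.matrix(daily_targets[, emotions, drop = FALSE])
  q <- sweep(1 + targets / 100, 2, pB / 100, `*`)
  if (any(q < 0 | q > 1)) {
    abort("infeasible target: implied token-match probability outside [0, 1]")
  }
  if (any(rowSums(q) > 1)) {
    abort("infeasible target: per-token match probabilities sum above 1")
  }

  # vocabulary: per-emotion words that match only their own emotion,
  # plus fillers that match nothing
  vocab <- lapply(emotions, function(em) {
    w <- lex[[em]]$words
    w <- w[grepl("^[a-z]+$", w)]
    for (other in setdiff(emotions, em)) {
      w <- w[!token_matches_lexicon(w, lex[[other]])]
    }
    # guard against the emotion's own prefixes being claimed by others later
    if (!length(w)) abort(sprintf("no usable generator words for '%s'", em))
    w
  })
  names(vocab) <- emotions
  fillers <- NEUTRAL_VOCAB
  for (em in emotions) {
    fillers <- fillers[!token_matches_lexicon(fillers, lex[[em]])]
  }
  if (!length(fillers)) abort("no neutral filler words survive the lexicon screen")

  tpd <- as.integer(tokens_per_doc)
  dpd <- as.integer(docs_per_day)
  n_docs <- n_days * dpd
  n_tok <- n_docs * tpd

  toks <- withr::with_seed(seed, {
    day_of_token <- rep(seq_len(n_days), each = dpd * tpd)
    u <- runif(n_tok)
    cum <- t(apply(q, 1, cumsum))           # n_days x K thresholds
    cat_idx <- integer(n_tok)               # 0 = filler
    for (m in rev(seq_along(emotions))) {
      upper_m <- cum[day_of_token, m]
      lower_m <- if (m == 1) 0 else cum[day_of_token, m - 1]
      cat_idx[u < upper_m & u >= lower_m] <- m
    }
    toks <- character(n_tok)
    fill <- cat_idx == 0L
    toks[fill] <- fillers[sample.int(length(fillers), sum(fill), replace = TRUE)]
    for (m in seq_along(emotions)) {
      sel <- cat_idx == m
      wm <- vocab[[m]]
      toks[sel] <- wm[sample.int(length(wm), sum(sel), replace = TRUE)]
    }
    toks
  })

  m <- matrix(toks, nrow = tpd)
  text <- do.call(paste, lapply(seq_len(tpd), function(i) m[i, ]))
  tibble::tibble(
    id = sprintf("doc%08d", seq_len(n_docs)),
    timestamp = format(rep(daily_targets$date, each = dpd)),
    text = text,
    lang = "en",
    country_code = "US"
  )
}

#' Interpolate weekly latent values to daily targets
#'
#' Linear interpolation through the center day of each 7-day block, constant
#' beyond the first/last centers. The analysis only consumes weekly means,
#' which interpolation preserves up to small edge effects.
#'
#' @param weekly Tibble with `week` and value columns (e.g. from
#'   [simulate_var_series()]).
#' @param start_date First day of week 0.
#' @param cols Columns to interpolate (default: all but `week`).
#' @return Tibble with `date` and the interpolated columns.
#' @export
daily_targets_from_weekly <- function(weekly, start_date,
                                      cols = setdiff(names(weekly), "week")) {
  start_date <- as.Date(start_date)
  n_weeks <- nrow(weekly)
  days <- seq.int(0L, 7L * n_weeks - 1L)
  centers <- 7 * weekly$week + 3
  out <- tibble::tibble(date = start_date + days)
  for (v in cols) {
    out[[v]] <- approx(centers, weekly[[v]], xout = days, rule = 2)$y
  }
  out
}

#' Generate a complete synthetic study bundle on disk
#'
#' Writes everything the analysis pipeline reads — a JSON-lines document
#' corpus whose expected daily emotion indices follow the latent VAR path, a
#' lexicon JSON, and a weekly Trends-style behavior CSV (the latent behavior
#' component affinely mapped onto `[0, 100]` and rounded to the integer
#' dialect) — plus a manifest recording the ground truth, the affine map,
#' every parameter and per-file MD5 checksums. Byte-identical for identical
#' configuration and seed.
#'
#' @param truth An `emovar_truth` (see [var_truth_preset()]).
#' @param out_dir Output directory (created if needed).
#' @param start_date First day of week 0.
#' @param lex Lexicon used for generation and shipped in the bundle.
#' @param seed Master seed; all randomness derives from it.
#' @param force Overwrite an existing manifest.
#' @return Invisibly, a list with `paths` (documents, lexicon, trends,
#'   manifest), `truth`, `latent` (the weekly latent tibble) and
#'   `behavior_map` (slope/intercept of the latent-to-index map).
#' @export
synthesize_study <- function(truth, out_dir, start_date = "2020-01-21",
                             lex = example_lexicon(), seed, force = FALSE) {
  stopifnot(inherits(truth, "emovar_truth"))
  if (missing(seed)) abort("synthesize_study requires a seed")
  start_date <- as.Date(start_date)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    documents = file.path(out_dir, "documents.jsonl"),
    lexicon = file.path(out_dir, "lexicon.json"),
    trends = file.path(out_dir, "trends.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  if (file.exists(paths$manifest) && !force) {
    abort(sprintf("manifest already exists at %s (use force = TRUE)",
                  paths$manifest))
  }
  seeds <- derive_seeds(seed, 2L)
  latent <- simulate_var_series(truth, seed = seeds[1])
  emotions <- names(lex)
  stopifnot(all(emotions %in% names(latent)))

  scaled <- latent
  for (em in emotions) scaled[[em]] <- truth$emotion_scale * latent[[em]]
  daily <- daily_targets_from_weekly(scaled, start_date, cols = emotions)
  docs <- corpus_from_emotion_series(daily, lex, truth$docs_per_day,
                                     truth$tokens_per_doc, seed = seeds[2])
  write_documents_jsonl(docs, paths$documents)
  write_lexicon(lex, paths$lexicon)

  b <- latent$behavior
  slope <- if (max(b) > min(b)) 99 / (max(b) - min(b)) else 0
  intercept <- 1 - slope * min(b)
  trends_val <- as.integer(round(intercept + slope * b))
  writeLines(c(
    "Category: All categories", "",
    "Week,hand sanitizer: (United States)",
    paste(format(start_date + 7L * latent$week), trends_val, sep = ",")
  ), paths$trends)

  manifest <- list(
    variables = truth$var_names, p = truth$p,
    intercept = truth$intercept,
    A = lapply(truth$A, function(m) unclass(as.data.frame(m))),
    Sigma = unclass(as.data.frame(truth$Sigma)),
    T = truth$T, burn_in = truth$burn_in,
    docs_per_day = truth$docs_per_day,
    tokens_per_doc = truth$tokens_per_doc,
    emotion_scale = truth$emotion_scale,
    base_rates = as.list(base_rates(lex)),
    start_date = format(start_date), seed = seed,
    behavior_map = list(slope = slope, intercept = intercept),
    checksums = as.list(tools::md5sum(unlist(paths[1:3])))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth, latent = latent,
                 behavior_map = c(slope = slope, intercept = intercept)))
}

write_documents_jsonl <- function(docs, path) {
  esc <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))
  lines <- sprintf(
    '{"id":"%s","created_at":"%s","text":"%s","lang":"%s","country_code":"%s"}',
    esc(docs$id), esc(docs$timestamp), esc(docs$text),
    esc(docs$lang), esc(docs$country_code))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
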