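# Independent oracles used to cross-check the implementation. These are
# deliberately naive and share no code with the package internals.

# Brute-force document scorer: enumerates every token position and every
# lexicon entry. Greedy phrase-first semantics, one count max per position
# per emotion.
brute_score <- function(tokens, lex) {
  out <- setNames(numeric(length(lex)), names(lex))
  nt <- length(tokens)
  if (nt == 0) stop("unscorable")
  for (em in names(lex)) {
    entry <- lex[[em]]
    phrases <- lapply(entry$phrases, function(p) strsplit(p, " +")[[1]])
    phrases <- phrases[order(-vapply(phrases, length, 0L))]
    used <- rep(FALSE, nt)
    count <- 0
    pos <- 1
    while (pos <= nt) {
      hit_len <- 0
      for (ph in phrases) {
        L <- length(ph)
        if (pos + L - 1 <= nt && all(tokens[pos:(pos + L - 1)] == ph)) {
          hit_len <- L
          break
        }
      }
      if (hit_len > 0) {
        count <- count + 1
        pos <- pos + hit_len
        next
      }
      tok <- tokens[pos]
      matched <- FALSE
      for (w in entry$words) if (tok == w) matched <- TRUE
      for (e in entry$emoticons) if (tok == e) matched <- TRUE
      for (pr in entry$prefixes) {
        if (nchar(tok) >= nchar(pr) &&
            substr(tok, 1, nchar(pr)) == pr) matched <- TRUE
      }
      if (matched) count <- count + 1
      pos <- pos + 1
    }
    out[em] <- 100 * count / nt
  }
  out
}

# normal-equations OLS, independent of the package's QR route
ols_oracle <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  list(beta = beta, rss = sum(res^2))
}

# brute-force two-regression Granger F test (explicit RSS computation)
granger_oracle <- function(Y, cause, effect, p) {
  K <- ncol(Y)
  T_total <- nrow(Y)
  nms <- colnames(Y)
  rows <- (p + 1):T_total
  y <- Y[rows, effect]
  X_u <- matrix(1, length(rows), 1)
  for (j in 1:p) X_u <- cbind(X_u, Y[rows - j, , drop = FALSE])
  keep <- rep(TRUE, ncol(X_u))
  for (j in 1:p) keep[1 + (j - 1) * K + which(nms == cause)] <- FALSE
  X_r <- X_u[, keep, drop = FALSE]
  rss_u <- ols_oracle(X_u, y)$rss
  rss_r <- ols_oracle(X_r, y)$rss
  df_den <- length(rows) - (K * p + 1)
  F_stat <- ((rss_r - rss_u) / p) / (rss_u / df_den)
  list(F = F_stat, p_value = pf(F_stat, p, df_den, lower.tail = FALSE),
       df_den = df_den)
}

# random token sequences over a vocabulary that mixes lexicon words,
# prefix-extensions, phrase fragments and neutral noise
random_docs <- function(n, lex, seed, max_len = 25) {
  all_words <- unlist(lapply(unclass(lex), function(e) {
    c(e$words, paste0(e$prefixes, "ing"), e$emoticons,
      unlist(strsplit(e$phrases, " ")))
  }), use.names = FALSE)
  vocab <- unique(c(all_words, "zqx", "vbn", "mlk", "wrt", "plq", "neutral"))
  phrases <- unlist(lapply(unclass(lex), `[[`, "phrases"), use.names = FALSE)
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      len <- sample(1:max_len, 1)
      toks <- sample(vocab, len, replace = TRUE)
      # occasionally splice in a full phrase so consumption paths are hit
      if (length(phrases) && runif(1) < 0.3) {
        ph <- strsplit(sample(phrases, 1), " ")[[1]]
        at <- sample(seq_len(len), 1)
        toks <- append(toks, ph, after = at)
      }
      toks
    })
  })
}

# simulate a VAR path directly (independent of simulate_var_series)
sim_var_direct <- function(A_list, Sigma, T, burn = 100, seed,
                           intercept = NULL) {
  K <- nrow(A_list[[1]])
  p <- length(A_list)
  intercept <- intercept %||% rep(0, K)
  withr::with_seed(seed, {
    n <- T + burn
    U <- chol(Sigma)
    eps <- matrix(rnorm(n * K), n, K) %*% U
    Y <- matrix(0, n + p, K)
    for (t in (p + 1):(n + p)) {
      acc <- intercept + eps[t - p, ]
      for (j in 1:p) acc <- acc + A_list[[j]] %*% Y[t - j, ]
      Y[t, ] <- acc
    }
    out <- Y[p + burn + 1:T, , drop = FALSE]
    colnames(out) <- paste0("y", 1:K)
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

table2_tweets <- function() {
  tibble::tibble(
    id = as.character(1:6),
    timestamp = "2020-03-01",
    text = c(
      "COVID-19 is starting to piss me off",
      "Hate, hate, hate, double hate, LOATHE ENTIRELY",
      "Fear. Fear. Fear. #COVID19",
      "I’m stressed and overwhelmed #COVID19",
      "Cry cry cry",
      "uhhhhhhhh ohhhhh :( :( :( :( #COVID19"
    ),
    label = c("anger", "anger", "anxiety", "anxiety", "sadness", "sadness")
  )
}
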