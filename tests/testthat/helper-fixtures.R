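# Shared fixtures and independent oracles, built in code at test time.

# A small deterministic corpus with awkward texts (emoji, newline, quotes).
make_tiny_corpus <- function(n = 5L) {
  texts <- c("plain complaint about my back",
             "line one\nline two with \"quotes\"",
             "emoji \U0001F495 and more \U0001F62D",
             "RT @someone: sooooo much back pain bit.ly/abc",
             "comma, and a backslash \\ here")
  tweet_corpus(id = sprintf("id%03d", seq_len(n)),
               created_at = as.POSIXct("2019-11-01 00:00:00", tz = "UTC") +
                 3600 * seq_len(n),
               text = rep_len(texts, n),
               lang = "en",
               geo_enabled = rep_len(c(FALSE, TRUE), n),
               country = rep_len(c(NA, "US"), n))
}

# Independent Krippendorff alpha oracle: naive double loop over unordered
# coder pairs per unit (pairable-values formulation), written without the
# coincidence matrix used by the implementation under test.
oracle_alpha <- function(m) {
  m <- as.matrix(m)
  n_units <- nrow(m)
  total_pairs_weighted_mismatch <- 0
  total_values <- 0
  all_vals <- c()
  for (u in seq_len(n_units)) {
    row <- m[u, ]
    row <- row[!is.na(row)]
    mu <- length(row)
    if (mu < 2) next
    mism <- 0
    for (i in seq_len(mu - 1)) {
      for (j in seq(i + 1, mu)) {
        if (row[i] != row[j]) mism <- mism + 1
      }
    }
    # each unordered pair counts twice among ordered pairs, weight 1/(mu-1)
    total_pairs_weighted_mismatch <- total_pairs_weighted_mismatch +
      2 * mism / (mu - 1)
    total_values <- total_values + mu
    all_vals <- c(all_vals, row)
  }
  D_o <- total_pairs_weighted_mismatch / total_values
  tab <- table(all_vals)
  n <- sum(tab)
  D_e <- (n^2 - sum(tab^2)) / (n * (n - 1))
  1 - D_o / D_e
}

# Annotation matrix helper: items x annotators character matrix -> tibble.
ann_tibble <- function(m) {
  out <- tibble::tibble(id = sprintf("i%d", seq_len(nrow(m))))
  for (j in seq_len(ncol(m))) out[[paste0("annotator_", j)]] <- m[, j]
  out
}

# A detector with oracle knowledge of the generator's ground-truth lang.
oracle_detector <- function(tweets) {
  lookup <- stats::setNames(tweets$lang, tweets$id)
  ids <- tweets$id
  txt <- if ("norm_text" %in% names(tweets)) tweets$norm_text else tweets$text
  by_text <- stats::setNames(tweets$lang, txt)
  function(text) {
    code <- unname(by_text[text])
    ifelse(is.na(code), "und", ifelse(code == "en", "en", code))
  }
}

small_sim <- function(seed = 1, days = 5, rate = 4, ...) {
  sim_config(seed = seed,
             period_a = c("2019-11-01", format(as.Date("2019-11-01") + days)),
             period_b = c("2020-11-01", format(as.Date("2020-11-01") + days)),
             base_hourly_rate = rate, ...)
}
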