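# Text normalization, language filtering and exact-text deduplication.

RULE_ORDER <- c("IMAGE", "CHAR_COLLAPSE", "RETWEET", "URL", "EMOJI")

#' Built-in emoji dictionary
#'
#' Maps pictographs to colon-delimited lowercase textual names
#' (e.g. "two hearts" becomes `:two_hearts:`). Pictographs outside the
#' dictionary fall back to the generic `:emoji:` token. The dictionary is
#' an argument of [normalize_text()] so the naming dialect can be swapped.
#'
#' @return Named character vector: names are emoji, values textual names.
#' @export
default_emoji_dict <- function() {
  c("\U0001F495" = ":two_hearts:",
    "\U0001F629" = ":weary_face:",
    "\U0001F62D" = ":loudly_crying_face:",
    "\U0001F525" = ":fire:",
    "\U0001F4AF" = ":hundred_points:",
    "\U0001F64F" = ":folded_hands:",
    "\U0001F624" = ":face_with_steam_from_nose:",
    "\U0001F915" = ":face_with_head_bandage:",
    "❤" = ":red_heart:",
    "\U0001F602" = ":face_with_tears_of_joy:")
}

.emoji_block_regex <- paste0(
  "[\\x{1F000}-\\x{1FAFF}\\x{2600}-\\x{27BF}\\x{2B00}-\\x{2BFF}",
  "\\x{FE00}-\\x{FE0F}\\x{200D}\\x{2190}-\\x{21FF}\\x{2700}-\\x{27BF}]+")

#' Normalize a tweet text
#'
#' Applies the five surface-normalization rules in fixed order:
#' image links (tokens containing `pic.twitter.com`) become `_IMAGE`;
#' runs of three or more identical characters collapse to two; a leading
#' retweet marker (`RT @handle:`) becomes `_RETWEET`; remaining link
#' tokens (starting with `http`/`https` or containing `bit.ly`,
#' `youtu.be`, `facebook.com`, `instagram.com`) become `_URL`; emoji are
#' replaced by textual names. The function is idempotent.
#'
#' @param text Character vector of nonempty texts.
#' @param emoji_dict Named character vector mapping emoji to textual names
#'   (see [default_emoji_dict()]).
#' @return A tibble with columns `norm_text`, `applied_rules` (list column
#'   of rule tags in rule order), and `artifact_only` (TRUE when the text
#'   consisted solely of removed/replaced artifacts).
#' @export
normalize_text <- function(text, emoji_dict = default_emoji_dict()) {
  if (length(text) && (anyNA(text) || any(!nzchar(text)))) {
    stop("text must be nonempty", call. = FALSE)
  }
  applied <- matrix(FALSE, length(text), 5L,
                    dimnames = list(NULL, RULE_ORDER))
  x <- text

  # 1. image links
  y <- stringi::stri_replace_all_regex(x, "\\S*pic\\.twitter\\.com\\S*", "_IMAGE")
  applied[, "IMAGE"] <- y != x
  x <- y
  # 2. character-run collapse (>= 3 identical chars -> exactly 2)
  y <- stringi::stri_replace_all_regex(x, "(.)\\1{2,}", "$1$1")
  applied[, "CHAR_COLLAPSE"] <- y != x
  x <- y
  # 3. retweet marker; the quoted text itself is kept
  y <- stringi::stri_replace_all_regex(x, "^RT @\\w+:\\s*", "_RETWEET ")
  applied[, "RETWEET"] <- y != x
  x <- y
  # 4. generic links (after the image rule so image links are not double-hit)
  url_re <- paste0("(?:\\bhttps?://\\S*|\\S*(?:bit\\.ly|youtu\\.be|",
                   "facebook\\.com|instagram\\.com)\\S*)")
  y <- stringi::stri_replace_all_regex(x, url_re, "_URL")
  applied[, "URL"] <- y != x
  x <- y
  # 5. emoji -> textual names; undictionaried pictographs -> :emoji:
  has_emoji <- stringi::stri_detect_regex(x, .emoji_block_regex)
  if (length(emoji_dict)) {
    has_emoji <- has_emoji |
      stringi::stri_detect_regex(x, paste0("[",
        paste(names(emoji_dict), collapse = ""), "]"))
    y <- stringi::stri_replace_all_fixed(
      x, names(emoji_dict), paste0(" ", unname(emoji_dict), " "),
      vectorize_all = FALSE)
  } else y <- x
  y <- stringi::stri_replace_all_regex(y, .emoji_block_regex, " :emoji: ")
  y <- trimws(stringi::stri_replace_all_regex(y, "\\s+", " "))
  applied[, "EMOJI"] <- has_emoji
  x <- y

  only_tokens <- stringi::stri_detect_regex(
    x, "^(?:(?:_IMAGE|_RETWEET|_URL|:[a-z0-9_]+:)\\s*)*$")
  tibble::tibble(
    norm_text = x,
    applied_rules = lapply(seq_along(x), function(i) RULE_ORDER[applied[i, ]]),
    artifact_only = only_tokens | !nzchar(x)
  )
}

#' Normalize every tweet in a corpus
#'
#' Vectorized wrapper around [normalize_text()] that returns the corpus
#' with `norm_text`, `applied_rules` and `artifact_only` columns added.
#'
#' @param tweets Corpus tibble.
#' @param emoji_dict Emoji dictionary, see [normalize_text()].
#' @return The corpus tibble with normalization columns appended.
#' @export
normalize_corpus <- function(tweets, emoji_dict = default_emoji_dict()) {
  norm <- normalize_text(tweets$text, emoji_dict)
  tweets$norm_text <- norm$norm_text
  tweets$applied_rules <- norm$applied_rules
  tweets$artifact_only <- norm$artifact_only
  tweets
}

#' Built-in word-list language detector
#'
#' A deliberately small heuristic with two word lists: common English
#' function/domain words and common non-English function words. A text is
#' called English when its English hits strictly outnumber its non-English
#' hits (and at least one English word is present). Placeholder tokens
#' (`_URL`, `_IMAGE`, ...) and emoji names carry no language signal and
#' are ignored; texts with no usable word tokens are reported as `"und"`
#' (undetermined).
#'
#' @return A detector function mapping a character vector to language
#'   codes (`"en"`, `"other"`, or `"und"`).
#' @export
builtin_language_detector <- function() {
  english <- c("my", "the", "is", "i", "im", "me", "so", "and", "a", "to",
               "of", "on", "for", "this", "that", "with", "you", "your",
               "our", "in", "it", "after", "from", "all", "again", "was",
               "has", "have", "back", "pain", "are", "can", "cant", "no",
               "not", "new", "help", "day", "need", "how", "why", "what",
               "up", "out", "since", "too", "now", "may", "just", "be",
               "do", "does", "am", "without", "only", "more", "time", "by",
               "at", "or", "but", "if", "we", "us", "they", "them", "their",
               "there", "here", "when", "who", "will", "would", "should",
               "could", "get", "got", "one", "two", "like", "even", "week",
               "today", "still", "over", "under", "than", "then", "very",
               "much", "many", "most", "some", "any", "every")
  foreign <- c("der", "die", "das", "und", "ist", "mein", "dein", "schon",
               "wieder", "heute", "tut", "weh", "schmerzen", "ruecken",
               "nicht", "sehr", "starke", "unteren", "furchtbar", "el",
               "la", "los", "las", "un", "una", "que", "de", "dolor",
               "espalda", "mucho", "muy", "hoy", "tengo", "otra", "vez",
               "tan", "esta", "semana", "le", "les", "du", "au", "dos",
               "mal", "depuis", "ce", "cette", "mon", "ma", "fait",
               "j'ai", "tellement", "semaine", "matin", "souffrir",
               "vraiment", "minhas", "costas", "estao", "doendo", "muito",
               "hoje", "mi", "fa", "malissimo", "schiena", "stamattina",
               "znowu", "strasznie", "bola", "mnie", "plecy", "od", "rana",
               "caly", "tydzien", "przy", "biurku")
  function(text) {
    # placeholder and emoji-name tokens carry no language signal
    stripped <- stringi::stri_replace_all_regex(
      text, "_[A-Z]+|:[a-z0-9_]+:", " ")
    toks <- stringi::stri_extract_all_regex(tolower(stripped), "[a-z']+")
    vapply(toks, function(tk) {
      tk <- tk[!is.na(tk)]
      if (length(tk) == 0L) return("und")
      en <- sum(tk %in% english)
      fo <- sum(tk %in% foreign)
      if (en >= 1L && en > fo) "en" else "other"
    }, character(1))
  }
}

#' Keep only English tweets
#'
#' Applies a language detector to the normalized (or raw) text and retains
#' tweets detected as English. Tweets on which detection fails or is
#' undetermined are conservatively removed; the removed subset is attached
#' as the `"excluded"` attribute for inspection.
#'
#' @param tweets Corpus tibble (uses `norm_text` if present, else `text`).
#' @param detector A function: character vector -> language codes; `"en"`
#'   is retained. Defaults to [builtin_language_detector()].
#' @return The English-only subset, with attribute `"excluded"`.
#' @export
filter_language <- function(tweets, detector = builtin_language_detector()) {
  txt <- if ("norm_text" %in% names(tweets)) tweets$norm_text else tweets$text
  code <- tryCatch(detector(txt), error = function(e) rep(NA_character_, length(txt)))
  if (length(code) != nrow(tweets)) code <- rep(NA_character_, nrow(tweets))
  keep <- !is.na(code) & code == "en"
  tweets$detected_lang <- code
  out <- tweets[keep, , drop = FALSE]
  excluded <- tweets[!keep, , drop = FALSE]
  if (nrow(excluded)) {
    message(sprintf("filter_language: removed %d non-English/undetectable tweet(s)",
                    nrow(excluded)))
  }
  attr(out, "excluded") <- excluded
  out
}

#' Drop tweets with duplicated texts
#'
#' Retains exactly one tweet per distinct raw text: the earliest by
#' `created_at`, ties broken by lexicographically smallest id.
#' Deduplication operates on the raw text, before normalization.
#'
#' @param tweets Corpus tibble.
#' @return A list with `tweets` (the deduplicated subset, original order
#'   preserved) and `report` (a `dedup_report`: `n_before`, `n_after`,
#'   `retained_fraction`).
#' @export
deduplicate <- function(tweets) {
  n_before <- nrow(tweets)
  if (n_before == 0L) {
    rep0 <- structure(list(n_before = 0L, n_after = 0L, retained_fraction = NA_real_),
                      class = "dedup_report")
    return(list(tweets = tweets, report = rep0))
  }
  ord <- order(tweets$created_at, tweets$id)
  first <- !duplicated(tweets$text[ord])
  keep_idx <- sort(ord[first])
  out <- tweets[keep_idx, , drop = FALSE]
  report <- structure(list(n_before = n_before, n_after = nrow(out),
                           retained_fraction = nrow(out) / n_before),
                      class = "dedup_report")
  list(tweets = out, report = report)
}

#' @export
print.dedup_report <- function(x, ...) {
  cat(sprintf("Deduplication: %d -> %d tweets (%.2f%% retained)\n",
              x$n_before, x$n_after, 100 * x$retained_fraction))
  invisible(x)
}
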