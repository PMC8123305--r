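# Corpus and label input/output.
#
# A tweet corpus is held as a tibble with one row per tweet and columns
# id (character, unique), created_at (POSIXct, UTC), text (character),
# lang (character or NA), geo_enabled (logical), country (character or NA).
# On disk the corpus is JSON lines: one JSON object per line, UTF-8,
# ISO-8601 timestamps. Unknown extra fields survive a round trip but are
# ignored by every pipeline stage.

TWEET_FIELDS <- c("id", "created_at", "text", "lang", "geo_enabled", "country")
LABEL_LEVELS <- c("complaint", "other")

#' Construct a tweet corpus tibble
#'
#' Validates and assembles the in-memory corpus representation used by every
#' pipeline stage: one row per tweet, timestamps resolved to UTC.
#'
#' @param id Character vector of unique, nonempty tweet identifiers.
#' @param created_at Timestamps (POSIXct, or ISO-8601 strings; resolved to
#'   UTC, with offset-free strings assumed UTC).
#' @param text Character vector of tweet texts (each nonempty).
#' @param lang Optional BCP-47-style language codes (NA when unknown).
#' @param geo_enabled Logical: did the author opt into localization?
#' @param country Optional ISO-3166 alpha-2 country codes.
#' @return A tibble with the six corpus columns.
#' @export
tweet_corpus <- function(id, created_at, text, lang = NA_character_,
                         geo_enabled = FALSE, country = NA_character_) {
  id <- as.character(id)
  if (length(id) == 0L) {
    return(tibble::tibble(id = character(), created_at = as.POSIXct(character(), tz = "UTC"),
                          text = character(), lang = character(),
                          geo_enabled = logical(), country = character()))
  }
  if (anyNA(id) || any(!nzchar(id))) stop("tweet ids must be nonempty", call. = FALSE)
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate tweet id: ", dup[[1L]], call. = FALSE)
  if (!inherits(created_at, "POSIXct")) created_at <- parse_utc(created_at)
  attr(created_at, "tzone") <- "UTC"
  if (anyNA(created_at)) stop("unparseable created_at timestamp", call. = FALSE)
  text <- as.character(text)
  if (anyNA(text) || any(!nzchar(text))) stop("tweet text must be nonempty", call. = FALSE)
  tibble::tibble(
    id = id, created_at = created_at, text = text,
    lang = rep_len(as.character(lang), length(id)),
    geo_enabled = rep_len(as.logical(geo_enabled), length(id)),
    country = rep_len(as.character(country), length(id))
  )
}

#' Read a JSON-lines tweet corpus
#'
#' One JSON object per line with fields `id`, `created_at`, `text` and
#' optional `lang`, `geo_enabled`, `country`. Records are returned in file
#' order; timestamps are normalized to UTC (records without an explicit
#' offset are assumed UTC). Extra fields are kept as extra columns.
#'
#' @param path Path to a JSON-lines file.
#' @return A corpus tibble (see [tweet_corpus()]).
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such corpus file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) return(tweet_corpus(character(), character(), character()))
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || !is.list(rec)) {
      stop(sprintf("malformed corpus record on line %d", line_no[[i]]), call. = FALSE)
    }
    for (f in c("id", "created_at", "text")) {
      if (is.null(rec[[f]]) || is.na(rec[[f]]) || !nzchar(as.character(rec[[f]]))) {
        stop(sprintf("line %d: missing or empty field '%s'", line_no[[i]], f),
             call. = FALSE)
      }
    }
    recs[[i]] <- rec
  }
  ids <- vapply(recs, function(r) as.character(r$id), character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate tweet id: ", dup[[1L]], call. = FALSE)
  ts <- parse_utc(vapply(recs, function(r) as.character(r$created_at), character(1)))
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop(sprintf("line %d: unparseable created_at", line_no[[bad[[1L]]]]), call. = FALSE)
  }
  opt_chr <- function(r, f) {
    v <- r[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) NA_character_ else as.character(v)
  }
  out <- tweet_corpus(
    id = ids, created_at = ts,
    text = vapply(recs, function(r) as.character(r$text), character(1)),
    lang = vapply(recs, opt_chr, character(1), f = "lang"),
    geo_enabled = vapply(recs, function(r) isTRUE(as.logical(r$geo_enabled %||% FALSE)),
                         logical(1)),
    country = vapply(recs, opt_chr, character(1), f = "country")
  )
  extra <- setdiff(unique(unlist(lapply(recs, names))), TWEET_FIELDS)
  for (f in extra) {
    out[[f]] <- vapply(recs, opt_chr, character(1), f = f)
  }
  out
}

#' Write a tweet corpus as JSON lines
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p))` reproduces
#' `x` field for field, including emoji and embedded newlines in texts.
#'
#' @param tweets A corpus tibble.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(tweets, path) {
  stopifnot(is.data.frame(tweets))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot write corpus to ", path, call. = FALSE)
  })
  on.exit(close(con))
  n <- nrow(tweets)
  if (n > 0L) {
    df <- as.data.frame(tweets)
    df$created_at <- format_utc(df$created_at)
    lines <- vapply(seq_len(n), function(i) {
      rec <- as.list(df[i, , drop = FALSE])
      rec <- rec[!vapply(rec, function(v) length(v) == 1L && is.na(v), logical(1))]
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a CSV label file
#'
#' Two layouts are accepted: adjudicated labels (`id,label`) or a raw
#' annotation matrix (`id,annotator_1,...,annotator_k`). Every label must be
#' `"complaint"` or `"other"`; anything else is rejected with the offending
#' row and value named.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with an `id` column plus either `label` or the
#'   annotator columns.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such label file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"id" %in% names(df)) stop("label file must have an 'id' column", call. = FALSE)
  lab_cols <- setdiff(names(df), "id")
  if (length(lab_cols) == 0L) stop("label file has no label columns", call. = FALSE)
  for (col in lab_cols) {
    bad <- which(!df[[col]] %in% LABEL_LEVELS)
    if (length(bad)) {
      stop(sprintf("row %d: unknown label '%s' in column '%s'",
                   bad[[1L]], df[[col]][[bad[[1L]]]], col), call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Write labels as CSV
#'
#' @param labels A tibble with `id` plus label column(s).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
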