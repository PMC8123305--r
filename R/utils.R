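# Internal helpers shared across modules.

#' @importFrom stats predict rbinom rpois runif sd
#' @importFrom utils read.csv write.csv
NULL

# Deterministic 24-bit polynomial string hash (bucket index in 1..mod).
# Doubles stay exact: h < 2^24, h*31 + byte < 2^29 before the modulus.
hash_string <- function(x, mod) {
  vapply(x, function(s) {
    bytes <- utf8ToInt(s)
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% 16777216
    as.integer(h %% mod) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# Parse ISO-8601 timestamps to POSIXct UTC. Accepts a trailing "Z",
# "+00:00"-style offsets, or no offset (assumed UTC by convention).
parse_utc <- function(x) {
  x <- as.character(x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(out)
  s <- x[ok]
  s <- sub("Z$", "+0000", s)
  s <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", s)
  has_off <- grepl("[+-]\\d{4}$", s)
  s[!has_off] <- paste0(s[!has_off], "+0000")
  s <- sub("T", " ", s, fixed = TRUE)
  parsed <- as.POSIXct(s, tz = "UTC", format = "%Y-%m-%d %H:%M:%S%z")
  no_time <- is.na(parsed) & grepl("^\\d{4}-\\d{2}-\\d{2}[+-]\\d{4}$", s)
  if (any(no_time)) {
    parsed[no_time] <- as.POSIXct(sub("([+-]\\d{4})$", " 00:00:00\\1", s[no_time]),
                                  tz = "UTC", format = "%Y-%m-%d %H:%M:%S%z")
  }
  attr(parsed, "tzone") <- "UTC"
  out[ok] <- parsed
  out
}

format_utc <- function(x) {
  format(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
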