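# Synthetic two-period tweet stream simulator.
#
# Emulates the statistical structure the analysis assumes: per-hour Poisson
# arrivals with a multiplicative period-B intensity factor, a fixed
# complaint/other mix, exact-text duplicates, a sprinkle of non-English
# texts, surface artifacts (emoji, URLs, image links, retweet prefixes,
# stretched characters), and a small localized (geo-opt-in) subpopulation
# whose period effect can be biased away from the global one.
#
# Texts come from slot-filled template grammars, not language models: the
# classifier contract only needs separable-but-noisy lexical signal, and
# templates keep everything desk-scale and seed-deterministic. Slot counts
# are chosen so the grammars span ~2 million distinct sentences, keeping
# accidental (non-injected) text collisions rare at the corpus sizes used.

.complaint_slots <- list(
  opener = c("my", "ugh my", "honestly my", "woke up and my", "cant sleep my",
             "this wfh life my", "day three and my", "ok so my",
             "not gonna lie my", "swear my", "help my", "yall my"),
  severity = c("killing me", "unbearable", "acting up again", "so bad",
               "driving me crazy", "the worst", "flaring up",
               "back with a vengeance", "off the charts", "ruining my day",
               "really bad today", "no joke"),
  timing = c("after sitting all day", "since this morning",
             "from this desk chair", "after that workout", "all week",
             "since monday", "from sleeping wrong", "after the long drive",
             "from standing all shift", "out of nowhere"),
  coping = c("need a heating pad", "cant even bend over",
             "sent me to the chiropractor", "and nothing helps",
             "might call the doctor", "stretching does nothing",
             "ice isnt helping", "cant focus on work", "had to lie down",
             "someone send help"),
  aside = c("", "and my neck too", "plus a headache", "cant get comfy",
            "my posture is awful", "this chair is trash", "need a massage",
            "wish i could stretch", "muscles are so tight",
            "need a new mattress", "sitting is the enemy", "my spine hates me"),
  closer = c("", "ouch", "smh", "im done", "pray for me", "fr", "this sucks",
             "lol not funny", "seriously", "again", "why me", "ugh"),
  place = c("", "at work", "at home", "in bed", "on the couch", "at my desk",
            "in the car", "at the gym", "on shift", "in this meeting",
            "on the bus", "upstairs")
)

.other_slots <- list(
  lead = c("new study shows", "our clinic offers", "discover how",
           "top five ways", "learn why", "this product", "experts reveal",
           "special offer", "free webinar on how", "research update",
           "ask your doctor how", "breaking news"),
  treatment = c("yoga", "physical therapy", "our memory foam mattress",
                "this posture corrector", "acupuncture",
                "spinal decompression", "core strengthening",
                "ergonomic chairs", "massage therapy", "inversion tables",
                "daily stretching routines", "laser therapy"),
  verb = c("relieves", "can reduce", "may help with", "eliminates", "targets",
           "is proven to ease", "soothes", "fixes", "treats", "helps manage"),
  tail = c("in just two weeks", "for office workers", "without surgery",
           "naturally", "according to experts", "for seniors", "guaranteed",
           "book now", "click to learn more", "limited time only"),
  extra = c("", "visit our website", "dm us for details",
            "consult a professional", "results may vary",
            "randomized trial results inside", "patients report relief",
            "flat rate shipping", "certified practitioners",
            "new location open", "insurance accepted", "five star rated"),
  cta = c("", "follow us", "tag a friend", "share this post", "link in bio",
          "call today", "stop by", "act fast", "read more", "sign up now",
          "get started", "dont wait"),
  audience = c("", "for athletes", "for new moms", "for gamers",
               "for drivers", "for nurses", "for teachers",
               "for remote workers", "for students", "for travelers",
               "for runners", "for desk workers")
)

# Small fixed multilingual pool so a word-list language detector can be
# exercised without any external detection package.
.nonenglish_pool <- data.frame(
  lang = c("es", "es", "de", "de", "fr", "fr", "pt", "it", "pl", "pl"),
  text = c("hoy tengo mucho dolor de espalda otra vez",
           "que dolor de espalda tan horrible esta semana",
           "mein ruecken tut heute wieder furchtbar weh",
           "schon wieder starke schmerzen im unteren ruecken",
           "j'ai tellement mal au dos depuis ce matin",
           "mon dos fait vraiment souffrir cette semaine",
           "minhas costas estao doendo muito hoje",
           "stamattina mi fa malissimo la schiena",
           "znowu strasznie bola mnie plecy od rana",
           "caly tydzien bola mnie plecy przy biurku"),
  stringsAsFactors = FALSE
)

.emoji_pool <- c("\U0001F495", "\U0001F629", "\U0001F62D", "\U0001F525",
                 "\U0001F4AF", "\U0001F64F", "\U0001F624", "\U0001F915")

.stretch_pool <- c("owwwwww", "ughhhhh", "noooooo", "aghhhhh", "helppppp")

sample_slots <- function(slots, n) {
  parts <- lapply(slots, function(v) v[sample.int(length(v), n, replace = TRUE)])
  out <- do.call(paste, parts)
  stringi::stri_replace_all_regex(trimws(out), "\\s+", " ")
}

#' Simulation configuration for the two-period tweet stream
#'
#' The defaults are the package's reference study conditions: two 30-day
#' periods a year apart, 20 expected tweets per hour in the reference
#' period, a period-B intensity multiplier of 1.84, a 59.5% complaint mix,
#' a 46% exact-duplicate rate and a 1.5% localization opt-in.
#'
#' @param seed Integer seed; identical seed and config give an identical
#'   corpus.
#' @param period_a,period_b Length-2 character/Date vectors `c(start, end)`,
#'   start inclusive, end exclusive (UTC midnights).
#' @param base_hourly_rate Expected tweets per hour in period A (lambda > 0).
#' @param period_ratio Multiplicative intensity factor for period B (r > 0).
#' @param complaint_prob Probability a generated tweet is a true complaint.
#' @param duplicate_rate Probability a tweet is an exact-text copy of a
#'   uniformly chosen earlier tweet in the same period (fresh id/timestamp).
#' @param nonenglish_rate Probability a tweet is drawn from the fixed
#'   non-English pool.
#' @param artifact_rates Named list of injection probabilities for
#'   `emoji`, `url`, `image`, `retweet`, `charrep`.
#' @param localized_optin Probability a tweet carries localization
#'   (geo_enabled, country "US").
#' @param localized_bias Multiplier applied to the localized subpopulation's
#'   period ratio only (1 = unbiased subsample).
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(seed = 1L,
                       period_a = c("2019-11-01", "2019-12-01"),
                       period_b = c("2020-11-01", "2020-12-01"),
                       base_hourly_rate = 20,
                       period_ratio = 1.84,
                       complaint_prob = 0.595,
                       duplicate_rate = 0.46,
                       nonenglish_rate = 0.02,
                       artifact_rates = list(emoji = 0.15, url = 0.10,
                                             image = 0.05, retweet = 0.10,
                                             charrep = 0.05),
                       localized_optin = 0.015,
                       localized_bias = 1) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (base_hourly_rate <= 0) stop("base_hourly_rate must be > 0", call. = FALSE)
  if (period_ratio <= 0) stop("period_ratio must be > 0", call. = FALSE)
  if (localized_bias <= 0) stop("localized_bias must be > 0", call. = FALSE)
  assert_prob(complaint_prob, "complaint_prob")
  assert_prob(duplicate_rate, "duplicate_rate")
  assert_prob(nonenglish_rate, "nonenglish_rate")
  assert_prob(localized_optin, "localized_optin")
  for (nm in c("emoji", "url", "image", "retweet", "charrep")) {
    assert_prob(artifact_rates[[nm]] %||% 0, paste0("artifact_rates$", nm))
  }
  as_period <- function(p, name) {
    p <- as.Date(p)
    if (length(p) != 2L || anyNA(p) || p[[2L]] <= p[[1L]]) {
      stop(sprintf("`%s` must be a nonempty c(start, end) date range", name),
           call. = FALSE)
    }
    p
  }
  structure(list(seed = as.integer(seed),
                 period_a = as_period(period_a, "period_a"),
                 period_b = as_period(period_b, "period_b"),
                 base_hourly_rate = base_hourly_rate,
                 period_ratio = period_ratio,
                 complaint_prob = complaint_prob,
                 duplicate_rate = duplicate_rate,
                 nonenglish_rate = nonenglish_rate,
                 artifact_rates = artifact_rates,
                 localized_optin = localized_optin,
                 localized_bias = localized_bias),
            class = "sim_config")
}

# One period's stream: hourly Poisson arrivals for the non-localized and
# localized subpopulations, template texts, artifacts, then duplicates
# (which copy the final text and the true label of an earlier tweet).
simulate_period <- function(config, period, rate_non, rate_loc, tag, id_offset) {
  hours <- seq(as.POSIXct(paste(period[[1L]], "00:00:00"), tz = "UTC"),
               as.POSIXct(paste(period[[2L]], "00:00:00"), tz = "UTC") - 3600,
               by = 3600)
  n_non <- rpois(length(hours), rate_non)
  n_loc <- rpois(length(hours), rate_loc)
  hour_of <- c(rep(hours, n_non), rep(hours, n_loc))
  localized <- rep(c(FALSE, TRUE), c(sum(n_non), sum(n_loc)))
  n <- length(hour_of)
  if (n == 0L) {
    return(list(tweets = tweet_corpus(character(), character(), character()),
                truth = tibble::tibble(id = character(), label = character())))
  }
  ts <- hour_of + runif(n, 0, 3600)
  ord <- order(ts)
  ts <- ts[ord]
  localized <- localized[ord]

  # Both grammars carry the fixed "back pain" anchor (the search phrase).
  is_complaint <- runif(n) < config$complaint_prob
  text <- character(n)
  text[is_complaint] <- sample_slots(
    c(.complaint_slots["opener"], list(anchor = "back pain is"),
      .complaint_slots[c("severity", "timing", "place", "coping", "aside",
                         "closer")]),
    sum(is_complaint))
  text[!is_complaint] <- sample_slots(
    c(.other_slots[c("lead", "treatment", "verb")],
      list(anchor = "back pain"),
      .other_slots[c("tail", "audience", "extra", "cta")]),
    sum(!is_complaint))
  lang <- rep("en", n)
  is_foreign <- runif(n) < config$nonenglish_rate
  if (any(is_foreign)) {
    pick <- sample.int(nrow(.nonenglish_pool), sum(is_foreign), replace = TRUE)
    text[is_foreign] <- .nonenglish_pool$text[pick]
    lang[is_foreign] <- .nonenglish_pool$lang[pick]
  }

  ar <- config$artifact_rates
  add <- function(p) runif(n) < (p %||% 0)
  w_stretch <- add(ar$charrep) & !is_foreign
  if (any(w_stretch)) {
    text[w_stretch] <- paste(text[w_stretch],
                             sample(.stretch_pool, sum(w_stretch), TRUE))
  }
  w_emoji <- add(ar$emoji)
  if (any(w_emoji)) {
    text[w_emoji] <- paste(text[w_emoji], sample(.emoji_pool, sum(w_emoji), TRUE))
  }
  w_url <- add(ar$url)
  if (any(w_url)) {
    text[w_url] <- paste(text[w_url],
                         paste0(sample(c("https://example.com/", "bit.ly/",
                                         "youtu.be/", "http://tiny.one/"),
                                       sum(w_url), TRUE),
                                format(sample.int(1e6, sum(w_url), TRUE))))
  }
  w_img <- add(ar$image)
  if (any(w_img)) {
    text[w_img] <- paste(text[w_img],
                         paste0("pic.twitter.com/",
                                format(sample.int(1e6, sum(w_img), TRUE))))
  }
  w_rt <- add(ar$retweet)
  if (any(w_rt)) {
    text[w_rt] <- paste0("RT @user", sample.int(9999, sum(w_rt), TRUE), ": ",
                         text[w_rt])
  }

  label <- ifelse(is_complaint, "complaint", "other")
  is_dup <- runif(n) < config$duplicate_rate
  is_dup[1L] <- FALSE
  for (j in which(is_dup)) {
    src <- sample.int(j - 1L, 1L)
    text[[j]] <- text[[src]]
    label[[j]] <- label[[src]]
    lang[[j]] <- lang[[src]]
  }

  id <- sprintf("%s%07d", tag, id_offset + seq_len(n))
  tw <- tweet_corpus(id = id, created_at = ts, text = text, lang = lang,
                     geo_enabled = localized,
                     country = ifelse(localized, "US", NA_character_))
  list(tweets = tw, truth = tibble::tibble(id = id, label = label))
}

#' Generate a synthetic two-period tweet corpus with ground-truth labels
#'
#' Per-hour tweet counts are Poisson(lambda) in period A and
#' Poisson(r * lambda) in period B; the localized subpopulation (opt-in
#' probability `localized_optin`) instead uses `r * localized_bias` in
#' period B, so a biased geo subsample can be emulated. Complaint and
#' "other" texts come from distinct template grammars (first-person pain
#' phrasing versus advertisement/professional/scam phrasing); duplicates
#' copy the full final text (and true label) of an earlier tweet in the
#' same period under a fresh id and timestamp.
#'
#' @param config A [sim_config()] object.
#' @return A list with `tweets` (corpus tibble, chronological within each
#'   period) and `truth` (tibble `id`, `label` with the true class).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    lam <- config$base_hourly_rate
    p <- config$localized_optin
    r <- config$period_ratio
    a <- simulate_period(config, config$period_a,
                         rate_non = lam * (1 - p), rate_loc = lam * p,
                         tag = "a", id_offset = 0L)
    b <- simulate_period(config, config$period_b,
                         rate_non = lam * (1 - p) * r,
                         rate_loc = lam * p * r * config$localized_bias,
                         tag = "b", id_offset = 0L)
  })
  list(tweets = rbind(a$tweets, b$tweets), truth = rbind(a$truth, b$truth))
}

#' Annotator noise model
#'
#' Each annotator reports the true binary label flipped independently with
#' their own probability. Flip probabilities must stay below 0.5 or
#' majority adjudication loses its guarantees.
#'
#' @param n_annotators Number of annotators (default 3; 1 is allowed as a
#'   degenerate case but agreement statistics then do not apply).
#' @param flip_prob Scalar or per-annotator vector of flip probabilities
#'   in `[0, 0.5)`.
#' @return An `annotator_model` object.
#' @export
annotator_model <- function(n_annotators = 3L, flip_prob = 0.05) {
  n_annotators <- as.integer(n_annotators)
  if (n_annotators < 1L) stop("need at least one annotator", call. = FALSE)
  flip_prob <- rep_len(flip_prob, n_annotators)
  if (any(flip_prob < 0 | flip_prob >= 0.5)) {
    stop("flip_prob must lie in [0, 0.5): at 0.5 or above majority adjudication is void",
         call. = FALSE)
  }
  structure(list(n_annotators = n_annotators, flip_prob = flip_prob),
            class = "annotator_model")
}

#' Simulate noisy annotations of true labels
#'
#' @param truth Tibble with columns `id` and `label` (the true classes).
#' @param model An [annotator_model()].
#' @param seed Integer seed.
#' @return An annotation matrix tibble: `id`, `annotator_1`, ...,
#'   `annotator_k`.
#' @export
generate_annotations <- function(truth, model, seed = 1L) {
  stopifnot(inherits(model, "annotator_model"))
  if (nrow(truth) == 0L) stop("truth labels must be nonempty", call. = FALSE)
  other_of <- ifelse(truth$label == "complaint", "other", "complaint")
  out <- tibble::tibble(id = truth$id)
  withr::with_seed(seed, {
    for (j in seq_len(model$n_annotators)) {
      flip <- runif(nrow(truth)) < model$flip_prob[[j]]
      out[[paste0("annotator_", j)]] <- ifelse(flip, other_of, truth$label)
    }
  })
  out
}
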