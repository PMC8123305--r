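# End-to-end orchestration: dedup -> normalize -> language filter ->
# annotate/adjudicate -> train -> predict -> filter -> aggregate -> test ->
# report, with stage-by-stage count accounting.

#' Count accounting for one search period
#'
#' The stage-by-stage bookkeeping reported for every run: tweets
#' downloaded, tweets left after exact-text deduplication, and tweets
#' predicted as legitimate complaints, each with the derived percentages
#' (of the original download and of the filtered set), rounded half-even
#' to 2 decimals.
#'
#' @param n_downloaded Tweets before deduplication.
#' @param n_after_dedup Tweets after deduplication.
#' @param n_complaints Tweets predicted as complaints.
#' @return A list of the three counts and three percentages
#'   (`pct_dedup_of_original`, `pct_complaints_of_original`,
#'   `pct_complaints_of_filtered`).
#' @export
count_accounting <- function(n_downloaded, n_after_dedup, n_complaints) {
  if (n_after_dedup > n_downloaded || n_complaints > n_after_dedup) {
    stop("counts must satisfy complaints <= after_dedup <= downloaded",
         call. = FALSE)
  }
  list(n_downloaded = n_downloaded,
       n_after_dedup = n_after_dedup,
       n_complaints = n_complaints,
       pct_dedup_of_original = round(100 * n_after_dedup / n_downloaded, 2),
       pct_complaints_of_original = round(100 * n_complaints / n_downloaded, 2),
       pct_complaints_of_filtered = round(100 * n_complaints / n_after_dedup, 2))
}

#' Pipeline configuration
#'
#' @param simulate A [sim_config()] to generate the corpus in-memory, or
#'   NULL when reading from `corpus_path`.
#' @param corpus_path,labels_path Input files (JSON-lines corpus; CSV
#'   annotation matrix), used when not simulating.
#' @param n_label_sample Number of tweets drawn (uniformly, seeded) for
#'   manual-style annotation when labels are simulated.
#' @param annotator An [annotator_model()] for simulated annotation.
#' @param agreement_floor Alpha acceptance floor (flagging only).
#' @param extractor Feature extractor (default [ngram_extractor()]).
#' @param k Cross-validation folds.
#' @param seed Master seed for sampling, folds and annotation noise.
#' @param model_params Booster overrides, see [fit_classifier()].
#' @param granularity `"day"` or `"hour"` for the comparison series.
#' @param trend_degree Display-trend polynomial degree.
#' @param alpha_level Significance threshold for all tests.
#' @param localized Also analyze the localized (geo-opt-in) subsample?
#' @param detector Language detector, see [filter_language()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, corpus_path = NULL,
                            labels_path = NULL, n_label_sample = 5000L,
                            annotator = annotator_model(3L, 0.05),
                            agreement_floor = 0.8,
                            extractor = ngram_extractor(),
                            k = 5L, seed = 1L, model_params = list(),
                            granularity = "day", trend_degree = 6L,
                            alpha_level = 0.05, localized = FALSE,
                            detector = builtin_language_detector()) {
  if (is.null(simulate) && is.null(corpus_path)) {
    stop("config must provide either `simulate` or `corpus_path`", call. = FALSE)
  }
  if (!is.null(corpus_path) && !file.exists(corpus_path)) {
    stop("corpus_path does not exist: ", corpus_path, call. = FALSE)
  }
  if (!is.null(labels_path) && !file.exists(labels_path)) {
    stop("labels_path does not exist: ", labels_path, call. = FALSE)
  }
  structure(list(simulate = simulate, corpus_path = corpus_path,
                 labels_path = labels_path,
                 n_label_sample = as.integer(n_label_sample),
                 annotator = annotator, agreement_floor = agreement_floor,
                 extractor = extractor, k = as.integer(k),
                 seed = as.integer(seed), model_params = model_params,
                 granularity = granularity,
                 trend_degree = as.integer(trend_degree),
                 alpha_level = alpha_level, localized = localized,
                 detector = detector),
            class = "pipeline_config")
}

period_of <- function(config) {
  if (!is.null(config$simulate)) {
    list(a = config$simulate$period_a, b = config$simulate$period_b)
  } else {
    NULL
  }
}

#' Run the full surveillance pipeline
#'
#' Executes deduplication, normalization, language filtering, annotation
#' (simulated or from file) with agreement screening and adjudication,
#' cross-validated classifier training, whole-corpus inference with a
#' model refit on all labeled items (set `inference = "fold1"` to instead
#' reuse the first fold's model), complaint filtering, per-period count
#' aggregation, normality and ANOVA testing, trend fitting, and the
#' percent-change summary. Identical config and seed give an identical
#' report.
#'
#' @param config A [pipeline_config()].
#' @param periods Optional list `list(a = c(start, end), b = ...)`
#'   overriding the analysis periods (required when reading a corpus from
#'   file).
#' @param inference `"refit"` (default: refit on all labeled items) or
#'   `"fold1"` (use the first cross-validation fold's model).
#' @return A `pipeline_report` list; see [report_json()].
#' @export
run_pipeline <- function(config, periods = NULL, inference = c("refit", "fold1")) {
  stopifnot(inherits(config, "pipeline_config"))
  inference <- match.arg(inference)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", generate_corpus(config$simulate))
    tweets <- sim$tweets
    truth <- sim$truth
  } else {
    tweets <- stage("read_corpus", read_corpus(config$corpus_path))
  }
  periods <- periods %||% period_of(config)
  if (is.null(periods)) stop("analysis periods required", call. = FALSE)

  n_downloaded <- nrow(tweets)
  dd <- stage("deduplicate", deduplicate(tweets))
  tweets <- dd$tweets
  tweets <- stage("normalize", normalize_corpus(tweets))
  tweets <- stage("filter_language",
                  suppressMessages(filter_language(tweets, config$detector)))

  # Annotation: either a provided matrix or simulated three-annotator noise
  # on a seeded uniform sample of the corpus truth.
  agreement <- NULL
  if (!is.null(config$labels_path)) {
    ann <- stage("read_labels", read_labels(config$labels_path))
  } else {
    if (is.null(truth)) stop("labels_path required when not simulating", call. = FALSE)
    pool <- truth[truth$id %in% tweets$id, , drop = FALSE]
    n_samp <- min(config$n_label_sample, nrow(pool))
    samp <- withr::with_seed(config$seed,
                             pool[sample.int(nrow(pool), n_samp), , drop = FALSE])
    ann <- stage("annotate",
                 generate_annotations(samp, config$annotator,
                                      seed = config$seed + 1L))
  }
  agreement <- stage("agreement", krippendorff_alpha(ann))
  agreement_ok <- suppressWarnings(agreement_acceptable(agreement,
                                                        config$agreement_floor))
  gold <- stage("adjudicate", adjudicate(ann))
  gold <- gold[!gold$unresolved, , drop = FALSE]

  labeled <- tweets[match(gold$id, tweets$id), , drop = FALSE]
  keep <- !is.na(labeled$id)
  labeled <- labeled[keep, , drop = FALSE]
  gold <- gold[keep, , drop = FALSE]

  feats <- stage("extract_features",
                 extract_features(labeled$norm_text, config$extractor,
                                  ids = labeled$id))
  folds <- stage("make_folds",
                 make_folds(labeled$id, k = config$k, seed = config$seed,
                            stratify_by = gold$label))
  cv <- stage("crossval_train",
              crossval_train(feats, gold$label, folds,
                             model_params = config$model_params))
  cm <- confusion(cv$predictions)
  metrics <- compute_metrics(cm)

  final_model <- if (inference == "refit") {
    stage("fit_final", fit_classifier(feats, gold$label, config$model_params))
  } else {
    cv$models[[1L]]
  }
  all_feats <- stage("extract_features_all",
                     extract_features(tweets$norm_text, config$extractor,
                                      ids = tweets$id))
  preds <- stage("predict", predict_corpus(final_model, all_feats))
  complaints <- stage("filter_complaints", filter_complaints(tweets, preds))

  analyze_subset <- function(tw) {
    sa <- aggregate_counts(tw, config$granularity, periods$a, "period_a")
    sb <- aggregate_counts(tw, config$granularity, periods$b, "period_b")
    norm_a <- tryCatch(normality_test(sa, config$alpha_level),
                       error = function(e) NULL)
    norm_b <- tryCatch(normality_test(sb, config$alpha_level),
                       error = function(e) NULL)
    anova <- tryCatch(compare_groups(sa, sb, config$alpha_level),
                      error = function(e) NULL)
    if ((!is.null(norm_a) && !norm_a$normal) ||
        (!is.null(norm_b) && !norm_b$normal)) {
      warning("normality rejected for at least one period; ANOVA reported alongside the normality result",
              call. = FALSE)
    }
    list(series_a = sa, series_b = sb, n_tweets = nrow(tw),
         empty = nrow(tw) == 0L,
         normality_a = norm_a, normality_b = norm_b, anova = anova,
         ratio = tryCatch(ratio_report(sum(sa$count), sum(sb$count)),
                          error = function(e) NULL),
         trend_a = tryCatch(trend_fit(sa, config$trend_degree),
                            error = function(e) NULL),
         trend_b = tryCatch(trend_fit(sb, config$trend_degree),
                            error = function(e) NULL))
  }
  full <- stage("analyze", suppressWarnings(analyze_subset(complaints)))
  localized <- NULL
  if (isTRUE(config$localized)) {
    localized <- stage("analyze_localized", suppressWarnings(
      analyze_subset(complaints[complaints$geo_enabled, , drop = FALSE])))
  }

  accounting <- count_accounting(n_downloaded, dd$report$n_after,
                                 nrow(complaints))
  structure(list(
    seed = config$seed,
    accounting = accounting,
    dedup = dd$report,
    agreement = agreement,
    agreement_ok = agreement_ok,
    n_labeled = nrow(gold),
    label_counts = as.list(table(gold$label)),
    confusion = cm,
    metrics = metrics,
    misclassification_rate = misclassification_rate(cm),
    analysis = full,
    localized_analysis = localized
  ), class = "pipeline_report")
}

#' Serialize a pipeline report to JSON
#'
#' Every number shown in the printed summary is present in the JSON.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Optional output path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  strip <- function(an) {
    if (is.null(an)) return(NULL)
    list(
      counts = list(period_a = sum(an$series_a$count),
                    period_b = sum(an$series_b$count)),
      empty = an$empty,
      normality = list(
        period_a = if (is.null(an$normality_a)) NULL else
          an$normality_a[c("W", "p_value", "alpha_level", "normal")],
        period_b = if (is.null(an$normality_b)) NULL else
          an$normality_b[c("W", "p_value", "alpha_level", "normal")]),
      anova = if (is.null(an$anova)) NULL else
        an$anova[c("F", "p_value", "df_between", "df_within", "significant")],
      ratio = an$ratio)
  }
  obj <- list(
    seed = report$seed,
    accounting = report$accounting,
    agreement = if (is.null(report$agreement)) NULL else
      report$agreement[c("alpha", "D_o", "D_e", "n_pairable")],
    agreement_ok = report$agreement_ok,
    n_labeled = report$n_labeled,
    label_counts = report$label_counts,
    confusion = unclass(report$confusion),
    metrics = report$metrics[c("accuracy", "balanced_accuracy", "f1_macro",
                               "f1_micro", "f1_weighted", "mcc",
                               "precision_macro", "recall_macro")],
    misclassification_rate = report$misclassification_rate,
    analysis = strip(report$analysis),
    localized_analysis = strip(report$localized_analysis)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.pipeline_report <- function(x, ...) {
  a <- x$accounting
  cat("== Complaint surveillance report ==\n")
  cat(sprintf("downloaded %d | after dedup %d (%.2f%%) | complaints %d (%.2f%% of original, %.2f%% of filtered)\n",
              a$n_downloaded, a$n_after_dedup, a$pct_dedup_of_original,
              a$n_complaints, a$pct_complaints_of_original,
              a$pct_complaints_of_filtered))
  if (!is.null(x$agreement)) {
    cat(sprintf("agreement alpha %.4f (%s)\n", x$agreement$alpha,
                if (isTRUE(x$agreement_ok)) "accepted" else "below floor"))
  }
  cat(sprintf("labeled %d items; CV misclassification %.4f\n",
              x$n_labeled, x$misclassification_rate))
  print(x$metrics)
  an <- x$analysis
  if (isTRUE(an$empty)) {
    cat("complaint subset is empty: no period comparison possible\n")
  } else {
    cat(sprintf("period counts: A %d, B %d", sum(an$series_a$count),
                sum(an$series_b$count)))
    if (!is.null(an$ratio)) {
      cat(sprintf("; ratio %.2f%% (change %+d%%)",
                  an$ratio$ratio_pct, an$ratio$change_headline))
    }
    cat("\n")
    if (!is.null(an$anova)) print(an$anova)
  }
  invisible(x)
}

#' Worked-example report from printed stage counts and a confusion matrix
#'
#' An offline mode that accepts already-tabulated numbers (per-period
#' download/dedup/complaint counts and a pooled confusion matrix) and runs
#' only the arithmetic stages: accounting percentages, the metric suite,
#' and the between-period ratio summary. No corpus is needed.
#'
#' @param counts A data frame with columns `period`, `downloaded`,
#'   `after_dedup`, `complaints` (one row per search period).
#' @param cm Optional `confusion_2x2`.
#' @param ratio_pairs Optional list of `c(ref_period, cmp_period)` name
#'   pairs to summarize as ratios.
#' @return A list: per-period `accounting`, `metrics` (+
#'   `misclassification_rate`) when `cm` is given, and `ratios`.
#' @export
worked_example_report <- function(counts, cm = NULL, ratio_pairs = NULL) {
  stopifnot(all(c("period", "downloaded", "after_dedup", "complaints")
                %in% names(counts)))
  accounting <- lapply(seq_len(nrow(counts)), function(i) {
    count_accounting(counts$downloaded[[i]], counts$after_dedup[[i]],
                     counts$complaints[[i]])
  })
  names(accounting) <- counts$period
  out <- list(accounting = accounting)
  if (!is.null(cm)) {
    out$metrics <- compute_metrics(cm)
    out$misclassification_rate <- misclassification_rate(cm)
  }
  if (!is.null(ratio_pairs)) {
    out$ratios <- lapply(ratio_pairs, function(pr) {
      ref <- counts$complaints[[match(pr[[1L]], counts$period)]]
      cmp <- counts$complaints[[match(pr[[2L]], counts$period)]]
      ratio_report(ref, cmp)
    })
    names(out$ratios) <- vapply(ratio_pairs, paste, character(1), collapse = "_vs_")
  }
  out
}
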