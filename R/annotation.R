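# Inter-annotator agreement and label adjudication.

# Coerce an id + annotator_* tibble (or plain matrix) to a character
# matrix of labels, items in rows.
as_label_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- grep("^annotator_", names(x), value = TRUE)
    if (length(cols) == 0L) cols <- setdiff(names(x), "id")
    m <- as.matrix(x[cols])
    rownames(m) <- if ("id" %in% names(x)) x$id else NULL
    m
  } else {
    as.matrix(x)
  }
}

#' Krippendorff's alpha (nominal metric)
#'
#' Chance-corrected agreement for an items-by-annotators categorical label
#' matrix, computed via the coincidence-matrix formulation: within each
#' unit with m pairable values, every ordered pair of coder values
#' contributes 1/(m - 1) to the value-pair coincidence counts;
#' alpha = 1 - D_o / D_e, where D_o is the mismatched share of
#' coincidences and D_e = sum over v != v' of n_v n_v' / (n (n - 1)).
#' Units with fewer than two non-missing values are skipped.
#'
#' @param x Annotation matrix: tibble with `id` and `annotator_*` columns
#'   (as produced by [generate_annotations()] or [read_labels()]), or a
#'   plain items-by-annotators matrix. At least 2 annotators and 2 items.
#' @return An `agreement_result` list: `alpha`, `D_o`, `D_e`,
#'   `n_pairable`.
#' @export
krippendorff_alpha <- function(x) {
  m <- as_label_matrix(x)
  if (ncol(m) < 2L) stop("need at least 2 annotators", call. = FALSE)
  if (nrow(m) < 2L) stop("need at least 2 items", call. = FALSE)
  vals <- sort(unique(as.vector(m[!is.na(m)])))
  k <- length(vals)
  coin <- matrix(0, k, k, dimnames = list(vals, vals))
  for (u in seq_len(nrow(m))) {
    row <- m[u, ]
    row <- row[!is.na(row)]
    mu <- length(row)
    if (mu < 2L) next
    idx <- match(row, vals)
    tab <- tabulate(idx, k)
    # ordered pairs within the unit, each weighted 1/(mu - 1)
    pair <- (outer(tab, tab) - diag(tab, k)) / (mu - 1)
    coin <- coin + pair
  }
  n_tot <- sum(coin)
  if (n_tot == 0) stop("no pairable values", call. = FALSE)
  n_v <- rowSums(coin)
  D_o <- (n_tot - sum(diag(coin))) / n_tot
  D_e <- (n_tot^2 - sum(n_v^2)) / (n_tot * (n_tot - 1))
  if (D_e <= 0) {
    stop("alpha undefined: every label identical (expected disagreement is zero)",
         call. = FALSE)
  }
  structure(list(alpha = 1 - D_o / D_e, D_o = D_o, D_e = D_e,
                 n_pairable = n_tot),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Krippendorff alpha (nominal): %.4f  (D_o = %.4f, D_e = %.4f, n = %g)\n",
              x$alpha, x$D_o, x$D_e, x$n_pairable))
  invisible(x)
}

#' Check agreement against an acceptance floor
#'
#' The labeling workflow accepts a round of annotation only when alpha
#' reaches a configurable floor (default 0.8); below it the round should
#' be repeated after a clarifying session. Re-annotation is a human step:
#' this function only flags, it never blocks.
#'
#' @param result An `agreement_result`.
#' @param floor Acceptance threshold for alpha.
#' @return Logical: does agreement meet the floor? (with a warning when not)
#' @export
agreement_acceptable <- function(result, floor = 0.8) {
  ok <- result$alpha >= floor
  if (!ok) {
    warning(sprintf(
      "inter-annotator agreement alpha = %.3f is below the %.2f floor; labels should be re-annotated",
      result$alpha, floor), call. = FALSE)
  }
  ok
}

#' Adjudicate multi-annotator labels to one gold label per item
#'
#' Unanimous labels are retained; otherwise the majority label is taken
#' (guaranteed to exist for an odd number of annotators on binary labels).
#' With an even annotator count an exact tie cannot be resolved and the
#' item is flagged unresolved (`label` NA).
#'
#' @param x Annotation matrix (see [krippendorff_alpha()]).
#' @return Tibble `id`, `label`, `unresolved`.
#' @export
adjudicate <- function(x) {
  m <- as_label_matrix(x)
  if (ncol(m) < 2L) stop("need at least 2 annotators to adjudicate", call. = FALSE)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  n_complaint <- unname(rowSums(m == "complaint"))
  n_other <- unname(rowSums(m == "other"))
  label <- ifelse(n_complaint > n_other, "complaint",
                  ifelse(n_other > n_complaint, "other", NA_character_))
  tibble::tibble(id = ids, label = label, unresolved = is.na(label))
}
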