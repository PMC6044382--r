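#' Label reference records as positive or negative for ROC analysis
#'
#' Positives are compound records whose perturbagen name equals the query
#' compound name (case-insensitive, surrounding and internal whitespace
#' normalised); all other records are negatives. Genetic perturbations are
#' never positives.
#'
#' @param query_name compound name of the query condition.
#' @param db a `reference_db`, or a data.frame with columns `pert_type` and
#'   `pert_name` (e.g. a score table).
#' @return logical vector, one element per record.
#' @export
label_records <- function(query_name, db) {
  if (!nzchar(query_name)) stop("query_name must be non-empty")
  meta <- if (inherits(db, "reference_db")) db$meta else as.data.frame(db)
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  meta$pert_type == "compound" & norm(meta$pert_name) == norm(query_name)
}

#' Concordance index (area under the ROC curve) with a floor at 0.5
#'
#' Computes the Mann-Whitney AUC (ties between a positive and a negative
#' score count 0.5) and floors the result at 0.5: an AUC below 0.5 means the
#' two sets of conditions are not comparable, so no discrimination (0.5) is
#' reported instead.
#'
#' @param scores numeric vector of similarity scores.
#' @param labels logical (or 0/1) vector; `TRUE` = positive.
#' @return the floored c-index, in [0.5, 1].
#' @export
c_index <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < 1L || n_neg < 1L) {
    stop("c_index needs at least one positive and one negative")
  }
  r <- rank(scores)  # midranks handle ties as 0.5 per pair
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  max(auc, 0.5)
}

#' Cutoff maximising Youden's J statistic
#'
#' Evaluates J = sensitivity + specificity - 1 at every observed score value
#' with the predicate "score >= cutoff predicts positive" and returns the
#' maximising cutoff; ties in J are broken towards the largest cutoff (the
#' more stringent network).
#'
#' @inheritParams c_index
#' @return list with `cutoff`, `youden_j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < 1L || n_neg < 1L) {
    stop("youden_cutoff needs at least one positive and one negative")
  }
  cand <- sort(unique(scores), decreasing = TRUE)
  best <- NULL
  for (c0 in cand) {  # decreasing order: first max hit is the largest cutoff
    pred <- scores >= c0
    sens <- sum(pred & labels) / n_pos
    spec <- sum(!pred & !labels) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12) {
      best <- list(cutoff = c0, youden_j = j, sensitivity = sens,
                   specificity = spec)
    }
  }
  best
}

#' Run the ROC analysis used for similarity-score cutoff selection
#'
#' Scores are labelled by same-name compound records and summarised by the
#' floored c-index and the Youden-optimal cutoff.
#'
#' @param score_table data.frame from [score_reference()].
#' @param query_name compound name of the query condition.
#' @return list of class `roc_analysis`: `c_index`, `best_cutoff`,
#'   `youden_j`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(score_table, query_name) {
  labels <- label_records(query_name, score_table)
  ok <- !is.na(score_table$score)
  scores <- score_table$score[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < 1L) {
    warning("no same-name compound record; ROC analysis has no positives")
    return(structure(list(c_index = NA_real_, best_cutoff = NA_real_,
                          youden_j = NA_real_, n_pos = 0L, n_neg = n_neg),
                     class = "roc_analysis"))
  }
  y <- youden_cutoff(scores, labels)
  structure(list(c_index = c_index(scores, labels), best_cutoff = y$cutoff,
                 youden_j = y$youden_j, n_pos = n_pos, n_neg = n_neg),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat("ROC cutoff analysis\n")
  cat(sprintf("  positives: %d, negatives: %d\n", x$n_pos, x$n_neg))
  cat(sprintf("  c-index: %s, best cutoff: %s (Youden J = %s)\n",
              format(x$c_index), format(x$best_cutoff), format(x$youden_j)))
  invisible(x)
}

#' Resolve the similarity-score cutoff for upstream selection
#'
#' In `"auto"` mode the cutoff is chosen by ROC analysis against same-name
#' compound records (Youden's J); when no positive exists or the ROC is
#' degenerate (all scores identical), the fixed default of 0.2 is used
#' instead — the score range found acceptable when no cutoff can be
#' estimated. In `"fixed"` mode `fixed_value` is returned directly.
#'
#' @param query a `query_signature`; `query$meta$name` provides the compound
#'   name for labelling.
#' @param db a `reference_db`.
#' @param mode `"auto"` or `"fixed"`.
#' @param fixed_value cutoff used in fixed mode and as the auto fallback.
#' @param score_table optional precomputed [score_reference()] table (avoids
#'   rescoring).
#' @param roc_cell_filter optional cell line restriction for the ROC records.
#' @param scaling score scaling passed to [score_reference()].
#' @return list with `cutoff`, `provenance` (`"youden"`, `"fallback"` or
#'   `"fixed"`), and `roc` (the `roc_analysis` or `NULL`).
#' @export
resolve_cutoff <- function(query, db, mode = c("auto", "fixed"),
                           fixed_value = 0.2, score_table = NULL,
                           roc_cell_filter = NULL,
                           scaling = c("half", "batch_max")) {
  mode <- match.arg(mode)
  scaling <- match.arg(scaling)
  if (mode == "fixed") {
    if (!(fixed_value > 0 && fixed_value < 1)) {
      stop("fixed_value must lie in (0, 1)")
    }
    return(list(cutoff = fixed_value, provenance = "fixed", roc = NULL))
  }
  query_name <- query$meta$name
  if (is.null(query_name) || !nzchar(query_name)) {
    warning("query has no compound name; falling back to fixed cutoff")
    return(list(cutoff = fixed_value, provenance = "fallback", roc = NULL))
  }
  if (is.null(score_table) || !is.null(roc_cell_filter)) {
    score_table <- score_reference(query, db, cell_filter = roc_cell_filter,
                                   scaling = scaling)
  }
  roc <- roc_analysis(score_table, query_name)
  degenerate <- is.na(roc$best_cutoff) ||
    length(unique(stats::na.omit(score_table$score))) < 2L
  if (roc$n_pos < 1L || degenerate) {
    return(list(cutoff = fixed_value, provenance = "fallback", roc = roc))
  }
  list(cutoff = roc$best_cutoff, provenance = "youden", roc = roc)
}
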