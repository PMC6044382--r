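#' Kolmogorov-Smirnov enrichment statistic of tag positions in a ranked list
#'
#' Given the positions of t tag genes within a ranked list of n genes
#' (position 1 = most up-regulated), computes the signed KS running-sum
#' extremum used by connectivity-map style signature matching:
#' a = max_j ( j/t - V(j)/n ), b = max_j ( V(j)/n - (j-1)/t ), and the
#' statistic is a when a >= b, else -b. Values near +1 mean the tags
#' concentrate at the top of the list, near -1 at the bottom.
#'
#' @param tag_positions integer positions in `1:n` (need not be sorted).
#' @param n length of the ranked list.
#' @return the enrichment statistic, in (-1, 1].
#' @export
ks_enrichment <- function(tag_positions, n) {
  t <- length(tag_positions)
  if (t < 1L) stop("empty tag list")
  v <- sort(as.integer(tag_positions))
  if (anyDuplicated(v)) stop("tag positions must be distinct")
  if (v[1L] < 1L || v[t] > n) stop("tag positions out of range 1..n")
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a >= b) a else -b
}

#' Connectivity score of a query signature against one rank vector
#'
#' Computes the up-tag and down-tag KS statistics against a reference
#' record's gene ranking and combines them: when the two statistics have
#' opposite signs the score is (ks_up - ks_down) / 2 (so a record that drives
#' the up tags to the top and the down tags to the bottom approaches +1);
#' when they share a sign the profile is not concordant and the score is 0.
#' If one tag set is empty after restriction to ranked genes, its statistic
#' is taken as 0 and the score is half of the other's.
#'
#' @param up_tags,down_tags character vectors of query gene symbols; genes
#'   absent from `rank` are dropped.
#' @param rank named integer rank vector (1 = most up-regulated), a
#'   permutation of `1:length(rank)`.
#' @return list with `ks_up`, `ks_down`, `score`, and `n_dropped` (tags not
#'   found in the ranking).
#' @export
connectivity_score <- function(up_tags, down_tags, rank) {
  genes <- names(rank)
  if (is.null(genes)) stop("'rank' must be named by gene symbol")
  n <- length(rank)
  up <- intersect(up_tags, genes)
  down <- intersect(down_tags, genes)
  n_dropped <- (length(unique(up_tags)) - length(up)) +
    (length(unique(down_tags)) - length(down))
  if (!length(up) && !length(down)) {
    stop("no overlap between query tags and ranked genes")
  }
  ks_up <- if (length(up)) ks_enrichment(rank[up], n) else 0
  ks_down <- if (length(down)) ks_enrichment(rank[down], n) else 0
  score <- if (ks_up != 0 && ks_down != 0 && sign(ks_up) == sign(ks_down)) {
    0
  } else {
    (ks_up - ks_down) / 2
  }
  list(ks_up = ks_up, ks_down = ks_down, score = score, n_dropped = n_dropped)
}

#' Score a query signature against every record of a reference database
#'
#' Applies [connectivity_score()] to each (optionally cell-line filtered)
#' record. Records whose ranking shares no gene with the query tags get an
#' `NA` score and are flagged `unscored`.
#'
#' @param query a `query_signature`.
#' @param db a `reference_db`.
#' @param cell_filter optional cell-line name; only matching records are
#'   scored.
#' @param scaling `"half"` (default; raw ks_up - ks_down divided by 2) or
#'   `"batch_max"` (connectivity-map style rescaling of the raw difference by
#'   the batch maximum/minimum, which makes scores relative to the scored
#'   set).
#' @return data.frame with one row per record: record_id, pert_id, pert_type,
#'   target_gene, pert_name, cell_line, ks_up, ks_down, score, unscored.
#' @export
score_reference <- function(query, db, cell_filter = NULL,
                            scaling = c("half", "batch_max")) {
  stopifnot(inherits(query, "query_signature"), inherits(db, "reference_db"))
  scaling <- match.arg(scaling)
  meta <- db$meta
  if (!is.null(cell_filter)) {
    keep <- meta$cell_line == cell_filter
    if (!any(keep)) stop("cell_filter matches no record: ", cell_filter)
    meta <- meta[keep, , drop = FALSE]
  }
  if (!nrow(meta)) stop("empty reference database")
  up <- intersect(query$up_degs, db$landmark_genes)
  down <- intersect(query$down_degs, db$landmark_genes)
  dropped <- length(query$up_degs) + length(query$down_degs) -
    length(up) - length(down)
  if (dropped > 0) {
    message(dropped, " non-landmark query gene(s) dropped before scoring")
  }
  n <- length(db$landmark_genes)
  res <- data.frame(meta[c("record_id", "pert_id", "pert_type", "target_gene",
                           "pert_name", "cell_line")],
                    ks_up = NA_real_, ks_down = NA_real_, score = NA_real_,
                    unscored = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(meta))) {
    rk <- db$rank[, meta$record_id[i]]
    names(rk) <- db$landmark_genes
    if (!length(up) && !length(down)) {
      res$unscored[i] <- TRUE
      next
    }
    cs <- connectivity_score(up, down, rk)
    res$ks_up[i] <- cs$ks_up
    res$ks_down[i] <- cs$ks_down
    res$score[i] <- cs$score
  }
  if (scaling == "batch_max") {
    raw <- res$ks_up - res$ks_down
    raw[res$ks_up != 0 & res$ks_down != 0 &
          sign(res$ks_up) == sign(res$ks_down)] <- 0
    p <- max(raw, na.rm = TRUE)
    q <- min(raw, na.rm = TRUE)
    sc <- rep(0, length(raw))
    if (p > 0) sc[!is.na(raw) & raw > 0] <- raw[!is.na(raw) & raw > 0] / p
    if (q < 0) sc[!is.na(raw) & raw < 0] <- -raw[!is.na(raw) & raw < 0] / q
    sc[is.na(raw)] <- NA_real_
    res$score <- sc
  }
  res
}
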