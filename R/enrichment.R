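#' Signed log-FDR significance scores for enrichment results
#'
#' Summarises a two-direction enrichment result table (gene sets tested
#' against genes with increased and with decreased expression) into one
#' signed score per gene set. Within each direction: gene sets absent from
#' the table are assigned FDR 1 (not enriched at all); an FDR of exactly 0
#' is replaced by the minimum nonzero FDR of that direction's table. The
#' directional score is -log(FDR) with a positive sign for enrichment in
#' increased genes and a negative sign for decreased genes; when a gene set
#' is marginally enriched in both directions, the two signed scores are
#' summed.
#'
#' @param rows data.frame with columns `gene_set`, `direction`
#'   (`"increased"`/`"decreased"`) and `fdr` in [0, 1]; at most one row per
#'   (gene_set, direction).
#' @param universe character vector of all gene sets to score; must contain
#'   every gene set in `rows`.
#' @param log_base base of the logarithm (default 10, reported in output).
#' @return data.frame with columns `gene_set`, `score` and attribute
#'   `log_base`. A direction whose table is all-zero FDR (no substitute
#'   available) yields `NA` scores with a warning.
#' @export
signed_fdr_scores <- function(rows, universe, log_base = 10) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- c("gene_set", "direction", "fdr")
  if (!all(need %in% names(rows))) {
    stop("rows must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(rows)) {
    if (!all(rows$direction %in% c("increased", "decreased"))) {
      stop("direction must be 'increased' or 'decreased'")
    }
    if (any(rows$fdr < 0 | rows$fdr > 1 | !is.finite(rows$fdr))) {
      stop("fdr values must lie in [0, 1]")
    }
    if (anyDuplicated(rows[c("gene_set", "direction")])) {
      stop("a gene set appears more than once in one direction")
    }
    extra <- setdiff(rows$gene_set, universe)
    if (length(extra)) {
      stop("gene sets outside the universe: ", paste(extra, collapse = ", "))
    }
  }
  direction_fdr <- function(dirn) {
    sub <- rows[rows$direction == dirn, , drop = FALSE]
    fdr <- stats::setNames(rep(1, length(universe)), universe)
    fdr[sub$gene_set] <- sub$fdr
    if (any(fdr == 0)) {
      nz <- sub$fdr[sub$fdr > 0]
      if (!length(nz)) {
        warning("all FDR values are 0 in the ", dirn,
                " direction; scores set to NA")
        fdr[fdr == 0] <- NA_real_
      } else {
        fdr[fdr == 0] <- min(nz)
      }
    }
    fdr
  }
  inc <- direction_fdr("increased")
  dec <- direction_fdr("decreased")
  score <- (-log(inc, base = log_base)) + log(dec, base = log_base)
  out <- data.frame(gene_set = universe, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(out, "log_base") <- log_base
  out
}
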