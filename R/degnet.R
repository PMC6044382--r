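#' Fit a directed DEG network and rank hub genes
#'
#' The main entry point. Runs the full analysis on a query DEG signature and
#' a perturbation reference database: (1) score every reference record
#' against the query with the KS connectivity score; (2) resolve the
#' similarity-score cutoff, by ROC analysis against same-name compound
#' records (Youden's J) or a fixed value; (3) select direction-consistent
#' upstream perturbation records at or above the cutoff, deduplicated per
#' perturbagen id and with the two-shRNA off-target guard; (4) connect
#' upstream genes to the query DEGs they significantly regulate in the same
#' direction; (5) weight each edge by alpha x delta (upstream fold-change
#' ratio times the record's DEG-coverage penalty) and compute Kleinberg
#' hub/authority scores, normalised so the most influential gene scores 1.
#'
#' An empty network (no upstream record surviving the cutoff) is a valid
#' result, not an error.
#'
#' @param query a [query_signature()].
#' @param reference a [reference_db()].
#' @param cutoff `"auto"` (ROC/Youden with fallback), `"fixed"`, or a number
#'   in (0, 1) (shorthand for fixed).
#' @param cutoff_value fixed cutoff and auto fallback (default 0.2).
#' @param cell_filter optional cell line restriction for connectivity
#'   scoring. Upstream selection deliberately uses all cell lines by
#'   default; genetic-perturbation coverage of any one line is sparse.
#' @param roc_cell_filter optional cell line restriction for the ROC records
#'   only.
#' @param scaling connectivity score scaling, `"half"` or `"batch_max"`.
#' @param alpha_mode `"raw"` or `"symmetric"` (see [assign_weights()]).
#' @param delta_numerator `"all"` or `"landmark_only"` (see
#'   [assign_weights()]).
#' @param downstream_combine `"union"` or `"intersection"` (see
#'   [connect_downstream()]).
#' @return object of class `degnet` with components `scores` (per-record
#'   connectivity table), `roc`, `cutoff` (value + provenance), `upstream`,
#'   `network` (a `deg_network` with weights), `hub` (a `hub_scores`),
#'   `hub_table`, `params` and `call`.
#' @examples
#' spec <- planted_network_spec(seed = 7)
#' db <- generate_reference(spec)
#' q <- generate_query(spec)
#' rt <- treatment_control_ratio(q$treated, q$control)
#' sig <- call_degs(rt, meta = list(name = spec$compound_name))
#' fit <- degnet(sig, db)
#' head(coef(fit))
#' @export
degnet <- function(query, reference,
                   cutoff = c("auto", "fixed"), cutoff_value = 0.2,
                   cell_filter = NULL, roc_cell_filter = NULL,
                   scaling = c("half", "batch_max"),
                   alpha_mode = c("raw", "symmetric"),
                   delta_numerator = c("all", "landmark_only"),
                   downstream_combine = c("union", "intersection")) {
  stopifnot(inherits(query, "query_signature"),
            inherits(reference, "reference_db"))
  if (is.numeric(cutoff)) {
    cutoff_value <- cutoff
    cutoff <- "fixed"
  }
  cutoff <- match.arg(cutoff)
  scaling <- match.arg(scaling)
  alpha_mode <- match.arg(alpha_mode)
  delta_numerator <- match.arg(delta_numerator)
  downstream_combine <- match.arg(downstream_combine)

  scores <- score_reference(query, reference, cell_filter = cell_filter,
                            scaling = scaling)
  res_cut <- resolve_cutoff(query, reference, mode = cutoff,
                            fixed_value = cutoff_value,
                            score_table = if (is.null(roc_cell_filter)) scores,
                            roc_cell_filter = roc_cell_filter,
                            scaling = scaling)
  upstream <- select_upstream(scores, res_cut$cutoff, query)
  raw_edges <- connect_downstream(upstream, reference, query,
                                  combine = downstream_combine)
  net <- simplify_graph(raw_edges, upstream = upstream, query = query)
  net$cutoff_used <- res_cut$cutoff
  net <- assign_weights(net, query, reference, alpha_mode = alpha_mode,
                        delta_numerator = delta_numerator)
  hs <- hub_scores(net)
  structure(list(scores = scores, roc = res_cut$roc,
                 cutoff = list(value = res_cut$cutoff,
                               provenance = res_cut$provenance),
                 upstream = upstream, network = net, hub = hs,
                 hub_table = hub_table(net, hs),
                 query = query,
                 params = list(cutoff = cutoff, cutoff_value = cutoff_value,
                               cell_filter = cell_filter,
                               roc_cell_filter = roc_cell_filter,
                               scaling = scaling, alpha_mode = alpha_mode,
                               delta_numerator = delta_numerator,
                               downstream_combine = downstream_combine),
                 call = match.call()),
            class = "degnet")
}

#' @export
print.degnet <- function(x, ...) {
  cat("Directed DEG network fit\n")
  cat(sprintf("  query: %d UP / %d DOWN DEGs; reference: %d records\n",
              length(x$query$up_degs), length(x$query$down_degs),
              nrow(x$scores)))
  cat(sprintf("  cutoff: %g (%s)\n", x$cutoff$value, x$cutoff$provenance))
  cat(sprintf("  network: %d nodes, %d edges\n", nrow(x$network$nodes),
              nrow(x$network$edges)))
  if (nrow(x$hub_table) && nrow(x$network$edges)) {
    top <- x$hub_table[1L, ]
    cat(sprintf("  top hub: %s (hub score %.3f)\n", top$gene, top$hub_score))
  } else {
    cat("  empty network: no upstream perturbation survived the cutoff\n")
  }
  invisible(x)
}

#' @export
summary.degnet <- function(object, ...) {
  structure(list(fit = object,
                 filter_counts = attr(object$upstream, "filter_counts")),
            class = "summary.degnet")
}

#' @export
print.summary.degnet <- function(x, ...) {
  print(x$fit)
  fc <- x$filter_counts
  if (!is.null(fc)) {
    cat("  upstream filter cascade (records surviving):\n")
    lab <- c(genetic = "genetic-perturbation records",
             cutoff = "score >= cutoff",
             direction = "direction-consistent",
             dedup = "best record per perturbagen id",
             min_pert_ids = ">= 2 shRNA ids for knockdowns")
    for (nm in names(fc)) cat(sprintf("    %-35s %d\n", lab[[nm]], fc[[nm]]))
  }
  if (!is.null(x$fit$roc)) {
    cat(sprintf("  ROC: c-index %.3f, Youden J %.3f (%d pos / %d neg)\n",
                x$fit$roc$c_index, x$fit$roc$youden_j, x$fit$roc$n_pos,
                x$fit$roc$n_neg))
  }
  top <- utils::head(x$fit$hub_table, 5L)
  if (nrow(top)) {
    cat("  top hub genes:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Extract hub scores from a fitted DEG network
#'
#' @param object a `degnet` fit.
#' @param type `"hub"` (default) or `"authority"`.
#' @param ... ignored.
#' @return named numeric vector sorted by decreasing score.
#' @export
coef.degnet <- function(object, type = c("hub", "authority"), ...) {
  type <- match.arg(type)
  sort(object$hub[[type]], decreasing = TRUE)
}

#' Plot a fitted DEG network
#'
#' Draws the directed network with igraph: node colour encodes the DEG
#' direction (UP = gold, DOWN = steel blue), node size scales with the hub
#' score.
#'
#' @param x a `degnet` fit.
#' @param ... further arguments passed to [igraph::plot.igraph()].
#' @export
plot.degnet <- function(x, ...) {
  g <- as_igraph(x$network)
  if (igraph::vcount(g) == 0L) {
    warning("empty network; nothing to plot")
    return(invisible(NULL))
  }
  hub <- x$hub$hub[igraph::V(g)$name]
  dirn <- igraph::V(g)$direction
  col <- ifelse(is.na(dirn), "grey80",
                ifelse(dirn == "up", "gold", "steelblue"))
  igraph::plot.igraph(g, vertex.color = col,
                      vertex.size = 6 + 14 * hub,
                      vertex.label.cex = 0.7,
                      edge.arrow.size = 0.4, ...)
  invisible(x)
}
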