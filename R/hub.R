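#' Per-record delta penalty for edge weighting
#'
#' delta is the ratio of the number of UP (or DOWN) query DEGs to the number
#' of landmark genes up- (or down-) regulated by the record, capped at 1. A
#' record that perturbs many more genes than the query contains is penalised,
#' damping promiscuous (off-target-prone) perturbations; the cap prevents a
#' sparse record from being rewarded instead of merely not penalised.
#'
#' @param record_regulated a regulated-sets list (elements `up_set`,
#'   `down_set`), e.g. `db$regulated[[record_id]]`.
#' @param query a `query_signature`.
#' @param landmark_genes optional character vector; when supplied, the DEG
#'   counts in the numerator are restricted to landmark genes.
#' @return named numeric vector `c(delta_up=, delta_down=)`, each in [0, 1];
#'   0 when the record's corresponding regulated set is empty.
#' @export
compute_delta <- function(record_regulated, query, landmark_genes = NULL) {
  up_degs <- query$up_degs
  down_degs <- query$down_degs
  if (!is.null(landmark_genes)) {
    up_degs <- intersect(up_degs, landmark_genes)
    down_degs <- intersect(down_degs, landmark_genes)
  }
  n_up <- length(record_regulated$up_set)
  n_down <- length(record_regulated$down_set)
  c(delta_up = if (n_up > 0) min(1, length(up_degs) / n_up) else 0,
    delta_down = if (n_down > 0) min(1, length(down_degs) / n_down) else 0)
}

#' Assign alpha x delta weights to network edges
#'
#' Each edge's weight is alpha(source) times the best (largest) delta over
#' the edge's supporting records, where the delta component matches the
#' edge's direction. alpha is the upstream gene's query signal-intensity
#' ratio: mode `"raw"` uses the ratio as is (DOWN-DEG sources thus carry
#' alpha <= 0.5), mode `"symmetric"` uses max(ratio, 1/ratio) so fold change
#' magnitude counts equally in both directions.
#'
#' @param net a `deg_network`.
#' @param query a `query_signature` (source of alpha).
#' @param db a `reference_db` (source of per-record regulated sets).
#' @param alpha_mode `"raw"` or `"symmetric"`.
#' @param delta_numerator `"all"` (all query DEGs, default) or
#'   `"landmark_only"` (DEG counts restricted to landmark genes).
#' @return the network with `edges$weight` filled in.
#' @export
assign_weights <- function(net, query, db,
                           alpha_mode = c("raw", "symmetric"),
                           delta_numerator = c("all", "landmark_only")) {
  alpha_mode <- match.arg(alpha_mode)
  delta_numerator <- match.arg(delta_numerator)
  stopifnot(inherits(net, "deg_network"))
  e <- net$edges
  if (!nrow(e)) return(net)
  lg <- if (delta_numerator == "landmark_only") db$landmark_genes
  for (i in seq_len(nrow(e))) {
    src <- e$source[i]
    if (!src %in% names(query$gene_ratio)) {
      stop("no signal-intensity ratio (alpha) for upstream gene: ", src)
    }
    a <- query$gene_ratio[[src]]
    if (alpha_mode == "symmetric") a <- max(a, 1 / a)
    recs <- strsplit(e$supporting_records[i], ";", fixed = TRUE)[[1]]
    deltas <- vapply(recs, function(rid) {
      reg <- db$regulated[[rid]]
      if (is.null(reg)) stop("record not in reference database: ", rid)
      d <- compute_delta(reg, query, landmark_genes = lg)
      if (e$direction[i] == "up") d[["delta_up"]] else d[["delta_down"]]
    }, numeric(1))
    e$weight[i] <- a * max(deltas)
  }
  net$edges <- e
  net
}

#' Kleinberg hub and authority scores of a weighted DEG network
#'
#' Solves the mutually recursive hub/authority relationship — a node's hub
#' score is the weighted sum of the authority scores it points to, and a
#' node's authority score the weighted sum of the hub scores pointing at
#' it — by alternating power iteration on the weighted adjacency matrix W
#' (equivalently, the principal eigenvectors of W W' and W' W). Both vectors
#' are rescaled so their maximum entry is exactly 1; the gene with hub score
#' 1 is the most influential gene of the network. Initialisation is the
#' all-ones vector, so the result is fully deterministic. A network with no
#' edges returns all-zero scores.
#'
#' @param net a weighted `deg_network` (see [assign_weights()]), or any
#'   square numeric adjacency matrix with dimnames.
#' @param tol sup-norm convergence tolerance.
#' @param max_iter iteration cap; non-convergence is flagged, and the best
#'   iterate returned.
#' @return object of class `hub_scores`: list with named numeric vectors
#'   `hub` and `authority` (each in [0, 1]), `iterations` and `converged`.
#' @export
hub_scores <- function(net, tol = 1e-10, max_iter = 1000L) {
  W <- if (is.matrix(net)) net else adjacency_matrix(net)
  n <- nrow(W)
  genes <- rownames(W)
  if (n < 1L) {  # empty network: a valid, score-less result
    z <- stats::setNames(numeric(0), character(0))
    return(structure(list(hub = z, authority = z, iterations = 0L,
                          converged = TRUE), class = "hub_scores"))
  }
  if (all(W == 0)) {
    z <- stats::setNames(rep(0, n), genes)
    return(structure(list(hub = z, authority = z, iterations = 0L,
                          converged = TRUE), class = "hub_scores"))
  }
  h <- rep(1, n)
  a <- rep(0, n)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    a_new <- as.numeric(crossprod(W, h))   # authority <- sum of pointing hubs
    a_new <- a_new / max(a_new)
    h_new <- as.numeric(W %*% a_new)       # hub <- sum of pointed authorities
    h_new <- h_new / max(h_new)
    if (max(abs(h_new - h)) < tol && max(abs(a_new - a)) < tol) {
      h <- h_new; a <- a_new
      converged <- TRUE
      break
    }
    h <- h_new; a <- a_new
  }
  structure(list(hub = stats::setNames(h, genes),
                 authority = stats::setNames(a, genes),
                 iterations = iter, converged = converged),
            class = "hub_scores")
}

#' @export
print.hub_scores <- function(x, n = 10L, ...) {
  cat("Hub/authority scores (top hub = 1)\n")
  top <- sort(x$hub, decreasing = TRUE)
  top <- utils::head(top, n)
  for (g in names(top)) {
    cat(sprintf("  %-15s hub %.4f  authority %.4f\n", g, x$hub[[g]],
                x$authority[[g]]))
  }
  if (!x$converged) cat("  warning: power iteration did not converge\n")
  invisible(x)
}

adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "deg_network"))
  genes <- net$nodes$gene
  W <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  e <- net$edges
  if (nrow(e)) {
    w <- e$weight
    if (anyNA(w)) stop("edges have no weights; run assign_weights() first")
    W[cbind(e$source, e$target)] <- w
  }
  W
}

#' Tabulate hub results
#'
#' @param net a weighted `deg_network`.
#' @param hs a `hub_scores` object for the same network.
#' @return data.frame sorted by decreasing hub score: gene, direction,
#'   ratio, hub_score, authority_score, n_out_edges, n_in_edges.
#' @export
hub_table <- function(net, hs) {
  nodes <- net$nodes
  out_deg <- table(factor(net$edges$source, levels = nodes$gene))
  in_deg <- table(factor(net$edges$target, levels = nodes$gene))
  tab <- data.frame(gene = nodes$gene, direction = nodes$direction,
                    ratio = nodes$ratio,
                    hub_score = as.numeric(hs$hub[nodes$gene]),
                    authority_score = as.numeric(hs$authority[nodes$gene]),
                    n_out_edges = as.integer(out_deg[nodes$gene]),
                    n_in_edges = as.integer(in_deg[nodes$gene]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$hub_score, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
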