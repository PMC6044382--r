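#' Select upstream candidate records
#'
#' Applies the four-stage upstream filter to a connectivity score table:
#' (1) keep genetic-perturbation records (knockdown, overexpression, ligand)
#' scoring at or above the cutoff; (2) keep records whose perturbation
#' direction is consistent with the target gene's DEG direction — a knocked
#' down gene must be a DOWN DEG, an overexpressed or ligand-treated gene must
#' be an UP DEG; (3) within each (target gene, perturbagen id) keep only the
#' highest-scoring record; (4) drop knockdown target genes supported by fewer
#' than two distinct perturbagen ids, to guard against shRNA off-target
#' effects. Compound records are never upstream candidates.
#'
#' @param scores data.frame from [score_reference()].
#' @param cutoff similarity-score cutoff (records with score >= cutoff pass).
#' @param query a `query_signature`.
#' @param db a `reference_db` (used for record lookup downstream; the filter
#'   itself uses only `scores` and `query`).
#' @param counts if `TRUE`, attach a `filter_counts` attribute recording the
#'   number of records surviving each stage.
#' @return data.frame of retained records (columns of `scores`), one row per
#'   kept record; zero rows is a valid result.
#' @export
select_upstream <- function(scores, cutoff, query, db = NULL, counts = TRUE) {
  stopifnot(is.finite(cutoff))
  s <- scores[scores$pert_type %in% genetic_pert_types &
                !is.na(scores$score), , drop = FALSE]
  n0 <- nrow(s)
  s <- s[s$score >= cutoff, , drop = FALSE]
  n_cutoff <- nrow(s)
  kd <- s$pert_type == "knockdown"
  ok <- (kd & s$target_gene %in% query$down_degs) |
    (!kd & s$target_gene %in% query$up_degs)
  s <- s[ok, , drop = FALSE]
  n_direction <- nrow(s)
  if (nrow(s)) {
    # per (target_gene, pert_id): keep the highest-scoring record
    key <- paste(s$target_gene, s$pert_id, sep = "\r")
    s <- s[order(key, -s$score), , drop = FALSE]
    s <- s[!duplicated(paste(s$target_gene, s$pert_id, sep = "\r")), ,
           drop = FALSE]
  }
  n_dedup <- nrow(s)
  if (nrow(s)) {
    kd <- s$pert_type == "knockdown"
    n_ids <- tapply(s$pert_id[kd], s$target_gene[kd],
                    function(x) length(unique(x)))
    weak <- names(n_ids)[n_ids < 2L]
    s <- s[!(s$pert_type == "knockdown" & s$target_gene %in% weak), ,
           drop = FALSE]
  }
  rownames(s) <- NULL
  if (counts) {
    attr(s, "filter_counts") <- c(genetic = n0, cutoff = n_cutoff,
                                  direction = n_direction, dedup = n_dedup,
                                  min_pert_ids = nrow(s))
  }
  s
}

#' Connect upstream genes to their downstream DEGs
#'
#' For every retained upstream record, downstream genes are the query UP DEGs
#' found in the record's up-regulated set (edges of direction `"up"`) and the
#' query DOWN DEGs found in its down-regulated set (direction `"down"`): a
#' downstream gene must be significantly regulated by the perturbation and
#' move in the same direction as in the query.
#'
#' @param upstream data.frame from [select_upstream()].
#' @param db a `reference_db`.
#' @param query a `query_signature`.
#' @param combine `"union"` (default) keeps the union of downstream genes
#'   across a gene's retained records; `"intersection"` keeps only genes
#'   supported by every retained record of that upstream gene.
#' @return data.frame of raw edges: source, target, direction, record_id.
#' @export
connect_downstream <- function(upstream, db, query,
                               combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  stopifnot(inherits(db, "reference_db"))
  edges <- list()
  for (i in seq_len(nrow(upstream))) {
    rid <- upstream$record_id[i]
    src <- upstream$target_gene[i]
    reg <- db$regulated[[rid]]
    if (is.null(reg)) stop("record not in reference database: ", rid)
    up_t <- intersect(reg$up_set, query$up_degs)
    down_t <- intersect(reg$down_set, query$down_degs)
    if (length(up_t) + length(down_t) == 0L) next
    edges[[length(edges) + 1L]] <- data.frame(
      source = src,
      target = c(up_t, down_t),
      direction = rep(c("up", "down"), c(length(up_t), length(down_t))),
      record_id = rid, stringsAsFactors = FALSE)
  }
  e <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(),
               direction = character(), record_id = character(),
               stringsAsFactors = FALSE)
  if (combine == "intersection" && nrow(e)) {
    n_rec <- tapply(upstream$record_id, upstream$target_gene,
                    function(x) length(unique(x)))
    supp <- stats::aggregate(record_id ~ source + target, data = e,
                             FUN = function(x) length(unique(x)))
    keep_key <- paste(supp$source, supp$target)[
      supp$record_id >= n_rec[supp$source]]
    e <- e[paste(e$source, e$target) %in% keep_key, , drop = FALSE]
  }
  rownames(e) <- NULL
  e
}

#' Simplify the raw edge list into a simple directed DEG network
#'
#' Removes self-loops, merges parallel edges between the same source and
#' target (pooling their supporting record ids), and assembles the node
#' table: every endpoint of a surviving edge plus any upstream gene left with
#' no edge (its perturbation passed the cutoff, but no downstream gene moved
#' in the query's direction).
#'
#' @param edges data.frame from [connect_downstream()].
#' @param upstream data.frame from [select_upstream()] (provides isolated
#'   upstream nodes and provenance).
#' @param query optional `query_signature` used to annotate node direction
#'   and ratio.
#' @return object of class `deg_network`: list with `nodes` (data.frame:
#'   gene, direction, ratio, is_upstream), `edges` (data.frame: source,
#'   target, direction, supporting_records, weight) and `upstream`.
#' @export
simplify_graph <- function(edges, upstream = NULL, query = NULL) {
  e <- edges[edges$source != edges$target, , drop = FALSE]
  if (nrow(e)) {
    key <- paste(e$source, e$target, sep = "\r")
    supp <- tapply(e$record_id, key, function(x)
      paste(sort(unique(x)), collapse = ";"))
    first <- e[!duplicated(key), , drop = FALSE]
    first_key <- paste(first$source, first$target, sep = "\r")
    merged <- data.frame(source = first$source, target = first$target,
                         direction = first$direction,
                         supporting_records = as.character(supp[first_key]),
                         weight = NA_real_, stringsAsFactors = FALSE)
  } else {
    merged <- data.frame(source = character(), target = character(),
                         direction = character(),
                         supporting_records = character(),
                         weight = numeric(), stringsAsFactors = FALSE)
  }
  up_genes <- if (!is.null(upstream) && nrow(upstream))
    unique(upstream$target_gene) else character()
  genes <- unique(c(merged$source, merged$target, up_genes))
  direction <- ratio <- rep(NA_character_, length(genes))
  ratio <- rep(NA_real_, length(genes))
  if (!is.null(query)) {
    direction[genes %in% query$up_degs] <- "up"
    direction[genes %in% query$down_degs] <- "down"
    hit <- genes %in% names(query$gene_ratio)
    ratio[hit] <- query$gene_ratio[genes[hit]]
  }
  nodes <- data.frame(gene = genes, direction = direction, ratio = ratio,
                      is_upstream = genes %in% up_genes,
                      stringsAsFactors = FALSE)
  rownames(merged) <- NULL
  structure(list(nodes = nodes, edges = merged, upstream = upstream,
                 cutoff_used = NA_real_),
            class = "deg_network")
}

#' @export
print.deg_network <- function(x, ...) {
  cat("Directed DEG network\n")
  cat(sprintf("  %d nodes (%d upstream), %d edges\n", nrow(x$nodes),
              sum(x$nodes$is_upstream), nrow(x$edges)))
  if (!is.na(x$cutoff_used)) {
    cat(sprintf("  similarity-score cutoff: %g\n", x$cutoff_used))
  }
  invisible(x)
}

#' Convert a DEG network to an igraph object
#'
#' Node attributes: direction, ratio, is_upstream (plus hub/authority scores
#' when present). Edge attributes: direction, weight, supporting_records.
#'
#' @param net a `deg_network`.
#' @return an [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "deg_network"))
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}
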