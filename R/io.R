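#' Write all artifacts of a fitted DEG network
#'
#' Emits into `dir`: `scores.tsv` (per-record connectivity scores),
#' `roc_report.tsv`, `upstream_candidates.tsv`, `network.sif`
#' (source, regulates_up/regulates_down, target), `network.graphml` (node
#' attributes direction/ratio/hub/authority, edge attributes
#' weight/supporting_records) and `hubs.tsv` (sorted by hub score), plus
#' `run_metadata.json` recording every parameter and the cutoff provenance.
#'
#' @param fit a `degnet` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of paths written.
#' @export
write_degnet <- function(fit, dir) {
  stopifnot(inherits(fit, "degnet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(tsv(fit$scores, "scores.tsv"),
             tsv(roc_report(fit), "roc_report.tsv"),
             tsv(fit$upstream, "upstream_candidates.tsv"),
             tsv(hub_output_table(fit), "hubs.tsv"))

  sif <- fit$network$edges
  sif_path <- file.path(dir, "network.sif")
  if (nrow(sif)) {
    writeLines(paste(sif$source, paste0("regulates_", sif$direction),
                     sif$target, sep = "\t"), sif_path)
  } else {
    writeLines(character(), sif_path)
  }
  graphml_path <- file.path(dir, "network.graphml")
  g <- as_igraph(fit$network)
  if (igraph::vcount(g) > 0L) {
    igraph::V(g)$hub_score <- as.numeric(fit$hub$hub[igraph::V(g)$name])
    igraph::V(g)$authority_score <-
      as.numeric(fit$hub$authority[igraph::V(g)$name])
  }
  igraph::write_graph(g, graphml_path, format = "graphml")

  meta_path <- file.path(dir, "run_metadata.json")
  meta <- c(fit$params,
            list(cutoff_used = fit$cutoff$value,
                 cutoff_provenance = fit$cutoff$provenance,
                 n_up_degs = length(fit$query$up_degs),
                 n_down_degs = length(fit$query$down_degs),
                 n_records_scored = sum(!fit$scores$unscored),
                 filter_counts = as.list(attr(fit$upstream, "filter_counts")),
                 n_nodes = nrow(fit$network$nodes),
                 n_edges = nrow(fit$network$edges),
                 hub_converged = fit$hub$converged,
                 package_version = as.character(utils::packageVersion("degnet"))))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, sif_path, graphml_path, meta_path))
}

roc_report <- function(fit) {
  roc <- fit$roc
  data.frame(query_name = if (!is.null(fit$query$meta$name))
               fit$query$meta$name else "",
             n_pos = if (!is.null(roc)) roc$n_pos else NA_integer_,
             n_neg = if (!is.null(roc)) roc$n_neg else NA_integer_,
             c_index = if (!is.null(roc)) roc$c_index else NA_real_,
             best_cutoff = fit$cutoff$value,
             youden_j = if (!is.null(roc)) roc$youden_j else NA_real_,
             provenance = fit$cutoff$provenance,
             stringsAsFactors = FALSE)
}

hub_output_table <- function(fit) {
  fit$hub_table
}

#' Run the full pipeline from files to artifacts
#'
#' File-level orchestration of [degnet()]: loads the reference TSV triple
#' and the query (an expression table or a precomputed signature), fits the
#' network and writes every artifact into `out_dir`. Settings mirror the
#' arguments of [degnet()] plus the DEG-calling parameters.
#'
#' @param reference_dir directory holding `reference_meta.tsv`,
#'   `reference_zscore.tsv` and optionally `reference_expr.tsv`.
#' @param query_path path to `query_expression.tsv`
#'   (identifier/treated/control) or `query_signature.tsv` (gene/direction
#'   [/ratio]); detected by the header.
#' @param out_dir output directory.
#' @param query_name compound name of the query condition (enables the auto
#'   ROC cutoff).
#' @param probe_map_path optional probe-to-gene map for expression queries.
#' @param floor,up_threshold,down_threshold DEG-calling parameters.
#' @param ... further arguments passed to [degnet()].
#' @return the `degnet` fit, invisibly; artifacts are written to `out_dir`.
#' @export
run_pipeline <- function(reference_dir, query_path, out_dir,
                         query_name = NULL, probe_map_path = NULL,
                         floor = 50, up_threshold = 2, down_threshold = 0.5,
                         ...) {
  db <- load_reference(file.path(reference_dir, "reference_meta.tsv"),
                       file.path(reference_dir, "reference_zscore.tsv"),
                       expr_path = {
                         p <- file.path(reference_dir, "reference_expr.tsv")
                         if (file.exists(p)) p
                       })
  header <- names(utils::read.delim(query_path, nrows = 1L))
  meta <- list(name = query_name)
  query <- if ("identifier" %in% header) {
    read_query_expression(query_path, probe_map_path = probe_map_path,
                          floor = floor, up_threshold = up_threshold,
                          down_threshold = down_threshold, meta = meta)
  } else {
    read_query_signature(query_path, meta = meta)
  }
  fit <- degnet(query, db, ...)
  write_degnet(fit, out_dir)
  invisible(fit)
}
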