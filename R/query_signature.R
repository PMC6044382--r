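#' Treatment-to-control intensity ratios with an intensity floor
#'
#' Computes per-identifier treatment/control ratios after flooring both
#' intensities: any value below `floor` is replaced by `floor` before
#' dividing, which stabilises ratios for probes near the detection limit.
#'
#' @param treated,control named non-negative numeric vectors on the same
#'   identifiers (probes or genes).
#' @param floor intensity floor (default 50).
#' @return list of class `ratio_table` with elements `ratio` (named numeric)
#'   and `floor`.
#' @examples
#' treatment_control_ratio(c(p1 = 30), c(p1 = 200))$ratio  # 0.25
#' @export
treatment_control_ratio <- function(treated, control, floor = 50) {
  if (is.null(names(treated)) || is.null(names(control))) {
    stop("'treated' and 'control' must be named by identifier")
  }
  if (!setequal(names(treated), names(control)) ||
      length(treated) != length(control)) {
    stop("identifier mismatch between treated and control")
  }
  control <- control[names(treated)]
  if (any(treated < 0) || any(control < 0)) stop("negative intensity value")
  if (!all(is.finite(treated)) || !all(is.finite(control))) {
    stop("non-finite intensity value")
  }
  ratio <- pmax(treated, floor) / pmax(control, floor)
  structure(list(ratio = ratio, floor = floor), class = "ratio_table")
}

as_ratio_table <- function(x, floor = 50) {
  if (inherits(x, "ratio_table")) return(x)
  if (is.numeric(x) && (length(x) == 0L || !is.null(names(x)))) {
    return(structure(list(ratio = x, floor = floor), class = "ratio_table"))
  }
  stop("expected a ratio_table or a named numeric vector of ratios")
}

#' Average probe-level ratios to gene level
#'
#' Assigns each gene the arithmetic mean of its probes' treatment-to-control
#' ratios. Probes with no gene mapping are dropped (with a message giving the
#' count).
#'
#' @param probe_ratios `ratio_table` (or named numeric vector) keyed by probe.
#' @param probe_map data.frame with columns `probe` and `gene`; each probe may
#'   map to at most one gene.
#' @param geometric if `TRUE`, average on the log scale (geometric mean)
#'   instead of the default arithmetic mean of ratios.
#' @return a `ratio_table` keyed by gene symbol.
#' @export
aggregate_to_genes <- function(probe_ratios, probe_map, geometric = FALSE) {
  rt <- as_ratio_table(probe_ratios)
  probe_map <- as.data.frame(probe_map, stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    stop("probe_map must have columns 'probe' and 'gene'")
  }
  if (anyDuplicated(probe_map$probe)) {
    stop("a probe maps to more than one gene")
  }
  gene <- probe_map$gene[match(names(rt$ratio), probe_map$probe)]
  unmapped <- is.na(gene) | gene == ""
  if (any(unmapped)) {
    message(sum(unmapped), " unmapped probe(s) dropped during gene aggregation")
  }
  r <- rt$ratio[!unmapped]
  g <- gene[!unmapped]
  if (!length(r)) stop("no probe could be mapped to a gene")
  agg <- if (geometric) {
    exp(tapply(log(r), g, mean))
  } else {
    tapply(r, g, mean)
  }
  structure(list(ratio = stats::setNames(as.numeric(agg), names(agg)),
                 floor = rt$floor),
            class = "ratio_table")
}

#' Call differentially expressed genes from ratio statistics
#'
#' Genes with treatment-to-control ratio at or above `up_threshold` become UP
#' DEGs and genes at or below `down_threshold` become DOWN DEGs (boundaries
#' inclusive); everything strictly in between is unchanged.
#'
#' @param ratios `ratio_table` (or named numeric vector) keyed by gene.
#' @param up_threshold,down_threshold inclusive ratio cutoffs, defaults 2 and
#'   0.5.
#' @param meta optional named list of free-text labels (e.g. drug, cell line,
#'   duration; the element `name` is used to find same-name compound records
#'   during ROC cutoff selection).
#' @return an object of class `query_signature` with elements `up_degs`,
#'   `down_degs`, `gene_ratio` and `meta`.
#' @export
call_degs <- function(ratios, up_threshold = 2, down_threshold = 0.5,
                      meta = list()) {
  rt <- as_ratio_table(ratios)
  if (!length(rt$ratio)) stop("empty ratio table")
  if (!(down_threshold > 0 && down_threshold < up_threshold)) {
    stop("need 0 < down_threshold < up_threshold")
  }
  if (any(rt$ratio <= 0) || !all(is.finite(rt$ratio))) {
    stop("ratios must be positive and finite")
  }
  genes <- names(rt$ratio)
  query_signature(up_degs = genes[rt$ratio >= up_threshold],
                  down_degs = genes[rt$ratio <= down_threshold],
                  gene_ratio = rt$ratio, meta = meta)
}

#' Construct a query DEG signature
#'
#' A query signature is the pair of UP and DOWN DEG sets plus the per-gene
#' treatment-to-control ratios that produced them (the ratios later provide
#' the alpha factor of the network edge weights). When a precomputed DEG list
#' is supplied without ratios, all ratios default to 1 with a warning, so
#' every upstream gene carries equal alpha weight.
#'
#' @param up_degs,down_degs character vectors of gene symbols (disjoint).
#' @param gene_ratio named numeric vector of positive ratios covering at
#'   least the DEGs, or `NULL`.
#' @param meta named list of free-text labels.
#' @return an object of class `query_signature`.
#' @export
query_signature <- function(up_degs, down_degs, gene_ratio = NULL,
                            meta = list()) {
  up_degs <- unique(as.character(up_degs))
  down_degs <- unique(as.character(down_degs))
  if (length(intersect(up_degs, down_degs))) {
    stop("UP and DOWN DEG sets overlap")
  }
  if (is.null(gene_ratio)) {
    warning("no ratios supplied; alpha defaults to 1 for all genes")
    gene_ratio <- stats::setNames(rep(1, length(up_degs) + length(down_degs)),
                                  c(up_degs, down_degs))
  }
  if (any(gene_ratio <= 0) || !all(is.finite(gene_ratio))) {
    stop("gene_ratio values must be positive and finite")
  }
  missing <- setdiff(c(up_degs, down_degs), names(gene_ratio))
  if (length(missing)) {
    stop("gene_ratio is missing DEGs: ", paste(missing, collapse = ", "))
  }
  structure(list(up_degs = up_degs, down_degs = down_degs,
                 gene_ratio = gene_ratio, meta = meta),
            class = "query_signature")
}

#' @export
print.query_signature <- function(x, ...) {
  cat("Query DEG signature\n")
  cat(sprintf("  %d UP DEGs, %d DOWN DEGs\n",
              length(x$up_degs), length(x$down_degs)))
  if (!is.null(x$meta$name)) cat("  name:", x$meta$name, "\n")
  invisible(x)
}

#' Derive a query signature from expression or signature files
#'
#' `read_query_expression()` reads a table with columns `identifier`,
#' `treated`, `control` (optionally mapping probes to genes through
#' `probe_map_path`, a TSV with columns `probe`, `gene`) and derives the DEG
#' signature by the floor/ratio/threshold rules. `read_query_signature()`
#' reads a precomputed signature table with columns `gene`,
#' `direction` (UP/DOWN) and optionally `ratio`.
#'
#' @param path input TSV path.
#' @param probe_map_path optional probe-to-gene map TSV.
#' @param floor intensity floor.
#' @param up_threshold,down_threshold DEG ratio cutoffs.
#' @param deg_level `"gene"` (default: aggregate probes to genes, then
#'   threshold) or `"probe"` (threshold probes, then aggregate the DEG
#'   probes' ratios).
#' @param meta named list of labels attached to the signature.
#' @return a `query_signature`.
#' @export
read_query_expression <- function(path, probe_map_path = NULL, floor = 50,
                                  up_threshold = 2, down_threshold = 0.5,
                                  deg_level = c("gene", "probe"),
                                  meta = list()) {
  deg_level <- match.arg(deg_level)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("identifier", "treated", "control")
  if (!all(need %in% names(tab))) {
    stop("query expression table needs columns: ",
         paste(need, collapse = ", "))
  }
  treated <- stats::setNames(as.numeric(tab$treated), tab$identifier)
  control <- stats::setNames(as.numeric(tab$control), tab$identifier)
  rt <- treatment_control_ratio(treated, control, floor = floor)
  if (!is.null(probe_map_path)) {
    pm <- utils::read.delim(probe_map_path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (deg_level == "gene") {
      rt <- aggregate_to_genes(rt, pm)
    } else {
      sig <- call_degs(rt, up_threshold, down_threshold, meta = meta)
      keep <- c(sig$up_degs, sig$down_degs)
      rt$ratio <- rt$ratio[names(rt$ratio) %in% keep]
      rt <- aggregate_to_genes(rt, pm)
    }
  }
  sig <- call_degs(rt, up_threshold, down_threshold, meta = meta)
  sig$meta$deg_level <- deg_level
  sig
}

#' @rdname read_query_expression
#' @export
read_query_signature <- function(path, meta = list()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(tab))) {
    stop("signature table needs columns 'gene' and 'direction'")
  }
  dirn <- toupper(tab$direction)
  if (!all(dirn %in% c("UP", "DOWN"))) {
    stop("direction must be UP or DOWN")
  }
  ratio <- if ("ratio" %in% names(tab)) {
    stats::setNames(as.numeric(tab$ratio), tab$gene)
  }
  query_signature(up_degs = tab$gene[dirn == "UP"],
                  down_degs = tab$gene[dirn == "DOWN"],
                  gene_ratio = ratio, meta = meta)
}
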