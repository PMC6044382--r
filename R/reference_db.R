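#' Build a rank vector from a z-score profile
#'
#' Ranks genes by differential-expression z-score in descending order, so rank
#' 1 is the most strongly up-regulated gene. Exact ties in z are broken in
#' favour of the gene with the higher absolute expression level when an
#' expression vector is available; any residual ties are broken by position in
#' the landmark gene list, which keeps rank matrices fully reproducible.
#'
#' @param z numeric vector of z-scores, one per landmark gene.
#' @param expr optional numeric vector of non-negative expression levels of the
#'   same length, used only to break exact ties in `z`.
#' @return integer vector of ranks (a permutation of `1:length(z)`).
#' @examples
#' build_rank_vector(c(2, 2, -1), expr = c(100, 200, 10))  # 2 1 3
#' @export
build_rank_vector <- function(z, expr = NULL) {
  if (length(z) < 1L) stop("'z' must have length >= 1")
  if (!all(is.finite(z))) stop("'z' contains non-finite values")
  if (!is.null(expr)) {
    if (length(expr) != length(z)) stop("'expr' must match 'z' in length")
    if (!all(is.finite(expr))) stop("'expr' contains non-finite values")
    ord <- order(-z, -expr, seq_along(z))
  } else {
    ord <- order(-z, seq_along(z))
  }
  rank <- integer(length(z))
  rank[ord] <- seq_along(z)
  rank
}

#' Up- and down-regulated gene sets of a perturbation record
#'
#' Genes with z >= threshold form the up-regulated set and genes with
#' z <= -threshold the down-regulated set (boundaries inclusive). The default
#' threshold of 2 is the conventional significance cutoff for perturbation
#' z-scores.
#'
#' @param z named numeric vector of z-scores (names are gene symbols).
#' @param threshold positive z-score cutoff.
#' @return list with character vectors `up_set` and `down_set` and the
#'   `threshold` used.
#' @export
regulated_sets <- function(z, threshold = 2) {
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0) {
    stop("'threshold' must be a single positive number")
  }
  genes <- names(z)
  if (is.null(genes)) stop("'z' must be named by gene symbol")
  list(up_set = genes[z >= threshold],
       down_set = genes[z <= -threshold],
       threshold = threshold)
}

valid_pert_types <- c("knockdown", "overexpression", "ligand", "compound")
genetic_pert_types <- c("knockdown", "overexpression", "ligand")

#' Construct a perturbation reference database
#'
#' Bundles a perturbation metadata table with a landmark-gene x record z-score
#' matrix (and an optional same-shape expression matrix used for rank
#' tie-breaking) and precomputes, per record, the descending-z rank vector and
#' the |z| >= threshold regulated gene sets.
#'
#' @param meta data.frame with columns `record_id`, `pert_id`, `pert_type`,
#'   `target_gene`, `pert_name`, `cell_line`. `pert_type` must be one of
#'   `"knockdown"`, `"overexpression"`, `"ligand"`, `"compound"`; genetic
#'   perturbations must carry a non-empty `target_gene`, compounds must not.
#' @param zscore numeric matrix, rows = landmark genes (rownames), columns =
#'   records in `meta$record_id` order (colnames).
#' @param expr optional numeric matrix of non-negative expression values with
#'   identical dimnames, used to break z-score ties when ranking.
#' @param z_threshold z-score cutoff defining the regulated sets.
#' @return an object of class `reference_db`.
#' @export
reference_db <- function(meta, zscore, expr = NULL, z_threshold = 2) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("record_id", "pert_id", "pert_type", "target_gene",
                "pert_name", "cell_line")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("meta is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  meta$record_id <- as.character(meta$record_id)
  if (anyDuplicated(meta$record_id)) stop("duplicate record_id in meta")
  bad_type <- setdiff(unique(meta$pert_type), valid_pert_types)
  if (length(bad_type)) {
    stop("unknown pert_type: ", paste(bad_type, collapse = ", "))
  }
  zscore <- as.matrix(zscore)
  if (is.null(rownames(zscore)) || is.null(colnames(zscore))) {
    stop("zscore matrix must have gene rownames and record colnames")
  }
  if (anyDuplicated(rownames(zscore))) stop("duplicate landmark gene symbols")
  if (ncol(zscore) != nrow(meta) ||
      !setequal(colnames(zscore), meta$record_id)) {
    stop("zscore columns do not match meta record_id (dimension mismatch)")
  }
  zscore <- zscore[, meta$record_id, drop = FALSE]
  if (!all(is.finite(zscore))) stop("zscore matrix contains non-finite values")
  genetic <- meta$pert_type %in% genetic_pert_types
  tg <- meta$target_gene
  tg[is.na(tg)] <- ""
  if (any(genetic & tg == "")) {
    stop("genetic-perturbation records must have a target_gene")
  }
  if (!is.null(expr)) {
    expr <- as.matrix(expr)
    if (!identical(dim(expr), dim(zscore))) {
      stop("expr matrix dimensions do not match zscore (dimension mismatch)")
    }
    if (!setequal(rownames(expr), rownames(zscore)) ||
        !setequal(colnames(expr), colnames(zscore))) {
      stop("expr dimnames do not match zscore")
    }
    expr <- expr[rownames(zscore), colnames(zscore), drop = FALSE]
    if (any(expr < 0)) stop("expr values must be non-negative")
  }
  genes <- rownames(zscore)
  n <- length(genes)
  rank <- matrix(0L, n, ncol(zscore), dimnames = dimnames(zscore))
  regulated <- vector("list", ncol(zscore))
  names(regulated) <- colnames(zscore)
  for (j in seq_len(ncol(zscore))) {
    zj <- zscore[, j]
    names(zj) <- genes
    rank[, j] <- build_rank_vector(zj, expr = if (!is.null(expr)) expr[, j])
    regulated[[j]] <- regulated_sets(zj, threshold = z_threshold)
  }
  structure(list(landmark_genes = genes, meta = meta, zscore = zscore,
                 expr = expr, rank = rank, regulated = regulated,
                 z_threshold = z_threshold),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Perturbation reference database\n")
  cat(sprintf("  %d landmark genes, %d records\n",
              length(x$landmark_genes), nrow(x$meta)))
  tab <- table(x$meta$pert_type)
  cat("  records by perturbation type:\n")
  for (nm in names(tab)) cat(sprintf("    %-15s %d\n", nm, tab[[nm]]))
  cat(sprintf("  regulated-set z threshold: +/-%g\n", x$z_threshold))
  invisible(x)
}

#' Load a reference database from tab-separated files
#'
#' Reads the metadata table and the z-score matrix (plus an optional
#' expression matrix) and assembles an indexed [reference_db()]. Matrices may
#' be plain TSV (first column = gene symbol, one column per record) or GCT
#' v1.2/1.3 text.
#'
#' @param meta_path path to `reference_meta.tsv`.
#' @param zscore_path path to the z-score matrix (TSV or GCT text).
#' @param expr_path optional path to the expression matrix.
#' @param z_threshold z-score cutoff for the regulated sets.
#' @return a `reference_db` object.
#' @export
load_reference <- function(meta_path, zscore_path, expr_path = NULL,
                           z_threshold = 2) {
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  zscore <- read_matrix_auto(zscore_path)
  expr <- if (!is.null(expr_path)) read_matrix_auto(expr_path)
  reference_db(meta, zscore, expr = expr, z_threshold = z_threshold)
}

#' Write a reference database as a TSV triple
#'
#' Emits `reference_meta.tsv`, `reference_zscore.tsv` and, when expression
#' data are present, `reference_expr.tsv` into `dir`. The output round-trips
#' through [load_reference()].
#'
#' @param db a `reference_db` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_reference <- function(db, dir) {
  stopifnot(inherits(db, "reference_db"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(meta = file.path(dir, "reference_meta.tsv"),
             zscore = file.path(dir, "reference_zscore.tsv"))
  utils::write.table(db$meta, paths[["meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gene_matrix(db$zscore, paths[["zscore"]])
  if (!is.null(db$expr)) {
    paths <- c(paths, expr = file.path(dir, "reference_expr.tsv"))
    write_gene_matrix(db$expr, paths[["expr"]])
  }
  invisible(paths)
}

write_gene_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_auto <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.2") || startsWith(first, "#1.3")) {
    read_gct(path)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
  }
}

#' Read a GCT v1.2/1.3 text matrix
#'
#' Parses the text GCT dialect: a version line, a dimension line, then a table
#' whose first column is the row (gene) identifier. Extra annotation columns
#' (the `Description` column of v1.2, or the row-metadata columns declared on
#' the v1.3 dimension line) are dropped.
#'
#' @param path path to a `.gct` file.
#' @return numeric matrix with gene rownames and record colnames.
#' @export
read_gct <- function(path) {
  version <- readLines(path, n = 1L)
  dims <- scan(path, what = integer(), skip = 1L, nlines = 1L, quiet = TRUE)
  if (startsWith(version, "#1.3")) {
    if (length(dims) < 4L) stop("malformed GCT 1.3 dimension line")
    n_row_meta <- dims[3L]
  } else if (startsWith(version, "#1.2")) {
    n_row_meta <- 1L  # the Description column
  } else {
    stop("unsupported GCT version: ", version)
  }
  tab <- utils::read.delim(path, skip = 2L, stringsAsFactors = FALSE,
                           check.names = FALSE)
  # v1.3 has n_col_meta extra header rows under the column ids; drop them
  if (startsWith(version, "#1.3") && dims[4L] > 0L) {
    tab <- tab[-seq_len(dims[4L]), , drop = FALSE]
  }
  keep <- setdiff(seq_along(tab), 1L + seq_len(n_row_meta))
  m <- as.matrix(tab[, keep[-1L], drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  if (nrow(m) != dims[1L] || ncol(m) != dims[2L]) {
    stop("GCT dimension line does not match table")
  }
  m
}
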