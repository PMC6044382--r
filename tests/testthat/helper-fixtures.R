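# Small hand-built fixtures shared across test files.

# Reference database over 5 genes with one knockdown pair, one
# overexpression record and one compound record.
toy_reference <- function() {
  genes <- c("A", "B", "C", "D", "E")
  z <- cbind(
    K1 = c(-3.0,  2.5,  0.1, -0.2, 0.4),   # knockdown of A, up-regulates B
    K2 = c(-2.8,  2.2, -0.4,  0.3, 0.1),   # second shRNA for A
    OV = c( 0.2, -2.1,  3.0,  0.5, 0.0),   # overexpression of C
    CP = c(-2.5,  2.0,  0.2,  0.1, 0.3))   # compound record
  rownames(z) <- genes
  meta <- data.frame(
    record_id = c("K1", "K2", "OV", "CP"),
    pert_id = c("sh_A_1", "sh_A_2", "oe_C_1", "cp_1"),
    pert_type = c("knockdown", "knockdown", "overexpression", "compound"),
    target_gene = c("A", "A", "C", ""),
    pert_name = c("A", "A", "C", "etoposide"),
    cell_line = c("HT29", "HT29", "A375", "HT29"),
    stringsAsFactors = FALSE)
  reference_db(meta, z)
}

toy_query <- function() {
  query_signature(up_degs = c("B", "C"), down_degs = c("A", "D"),
                  gene_ratio = c(A = 0.25, B = 4, C = 2.5, D = 0.4, E = 1),
                  meta = list(name = "etoposide"))
}

# A weighted two-source network whose HITS solution is known in closed form:
# u points to d1, d2, d3 and v points to d1 with unit weights, so
# hub(u) = 1 and hub(v) = sqrt(2) - 1.
star_network <- function() {
  edges <- data.frame(
    source = c("u", "u", "u", "v"),
    target = c("d1", "d2", "d3", "d1"),
    direction = "up",
    supporting_records = "r",
    weight = 1, stringsAsFactors = FALSE)
  nodes <- data.frame(gene = c("u", "v", "d1", "d2", "d3"),
                      direction = NA_character_, ratio = NA_real_,
                      is_upstream = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, upstream = NULL,
                 cutoff_used = NA_real_), class = "deg_network")
}

# Run the whole pipeline on the default synthetic conditions for one seed
# and return the fit together with the planted truth.
synthetic_run <- function(seed, ...) {
  spec <- planted_network_spec(seed = seed, ...)
  db <- generate_reference(spec)
  q <- generate_query(spec)
  rt <- treatment_control_ratio(q$treated, q$control)
  sig <- call_degs(rt, meta = list(name = spec$compound_name))
  fit <- suppressMessages(degnet(sig, db))
  list(spec = spec, db = db, query = q, signature = sig, fit = fit)
}
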