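make_scores <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(record_id = r[[1]], pert_id = r[[2]], pert_type = r[[3]],
               target_gene = r[[4]], pert_name = r[[4]], cell_line = "HT29",
               ks_up = NA_real_, ks_down = NA_real_,
               score = as.numeric(r[[5]]), unscored = FALSE,
               stringsAsFactors = FALSE)
  }))
}

test_that("upstream selection enforces the four rules", {
  q <- query_signature(up_degs = "A", down_degs = c("B", "C"),
                       gene_ratio = c(A = 3, B = 0.4, C = 0.3))
  scores <- make_scores(
    list("r1", "p1", "knockdown", "B", 0.5),       # kept
    list("r2", "p2", "knockdown", "B", 0.4),       # kept (2nd shRNA for B)
    list("r3", "p1", "knockdown", "B", 0.45),      # same (B, p1): loses to r1
    list("r4", "p3", "knockdown", "C", 0.6),       # only one shRNA id for C
    list("r5", "p4", "overexpression", "A", 0.2),  # below cutoff
    list("r6", "p5", "knockdown", "A", 0.9))       # A is an UP DEG
  up <- select_upstream(scores, 0.3, q)
  expect_setequal(up$record_id, c("r1", "r2"))
  expect_equal(attr(up, "filter_counts"),
               c(genetic = 6, cutoff = 5, direction = 4, dedup = 3,
                 min_pert_ids = 2))
  # overexpression/ligand genes must be UP DEGs and need no shRNA pair
  scores2 <- make_scores(list("r7", "p7", "overexpression", "A", 0.8),
                         list("r8", "p8", "ligand", "A", 0.5),
                         list("r9", "p9", "overexpression", "B", 0.8))
  up2 <- select_upstream(scores2, 0.3, q)
  expect_setequal(up2$record_id, c("r7", "r8"))
  # compounds are never upstream candidates
  scores3 <- make_scores(list("r10", "cp", "compound", "", 0.99))
  expect_equal(nrow(select_upstream(scores3, 0.3, q)), 0)
})

test_that("downstream connection intersects regulated sets with DEGs", {
  db <- toy_reference()
  # K1: up_set {B}, down_set {A}; OV: up_set {C}, down_set {B}
  q <- query_signature(up_degs = c("B", "C"), down_degs = c("A", "D"),
                       gene_ratio = c(A = 0.2, B = 4, C = 3, D = 0.4))
  upstream <- data.frame(record_id = c("K1", "K2"), pert_id = c("sh_A_1",
                         "sh_A_2"), pert_type = "knockdown",
                         target_gene = "A", stringsAsFactors = FALSE)
  e <- connect_downstream(upstream, db, q)
  # A -> B (up) from both records, A -> A self loop from down_set
  expect_setequal(paste(e$source, e$target, e$direction),
                  c("A B up", "A A down", "A B up", "A A down"))
  # direction mismatch produces no edge: B is an UP DEG, OV down-regulates B
  upstream_ov <- data.frame(record_id = "OV", pert_id = "oe_C_1",
                            pert_type = "overexpression", target_gene = "C",
                            stringsAsFactors = FALSE)
  q2 <- query_signature(up_degs = c("B", "C"), down_degs = "D",
                        gene_ratio = c(B = 4, C = 3, D = 0.4))
  e2 <- connect_downstream(upstream_ov, db, q2)
  expect_equal(nrow(e2), 1)  # only C -> C (up), no C -> B
  expect_equal(e2$target, "C")
  # intersection mode keeps only targets supported by every record
  db2 <- local({
    genes <- c("A", "B", "C")
    z <- cbind(K1 = c(-3, 2.5, 2.5), K2 = c(-3, 2.5, 0))
    rownames(z) <- genes
    meta <- data.frame(record_id = c("K1", "K2"),
                       pert_id = c("p1", "p2"), pert_type = "knockdown",
                       target_gene = "A", pert_name = "A", cell_line = "X",
                       stringsAsFactors = FALSE)
    reference_db(meta, z)
  })
  q3 <- query_signature(up_degs = c("B", "C"), down_degs = "A",
                        gene_ratio = c(A = 0.2, B = 4, C = 3))
  up3 <- data.frame(record_id = c("K1", "K2"), pert_id = c("p1", "p2"),
                    pert_type = "knockdown", target_gene = "A",
                    stringsAsFactors = FALSE)
  e_union <- connect_downstream(up3, db2, q3, combine = "union")
  e_int <- connect_downstream(up3, db2, q3, combine = "intersection")
  expect_true("C" %in% e_union$target)
  expect_false("C" %in% e_int$target)   # only K1 supports A -> C
  expect_true("B" %in% e_int$target)    # both records support A -> B
})

test_that("graph simplification removes loops and merges parallels", {
  e <- data.frame(source = c("G", "G", "G"), target = c("G", "A", "A"),
                  direction = c("down", "up", "up"),
                  record_id = c("r1", "r1", "r2"), stringsAsFactors = FALSE)
  net <- simplify_graph(e)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$supporting_records, "r1;r2")
  expect_setequal(net$nodes$gene, c("G", "A"))
  # an upstream candidate with no surviving edge stays as an isolated node
  up <- data.frame(record_id = "r9", pert_id = "p9", pert_type = "knockdown",
                   target_gene = "Z", stringsAsFactors = FALSE)
  net2 <- simplify_graph(e[0, ], upstream = up)
  expect_equal(net2$nodes$gene, "Z")
  expect_equal(nrow(net2$edges), 0)
})

test_that("random multigraphs simplify to the set-based dedup", {
  set.seed(21)
  for (i in 1:20) {
    m <- sample(5:40, 1)
    e <- data.frame(source = sample(LETTERS[1:6], m, replace = TRUE),
                    target = sample(LETTERS[1:6], m, replace = TRUE),
                    direction = "up",
                    record_id = sample(paste0("r", 1:8), m, replace = TRUE),
                    stringsAsFactors = FALSE)
    net <- simplify_graph(e)
    keep <- e[e$source != e$target, ]
    expected_pairs <- unique(paste(keep$source, keep$target))
    expect_setequal(paste(net$edges$source, net$edges$target), expected_pairs)
    for (j in seq_len(nrow(net$edges))) {
      sel <- keep$source == net$edges$source[j] &
        keep$target == net$edges$target[j]
      expect_setequal(strsplit(net$edges$supporting_records[j], ";")[[1]],
                      unique(keep$record_id[sel]))
    }
  }
})

test_that("fitted networks respect the structural invariants", {
  run <- synthetic_run(5)
  fit <- run$fit
  e <- fit$network$edges
  # every edge target is a query DEG moving in the edge's direction
  up_e <- e$target[e$direction == "up"]
  down_e <- e$target[e$direction == "down"]
  expect_true(all(up_e %in% run$signature$up_degs))
  expect_true(all(down_e %in% run$signature$down_degs))
  expect_true(all(e$source != e$target))
  expect_equal(anyDuplicated(paste(e$source, e$target)), 0)
  # knockdown-derived sources carry >= 2 distinct perturbagen ids
  kd <- fit$upstream[fit$upstream$pert_type == "knockdown", ]
  for (g in unique(kd$target_gene)) {
    expect_gte(length(unique(kd$pert_id[kd$target_gene == g])), 2)
  }
})

test_that("raising the cutoff only shrinks the network", {
  run <- synthetic_run(6)
  cuts <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  prev_nodes <- NULL
  prev_edges <- NULL
  for (ct in cuts) {
    fit <- suppressMessages(degnet(run$signature, run$db, cutoff = ct))
    nodes <- fit$network$nodes$gene
    edges <- paste(fit$network$edges$source, fit$network$edges$target)
    if (!is.null(prev_nodes)) {
      expect_true(all(nodes %in% prev_nodes))
      expect_true(all(edges %in% prev_edges))
    }
    prev_nodes <- nodes
    prev_edges <- edges
  }
})
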