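test_that("delta penalties are coverage ratios capped at one", {
  q <- query_signature(up_degs = paste0("u", 1:50), down_degs = "d1",
                       gene_ratio = stats::setNames(
                         c(rep(3, 50), 0.2), c(paste0("u", 1:50), "d1")))
  reg <- list(up_set = paste0("x", 1:200), down_set = character())
  d <- compute_delta(reg, q)
  expect_equal(d[["delta_up"]], 0.25)
  expect_equal(d[["delta_down"]], 0)       # empty down set is vacuous
  reg2 <- list(up_set = paste0("x", 1:10), down_set = paste0("y", 1:2))
  d2 <- compute_delta(reg2, q)
  expect_equal(d2[["delta_up"]], 1)        # 50/10 capped
  expect_equal(d2[["delta_down"]], 0.5)
  # landmark-restricted numerator
  d3 <- compute_delta(reg2, q, landmark_genes = c(paste0("u", 1:5), "d1"))
  expect_equal(d3[["delta_up"]], 0.5)      # 5/10
})

test_that("edge weights are alpha times the best matching delta", {
  db <- local({
    genes <- paste0("g", 1:8)
    z <- cbind(r1 = c(-4, rep(2.5, 4), 0, 0, 0),    # up-regulates g2..g5
               r2 = c(-4, 2.5, 2.5, 0, 0, 0, 0, 0)) # up-regulates g2..g3
    rownames(z) <- genes
    meta <- data.frame(record_id = c("r1", "r2"), pert_id = c("p1", "p2"),
                       pert_type = "knockdown", target_gene = "g1",
                       pert_name = "g1", cell_line = "X",
                       stringsAsFactors = FALSE)
    reference_db(meta, z)
  })
  q <- query_signature(up_degs = "g2", down_degs = "g1",
                       gene_ratio = c(g1 = 0.25, g2 = 4))
  e <- data.frame(source = "g1", target = "g2", direction = "up",
                  supporting_records = "r1;r2", weight = NA_real_,
                  stringsAsFactors = FALSE)
  net <- structure(list(nodes = data.frame(gene = c("g1", "g2"),
                                           direction = c("down", "up"),
                                           ratio = c(0.25, 4),
                                           is_upstream = c(TRUE, FALSE)),
                        edges = e, upstream = NULL, cutoff_used = NA_real_),
                   class = "deg_network")
  # deltas: r1 gives 1/4, r2 gives 1/2 -> max 0.5; alpha raw = 0.25
  w <- assign_weights(net, q, db)
  expect_equal(w$edges$weight, 0.25 * 0.5)
  # symmetric alpha turns the 0.25 ratio into 4
  ws <- assign_weights(net, q, db, alpha_mode = "symmetric")
  expect_equal(ws$edges$weight, 4 * 0.5)
  # a missing alpha is an error
  q2 <- query_signature(up_degs = "g2", down_degs = character(),
                        gene_ratio = c(g2 = 4))
  expect_error(assign_weights(net, q2, db), "alpha")
})

test_that("hub scores match the closed-form two-source network", {
  hs <- hub_scores(star_network())
  expect_equal(hs$hub[["u"]], 1)
  expect_equal(hs$hub[["v"]], sqrt(2) - 1, tolerance = 1e-8)
  expect_equal(unname(hs$hub[c("d1", "d2", "d3")]), c(0, 0, 0))
  expect_true(hs$converged)
  # single edge: pure hub and pure authority
  W <- matrix(c(0, 7, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("u", "d"), c("u", "d")))
  hs2 <- hub_scores(W)
  expect_equal(unname(hs2$hub), c(1, 0))
  expect_equal(unname(hs2$authority), c(0, 1))
})

test_that("an edge-free network scores all zeros", {
  up <- data.frame(record_id = "r", pert_id = "p", pert_type = "knockdown",
                   target_gene = "Z", stringsAsFactors = FALSE)
  net <- simplify_graph(data.frame(source = character(), target = character(),
                                   direction = character(),
                                   record_id = character()), upstream = up)
  hs <- hub_scores(net)
  expect_equal(unname(hs$hub), 0)
  expect_true(hs$converged)
})

test_that("power iteration matches the dense eigen oracle", {
  set.seed(55)
  for (i in 1:50) {
    W <- random_digraph(sample(3:30, 1))
    hs <- hub_scores(W)
    o <- hits_oracle(W)
    expect_lt(max(abs(hs$hub - o$hub)), 1e-8)
    expect_lt(max(abs(hs$authority - o$authority)), 1e-8)
  }
})

test_that("hub scores are scale invariant and max-normalised", {
  set.seed(66)
  for (i in 1:20) {
    W <- random_digraph(sample(4:20, 1))
    hs <- hub_scores(W)
    expect_identical(max(hs$hub), 1)
    hs_scaled <- hub_scores(17.3 * W)
    expect_equal(hs$hub, hs_scaled$hub, tolerance = 1e-9)
  }
})

test_that("hub scores agree with the igraph implementation", {
  set.seed(14)
  W <- random_digraph(12)
  hs <- hub_scores(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                           weighted = TRUE)
  ig <- igraph::hits_scores(g, scale = TRUE)
  expect_equal(unname(hs$hub[igraph::V(g)$name]), unname(ig$hub),
               tolerance = 1e-6)
})

test_that("adding an out-edge never lowers a node's pre-normalised hub rank", {
  set.seed(91)
  for (i in 1:20) {
    W <- random_digraph(10, p = 0.2)
    zero <- which(W == 0 & row(W) != col(W), arr.ind = TRUE)
    if (!nrow(zero)) next
    pick <- zero[sample(nrow(zero), 1), ]
    # pre-normalisation hub values via the principal eigenvector equation
    pre_hub <- function(M) {
      e <- eigen(M %*% t(M), symmetric = TRUE)
      v <- abs(e$vectors[, 1])
      v / sqrt(sum(v^2))
    }
    h0 <- pre_hub(W)
    W2 <- W
    W2[pick[1], pick[2]] <- 1
    h1 <- pre_hub(W2)
    expect_gte(h1[pick[1]] + 1e-9, h0[pick[1]])
  }
})
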