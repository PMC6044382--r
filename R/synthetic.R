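#' Specification of a synthetic perturbation reference with planted hierarchy
#'
#' Describes a small LINCS-like reference database plus a matched drug-
#' treatment query in which a known regulatory hierarchy is planted, so the
#' whole pipeline — scoring, cutoff selection, network rules and hub
#' recovery — can be exercised end to end without any external data.
#'
#' The default hierarchy has one master regulator (`G001`, knocked down by
#' the simulated drug) that activates 29 direct targets and represses one
#' (`G003`); `G002` and `G003` are second-level regulators with their own
#' target blocks. Every regulator receives two independent shRNA knockdown
#' records (so knockdown candidates can pass the two-perturbagen-id
#' off-target filter), up-regulated second-level regulators additionally
#' receive overexpression and ligand records, decoy genes contribute
#' noise-only knockdown records, and compound records named
#' `compound_name` carry noisy copies of the drug's effect profile so ROC
#' cutoff selection has same-name positives. Compound records get twice the
#' genetic noise level: chemical perturbations are noisier than clean
#' genetic ones.
#'
#' @param n_landmark number of landmark genes.
#' @param regulators list of regulator descriptions, each a list with
#'   elements `gene`, `level` (1 = hit directly by the drug), `targets`
#'   (character vector) and `effect` (+1 activates / -1 represses, recycled
#'   over targets).
#' @param effect_z mean |z| of true targets in perturbation records.
#' @param noise_sd standard deviation of the null z-scores.
#' @param effect_fold planted expression fold change of affected genes in
#'   the query (ratio `effect_fold` for up, `1/effect_fold` for down).
#' @param query_noise_sd log-scale noise of the treated/control ratios
#'   (0 gives a noise-free query whose DEG set equals the planted one).
#' @param n_shrna_per_gene independent shRNA ids per knocked-down gene
#'   (must be >= 2).
#' @param n_compound_records number of same-name compound records.
#' @param compound_name name shared by the drug query and its compound
#'   records.
#' @param n_decoy_genes number of non-DEG genes with noise-only knockdown
#'   records.
#' @param cell_line cell line label of the planted records.
#' @param seed integer seed; all generator output is a pure function of the
#'   spec including the seed.
#' @return object of class `planted_network_spec`.
#' @export
planted_network_spec <- function(n_landmark = 200,
                                 regulators = NULL,
                                 effect_z = 4,
                                 noise_sd = 1,
                                 effect_fold = 4,
                                 query_noise_sd = 0.1,
                                 n_shrna_per_gene = 2,
                                 n_compound_records = 3,
                                 compound_name = "drugA",
                                 n_decoy_genes = 4,
                                 cell_line = "HT29",
                                 seed = 1) {
  genes <- sprintf("G%03d", seq_len(n_landmark))
  if (is.null(regulators)) {
    if (n_landmark < 120) stop("default hierarchy needs >= 120 landmark genes")
    regulators <- list(
      list(gene = "G001", level = 1L, targets = genes[2:31],
           effect = c(1, -1, rep(1, 28))),   # G003 is repressed
      list(gene = "G002", level = 2L, targets = genes[32:46], effect = 1),
      list(gene = "G003", level = 2L, targets = genes[47:56], effect = 1))
  }
  for (r in regulators) {
    if (!all(r$targets %in% genes)) stop("regulator targets outside landmark genes")
    if (r$gene %in% r$targets) stop("a regulator cannot target itself")
  }
  if (n_shrna_per_gene < 2L) {
    stop("n_shrna_per_gene must be >= 2 so knockdowns can pass the off-target filter")
  }
  structure(list(n_landmark = n_landmark, landmark_genes = genes,
                 regulators = regulators, effect_z = effect_z,
                 noise_sd = noise_sd, effect_fold = effect_fold,
                 query_noise_sd = query_noise_sd,
                 n_shrna_per_gene = n_shrna_per_gene,
                 n_compound_records = n_compound_records,
                 compound_name = compound_name,
                 n_decoy_genes = n_decoy_genes,
                 cell_line = cell_line, seed = seed),
            class = "planted_network_spec")
}

# Signed effect (+1/-1/0 per landmark gene) of perturbing `root` in the
# given direction, propagated down the planted hierarchy (levels processed
# in order; a gene's sign is set once and never overwritten).
planted_effect <- function(spec, root, direction) {
  e <- stats::setNames(rep(0, spec$n_landmark), spec$landmark_genes)
  e[root] <- direction
  regs <- spec$regulators[order(vapply(spec$regulators, `[[`, 0, "level"))]
  for (r in regs) {
    if (e[r$gene] == 0) next
    eff <- rep(r$effect, length.out = length(r$targets))
    for (k in seq_along(r$targets)) {
      t <- r$targets[k]
      if (e[t] == 0) e[t] <- e[r$gene] * eff[k]
    }
  }
  e
}

# The simulated drug knocks down the first level-1 regulator.
drug_effect <- function(spec) {
  planted_effect(spec, master_regulator(spec), -1)
}

master_regulator <- function(spec) {
  levels <- vapply(spec$regulators, `[[`, 0, "level")
  spec$regulators[[which.min(levels)]]$gene
}

#' Generate the synthetic perturbation reference database
#'
#' Emits, per regulator, `n_shrna_per_gene` knockdown records whose z
#' profiles propagate the loss of that regulator through the planted
#' hierarchy (plus Gaussian noise), overexpression and ligand records for
#' regulators that the drug pushes up, noise-only knockdown records for the
#' decoy genes, and `n_compound_records` compound records named
#' `compound_name` carrying noisy copies of the drug effect. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [planted_network_spec()].
#' @return a `reference_db`.
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "planted_network_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  n <- spec$n_landmark
  genes <- spec$landmark_genes
  drug <- drug_effect(spec)
  meta <- list(); zcols <- list()
  add <- function(pert_id, pert_type, target, name, z) {
    i <- length(meta) + 1L
    meta[[i]] <<- data.frame(record_id = sprintf("R%03d", i),
                             pert_id = pert_id, pert_type = pert_type,
                             target_gene = target, pert_name = name,
                             cell_line = spec$cell_line,
                             stringsAsFactors = FALSE)
    zcols[[i]] <<- z
  }
  for (r in spec$regulators) {
    kd <- planted_effect(spec, r$gene, -1)
    for (k in seq_len(spec$n_shrna_per_gene)) {
      add(sprintf("shRNA_%s_%d", r$gene, k), "knockdown", r$gene, r$gene,
          spec$effect_z * kd + stats::rnorm(n, 0, spec$noise_sd))
    }
    if (drug[r$gene] > 0) {  # drug-up regulators get overexpression + ligand
      oe <- planted_effect(spec, r$gene, +1)
      add(sprintf("OE_%s_1", r$gene), "overexpression", r$gene, r$gene,
          spec$effect_z * oe + stats::rnorm(n, 0, spec$noise_sd))
      add(sprintf("LIG_%s_1", r$gene), "ligand", r$gene, r$gene,
          spec$effect_z * oe + stats::rnorm(n, 0, spec$noise_sd))
    }
  }
  if (spec$n_decoy_genes > 0) {
    reg_genes <- vapply(spec$regulators, `[[`, "", "gene")
    affected <- names(drug)[drug != 0]
    pool <- setdiff(genes, c(affected, reg_genes))
    decoys <- utils::tail(pool, spec$n_decoy_genes)
    for (g in decoys) {
      for (k in seq_len(spec$n_shrna_per_gene)) {
        z <- stats::rnorm(n, 0, spec$noise_sd)
        z[match(g, genes)] <- -spec$effect_z  # knockdown silences its target
        add(sprintf("shRNA_%s_%d", g, k), "knockdown", g, g, z)
      }
    }
  }
  for (k in seq_len(spec$n_compound_records)) {
    add(sprintf("CP_%d", k), "compound", "", spec$compound_name,
        spec$effect_z * drug + stats::rnorm(n, 0, 2 * spec$noise_sd))
  }
  meta <- do.call(rbind, meta)
  z <- do.call(cbind, zcols)
  dimnames(z) <- list(genes, meta$record_id)
  expr <- matrix(100 * exp(stats::rnorm(length(z), 0, 0.3)), nrow(z), ncol(z),
                 dimnames = dimnames(z))
  reference_db(meta, z, expr = expr)
}

#' Generate the matched synthetic drug-treatment query
#'
#' Control intensities are lognormal; genes the drug represses start from a
#' higher baseline (repression is only measurable for well-expressed genes),
#' keeping all intensities above the default floor of 50. Treated
#' intensities multiply the control by the planted fold change (up
#' `effect_fold`, down `1/effect_fold`) with lognormal noise
#' `query_noise_sd`, so the default DEG thresholds of 2 and 0.5 recover the
#' planted gene set.
#'
#' @param spec a [planted_network_spec()].
#' @return list with named numeric vectors `treated` and `control`, the
#'   planted signed effect `signed_effect` (+1/-1/0 per gene), and
#'   `ground_truth_hub`, the master regulator the pipeline should rank as
#'   the top hub.
#' @export
generate_query <- function(spec) {
  stopifnot(inherits(spec, "planted_network_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed + 1000003L)
  e <- drug_effect(spec)
  n <- spec$n_landmark
  baseline <- ifelse(e < 0, 400, 100)
  control <- baseline * exp(stats::rnorm(n, 0, 0.2))
  ratio <- spec$effect_fold^e * exp(stats::rnorm(n, 0, spec$query_noise_sd))
  treated <- control * ratio
  names(treated) <- names(control) <- spec$landmark_genes
  list(treated = treated, control = control, signed_effect = e,
       ground_truth_hub = master_regulator(spec))
}

#' Write a complete synthetic run to disk
#'
#' Emits the reference TSV triple, `query_expression.tsv` and
#' `ground_truth.tsv` into `dir`.
#'
#' @param spec a [planted_network_spec()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_synthetic_run <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  db <- generate_reference(spec)
  write_reference(db, dir)
  q <- generate_query(spec)
  utils::write.table(
    data.frame(identifier = names(q$treated), treated = q$treated,
               control = q$control),
    file.path(dir, "query_expression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(q$signed_effect),
               planted_effect = q$signed_effect,
               is_master_regulator = names(q$signed_effect) ==
                 q$ground_truth_hub),
    file.path(dir, "ground_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
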