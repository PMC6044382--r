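---
title: "Reconstructing drug-induced DEG networks and ranking hub genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing drug-induced DEG networks and ranking hub genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degnet)
```

## The problem

A drug treatment changes the expression of hundreds of genes at once. The
list of differentially expressed genes (DEGs) says *what* moved but not
*which gene drove the rest*. Public perturbation compendia such as LINCS
L1000 record, for thousands of genes, what happens to the transcriptome when
that one gene is knocked down, overexpressed or stimulated with a ligand.
degnet uses such a reference to orient edges among the query DEGs — if
knocking down gene A reproduces the drug's signature and significantly moves
gene B in the same direction the drug does, then A sits upstream of B — and
then ranks the DEGs by how much of the network they explain, using weighted
Kleinberg hub scores. The gene with hub score 1 is the most influential gene
of the network.

## The procedure

1. **Connectivity scoring.** Each reference record is summarised by the rank
   of its z-scores in descending order (rank 1 = most up-regulated; exact
   ties are broken towards the gene with the higher expression level, then
   by landmark-list position). For a query with UP tag set of size $t_u$ and
   DOWN tag set of size $t_d$ in a list of $n$ landmark genes, each tag set
   gets the two-sided Kolmogorov–Smirnov statistic
   $a = \max_j (j/t - V_j/n)$, $b = \max_j (V_j/n - (j-1)/t)$, ES $= a$ if
   $a \ge b$ else $-b$, where $V_1 < \dots < V_t$ are the tag positions. The
   record's score is $(\mathrm{ES}_{up} - \mathrm{ES}_{down})/2 \in [-1,1]$
   when the two statistics disagree in sign, and 0 otherwise.
2. **Cutoff selection.** When the reference contains compound records with
   the same name as the query condition, those records are labelled positive
   and everything else negative; the similarity-score ROC curve gives the
   concordance index (floored at 0.5 — an AUC below chance means the two
   data sets are not comparable) and the cutoff maximising Youden's
   $J = \text{sensitivity} + \text{specificity} - 1$. Without usable
   positives the fixed default 0.2 is used, the lower end of the range in
   which estimated cutoffs fall on well-behaved data.
3. **Network rules.** Genetic-perturbation records scoring at or above the
   cutoff propose their target gene as an upstream node, subject to
   direction consistency (a knocked-down gene must be a DOWN DEG; an
   overexpressed or ligand-stimulated gene must be an UP DEG), one best
   record per (gene, perturbagen id), and at least two independent shRNA ids
   per knockdown gene to guard against off-target artifacts. Each retained
   record then connects its target to every query DEG it significantly
   regulates ($|z| \ge 2$) in the query's direction. Self-loops are removed
   and parallel edges merged; an upstream gene whose perturbation passed the
   cutoff but produced no concordant downstream gene stays in the node table
   as an isolated node (it scores 0 regardless, and keeping it makes the
   filter cascade auditable).
4. **Hub scoring.** Edge $u \to v$ gets weight $\alpha \times \delta$:
   $\alpha$ is the upstream gene's treatment/control ratio in the query and
   $\delta$ is the ratio of the number of UP (or DOWN, matching the edge
   direction) query DEGs to the number of landmark genes the supporting
   record up- (or down-) regulates, capped at 1. $\delta$ is a penalty for
   promiscuous records; the cap prevents a sparse record from being rewarded
   rather than merely unpenalised. Hub and authority scores are the
   principal eigenvectors of $WW^\top$ and $W^\top W$, computed by
   deterministic alternating power iteration (all-ones start, sup-norm
   renormalisation, tolerance $10^{-10}$, 1000-iteration cap) and rescaled
   so the top score is exactly 1.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `floor` | 50 | intensity floor applied to both channels before ratios |
| `up_threshold`, `down_threshold` | 2, 0.5 | inclusive DEG ratio cutoffs |
| `z_threshold` | 2 | reference regulated-set cutoff, $|z| \ge 2$ |
| `cutoff_value` | 0.2 | fixed cutoff and auto-mode fallback |
| `scaling` | `"half"` | `"batch_max"` rescales by the scored batch extremes |
| `alpha_mode` | `"raw"` | `"symmetric"` uses $\max(r, 1/r)$ |
| `delta_numerator` | `"all"` | `"landmark_only"` restricts DEG counts |
| `downstream_combine` | `"union"` | `"intersection"` across a gene's records |

Design choices where the convention was genuinely open:

* **Score scaling.** The classical connectivity-map build rescales raw
  scores by the batch maximum/minimum, which makes any fixed cutoff depend
  on what else happened to be scored. The default here divides the raw
  difference by 2, so a cutoff of, say, 0.2 means the same thing for every
  query; the batch-relative behaviour remains available as
  `scaling = "batch_max"`.
* **Alpha for DOWN-DEG sources.** Raw ratios systematically hand DOWN-DEG
  hubs a smaller $\alpha$ ($\le 0.5$ by construction). The default stays
  faithful to "alpha is the signal-intensity ratio"; `alpha_mode =
  "symmetric"` treats 4-fold induction and 4-fold repression equally. Within
  the typical network all upstream knockdown genes carry comparable ratios,
  so the ranking rarely changes, but the choice is logged per run.
* **Downstream union vs intersection.** A knockdown gene retains one record
  per shRNA. Union of their downstream sets is the default: the per-shRNA
  dedup already limits noise, and intersection empties most pairs because
  two shRNAs rarely cross the $|z| \ge 2$ line for identical gene sets.
* **Youden ties.** When several cutoffs achieve the same $J$, the largest
  (most stringent) is chosen, giving smaller, higher-confidence networks.
* **Probe handling.** Probe ratios are averaged per gene on the ratio scale
  (arithmetic mean), before DEG calling by default (`deg_level = "gene"`;
  network nodes are genes). A geometric-mean option and probe-level calling
  exist for sensitivity analyses.
* **FDR transform.** The signed enrichment summary uses base-10 logs; a
  gene set absent from one direction's table contributes $-\log_{10}(1) = 0$
  for that direction, an FDR of exactly 0 borrows the minimum nonzero FDR of
  its own direction's table (not the pooled table), and marginal enrichment
  in both directions sums the two signed values.

## What the synthetic generator emulates

`planted_network_spec()` describes a 200-landmark-gene reference with a
three-regulator hierarchy: a master regulator (`G001`) whose loss the
simulated drug causes, a second-level activated regulator (`G002`), and a
second-level repressed regulator (`G003`) that therefore rises under
treatment. Each regulator gets two independent shRNA knockdown records whose
z profiles propagate the loss through the hierarchy with unit Gaussian
noise around a planted effect of $|z| = 4$ (so a true target crosses the
$|z| \ge 2$ line with probability $\approx 0.977$); drug-up regulators
additionally get overexpression and ligand records; four decoy genes
contribute noise-only knockdowns; and three compound records named like the
query carry the drug's effect profile with twice the genetic noise —
chemical perturbations are noisier than clean genetic ones, and this is
what lets the ROC-estimated cutoff admit the matching genetic records.
Query control intensities are lognormal around 100 (around 400 for genes
the drug represses: repression is only measurable for well-expressed
genes, and this keeps all intensities above the floor of 50); treated
intensities apply a planted 4-fold change with lognormal noise (sd 0.1 on
the log scale), so the default thresholds 2/0.5 recover the planted DEG
set.

What it deliberately does **not** emulate: microarray probe effects, batch
effects, the L1000 deconvolution/inference step, dose and time series,
correlated biological noise, or feedback loops. Passing the planted-hub
test therefore shows the pipeline's rules and scores are implemented
correctly, not that real LINCS-scale data would yield the same hubs.

## Numerical choices and degenerate inputs

* Rank ties are resolved deterministically (expression, then list order),
  so rank matrices are reproducible byte for byte.
* Power iteration is deterministic; an empty network returns all-zero
  scores and `converged = TRUE`; hitting the iteration cap is flagged, and
  the best iterate returned.
* A query with only UP (or only DOWN) DEGs is scored with the missing
  side's statistic set to 0.
* An empty network — no genetic record above the cutoff — is a valid
  result (it happens for real compounds with extreme estimated cutoffs),
  and every writer emits well-formed, empty artifacts.
* The problem sizes used in the test suite (200 landmark genes, ~20
  records, 40 seeds for the recovery study) keep the whole suite within a
  few tens of seconds while leaving the binomial headroom to detect a
  recovery rate below 95%.

## Known limitations

* Upstream candidates are restricted to perturbations catalogued in the
  reference; a true driver with no knockdown/overexpression record can
  never be ranked.
* The c-index floor makes 0.5 both "chance" and "worse than chance";
  provenance of the cutoff (Youden vs fallback) is recorded in
  `roc_report.tsv` so such cases are visible.
* Hub scores are relative to the reconstructed network: an isolated
  upstream gene scores 0 even if its perturbation matched the query well.
* Only the landmark gene space is scored; genes inferred from landmarks
  can be supplied as extra rows of the reference matrices, but nothing in
  the package optimises for that regime.

## A worked run

```{r example}
spec <- planted_network_spec(seed = 7)
db <- generate_reference(spec)
q <- generate_query(spec)
sig <- call_degs(treatment_control_ratio(q$treated, q$control),
                 meta = list(name = spec$compound_name))
fit <- degnet(sig, db)
summary(fit)
q$ground_truth_hub
```
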