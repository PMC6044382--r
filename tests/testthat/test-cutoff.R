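test_that("record labelling matches same-name compounds only", {
  meta <- data.frame(
    pert_type = c("compound", "compound", "knockdown", "compound"),
    pert_name = c("etoposide", " Etoposide ", "etoposide", "gemcitabine"),
    stringsAsFactors = FALSE)
  lab <- label_records("etoposide", meta)
  expect_equal(lab, c(TRUE, TRUE, FALSE, FALSE))  # case/whitespace normalised
  expect_equal(sum(label_records("absent", meta)), 0)
  expect_error(label_records("", meta), "non-empty")
})

test_that("c-index separates, floors at 0.5, and handles ties", {
  expect_equal(c_index(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # positives entirely below negatives: raw AUC 0 floored to 0.5
  expect_identical(c_index(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.5)
  # a tied positive/negative pair counts one half
  expect_equal(c_index(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(c_index(c(1, 2), c(1, 1)), "positive and")
})

test_that("c-index equals the pairwise-comparison oracle", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(round(stats::runif(n), 1))  # coarse grid forces ties
    labels <- c(TRUE, FALSE, stats::runif(n - 2) < 0.4)
    expect_equal(c_index(scores, labels), c_index_oracle(scores, labels))
  }
})

test_that("c-index is invariant under strictly monotone transforms", {
  set.seed(8)
  scores <- stats::rnorm(40)
  labels <- stats::runif(40) < 0.3
  labels[1:2] <- c(TRUE, FALSE)
  base <- c_index(scores, labels)
  expect_equal(c_index(exp(scores), labels), base)
  expect_equal(c_index(scores^3 + 5 * scores, labels), base)
})

test_that("c-index agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- stats::rnorm(60)
  labels <- stats::runif(60) < 0.5
  labels[1:2] <- c(TRUE, FALSE)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(c_index(scores, labels), max(ref, 0.5))
})

test_that("Youden cutoff maximises J and breaks ties upward", {
  y <- youden_cutoff(c(0.9, 0.7, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(y$cutoff, 0.7)
  expect_equal(y$youden_j, 1)
  # tie in J: cutoffs 0.9 and 0.5 both give J = 0.5; the larger is chosen
  y2 <- youden_cutoff(c(0.9, 0.5, 0.7, 0.1), c(1, 1, 0, 0))
  expect_equal(y2$youden_j, 0.5)
  expect_equal(y2$cutoff, 0.9)
  # perfectly interleaved scores leave no discrimination
  y3 <- youden_cutoff(c(4, 3, 2, 1), c(1, 0, 1, 0))
  expect_equal(y3$youden_j, 0.5)
})

test_that("Youden cutoff equals exhaustive threshold enumeration", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(round(stats::runif(n), 1))  # duplicates across classes
    labels <- c(TRUE, FALSE, stats::runif(n - 2) < 0.4)
    y <- youden_cutoff(scores, labels)
    o <- youden_oracle(scores, labels)
    expect_equal(y$youden_j, o$youden_j)
    expect_equal(y$cutoff, o$cutoff)
  }
})

test_that("separable synthetic scores give c-index 1 and a clean split", {
  set.seed(4)
  neg <- stats::rnorm(50)
  pos <- stats::rnorm(10) + 3 * stats::sd(neg) + max(neg) - min(neg)
  scores <- c(pos, neg)
  labels <- rep(c(TRUE, FALSE), c(10, 50))
  expect_equal(c_index(scores, labels), 1)
  y <- youden_cutoff(scores, labels)
  expect_equal(y$youden_j, 1)
  expect_true(all(pos >= y$cutoff) && all(neg < y$cutoff))
})

test_that("cutoff resolution dispatches between ROC and the fallback", {
  run <- synthetic_run(3)
  # auto mode with same-name compounds present uses the Youden cutoff
  rc <- suppressMessages(resolve_cutoff(run$signature, run$db))
  expect_equal(rc$provenance, "youden")
  lab <- label_records(run$spec$compound_name, run$fit$scores)
  expect_equal(rc$cutoff,
               youden_cutoff(run$fit$scores$score, lab)$cutoff)
  # a query name absent from the reference falls back to 0.2
  sig2 <- run$signature
  sig2$meta$name <- "not_in_reference"
  suppressMessages(expect_warning(rc2 <- resolve_cutoff(sig2, run$db),
                                  "no positives"))
  expect_equal(rc2$provenance, "fallback")
  expect_equal(rc2$cutoff, 0.2)
  # fixed mode returns the requested value
  rc3 <- resolve_cutoff(run$signature, run$db, mode = "fixed",
                        fixed_value = 0.3)
  expect_equal(rc3, list(cutoff = 0.3, provenance = "fixed", roc = NULL))
  expect_error(resolve_cutoff(run$signature, run$db, mode = "fixed",
                              fixed_value = 1.5), "fixed_value")
})
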