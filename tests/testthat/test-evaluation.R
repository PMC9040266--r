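test_that("predicted sets use strict thresholding", {
  prof <- structure(list(layers = list(
    layer2 = c(A = 0.6, B = 0.4, C = 0.0))), class = "contribution_profile")
  expect_identical(predicted_set(prof, 2, 0.5), "A")
  expect_identical(predicted_set(prof, 2, 0), c("A", "B"))
  expect_length(predicted_set(prof, 2, 1), 0L)
  expect_identical(predicted_set(prof, 2, 0.4), "A")  # strict: 0.4 excluded
})

test_that("confusion counts equal exhaustive enumeration", {
  scores <- matrix(c(0.9, 0.2,
                     0.6, 0.7), 2, 2, byrow = TRUE,
                   dimnames = list(NULL, c("A", "B")))
  truth <- matrix(c(1, 0,
                    0, 1), 2, 2, byrow = TRUE,
                  dimnames = list(NULL, c("A", "B")))
  cc <- confusion_counts(scores, truth, 0.5)
  expect_equal(cc$TP, c(1, 1))
  expect_equal(cc$FP, c(1, 0))
  expect_equal(cc$FN, c(0, 0))
  expect_equal(cc$TN, c(0, 1))
  expect_true(all(cc$TP + cc$TN + cc$FP + cc$FN == 2))

  # empty predictions at t = 1: TP = FP = 0, FN = biome support
  cc1 <- confusion_counts(scores, truth, 1)
  expect_true(all(cc1$TP == 0 & cc1$FP == 0))
  expect_equal(cc1$FN, unname(colSums(truth)))

  set.seed(19)
  for (rep in 1:20) {
    inst <- random_instance()
    t <- sample(seq(0, 1, 0.01), 1L)
    got <- confusion_counts(inst$scores, inst$truth, t)
    want <- oracle_metrics(inst$scores, inst$truth, t)
    expect_equal(got$TP, want$TP[1, ])
    expect_equal(got$TN, want$TN[1, ])
    expect_equal(got$FP, want$FP[1, ])
    expect_equal(got$FN, want$FN[1, ])
  }
})

test_that("macro curves average per-biome rates with 0/0 exclusions", {
  # one biome: macro equals the biome's own curve
  set.seed(11)
  scores <- matrix(runif(20), 20, 1, dimnames = list(NULL, "A"))
  truth <- matrix(rbinom(20, 1, 0.5), 20, 1, dimnames = list(NULL, "A"))
  truth[1] <- 1; truth[2] <- 0
  rep1 <- eval_report(scores, truth)
  want <- oracle_metrics(scores, truth)
  expect_equal(rep1$TPR, want$TPR, tolerance = 1e-12)
  expect_equal(rep1$FPR, want$FPR, tolerance = 1e-12)

  # two biomes with per-biome TPR 1 and 0 at a threshold average to 0.5
  s2 <- matrix(c(0.9, 0.1,
                 0.1, 0.1), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("A", "B")))
  t2 <- matrix(c(1, 0,
                 0, 1), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("A", "B")))
  r2 <- eval_report(s2, t2, thresholds = 0.5)
  expect_equal(unname(r2$TPR), 0.5)

  # curves are non-increasing in the threshold
  set.seed(23)
  inst <- random_instance()
  r <- eval_report(inst$scores, inst$truth)
  expect_true(all(diff(r$TPR) <= 1e-12))
  expect_true(all(diff(r$FPR) <= 1e-12))
  expect_true(all(r$TP + r$TN + r$FP + r$FN == nrow(inst$scores)))
})

test_that("AUC hits its closed-form anchors", {
  # perfect separation
  n <- 40
  truth <- matrix(0, n, 2, dimnames = list(NULL, c("A", "B")))
  truth[1:20, 1] <- 1; truth[21:40, 2] <- 1
  scores <- truth * 0.9 + (1 - truth) * 0.1
  r <- eval_report(scores, truth)
  expect_equal(r$auc, 1.0, tolerance = 1e-12)
  expect_equal(r$f_max, 1.0, tolerance = 1e-12)

  # constant scores: TPR(t) == FPR(t) everywhere => 0.5
  const <- matrix(0.4, n, 2, dimnames = list(NULL, c("A", "B")))
  rc <- eval_report(const, truth)
  expect_equal(rc$auc, 0.5, tolerance = 1e-12)
  expect_true(rc$auc >= 0 && rc$auc <= 1)
})

test_that("precision/recall/accuracy follow the count formulas", {
  # hand case: TP=1, FP=1, FN=0, TN=2 on 4 samples
  scores <- matrix(c(0.9, 0.8, 0.1, 0.2), 4, 1, dimnames = list(NULL, "A"))
  truth <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(NULL, "A"))
  r <- eval_report(scores, truth)
  s <- precision_recall_accuracy(r, 0.5)
  expect_equal(s$precision, 0.5)
  expect_equal(s$recall, 1.0)
  expect_equal(s$accuracy, 0.75)
  expect_error(precision_recall_accuracy(r, 0.123), "grid")

  # no predictions at t: precision undefined, excluded from the mean
  s99 <- precision_recall_accuracy(r, 0.99)
  expect_true(is.nan(s99$precision) || is.na(s99$precision))
})

test_that("F_max equals an exhaustive threshold scan", {
  set.seed(29)
  for (rep in 1:10) {
    inst <- random_instance()
    r <- eval_report(inst$scores, inst$truth)
    want <- oracle_metrics(inst$scores, inst$truth)
    expect_equal(r$f_max, want$f_max, tolerance = 1e-12)
    expect_equal(r$auc, want$auc, tolerance = 1e-12)
  }
  # degenerate: nothing ever predicted
  z <- matrix(0, 5, 2, dimnames = list(NULL, c("A", "B")))
  tr <- matrix(c(1, 0), 5, 2, byrow = TRUE, dimnames = list(NULL, c("A", "B")))
  expect_warning(rz <- eval_report(z, tr), "F_max")
  expect_equal(rz$f_max, 0)
})

test_that("remolding lifts flat leaf vectors exactly", {
  ont <- build_ontology(c("Root-A-A1", "Root-A-A2", "Root-B-B1"))
  prof <- remold_flat(c("Root-A-A1" = 0.3, "Root-A-A2" = 0.2,
                        "Root-B-B1" = 0.4), ont)
  expect_equal(prof$layers$layer2, c("Root-A" = 0.5, "Root-B" = 0.4))
  expect_equal(prof$layers$layer3[["Root-A-A1"]], 0.3)
  expect_equal(unname(prof$unknown["layer2"]), 1 - 0.9, tolerance = 1e-12)

  chain <- build_ontology("Root-A-A1")
  d <- remold_flat(c("Root-A-A1" = 1.0), chain)
  expect_true(all(unlist(d$layers) == 1.0))

  zero <- remold_flat(c("Root-A-A1" = 0, "Root-A-A2" = 0, "Root-B-B1" = 0),
                      ont)
  expect_true(all(unlist(zero$layers) == 0))
  expect_error(remold_flat(c("Root-X" = 1), ont), "non-leaf|unknown")
})

test_that("remolded score matrices plug into the evaluator", {
  ont <- build_ontology(c("Root-A-A1", "Root-A-A2", "Root-B-B1"))
  labels <- c("Root-A-A1", "Root-B-B1", "Root-A-A2", "Root-A-A1")
  flat <- matrix(0.05, 4, 3,
                 dimnames = list(NULL, c("Root-A-A1", "Root-A-A2", "Root-B-B1")))
  flat[cbind(1:4, match(labels, colnames(flat)))] <- 0.9
  sc <- remold_scores(flat, ont)
  ds <- list(labels = labels)
  ev <- evaluate(sc, ds)
  expect_equal(ev$summary$auc, c(1, 1), tolerance = 1e-12)
  expect_equal(ev$summary$f_max, c(1, 1), tolerance = 1e-12)
  # layer-2 scores are the sums of the children's
  expect_equal(unname(sc$layer2[1, "Root-A"]), 0.95, tolerance = 1e-12)
})

test_that("random-output models sit at the AUC null", {
  ont <- make_toy_ontology(c(2, 2))
  set.seed(31)
  n <- 400
  leaves <- layer_nodes(ont, 3)$lineage
  labels <- sample(leaves, n, replace = TRUE)
  flat <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, leaves))
  ev <- evaluate(remold_scores(flat, ont), list(labels = labels),
                 layers = 3L)
  expect_lt(abs(ev$summary$auc - 0.5), 0.07)
})

test_that("evaluation exports summary, grid, and ROC files", {
  fx <- toy_trained_fit()
  ev <- evaluate(fx$fit$model, fx$ds)
  prefix <- tempfile()
  write_evaluation(ev, prefix)
  expect_true(file.exists(paste0(prefix, ".json")))
  summ <- utils::read.delim(paste0(prefix, ".summary.tsv"))
  expect_identical(names(summ),
                   c("layer", "precision", "recall", "accuracy", "f_max", "auc"))
  roc <- utils::read.delim(paste0(prefix, ".roc.tsv"))
  expect_equal(nrow(roc), 2 * 101)
})
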