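test_that("initialization mirrors the ontology and is seed-reproducible", {
  ont <- make_toy_ontology(c(2, 2))  # layer widths 1/2/4
  vocab <- make_toy_vocabulary(14)
  m1 <- onn_init(ont, vocab, d_ext = 8, d_enc = 4, seed = 9)
  expect_equal(ncol(m1$params$head[[2]]$W), 2L)
  expect_equal(ncol(m1$params$head[[3]]$W), 4L)
  m2 <- onn_init(ont, vocab, d_ext = 8, d_enc = 4, seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- onn_init(ont, vocab, d_ext = 8, d_enc = 4, seed = 10)
  expect_false(identical(m1$params, m3$params))
})

test_that("forward outputs live strictly inside (0,1); zero weights give 0.5", {
  ont <- make_toy_ontology(c(2, 3))
  vocab <- make_toy_vocabulary(10)
  model <- onn_init(ont, vocab, d_ext = 6, d_enc = 4, seed = 2)
  sig <- make_signatures(ont, vocab, seed = 3)
  s <- sample_dataset(sig, n_per_leaf = 2, seed = 4)$samples[[1L]]
  prof <- onn_forward(model, s)
  vals <- unlist(prof$layers)
  expect_true(all(vals > 0 & vals < 1))
  expect_equal(prof$unknown,
               vapply(prof$layers, function(v) max(0, 1 - sum(v)), 0))

  zero <- model
  zero$params <- rapply(zero$params, function(x) x * 0, how = "replace")
  prof0 <- onn_forward(zero, s)
  expect_true(all(unlist(prof0$layers) == 0.5))

  wrong <- s
  attr(wrong, "vocabulary_hash") <- "nope"
  expect_error(onn_forward(model, wrong), "vocabulary")
})

test_that("loss matches its closed forms and hinge hand case", {
  ont <- build_ontology(c("Root-A-A1", "Root-A-A2", "Root-B-B1"))
  uniform <- structure(list(layers = list(
    layer2 = c("Root-A" = 0.5, "Root-B" = 0.5),
    layer3 = c("Root-A-A1" = 0.5, "Root-A-A2" = 0.5, "Root-B-B1" = 0.5)),
    unknown = c(layer2 = 0, layer3 = 0)), class = "contribution_profile")
  expect_equal(onn_loss(uniform, "Root-A-A1", ont, lambda = 0),
               5 * log(2), tolerance = 1e-12)

  # one violating edge, child 0.9 above parent 0.1: hinge adds lambda * 0.8
  prof <- structure(list(layers = list(
    layer2 = c("Root-A" = 0.1, "Root-B" = 0.5),
    layer3 = c("Root-A-A1" = 0.9, "Root-A-A2" = 0.05, "Root-B-B1" = 0.5)),
    unknown = c(layer2 = 0, layer3 = 0)), class = "contribution_profile")
  l0 <- onn_loss(prof, "Root-A-A1", ont, lambda = 0)
  l1 <- onn_loss(prof, "Root-A-A1", ont, lambda = 1)
  expect_equal(l1 - l0, 0.8, tolerance = 1e-12)

  # a perfect (clipped) profile is minimal among perturbations
  perfect <- structure(list(layers = list(
    layer2 = c("Root-A" = 1, "Root-B" = 0),
    layer3 = c("Root-A-A1" = 1, "Root-A-A2" = 0, "Root-B-B1" = 0)),
    unknown = c(layer2 = 0, layer3 = 0)), class = "contribution_profile")
  lp <- onn_loss(perfect, "Root-A-A1", ont)
  expect_lt(lp, onn_loss(uniform, "Root-A-A1", ont))
  expect_error(onn_loss(perfect, "Root-C", ont), "not in ontology")
})

test_that("backpropagated gradients agree with finite differences", {
  ont <- make_toy_ontology(c(2, 2))
  vocab <- make_toy_vocabulary(8)
  model <- onn_init(ont, vocab, d_ext = 5, d_enc = 3, seed = 21)
  sig <- make_signatures(ont, vocab, seed = 22)
  ds <- sample_dataset(sig, n_per_leaf = 2, seed = 23)
  X <- ontosource:::.stack_samples(ds$samples)
  Tg <- ontosource:::.targets_for_labels(ds$labels, model)
  L <- ont$n_layers
  lambda <- 0.3

  loss_at <- function(params) {
    fw <- ontosource:::.onn_forward_batch(params, X, L)
    ontosource:::.batch_loss(fw$P, Tg, model$parent_maps, lambda, L)
  }
  fw <- ontosource:::.onn_forward_batch(model$params, X, L)
  g <- ontosource:::.onn_backward(model$params, fw, X, Tg,
                                  model$parent_maps, lambda, L)
  h <- 1e-5
  check <- function(path_get, path_set, grad, n_check = 6L) {
    w <- path_get(model$params)
    idx <- sample(length(w), min(n_check, length(w)))
    for (i in idx) {
      pp <- model$params
      wp <- w; wp[i] <- wp[i] + h
      pm <- w; pm[i] <- pm[i] - h
      num <- (loss_at(path_set(pp, wp)) - loss_at(path_set(pp, pm))) / (2 * h)
      expect_lt(abs(grad[i] - num), 1e-6 + 1e-4 * abs(num))
    }
  }
  set.seed(77)
  check(function(p) p$ext$W, function(p, w) { p$ext$W <- w; p }, g$ext$W)
  check(function(p) p$enc[[3]]$W,
        function(p, w) { p$enc[[3]]$W <- w; p }, g$enc[[3]]$W)
  check(function(p) p$inc[[2]]$W,
        function(p, w) { p$inc[[2]]$W <- w; p }, g$inc[[2]]$W)
  check(function(p) p$head[[3]]$W,
        function(p, w) { p$head[[3]]$W <- w; p }, g$head[[3]]$W)
  check(function(p) p$head[[2]]$b,
        function(p, w) { p$head[[2]]$b <- w; p }, g$head[[2]]$b)
})

test_that("fold splitting is disjoint, covering, balanced, and seeded", {
  folds <- split_folds(16L, k = 8L, seed = 5)
  expect_length(folds, 8L)
  sizes <- vapply(folds, function(f) length(f$test), 0L)
  expect_true(all(sizes == 2L))
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(all_test, 1:16)
  for (f in folds) {
    expect_identical(sort(c(f$train, f$test)), 1:16)
    expect_length(intersect(f$train, f$test), 0L)
  }
  expect_identical(split_folds(17L, 4L, seed = 3), split_folds(17L, 4L, seed = 3))
  sizes17 <- vapply(split_folds(17L, 4L, seed = 3),
                    function(f) length(f$test), 0L)
  expect_true(max(sizes17) - min(sizes17) <= 1L)
  expect_error(split_folds(5L, 8L), "smaller")
})

test_that("training recovers a separable toy problem and is deterministic", {
  fx <- toy_trained_fit()
  expect_equal(max(fx$fit$history$accuracy), 1.0)
  # determinism: retrain from scratch with the same seeds
  model <- onn_init(fx$ont, fx$vocab, d_ext = 32, d_enc = 16, seed = 13)
  fit2 <- onn_train(model, fx$ds,
                    train_config(batch_size = 64, max_iterations = 600,
                                 convergence_window = 200, seed = 13))
  expect_identical(fit2$model$params, fx$fit$model$params)
  expect_identical(fit2$history, fx$fit$history)

  # zero-iteration budget returns the initial model untouched
  fit0 <- onn_train(model, fx$ds, train_config(max_iterations = 0L))
  expect_identical(fit0$model$params, model$params)
  expect_equal(nrow(fit0$history), 0L)
})

test_that("trained toy model ranks the true path first on held-out draws", {
  fx <- toy_trained_fit()
  held <- sample_dataset(fx$sig, n_per_leaf = 5, noise_concentration = 60,
                         seed = 99)
  ok <- 0L
  for (i in seq_along(held$samples)) {
    p <- predict_source(fx$fit$model, held$samples[[i]])
    if (p$path$lineage[nrow(p$path)] == held$labels[i]) ok <- ok + 1L
  }
  expect_gte(ok / length(held$samples), 0.9)
})

test_that("consistency pressure keeps children near or below parents", {
  fx <- toy_trained_fit()
  held <- sample_dataset(fx$sig, n_per_leaf = 5, noise_concentration = 60,
                         seed = 100)
  sc <- onn_scores(fx$fit$model, held)
  pm <- fx$fit$model$parent_maps[[3]]$parent_pos
  child <- sc$layer3
  parent <- sc$layer2[, pm, drop = FALSE]
  expect_gte(mean(parent >= child - 0.05), 0.95)
})

test_that("argmax prediction breaks ties toward the lower node index", {
  ont <- make_toy_ontology(c(3))
  vocab <- make_toy_vocabulary(8)
  model <- onn_init(ont, vocab, d_ext = 4, d_enc = 3, seed = 1)
  model$params <- rapply(model$params, function(x) x * 0, how = "replace")
  s <- sample_dataset(make_signatures(ont, vocab, seed = 2), 1, seed = 3)$samples[[1L]]
  p <- predict_source(model, s)   # all contributions are exactly 0.5
  expect_identical(p$path$lineage, layer_nodes(ont, 2)$lineage[1L])
  expect_length(p$predicted_sets[[1L]], 0L)  # strict > 0.5 excludes ties
})

test_that("single-node layers are always the predicted source", {
  ont <- build_ontology("Root-Only-Leaf")
  vocab <- make_toy_vocabulary(8)
  model <- onn_init(ont, vocab, d_ext = 4, d_enc = 3, seed = 8)
  s <- sample_dataset(make_signatures(ont, vocab, seed = 2), 1, seed = 3)$samples[[1L]]
  p <- predict_source(model, s)
  expect_identical(p$path$lineage, c("Root-Only", "Root-Only-Leaf"))
})

test_that("model bundles round-trip bit-identically and verify hashes", {
  fx <- toy_trained_fit()
  dir <- tempfile()
  save_model(fx$fit$model, dir)
  back <- load_model(dir, vocabulary = fx$vocab, ontology = fx$ont)
  probe <- sample_dataset(fx$sig, n_per_leaf = 2, seed = 55)
  sc1 <- onn_scores(fx$fit$model, probe)
  sc2 <- onn_scores(back, probe)
  expect_identical(sc1, sc2)

  other_vocab <- make_toy_vocabulary(31)
  expect_error(load_model(dir, vocabulary = other_vocab), "hash")
  expect_error(load_model(tempfile()), "not a model bundle")

  # corrupt the format tag
  meta <- jsonlite::read_json(file.path(dir, "model.json"))
  meta$format <- "something-else"
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE)
  expect_error(load_model(dir), "format")

  # truncated weights
  save_model(fx$fit$model, dir)
  writeBin(readBin(file.path(dir, "weights.rds"), "raw", 50L),
           file.path(dir, "weights.rds"))
  expect_error(load_model(dir), "weights")
})
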