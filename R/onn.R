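# The ontology-aware neural network. Four functional stages, all
# fully-connected: a feature extractor (ReLU) shared by all ontology layers;
# per-layer feature encoders (ReLU); per-layer incorporators (ReLU) that
# combine the layer's encoding with the incorporated state of the layer
# above (top-down information flow; the state above layer 2 is the extractor
# output itself); and per-layer sigmoid heads, one output unit per ontology
# node, read as that node's source contribution. Training minimizes, per
# sample, the sum over layers and nodes of binary cross-entropy against the
# one-hot ancestor path of the sample's biome, plus a hinge penalty
# lambda * sum over edges of max(0, child - parent) that pushes predictions
# toward ontology consistency (a node can contribute no more than its
# parent). Implemented directly with dense matrix algebra and a hand-rolled
# Adam optimizer so the gradient of the consistency penalty is exact.

MODEL_FORMAT_VERSION <- "ontosource-onn-1"

.flatten <- function(m) as.vector(t(m))  # row-major N x 7 -> 7N

.stack_samples <- function(samples) {
  t(vapply(samples, .flatten, numeric(length(samples[[1L]]))))
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

.init_dense <- function(fan_in, fan_out) {
  list(W = matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
                  fan_in, fan_out),
       b = numeric(fan_out))
}

#' Training protocol configuration
#'
#' @param batch_size Minibatch size.
#' @param max_iterations Iteration budget.
#' @param folds Cross-validation folds.
#' @param learning_rate Adam step size.
#' @param lambda Weight of the ontology-consistency hinge penalty.
#' @param convergence_window Stop when best training accuracy has not improved
#'   by more than `convergence_tol` over this many consecutive iterations.
#' @param convergence_tol Minimum accuracy improvement that resets the window.
#' @param eval_every Training-accuracy evaluation period (iterations).
#' @param seed Integer seed for initialization and batching.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 512L, max_iterations = 30000L,
                         folds = 8L, learning_rate = 1e-3, lambda = 0.1,
                         convergence_window = 500L, convergence_tol = 1e-4,
                         eval_every = 10L, seed = 1L) {
  stopifnot(batch_size >= 1L, folds >= 2L, max_iterations >= 0L,
            learning_rate > 0, lambda >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 max_iterations = as.integer(max_iterations),
                 folds = as.integer(folds), learning_rate = learning_rate,
                 lambda = lambda,
                 convergence_window = as.integer(convergence_window),
                 convergence_tol = convergence_tol,
                 eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

# per ontology layer i >= 3: position of each node's parent within layer i-1,
# in output order; and the child -> parent indicator matrix
.layer_parent_maps <- function(ontology) {
  L <- ontology$n_layers
  out <- vector("list", L)
  for (i in seq_len(L)) {
    if (i < 3L) next
    idx <- ontology$layer_index[[i]]
    up <- ontology$layer_index[[i - 1L]]
    pm <- match(ontology$nodes$parent[idx], up)
    A <- matrix(0, length(idx), length(up))
    A[cbind(seq_along(idx), pm)] <- 1
    out[[i]] <- list(parent_pos = pm, A = A)
  }
  out
}

#' Initialize an ontology-aware network
#'
#' Weights are drawn reproducibly from `seed` (He-scaled normals, zero
#' biases). Head widths mirror the ontology's per-layer node counts.
#'
#' @param ontology A `biome_ontology` with at least 2 layers.
#' @param vocabulary The `feature_vocabulary` the model consumes.
#' @param d_ext Extractor width.
#' @param d_enc Encoder/incorporator width per ontology layer.
#' @param seed Integer seed.
#' @return An `onn_model`.
#' @export
onn_init <- function(ontology, vocabulary, d_ext = 256L, d_enc = 128L,
                     seed = 1L) {
  stopifnot(inherits(ontology, "biome_ontology"), ontology$n_layers >= 2L)
  n_features <- nrow(vocabulary)
  if (n_features < 1L) stop("empty vocabulary", call. = FALSE)
  widths <- vapply(ontology$layer_index, length, 0L)
  if (any(widths == 0L)) stop("empty ontology layer", call. = FALSE)
  L <- ontology$n_layers
  D <- n_features * length(TAX_LEVELS)

  set.seed(seed)
  params <- list(ext = .init_dense(D, d_ext),
                 enc = vector("list", L), inc = vector("list", L),
                 head = vector("list", L))
  for (i in seq(2L, L)) {
    params$enc[[i]] <- .init_dense(d_ext, d_enc)
    d_prev <- if (i == 2L) d_ext else d_enc
    params$inc[[i]] <- .init_dense(d_enc + d_prev, d_enc)
    params$head[[i]] <- .init_dense(d_enc, widths[i])
  }

  structure(
    list(params = params, ontology = ontology,
         layer_lineages = lapply(seq_len(L), function(l) {
           ontology$nodes$lineage[ontology$layer_index[[l]]]
         }),
         parent_maps = .layer_parent_maps(ontology),
         d_ext = as.integer(d_ext), d_enc = as.integer(d_enc),
         n_features = n_features,
         vocabulary_hash = vocabulary_hash(vocabulary),
         ontology_hash = ontology_hash(ontology),
         seed = as.integer(seed), format = MODEL_FORMAT_VERSION),
    class = "onn_model")
}

#' @export
print.onn_model <- function(x, ...) {
  cat("onn_model:", x$n_features, "features, layers 2..",
      x$ontology$n_layers, " (widths ",
      paste(vapply(x$ontology$layer_index, length, 0L)[-1L], collapse = "/"),
      "), d_ext ", x$d_ext, ", d_enc ", x$d_enc, "\n", sep = "")
  invisible(x)
}

# batch forward pass; returns activations needed for backprop
.onn_forward_batch <- function(params, X, L) {
  H0 <- relu(sweep(X %*% params$ext$W, 2L, params$ext$b, "+"))
  enc <- inc <- P <- vector("list", L)
  prev <- H0
  for (i in seq(2L, L)) {
    enc[[i]] <- relu(sweep(H0 %*% params$enc[[i]]$W, 2L, params$enc[[i]]$b, "+"))
    inp <- cbind(enc[[i]], prev)
    inc[[i]] <- relu(sweep(inp %*% params$inc[[i]]$W, 2L, params$inc[[i]]$b, "+"))
    P[[i]] <- sigmoid(sweep(inc[[i]] %*% params$head[[i]]$W, 2L,
                            params$head[[i]]$b, "+"))
    prev <- inc[[i]]
  }
  list(H0 = H0, enc = enc, inc = inc, P = P)
}

#' Per-layer contribution scores for a set of samples
#'
#' @param model An `onn_model`.
#' @param samples A `labeled_dataset`, list of `sample_matrix`, or one
#'   `sample_matrix`.
#' @return List over ontology layers 2..L of score matrices
#'   (samples x layer nodes, named columns), values in (0, 1).
#' @export
onn_scores <- function(model, samples) {
  if (inherits(samples, "labeled_dataset")) samples <- samples$samples
  if (inherits(samples, "sample_matrix")) samples <- list(samples)
  for (s in samples) {
    if (!identical(attr(s, "vocabulary_hash"), model$vocabulary_hash)) {
      stop("sample vocabulary does not match the model's", call. = FALSE)
    }
  }
  X <- .stack_samples(samples)
  L <- model$ontology$n_layers
  fw <- .onn_forward_batch(model$params, X, L)
  out <- fw$P
  for (i in seq(2L, L)) colnames(out[[i]]) <- model$layer_lineages[[i]]
  names(out) <- paste0("layer", seq_len(L))
  out[-1L]
}

#' Contribution profile of one sample
#'
#' Runs the network and reports, per ontology layer, every node's source
#' contribution in (0, 1) plus the layer's unknown mass
#' `max(0, 1 - sum(contributions))`.
#'
#' @param model An `onn_model`.
#' @param matrix A `sample_matrix` over the model's vocabulary.
#' @return A `contribution_profile`: list with `layers` (named vectors keyed
#'   by lineage) and `unknown` (per-layer scalar).
#' @export
onn_forward <- function(model, matrix) {
  sc <- onn_scores(model, matrix)
  layers <- lapply(sc, function(m) m[1L, ])
  unknown <- vapply(layers, function(v) max(0, 1 - sum(v)), 0)
  structure(list(layers = layers, unknown = unknown),
            class = "contribution_profile")
}

# ancestor one-hot targets: list over layers of samples x nodes 0/1 matrices
.targets_for_labels <- function(labels, model) {
  ont <- model$ontology
  L <- ont$n_layers
  node_of <- match(labels, ont$nodes$lineage)
  if (anyNA(node_of)) {
    stop("labels not in ontology: ",
         paste(unique(labels[is.na(node_of)]), collapse = ", "), call. = FALSE)
  }
  Tg <- vector("list", L)
  # walk each label's path bottom-up
  anc <- matrix(NA_integer_, length(labels), L)  # node index per layer
  for (s in seq_along(labels)) {
    i <- node_of[s]
    while (!is.na(i)) {
      anc[s, ont$nodes$layer[i]] <- i
      i <- ont$nodes$parent[i]
    }
  }
  for (l in seq(2L, L)) {
    pos <- match(anc[, l], ont$layer_index[[l]])
    Tg[[l]] <- matrix(0, length(labels), length(ont$layer_index[[l]]))
    ok <- !is.na(pos)
    Tg[[l]][cbind(which(ok), pos[ok])] <- 1
  }
  Tg
}

# mean per-sample loss of a forward pass against targets
.batch_loss <- function(P, Tg, parent_maps, lambda, L) {
  eps <- 1e-7
  total <- 0
  for (i in seq(2L, L)) {
    p <- pmin(pmax(P[[i]], eps), 1 - eps)
    total <- total - sum(Tg[[i]] * log(p) + (1 - Tg[[i]]) * log(1 - p))
    if (lambda > 0 && i >= 3L) {
      gap <- P[[i]] - P[[i - 1L]][, parent_maps[[i]]$parent_pos, drop = FALSE]
      total <- total + lambda * sum(pmax(gap, 0))
    }
  }
  total / nrow(Tg[[2L]])
}

#' Loss of a contribution profile against a true biome lineage
#'
#' Per-layer binary cross-entropy against the one-hot ancestor path of
#' `lineage` (summed over nodes and layers), plus
#' `lambda * sum over edges of max(0, child - parent)`.
#'
#' @param profile A `contribution_profile`.
#' @param lineage The sample's true biome lineage.
#' @param ontology The governing `biome_ontology`.
#' @param lambda Consistency penalty weight.
#' @return Non-negative scalar.
#' @export
onn_loss <- function(profile, lineage, ontology, lambda = 0.1) {
  stopifnot(inherits(ontology, "biome_ontology"))
  L <- ontology$n_layers
  node <- match(lineage, ontology$nodes$lineage)
  if (is.na(node)) stop("lineage not in ontology: ", lineage, call. = FALSE)
  path <- integer(0)
  i <- node
  while (!is.na(i)) { path <- c(i, path); i <- ontology$nodes$parent[i] }
  eps <- 1e-7
  total <- 0
  prev <- NULL
  for (l in seq(2L, L)) {
    idx <- ontology$layer_index[[l]]
    v <- profile$layers[[l - 1L]]
    tgt <- as.numeric(idx %in% path)
    p <- pmin(pmax(as.numeric(v), eps), 1 - eps)
    total <- total - sum(tgt * log(p) + (1 - tgt) * log(1 - p))
    if (lambda > 0 && l >= 3L) {
      ppos <- match(ontology$nodes$parent[idx], ontology$layer_index[[l - 1L]])
      total <- total + lambda * sum(pmax(as.numeric(v) - prev[ppos], 0))
    }
    prev <- as.numeric(v)
  }
  total
}

# full backward pass; returns gradients with the params' structure
.onn_backward <- function(params, fw, X, Tg, parent_maps, lambda, L) {
  B <- nrow(X)
  g <- list(ext = list(W = 0, b = 0), enc = vector("list", L),
            inc = vector("list", L), head = vector("list", L))

  # output-side gradients dL/dz per layer (BCE + hinge routed through the
  # sigmoid derivative)
  dZ <- vector("list", L)
  for (i in seq(2L, L)) dZ[[i]] <- (fw$P[[i]] - Tg[[i]]) / B
  if (lambda > 0 && L >= 3L) {
    for (i in seq(L, 3L)) {
      pm <- parent_maps[[i]]
      M <- (fw$P[[i]] > fw$P[[i - 1L]][, pm$parent_pos, drop = FALSE]) * 1
      dP_child <- lambda * M / B
      dP_parent <- -lambda * (M %*% pm$A) / B
      dZ[[i]] <- dZ[[i]] + dP_child * fw$P[[i]] * (1 - fw$P[[i]])
      dZ[[i - 1L]] <- dZ[[i - 1L]] +
        dP_parent * fw$P[[i - 1L]] * (1 - fw$P[[i - 1L]])
    }
  }

  dH0 <- matrix(0, B, ncol(fw$H0))
  carry <- NULL  # gradient flowing into inc[[i]] from the layer below
  for (i in seq(L, 2L)) {
    dInc <- dZ[[i]] %*% t(params$head[[i]]$W)
    if (!is.null(carry)) dInc <- dInc + carry
    g$head[[i]] <- list(W = t(fw$inc[[i]]) %*% dZ[[i]], b = colSums(dZ[[i]]))

    dA <- dInc * (fw$inc[[i]] > 0)
    prev <- if (i == 2L) fw$H0 else fw$inc[[i - 1L]]
    inp <- cbind(fw$enc[[i]], prev)
    g$inc[[i]] <- list(W = t(inp) %*% dA, b = colSums(dA))
    dInp <- dA %*% t(params$inc[[i]]$W)
    d_enc_w <- ncol(fw$enc[[i]])
    dEnc <- dInp[, seq_len(d_enc_w), drop = FALSE]
    dPrev <- dInp[, -seq_len(d_enc_w), drop = FALSE]
    if (i == 2L) dH0 <- dH0 + dPrev else carry <- dPrev

    dB <- dEnc * (fw$enc[[i]] > 0)
    g$enc[[i]] <- list(W = t(fw$H0) %*% dB, b = colSums(dB))
    dH0 <- dH0 + dB %*% t(params$enc[[i]]$W)
  }
  dE <- dH0 * (fw$H0 > 0)
  g$ext <- list(W = t(X) %*% dE, b = colSums(dE))
  g
}

# Adam over the nested parameter list (layer-1 slots are NULL)
.adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.null(p)) return(NULL)
    if (is.list(p)) return(lapply(p, zero_like))
    p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, gr, m, v) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is.list(p)) {
      out <- Map(walk, p, gr, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * gr
    v <- beta2 * v + (1 - beta2) * gr^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  # drop NULL slots (layer 1 holds no parameters)
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

# mean over layers of argmax accuracy
.layer_argmax_accuracy <- function(P, Tg, L) {
  acc <- vapply(seq(2L, L), function(i) {
    pred <- max.col(P[[i]], ties.method = "first")
    truth <- max.col(Tg[[i]], ties.method = "first")
    has <- rowSums(Tg[[i]]) > 0
    if (!any(has)) return(NA_real_)
    mean(pred[has] == truth[has])
  }, 0)
  mean(acc, na.rm = TRUE)
}

#' Seeded k-fold split
#'
#' Produces `k` disjoint test sets covering the dataset (sizes differing by
#' at most 1), each paired with the complementary training set.
#'
#' @param n Number of samples (or a `labeled_dataset`).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` lists with `train` and `test` integer index vectors.
#' @export
split_folds <- function(n, k = 8L, seed = 1L) {
  if (inherits(n, "labeled_dataset")) n <- length(n$samples)
  if (n < k) stop("dataset smaller than the number of folds", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) {
    test <- sort(perm[fold_of == f])
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Train an ontology-aware network
#'
#' Minibatch Adam on the per-layer cross-entropy plus consistency hinge.
#' Training accuracy (mean over layers of argmax accuracy on the training
#' set) is evaluated every `eval_every` iterations; the checkpoint with the
#' highest training accuracy is returned. Training stops at
#' `max_iterations`, or earlier once the best accuracy has not improved by
#' more than `convergence_tol` for `convergence_window` consecutive
#' iterations.
#'
#' @param model An `onn_model`.
#' @param dataset A `labeled_dataset` whose labels resolve in the model's
#'   ontology.
#' @param config A [train_config()].
#' @return List with `model` (best checkpoint) and `history` (data.frame of
#'   iteration, loss, accuracy at each evaluation).
#' @export
onn_train <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "onn_model"), inherits(config, "train_config"))
  if (!length(dataset$samples)) stop("empty dataset", call. = FALSE)
  L <- model$ontology$n_layers
  X <- .stack_samples(dataset$samples)
  vh <- vapply(dataset$samples, function(s) attr(s, "vocabulary_hash"), "")
  if (!all(vh == model$vocabulary_hash)) {
    stop("dataset vocabulary does not match the model's", call. = FALSE)
  }
  Tg <- .targets_for_labels(dataset$labels, model)
  n <- nrow(X)

  history <- data.frame(iteration = integer(), loss = numeric(),
                        accuracy = numeric())
  if (config$max_iterations == 0L) {
    return(list(model = model, history = history))
  }

  set.seed(config$seed)
  params <- model$params
  opt <- .adam_init(params)
  best <- list(params = params, accuracy = -Inf, iteration = 0L)

  for (it in seq_len(config$max_iterations)) {
    idx <- if (n <= config$batch_size) seq_len(n) else
      sample.int(n, config$batch_size)
    Xb <- X[idx, , drop = FALSE]
    Tb <- lapply(Tg, function(tm) if (is.null(tm)) NULL else
      tm[idx, , drop = FALSE])
    fw <- .onn_forward_batch(params, Xb, L)
    grads <- .onn_backward(params, fw, Xb, Tb, model$parent_maps,
                           config$lambda, L)
    stepped <- .adam_step(params, grads, opt, config$learning_rate)
    params <- stepped$params
    opt <- stepped$state

    if (it %% config$eval_every == 0L || it == config$max_iterations) {
      fw_all <- .onn_forward_batch(params, X, L)
      acc <- .layer_argmax_accuracy(fw_all$P, Tg, L)
      loss <- .batch_loss(fw_all$P, Tg[seq_len(L)], model$parent_maps,
                          config$lambda, L)
      history <- rbind(history,
                       data.frame(iteration = it, loss = loss, accuracy = acc))
      if (acc > best$accuracy + config$convergence_tol) {
        best <- list(params = params, accuracy = acc, iteration = it)
      }
      if (it - best$iteration >= config$convergence_window) break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  list(model = model, history = history)
}

#' Predict source biomes for one sample
#'
#' Per ontology layer, the predicted source is the node with the largest
#' contribution (ties broken toward the lower node index); nodes with
#' contribution strictly above `threshold` form the layer's predicted biome
#' set.
#'
#' @param model An `onn_model`.
#' @param matrix A `sample_matrix`.
#' @param threshold Membership threshold for the predicted set.
#' @return A `source_prediction`: data.frame `path` (layer, lineage,
#'   contribution), list `predicted_sets`, and the full
#'   `contribution_profile`.
#' @export
predict_source <- function(model, matrix, threshold = 0.5) {
  profile <- onn_forward(model, matrix)
  L <- model$ontology$n_layers
  rows <- lapply(seq(2L, L), function(l) {
    v <- profile$layers[[l - 1L]]
    j <- which.max(v)
    data.frame(layer = l, lineage = names(v)[j], contribution = unname(v[j]),
               stringsAsFactors = FALSE)
  })
  sets <- lapply(profile$layers, function(v) names(v)[v > threshold])
  structure(list(path = do.call(rbind, rows), predicted_sets = sets,
                 profile = profile, threshold = threshold),
            class = "source_prediction")
}

#' @export
print.source_prediction <- function(x, ...) {
  cat("source_prediction (threshold ", x$threshold, "):\n", sep = "")
  print(x$path, row.names = FALSE)
  invisible(x)
}

#' Save / load a model bundle
#'
#' The bundle directory holds the weights (`weights.rds`), the model
#' metadata with format tag and vocabulary/ontology hashes
#' (`model.json`), and the ontology (`ontology.json`). Loading verifies the
#' format tag and, when a vocabulary or ontology is supplied, their hashes;
#' a reloaded model reproduces forward outputs bit-identically.
#'
#' @param model An `onn_model`.
#' @param dir Bundle directory.
#' @return `dir` invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "onn_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  meta <- list(format = model$format, d_ext = model$d_ext,
               d_enc = model$d_enc, n_features = model$n_features,
               seed = model$seed, vocabulary_hash = model$vocabulary_hash,
               ontology_hash = model$ontology_hash,
               trained = isTRUE(model$trained))
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE)
  write_ontology_json(model$ontology, file.path(dir, "ontology.json"))
  invisible(dir)
}

#' @rdname save_model
#' @param vocabulary Optional `feature_vocabulary` to verify against the
#'   stored hash.
#' @param ontology Optional `biome_ontology` to verify likewise.
#' @export
load_model <- function(dir, vocabulary = NULL, ontology = NULL) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) stop("not a model bundle: ", dir, call. = FALSE)
  meta <- jsonlite::read_json(meta_path)
  if (!identical(meta$format, MODEL_FORMAT_VERSION)) {
    stop("model format '", meta$format, "' not supported (expected ",
         MODEL_FORMAT_VERSION, ")", call. = FALSE)
  }
  params <- tryCatch(readRDS(file.path(dir, "weights.rds")),
                     error = function(e) stop("unreadable weights: ",
                                              conditionMessage(e), call. = FALSE))
  ont <- read_ontology_json(file.path(dir, "ontology.json"))
  if (!identical(ontology_hash(ont), meta$ontology_hash)) {
    stop("stored ontology does not match its recorded hash", call. = FALSE)
  }
  if (!is.null(vocabulary) &&
      !identical(vocabulary_hash(vocabulary), meta$vocabulary_hash)) {
    stop("supplied vocabulary does not match the model's hash", call. = FALSE)
  }
  if (!is.null(ontology) &&
      !identical(ontology_hash(ontology), meta$ontology_hash)) {
    stop("supplied ontology does not match the model's hash", call. = FALSE)
  }
  model <- structure(
    list(params = params, ontology = ont,
         layer_lineages = lapply(seq_len(ont$n_layers), function(l) {
           ont$nodes$lineage[ont$layer_index[[l]]]
         }),
         parent_maps = .layer_parent_maps(ont),
         d_ext = meta$d_ext, d_enc = meta$d_enc,
         n_features = meta$n_features,
         vocabulary_hash = meta$vocabulary_hash,
         ontology_hash = meta$ontology_hash,
         seed = meta$seed, format = meta$format,
         trained = isTRUE(meta$trained)),
    class = "onn_model")
  model
}
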