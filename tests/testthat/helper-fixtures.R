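# Shared fixtures and independent oracles. The oracles deliberately use
# plain loops and scalar formulas so they share no code path with the
# package's vectorized implementations.

toy_records <- function() {
  data.frame(
    lineage = c("sk__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae;g__Blautia",
                "sk__Bacteria;p__Firmicutes;c__Bacilli;o__Lactobacillales;f__Streptococcaceae;g__Streptococcus",
                "sk__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides"),
    abundance = c(30, 70, 100),
    stringsAsFactors = FALSE)
}

write_abundance_file <- function(records, path = tempfile(fileext = ".tsv")) {
  writeLines(paste(records$lineage, records$abundance, sep = "\t"), path)
  path
}

# random rooted tree as a lineage list: each new node attaches to any
# existing node not already at max depth
random_tree_lineages <- function(n_extra, max_depth = 5L) {
  lineages <- "Root"
  depths <- 1L
  for (i in seq_len(n_extra)) {
    ok <- which(depths < max_depth + 1L)
    p <- ok[sample.int(length(ok), 1L)]
    lineages <- c(lineages, paste0(lineages[p], "-N", i))
    depths <- c(depths, depths[p] + 1L)
  }
  lineages
}

# recursive summation oracle for hierarchical aggregation
oracle_aggregate <- function(leaf_values, lineages) {
  sapply(lineages, function(lin) {
    pref <- paste0(lin, "-")
    leaves <- names(leaf_values)
    sum(leaf_values[leaves == lin | startsWith(leaves, pref)])
  })
}

# exhaustive-enumeration oracle for the threshold-sweep metrics: loops over
# thresholds and biomes, scalar formulas throughout
oracle_metrics <- function(scores, truth, thresholds = seq(0, 1, by = 0.01)) {
  n <- nrow(scores); nb <- ncol(scores); nt <- length(thresholds)
  TP <- TN <- FP <- FN <- matrix(0, nt, nb)
  TPR <- FPR <- f1 <- numeric(nt)
  for (k in seq_len(nt)) {
    t <- thresholds[k]
    for (f in seq_len(nb)) {
      tp <- fp <- tn <- fn <- 0
      for (i in seq_len(n)) {
        in_pred <- scores[i, f] > t
        in_true <- truth[i, f] == 1
        if (in_pred && in_true) tp <- tp + 1
        if (in_pred && !in_true) fp <- fp + 1
        if (!in_pred && !in_true) tn <- tn + 1
        if (!in_pred && in_true) fn <- fn + 1
      }
      TP[k, f] <- tp; FP[k, f] <- fp; TN[k, f] <- tn; FN[k, f] <- fn
    }
    tprs <- fprs <- c()
    for (f in seq_len(nb)) {
      if (TP[k, f] + FN[k, f] > 0) tprs <- c(tprs, TP[k, f] / (TP[k, f] + FN[k, f]))
      if (FP[k, f] + TN[k, f] > 0) fprs <- c(fprs, FP[k, f] / (FP[k, f] + TN[k, f]))
    }
    TPR[k] <- mean(tprs); FPR[k] <- mean(fprs)
    prs <- rcs <- c()
    for (f in seq_len(nb)) {
      predicted <- TP[k, f] + FP[k, f] > 0
      actual <- TP[k, f] + FN[k, f] > 0
      if (predicted && actual) {
        prs <- c(prs, TP[k, f] / (TP[k, f] + FP[k, f]))
        rcs <- c(rcs, TP[k, f] / (TP[k, f] + FN[k, f]))
      }
    }
    f1[k] <- if (!length(prs)) NA_real_ else {
      pr <- mean(prs); rc <- mean(rcs)
      if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    }
  }
  # trapezoid over (FPR, TPR) with endpoints, own loop
  ord <- order(FPR, TPR)
  xs <- c(0, FPR[ord], 1); ys <- c(0, TPR[ord], 1)
  auc <- 0
  for (j in seq_len(length(xs) - 1L)) {
    auc <- auc + (xs[j + 1L] - xs[j]) * (ys[j] + ys[j + 1L]) / 2
  }
  fmax <- if (all(is.na(f1))) 0 else max(f1, na.rm = TRUE)
  list(TP = TP, TN = TN, FP = FP, FN = FN, TPR = TPR, FPR = FPR,
       f1 = f1, f_max = fmax, auc = auc)
}

# a random small evaluation instance on a seeded RNG
random_instance <- function(n_max = 30L, b_max = 6L) {
  n <- sample(3:n_max, 1L)
  nb <- sample(2:b_max, 1L)
  scores <- matrix(runif(n * nb), n, nb,
                   dimnames = list(NULL, paste0("B", seq_len(nb))))
  lab <- sample.int(nb, n, replace = TRUE)
  truth <- matrix(0, n, nb, dimnames = dimnames(scores))
  truth[cbind(seq_len(n), lab)] <- 1
  list(scores = scores, truth = truth)
}

# planted dataset: one genus-level feature carries the class signal, the
# rest are exchangeable noise
planted_dataset <- function(n_per_class = 30L, n_noise = 12L, seed = 101L) {
  set.seed(seed)
  ont <- build_ontology(c("Root-BiomeA", "Root-BiomeB"))
  lv <- c("g", rep("g", n_noise))
  nm <- c("g__planted", sprintf("g__noise%02d", seq_len(n_noise)))
  vocab <- data.frame(row = seq_along(nm), level = lv, name = nm,
                      stringsAsFactors = FALSE)
  class(vocab) <- c("feature_vocabulary", "data.frame")
  vh <- vocabulary_hash(vocab)
  mk <- function(planted_high) {
    raw <- stats::runif(length(nm), 0.2, 1)
    raw[1L] <- if (planted_high) stats::runif(1, 5, 6) else stats::runif(1, 0.01, 0.05)
    vals <- raw / sum(raw)
    m <- matrix(0, length(nm), 7L, dimnames = list(NULL, TAX_LEVELS))
    m[, "g"] <- vals
    structure(m, class = c("sample_matrix", "matrix", "array"),
              vocabulary_hash = vh, sample_id = NA_character_)
  }
  samples <- c(lapply(seq_len(n_per_class), function(i) mk(TRUE)),
               lapply(seq_len(n_per_class), function(i) mk(FALSE)))
  labels <- rep(c("Root-BiomeA", "Root-BiomeB"), each = n_per_class)
  list(ds = labeled_dataset(samples, labels, vocab, ont), ont = ont)
}

# small trained-model fixture shared by model tests; built once per run
toy_trained_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ont <- make_toy_ontology(c(2, 2))
    vocab <- make_toy_vocabulary(30)
    sig <- make_signatures(ont, vocab, drift = 0.4, seed = 11)
    ds <- sample_dataset(sig, n_per_leaf = 25, noise_concentration = 60,
                         seed = 12)
    model <- onn_init(ont, vocab, d_ext = 32, d_enc = 16, seed = 13)
    fit <- onn_train(model, ds,
                     train_config(batch_size = 64, max_iterations = 600,
                                  convergence_window = 200, seed = 13))
    cache <<- list(fit = fit, ds = ds, ont = ont, vocab = vocab, sig = sig)
    cache
  }
})
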