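# Hierarchical benchmarking: per-biome confusion counts swept over a
# threshold grid, macro-averaged TPR/FPR curves, trapezoidal AUC, and F_max
# (maximum over thresholds of the harmonic mean of macro precision and
# recall, averaging only biomes predicted at least once at that threshold).
# Conventions: set membership uses strict ">"; biomes without positive
# (resp. negative) samples are excluded from the TPR (resp. FPR) macro mean.

#' The default threshold grid: 0 to 1 in steps of 0.01
#' @export
threshold_grid <- function(step = 0.01) seq(0, 1, by = step)

#' Predicted biome set of one profile at a threshold
#'
#' @param profile A `contribution_profile`.
#' @param layer Ontology layer (2-based; layer 1 is the root).
#' @param t Threshold in \[0, 1\]; membership is strict (`> t`).
#' @return Character vector of node lineages.
#' @export
predicted_set <- function(profile, layer, t) {
  stopifnot(t >= 0, t <= 1)
  v <- profile$layers[[layer - 1L]]
  names(v)[v > t]
}

# scores: samples x biomes matrix; truth: 0/1 matrix same shape
.counts_at <- function(scores, truth, t) {
  pred <- scores > t
  pos <- truth == 1
  TP <- colSums(pred & pos)
  FP <- colSums(pred & !pos)
  FN <- colSums(!pred & pos)
  TN <- colSums(!pred & !pos)
  list(TP = TP, TN = TN, FP = FP, FN = FN)
}

#' Per-biome confusion counts at one threshold
#'
#' Counts over samples of the four indicator sums: a biome f is a true
#' positive for sample i at threshold t when f is in both the predicted set
#' (score strictly above t) and the actual set.
#'
#' @param scores Samples x biomes score matrix (named columns).
#' @param truth 0/1 matrix of the same shape: actual biome sets.
#' @param t Threshold.
#' @return Data frame with `biome`, `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(scores, truth, t) {
  stopifnot(all(dim(scores) == dim(truth)))
  ct <- .counts_at(scores, truth, t)
  data.frame(biome = colnames(scores), TP = ct$TP, TN = ct$TN, FP = ct$FP,
             FN = ct$FN, row.names = NULL, stringsAsFactors = FALSE)
}

#' Full threshold-sweep evaluation report for one layer
#'
#' @param scores Samples x biomes score matrix (named columns).
#' @param truth 0/1 matrix of actual biome sets, same shape.
#' @param thresholds Threshold grid.
#' @return An `eval_report`: per-threshold count arrays, macro TPR/FPR
#'   curves, `auc`, `f_max`, and the t = 0.5 summary (`precision`, `recall`,
#'   `accuracy` macro means).
#' @export
eval_report <- function(scores, truth, thresholds = threshold_grid()) {
  stopifnot(all(dim(scores) == dim(truth)))
  n_b <- ncol(scores)
  nt <- length(thresholds)
  TP <- TN <- FP <- FN <- matrix(0, nt, n_b,
                                 dimnames = list(NULL, colnames(scores)))
  for (k in seq_len(nt)) {
    ct <- .counts_at(scores, truth, thresholds[k])
    TP[k, ] <- ct$TP; TN[k, ] <- ct$TN; FP[k, ] <- ct$FP; FN[k, ] <- ct$FN
  }

  pos <- TP + FN  # per-biome positives (constant over t)
  neg <- FP + TN
  tpr_b <- ifelse(pos > 0, TP / pos, NA_real_)
  fpr_b <- ifelse(neg > 0, FP / neg, NA_real_)
  TPR <- rowMeans(tpr_b, na.rm = TRUE)
  FPR <- rowMeans(fpr_b, na.rm = TRUE)
  if (all(pos[1L, ] == 0) || all(neg[1L, ] == 0)) {
    stop("no evaluable biome (all-positive or all-negative truth)",
         call. = FALSE)
  }

  # F_max: macro precision/recall at each t over biomes predicted >= once
  f1 <- vapply(seq_len(nt), function(k) {
    predicted <- (TP[k, ] + FP[k, ]) > 0
    use <- predicted & pos[k, ] > 0
    if (!any(use)) return(NA_real_)
    pr <- mean(TP[k, use] / (TP[k, use] + FP[k, use]))
    rc <- mean(TP[k, use] / pos[k, use])
    if (pr + rc == 0) return(0)
    2 * pr * rc / (pr + rc)
  }, 0)
  f_max <- if (all(is.na(f1))) {
    warning("no biome was ever predicted; F_max reported as 0", call. = FALSE)
    0
  } else max(f1, na.rm = TRUE)

  structure(
    list(thresholds = thresholds, TP = TP, TN = TN, FP = FP, FN = FN,
         TPR = TPR, FPR = FPR, f1 = f1, f_max = f_max,
         auc = auc_from_curves(TPR, FPR),
         n_samples = nrow(scores), n_biomes = n_b),
    class = "eval_report")
}

#' Trapezoidal AUC from macro ROC curves
#'
#' Integrates TPR over FPR across the threshold-swept points, augmented with
#' the (0, 0) and (1, 1) endpoints.
#'
#' @param TPR,FPR Macro curves over the threshold grid.
#' @return AUC in \[0, 1\].
#' @export
auc_from_curves <- function(TPR, FPR) {
  ord <- order(FPR, TPR)
  x <- c(0, FPR[ord], 1)
  y <- c(0, TPR[ord], 1)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Macro precision, recall, and accuracy at one threshold
#'
#' Per-biome values by the standard confusion-count formulas, macro-averaged
#' over biomes; precision is defined only for biomes with at least one
#' prediction (TP + FP > 0), which are the only ones entering its mean.
#'
#' @param report An `eval_report`.
#' @param t Threshold (must be on the report's grid).
#' @return List with `per_biome` data.frame and macro `precision`, `recall`,
#'   `accuracy`.
#' @export
precision_recall_accuracy <- function(report, t = 0.5) {
  k <- match(TRUE, abs(report$thresholds - t) < 1e-9)
  if (is.na(k)) stop("t = ", t, " is not on the threshold grid", call. = FALSE)
  TP <- report$TP[k, ]; TN <- report$TN[k, ]
  FP <- report$FP[k, ]; FN <- report$FN[k, ]
  n <- report$n_samples
  prec <- ifelse(TP + FP > 0, TP / (TP + FP), NA_real_)
  rec <- ifelse(TP + FN > 0, TP / (TP + FN), NA_real_)
  acc <- (TP + TN) / n
  list(per_biome = data.frame(biome = colnames(report$TP), TP = TP, TN = TN,
                              FP = FP, FN = FN, precision = prec,
                              recall = rec, accuracy = acc, row.names = NULL,
                              stringsAsFactors = FALSE),
       precision = mean(prec, na.rm = TRUE),
       recall = mean(rec, na.rm = TRUE),
       accuracy = mean(acc))
}

#' @export
print.eval_report <- function(x, ...) {
  s <- precision_recall_accuracy(x, 0.5)
  cat(sprintf(
    "eval_report: %d samples, %d biomes | Pr %.3f Rc %.3f Acc %.3f F_max %.3f AUC %.3f\n",
    x$n_samples, x$n_biomes, s$precision, s$recall, s$accuracy, x$f_max,
    x$auc))
  invisible(x)
}

#' Lift flat bottom-layer contributions to every ontology layer
#'
#' Remolds a flat per-leaf vector (as produced by non-hierarchical methods)
#' into a hierarchical contribution profile: upper layers are the exact sums
#' of their children, the bottom layer passes through unchanged.
#'
#' @param flat Numeric vector over bottom-layer nodes (named by lineage, or
#'   in bottom-layer node order).
#' @param ontology A `biome_ontology`.
#' @return A `contribution_profile`.
#' @export
remold_flat <- function(flat, ontology) {
  layers <- aggregate_up(flat, ontology)
  unknown <- vapply(layers, function(v) max(0, 1 - sum(v)), 0)
  structure(list(layers = layers, unknown = unknown),
            class = "contribution_profile")
}

#' Remold a matrix of flat leaf scores for many samples
#'
#' Applies [remold_flat()] row-wise and returns per-layer score matrices in
#' the layout [evaluate()] accepts.
#'
#' @param flat_matrix Samples x bottom-layer-nodes matrix (columns in
#'   bottom-layer node order or named by lineage).
#' @param ontology A `biome_ontology`.
#' @return Named list `layer2..layerL` of score matrices with an `ontology`
#'   attribute.
#' @export
remold_scores <- function(flat_matrix, ontology) {
  L <- ontology$n_layers
  leaves <- ontology$layer_index[[L]]
  lin <- ontology$nodes$lineage[leaves]
  if (!is.null(colnames(flat_matrix))) {
    flat_matrix <- flat_matrix[, lin, drop = FALSE]
  } else if (ncol(flat_matrix) != length(leaves)) {
    stop("flat matrix misaligned with the bottom layer", call. = FALSE)
  }
  out <- lapply(seq(2L, L), function(l) {
    idx <- ontology$layer_index[[l]]
    m <- matrix(0, nrow(flat_matrix), length(idx),
                dimnames = list(NULL, ontology$nodes$lineage[idx]))
    m
  })
  names(out) <- paste0("layer", seq(2L, L))
  for (s in seq_len(nrow(flat_matrix))) {
    prof <- aggregate_up(stats::setNames(flat_matrix[s, ], lin), ontology)
    for (nm in names(out)) out[[nm]][s, ] <- prof[[nm]]
  }
  attr(out, "ontology") <- ontology
  out
}

# truth matrix for a layer: sample x nodes, 1 on the label's ancestor node
.truth_matrix <- function(labels, ontology, layer) {
  idx <- ontology$layer_index[[layer]]
  lin <- ontology$nodes$lineage[idx]
  out <- matrix(0, length(labels), length(idx),
                dimnames = list(NULL, lin))
  node_of <- match(labels, ontology$nodes$lineage)
  if (anyNA(node_of)) {
    stop("labels not in ontology: ",
         paste(unique(labels[is.na(node_of)]), collapse = ", "), call. = FALSE)
  }
  for (s in seq_along(labels)) {
    i <- node_of[s]
    while (!is.na(i)) {
      if (ontology$nodes$layer[i] == layer) {
        out[s, match(i, idx)] <- 1
        break
      }
      i <- ontology$nodes$parent[i]
    }
  }
  out
}

#' Evaluate a model (or precomputed profiles) on a labeled dataset
#'
#' Runs the full threshold sweep per requested ontology layer and reports
#' the summary columns at t = 0.5 alongside F_max and AUC.
#'
#' @param model An `onn_model`, or a list of per-layer score matrices as
#'   returned by [onn_scores()] (e.g. remolded flat predictions).
#' @param dataset A `labeled_dataset` (used for samples and/or labels).
#' @param layers Ontology layers to evaluate (default: all below the root).
#' @param thresholds Threshold grid.
#' @return List with `reports` (per layer `eval_report`) and `summary`
#'   (data.frame: layer, precision, recall, accuracy, f_max, auc).
#' @export
evaluate <- function(model, dataset, layers = NULL,
                     thresholds = threshold_grid()) {
  if (inherits(model, "onn_model")) {
    ontology <- model$ontology
    scores <- onn_scores(model, dataset)
  } else {
    scores <- model
    ontology <- attr(scores, "ontology")
    if (is.null(ontology)) stop("score list needs an 'ontology' attribute",
                                call. = FALSE)
  }
  L <- ontology$n_layers
  if (is.null(layers)) layers <- seq(2L, L)
  reports <- lapply(layers, function(l) {
    sc <- scores[[paste0("layer", l)]]
    if (is.null(sc)) stop("no scores for layer ", l, call. = FALSE)
    eval_report(sc, .truth_matrix(dataset$labels, ontology, l), thresholds)
  })
  names(reports) <- paste0("layer", layers)
  summary <- do.call(rbind, lapply(seq_along(layers), function(j) {
    r <- reports[[j]]
    s <- precision_recall_accuracy(r, 0.5)
    data.frame(layer = layers[j], precision = s$precision, recall = s$recall,
               accuracy = s$accuracy, f_max = r$f_max, auc = r$auc)
  }))
  list(reports = reports, summary = summary)
}

#' Export an evaluation to disk
#'
#' Writes a JSON file with the full per-threshold grid per layer, a TSV
#' summary (layer, precision, recall, accuracy, f_max, auc), and a TSV of
#' ROC points for plotting.
#'
#' @param evaluation Result of [evaluate()].
#' @param prefix Output path prefix; files `<prefix>.json`,
#'   `<prefix>.summary.tsv`, `<prefix>.roc.tsv` are written.
#' @return `prefix` invisibly.
#' @export
write_evaluation <- function(evaluation, prefix) {
  full <- lapply(evaluation$reports, function(r) {
    list(thresholds = r$thresholds, TP = r$TP, TN = r$TN, FP = r$FP,
         FN = r$FN, TPR = r$TPR, FPR = r$FPR, f1 = r$f1, f_max = r$f_max,
         auc = r$auc)
  })
  jsonlite::write_json(full, paste0(prefix, ".json"), digits = NA)
  utils::write.table(evaluation$summary, paste0(prefix, ".summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  roc <- do.call(rbind, lapply(names(evaluation$reports), function(nm) {
    r <- evaluation$reports[[nm]]
    data.frame(layer = nm, threshold = r$thresholds, TPR = r$TPR,
               FPR = r$FPR)
  }))
  utils::write.table(roc, paste0(prefix, ".roc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}
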