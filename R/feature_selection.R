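# Two-stage adaptive feature reduction: an abundance pre-filter followed by a
# random-forest importance selection, each with per-taxonomic-level adaptive
# thresholds C * mean(statistic at that level). Both comparisons are strict
# (">"): a feature must be above its level's threshold to survive.

#' Configuration for feature selection
#'
#' @param C Dimensionless threshold coefficient; both stage thresholds are
#'   `C` times the level mean of the stage statistic.
#' @param n_trees Trees in the importance forest.
#' @param seed Integer seed (mandatory; the forest is stochastic).
#' @return A `selection_config` list.
#' @export
selection_config <- function(C = 0.001, n_trees = 100L, seed) {
  stopifnot(C >= 0, n_trees >= 1L)
  if (missing(seed)) stop("seed is mandatory in selection_config", call. = FALSE)
  structure(list(C = C, n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "selection_config")
}

# samples x features value matrix: each feature's single meaningful cell
dataset_feature_matrix <- function(dataset) {
  vocab <- dataset$vocabulary
  col <- match(vocab$level, TAX_LEVELS)
  idx <- cbind(vocab$row, col)
  X <- t(vapply(dataset$samples, function(m) m[idx], numeric(nrow(vocab))))
  colnames(X) <- paste(vocab$level, vocab$name, sep = "|")
  X
}

#' Mean relative abundance of every feature over a dataset
#'
#' @param dataset A `labeled_dataset`.
#' @return Numeric vector over vocabulary rows (arithmetic mean across
#'   samples; 0 for features absent everywhere).
#' @export
mean_abundance_per_feature <- function(dataset) {
  if (!length(dataset$samples)) stop("dataset is empty", call. = FALSE)
  colMeans(dataset_feature_matrix(dataset))
}

#' Abundance-based pre-filter with per-level adaptive thresholds
#'
#' Within each taxonomic level l the threshold is `C` times the mean of the
#' per-feature mean abundances over all level-l features; features strictly
#' above it are kept.
#'
#' @param means Per-feature mean abundances (from
#'   [mean_abundance_per_feature()]).
#' @param vocabulary The `feature_vocabulary` the means are aligned to.
#' @param C Threshold coefficient (>= 0).
#' @return List with `kept` (integer vocabulary rows) and `thresholds`
#'   (named per-level numeric).
#' @export
abundance_prefilter <- function(means, vocabulary, C = 0.001) {
  stopifnot(C >= 0, length(means) == nrow(vocabulary))
  thresholds <- stats::setNames(numeric(length(TAX_LEVELS)), TAX_LEVELS)
  kept <- integer()
  for (lv in TAX_LEVELS) {
    rows <- which(vocabulary$level == lv)
    if (!length(rows)) {
      thresholds[[lv]] <- NA_real_
      next
    }
    thr <- C * mean(means[rows])
    thresholds[[lv]] <- thr
    kept <- c(kept, rows[means[rows] > thr])
  }
  list(kept = sort(kept), thresholds = thresholds)
}

#' Importance-based selection on pre-filter survivors
#'
#' Fits a random-forest regression from the surviving features to the one-hot
#' encoding of the bottom-layer biome label (one regression forest per biome
#' column; impurity importances are averaged across columns), then keeps,
#' within each taxonomic level, the features whose importance is strictly
#' above `C` times the mean importance of that level's survivors.
#'
#' @param dataset A `labeled_dataset`.
#' @param kept Integer vocabulary rows surviving the abundance pre-filter.
#' @param config A [selection_config()].
#' @param abundance_thresholds Optional per-level thresholds from the
#'   pre-filter stage, recorded in the result.
#' @return A `selection_result`: list with `kept` (final rows), `stage1_kept`,
#'   `importance` (named over stage-1 rows), `per_level_thresholds`
#'   (data.frame level/abundance/importance), `vocabulary_hash`, `provenance`
#'   (per dropped feature, the stage that removed it).
#' @export
importance_select <- function(dataset, kept, config,
                              abundance_thresholds = NULL) {
  stopifnot(inherits(config, "selection_config"), length(kept) >= 1L)
  labels <- dataset$labels
  if (length(unique(labels)) < 2L) {
    stop("degenerate labels: need >= 2 distinct biomes", call. = FALSE)
  }
  vocab <- dataset$vocabulary
  X <- dataset_feature_matrix(dataset)[, kept, drop = FALSE]
  classes <- sort(unique(labels))
  Y <- outer(labels, classes, `==`) * 1

  imp <- numeric(length(kept))
  df <- as.data.frame(X)
  names(df) <- sprintf("f%06d", kept)
  for (j in seq_along(classes)) {
    df$.y <- Y[, j]
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = config$n_trees, importance = "impurity",
      seed = config$seed + j, num.threads = 1L, verbose = FALSE)
    imp <- imp + fit$variable.importance[names(df)[seq_along(kept)]] /
      length(classes)
  }
  names(imp) <- names(df)[seq_along(kept)]

  lv_kept <- vocab$level[kept]
  imp_thr <- stats::setNames(rep(NA_real_, length(TAX_LEVELS)), TAX_LEVELS)
  final <- integer()
  for (lv in TAX_LEVELS) {
    at <- which(lv_kept == lv)
    if (!length(at)) next
    thr <- config$C * mean(imp[at])
    imp_thr[[lv]] <- thr
    final <- c(final, kept[at][imp[at] > thr])
  }
  final <- sort(final)

  provenance <- rep("kept", nrow(vocab))
  provenance[setdiff(seq_len(nrow(vocab)), kept)] <- "abundance_prefilter"
  provenance[setdiff(kept, final)] <- "importance_select"
  ab_thr <- if (is.null(abundance_thresholds)) {
    stats::setNames(rep(NA_real_, length(TAX_LEVELS)), TAX_LEVELS)
  } else abundance_thresholds

  structure(
    list(kept = final, stage1_kept = kept, importance = imp,
         per_level_thresholds = data.frame(
           level = TAX_LEVELS, abundance = as.numeric(ab_thr[TAX_LEVELS]),
           importance = as.numeric(imp_thr[TAX_LEVELS])),
         vocabulary_hash = vocabulary_hash(vocab),
         provenance = provenance, config = config),
    class = "selection_result")
}

#' Run both selection stages in order
#'
#' @param dataset A `labeled_dataset`.
#' @param config A [selection_config()].
#' @return A `selection_result`.
#' @export
select_features <- function(dataset, config) {
  means <- mean_abundance_per_feature(dataset)
  pre <- abundance_prefilter(means, dataset$vocabulary, config$C)
  if (!length(pre$kept)) stop("pre-filter removed every feature", call. = FALSE)
  importance_select(dataset, pre$kept, config, pre$thresholds)
}

#' Restrict a sample matrix to the selected features
#'
#' @param matrix A `sample_matrix`.
#' @param result A `selection_result` built on the same vocabulary.
#' @return The reduced `sample_matrix` (rows restricted to `result$kept`, in
#'   original order).
#' @export
apply_selection <- function(matrix, result) {
  stopifnot(inherits(result, "selection_result"))
  if (!identical(attr(matrix, "vocabulary_hash"), result$vocabulary_hash)) {
    stop("selection built on a different vocabulary", call. = FALSE)
  }
  if (!length(result$kept)) stop("selection kept no features", call. = FALSE)
  m <- matrix[result$kept, , drop = FALSE]
  structure(m, class = class(matrix),
            vocabulary_hash = paste0(result$vocabulary_hash, ":",
                                     rlang::hash(result$kept)),
            sample_id = attr(matrix, "sample_id"))
}

#' Reduce every sample of a dataset to the selected features
#'
#' @param dataset A `labeled_dataset`.
#' @param result A `selection_result`.
#' @return A `labeled_dataset` over the reduced vocabulary.
#' @export
apply_selection_dataset <- function(dataset, result) {
  vocab <- dataset$vocabulary[result$kept, , drop = FALSE]
  vocab$row <- seq_len(nrow(vocab))
  class(vocab) <- c("feature_vocabulary", "data.frame")
  vh <- vocabulary_hash(vocab)
  samples <- lapply(dataset$samples, function(m) {
    mm <- m[result$kept, , drop = FALSE]
    structure(mm, class = class(m), vocabulary_hash = vh,
              sample_id = attr(m, "sample_id"))
  })
  labeled_dataset(samples, dataset$labels, vocab)
}

#' Serialize / read a selection result as TSV
#'
#' Columns: `row`, `level`, `name`, `stage` (`kept`, `abundance_prefilter`,
#' or `importance_select` — the stage that dropped the feature, or `kept`).
#'
#' @param result A `selection_result`.
#' @param vocabulary The vocabulary it was built on.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_selection_tsv <- function(result, vocabulary, path) {
  utils::write.table(
    data.frame(row = vocabulary$row, level = vocabulary$level,
               name = vocabulary$name, stage = result$provenance),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
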