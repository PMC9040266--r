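# Dirichlet compositional simulator: toy ontologies, parent-correlated biome
# signatures, labeled sample sets, and known-weight source mixtures. The
# generative assumption mirrors the one the classifier relies on: samples
# from the same biome share a compositional signature, and signatures of
# sibling biomes resemble their parent's more than unrelated biomes'.

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), ncol = k,
              byrow = TRUE)
  sw <- rowSums(x)
  # guard against all-zero draws at tiny alpha
  zero <- sw == 0
  if (any(zero)) {
    x[zero, ] <- 1 / k
    sw[zero] <- 1
  }
  x / sw
}

#' Build a complete toy ontology
#'
#' A complete tree with `Root` plus one layer per entry of `branching`; the
#' node added as child j of parent labelled P is labelled `P.j` style
#' (`L<layer>_<index>`), so all labels are unique.
#'
#' @param branching Integer vector; entry i is the number of children each
#'   layer-i node has.
#' @return A `biome_ontology`.
#' @export
make_toy_ontology <- function(branching) {
  stopifnot(length(branching) >= 1L, all(branching >= 1L))
  lineages <- "Root"
  frontier <- "Root"
  for (d in seq_along(branching)) {
    idx <- 0L
    nxt <- character()
    for (p in frontier) {
      for (j in seq_len(branching[d])) {
        idx <- idx + 1L
        nxt <- c(nxt, paste0(p, "-", sprintf("L%d_%d", d + 1L, idx)))
      }
    }
    lineages <- c(lineages, nxt)
    frontier <- nxt
  }
  build_ontology(lineages)
}

#' A small synthetic vocabulary spread over the seven levels
#'
#' @param n_features Total number of features, distributed as evenly as
#'   possible across the seven taxonomic levels.
#' @return A `feature_vocabulary`.
#' @export
make_toy_vocabulary <- function(n_features) {
  stopifnot(n_features >= length(TAX_LEVELS))
  per <- diff(round(seq(0, n_features, length.out = length(TAX_LEVELS) + 1L)))
  lv <- rep(TAX_LEVELS, per)
  nm <- unlist(lapply(seq_along(TAX_LEVELS), function(i) {
    sprintf("%s__taxon%03d", TAX_LEVELS[i], seq_len(per[i]))
  }))
  vocab <- data.frame(row = seq_along(lv), level = lv, name = nm,
                      stringsAsFactors = FALSE)
  class(vocab) <- c("feature_vocabulary", "data.frame")
  vocab
}

#' Draw parent-correlated compositional signatures for every ontology node
#'
#' Per taxonomic level, the root signature is a symmetric Dirichlet draw over
#' the level's vocabulary features; each child's signature is the renormalized
#' mixture `(1 - drift) * parent + drift * fresh`, with `fresh` an independent
#' symmetric Dirichlet draw. `drift = 0` copies the parent everywhere;
#' `drift = 1` makes children independent.
#'
#' @param ontology A `biome_ontology`.
#' @param vocabulary A `feature_vocabulary`.
#' @param concentration Symmetric Dirichlet parameter (> 0) for fresh draws.
#' @param drift Parent-to-child perturbation scale in \[0, 1\].
#' @param seed Integer seed.
#' @return A `signature_set`: list with `signatures` (per node lineage, an
#'   N x 7 `sample_matrix`-shaped signature), `vocabulary`, `ontology`,
#'   and the generating parameters.
#' @export
make_signatures <- function(ontology, vocabulary, concentration = 0.8,
                            drift = 0.3, seed = 1L) {
  stopifnot(concentration > 0, drift >= 0, drift <= 1)
  set.seed(seed)
  lv_rows <- lapply(TAX_LEVELS, function(lv) which(vocabulary$level == lv))
  names(lv_rows) <- TAX_LEVELS
  N <- nrow(vocabulary)

  fresh <- function() {
    m <- matrix(0, N, length(TAX_LEVELS), dimnames = list(NULL, TAX_LEVELS))
    for (lv in TAX_LEVELS) {
      rows <- lv_rows[[lv]]
      if (length(rows)) {
        m[rows, lv] <- rdirichlet(1L, rep(concentration, length(rows)))[1L, ]
      }
    }
    m
  }

  sigs <- vector("list", ontology$n_nodes)
  # nodes are stored layer by layer, so parents precede children
  for (i in seq_len(ontology$n_nodes)) {
    p <- ontology$nodes$parent[i]
    if (is.na(p)) {
      sigs[[i]] <- fresh()
    } else {
      m <- (1 - drift) * sigs[[p]] + drift * fresh()
      # renormalize each level's simplex
      cs <- colSums(m)
      nz <- cs > 0
      m[, nz] <- sweep(m[, nz, drop = FALSE], 2L, cs[nz], "/")
      sigs[[i]] <- m
    }
  }
  names(sigs) <- ontology$nodes$lineage
  structure(list(signatures = sigs, vocabulary = vocabulary,
                 ontology = ontology, concentration = concentration,
                 drift = drift, seed = seed),
            class = "signature_set")
}

# one noisy draw around a signature matrix: per level, Dirichlet with
# mean = signature and precision = noise_concentration
.noisy_draw <- function(sig, noise_concentration, vocabulary_hash, sample_id) {
  m <- sig
  for (lv in colnames(sig)) {
    rows <- which(sig[, lv] > 0)
    if (length(rows) > 1L) {
      m[rows, lv] <- rdirichlet(1L, noise_concentration * sig[rows, lv])[1L, ]
    }
  }
  structure(m, class = c("sample_matrix", class(m)),
            vocabulary_hash = vocabulary_hash, sample_id = sample_id)
}

#' Simulate a labeled dataset from biome signatures
#'
#' For each bottom-layer node, draws `n_per_leaf` compositions from a
#' Dirichlet centered on the node's signature with precision
#' `noise_concentration` (larger = less sample-to-sample noise), labelled
#' with the leaf's lineage.
#'
#' @param signatures A `signature_set`.
#' @param n_per_leaf Samples per bottom-layer biome.
#' @param noise_concentration Dirichlet precision of the sampling noise.
#' @param seed Integer seed.
#' @return A `labeled_dataset`.
#' @export
sample_dataset <- function(signatures, n_per_leaf = 50L,
                           noise_concentration = 50, seed = 1L) {
  stopifnot(inherits(signatures, "signature_set"), n_per_leaf >= 1L)
  set.seed(seed)
  ont <- signatures$ontology
  vh <- vocabulary_hash(signatures$vocabulary)
  leaves <- ont$layer_index[[ont$n_layers]]
  samples <- list(); labels <- character()
  k <- 0L
  for (i in leaves) {
    lin <- ont$nodes$lineage[i]
    for (r in seq_len(n_per_leaf)) {
      k <- k + 1L
      samples[[k]] <- .noisy_draw(signatures$signatures[[i]],
                                  noise_concentration, vh,
                                  sprintf("sim%05d", k))
      labels[k] <- lin
    }
  }
  labeled_dataset(samples, labels, signatures$vocabulary, ont)
}

#' Simulate samples mixed from several leaf sources with known weights
#'
#' Each sample's expected composition is the weight-blended mixture of the
#' source leaves' signatures, observed through Dirichlet noise. The ground
#' truth per-layer contributions are the weights aggregated up the ontology.
#'
#' @param signatures A `signature_set`.
#' @param weights Named non-negative vector over bottom-layer lineages,
#'   summing to 1.
#' @param n Number of samples.
#' @param noise_concentration Dirichlet precision of the sampling noise.
#' @param seed Integer seed.
#' @return List with `samples` (list of `sample_matrix`), `truth` (per-layer
#'   contribution list from [aggregate_up()]), and `weights`.
#' @export
mix_sources <- function(signatures, weights, n = 1L,
                        noise_concentration = 50, seed = 1L) {
  stopifnot(inherits(signatures, "signature_set"))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be a simplex over leaf lineages", call. = FALSE)
  }
  ont <- signatures$ontology
  leaf_lin <- ont$nodes$lineage[ont$layer_index[[ont$n_layers]]]
  if (!all(names(weights) %in% leaf_lin)) {
    stop("weights must be named by bottom-layer lineages", call. = FALSE)
  }
  set.seed(seed)
  vh <- vocabulary_hash(signatures$vocabulary)
  blend <- Reduce(`+`, lapply(names(weights), function(lin) {
    weights[[lin]] * signatures$signatures[[lin]]
  }))
  cs <- colSums(blend); nz <- cs > 0
  blend[, nz] <- sweep(blend[, nz, drop = FALSE], 2L, cs[nz], "/")
  samples <- lapply(seq_len(n), function(k) {
    .noisy_draw(blend, noise_concentration, vh, sprintf("mix%05d", k))
  })
  full <- stats::setNames(rep(0, length(leaf_lin)), leaf_lin)
  full[names(weights)] <- weights
  list(samples = samples, truth = aggregate_up(full, ont), weights = weights)
}

#' Write a synthetic feature-list file and its selection flags
#'
#' Emits, in the package's feature-list TSV dialect (`row`, `level`, `name`,
#' `selected`), a synthetic stand-in for a published feature inventory: it
#' reproduces requested totals with generated taxon names, and is clearly not
#' the original inventory. Level sizes follow a fixed proportion ladder that
#' grows toward the finer ranks, as real taxonomies do.
#'
#' @param path Output file.
#' @param n_total Total number of features.
#' @param n_selected Number flagged as selected (must be <= `n_total`).
#' @param seed Integer seed for which features carry the selected flag.
#' @return `path` invisibly.
#' @export
make_synthetic_feature_list <- function(path, n_total = 44668L,
                                        n_selected = 1462L, seed = 1L) {
  stopifnot(n_selected <= n_total, n_total >= length(TAX_LEVELS))
  prop <- c(sk = 0.0002, k = 0.0008, p = 0.01, c = 0.04, o = 0.12, f = 0.27,
            g = 0.559)
  per <- pmax(1L, as.integer(floor(prop * n_total)))
  per[length(per)] <- per[length(per)] + (n_total - sum(per))
  lv <- rep(TAX_LEVELS, per)
  nm <- unlist(lapply(seq_along(TAX_LEVELS), function(i) {
    sprintf("%s__taxon%06d", TAX_LEVELS[i], seq_len(per[i]))
  }))
  set.seed(seed)
  sel <- logical(n_total)
  sel[sample.int(n_total, n_selected)] <- TRUE
  utils::write.table(
    data.frame(row = seq_len(n_total), level = lv, name = nm,
               selected = as.integer(sel)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature-list file
#'
#' Parses the feature-list TSV dialect (`row`, `level`, `name`, optional
#' `selected` flag) and reports its totals.
#'
#' @param path File path.
#' @return List with `vocabulary` (a `feature_vocabulary`), `selected`
#'   (logical vector), `n_total`, `n_selected`.
#' @export
read_feature_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("row", "level", "name")
  if (!all(need %in% names(tab))) {
    stop("feature list needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vocab <- tab[need]
  class(vocab) <- c("feature_vocabulary", "data.frame")
  sel <- if ("selected" %in% names(tab)) as.logical(tab$selected) else
    rep(NA, nrow(tab))
  list(vocabulary = vocab, selected = sel, n_total = nrow(tab),
       n_selected = sum(sel, na.rm = TRUE))
}
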