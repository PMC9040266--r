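#' Split a biome lineage string into its labels
#'
#' A biome lineage is a path through the biome ontology written root-to-leaf
#' with `"-"` as separator, e.g.
#' `"Root-Host_associated-Human-Digestive_system-Oral-Throat"`. Layer 1 is
#' always `"Root"`. Because `"-"` is reserved as the separator, biome labels
#' themselves must not contain it.
#'
#' @param lineage A single lineage string.
#' @return Character vector of labels in root-to-leaf order; its length is the
#'   layer of the named biome.
#' @examples
#' parse_lineage("Root-Environmental-Aquatic")
#' @export
parse_lineage <- function(lineage) {
  if (!is.character(lineage) || length(lineage) != 1L || is.na(lineage) ||
      !nzchar(lineage)) {
    stop("malformed lineage: expected a single non-empty string", call. = FALSE)
  }
  tokens <- strsplit(lineage, "-", fixed = TRUE)[[1L]]
  if (tokens[1L] != "Root") {
    stop("malformed lineage: must start with 'Root', got '", lineage, "'",
         call. = FALSE)
  }
  if (any(!nzchar(tokens))) {
    stop("malformed lineage: empty label in '", lineage, "'", call. = FALSE)
  }
  tokens
}

#' Build a biome ontology tree from lineage strings
#'
#' Every prefix of every input lineage becomes a node, so internal biomes need
#' not be listed explicitly. A biome label occurring under k distinct parents
#' yields k distinct nodes (multi-parent biomes are split into separate nodes,
#' so the result is always a tree); all nodes carrying the label are recorded
#' in `biome_index`. Within each layer nodes are ordered lexicographically by
#' full lineage, which fixes the index map used by model outputs.
#'
#' @param lineages Character vector of lineage strings.
#' @param sample_counts Optional numeric vector parallel to `lineages` with
#'   per-biome sample counts (kept as node metadata, `NA` elsewhere).
#' @return A `biome_ontology` object: a list with `nodes` (data.frame with
#'   `lineage`, `label`, `layer`, `parent` index, `n_samples`), `layer_index`
#'   (list of node-index vectors per layer), `biome_index` (label -> node
#'   indices), `n_layers`, `n_nodes`, `n_biomes`.
#' @export
build_ontology <- function(lineages, sample_counts = NULL) {
  if (length(lineages) == 0L) stop("no lineages supplied", call. = FALSE)
  if (!is.null(sample_counts) && length(sample_counts) != length(lineages)) {
    stop("sample_counts must parallel lineages", call. = FALSE)
  }
  token_list <- lapply(lineages, parse_lineage)

  # prefix closure: every ancestor of a listed biome is a node
  all_lineages <- unique(unlist(lapply(token_list, function(tok) {
    vapply(seq_along(tok), function(k) paste(tok[seq_len(k)], collapse = "-"), "")
  })))
  tok <- strsplit(all_lineages, "-", fixed = TRUE)
  layer <- lengths(tok)
  ord <- order(layer, all_lineages, method = "radix")
  all_lineages <- all_lineages[ord]
  tok <- tok[ord]
  layer <- layer[ord]

  label <- vapply(tok, function(x) x[length(x)], "")
  parent_lineage <- vapply(tok, function(x) {
    if (length(x) == 1L) NA_character_ else paste(x[-length(x)], collapse = "-")
  }, "")
  parent <- match(parent_lineage, all_lineages)

  n_samples <- rep(NA_real_, length(all_lineages))
  if (!is.null(sample_counts)) {
    idx <- match(lineages, all_lineages)
    n_samples[idx] <- as.numeric(sample_counts)
  }

  nodes <- data.frame(
    lineage = all_lineages, label = label, layer = layer,
    parent = parent, n_samples = n_samples,
    stringsAsFactors = FALSE
  )
  n_layers <- max(layer)
  layer_index <- lapply(seq_len(n_layers), function(l) which(layer == l))
  biome_index <- split(seq_along(label), label)

  structure(
    list(nodes = nodes, layer_index = layer_index, biome_index = biome_index,
         n_layers = n_layers, n_nodes = nrow(nodes),
         n_biomes = length(biome_index)),
    class = "biome_ontology"
  )
}

#' @export
print.biome_ontology <- function(x, ...) {
  cat("biome_ontology:", x$n_nodes, "nodes,", x$n_biomes, "biomes,",
      x$n_layers, "layers\n")
  cat("nodes per layer:", vapply(x$layer_index, length, 0L), "\n")
  invisible(x)
}

#' Nodes of one ontology layer, in output order
#'
#' @param ontology A `biome_ontology`.
#' @param layer Layer number, 1-based from the root.
#' @return Data frame of the layer's nodes (rows of `ontology$nodes`), in the
#'   deterministic lexicographic-by-lineage order used for model outputs.
#' @export
layer_nodes <- function(ontology, layer) {
  stopifnot(inherits(ontology, "biome_ontology"))
  if (length(layer) != 1L || is.na(layer) || layer < 1 || layer > ontology$n_layers) {
    stop("layer out of range [1, ", ontology$n_layers, "]", call. = FALSE)
  }
  ontology$nodes[ontology$layer_index[[layer]], , drop = FALSE]
}

#' Aggregate bottom-layer contributions up the ontology
#'
#' Each internal node's contribution is the exact sum of its children's, layer
#' by layer from the bottom up: the hierarchical remolding rule
#' P(f) = sum over children c of f of P(c).
#'
#' @param leaf_contributions Named numeric vector over bottom-layer node
#'   lineages (names must be the lineages of `layer_nodes(ontology, n_layers)`,
#'   in any order), or an unnamed vector in that layer's node order.
#' @param ontology A `biome_ontology`.
#' @return Named list `layers` with one named contribution vector per layer
#'   from 2 up to the bottom layer (bottom layer passed through unchanged),
#'   each aligned to that layer's node order.
#' @export
aggregate_up <- function(leaf_contributions, ontology) {
  stopifnot(inherits(ontology, "biome_ontology"))
  L <- ontology$n_layers
  if (L < 2L) stop("ontology has no layers below the root", call. = FALSE)
  leaves <- ontology$layer_index[[L]]
  leaf_lin <- ontology$nodes$lineage[leaves]
  v <- as.numeric(leaf_contributions)
  if (!is.null(names(leaf_contributions))) {
    unknown <- setdiff(names(leaf_contributions), leaf_lin)
    if (length(unknown)) {
      stop("contribution supplied for non-leaf or unknown node: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    v <- v[match(leaf_lin, names(leaf_contributions))]
    v[is.na(v)] <- 0
  } else if (length(v) != length(leaves)) {
    stop("unnamed leaf_contributions must have length ", length(leaves),
         call. = FALSE)
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("contributions must be finite and non-negative", call. = FALSE)
  }

  per_node <- rep(0, ontology$n_nodes)
  per_node[leaves] <- v
  children <- vector("list", ontology$n_nodes)
  pr <- ontology$nodes$parent
  for (i in seq_len(ontology$n_nodes)) {
    if (!is.na(pr[i])) children[[pr[i]]] <- c(children[[pr[i]]], i)
  }
  # bottom-up: each internal node is sum() over its (already complete)
  # children in node order, so conservation is exact, not approximate
  for (l in seq(L - 1L, 1L)) {
    for (i in ontology$layer_index[[l]]) {
      if (length(children[[i]])) per_node[i] <- sum(per_node[children[[i]]])
    }
  }
  out <- lapply(seq(2L, L), function(l) {
    idx <- ontology$layer_index[[l]]
    stats::setNames(per_node[idx], ontology$nodes$lineage[idx])
  })
  names(out) <- paste0("layer", seq(2L, L))
  out
}

#' Total contribution of a biome label across its nodes
#'
#' A biome split under several parents occupies several nodes; its total is
#' the sum of contributions over every node carrying the label.
#'
#' @param profile Per-layer contribution list as returned by [aggregate_up()]
#'   (named vectors keyed by lineage).
#' @param biome_label A biome label known to the ontology.
#' @param ontology A `biome_ontology`.
#' @return Numeric scalar.
#' @export
biome_total <- function(profile, biome_label, ontology) {
  stopifnot(inherits(ontology, "biome_ontology"))
  idx <- ontology$biome_index[[biome_label]]
  if (is.null(idx)) stop("unknown biome label: ", biome_label, call. = FALSE)
  lin <- ontology$nodes$lineage[idx]
  total <- 0
  for (vec in profile) total <- total + sum(vec[names(vec) %in% lin])
  total
}

#' Read a biome lineage list file
#'
#' Plain-text dialect: one lineage per line, optionally followed by a
#' tab-separated per-biome sample count; `#` comment lines and blank lines are
#' ignored.
#'
#' @param path File path.
#' @return Data frame with `lineage` and `n_samples` (NA when absent).
#' @export
read_lineages <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no lineages in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lineage <- vapply(parts, `[[`, "", 1L)
  n_samples <- vapply(parts, function(p) {
    if (length(p) >= 2L) suppressWarnings(as.numeric(p[[2L]])) else NA_real_
  }, 0)
  data.frame(lineage = lineage, n_samples = n_samples, stringsAsFactors = FALSE)
}

#' Sample count recorded for a biome lineage
#'
#' @param ontology A `biome_ontology` built with sample counts.
#' @param lineage Full lineage string of the biome.
#' @return Numeric count (NA if none recorded).
#' @export
lineage_sample_count <- function(ontology, lineage) {
  stopifnot(inherits(ontology, "biome_ontology"))
  i <- match(lineage, ontology$nodes$lineage)
  if (is.na(i)) stop("lineage not in ontology: ", lineage, call. = FALSE)
  ontology$nodes$n_samples[i]
}

ontology_as_nested <- function(ontology, node = 1L) {
  children <- which(!is.na(ontology$nodes$parent) &
                      ontology$nodes$parent == node)
  out <- list(label = ontology$nodes$label[node],
              lineage = ontology$nodes$lineage[node],
              layer = ontology$nodes$layer[node])
  ns <- ontology$nodes$n_samples[node]
  if (!is.na(ns)) out$n_samples <- ns
  if (length(children)) {
    out$children <- lapply(children, function(ch) ontology_as_nested(ontology, ch))
  }
  out
}

#' Export an ontology as nested JSON
#'
#' @param ontology A `biome_ontology`.
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_ontology_json <- function(ontology, path = NULL) {
  stopifnot(inherits(ontology, "biome_ontology"))
  nested <- ontology_as_nested(ontology)
  js <- jsonlite::toJSON(nested, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read an ontology from nested JSON written by [write_ontology_json()]
#'
#' @param path JSON file path.
#' @return A `biome_ontology`.
#' @export
read_ontology_json <- function(path) {
  nested <- jsonlite::read_json(path)
  acc_lineage <- character()
  acc_count <- numeric()
  walk <- function(node) {
    acc_lineage[[length(acc_lineage) + 1L]] <<- node$lineage
    acc_count[[length(acc_count) + 1L]] <<-
      if (!is.null(node$n_samples)) as.numeric(node$n_samples) else NA_real_
    for (ch in node$children) walk(ch)
  }
  walk(nested)
  build_ontology(acc_lineage, acc_count)
}

#' Stable fingerprint of an ontology's structure
#'
#' Used to bind trained models to the ontology they were trained on.
#' @param ontology A `biome_ontology`.
#' @return Character hash.
#' @export
ontology_hash <- function(ontology) {
  stopifnot(inherits(ontology, "biome_ontology"))
  rlang::hash(ontology$nodes$lineage)
}
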