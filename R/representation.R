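# Per-sample representation: taxa collapsed to the seven standard taxonomic
# levels (super-kingdom .. genus), laid out as an N-feature x 7-level matrix
# of relative abundances over a shared, frozen vocabulary.

#' The seven taxonomic levels, in rank order
#' @export
TAX_LEVELS <- c("sk", "k", "p", "c", "o", "f", "g")

# rank prefixes accepted in taxon lineage tokens, e.g. "p__Firmicutes"
.rank_prefix <- c(sk = "sk__", k = "k__", p = "p__", c = "c__", o = "o__",
                  f = "f__", g = "g__")

#' Read a two-column taxon abundance table
#'
#' Expected input: TSV with a taxon lineage column and a numeric abundance
#' column, one taxon per row, as produced by standard amplicon/metagenomic
#' profilers. A header line is detected by a non-numeric second field.
#'
#' @param path File path.
#' @return Data frame with `lineage` (verbatim) and `abundance` (non-negative).
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) {
    return(data.frame(lineage = character(), abundance = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  first_ab <- suppressWarnings(as.numeric(parts[[1L]][2L]))
  start <- if (length(parts[[1L]]) >= 2L && is.na(first_ab)) 2L else 1L
  if (start > length(parts)) {
    return(data.frame(lineage = character(), abundance = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- seq(start, length(parts))
  lineage <- character(length(rows)); abundance <- numeric(length(rows))
  for (j in seq_along(rows)) {
    p <- parts[[rows[j]]]
    if (length(p) < 2L) {
      stop("line ", rows[j], ": expected 2 tab-separated columns", call. = FALSE)
    }
    ab <- suppressWarnings(as.numeric(p[[2L]]))
    if (is.na(ab)) {
      stop("line ", rows[j], ": unparseable abundance '", p[[2L]], "'",
           call. = FALSE)
    }
    if (ab < 0) {
      stop("line ", rows[j], ": negative abundance ", ab, call. = FALSE)
    }
    lineage[j] <- p[[1L]]; abundance[j] <- ab
  }
  data.frame(lineage = lineage, abundance = abundance, stringsAsFactors = FALSE)
}

#' Read a multi-sample taxon abundance table
#'
#' TSV with a lineage column (first) and one numeric column per sample, with a
#' header row of sample ids.
#'
#' @param path File path.
#' @return Named list of per-sample record data frames (as
#'   [read_abundance_table()] returns).
#' @export
read_multi_abundance_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 2L) stop("expected lineage column plus sample columns",
                           call. = FALSE)
  lineage <- as.character(tab[[1L]])
  out <- lapply(seq(2L, ncol(tab)), function(j) {
    ab <- as.numeric(tab[[j]])
    if (any(is.na(ab) | ab < 0)) {
      stop("column '", names(tab)[j], "': abundances must be non-negative numbers",
           call. = FALSE)
    }
    data.frame(lineage = lineage, abundance = ab, stringsAsFactors = FALSE)
  })
  names(out) <- names(tab)[-1L]
  out
}

#' Read a BIOM-format JSON table
#'
#' Thin adapter for the dense or sparse JSON dialect of the BIOM format:
#' taxonomy is taken from each observation's `metadata$taxonomy` (joined with
#' `";"`) or, failing that, its `id`.
#'
#' @param path BIOM JSON file.
#' @return Named list of per-sample record data frames.
#' @export
read_biom_json <- function(path) {
  b <- jsonlite::read_json(path)
  obs <- b$rows; samps <- b$columns
  lineage <- vapply(obs, function(r) {
    tx <- r$metadata$taxonomy
    if (!is.null(tx)) paste(unlist(tx), collapse = ";") else r$id
  }, "")
  n_obs <- length(obs); n_smp <- length(samps)
  mat <- matrix(0, n_obs, n_smp)
  if (identical(b$matrix_type, "sparse")) {
    for (trip in b$data) {
      mat[trip[[1L]] + 1L, trip[[2L]] + 1L] <- as.numeric(trip[[3L]])
    }
  } else {
    for (i in seq_len(n_obs)) mat[i, ] <- as.numeric(unlist(b$data[[i]]))
  }
  out <- lapply(seq_len(n_smp), function(j) {
    data.frame(lineage = lineage, abundance = mat[, j], stringsAsFactors = FALSE)
  })
  names(out) <- vapply(samps, `[[`, "", "id")
  out
}

#' Collapse taxon records to the seven taxonomic levels
#'
#' Taxon lineages use rank-prefixed, semicolon-separated tokens
#' (`"sk__Bacteria;p__Firmicutes;...;g__Blautia"`); ranks below genus are
#' ignored. For each level, abundances of records sharing the collapsed prefix
#' are summed and then normalized so the level's total over assigned taxa is
#' 1; records lacking the rank contribute nothing at that level.
#'
#' @param records Data frame with `lineage` and `abundance`.
#' @return Data frame with `level`, `name` (the collapsed prefix), and
#'   `abundance` (relative, per level).
#' @export
collapse_to_levels <- function(records) {
  empty <- data.frame(level = character(), name = character(),
                      abundance = numeric(), stringsAsFactors = FALSE)
  if (nrow(records) == 0L) return(empty)
  toks <- strsplit(records$lineage, ";", fixed = TRUE)
  toks <- lapply(toks, trimws)
  out_level <- character(); out_name <- character(); out_ab <- numeric()
  for (lv in TAX_LEVELS) {
    pref <- .rank_prefix[[lv]]
    name <- vapply(seq_along(toks), function(i) {
      tk <- toks[[i]]
      hit <- which(startsWith(tk, pref))
      if (!length(hit)) return(NA_character_)
      h <- hit[1L]
      if (!nzchar(substring(tk[h], nchar(pref) + 1L))) return(NA_character_)
      paste(tk[seq_len(h)], collapse = ";")
    }, "")
    keep <- !is.na(name) & records$abundance > 0
    if (!any(keep)) next
    agg <- rowsum(records$abundance[keep], name[keep])
    vals <- agg[, 1L] / sum(agg[, 1L])
    out_level <- c(out_level, rep(lv, length(vals)))
    out_name <- c(out_name, rownames(agg))
    out_ab <- c(out_ab, vals)
  }
  data.frame(level = out_level, name = out_name, abundance = out_ab,
             stringsAsFactors = FALSE)
}

#' Build a feature vocabulary from a corpus of collapsed samples
#'
#' The vocabulary is the union of all (level, name) pairs seen in the corpus,
#' ordered by level (sk before g) and then name: deterministic and invariant
#' to corpus order.
#'
#' @param corpus List of collapsed maps from [collapse_to_levels()].
#' @return A `feature_vocabulary`: data.frame with `row` (1-based), `level`,
#'   `name`.
#' @export
build_vocabulary <- function(corpus) {
  if (!length(corpus)) stop("corpus is empty", call. = FALSE)
  lv <- unlist(lapply(corpus, `[[`, "level"), use.names = FALSE)
  nm <- unlist(lapply(corpus, `[[`, "name"), use.names = FALSE)
  key <- paste(lv, nm, sep = "\r")
  keep <- !duplicated(key)
  lv <- lv[keep]; nm <- nm[keep]
  ord <- order(match(lv, TAX_LEVELS), nm, method = "radix")
  vocab <- data.frame(row = seq_along(ord), level = lv[ord], name = nm[ord],
                      stringsAsFactors = FALSE)
  class(vocab) <- c("feature_vocabulary", "data.frame")
  vocab
}

#' Stable fingerprint of a vocabulary
#' @param vocabulary A `feature_vocabulary`.
#' @return Character hash.
#' @export
vocabulary_hash <- function(vocabulary) {
  rlang::hash(paste(vocabulary$level, vocabulary$name, sep = "\r"))
}

#' Place a collapsed sample into the feature-by-level matrix
#'
#' Returns the N x 7 sample representation: each vocabulary feature is one
#' row, holding its relative abundance in the single column matching the
#' feature's taxonomic level. Taxa absent from the vocabulary are dropped with
#' a warning (a trained model's vocabulary is frozen; unseen query taxa are
#' not an error).
#'
#' @param collapsed Output of [collapse_to_levels()].
#' @param vocabulary A `feature_vocabulary`.
#' @param sample_id Optional sample identifier.
#' @return A `sample_matrix`: numeric N x 7 matrix with attributes
#'   `vocabulary_hash` and `sample_id`; column names are `TAX_LEVELS`.
#' @export
to_matrix <- function(collapsed, vocabulary, sample_id = NA_character_) {
  if (!nrow(vocabulary)) stop("vocabulary is empty", call. = FALSE)
  m <- matrix(0, nrow = nrow(vocabulary), ncol = length(TAX_LEVELS),
              dimnames = list(NULL, TAX_LEVELS))
  if (nrow(collapsed)) {
    vkey <- paste(vocabulary$level, vocabulary$name, sep = "\r")
    ckey <- paste(collapsed$level, collapsed$name, sep = "\r")
    row <- match(ckey, vkey)
    if (anyNA(row)) {
      warning(sum(is.na(row)), " taxa not in vocabulary were dropped",
              call. = FALSE)
    }
    ok <- !is.na(row)
    m[cbind(row[ok], match(collapsed$level[ok], TAX_LEVELS))] <-
      collapsed$abundance[ok]
  }
  structure(m, class = c("sample_matrix", class(m)),
            vocabulary_hash = vocabulary_hash(vocabulary),
            sample_id = sample_id)
}

#' Validate sample-matrix invariants
#'
#' Checks non-negativity/finiteness, one non-zero entry per row at most, and
#' per-column sums bounded by 1 (+1e-6).
#'
#' @param m A `sample_matrix`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_sample_matrix <- function(m) {
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("sample matrix entries must be finite and >= 0", call. = FALSE)
  }
  if (any(rowSums(m > 0) > 1L)) {
    stop("each feature row may be non-zero in one level column only",
         call. = FALSE)
  }
  if (any(colSums(m) > 1 + 1e-6)) {
    stop("column sums must not exceed 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Bundle samples with their biome labels
#'
#' @param samples List of `sample_matrix` objects sharing one vocabulary.
#' @param labels Character vector of biome lineage strings, one per sample.
#' @param vocabulary The shared `feature_vocabulary`.
#' @param ontology Optional `biome_ontology`; when given, every label must
#'   resolve to one of its nodes.
#' @return A `labeled_dataset` list with `samples`, `labels`, `vocabulary`.
#' @export
labeled_dataset <- function(samples, labels, vocabulary, ontology = NULL) {
  stopifnot(length(samples) == length(labels))
  vh <- vocabulary_hash(vocabulary)
  for (s in samples) {
    if (!identical(attr(s, "vocabulary_hash"), vh)) {
      stop("sample built on a different vocabulary", call. = FALSE)
    }
  }
  if (!is.null(ontology)) {
    bad <- setdiff(unique(labels), ontology$nodes$lineage)
    if (length(bad)) {
      stop("labels not in ontology: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(samples = samples, labels = labels, vocabulary = vocabulary),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", length(x$samples), "samples,",
      nrow(x$vocabulary), "features,", length(unique(x$labels)), "biomes\n")
  invisible(x)
}

#' Write / read a dataset bundle directory
#'
#' Layout: `vocabulary.tsv` (row, level, name), `labels.tsv` (sample_id,
#' lineage), and one `<sample_id>.triplets.tsv` per sample (row, level, value;
#' sparse non-zero cells only).
#'
#' @param dataset A `labeled_dataset`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_dataset_bundle <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$vocabulary,
                     file.path(dir, "vocabulary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ids <- vapply(seq_along(dataset$samples), function(i) {
    id <- attr(dataset$samples[[i]], "sample_id")
    if (is.na(id)) sprintf("sample%05d", i) else id
  }, "")
  utils::write.table(
    data.frame(sample_id = ids, lineage = dataset$labels),
    file.path(dir, "labels.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  for (i in seq_along(dataset$samples)) {
    m <- dataset$samples[[i]]
    nz <- which(m != 0, arr.ind = TRUE)
    utils::write.table(
      data.frame(row = nz[, 1L], level = TAX_LEVELS[nz[, 2L]],
                 value = m[nz]),
      file.path(dir, paste0(ids[i], ".triplets.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_dataset_bundle
#' @export
read_dataset_bundle <- function(dir) {
  vocab <- utils::read.delim(file.path(dir, "vocabulary.tsv"),
                             stringsAsFactors = FALSE)
  class(vocab) <- c("feature_vocabulary", "data.frame")
  lab <- utils::read.delim(file.path(dir, "labels.tsv"),
                           stringsAsFactors = FALSE)
  vh <- vocabulary_hash(vocab)
  samples <- lapply(seq_len(nrow(lab)), function(i) {
    tri <- utils::read.delim(
      file.path(dir, paste0(lab$sample_id[i], ".triplets.tsv")),
      stringsAsFactors = FALSE)
    m <- matrix(0, nrow(vocab), length(TAX_LEVELS),
                dimnames = list(NULL, TAX_LEVELS))
    if (nrow(tri)) m[cbind(tri$row, match(tri$level, TAX_LEVELS))] <- tri$value
    structure(m, class = c("sample_matrix", class(m)),
              vocabulary_hash = vh, sample_id = lab$sample_id[i])
  })
  labeled_dataset(samples, lab$lineage, vocab)
}
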