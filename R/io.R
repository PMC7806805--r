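#' Read and write node, edge and fingerprint tables
#'
#' Plain CSV dialects shared by all pipeline stages:
#' \describe{
#'   \item{nodes}{header `node_id,name,node_type,category`; `node_type` one of
#'     `ingredient`, `flavor_compound`, `drug_compound`; empty category allowed.}
#'   \item{edges}{header `src,dst,edge_type,weight`; `edge_type` one of `ii`,
#'     `if`, `id`; `weight` required for `ii` (the NPMI score), empty otherwise.}
#'   \item{fingerprints}{header `node_id,bits`; `bits` is an 881-character
#'     string of 0/1.}
#' }
#' Writing then reading reproduces the table exactly.  Malformed rows are
#' rejected with their line number (header = line 1).
#'
#' @param path file path.
#' @return `read_nodes_csv` and `read_edges_csv` return data.frames in the
#'   dialects above; `read_fingerprints_csv` returns an integer matrix with
#'   one row per compound (rownames = `node_id`, 881 columns).
#' @name graph_io
NULL

#' @rdname graph_io
#' @export
read_nodes_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  .require_columns(df, c("node_id", "name", "node_type", "category"), path)
  bad <- !df$node_type %in% NODE_TYPES
  if (any(bad)) {
    stop(path, " line ", which(bad)[1L] + 1L, ": invalid node_type '",
         df$node_type[bad][1L], "'", call. = FALSE)
  }
  df$category[df$category == ""] <- NA_character_
  df
}

#' @rdname graph_io
#' @param nodes data.frame as returned by [read_nodes_csv()] or the `nodes`
#'   element of a `hetero_graph` (the derived `is_hub` column is dropped).
#' @export
write_nodes_csv <- function(nodes, path) {
  out <- nodes[, c("node_id", "name", "node_type", "category")]
  out$category[is.na(out$category)] <- ""
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname graph_io
#' @export
read_edges_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  .require_columns(df, c("src", "dst", "edge_type", "weight"), path)
  bad <- !df$edge_type %in% c("ii", "if", "id")
  if (any(bad)) {
    stop(path, " line ", which(bad)[1L] + 1L, ": invalid edge_type '",
         df$edge_type[bad][1L], "'", call. = FALSE)
  }
  w <- suppressWarnings(as.numeric(df$weight))
  need_w <- df$edge_type == "ii"
  if (any(need_w & is.na(w))) {
    stop(path, " line ", which(need_w & is.na(w))[1L] + 1L,
         ": ii edge without numeric weight", call. = FALSE)
  }
  df$weight <- w
  df
}

#' @rdname graph_io
#' @param edges data.frame with `src`, `dst`, `edge_type`, `weight` columns
#'   (e.g. the `edges` element of a `hetero_graph`).
#' @export
write_edges_csv <- function(edges, path) {
  out <- edges[, c("src", "dst", "edge_type", "weight")]
  out$weight <- ifelse(is.na(out$weight), "",
                       format(out$weight, digits = 17, trim = TRUE,
                              scientific = FALSE))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname graph_io
#' @export
read_fingerprints_csv <- function(path) {
  df <- read.csv(path, colClasses = "character")
  .require_columns(df, c("node_id", "bits"), path)
  n <- nrow(df)
  if (n == 0L) {
    return(matrix(integer(), nrow = 0, ncol = FINGERPRINT_LENGTH))
  }
  len <- nchar(df$bits)
  if (any(len != FINGERPRINT_LENGTH)) {
    i <- which(len != FINGERPRINT_LENGTH)[1L]
    stop(path, " line ", i + 1L, ": fingerprint has ", len[i],
         " characters, expected ", FINGERPRINT_LENGTH, call. = FALSE)
  }
  if (any(grepl("[^01]", df$bits))) {
    i <- which(grepl("[^01]", df$bits))[1L]
    stop(path, " line ", i + 1L, ": fingerprint contains non-binary characters",
         call. = FALSE)
  }
  fp <- matrix(
    as.integer(unlist(strsplit(df$bits, "", fixed = TRUE), use.names = FALSE)),
    nrow = n, ncol = FINGERPRINT_LENGTH, byrow = TRUE
  )
  rownames(fp) <- df$node_id
  fp
}

#' @rdname graph_io
#' @param fingerprints integer matrix (rows = compounds, 881 columns) with
#'   rownames giving the compound `node_id`s.
#' @export
write_fingerprints_csv <- function(fingerprints, path) {
  bits <- apply(fingerprints, 1L, paste, collapse = "")
  write.csv(data.frame(node_id = rownames(fingerprints), bits = bits,
                       stringsAsFactors = FALSE),
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(path, " line 1: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a recipe corpus from a text file
#'
#' One recipe per line; ingredient tokens separated by whitespace or commas
#' (auto-detected per file unless `delim` is given).  Duplicate tokens within
#' a line are collapsed: a recipe is a *set* of ingredients.
#'
#' @param path file path.
#' @param delim `"auto"` (default), `"space"` or `"comma"`.
#' @return A `recipe_corpus` (see [recipe_corpus()]).
#' @export
read_recipes <- function(path, delim = c("auto", "space", "comma")) {
  delim <- match.arg(delim)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (delim == "auto") {
    delim <- if (any(grepl(",", lines, fixed = TRUE))) "comma" else "space"
  }
  split_re <- if (delim == "comma") "[,[:space:]]+" else "[[:space:]]+"
  recipes <- lapply(strsplit(trimws(lines), split_re), unique)
  recipe_corpus(recipes)
}

#' @rdname read_recipes
#' @param corpus a `recipe_corpus`.
#' @export
write_recipes <- function(corpus, path, delim = c("space", "comma")) {
  delim <- match.arg(delim)
  sep <- if (delim == "comma") "," else " "
  writeLines(vapply(corpus$recipes, paste, character(1), collapse = sep), path)
  invisible(path)
}

#' Read and write walk corpora
#'
#' One walk per line, space-separated node tokens.  Header comment lines
#' record provenance: `#schema=<tag>` runs apply to all following walks until
#' the next schema line; `#seed=<int>` records the generator seed.
#'
#' @param corpus a `walk_corpus` (see [generate_metapath_walks()]).
#' @param path file path.
#' @export
write_walks <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(corpus$seed)) writeLines(paste0("#seed=", corpus$seed), con)
  prov <- corpus$provenance
  n <- length(corpus$walks)
  last <- ""
  for (i in seq_len(n)) {
    if (prov[i] != last) {
      writeLines(paste0("#schema=", prov[i]), con)
      last <- prov[i]
    }
    writeLines(paste(corpus$walks[[i]], collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_walks
#' @export
read_walks <- function(path) {
  lines <- readLines(path)
  seed <- NULL
  schema <- "UNKNOWN"
  walks <- vector("list", length(lines))
  prov <- character(length(lines))
  k <- 0L
  for (ln in lines) {
    if (startsWith(ln, "#seed=")) {
      seed <- as.integer(sub("^#seed=", "", ln))
    } else if (startsWith(ln, "#schema=")) {
      schema <- sub("^#schema=", "", ln)
    } else if (nzchar(trimws(ln))) {
      k <- k + 1L
      walks[[k]] <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
      prov[k] <- schema
    }
  }
  walk_corpus(walks[seq_len(k)], prov[seq_len(k)], seed = seed)
}

#' Read and write embeddings in word2vec text format
#'
#' First line `<vocab_size> <dim>`, then one `token v1 ... v_dim` line per
#' node.  Only the center vectors are serialized; [write_csp_weights()] stores
#' the chemical-structure-prediction head separately as TSV.
#'
#' @param model an `embedding_model` (see [train_embeddings()]).
#' @param path file path.
#' @export
write_embeddings <- function(model, path) {
  emb <- model$center
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb), ncol(emb)), con)
  rows <- apply(emb, 1L, function(v) {
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  writeLines(paste(rownames(emb), rows), con)
  invisible(path)
}

#' @rdname write_embeddings
#' @return `read_embeddings` returns a numeric matrix with tokens as rownames.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1L], " ")[[1L]])
  parts <- strsplit(lines[-1L], " ", fixed = TRUE)
  emb <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[2L])))
  rownames(emb) <- vapply(parts, `[[`, character(1), 1L)
  stopifnot(nrow(emb) == hdr[1L])
  emb
}

#' @rdname write_embeddings
#' @export
write_csp_weights <- function(model, path) {
  W <- rbind(model$csp_weights, bias = model$csp_bias)
  write.table(W, path, sep = "\t", col.names = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @return `read_csp_weights` returns a list with `weights` (d x 881) and
#'   `bias` (length 881).
#' @export
read_csp_weights <- function(path) {
  W <- as.matrix(read.table(path, sep = "\t"))
  dimnames(W) <- NULL
  list(weights = W[-nrow(W), , drop = FALSE], bias = W[nrow(W), ])
}
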