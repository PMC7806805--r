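#' Metapath schemas
#'
#' A metapath schema is an ordered list of node-class symbols -- `C` (any
#' compound), `H` (chemical-hub ingredient), `N` (non-hub ingredient) --
#' that constrains a random walk on the heterogeneous graph.  The two
#' food-specific schemas route chemical information through hubs:
#' `C-H-N-H-C` starts and ends at compounds, `N-H-C-H-N` at non-hub
#' ingredients.  Walks longer than the pattern extend it cyclically (the
#' duplicated junction symbol is not repeated), so a `C-H-N-H-C` walk
#' continues `...-H-N-H-C-H-N-...` up to the length cap.
#'
#' @param pattern character vector of symbols from `C`, `H`, `N`, or a
#'   single string such as `"CHNHC"`.
#' @param distinct_rule logical; when `TRUE` a step may not revisit the most
#'   recent node of the same class (so C and C' differ) unless that node is
#'   the only eligible neighbor, in which case the walk terminates.
#' @return An object of class `metapath_schema`.
#' @export
metapath_schema <- function(pattern, distinct_rule = TRUE) {
  if (is.character(pattern) && length(pattern) == 1L && nchar(pattern) > 1L) {
    pattern <- strsplit(toupper(pattern), "")[[1L]]
  }
  pattern <- toupper(as.character(pattern))
  if (length(pattern) < 2L || !all(pattern %in% c("C", "H", "N"))) {
    stop("pattern must be >= 2 symbols from C, H, N", call. = FALSE)
  }
  # adjacency allowed by the graph schema: C-H (compound edges),
  # H-N / N-H / H-H (NPMI edges)
  ok_adjacent <- function(a, b) {
    (a == "C" & b == "H") | (a == "H" & b == "C") |
      (a == "H" & b == "N") | (a == "N" & b == "H") |
      (a == "H" & b == "H")
  }
  a <- pattern[-length(pattern)]
  b <- pattern[-1L]
  bad <- !ok_adjacent(a, b)
  if (any(bad)) {
    stop("schema symbols ", a[bad][1L], "-", b[bad][1L],
         " are not connectable by any edge type", call. = FALSE)
  }
  structure(list(pattern = pattern, distinct_rule = isTRUE(distinct_rule),
                 tag = paste(pattern, collapse = "")),
            class = "metapath_schema")
}

# class symbol expected at 1-based walk position i, under cyclic extension
.schema_class_at <- function(schema, i) {
  p <- schema$pattern
  L <- length(p)
  cyc <- if (p[1L] == p[L]) L - 1L else L
  p[((i - 1L) %% cyc) + 1L]
}

#' Walk corpus
#'
#' @param walks list of character vectors (node-token sequences).
#' @param provenance character vector of per-walk schema tags (`"CHNHC"`,
#'   `"NHCHN"`, `"UNIFORM"`, ...), recycled if length 1.
#' @param seed integer seed recorded for reproducibility (or `NULL`).
#' @return An object of class `walk_corpus`.
#' @export
walk_corpus <- function(walks, provenance = "UNIFORM", seed = NULL) {
  stopifnot(is.list(walks))
  provenance <- rep_len(as.character(provenance), length(walks))
  structure(list(walks = walks, provenance = provenance, seed = seed),
            class = "walk_corpus")
}

#' @export
print.walk_corpus <- function(x, ...) {
  n <- length(x$walks)
  cat(sprintf("<walk_corpus> %d walks, mean length %.2f\n",
              n, if (n) mean(lengths(x$walks)) else 0))
  if (n) print(table(x$provenance))
  invisible(x)
}

# run expr with a temporary RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# neighbor index lists per node and walk class, 0-based for the C++ walker
.adjacency_by_class <- function(graph) {
  ids <- graph$nodes$node_id
  idx <- seq_along(ids)
  names(idx) <- ids
  cls <- .walk_class(graph)
  e <- graph$edges
  si <- idx[e$src]
  di <- idx[e$dst]
  # undirected incidence
  from <- c(si, di)
  to <- c(di, si)
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  nb <- split(to, factor(from, levels = idx))
  lapply(idx, function(i) {
    v <- nb[[i]]
    if (is.null(v)) v <- integer()
    v <- sort(unique(v))
    list(
      C = v[cls[v] == "C"] - 1L,
      H = v[cls[v] == "H"] - 1L,
      N = v[cls[v] == "N"] - 1L,
      ALL = v - 1L
    )
  })
}

#' Generate metapath-constrained random walks
#'
#' From every node matching the schema's first symbol, up to
#' `walks_per_start` walks are generated.  Each step draws the next node
#' uniformly among neighbors of the class required by the (cyclically
#' extended) schema; under the distinct rule the most recent node of that
#' class is excluded when alternatives exist.  A walk ends at `max_len`
#' nodes or as soon as no eligible neighbor remains -- early termination is
#' expected on sparse graphs, never an error.
#'
#' @param graph a `hetero_graph`.
#' @param schema a [metapath_schema()].
#' @param walks_per_start walks started from each eligible node (default 100).
#' @param max_len maximum walk length in nodes (default 50).
#' @param seed integer RNG seed; identical seeds reproduce identical corpora.
#' @return A `walk_corpus` tagged with the schema pattern.
#' @export
generate_metapath_walks <- function(graph, schema, walks_per_start = 100L,
                                    max_len = 50L, seed = 1L) {
  stopifnot(inherits(graph, "hetero_graph"),
            inherits(schema, "metapath_schema"))
  ids <- graph$nodes$node_id
  cls <- .walk_class(graph)
  ord <- order(ids)
  starts <- ord[cls[ord] == schema$pattern[1L]]
  if (!length(starts)) {
    warning("no nodes of class ", schema$pattern[1L], "; empty corpus")
    return(walk_corpus(list(), schema$tag, seed = seed))
  }
  adj <- .adjacency_by_class(graph)
  p <- schema$pattern
  L <- length(p)
  cyc <- if (p[1L] == p[L]) L - 1L else L
  code <- c(C = 0L, H = 1L, N = 2L)
  res <- walk_metapath_cpp(
    adj, code[cls], code[p[seq_len(cyc)]], starts - 1L,
    as.integer(walks_per_start), as.integer(max_len),
    schema$distinct_rule, as.integer(seed)
  )
  walk_corpus(lapply(res, function(w) ids[w + 1L]), schema$tag, seed = seed)
}

#' Generate uniform (untyped) random walks
#'
#' Plain random walks started from every node of every type: the next node
#' is drawn uniformly among all neighbors regardless of class, reflecting
#' all nodes in a balanced way.  Dead ends terminate early; an isolated
#' node yields single-node walks.
#'
#' @inheritParams generate_metapath_walks
#' @return A `walk_corpus` tagged `"UNIFORM"`.
#' @export
generate_uniform_walks <- function(graph, walks_per_start = 100L,
                                   max_len = 50L, seed = 1L) {
  stopifnot(inherits(graph, "hetero_graph"))
  if (nrow(graph$nodes) == 0L) stop("empty graph", call. = FALSE)
  ids <- graph$nodes$node_id
  starts <- order(ids)
  adj <- .adjacency_by_class(graph)
  res <- walk_uniform_cpp(adj, starts - 1L, as.integer(walks_per_start),
                          as.integer(max_len), as.integer(seed))
  walk_corpus(lapply(res, function(w) ids[w + 1L]), "UNIFORM", seed = seed)
}

#' Merge walk corpora
#'
#' Concatenates corpora and applies a deterministic shuffle so the trainer
#' interleaves walk strategies; provenance tags are preserved.
#'
#' @param corpora list of `walk_corpus` objects.
#' @param seed integer shuffle seed.
#' @return A merged `walk_corpus`.
#' @export
merge_corpora <- function(corpora, seed = 1L) {
  stopifnot(all(vapply(corpora, inherits, logical(1), "walk_corpus")))
  walks <- do.call(c, c(lapply(corpora, `[[`, "walks"), list(list())))
  prov <- unlist(lapply(corpora, `[[`, "provenance"), use.names = FALSE)
  if (length(walks)) {
    perm <- .with_seed(seed, sample.int(length(walks)))
    walks <- walks[perm]
    prov <- prov[perm]
  }
  walk_corpus(walks, if (length(prov)) prov else character(), seed = seed)
}

#' Validate a walk against a schema and graph
#'
#' `TRUE` iff every consecutive pair of nodes is an edge of the graph and
#' the class sequence matches the cyclically extended schema.
#'
#' @param walk character vector of node tokens.
#' @param schema a [metapath_schema()].
#' @param graph a `hetero_graph`.
#' @return Logical scalar.
#' @export
validate_walk <- function(walk, schema, graph) {
  stopifnot(inherits(schema, "metapath_schema"),
            inherits(graph, "hetero_graph"))
  if (!length(walk) || !all(walk %in% graph$nodes$node_id)) return(FALSE)
  idx <- match(walk, graph$nodes$node_id)
  cls <- .walk_class(graph)[idx]
  want <- vapply(seq_along(walk), function(i) .schema_class_at(schema, i),
                 character(1))
  if (!all(cls == want)) return(FALSE)
  if (length(walk) == 1L) return(TRUE)
  ekeys <- .pair_key(graph$edges$src, graph$edges$dst)
  steps <- .pair_key(walk[-length(walk)], walk[-1L])
  all(steps %in% ekeys)
}
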