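#' Heterogeneous food-chemical graph
#'
#' A `hetero_graph` holds three node types -- food ingredients, flavor
#' compounds and drug compounds -- together with ingredient-ingredient edges
#' weighted by normalized pointwise mutual information (NPMI) and unweighted
#' ingredient-compound edges.  Ingredients with at least one compound edge are
#' *chemical hubs*: they are the only conduit through which chemical
#' information can reach the remaining (non-hub) ingredients.
#'
#' @param nodes data.frame with columns `node_id`, `name`, `node_type`
#'   (one of `"ingredient"`, `"flavor_compound"`, `"drug_compound"`) and
#'   optionally `category` (one of the nine food categories, or `NA`).
#' @param ii_edges data.frame of ingredient-ingredient edges with columns
#'   `src`, `dst`, `weight` (NPMI score).  May be empty or `NULL`.
#' @param ic_edges data.frame of ingredient-compound edges with columns
#'   `src`, `dst` and optionally `edge_type` (`"if"` or `"id"`; inferred from
#'   the compound's node type when absent).  May be empty or `NULL`.
#' @param fingerprints optional named list or matrix of 881-bit fingerprints
#'   for compound nodes (see [read_fingerprints_csv()]).
#'
#' @return An object of class `hetero_graph`: a list with elements `nodes`
#'   (data.frame incl. derived `is_hub`), `edges` (data.frame with `src`,
#'   `dst`, `edge_type`, `weight`) and `fingerprints` (integer matrix with one
#'   row per labeled compound, or `NULL`).
#'
#' @examples
#' nodes <- data.frame(
#'   node_id = c("tomato", "basil", "linalool"),
#'   name = c("tomato", "basil", "linalool"),
#'   node_type = c("ingredient", "ingredient", "flavor_compound")
#' )
#' g <- build_graph(nodes,
#'   ii_edges = data.frame(src = "tomato", dst = "basil", weight = 0.4),
#'   ic_edges = data.frame(src = "basil", dst = "linalool")
#' )
#' g$nodes$is_hub
#' @export
build_graph <- function(nodes, ii_edges = NULL, ic_edges = NULL,
                        fingerprints = NULL) {
  nodes <- .normalize_nodes(nodes)
  if (anyDuplicated(nodes$node_id)) {
    dup <- nodes$node_id[duplicated(nodes$node_id)][1L]
    stop("duplicate node_id: '", dup, "'", call. = FALSE)
  }
  type_of <- setNames(nodes$node_type, nodes$node_id)

  ii <- .normalize_ii_edges(ii_edges, type_of)
  ic <- .normalize_ic_edges(ic_edges, type_of)
  edges <- rbind(ii, ic)
  rownames(edges) <- NULL

  fp <- .normalize_fingerprints(fingerprints, nodes)

  g <- structure(
    list(nodes = nodes, edges = edges, fingerprints = fp),
    class = "hetero_graph"
  )
  classify_hubs(g)
}

#' Recompute chemical-hub flags
#'
#' An ingredient is a chemical hub iff it has at least one edge to a flavor or
#' drug compound.  The operation is idempotent and depends only on
#' compound-edge incidence.
#'
#' @param graph a [build_graph()] result.
#' @return The graph with `nodes$is_hub` recomputed.
#' @export
classify_hubs <- function(graph) {
  stopifnot(inherits(graph, "hetero_graph"))
  comp_edges <- graph$edges[graph$edges$edge_type %in% c("if", "id"), ,
                            drop = FALSE]
  hubs <- unique(comp_edges$src)
  graph$nodes$is_hub <- graph$nodes$node_type == "ingredient" &
    graph$nodes$node_id %in% hubs
  graph
}

#' @export
print.hetero_graph <- function(x, ...) {
  tn <- table(factor(x$nodes$node_type, levels = NODE_TYPES))
  te <- table(factor(x$edges$edge_type, levels = c("ii", "if", "id")))
  cat("<hetero_graph>\n")
  cat(sprintf("  nodes: %d ingredient (%d hubs), %d flavor_compound, %d drug_compound\n",
              tn[["ingredient"]], sum(x$nodes$is_hub),
              tn[["flavor_compound"]], tn[["drug_compound"]]))
  cat(sprintf("  edges: %d ii (NPMI-weighted), %d if, %d id\n",
              te[["ii"]], te[["if"]], te[["id"]]))
  cat(sprintf("  fingerprints: %d compounds labeled (%d bits)\n",
              if (is.null(x$fingerprints)) 0L else nrow(x$fingerprints),
              FINGERPRINT_LENGTH))
  invisible(x)
}

#' Neighbors of a node, filtered by class
#'
#' @param graph a `hetero_graph`.
#' @param node_id a node identifier present in the graph.
#' @param wanted one of `"FLAVOR_COMPOUND"`, `"DRUG_COMPOUND"`,
#'   `"ANY_COMPOUND"`, `"HUB_INGREDIENT"`, `"NONHUB_INGREDIENT"`,
#'   `"ANY_INGREDIENT"`.
#' @return Sorted character vector of unique neighbor ids of that class.
#' @export
neighbors_by_type <- function(graph, node_id, wanted) {
  stopifnot(inherits(graph, "hetero_graph"))
  if (!node_id %in% graph$nodes$node_id) {
    stop("unknown node_id: '", node_id, "'", call. = FALSE)
  }
  if (!is.character(wanted) || length(wanted) != 1L ||
      !wanted %in% NEIGHBOR_CLASSES) {
    stop("unknown neighbor class: '", paste(wanted, collapse = ","), "'",
         call. = FALSE)
  }
  e <- graph$edges
  nb <- c(e$dst[e$src == node_id], e$src[e$dst == node_id])
  nb <- unique(nb)
  keep <- .node_in_class(graph, nb, wanted)
  sort(nb[keep])
}

# Membership of node ids in a walk/neighbor class.
.node_in_class <- function(graph, ids, class) {
  idx <- match(ids, graph$nodes$node_id)
  ty <- graph$nodes$node_type[idx]
  hub <- graph$nodes$is_hub[idx]
  switch(class,
    FLAVOR_COMPOUND = ty == "flavor_compound",
    DRUG_COMPOUND = ty == "drug_compound",
    ANY_COMPOUND = ty %in% c("flavor_compound", "drug_compound"),
    HUB_INGREDIENT = ty == "ingredient" & hub,
    NONHUB_INGREDIENT = ty == "ingredient" & !hub,
    ANY_INGREDIENT = ty == "ingredient",
    stop("unknown neighbor class: '", class, "'", call. = FALSE)
  )
}

# Walk-level class symbol (C / H / N) of every node, in node-table order.
.walk_class <- function(graph) {
  ifelse(graph$nodes$node_type != "ingredient", "C",
         ifelse(graph$nodes$is_hub, "H", "N"))
}

.normalize_nodes <- function(nodes) {
  if (!is.data.frame(nodes) || !all(c("node_id", "node_type") %in% names(nodes))) {
    stop("nodes must be a data.frame with node_id and node_type columns",
         call. = FALSE)
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$name)) nodes$name <- nodes$node_id
  if (is.null(nodes$category)) nodes$category <- NA_character_
  nodes$node_id <- as.character(nodes$node_id)
  nodes$name <- as.character(nodes$name)
  nodes$node_type <- as.character(nodes$node_type)
  nodes$category <- as.character(nodes$category)
  nodes$category[!is.na(nodes$category) & nodes$category == ""] <- NA_character_
  bad <- !nodes$node_type %in% NODE_TYPES
  if (any(bad)) {
    stop("invalid node_type '", nodes$node_type[bad][1L], "' for node '",
         nodes$node_id[bad][1L], "'", call. = FALSE)
  }
  badcat <- !is.na(nodes$category) & !nodes$category %in% FOOD_CATEGORIES
  if (any(badcat)) {
    stop("invalid category '", nodes$category[badcat][1L], "' for node '",
         nodes$node_id[badcat][1L], "'", call. = FALSE)
  }
  nodes$is_hub <- FALSE
  nodes[, c("node_id", "name", "node_type", "category", "is_hub")]
}

.normalize_ii_edges <- function(ii_edges, type_of) {
  empty <- data.frame(src = character(), dst = character(),
                      edge_type = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(ii_edges) || nrow(ii_edges) == 0L) return(empty)
  src <- as.character(ii_edges$src)
  dst <- as.character(ii_edges$dst)
  if (is.null(ii_edges$weight)) {
    stop("ii edges require a weight (NPMI) column", call. = FALSE)
  }
  w <- as.numeric(ii_edges$weight)
  .check_endpoints(c(src, dst), type_of)
  if (any(src == dst)) {
    stop("self-loop on '", src[src == dst][1L], "'", call. = FALSE)
  }
  bad <- type_of[src] != "ingredient" | type_of[dst] != "ingredient"
  if (any(bad)) {
    stop("ii edge endpoints must both be ingredients: ",
         src[bad][1L], " -- ", dst[bad][1L], call. = FALSE)
  }
  # canonical orientation: lexicographically smaller id first (NPMI symmetric)
  flip <- src > dst
  tmp <- src[flip]; src[flip] <- dst[flip]; dst[flip] <- tmp
  key <- paste(src, dst, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate ii edge: ", src[d], " -- ", dst[d], call. = FALSE)
  }
  o <- order(src, dst)
  data.frame(src = src[o], dst = dst[o], edge_type = "ii", weight = w[o],
             stringsAsFactors = FALSE)
}

.normalize_ic_edges <- function(ic_edges, type_of) {
  empty <- data.frame(src = character(), dst = character(),
                      edge_type = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(ic_edges) || nrow(ic_edges) == 0L) return(empty)
  src <- as.character(ic_edges$src)
  dst <- as.character(ic_edges$dst)
  .check_endpoints(c(src, dst), type_of)
  # orient ingredient -> compound
  flip <- type_of[src] != "ingredient" & type_of[dst] == "ingredient"
  tmp <- src[flip]; src[flip] <- dst[flip]; dst[flip] <- tmp
  bad <- type_of[src] != "ingredient" |
    !type_of[dst] %in% c("flavor_compound", "drug_compound")
  if (any(bad)) {
    stop("ingredient-compound edge must join an ingredient and a compound: ",
         src[bad][1L], " -- ", dst[bad][1L], call. = FALSE)
  }
  et <- ifelse(type_of[dst] == "flavor_compound", "if", "id")
  if (!is.null(ic_edges$edge_type)) {
    given <- as.character(ic_edges$edge_type)
    ok <- is.na(given) | given == "" | given == et
    if (!all(ok)) {
      stop("edge_type '", given[!ok][1L], "' inconsistent with compound type for ",
           src[!ok][1L], " -- ", dst[!ok][1L], call. = FALSE)
    }
  }
  key <- paste(src, dst, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate compound edge: ", src[d], " -- ", dst[d], call. = FALSE)
  }
  o <- order(src, dst)
  data.frame(src = src[o], dst = dst[o], edge_type = et[o],
             weight = NA_real_, stringsAsFactors = FALSE)
}

.check_endpoints <- function(ids, type_of) {
  missing <- setdiff(unique(ids), names(type_of))
  if (length(missing)) {
    stop("edge references unknown node_id: '", missing[1L], "'", call. = FALSE)
  }
  invisible(TRUE)
}

.normalize_fingerprints <- function(fingerprints, nodes) {
  if (is.null(fingerprints)) return(NULL)
  if (is.list(fingerprints) && !is.data.frame(fingerprints)) {
    fingerprints <- do.call(rbind, fingerprints)
  }
  fp <- as.matrix(fingerprints)
  storage.mode(fp) <- "integer"
  if (ncol(fp) != FINGERPRINT_LENGTH) {
    stop("fingerprints must have exactly ", FINGERPRINT_LENGTH,
         " bits, got ", ncol(fp), call. = FALSE)
  }
  if (is.null(rownames(fp))) {
    stop("fingerprints must be named by compound node_id", call. = FALSE)
  }
  if (!all(fp %in% c(0L, 1L))) {
    stop("fingerprint bits must be 0 or 1", call. = FALSE)
  }
  idx <- match(rownames(fp), nodes$node_id)
  if (anyNA(idx)) {
    stop("fingerprint for unknown node_id: '",
         rownames(fp)[is.na(idx)][1L], "'", call. = FALSE)
  }
  ty <- nodes$node_type[idx]
  if (any(ty == "ingredient")) {
    stop("fingerprints attach to compound nodes, not ingredients ('",
         rownames(fp)[ty == "ingredient"][1L], "')", call. = FALSE)
  }
  fp[order(rownames(fp)), , drop = FALSE]
}
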