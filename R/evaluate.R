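#' Cosine similarity
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return `a . b / (||a|| ||b||)`, in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector in cosine similarity", call. = FALSE)
  sum(a * b) / (na * nb)
}

# cosine of one query vector against rows of a matrix
.cosine_rows <- function(mat, q) {
  qn <- sqrt(sum(q^2))
  if (qn == 0) stop("zero query vector", call. = FALSE)
  rn <- sqrt(rowSums(mat^2))
  if (any(rn == 0)) stop("zero embedding vector for token '",
                         rownames(mat)[rn == 0][1L], "'", call. = FALSE)
  as.numeric(mat %*% q) / (rn * qn)
}

#' Similarity-based pairing recommendation
#'
#' Sums the center vectors of the query tokens and ranks candidate nodes by
#' cosine similarity to the summed query vector, descending, ties broken by
#' token id.  Query tokens are not excluded from the results (a
#' single-token query typically ranks itself first).
#'
#' @param model an [embedding_model()].
#' @param query_tokens one or more tokens; their vectors are summed
#'   element-wise.
#' @param k number of recommendations.
#' @param graph optional `hetero_graph`, required when `restrict` is a
#'   node-class name.
#' @param restrict `NULL` (whole vocabulary), a neighbor-class name such as
#'   `"NONHUB_INGREDIENT"` (with `graph`), or a character vector of
#'   candidate tokens.
#' @return data.frame with columns `token`, `score`, at most `k` rows.
#' @export
pairing_query <- function(model, query_tokens, k = 10L, graph = NULL,
                          restrict = NULL) {
  stopifnot(inherits(model, "embedding_model"), k >= 1)
  qi <- .token_index(model, query_tokens)
  q <- colSums(model$center[qi, , drop = FALSE])

  candidates <- model$vocab
  if (!is.null(restrict)) {
    if (length(restrict) == 1L && restrict %in% NEIGHBOR_CLASSES) {
      if (is.null(graph)) {
        stop("restrict by node class requires the graph", call. = FALSE)
      }
      ids <- graph$nodes$node_id
      candidates <- intersect(model$vocab,
                              ids[.node_in_class(graph, ids, restrict)])
    } else {
      candidates <- intersect(model$vocab, as.character(restrict))
    }
  }
  if (!length(candidates)) {
    return(data.frame(token = character(), score = numeric()))
  }
  candidates <- sort(candidates)
  sc <- .cosine_rows(model$center[candidates, , drop = FALSE], q)
  o <- order(-sc, candidates)
  top <- head(o, k)
  data.frame(token = candidates[top], score = sc[top],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalized mutual information between two labelings
#'
#' Arithmetic-mean normalization: `NMI = 2 I(A;B) / (H(A) + H(B))`, in
#' \[0, 1\].  Two constant labelings (zero entropy on both sides) are
#' identical partitions and score 1.
#'
#' @param a,b vectors of equal length (any label type).
#' @return NMI in \[0, 1\].
#' @export
nmi_score <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  if (ha + hb == 0) return(1)
  max(0, min(1, 2 * mi / (ha + hb)))
}

#' Cluster labeled nodes and score against categories
#'
#' Runs k-means (Euclidean, `n_init` restarts, fixed seed) on the center
#' vectors of the labeled nodes and reports the NMI between cluster
#' assignments and the reference categories.
#'
#' @param model an [embedding_model()].
#' @param labeled_nodes named character vector: `node token -> category`.
#' @param k number of clusters (default 9, one per food category).
#' @param n_init k-means restarts.
#' @param seed RNG seed for k-means.
#' @return A `clustering_result`: list with `assignments` (named integer
#'   vector), `nmi`, `k`, `seed`.
#' @export
cluster_and_score <- function(model, labeled_nodes, k = 9L, n_init = 10L,
                              seed = 0L) {
  stopifnot(inherits(model, "embedding_model"),
            !is.null(names(labeled_nodes)))
  if (length(labeled_nodes) < k) {
    stop("need at least k = ", k, " labeled nodes, got ",
         length(labeled_nodes), call. = FALSE)
  }
  idx <- .token_index(model, names(labeled_nodes))
  X <- model$center[idx, , drop = FALSE]
  km <- .with_seed(seed, kmeans(X, centers = k, nstart = n_init,
                                iter.max = 100L))
  assignments <- setNames(km$cluster, names(labeled_nodes))
  structure(list(assignments = assignments,
                 nmi = nmi_score(assignments, unname(labeled_nodes)),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> k = %d, n = %d, NMI = %.3f\n",
              x$k, length(x$assignments), x$nmi))
  invisible(x)
}

#' Category-level Jaccard similarity of chemical profiles
#'
#' Each chemical-hub ingredient's profile is its set of connected
#' compounds.  Entry (g, h) is the mean Jaccard similarity
#' `|C_i over C_j| / |C_i union C_j|` over all pairs with i in category g,
#' j in category h, i != j.  Categories with no hubs yield `NA` entries.
#'
#' @param graph a `hetero_graph` whose hub ingredients carry categories.
#' @param categories category levels for the matrix (defaults to the levels
#'   present among hubs).
#' @return Symmetric numeric matrix of mean Jaccard similarities.
#' @export
jaccard_category_matrix <- function(graph, categories = NULL) {
  stopifnot(inherits(graph, "hetero_graph"))
  nodes <- graph$nodes
  hubs <- nodes$node_id[nodes$is_hub & !is.na(nodes$category)]
  cats <- setNames(nodes$category, nodes$node_id)[hubs]
  if (is.null(categories)) categories <- sort(unique(unname(cats)))
  ce <- graph$edges[graph$edges$edge_type %in% c("if", "id"), , drop = FALSE]
  sets <- split(ce$dst, ce$src)[hubs]
  names(sets) <- hubs

  jac <- function(i, j) {
    a <- sets[[i]]; b <- sets[[j]]
    length(intersect(a, b)) / length(union(a, b))
  }
  m <- matrix(NA_real_, length(categories), length(categories),
              dimnames = list(categories, categories))
  for (gi in seq_along(categories)) {
    for (hi in gi:length(categories)) {
      g_ids <- hubs[cats == categories[gi]]
      h_ids <- hubs[cats == categories[hi]]
      if (!length(g_ids) || !length(h_ids)) next
      if (gi == hi) {
        if (length(g_ids) < 2L) next
        pairs <- combn(g_ids, 2L)
        vals <- mapply(jac, pairs[1L, ], pairs[2L, ])
      } else {
        grid <- expand.grid(i = g_ids, j = h_ids, stringsAsFactors = FALSE)
        vals <- mapply(jac, grid$i, grid$j)
      }
      m[gi, hi] <- m[hi, gi] <- mean(vals)
    }
  }
  m
}

#' Predict compound-food relations by similarity threshold
#'
#' An edge (compound, food) is predicted iff the cosine similarity of their
#' center vectors is at least `threshold`.  Monotone: raising the threshold
#' shrinks the predicted set.
#'
#' @param model an [embedding_model()].
#' @param compound_tokens,food_tokens tokens present in the vocabulary.
#' @param threshold cosine threshold in \[-1, 1\].
#' @return data.frame with columns `src` (compound), `dst` (food), `score`.
#' @export
predict_relations <- function(model, compound_tokens, food_tokens, threshold) {
  stopifnot(inherits(model, "embedding_model"))
  ci <- .token_index(model, compound_tokens)
  fi <- .token_index(model, food_tokens)
  C <- model$center[ci, , drop = FALSE]
  F <- model$center[fi, , drop = FALSE]
  cn <- sqrt(rowSums(C^2)); fn <- sqrt(rowSums(F^2))
  if (any(cn == 0) || any(fn == 0)) {
    stop("zero embedding vector in relation prediction", call. = FALSE)
  }
  S <- (C %*% t(F)) / outer(cn, fn)
  hit <- which(S >= threshold, arr.ind = TRUE)
  out <- data.frame(src = compound_tokens[hit[, 1L]],
                    dst = food_tokens[hit[, 2L]],
                    score = S[hit], stringsAsFactors = FALSE)
  out <- out[order(out$src, out$dst), ]
  rownames(out) <- NULL
  out
}

.edge_keys <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(character())
  paste(edges[[1L]], edges[[2L]], sep = "\r")
}

#' Confusion metrics for relation prediction
#'
#' Scores a predicted edge set against gold relations within an explicit
#' candidate universe.  `tp = |predicted over gold|`,
#' `fp = |predicted minus gold|`, `fn = |gold minus predicted|`,
#' `tn = |universe minus (predicted union gold)|`.  Precision, recall and F1
#' depend only on predicted/gold; accuracy and Matthews correlation require
#' the universe (MCC is 0 by convention when any marginal factor is 0).
#'
#' @param predicted,gold,candidate_universe two-column data.frames of edges
#'   (src, dst); `predicted` and `gold` must be subsets of the universe.
#' @return A `relation_prediction_eval`: list with counts (`n_gold`,
#'   `n_pred`, `tp`, `fp_unknown`, `fn`, `tn`) and metrics (`accuracy`,
#'   `precision`, `recall`, `f1`, `mcc`).
#' @export
confusion_metrics <- function(predicted, gold, candidate_universe) {
  pk <- unique(.edge_keys(predicted))
  gk <- unique(.edge_keys(gold))
  uk <- unique(.edge_keys(candidate_universe))
  if (!length(uk)) stop("empty candidate universe", call. = FALSE)
  if (!all(pk %in% uk) || !all(gk %in% uk)) {
    stop("predicted and gold edges must lie within the candidate universe",
         call. = FALSE)
  }
  tp <- length(intersect(pk, gk))
  fp <- length(setdiff(pk, gk))
  fn <- length(setdiff(gk, pk))
  tn <- length(uk) - length(union(pk, gk))
  n_pred <- length(pk)
  n_gold <- length(gk)
  precision <- if (n_pred > 0) tp / n_pred else 0
  recall <- if (n_gold > 0) tp / n_gold else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(list(n_gold = n_gold, n_pred = n_pred, tp = tp,
                 fp_unknown = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / length(uk),
                 precision = precision, recall = recall, f1 = f1, mcc = mcc),
            class = "relation_prediction_eval")
}

#' @export
print.relation_prediction_eval <- function(x, ...) {
  cat("<relation_prediction_eval>\n")
  cat(sprintf("  gold %d | predicted %d (known %d, unknown %d) | missed %d\n",
              x$n_gold, x$n_pred, x$tp, x$fp_unknown, x$fn))
  cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f  MCC %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$mcc))
  invisible(x)
}

#' Pick the F1-maximizing relation threshold
#'
#' Scans the cosine scores of all (compound, food) candidates and returns
#' the threshold maximizing F1 against the gold edges.
#'
#' @inheritParams predict_relations
#' @param gold two-column data.frame of known relations.
#' @return List with `threshold` and `f1`.
#' @export
calibrate_threshold <- function(model, compound_tokens, food_tokens, gold) {
  all_pred <- predict_relations(model, compound_tokens, food_tokens, -1)
  gk <- .edge_keys(gold)
  scores <- sort(unique(all_pred$score), decreasing = TRUE)
  keys <- .edge_keys(all_pred)
  best <- list(threshold = 1, f1 = 0)
  for (th in scores) {
    pk <- keys[all_pred$score >= th]
    tp <- sum(pk %in% gk)
    prec <- tp / length(pk)
    rec <- tp / length(gk)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    if (f1 > best$f1) best <- list(threshold = th, f1 = f1)
  }
  best
}

#' Leave-one-out AUC of fingerprint-bit recovery from embeddings
#'
#' A linear-decodability probe of how much chemical-structure information
#' the compound embeddings carry, independent of the trained CSP head: for
#' every fingerprint bit with at least two compounds in each class, a ridge
#' regression from the (centered) compound embeddings to the bit is
#' evaluated by exact leave-one-out prediction (hat-matrix identity), and
#' the AUC of the held-out scores is averaged over those bits.  The probe's
#' hypothesis class (a linear map from embedding to bit) matches what the
#' CSP head optimizes, so it measures precisely the information that head
#' is meant to inject.
#'
#' @param model an [embedding_model()].
#' @param fingerprints integer matrix (rownames = compound tokens).
#' @param ridge ridge penalty (default 1).
#' @return Mean leave-one-out AUC over informative bits.
#' @export
fingerprint_auc <- function(model, fingerprints, ridge = 1) {
  toks <- intersect(rownames(fingerprints), model$vocab)
  stopifnot(length(toks) >= 5L)
  X <- model$center[toks, , drop = FALSE]
  X <- scale(X, center = TRUE, scale = FALSE)
  n <- nrow(X)
  Y <- fingerprints[toks, , drop = FALSE]
  pos <- colSums(Y)
  keep <- pos >= 2 & pos <= n - 2
  if (!any(keep)) stop("no fingerprint bit has >= 2 compounds per class",
                       call. = FALSE)
  K <- X %*% solve(crossprod(X) + ridge * diag(ncol(X)), t(X))
  h <- diag(K)
  Yk <- Y[, keep, drop = FALSE]
  Yc <- scale(Yk, center = TRUE, scale = FALSE)
  fit <- K %*% Yc
  loo <- Yc - (Yc - fit) / (1 - h) # exact LOO for a linear smoother
  aucs <- vapply(seq_len(ncol(Yk)), function(j) .auc(loo[, j], Yk[, j]),
                 numeric(1))
  mean(aucs)
}

# rank-based (Mann-Whitney) AUC with midranks for ties
.auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1)
  n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
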