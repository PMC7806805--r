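# Shared fixtures and independent brute-force oracles.  Everything is built
# in code; oracles deliberately use the dumbest possible algorithm.

# minimal path graph c1 - h1 - n1 (one compound, one hub, one non-hub)
path_graph <- function() {
  nodes <- data.frame(
    node_id = c("c1", "h1", "n1"),
    name = c("c1", "h1", "n1"),
    node_type = c("flavor_compound", "ingredient", "ingredient")
  )
  build_graph(nodes,
              ii_edges = data.frame(src = "h1", dst = "n1", weight = 0.3),
              ic_edges = data.frame(src = "h1", dst = "c1"))
}

# two hubs, two compounds, one non-hub: supports full C-H-N-H-C traversal
pentagon_graph <- function() {
  nodes <- data.frame(
    node_id = c("c1", "c2", "h1", "h2", "n1"),
    name = c("c1", "c2", "h1", "h2", "n1"),
    node_type = c("flavor_compound", "drug_compound", "ingredient",
                  "ingredient", "ingredient")
  )
  build_graph(
    nodes,
    ii_edges = data.frame(src = c("h1", "h2"), dst = c("n1", "n1"),
                          weight = c(0.4, 0.5)),
    ic_edges = data.frame(src = c("h1", "h2"), dst = c("c1", "c2"))
  )
}

# random heterogeneous graph for property tests (deterministic under seed)
random_graph <- function(seed, n_ing = 10L, n_cmp = 5L, p_ii = 0.3,
                         p_ic = 0.25) {
  withr::local_seed(seed)
  ing <- sprintf("i%02d", seq_len(n_ing))
  cmp <- sprintf("c%02d", seq_len(n_cmp))
  cmp_type <- sample(c("flavor_compound", "drug_compound"), n_cmp,
                     replace = TRUE)
  nodes <- data.frame(
    node_id = c(ing, cmp), name = c(ing, cmp),
    node_type = c(rep("ingredient", n_ing), cmp_type)
  )
  pairs <- t(combn(ing, 2L))
  keep <- runif(nrow(pairs)) < p_ii
  ii <- data.frame(src = pairs[keep, 1L], dst = pairs[keep, 2L],
                   weight = round(runif(sum(keep), -1, 1), 3))
  grid <- expand.grid(src = ing, dst = cmp, stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < p_ic, ]
  build_graph(nodes, ii, grid)
}

# random small recipe corpus
random_corpus <- function(seed, n_recipes = 50L, vocab_size = 12L,
                          max_size = 6L) {
  withr::local_seed(seed)
  vocab <- sprintf("t%02d", seq_len(vocab_size))
  recipe_corpus(lapply(seq_len(n_recipes), function(i) {
    sample(vocab, sample.int(max_size, 1L))
  }))
}

# independent node-class membership straight from the node table
class_members <- function(g, cls) {
  ty <- g$nodes$node_type
  hub <- g$nodes$is_hub
  id <- g$nodes$node_id
  switch(cls,
    FLAVOR_COMPOUND = id[ty == "flavor_compound"],
    DRUG_COMPOUND = id[ty == "drug_compound"],
    ANY_COMPOUND = id[ty != "ingredient"],
    HUB_INGREDIENT = id[ty == "ingredient" & hub],
    NONHUB_INGREDIENT = id[ty == "ingredient" & !hub],
    ANY_INGREDIENT = id[ty == "ingredient"]
  )
}

# brute-force co-occurrence: double loop over recipes and token pairs
oracle_cooccurrence <- function(corpus) {
  unigram <- list()
  joint <- list()
  for (r in corpus$recipes) {
    for (x in r) unigram[[x]] <- (unigram[[x]] %||% 0L) + 1L
    if (length(r) >= 2L) {
      for (a in seq_len(length(r) - 1L)) {
        for (b in (a + 1L):length(r)) {
          k <- paste(sort(c(r[a], r[b])), collapse = "\r")
          joint[[k]] <- (joint[[k]] %||% 0L) + 1L
        }
      }
    }
  }
  list(unigram = unlist(unigram), joint = unlist(joint))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# direct NPMI from probabilities, independent of the package's count-space
# formulation
oracle_npmi <- function(n, cx, cy, cxy) {
  if (cxy == 0L) return(-1)
  px <- cx / n; py <- cy / n; pxy <- cxy / n
  if (pxy == 1) return(1)
  log(pxy / (px * py)) / (-log(pxy))
}

# literal A-union-B-union-C edge filter over every token pair
oracle_select_edges <- function(stats, min_unigram = 20L, min_joint = 5L,
                                npmi_min = 0.25, rescue_top_k = 20L) {
  toks <- sort(names(stats$unigram))
  if (length(toks) < 2L) {
    return(data.frame(src = character(), dst = character(),
                      weight = numeric()))
  }
  pairs <- t(combn(toks, 2L))
  n <- stats$n_recipes
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- pairs[i, 1L]; y <- pairs[i, 2L]
    key <- paste(x, y, sep = "\r")
    cxy <- stats$joint[key]
    cxy <- if (is.na(cxy)) 0L else cxy
    data.frame(src = x, dst = y, cxy = cxy,
               cx = stats$unigram[[x]], cy = stats$unigram[[y]],
               npmi = oracle_npmi(n, stats$unigram[[x]],
                                  stats$unigram[[y]], cxy))
  })
  df <- do.call(rbind, rows)
  a <- df$cx > min_unigram & df$cy > min_unigram & df$cxy > min_joint
  b <- df$npmi >= npmi_min
  below <- df[!b, ]
  below <- below[order(-below$npmi, below$src, below$dst), ]
  ck <- head(paste(below$src, below$dst, sep = "\r"), rescue_top_k)
  c_rule <- paste(df$src, df$dst, sep = "\r") %in% ck
  # rescue pool only covers enumerable vocabularies, same as the package
  sel <- df[(a | b | c_rule) & (df$cxy > 0L | c_rule), ]
  sel <- sel[order(sel$src, sel$dst), c("src", "dst", "npmi")]
  names(sel)[3L] <- "weight"
  rownames(sel) <- NULL
  sel
}

# full-scan ranking oracle for pairing queries
oracle_topk <- function(model, query_tokens, k, candidates) {
  q <- colSums(model$center[query_tokens, , drop = FALSE])
  sc <- vapply(candidates, function(tok) {
    cosine_similarity(model$center[tok, ], q)
  }, numeric(1))
  o <- order(-sc, candidates)
  data.frame(token = candidates[o][seq_len(min(k, length(candidates)))],
             score = unname(sc[o][seq_len(min(k, length(candidates)))]),
             stringsAsFactors = FALSE)
}

# random embedding model with nonzero rows
random_model <- function(seed, vocab, d = 8L) {
  withr::local_seed(seed)
  center <- matrix(rnorm(length(vocab) * d), length(vocab), d,
                   dimnames = list(vocab, NULL))
  context <- matrix(rnorm(length(vocab) * d), length(vocab), d,
                    dimnames = list(vocab, NULL))
  m <- embedding_model(center, context)
  m$csp_weights <- matrix(rnorm(d * 881, sd = 0.3), d, 881)
  m$csp_bias <- rnorm(881, sd = 0.3)
  m
}

random_fingerprint <- function(seed, p = 0.3) {
  withr::local_seed(seed)
  as.integer(runif(881) < p)
}

# tiny trained world reused across embedding tests (cached per session)
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_synthetic_world(synthetic_spec(n_recipes = 250L,
                                                    seed = 7L))
    }
    cache
  }
})

small_walks <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- small_world()$graph
      cache <<- merge_corpora(list(
        generate_metapath_walks(g, metapath_schema("CHNHC"), 10L, 50L, 1L),
        generate_metapath_walks(g, metapath_schema("NHCHN"), 10L, 50L, 2L),
        generate_uniform_walks(g, 10L, 50L, 3L)
      ), seed = 4L)
    }
    cache
  }
})
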