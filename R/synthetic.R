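#' Synthetic-world specification
#'
#' Parameters of the deterministic generator that emulates the pipeline's
#' real inputs: a recipe corpus with planted ingredient communities and a
#' compound layer whose fingerprints carry community-specific bit
#' signatures (same-category foods share compounds; same-community
#' compounds share substructure bits).  Defaults are sized so the full
#' corpus-to-clustering pipeline runs in minutes on one CPU: 3 communities
#' of 20 ingredients (30% hubs), 10 compounds per community, 2000 recipes
#' of 6 ingredients.
#'
#' @param n_communities number of planted communities.
#' @param ingredients_per_community ingredients per community.
#' @param hub_fraction fraction of each community's ingredients that get
#'   compound edges (chemical hubs), in (0, 1].
#' @param compounds_per_community compounds per community (the last one of
#'   each community is a drug compound, the rest flavor compounds).
#' @param n_recipes,recipe_size corpus shape.
#' @param within_community_prob,cross_community_prob sampling weight of the
#'   recipe's home community vs. each other community when drawing
#'   ingredients (normalized; within must exceed cross for planted
#'   structure).
#' @param signal_bits_per_community fingerprint bits reserved per community
#'   (blocks are disjoint; at most `881 / n_communities`).
#' @param bit_noise probability of flipping each fingerprint bit.
#' @param seed generator seed; outputs are byte-identical under the same
#'   seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_communities = 3L, ingredients_per_community = 20L,
                           hub_fraction = 0.3, compounds_per_community = 10L,
                           n_recipes = 2000L, recipe_size = 6L,
                           within_community_prob = 0.8,
                           cross_community_prob = 0.1,
                           signal_bits_per_community = 40L, bit_noise = 0.02,
                           seed = 7L) {
  stopifnot(n_communities >= 1, ingredients_per_community >= 1,
            hub_fraction > 0, hub_fraction <= 1,
            compounds_per_community >= 1, n_recipes >= 1, recipe_size >= 1,
            within_community_prob >= 0, within_community_prob <= 1,
            cross_community_prob >= 0, cross_community_prob <= 1,
            bit_noise >= 0, bit_noise <= 1)
  if (n_communities > 1 && within_community_prob <= cross_community_prob) {
    stop("within_community_prob must exceed cross_community_prob for planted structure",
         call. = FALSE)
  }
  if (n_communities * signal_bits_per_community > FINGERPRINT_LENGTH) {
    stop("signal bit blocks must be disjoint within ", FINGERPRINT_LENGTH,
         " bits", call. = FALSE)
  }
  if (recipe_size > n_communities * ingredients_per_community) {
    stop("recipe_size exceeds the total number of ingredients", call. = FALSE)
  }
  if (n_communities > length(FOOD_CATEGORIES)) {
    stop("at most ", length(FOOD_CATEGORIES), " communities (one category each)",
         call. = FALSE)
  }
  structure(list(
    n_communities = as.integer(n_communities),
    ingredients_per_community = as.integer(ingredients_per_community),
    hub_fraction = hub_fraction,
    compounds_per_community = as.integer(compounds_per_community),
    n_recipes = as.integer(n_recipes), recipe_size = as.integer(recipe_size),
    within_community_prob = within_community_prob,
    cross_community_prob = cross_community_prob,
    signal_bits_per_community = as.integer(signal_bits_per_community),
    bit_noise = bit_noise, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

.synth_ingredients <- function(spec) {
  k <- rep(seq_len(spec$n_communities), each = spec$ingredients_per_community)
  id <- sprintf("ing_c%d_%02d", k,
                sequence(rep(spec$ingredients_per_community,
                             spec$n_communities)))
  setNames(k, id)
}

.synth_compounds <- function(spec) {
  k <- rep(seq_len(spec$n_communities), each = spec$compounds_per_community)
  id <- sprintf("cmp_c%d_%02d", k,
                sequence(rep(spec$compounds_per_community,
                             spec$n_communities)))
  setNames(k, id)
}

#' Generate a synthetic recipe corpus with planted communities
#'
#' Each recipe draws a home community uniformly, then samples
#' `recipe_size` distinct ingredients: community membership of each slot is
#' drawn with weight `within_community_prob` for the home community and
#' `cross_community_prob` for each other community (normalized), and
#' ingredients are drawn without replacement within each community.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `corpus` (a [recipe_corpus()]), `communities` (named
#'   integer vector ingredient -> community), `home` (integer vector of each
#'   recipe's home community).
#' @export
make_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  communities <- .synth_ingredients(spec)
  by_comm <- split(names(communities), communities)
  K <- spec$n_communities
  .with_seed(spec$seed, {
    home <- sample.int(K, spec$n_recipes, replace = TRUE)
    recipes <- vector("list", spec$n_recipes)
    for (r in seq_len(spec$n_recipes)) {
      w <- rep(spec$cross_community_prob, K)
      w[home[r]] <- spec$within_community_prob
      if (sum(w) == 0) w[] <- 1
      slots <- sample.int(K, spec$recipe_size, replace = TRUE, prob = w)
      counts <- tabulate(slots, nbins = K)
      counts <- pmin(counts, lengths(by_comm)) # sets cannot exceed pool size
      recipes[[r]] <- unlist(lapply(seq_len(K), function(kk) {
        if (counts[kk] == 0L) return(character())
        sample(by_comm[[kk]], counts[kk])
      }), use.names = FALSE)
    }
    list(corpus = recipe_corpus(recipes), communities = communities,
         home = home)
  })
}

#' Build the synthetic graph and fingerprints
#'
#' Turns a synthetic corpus into a full heterogeneous graph: NPMI-selected
#' ingredient-ingredient edges, hub ingredients (the first
#' `ceil(hub_fraction * n)` of each community) linked to every compound of
#' their community, community-signature fingerprints (signal-block bits set,
#' then each of the 881 bits flipped with probability `bit_noise`), and
#' category labels mapping community k to the k-th food category.
#'
#' @param spec a [synthetic_spec()].
#' @param corpus_info result of [make_corpus()] (generated from `spec` when
#'   omitted).
#' @param edge_args list of arguments to [select_ingredient_edges()].  The
#'   default disables the absolute-count rule and selects pairs with
#'   NPMI > 0 (positive association): the production thresholds (counts
#'   over a million-recipe corpus, NPMI 0.25) are calibrated to a much
#'   larger, sparser world, while a desk-scale corpus of a few thousand
#'   recipes over 60 ingredients has p(x, y) large enough that every pair
#'   passes the count rule and no pair can reach NPMI 0.25; the
#'   independence point 0 is the scale-free boundary between the planted
#'   within-community association and cross-community noise.
#' @return List with `graph` (`hetero_graph`), `fingerprints` (matrix),
#'   `labels` (named character vector: ingredient -> category),
#'   `communities`, `corpus` and `bookkeeping` (expected node/edge counts).
#' @export
make_graph_and_fingerprints <- function(spec, corpus_info = NULL,
                                        edge_args = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(edge_args)) {
    # counts can never exceed n_recipes, so these bounds disable rule A
    edge_args <- list(min_unigram = spec$n_recipes, min_joint = spec$n_recipes,
                      npmi_min = 0, rescue_top_k = 0L)
  }
  if (is.null(corpus_info)) corpus_info <- make_corpus(spec)
  communities <- corpus_info$communities
  compounds <- .synth_compounds(spec)
  K <- spec$n_communities

  n_hub <- ceiling(spec$hub_fraction * spec$ingredients_per_community)
  by_comm <- split(names(communities), communities)
  hubs <- unlist(lapply(by_comm, head, n_hub), use.names = FALSE)

  comp_type <- ifelse(
    spec$compounds_per_community >= 2 &
      seq_along(compounds) %% spec$compounds_per_community == 0,
    "drug_compound", "flavor_compound"
  )
  nodes <- rbind(
    data.frame(node_id = names(communities), name = names(communities),
               node_type = "ingredient",
               category = FOOD_CATEGORIES[communities],
               stringsAsFactors = FALSE),
    data.frame(node_id = names(compounds), name = names(compounds),
               node_type = comp_type, category = NA_character_,
               stringsAsFactors = FALSE)
  )

  ic_edges <- do.call(rbind, lapply(hubs, function(h) {
    data.frame(src = h, dst = names(compounds)[compounds == communities[[h]]],
               stringsAsFactors = FALSE)
  }))

  stats <- count_cooccurrence(corpus_info$corpus)
  ii_edges <- do.call(select_ingredient_edges, c(list(stats), edge_args))

  fp <- .with_seed(spec$seed + 1L, {
    m <- matrix(0L, length(compounds), FINGERPRINT_LENGTH,
                dimnames = list(names(compounds), NULL))
    for (i in seq_along(compounds)) {
      kk <- compounds[i]
      bits <- ((kk - 1L) * spec$signal_bits_per_community + 1L):
        (kk * spec$signal_bits_per_community)
      m[i, bits] <- 1L
      if (spec$bit_noise > 0) {
        flip <- runif(FINGERPRINT_LENGTH) < spec$bit_noise
        m[i, flip] <- 1L - m[i, flip]
      }
    }
    m
  })

  graph <- build_graph(nodes, ii_edges, ic_edges, fp)
  labels <- setNames(FOOD_CATEGORIES[communities], names(communities))
  bookkeeping <- list(
    n_nodes = length(communities) + length(compounds),
    n_ingredients = length(communities),
    n_compounds = length(compounds),
    n_hubs = length(hubs),
    n_ii_edges = nrow(ii_edges),
    n_ic_edges = nrow(ic_edges),
    hub_ids = sort(hubs)
  )
  list(graph = graph, fingerprints = fp, labels = labels,
       communities = communities, corpus = corpus_info$corpus,
       bookkeeping = bookkeeping)
}

#' One-call synthetic world
#'
#' @param spec a [synthetic_spec()].
#' @return See [make_graph_and_fingerprints()].
#' @export
make_synthetic_world <- function(spec = synthetic_spec()) {
  make_graph_and_fingerprints(spec, make_corpus(spec))
}

#' Write a synthetic world to disk in the standard CSV dialects
#'
#' Emits `recipes.txt`, `nodes.csv`, `edges.csv`, `fingerprints.csv` and
#' `labels.csv` under `dir`.
#'
#' @param world result of [make_synthetic_world()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_recipes(world$corpus, file.path(dir, "recipes.txt"))
  write_nodes_csv(world$graph$nodes, file.path(dir, "nodes.csv"))
  write_edges_csv(world$graph$edges, file.path(dir, "edges.csv"))
  write_fingerprints_csv(world$fingerprints, file.path(dir, "fingerprints.csv"))
  write.csv(data.frame(node_id = names(world$labels),
                       category = unname(world$labels)),
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
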