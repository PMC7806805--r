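#' Recipe corpus
#'
#' A corpus is a list of recipes, each a *set* of ingredient tokens; it backs
#' the co-occurrence probabilities p(x), p(y) and p(x, y) from which
#' ingredient pairing scores are computed.
#'
#' @param recipes list of character vectors (one per recipe).  Tokens within
#'   a recipe must be unique.
#' @return An object of class `recipe_corpus` with elements `recipes` and
#'   `n_recipes`.
#' @export
recipe_corpus <- function(recipes) {
  stopifnot(is.list(recipes))
  recipes <- lapply(recipes, as.character)
  dup <- vapply(recipes, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    stop("recipe ", which(dup)[1L], " contains duplicate tokens", call. = FALSE)
  }
  structure(list(recipes = recipes, n_recipes = length(recipes)),
            class = "recipe_corpus")
}

#' @export
print.recipe_corpus <- function(x, ...) {
  sizes <- lengths(x$recipes)
  cat(sprintf("<recipe_corpus> %d recipes, %d distinct ingredients, mean size %.1f\n",
              x$n_recipes, length(unique(unlist(x$recipes))),
              if (x$n_recipes) mean(sizes) else 0))
  invisible(x)
}

# canonical unordered-pair keys (smaller token first, \r separator cannot
# appear in tokens read from the supported file dialects)
.pair_key <- function(x, y) {
  paste(pmin(x, y), pmax(x, y), sep = "\r")
}

#' Count recipe co-occurrence
#'
#' Tallies, for every ingredient, the number of recipes containing it and,
#' for every unordered ingredient pair, the number of recipes containing
#' both.  These counts divided by the number of recipes are the probabilities
#' entering the PMI/NPMI pairing score.
#'
#' @param corpus a [recipe_corpus()].
#' @return An object of class `cooccurrence_stats`: list with `n_recipes`,
#'   `unigram` (named integer vector) and `joint` (named integer vector keyed
#'   by canonical pair; absent pairs have count 0).
#' @export
count_cooccurrence <- function(corpus) {
  stopifnot(inherits(corpus, "recipe_corpus"))
  if (corpus$n_recipes == 0L) stop("empty corpus", call. = FALSE)
  uni_tab <- table(unlist(corpus$recipes, use.names = FALSE))
  unigram <- setNames(as.integer(uni_tab), names(uni_tab))
  keys <- unlist(lapply(corpus$recipes, function(r) {
    if (length(r) < 2L) return(character())
    s <- sort(r)
    cb <- combn(s, 2L)
    paste(cb[1L, ], cb[2L, ], sep = "\r")
  }), use.names = FALSE)
  if (length(keys)) {
    jt <- table(keys)
    joint <- setNames(as.integer(jt), names(jt))
  } else {
    joint <- setNames(integer(), character())
  }
  structure(list(n_recipes = corpus$n_recipes, unigram = unigram,
                 joint = joint),
            class = "cooccurrence_stats")
}

.joint_count <- function(stats, x, y) {
  j <- unname(stats$joint[.pair_key(x, y)])
  ifelse(is.na(j), 0L, j)
}

.check_tokens <- function(stats, tokens) {
  unknown <- setdiff(tokens, names(stats$unigram))
  if (length(unknown)) {
    stop("unknown token: '", unknown[1L], "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Pointwise mutual information of an ingredient pair
#'
#' `pmi(x, y) = ln( p(x, y) / (p(x) p(y)) )` in nats, with probabilities
#' estimated as recipe fractions.  When the pair never co-occurs the PMI is
#' undefined (`-Inf` is returned and callers must handle it).
#'
#' @param stats a [count_cooccurrence()] result.
#' @param x,y ingredient tokens with nonzero unigram counts.
#' @return The PMI in nats (`-Inf` for a never-co-occurring pair).
#' @export
pmi <- function(stats, x, y) {
  stopifnot(inherits(stats, "cooccurrence_stats"))
  .check_tokens(stats, c(x, y))
  cj <- .joint_count(stats, x, y)
  if (cj == 0L) return(-Inf)
  n <- stats$n_recipes
  # probability space keeps the formula symmetric in x, y at the bit level
  log((cj / n) / ((stats$unigram[[x]] / n) * (stats$unigram[[y]] / n)))
}

#' Normalized pointwise mutual information
#'
#' `npmi = pmi / (-ln p(x, y))`, bounded in \[-1, 1\]: -1 when the pair never
#' co-occurs (limit convention), 0 when the ingredients are independent, and
#' 1 when they co-occur perfectly (always together, never apart).  A pair
#' present in *every* recipe has a zero denominator; the limit value 1 is
#' returned with a warning.
#'
#' @inheritParams pmi
#' @return The NPMI score in \[-1, 1\].
#' @export
npmi <- function(stats, x, y) {
  stopifnot(inherits(stats, "cooccurrence_stats"))
  .check_tokens(stats, c(x, y))
  cj <- .joint_count(stats, x, y)
  if (cj == 0L) return(-1)
  if (cj == stats$n_recipes) {
    warning("pair (", x, ", ", y, ") occurs in every recipe; NPMI -> 1 by limit")
    return(1)
  }
  # perfect co-occurrence: always together, never apart (limit value)
  if (cj == stats$unigram[[x]] && cj == stats$unigram[[y]]) return(1)
  denom <- -log(cj / stats$n_recipes)
  val <- pmi(stats, x, y) / denom
  max(-1, min(1, val))
}

# vectorized npmi over canonical pair keys present in stats$joint
.npmi_observed <- function(stats) {
  keys <- names(stats$joint)
  if (!length(keys)) {
    return(data.frame(src = character(), dst = character(),
                      npmi = numeric(), joint = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  src <- vapply(parts, `[[`, character(1), 1L)
  dst <- vapply(parts, `[[`, character(1), 2L)
  cj <- as.integer(stats$joint)
  N <- stats$n_recipes
  cx <- as.integer(stats$unigram[src])
  cy <- as.integer(stats$unigram[dst])
  lp <- log((cj / N) / ((cx / N) * (cy / N)))
  denom <- -log(cj / N)
  val <- ifelse(denom == 0 | (cj == cx & cj == cy), 1, lp / denom)
  val <- pmax(-1, pmin(1, val))
  data.frame(src = src, dst = dst, npmi = as.numeric(val), joint = cj,
             stringsAsFactors = FALSE)
}

#' Select ingredient-ingredient edges
#'
#' A pair of ingredients becomes a graph edge if it satisfies any of three
#' conditions: (A) each ingredient appears in more than `min_unigram` recipes
#' and the pair co-occurs in more than `min_joint`; (B) its NPMI score is at
#' least `npmi_min`; or (C) it is among the `rescue_top_k` highest-NPMI pairs
#' below the threshold (global top-k, ties broken by canonical pair id).
#' Every returned edge carries its NPMI weight.
#'
#' Pairs that never co-occur have NPMI -1 and enter consideration only
#' through rule C; they are enumerated only when the vocabulary is small
#' enough (`max_enumerate` candidate pairs), which is the regime where such
#' pathological rescues can matter.
#'
#' @param stats a [count_cooccurrence()] result.
#' @param min_unigram,min_joint strict lower bounds for rule A (defaults 20
#'   and 5: "appears more than 20 times", "more than 5 times together").
#' @param npmi_min NPMI threshold for rule B (default 0.25).
#' @param rescue_top_k size of the below-threshold rescue set (default 20).
#' @param max_enumerate cap on `choose(V, 2)` above which never-co-occurring
#'   pairs are not enumerated for rule C (default 2e5).
#' @return data.frame with columns `src`, `dst`, `weight` (NPMI), canonically
#'   oriented (`src < dst`) and sorted by `src`, `dst`.
#' @export
select_ingredient_edges <- function(stats, min_unigram = 20L, min_joint = 5L,
                                    npmi_min = 0.25, rescue_top_k = 20L,
                                    max_enumerate = 2e5) {
  stopifnot(inherits(stats, "cooccurrence_stats"))
  obs <- .npmi_observed(stats)
  cu_src <- as.integer(stats$unigram[obs$src])
  cu_dst <- as.integer(stats$unigram[obs$dst])

  rule_a <- cu_src > min_unigram & cu_dst > min_unigram & obs$joint > min_joint
  rule_b <- obs$npmi >= npmi_min

  # rule C pool: everything below threshold, including (when tractable)
  # never-co-occurring pairs at NPMI -1
  pool <- obs[!rule_b, c("src", "dst", "npmi")]
  toks <- sort(names(stats$unigram))
  if (rescue_top_k > 0 && length(toks) > 1L &&
      choose(length(toks), 2L) <= max_enumerate) {
    cb <- combn(toks, 2L)
    all_keys <- paste(cb[1L, ], cb[2L, ], sep = "\r")
    zero <- !(all_keys %in% names(stats$joint))
    if (any(zero)) {
      pool <- rbind(pool, data.frame(src = cb[1L, zero], dst = cb[2L, zero],
                                     npmi = -1, stringsAsFactors = FALSE))
    }
  }
  rule_c <- pool[0L, ]
  if (rescue_top_k > 0 && nrow(pool) > 0L) {
    o <- order(-pool$npmi, pool$src, pool$dst)
    rule_c <- pool[o[seq_len(min(rescue_top_k, nrow(pool)))], ]
  }

  sel <- rbind(obs[rule_a | rule_b, c("src", "dst", "npmi")], rule_c)
  sel <- sel[!duplicated(paste(sel$src, sel$dst, sep = "\r")), ]
  sel <- sel[order(sel$src, sel$dst), ]
  rownames(sel) <- NULL
  names(sel)[3L] <- "weight"
  sel
}
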