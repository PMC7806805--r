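# logit clip used by all loss computations (matches the compiled trainer)
.LOGIT_CLIP <- 30

.clip <- function(x) pmax(-.LOGIT_CLIP, pmin(.LOGIT_CLIP, x))
.sigmoid <- function(x) 1 / (1 + exp(-.clip(x)))

#' Training configuration
#'
#' Hyperparameters for [train_embeddings()].  Defaults follow common
#' word2vec practice where the method leaves a value open: window 5,
#' 5 negatives, unigram^0.75 negative distribution, SGD from 0.025 decaying
#' linearly to `lr_min`.
#'
#' @param d embedding dimension (default 300).
#' @param window context radius: tokens within `window` positions of the
#'   center form its context set W(u).
#' @param negatives number of negative samples M per positive pair.
#' @param lambda weight of the chemical-structure-prediction loss, in
#'   \[0, 1\]; 0 disables the head and reduces training to plain
#'   metapath2vec.
#' @param epochs passes over the walk corpus.
#' @param lr,lr_min initial and floor learning rate (linear decay over all
#'   center positions).
#' @param neg_power exponent applied to corpus token frequencies to form the
#'   negative-sampling distribution Q.
#' @param seed integer seed; training is single-threaded and byte-identical
#'   under the same seed.
#' @param use_csp logical; `FALSE` removes the CSP head entirely (used to
#'   verify that `lambda = 0` is an exact reduction).
#' @param csp_mode `"per_occurrence"` applies the CSP loss every time a
#'   labeled node occurs as a center token; `"per_epoch"` applies it once
#'   per labeled node at the end of each epoch.
#' @return A `training_config` list.
#' @export
training_config <- function(d = 300L, window = 5L, negatives = 5L,
                            lambda = 0.5, epochs = 5L, lr = 0.025,
                            lr_min = 1e-4, neg_power = 0.75, seed = 1L,
                            use_csp = TRUE,
                            csp_mode = c("per_occurrence", "per_epoch")) {
  csp_mode <- match.arg(csp_mode)
  stopifnot(d >= 1, window >= 1, negatives >= 1, epochs >= 1,
            lambda >= 0, lambda <= 1, lr > 0, lr_min > 0, neg_power >= 0)
  structure(list(d = as.integer(d), window = as.integer(window),
                 negatives = as.integer(negatives), lambda = lambda,
                 epochs = as.integer(epochs), lr = lr, lr_min = lr_min,
                 neg_power = neg_power, seed = as.integer(seed),
                 use_csp = isTRUE(use_csp), csp_mode = csp_mode),
            class = "training_config")
}

#' Embedding model container
#'
#' Holds the center and context vector tables plus the CSP projection.
#' Constructed by [train_embeddings()]; exposed so tests and downstream
#' tools can build small models directly.
#'
#' @param center numeric matrix, one row per token (rownames = tokens).
#' @param context numeric matrix of the same shape (defaults to zeros).
#' @param csp_weights `d x 881` projection matrix (defaults to zeros).
#' @param csp_bias length-881 bias (defaults to zeros).
#' @return An `embedding_model`.
#' @export
embedding_model <- function(center, context = NULL, csp_weights = NULL,
                            csp_bias = NULL) {
  stopifnot(is.matrix(center), !is.null(rownames(center)))
  d <- ncol(center)
  if (is.null(context)) {
    context <- matrix(0, nrow(center), d, dimnames = dimnames(center))
  }
  if (is.null(csp_weights)) csp_weights <- matrix(0, d, FINGERPRINT_LENGTH)
  if (is.null(csp_bias)) csp_bias <- numeric(FINGERPRINT_LENGTH)
  stopifnot(identical(dim(context), dim(center)),
            nrow(csp_weights) == d, ncol(csp_weights) == FINGERPRINT_LENGTH,
            length(csp_bias) == FINGERPRINT_LENGTH)
  structure(list(vocab = rownames(center), center = center, context = context,
                 csp_weights = csp_weights, csp_bias = csp_bias, d = d),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %d tokens x %d dims\n",
              length(x$vocab), x$d))
  invisible(x)
}

.token_index <- function(model, token) {
  if (is.character(token)) {
    i <- match(token, model$vocab)
    if (anyNA(i)) {
      stop("unknown token: '", token[is.na(i)][1L], "'", call. = FALSE)
    }
    i
  } else {
    i <- as.integer(token)
    stopifnot(all(i >= 1L & i <= length(model$vocab)))
    i
  }
}

#' Draw negative samples
#'
#' Draws `m` token indices i.i.d. from the distribution `q`, resampling any
#' draw that collides with the excluded (positive context) token.  Uses the
#' R RNG stream.
#'
#' @param q numeric probability vector over the vocabulary (normalized
#'   internally).
#' @param m number of samples.
#' @param exclude index (or name, when `q` is named) of the token that may
#'   not be drawn.
#' @return Integer vector of `m` indices, none equal to `exclude`.
#' @export
negative_sample <- function(q, m, exclude) {
  if (length(q) < 2L) {
    stop("vocabulary of size ", length(q),
         ": cannot exclude a token and still sample", call. = FALSE)
  }
  if (is.character(exclude)) exclude <- match(exclude, names(q))
  exclude <- as.integer(exclude)
  stopifnot(length(exclude) == 1L, !is.na(exclude),
            exclude >= 1L, exclude <= length(q))
  q <- q / sum(q)
  if (sum(q[-exclude]) <= 0) {
    stop("no probability mass outside the excluded token", call. = FALSE)
  }
  out <- sample.int(length(q), m, replace = TRUE, prob = q)
  while (any(bad <- out == exclude)) {
    out[bad] <- sample.int(length(q), sum(bad), replace = TRUE, prob = q)
  }
  out
}

#' Skip-gram pair loss with negative sampling
#'
#' The per-pair objective (negated for minimization) is
#' `-ln sigma(x_c . x_u) - sum_m ln sigma(-x_{n_m} . x_c)` where `x_u` is the
#' center vector of the center token, `x_c` the context vector of the
#' context token, and `x_{n_m}` the center vectors of the M negatives.  Dot
#' products are clipped to +/-30 before exponentiation.
#'
#' @param model an [embedding_model()].
#' @param center,context single tokens (name or index).
#' @param negatives vector of M tokens.
#' @return List with `loss` (nonnegative scalar) and gradients
#'   `grad_center`, `grad_context` (length-d vectors) and `grad_negatives`
#'   (M x d matrix, one row per negative slot).
#' @export
skipgram_pair_loss <- function(model, center, context, negatives) {
  u <- .token_index(model, center)
  cc <- .token_index(model, context)
  ng <- .token_index(model, negatives)
  xu <- model$center[u, ]
  xc <- model$context[cc, ]
  xn <- model$center[ng, , drop = FALSE]

  s <- .sigmoid(sum(xc * xu))
  loss <- -log(s)
  g <- s - 1
  grad_center <- g * xc
  grad_context <- g * xu

  dn <- as.numeric(xn %*% xc)
  s2 <- .sigmoid(dn)
  loss <- loss + sum(-log(.sigmoid(-dn)))
  grad_context <- grad_context + as.numeric(crossprod(xn, s2))
  grad_negatives <- s2 * matrix(xc, length(ng), model$d, byrow = TRUE)

  list(loss = loss, grad_center = grad_center, grad_context = grad_context,
       grad_negatives = grad_negatives)
}

#' Chemical-structure-prediction loss
#'
#' The CSP head maps a center embedding to 881 substructure probabilities,
#' `f(u) = sigma(W^T x_u + b)`, and is scored by the mean binary
#' cross-entropy against the compound's 881-bit fingerprint.  Gradients flow
#' into the head weights, bias and the center embedding.  The returned loss
#' is unweighted; the caller applies lambda.
#'
#' @param model an [embedding_model()].
#' @param node a token (name or index) carrying a fingerprint label.
#' @param fingerprint 0/1 vector of length 881.
#' @return List with `loss` and gradients `grad_center` (length d),
#'   `grad_weights` (d x 881), `grad_bias` (length 881).
#' @export
csp_loss <- function(model, node, fingerprint) {
  u <- .token_index(model, node)
  y <- as.numeric(fingerprint)
  stopifnot(length(y) == FINGERPRINT_LENGTH, all(y %in% c(0, 1)))
  x <- model$center[u, ]
  z <- as.numeric(crossprod(model$csp_weights, x)) + model$csp_bias
  p <- .sigmoid(z)
  D <- FINGERPRINT_LENGTH
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  g <- (p - y) / D
  list(loss = loss,
       grad_center = as.numeric(model$csp_weights %*% g),
       grad_weights = outer(x, g),
       grad_bias = g)
}

#' Combined per-step loss
#'
#' One training step's objective for a skip-gram batch: the sum of the
#' skip-gram pair losses over the batch's contexts, plus
#' `lambda * csp_loss(center)` when the center token carries a fingerprint
#' label.  With `lambda = 0` (or an unlabeled center) it equals the
#' skip-gram term exactly -- the CSP branch is not evaluated.
#'
#' @param model an [embedding_model()].
#' @param batch list with elements `center` (one token), `contexts` (one or
#'   more tokens) and `negatives` (M-vector, or a matrix with one row per
#'   context).
#' @param fingerprint_lookup matrix of fingerprints (rownames = tokens), or
#'   `NULL` when no labels exist.
#' @param lambda CSP weight in \[0, 1\].
#' @return Nonnegative scalar loss.
#' @export
combined_step_loss <- function(model, batch, fingerprint_lookup = NULL,
                               lambda = 0.5) {
  stopifnot(is.list(batch), lambda >= 0, lambda <= 1)
  contexts <- batch$contexts
  negs <- batch$negatives
  if (!is.matrix(negs)) {
    negs <- matrix(rep(negs, length(contexts)), nrow = length(contexts),
                   byrow = TRUE)
  }
  loss <- 0
  for (i in seq_along(contexts)) {
    loss <- loss + skipgram_pair_loss(model, batch$center, contexts[i],
                                      negs[i, ])$loss
  }
  if (lambda > 0 && !is.null(fingerprint_lookup)) {
    tok <- if (is.character(batch$center)) batch$center else
      model$vocab[batch$center]
    if (tok %in% rownames(fingerprint_lookup)) {
      loss <- loss +
        lambda * csp_loss(model, batch$center, fingerprint_lookup[tok, ])$loss
    }
  }
  loss
}

#' Train node embeddings on a walk corpus
#'
#' Runs single-threaded stochastic gradient descent over the corpus: for
#' every center token and every context within the window, one skip-gram
#' update with `negatives` samples drawn from the unigram^`neg_power`
#' distribution; when the center token carries a fingerprint label the
#' lambda-weighted CSP update is applied as well (semi-supervised: unlabeled
#' tokens simply skip the term).  Deterministic given `config$seed`.
#'
#' @param walks a `walk_corpus`.
#' @param fingerprints integer matrix of 881-bit fingerprints with rownames
#'   naming compound tokens, or `NULL` for no CSP supervision.
#' @param config a [training_config()].
#' @return An [embedding_model()] with extra fields `n_pair_updates`,
#'   `epoch_losses` (mean per-update loss by epoch) and `config`.
#' @export
train_embeddings <- function(walks, fingerprints = NULL,
                             config = training_config()) {
  stopifnot(inherits(walks, "walk_corpus"), inherits(config, "training_config"))
  if (length(walks$walks) == 0L) stop("empty walk corpus", call. = FALSE)
  tokens_chr <- unlist(walks$walks, use.names = FALSE)
  vocab <- sort(unique(tokens_chr))
  if (length(vocab) < 2L) {
    stop("walk corpus must contain at least 2 distinct tokens", call. = FALSE)
  }
  tok <- match(tokens_chr, vocab) - 1L
  offsets <- c(0L, cumsum(lengths(walks$walks)))

  counts <- tabulate(tok + 1L, nbins = length(vocab))
  qw <- counts^config$neg_power
  neg_cum <- cumsum(qw / sum(qw))

  if (!is.null(fingerprints) && nrow(fingerprints) > 0L) {
    fp_row <- match(vocab, rownames(fingerprints)) - 1L
    fp_row[is.na(fp_row)] <- -1L
    Y <- fingerprints
    storage.mode(Y) <- "integer"
  } else {
    fp_row <- rep(-1L, length(vocab))
    Y <- matrix(integer(), 0L, FINGERPRINT_LENGTH)
  }

  fit <- train_cpp(tok, as.integer(offsets), length(vocab), config$d,
                   config$window, config$negatives, config$lambda,
                   config$epochs, config$lr, config$lr_min, neg_cum,
                   fp_row, Y, config$use_csp,
                   config$csp_mode == "per_epoch", config$seed)

  dimnames(fit$center) <- list(vocab, NULL)
  dimnames(fit$context) <- list(vocab, NULL)
  model <- embedding_model(fit$center, fit$context, fit$csp_weights,
                           as.numeric(fit$csp_bias))
  model$n_pair_updates <- fit$n_pair_updates
  model$epoch_losses <- as.numeric(fit$epoch_losses)
  model$token_counts <- setNames(counts, vocab)
  model$config <- config
  model
}

#' End-to-end graph embedding
#'
#' Convenience pipeline: generate the two food-specific metapath corpora
#' (`C-H-N-H-C`, `N-H-C-H-N`) and the uniform walks, merge them, and train
#' embeddings using the graph's fingerprints for CSP supervision.
#'
#' @param graph a `hetero_graph`.
#' @param config a [training_config()].
#' @param walks_per_start walks per eligible start node for each strategy.
#' @param max_len walk length cap.
#' @param seed seed for walk generation and shuffling (training uses
#'   `config$seed`).
#' @param schemas subset of `c("CHNHC", "NHCHN", "UNIFORM")`.
#' @return An [embedding_model()].
#' @export
embed_graph <- function(graph, config = training_config(),
                        walks_per_start = 100L, max_len = 50L, seed = 1L,
                        schemas = c("CHNHC", "NHCHN", "UNIFORM")) {
  schemas <- match.arg(schemas, several.ok = TRUE)
  corpora <- list()
  if ("CHNHC" %in% schemas) {
    corpora <- c(corpora, list(generate_metapath_walks(
      graph, metapath_schema("CHNHC"), walks_per_start, max_len, seed)))
  }
  if ("NHCHN" %in% schemas) {
    corpora <- c(corpora, list(generate_metapath_walks(
      graph, metapath_schema("NHCHN"), walks_per_start, max_len, seed + 1L)))
  }
  if ("UNIFORM" %in% schemas) {
    corpora <- c(corpora, list(generate_uniform_walks(
      graph, walks_per_start, max_len, seed + 2L)))
  }
  merged <- merge_corpora(corpora, seed = seed + 3L)
  train_embeddings(merged, graph$fingerprints, config)
}
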