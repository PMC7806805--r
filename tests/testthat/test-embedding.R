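test_that("training_config validates its ranges", {
  expect_error(training_config(lambda = 1.5))
  expect_error(training_config(negatives = 0L))
  expect_error(training_config(window = 0L))
  cfg <- training_config(d = 16L, lambda = 0)
  expect_s3_class(cfg, "training_config")
})

test_that("negative_sample excludes the positive token", {
  withr::local_seed(1L)
  q <- rep(0.1, 10L)
  for (i in 1:20) {
    out <- negative_sample(q, 3L, exclude = 4L)
    expect_length(out, 3L)
    expect_false(any(out == 4L))
  }
  # degenerate distribution: all mass on one non-excluded token
  q2 <- c(0, 1, 0)
  expect_identical(negative_sample(q2, 5L, exclude = 1L), rep(2L, 5L))
  expect_error(negative_sample(1, 2L, exclude = 1L), "size 1")
  expect_error(negative_sample(c(0, 1), 2L, exclude = 2L), "mass")
})

test_that("negative_sample frequencies match Q within 3 sigma", {
  withr::local_seed(7L)
  q <- c(0.05, 0.3, 0.15, 0.25, 0.1, 0.15)
  excl <- 2L
  n <- 1e5
  draws <- negative_sample(q, n, exclude = excl)
  # conditional distribution given the exclusion
  qc <- q[-excl] / sum(q[-excl])
  counts <- tabulate(draws, nbins = 6L)[-excl]
  expected <- n * qc
  sigma <- sqrt(n * qc * (1 - qc))
  expect_true(all(abs(counts - expected) < 3 * sigma))
})

test_that("skipgram_pair_loss reproduces its closed-form examples", {
  vocab <- c("a", "b", "c")
  zero <- embedding_model(matrix(0, 3, 4, dimnames = list(vocab, NULL)))
  r <- skipgram_pair_loss(zero, "a", "b", "c")
  expect_equal(r$loss, 2 * log(2), tolerance = 1e-12)

  # saturation: positive dot >> 0, negative dot << 0 -> loss ~ 0
  center <- matrix(0, 3, 2, dimnames = list(vocab, NULL))
  context <- center
  center["a", ] <- c(100, 0)    # center u
  context["b", ] <- c(1, 0)     # context c: dot +100 (clipped 30)
  center["c", ] <- c(-100, 0)   # negative: dot -100
  sat <- embedding_model(center, context)
  expect_lt(skipgram_pair_loss(sat, "a", "b", "c")$loss, 1e-10)
})

test_that("skip-gram gradients match central finite differences", {
  h <- 1e-5
  for (seed in 1:10) {
    vocab <- letters[1:8]
    m <- random_model(seed, vocab, d = 6L)
    u <- "a"; ctx <- "b"; negs <- c("c", "d", "e")
    r <- skipgram_pair_loss(m, u, ctx, negs)
    expect_gte(r$loss, 0)

    num_grad <- function(token, slot, i) {
      mp <- m; mm <- m
      mp[[slot]][token, i] <- mp[[slot]][token, i] + h
      mm[[slot]][token, i] <- mm[[slot]][token, i] - h
      (skipgram_pair_loss(mp, u, ctx, negs)$loss -
         skipgram_pair_loss(mm, u, ctx, negs)$loss) / (2 * h)
    }
    rel <- function(a, b) abs(a - b) / pmax(abs(a) + abs(b), 1e-8)
    for (i in 1:6) {
      expect_lt(rel(r$grad_center[i], num_grad(u, "center", i)), 1e-6)
      expect_lt(rel(r$grad_context[i], num_grad(ctx, "context", i)), 1e-6)
      expect_lt(rel(r$grad_negatives[2L, i], num_grad("d", "center", i)),
                1e-6)
    }
  }
})

test_that("csp_loss reproduces its closed-form examples", {
  vocab <- c("a", "b")
  m <- embedding_model(matrix(0.1, 2, 4, dimnames = list(vocab, NULL)))
  # zero weights and bias: every f_d = 0.5 -> loss = ln 2
  fp <- random_fingerprint(3L)
  expect_equal(csp_loss(m, "a", fp)$loss, log(2), tolerance = 1e-12)

  # perfect logits matching the labels -> loss ~ 0
  m2 <- m
  m2$csp_bias <- ifelse(fp == 1, 30, -30)
  m2$center[] <- 0
  expect_lt(csp_loss(m2, "a", fp)$loss, 1e-10)
})

test_that("csp gradients match central finite differences", {
  h <- 1e-5
  rel <- function(a, b) abs(a - b) / pmax(abs(a) + abs(b), 1e-8)
  for (seed in 1:10) {
    m <- random_model(seed + 100L, c("a", "b"), d = 5L)
    fp <- random_fingerprint(seed)
    r <- csp_loss(m, "a", fp)
    expect_gte(r$loss, 0)
    # center vector: all coordinates
    for (i in 1:5) {
      mp <- m; mm <- m
      mp$center["a", i] <- mp$center["a", i] + h
      mm$center["a", i] <- mm$center["a", i] - h
      num <- (csp_loss(mp, "a", fp)$loss - csp_loss(mm, "a", fp)$loss) /
        (2 * h)
      expect_lt(rel(r$grad_center[i], num), 1e-6)
    }
    # random subset of head weights and biases
    withr::local_seed(seed)
    for (idx in sample(881L, 4L)) {
      i <- sample(5L, 1L)
      mp <- m; mm <- m
      mp$csp_weights[i, idx] <- mp$csp_weights[i, idx] + h
      mm$csp_weights[i, idx] <- mm$csp_weights[i, idx] - h
      num <- (csp_loss(mp, "a", fp)$loss - csp_loss(mm, "a", fp)$loss) /
        (2 * h)
      expect_lt(rel(r$grad_weights[i, idx], num), 1e-6)

      mp <- m; mm <- m
      mp$csp_bias[idx] <- mp$csp_bias[idx] + h
      mm$csp_bias[idx] <- mm$csp_bias[idx] - h
      numb <- (csp_loss(mp, "a", fp)$loss - csp_loss(mm, "a", fp)$loss) /
        (2 * h)
      expect_lt(rel(r$grad_bias[idx], numb), 1e-6)
    }
  }
})

test_that("combined_step_loss composes the two terms", {
  vocab <- c("a", "b", "c")
  zero <- embedding_model(matrix(0, 3, 4, dimnames = list(vocab, NULL)))
  fp <- matrix(random_fingerprint(9L), 1L, 881L,
               dimnames = list("a", NULL))
  batch <- list(center = "a", contexts = "b", negatives = "c")
  # lambda = 0 reduces bit-for-bit to the skip-gram term
  expect_identical(combined_step_loss(zero, batch, fp, lambda = 0),
                   skipgram_pair_loss(zero, "a", "b", "c")$loss)
  # zero-init, lambda = 1, M = 1: 2 ln 2 + ln 2
  expect_equal(combined_step_loss(zero, batch, fp, lambda = 1),
               3 * log(2), tolerance = 1e-12)
  # random model: equals the independently computed sum
  m <- random_model(17L, vocab, d = 4L)
  want <- skipgram_pair_loss(m, "a", "b", "c")$loss +
    0.3 * csp_loss(m, "a", fp["a", ])$loss
  expect_equal(combined_step_loss(m, batch, fp, lambda = 0.3), want,
               tolerance = 1e-12)
  # unlabeled center: skip-gram only
  batch2 <- list(center = "b", contexts = "a", negatives = "c")
  expect_identical(combined_step_loss(m, batch2, fp, lambda = 0.9),
                   skipgram_pair_loss(m, "b", "a", "c")$loss)
})

test_that("train performs one update per center-context pair", {
  wc <- walk_corpus(list(c("a", "b")), "UNIFORM")
  cfg <- training_config(d = 4L, window = 5L, negatives = 2L, lambda = 0,
                         epochs = 1L, seed = 3L)
  m <- train_embeddings(wc, NULL, cfg)
  expect_equal(m$n_pair_updates, 2)
  expect_identical(sort(m$vocab), c("a", "b"))
  expect_true(all(is.finite(m$center)), all(is.finite(m$context)))
})

test_that("training is byte-identical under the same seed", {
  wc <- small_walks()
  fps <- small_world()$fingerprints
  cfg <- training_config(d = 8L, epochs = 1L, lambda = 0.5, seed = 11L)
  m1 <- train_embeddings(wc, fps, cfg)
  m2 <- train_embeddings(wc, fps, cfg)
  expect_identical(m1$center, m2$center)
  expect_identical(m1$context, m2$context)
  expect_identical(m1$csp_weights, m2$csp_weights)
  m3 <- train_embeddings(wc, fps, training_config(d = 8L, epochs = 1L,
                                                  lambda = 0.5, seed = 12L))
  expect_false(identical(m1$center, m3$center))
})

test_that("lambda = 0 training is step-identical to a CSP-free trainer", {
  wc <- small_walks()
  fps <- small_world()$fingerprints
  with_head <- train_embeddings(wc, fps,
                                training_config(d = 8L, epochs = 1L,
                                                lambda = 0, use_csp = TRUE,
                                                seed = 21L))
  without <- train_embeddings(wc, fps,
                              training_config(d = 8L, epochs = 1L,
                                              lambda = 0, use_csp = FALSE,
                                              seed = 21L))
  expect_identical(with_head$center, without$center)
  expect_identical(with_head$context, without$context)
})

test_that("mean epoch loss does not increase materially over early epochs", {
  wc <- small_walks()
  fps <- small_world()$fingerprints
  m <- train_embeddings(wc, fps, training_config(d = 16L, epochs = 3L,
                                                 lambda = 0.5, seed = 5L))
  el <- m$epoch_losses
  expect_length(el, 3L)
  expect_true(all(diff(el) <= 0.05 * el[-length(el)]))
})

test_that("train rejects degenerate corpora", {
  expect_error(train_embeddings(walk_corpus(list()), NULL,
                                training_config(d = 4L)),
               "empty")
  expect_error(train_embeddings(walk_corpus(list(c("a", "a"))), NULL,
                                training_config(d = 4L)),
               "2 distinct")
})
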