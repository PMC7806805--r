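test_that("cosine_similarity follows the formula", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  withr::local_seed(2L)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(cosine_similarity(a, b),
                 sum(a * b) / sqrt(sum(a^2) * sum(b^2)), tolerance = 1e-12)
    expect_lte(abs(cosine_similarity(a, b)), 1 + 1e-12)
  }
})

test_that("pairing_query behaves on an orthonormal toy model", {
  vocab <- c("e1", "e2", "e3", "e4")
  m <- embedding_model(diag(4) |> `rownames<-`(vocab))
  r1 <- pairing_query(m, "e2", k = 2L)
  expect_identical(r1$token[1L], "e2")
  expect_equal(r1$score[1L], 1)
  # summed query over an orthonormal basis: e1 and e2 tie at 1/sqrt(2),
  # order broken by token id
  r2 <- pairing_query(m, c("e1", "e2"), k = 3L)
  expect_identical(r2$token[1:2], c("e1", "e2"))
  expect_equal(r2$score[1:2], rep(1 / sqrt(2), 2L), tolerance = 1e-12)
  expect_error(pairing_query(m, "nope", 2L), "unknown token")
})

test_that("pairing_query equals the full-scan oracle for all k", {
  for (seed in 201:205) {
    vocab <- sprintf("n%02d", 1:15)
    m <- random_model(seed, vocab)
    withr::local_seed(seed)
    qt <- sample(vocab, sample(2L, 1L))
    for (k in c(1L, 5L, 15L)) {
      got <- pairing_query(m, qt, k)
      want <- oracle_topk(m, qt, k, sort(vocab))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("pairing_query honours class restrictions", {
  world <- small_world()
  g <- world$graph
  m <- embedding_model(matrix(rnorm(nrow(g$nodes) * 4), ncol = 4,
                              dimnames = list(g$nodes$node_id, NULL)))
  r <- pairing_query(m, g$nodes$node_id[1L], k = 10L, graph = g,
                     restrict = "NONHUB_INGREDIENT")
  nonhub <- g$nodes$node_id[g$nodes$node_type == "ingredient" &
                              !g$nodes$is_hub]
  expect_true(all(r$token %in% nonhub))
  expect_error(pairing_query(m, g$nodes$node_id[1L], 5L,
                             restrict = "NONHUB_INGREDIENT"),
               "requires the graph")
})

test_that("nmi_score has the expected fixed points and symmetry", {
  a <- rep(1:3, each = 10L)
  expect_equal(nmi_score(a, a), 1)
  expect_equal(nmi_score(a, sample(letters[1:3])[a]), 1) # relabeling
  withr::local_seed(4L)
  x <- sample(1:5, 4000L, replace = TRUE)
  y <- sample(1:5, 4000L, replace = TRUE)
  expect_lt(nmi_score(x, y), 0.05) # independence
  expect_equal(nmi_score(x, y), nmi_score(y, x))
})

test_that("cluster_and_score separates obvious blobs and rejects tiny input", {
  withr::local_seed(9L)
  centers <- rbind(c(10, 0), c(-10, 0), c(0, 10))
  lab <- rep(c("Fruit", "Dairy", "Seafood"), each = 20L)
  X <- centers[rep(1:3, each = 20L), ] + matrix(rnorm(120L, sd = 0.1),
                                                ncol = 2L)
  rownames(X) <- sprintf("n%02d", 1:60)
  m <- embedding_model(X)
  res <- cluster_and_score(m, setNames(lab, rownames(X)), k = 3L, seed = 1L)
  expect_equal(res$nmi, 1)
  # random labels on random vectors: NMI near zero
  m2 <- embedding_model(matrix(rnorm(600L), 100L, 6L,
                               dimnames = list(sprintf("r%03d", 1:100),
                                               NULL)))
  lab2 <- setNames(sample(LETTERS[1:4], 100L, replace = TRUE),
                   rownames(m2$center))
  res2 <- cluster_and_score(m2, lab2, k = 4L, seed = 2L)
  expect_lt(res2$nmi, 0.2)
  expect_error(cluster_and_score(m, setNames(lab[1:2], rownames(X)[1:2]),
                                 k = 3L),
               "at least k")
})

test_that("jaccard_category_matrix matches brute force", {
  # two hubs with identical compound sets in one category -> diagonal 1;
  # disjoint sets across categories -> off-diagonal 0
  nodes <- data.frame(
    node_id = c("a1", "a2", "b1", "c1", "c2", "c3"),
    name = c("a1", "a2", "b1", "c1", "c2", "c3"),
    node_type = c(rep("ingredient", 3L), rep("flavor_compound", 3L)),
    category = c("Fruit", "Fruit", "Dairy", NA, NA, NA)
  )
  g <- build_graph(nodes, ic_edges = data.frame(
    src = c("a1", "a1", "a2", "a2", "b1"),
    dst = c("c1", "c2", "c1", "c2", "c3")))
  m <- jaccard_category_matrix(g)
  expect_equal(m["Fruit", "Fruit"], 1)
  expect_equal(m["Fruit", "Dairy"], 0)
  expect_true(is.na(m["Dairy", "Dairy"])) # single hub: no within pair

  for (seed in 301:305) {
    world <- small_world()
    g <- world$graph
    got <- jaccard_category_matrix(g)
    # brute force over explicit pair enumeration
    hubs <- g$nodes$node_id[g$nodes$is_hub]
    cat_of <- setNames(g$nodes$category, g$nodes$node_id)
    ce <- g$edges[g$edges$edge_type %in% c("if", "id"), ]
    cs <- lapply(setNames(hubs, hubs), function(h) ce$dst[ce$src == h])
    for (g1 in rownames(got)) for (g2 in colnames(got)) {
      vals <- c()
      for (i in hubs) for (j in hubs) {
        if (i != j && cat_of[[i]] == g1 && cat_of[[j]] == g2) {
          vals <- c(vals, length(intersect(cs[[i]], cs[[j]])) /
                      length(union(cs[[i]], cs[[j]])))
        }
      }
      if (length(vals)) expect_equal(got[g1, g2], mean(vals))
    }
  }
})

test_that("predict_relations thresholds the similarity matrix", {
  vocab <- c("cmpA", "cmpB", "foodX", "foodY")
  m <- random_model(41L, vocab, d = 5L)
  cmp <- c("cmpA", "cmpB"); food <- c("foodX", "foodY")
  # threshold just above 1: empty
  expect_equal(nrow(predict_relations(m, cmp, food, 1 + 1e-9)), 0L)
  # threshold -1: complete bipartite set
  all_pred <- predict_relations(m, cmp, food, -1)
  expect_equal(nrow(all_pred), 4L)
  # brute force equality and monotonicity
  for (th in c(-0.5, 0, 0.3, 0.8)) {
    got <- predict_relations(m, cmp, food, th)
    want <- subset(all_pred, score >= th)
    expect_equal(got$src, want$src)
    expect_equal(got$dst, want$dst)
    prev <- predict_relations(m, cmp, food, th - 0.2)
    expect_true(all(paste(got$src, got$dst) %in%
                      paste(prev$src, prev$dst)))
  }
  expect_error(predict_relations(m, "nope", food, 0), "unknown token")
})

test_that("confusion_metrics reproduces printed precision/recall/F1", {
  # counts as printed: 53 known relations, 44 predictions, 38 correct
  gold <- data.frame(src = sprintf("c%02d", 1:53), dst = "f")
  pred <- data.frame(src = sprintf("c%02d", c(1:38, 101:106)), dst = "f")
  universe <- data.frame(src = sprintf("c%02d", 1:200), dst = "f")
  ev <- confusion_metrics(pred, gold, universe)
  expect_equal(ev$tp, 38L)
  expect_equal(ev$n_pred, 44L)
  expect_equal(ev$n_gold, 53L)
  expect_equal(round(ev$precision, 3), 0.864)
  expect_equal(round(ev$recall, 3), 0.717)
  expect_equal(round(ev$f1, 3), 0.784)
  expect_equal(ev$n_pred, ev$tp + ev$fp_unknown)
  expect_equal(ev$n_gold, ev$tp + ev$fn)
})

test_that("confusion_metrics edge cases and brute force", {
  u <- data.frame(src = letters[1:5], dst = "x")
  ev <- confusion_metrics(u, u, u)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f1, 1)
  expect_equal(ev$mcc, 0) # zero factors -> 0 by convention
  expect_error(confusion_metrics(u, u, u[0, ]), "universe")
  expect_error(confusion_metrics(u, u[1:2, ], u[2:5, ]), "within")

  withr::local_seed(5L)
  for (i in 1:20) {
    uni <- data.frame(src = sprintf("p%02d", 1:30), dst = "q")
    pred <- uni[runif(30) < 0.4, ]
    gold <- uni[runif(30) < 0.3, ]
    ev <- confusion_metrics(pred, gold, uni)
    pk <- paste(pred$src, pred$dst)
    gk <- paste(gold$src, gold$dst)
    tp <- length(intersect(pk, gk))
    fp <- length(setdiff(pk, gk))
    fn <- length(setdiff(gk, pk))
    tn <- 30L - length(union(pk, gk))
    expect_equal(ev$tp, tp); expect_equal(ev$fp_unknown, fp)
    expect_equal(ev$fn, fn); expect_equal(ev$tn, tn)
    expect_equal(ev$accuracy, (tp + tn) / 30)
    if (tp + fp > 0 && tp + fn > 0 && tn + fp > 0 && tn + fn > 0) {
      expect_equal(ev$mcc, (tp * tn - fp * fn) /
                     sqrt((tp + fp) * (tp + fn)) /
                     sqrt((tn + fp) * (tn + fn)))
    }
  }
})

test_that("calibrate_threshold finds the F1-maximizing cutoff", {
  vocab <- c("c1", "c2", "f1", "f2", "f3")
  m <- random_model(55L, vocab, d = 4L)
  cmp <- c("c1", "c2"); food <- c("f1", "f2", "f3")
  all_pred <- predict_relations(m, cmp, food, -1)
  gold <- all_pred[order(-all_pred$score), ][1:3, c("src", "dst")]
  cal <- calibrate_threshold(m, cmp, food, gold)
  ev_pred <- predict_relations(m, cmp, food, cal$threshold)
  expect_equal(nrow(ev_pred), 3L) # exactly the top-3 by construction
  expect_equal(cal$f1, 1)
})
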