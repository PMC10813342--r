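test_that("a single-topic model degenerates to smoothed corpus frequencies", {
  corp <- make_corpus(make_doc("1", c("a", "a", "b")), make_doc("2", c("b", "c")))
  voc <- build_vocabulary(corp, 1)
  m <- fit_lda(corp, voc, K = 1, iterations = 5, seed = 1)
  expect_equal(unname(m$theta[, 1]), c(1, 1))
  # phi = (count + beta) / (N + V beta)
  expected <- (as.numeric(voc$counts) + m$beta) / (5 + 3 * m$beta)
  expect_equal(unname(m$phi[1, ]), expected, tolerance = 1e-12)
})

test_that("phi and theta rows are probability distributions", {
  sim <- simulate_lda_corpus(K = 3, V = 30, n_docs = 25, doc_length = 20, seed = 2)
  voc <- build_vocabulary(sim$corpus, 1)
  m <- fit_lda(sim$corpus, voc, K = 3, iterations = 50, seed = 9)
  expect_true(all(m$phi >= 0) && all(m$theta >= 0))
  expect_equal(rowSums(m$phi), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(rowSums(m$theta)), rep(1, 25), tolerance = 1e-9)
})

test_that("identical inputs and seed give a bitwise-identical fit", {
  sim <- simulate_lda_corpus(K = 2, V = 20, n_docs = 15, doc_length = 15, seed = 4)
  voc <- build_vocabulary(sim$corpus, 1)
  m1 <- fit_lda(sim$corpus, voc, K = 2, iterations = 40, seed = 7)
  m2 <- fit_lda(sim$corpus, voc, K = 2, iterations = 40, seed = 7)
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$theta, m2$theta)
  m3 <- fit_lda(sim$corpus, voc, K = 2, iterations = 40, seed = 8)
  expect_false(identical(m1$phi, m3$phi))
})

test_that("two disjoint vocabulary blocks are recovered as two topics", {
  corp <- block_corpus(n_docs = 30, len = 25, seed = 5)
  voc <- build_vocabulary(corp, 1)
  m <- fit_lda(corp, voc, K = 2, iterations = 500, seed = 3)
  a_cols <- grepl("^a", voc$tokens)
  mass_on_a <- rowSums(m$phi[, a_cols, drop = FALSE])
  # one topic concentrates on block A, the other on block B
  expect_gt(max(mass_on_a), 0.95)
  expect_lt(min(mass_on_a), 0.05)
})

test_that("fit_lda validates its inputs", {
  corp <- make_corpus(make_doc("ok", c("a", "a")), make_doc("bad", "zzz"))
  voc <- build_vocabulary(make_corpus(make_doc("x", c("a", "a"))), 1)
  expect_error(fit_lda(corp, voc, K = 2, iterations = 5, seed = 1), "bad")
  expect_error(fit_lda(corp, voc, K = 0, iterations = 5, seed = 1), "K")
})

test_that("perplexity has the uniform-model closed form", {
  # uniform phi: every token has likelihood 1/v regardless of theta
  vocab <- make_vocab(c("u", "v", "w"), c(1L, 1L, 1L))
  m <- worked_model()
  m$vocabulary <- vocab
  m$phi <- matrix(1 / 3, 2, 3, dimnames = list(NULL, vocab$tokens))
  held <- make_corpus(make_doc("h1", c("u", "w", "w")))
  expect_equal(perplexity(m, held), 3, tolerance = 1e-12)
})

test_that("single-word degenerate model reaches perplexity 1", {
  vocab <- make_vocab("solo", 4L)
  m <- worked_model()
  m$vocabulary <- vocab
  m$phi <- matrix(1, 2, 1, dimnames = list(NULL, "solo"))
  held <- make_corpus(make_doc("h", rep("solo", 5)))
  expect_equal(perplexity(m, held), 1, tolerance = 1e-12)
})

test_that("perplexity matches a naive double-loop computation", {
  sim <- simulate_lda_corpus(K = 2, V = 15, n_docs = 10, doc_length = 12, seed = 6)
  voc <- build_vocabulary(sim$corpus, 1)
  m <- fit_lda(sim$corpus, voc, K = 2, iterations = 60, seed = 2)
  post <- word_topic_posterior(m)
  # independent oracle: explicit loops over documents and token occurrences
  ll <- 0; n <- 0
  for (d in sim$corpus$documents) {
    th <- infer_doc_topics(post, d$tokens, voc, warn = FALSE)$probs
    for (tok in d$tokens) {
      w <- voc$index[[tok]]
      p <- 0
      for (t in 1:2) p <- p + th[t] * m$phi[t, w]
      ll <- ll + log(p); n <- n + 1
    }
  }
  expect_equal(perplexity(m, sim$corpus), unname(exp(-ll / n)), tolerance = 1e-9)
})

test_that("out-of-vocabulary held-out tokens are skipped with a warning", {
  corp <- make_corpus(make_doc("1", c("a", "a", "b")))
  voc <- build_vocabulary(corp, 1)
  m <- fit_lda(corp, voc, K = 1, iterations = 5, seed = 1)
  held <- make_corpus(make_doc("h", c("a", "unknown")))
  expect_warning(px <- perplexity(m, held), "out-of-vocabulary")
  expect_true(is.finite(px) && px > 0)
})

test_that("training perplexity does not degrade with more sweeps", {
  sim <- simulate_lda_corpus(K = 3, V = 40, n_docs = 40, doc_length = 25, seed = 8)
  voc <- build_vocabulary(sim$corpus, 1)
  px <- function(iter, seed) {
    m <- fit_lda(sim$corpus, voc, K = 3, iterations = iter, seed = seed)
    suppressWarnings(perplexity(m, sim$corpus))
  }
  early <- vapply(1:5, function(s) px(10L, s), numeric(1))
  late <- vapply(1:5, function(s) px(500L, s), numeric(1))
  expect_lte(median(late), median(early))
})

test_that("predict() infers topic rows for new records", {
  sim <- simulate_lda_corpus(K = 2, V = 20, n_docs = 12, doc_length = 15, seed = 10)
  voc <- build_vocabulary(sim$corpus, 1)
  m <- fit_lda(sim$corpus, voc, K = 2, iterations = 50, seed = 1)
  p <- predict(m, sim$corpus$documents[[1]]$tokens)
  expect_equal(dim(p), c(1, 2))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  pc <- predict(m, sim$corpus)
  expect_equal(dim(pc), c(12, 2))
})

test_that("model bundles round-trip losslessly", {
  sim <- simulate_lda_corpus(K = 2, V = 15, n_docs = 8, doc_length = 10, seed = 3)
  voc <- build_vocabulary(sim$corpus, 1)
  m <- fit_lda(sim$corpus, voc, K = 2, iterations = 20, seed = 5)
  dir <- withr::local_tempdir()
  save_topic_model(m, dir)
  back <- load_topic_model(dir)
  expect_equal(back$phi, m$phi)
  expect_equal(back$theta, m$theta)
  expect_equal(back$vocabulary, m$vocabulary)
  expect_identical(back[c("K", "alpha", "beta", "iterations", "seed")],
                   m[c("K", "alpha", "beta", "iterations", "seed")])
})
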