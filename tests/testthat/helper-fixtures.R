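# Builders for small in-code fixtures shared across tests.

make_doc <- function(id, tokens, pos = NULL, primary = NULL, diff = NULL) {
  ddxtopics:::new_document(id, tokens, pos_tags = pos, primary_dx = primary,
                           differential_dx = diff)
}

make_corpus <- function(...) ddxtopics:::new_corpus(list(...))

# Vocabulary over explicit tokens with given counts (canonical order assumed).
make_vocab <- function(tokens, counts = rep(1L, length(tokens))) {
  idx <- seq_along(tokens); names(idx) <- tokens
  cnt <- as.integer(counts); names(cnt) <- tokens
  structure(list(tokens = tokens, index = idx, counts = cnt),
            class = "ddx_vocabulary")
}

# Hand-constructed 2-topic model used in the worked examples:
# phi rows [0.9, 0.1] / [0.2, 0.8] over words w1, w2;
# theta rows [0.5, 0.5] / [1, 0]  =>  raw topic prior [1.5, 0.5].
worked_model <- function() {
  vocab <- make_vocab(c("w1", "w2"), c(2L, 1L))
  structure(list(K = 2L,
                 phi = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE,
                              dimnames = list(NULL, vocab$tokens)),
                 theta = matrix(c(0.5, 0.5, 1, 0), 2, 2, byrow = TRUE),
                 alpha = 1, beta = 0.01, iterations = 1L, seed = 1L,
                 vocabulary = vocab, doc_ids = c("d1", "d2")),
            class = "topic_model")
}

# A random valid topic model (distribution rows) for property tests.
random_model <- function(K, V, seed) {
  set.seed(seed)
  vocab <- make_vocab(sprintf("w%02d", seq_len(V)),
                      sample.int(20, V, replace = TRUE))
  phi <- ddxtopics:::rdirichlet_rows(K, rep(0.5, V))
  colnames(phi) <- vocab$tokens
  theta <- ddxtopics:::rdirichlet_rows(sample(2:6, 1), rep(0.7, K))
  structure(list(K = K, phi = phi, theta = theta, alpha = 1, beta = 0.01,
                 iterations = 1L, seed = seed, vocabulary = vocab,
                 doc_ids = sprintf("d%d", seq_len(nrow(theta)))),
            class = "topic_model")
}

# Two-block corpus: documents draw words from only block A or only block B.
block_corpus <- function(n_docs = 30, len = 25, seed = 5) {
  set.seed(seed)
  a <- sprintf("a%02d", 1:8)
  b <- sprintf("b%02d", 1:8)
  docs <- lapply(seq_len(n_docs), function(i) {
    pool <- if (i %% 2 == 0) a else b
    make_doc(sprintf("doc%03d", i), sample(pool, len, replace = TRUE))
  })
  ddxtopics:::new_corpus(docs)
}

cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
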