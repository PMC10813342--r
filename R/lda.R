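#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Estimates the two matrices of a latent Dirichlet allocation model:
#' `phi`, the K topic-word distributions P(w|t), and `theta`, the n
#' document-topic distributions P(t|d). Per-token topic assignments are
#' resampled by collapsed Gibbs sampling with the mixture weights integrated
#' out, and the point estimates are the smoothed counts of the final state:
#' \deqn{\phi_{tw} = (N_{tw} + \beta) / (N_t + V\beta), \quad
#'       \theta_{dt} = (N_{dt} + \alpha) / (N_d + K\alpha).}
#' The fit is bitwise reproducible for identical inputs and `seed`.
#'
#' @param corpus A `ddx_corpus`; every document must keep at least one
#'   in-vocabulary token.
#' @param vocabulary A `ddx_vocabulary` built from (a superset of) the corpus.
#' @param K Number of topics, at least 1.
#' @param alpha Document-topic Dirichlet concentration; default `50 / K`.
#' @param beta Topic-word Dirichlet concentration; default 0.01.
#' @param iterations Number of full Gibbs sweeps; the only schedule knob
#'   (no burn-in or thinning — the estimate is read from the final state).
#' @param seed Integer RNG seed.
#' @return An object of class `topic_model` with elements `K`, `phi`
#'   (K x V matrix, rows sum to 1), `theta` (n x K matrix, rows sum to 1),
#'   `alpha`, `beta`, `iterations`, `seed`, `vocabulary`, `doc_ids`.
#' @seealso [perplexity()], [word_topic_posterior()], [predict.topic_model()]
#' @export
fit_lda <- function(corpus, vocabulary, K, alpha = 50 / K, beta = 0.01,
                    iterations = 1000L, seed = 1L) {
  stopifnot(inherits(corpus, "ddx_corpus"), inherits(vocabulary, "ddx_vocabulary"))
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be an integer >= 1")
  stopifnot(alpha > 0, beta > 0, iterations >= 1L)
  if (!length(corpus$documents)) stop("cannot fit on an empty corpus")

  docs <- lapply(corpus$documents, function(d) {
    ids <- unname(vocabulary$index[d$tokens])
    ids <- ids[!is.na(ids)]
    if (!length(ids))
      stop("document '", d$id, "' has no in-vocabulary token", call. = FALSE)
    as.integer(ids - 1L)
  })
  V <- length(vocabulary$tokens)

  set.seed(as.integer(seed))
  st <- gibbs_lda(docs, K, V, alpha, beta, as.integer(iterations))

  nkw <- st$nkw
  nk <- as.numeric(st$nk)
  phi <- (nkw + beta) / (nk + V * beta)
  ndk <- st$ndk
  nd <- rowSums(ndk)
  theta <- (ndk + alpha) / (nd + K * alpha)
  dimnames(phi) <- list(NULL, vocabulary$tokens)

  structure(list(K = K, phi = phi, theta = theta, alpha = alpha, beta = beta,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 vocabulary = vocabulary,
                 doc_ids = vapply(corpus$documents, function(d) d$id, character(1))),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat("LDA topic model (collapsed Gibbs)\n")
  cat("  topics:     ", x$K, "\n")
  cat("  vocabulary: ", length(x$vocabulary$tokens), "\n")
  cat("  documents:  ", nrow(x$theta), "\n")
  cat("  alpha =", format(x$alpha, digits = 4), " beta =", x$beta,
      " iterations =", x$iterations, " seed =", x$seed, "\n")
  invisible(x)
}

#' Summarise a topic model by its top-weight words
#'
#' @param object A `topic_model`.
#' @param n_words Number of top words per topic to display.
#' @param ... Unused.
#' @export
summary.topic_model <- function(object, n_words = 8L, ...) {
  tw <- top_words(object, n_words)
  structure(list(model = object, top_words = tw), class = "summary.topic_model")
}

#' @export
print.summary.topic_model <- function(x, ...) {
  print(x$model)
  cat("Top words per topic:\n")
  for (t in seq_along(x$top_words))
    cat(sprintf("  t%-3d %s\n", t, paste(x$top_words[[t]], collapse = " ")))
  invisible(x)
}

#' Top-probability words of each topic
#'
#' @param model A `topic_model`.
#' @param n Words per topic.
#' @return A list of character vectors, one per topic.
#' @export
top_words <- function(model, n = 10L) {
  lapply(seq_len(model$K), function(t) {
    o <- order(model$phi[t, ], decreasing = TRUE)[seq_len(min(n, ncol(model$phi)))]
    model$vocabulary$tokens[o]
  })
}

#' @export
coef.topic_model <- function(object, ...) object$phi

#' Topic inference for new documents via the word-topic posterior
#'
#' `predict` on a fitted model performs fold-in inference for records outside
#' the training corpus: it composes the model's word-topic posterior P(t|w)
#' and sums the rows of the document's in-vocabulary tokens (see
#' [infer_doc_topics()]).
#'
#' @param object A `topic_model`.
#' @param newdata A `ddx_corpus`, a single `ddx_document`, or a character
#'   vector of tokens.
#' @param ... Unused.
#' @return A matrix of document-topic distributions (one row per document).
#' @export
predict.topic_model <- function(object, newdata, ...) {
  post <- word_topic_posterior(object)
  toks <- if (inherits(newdata, "ddx_corpus"))
    lapply(newdata$documents, function(d) d$tokens)
  else if (inherits(newdata, "ddx_document")) list(newdata$tokens)
  else list(as.character(newdata))
  out <- t(vapply(toks, function(tk)
    infer_doc_topics(post, tk, object$vocabulary)$probs, numeric(object$K)))
  out
}

#' Held-out perplexity of a topic model
#'
#' Computes `exp(-(sum of per-token log mixture likelihoods) / N)` where the
#' token likelihood is `sum_t theta_d[t] * phi[t][w]`. Document-topic
#' distributions for the held-out records are obtained by fold-in through the
#' word-topic posterior ([infer_doc_topics()]), so the same code path scores
#' training and unseen text. Out-of-vocabulary tokens are skipped with a
#' warning.
#'
#' @param model A `topic_model`.
#' @param heldout A `ddx_corpus`; each document needs at least one
#'   in-vocabulary token.
#' @return A positive number; lower is better.
#' @export
perplexity <- function(model, heldout) {
  stopifnot(inherits(model, "topic_model"), inherits(heldout, "ddx_corpus"))
  post <- word_topic_posterior(model)
  loglik <- 0
  ntok <- 0L
  for (d in heldout$documents) {
    ids <- tokens_to_ids(d$tokens, model$vocabulary,
                         context = paste0("document '", d$id, "'"))
    if (!length(ids)) next
    th <- infer_doc_topics(post, d$tokens, model$vocabulary, warn = FALSE)$probs
    pw <- as.numeric(th %*% model$phi[, ids, drop = FALSE])
    loglik <- loglik + sum(log(pw))
    ntok <- ntok + length(ids)
  }
  if (ntok == 0L) stop("no in-vocabulary token in the held-out corpus")
  exp(-loglik / ntok)
}
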