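#' Corpus word frequencies P(w)
#'
#' Relative frequency of each vocabulary word in the corpus it was built
#' from: `P(w) = count(w) / sum(counts)`.
#'
#' @param vocabulary A `ddx_vocabulary` (its stored counts are the corpus
#'   frequencies after filtering and pruning).
#' @return A named numeric vector over the vocabulary summing to 1.
#' @export
word_frequency <- function(vocabulary) {
  stopifnot(inherits(vocabulary, "ddx_vocabulary"))
  if (!length(vocabulary$counts)) stop("empty vocabulary")
  vocabulary$counts / sum(vocabulary$counts)
}

#' Corpus-level topic prior P(t)
#'
#' The absolute distribution of topics over the training corpus: for each
#' topic, the sum of its document-topic probabilities over all documents,
#' taking each document's weight P(d) as the constant 1. The raw sums add to
#' the number of documents; `normalized` rescales them to a distribution.
#'
#' @param model A fitted `topic_model`.
#' @return A `topic_prior`: list with `raw` (length-K vector, sums to n) and
#'   `normalized` (sums to 1).
#' @export
topic_prior <- function(model) {
  stopifnot(inherits(model, "topic_model"))
  raw <- colSums(model$theta)
  structure(list(raw = raw, normalized = raw / sum(raw)), class = "topic_prior")
}

#' Word-topic posterior P(t|w)
#'
#' Inverts the model's topic-word distributions by Bayes' rule:
#' `P(t|w) \propto P(w|t) P(t)`, with the topic prior taken from the training
#' corpus ([topic_prior()]). The corpus word frequency P(w) is a constant per
#' word and cancels in the row normalization. Each vocabulary word gets a
#' distribution over topics, which is what lets the model score documents
#' that were not in the training corpus.
#'
#' @param model A fitted `topic_model`.
#' @param prior Optionally a precomputed `topic_prior` for the same model.
#' @return A `word_topic_posterior`: V x K matrix, rows are distributions,
#'   with the vocabulary as `rownames`.
#' @export
word_topic_posterior <- function(model, prior = topic_prior(model)) {
  stopifnot(inherits(model, "topic_model"), inherits(prior, "topic_prior"))
  unnorm <- t(model$phi) * rep(prior$raw, each = ncol(model$phi))
  rs <- rowSums(unnorm)
  if (any(rs <= 0))
    stop("word(s) with zero probability under every topic: cannot normalize")
  mat <- unnorm / rs
  rownames(mat) <- model$vocabulary$tokens
  structure(mat, class = c("word_topic_posterior", class(mat)))
}

#' Topic distribution of a (possibly unseen) document
#'
#' Fold-in inference through the word-topic posterior: sums the P(t|w) rows
#' of the document's in-vocabulary token occurrences (multiplicity counts)
#' and normalizes to a distribution. Out-of-vocabulary tokens are skipped
#' with a warning; a fully out-of-vocabulary document is an error.
#'
#' @param posterior A `word_topic_posterior`.
#' @param tokens Character vector of the document's tokens.
#' @param vocabulary The model's `ddx_vocabulary`.
#' @param warn Warn about skipped out-of-vocabulary tokens.
#' @param id Document identifier used in messages.
#' @return A `doc_topics`: list with `probs` (length-K distribution) and
#'   `n_tokens_used`.
#' @export
infer_doc_topics <- function(posterior, tokens, vocabulary, warn = TRUE,
                             id = "document") {
  stopifnot(inherits(posterior, "word_topic_posterior"))
  ids <- tokens_to_ids(tokens, vocabulary, warn = warn, context = id)
  if (!length(ids))
    stop("no in-vocabulary token in ", id, ": cannot infer topics")
  s <- colSums(posterior[ids, , drop = FALSE])
  structure(list(probs = s / sum(s), n_tokens_used = length(ids)),
            class = "doc_topics")
}

#' @export
print.doc_topics <- function(x, ...) {
  cat("Document topic distribution over", length(x$probs), "topics (",
      x$n_tokens_used, "tokens used); top:",
      paste(sprintf("t%d=%.3f", order(x$probs, decreasing = TRUE)[1:min(3, length(x$probs))],
                    sort(x$probs, decreasing = TRUE)[1:min(3, length(x$probs))]),
            collapse = ", "), "\n")
  invisible(x)
}
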