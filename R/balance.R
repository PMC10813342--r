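#' Similarity functions for Balance Similarity
#'
#' `cosine_sim` is the default pairwise similarity. `kl_sim` maps the
#' symmetrized Kullback-Leibler divergence into a similarity via
#' `1 / (1 + KLsym)`, so that larger always means more similar and the
#' argmin semantics of the selection criterion are preserved.
#'
#' @param a,b Non-negative numeric vectors (probability rows).
#' @return A single similarity value.
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' @rdname cosine_sim
#' @export
kl_sim <- function(a, b) {
  eps <- 1e-12
  a <- a + eps; b <- b + eps
  a <- a / sum(a); b <- b / sum(b)
  kl <- sum(a * log(a / b)) + sum(b * log(b / a))
  1 / (1 + kl)
}

# Sum of similarities over unordered distinct row pairs (i < j).
# For cosine this uses the identity sum_{i<j} r_i.r_j = (|sum r_i|^2 - m)/2
# on unit-normalized rows, avoiding the O(m^2) loop.
pairwise_sim_sum <- function(rows, sim) {
  m <- nrow(rows)
  if (m < 2) stop("need at least 2 rows to form a pair")
  if (identical(sim, cosine_sim)) {
    nrm <- sqrt(rowSums(rows^2))
    nz <- nrm > 0
    r <- rows[nz, , drop = FALSE] / nrm[nz]
    s <- colSums(r)
    return((sum(s * s) - nrow(r)) / 2)
  }
  tot <- 0
  for (i in seq_len(m - 1))
    for (j in seq(i + 1, m))
      tot <- tot + sim(rows[i, ], rows[j, ])
  tot
}

#' Pairwise topic similarity of a model
#'
#' Sum over all unordered pairs of topics of the similarity of their
#' word distributions P(w|t). High values flag redundant topics.
#'
#' @param model A `topic_model` with K >= 2.
#' @param sim Pairwise similarity function; default [cosine_sim()].
#' @return A non-negative number (for cosine), at most K(K-1)/2.
#' @export
simi_topic <- function(model, sim = cosine_sim) {
  stopifnot(inherits(model, "topic_model"))
  if (model$K < 2) stop("simi_topic needs K >= 2 (no topic pairs otherwise)")
  pairwise_sim_sum(model$phi, sim)
}

#' Pairwise word similarity of a word-topic posterior
#'
#' Sum over all unordered pairs of vocabulary words of the similarity of
#' their topic posteriors P(t|w). High values flag words that share one
#' semantic dimension (near-synonyms in topic space). Because the full sum
#' is quadratic in the vocabulary, `max_words` restricts it to the most
#' frequent words in the vocabulary's canonical order.
#'
#' @param posterior A `word_topic_posterior` (rows in vocabulary order, most
#'   frequent first).
#' @param sim Pairwise similarity function; default [cosine_sim()].
#' @param max_words Optional cap on the number of (most frequent) words.
#' @return A non-negative number (for cosine), at most v(v-1)/2.
#' @export
simi_word <- function(posterior, sim = cosine_sim, max_words = NULL) {
  stopifnot(inherits(posterior, "word_topic_posterior"))
  v <- nrow(posterior)
  if (!is.null(max_words)) v <- min(v, as.integer(max_words))
  if (v < 2) stop("simi_word needs at least 2 eligible words")
  pairwise_sim_sum(unclass(posterior)[seq_len(v), , drop = FALSE], sim)
}

#' Balance Similarity of a fitted model
#'
#' The topic-number quality criterion
#' \deqn{BalanceSimilarity(K) = SimiTopic \times SimiWord / K^2,}
#' where SimiTopic accumulates pairwise topic similarity ([simi_topic()]),
#' SimiWord accumulates pairwise word similarity in topic space
#' ([simi_word()]), and the K^2 denominator restrains the shrinkage or
#' expansion of the semantic space as the number of topics changes. Lower is
#' better; the selected K is its argmin over a scan.
#'
#' @inheritParams simi_topic
#' @inheritParams simi_word
#' @param posterior Optionally a precomputed posterior for `model`.
#' @param compute_perplexity Optional held-out corpus on which to record
#'   perplexity alongside (or NULL to skip).
#' @return A `balance_point`: list with `K`, `simi_topic`, `simi_word`,
#'   `balance`, `perplexity` (NA unless requested) and `seed`.
#' @export
balance_similarity <- function(model, posterior = word_topic_posterior(model),
                               sim = cosine_sim, max_words = 2000L,
                               compute_perplexity = NULL) {
  st <- simi_topic(model, sim)
  sw <- simi_word(posterior, sim, max_words)
  px <- if (!is.null(compute_perplexity)) perplexity(model, compute_perplexity) else NA_real_
  structure(list(K = model$K, simi_topic = st, simi_word = sw,
                 balance = st * sw / model$K^2, perplexity = px,
                 seed = model$seed),
            class = "balance_point")
}

#' @export
print.balance_point <- function(x, ...) {
  cat(sprintf("K = %d: SimiTopic = %.4f, SimiWord = %.4f, balance = %.6f\n",
              x$K, x$simi_topic, x$simi_word, x$balance))
  invisible(x)
}

#' Scan candidate topic numbers
#'
#' Fits one model per (K, seed) combination and records the Balance
#' Similarity point and (optionally) the training-corpus perplexity for
#' each. Deterministic given the seeds; results are ordered by K then seed.
#'
#' @param corpus,vocabulary Training data.
#' @param k_grid Integer vector of candidate topic numbers (each >= 2).
#' @param seeds Integer vector of fitting seeds.
#' @param alpha,beta,iterations Passed to [fit_lda()] (`alpha = NULL` means
#'   the per-K default 50/K).
#' @param sim,max_words Passed to [balance_similarity()].
#' @param with_perplexity Record training perplexity per point.
#' @param verbose Print progress lines.
#' @return A data.frame with columns K, seed, simi_topic, simi_word,
#'   balance, perplexity, of class `balance_curve`.
#' @export
scan_k <- function(corpus, vocabulary, k_grid, seeds = 1L, alpha = NULL,
                   beta = 0.01, iterations = 500L, sim = cosine_sim,
                   max_words = 2000L, with_perplexity = FALSE,
                   verbose = FALSE) {
  k_grid <- as.integer(k_grid)
  if (!length(k_grid)) stop("k_grid must be non-empty")
  if (any(k_grid < 2)) stop("every K in k_grid must be >= 2")
  rows <- list()
  for (K in sort(k_grid)) {
    for (s in as.integer(seeds)) {
      a <- if (is.null(alpha)) 50 / K else alpha
      m <- fit_lda(corpus, vocabulary, K, alpha = a, beta = beta,
                   iterations = iterations, seed = s)
      bp <- balance_similarity(m, sim = sim, max_words = max_words,
                               compute_perplexity = if (with_perplexity) corpus else NULL)
      if (verbose)
        message(sprintf("K=%d seed=%d balance=%.6g", K, s, bp$balance))
      rows[[length(rows) + 1L]] <- data.frame(
        K = K, seed = s, simi_topic = bp$simi_topic, simi_word = bp$simi_word,
        balance = bp$balance, perplexity = bp$perplexity)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("balance_curve", "data.frame")
  out
}

#' Select the number of topics from a balance curve
#'
#' `argmin` picks the K whose mean balance over seeds is smallest (the
#' printed form of the criterion); `elbow` picks the K with the largest
#' discrete curvature (second difference) of mean balance versus K, for
#' curves where an inflection rather than a global minimum marks the
#' transition. Ties break toward the smaller K.
#'
#' @param curve A `balance_curve` data.frame (or any data.frame with K and
#'   balance columns).
#' @param strategy `"argmin"` (default) or `"elbow"`.
#' @return The selected K (integer).
#' @export
select_k <- function(curve, strategy = c("argmin", "elbow")) {
  strategy <- match.arg(strategy)
  if (!nrow(curve)) stop("empty balance curve")
  mean_bal <- tapply(curve$balance, curve$K, mean)
  ks <- as.integer(names(mean_bal))
  o <- order(ks)
  ks <- ks[o]; mean_bal <- as.numeric(mean_bal)[o]
  if (strategy == "argmin")
    return(ks[which.min(mean_bal)])   # which.min takes the first = smaller K
  if (length(ks) < 3) stop("elbow selection needs at least 3 distinct K values")
  curvature <- mean_bal[-c(length(ks) - 1, length(ks))] -
    2 * mean_bal[-c(1, length(ks))] + mean_bal[-c(1, 2)]
  ks[-c(1, length(ks))][which.max(curvature)]
}

#' Write a balance curve as CSV
#'
#' @param curve A `balance_curve`.
#' @param path Output CSV path.
#' @export
write_balance_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
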