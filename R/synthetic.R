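#' Specification of a synthetic clinical corpus with planted structure
#'
#' Defines a generative setting in which the full pipeline is testable
#' without clinical data: topics are Dirichlet draws over a symbolic
#' vocabulary; each diagnosis is a mixture over a small set of topics;
#' designated differential pairs share `overlap` topics (similar clinical
#' manifestations are operationalized as topic overlap); each record is a
#' noisy draw around its diagnosis mixture, labelled with the primary
#' diagnosis and a set of true differentials.
#'
#' Diagnoses are arranged in groups: each group owns `overlap` shared topics
#' plus one unique topic per member diagnosis (so `topics_per_dx` must equal
#' `overlap + 1`), and the differential map is all within-group pairs (and
#' is therefore symmetric). The defaults use 8 diagnoses in 2 groups of 4
#' over exactly `K_true = 12` topics.
#'
#' The number of differentials recorded per record is drawn from
#' `diff_count_probs` over 1..5 (default mean 2.43) and capped at the
#' number of true differentials available for its diagnosis.
#'
#' @param K_true Number of planted topics.
#' @param V Vocabulary size.
#' @param n_diagnoses Number of diagnosis labels.
#' @param topics_per_dx Topics per diagnosis (= overlap + 1).
#' @param overlap Topics shared between a diagnosis and each designated
#'   differential.
#' @param records_per_dx Records generated per diagnosis.
#' @param doc_length Mean token count (Poisson, at least 1).
#' @param alpha_doc Concentration of the record-level Dirichlet around its
#'   diagnosis mixture (larger = less within-diagnosis noise).
#' @param beta_topic Topic-word Dirichlet concentration (smaller = sparser,
#'   better-separated topics).
#' @param diff_count_probs Probabilities of 1..5 recorded differentials.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(K_true = 12L, V = 300L, n_diagnoses = 8L,
                           topics_per_dx = 3L, overlap = 2L,
                           records_per_dx = 60L, doc_length = 40,
                           alpha_doc = 30, beta_topic = 0.1,
                           diff_count_probs = c(0.25, 0.30, 0.25, 0.17, 0.03),
                           seed = 1L) {
  spec <- list(K_true = as.integer(K_true), V = as.integer(V),
               n_diagnoses = as.integer(n_diagnoses),
               topics_per_dx = as.integer(topics_per_dx),
               overlap = as.integer(overlap),
               records_per_dx = as.integer(records_per_dx),
               doc_length = doc_length, alpha_doc = alpha_doc,
               beta_topic = beta_topic,
               diff_count_probs = diff_count_probs / sum(diff_count_probs),
               seed = as.integer(seed))
  with(spec, {
    stopifnot(K_true >= 1, V >= 2, n_diagnoses >= 2, records_per_dx >= 1,
              doc_length > 0, alpha_doc > 0, beta_topic > 0,
              overlap >= 0, overlap < topics_per_dx, topics_per_dx <= K_true,
              length(diff_count_probs) == 5, all(diff_count_probs >= 0))
  })
  if (spec$topics_per_dx != spec$overlap + 1L)
    stop("the group construction requires topics_per_dx = overlap + 1")
  spec$group_size <- feasible_group_size(spec)
  class(spec) <- "synthetic_spec"
  spec
}

# Smallest group count (largest groups) whose topic budget fits K_true:
# each group needs `overlap` shared + group_size unique topics.
feasible_group_size <- function(spec) {
  divisors <- which(spec$n_diagnoses %% seq_len(spec$n_diagnoses) == 0)
  for (g in sort(divisors, decreasing = TRUE)) {
    if (g < 2) next  # a singleton group has no differential pairs
    n_groups <- spec$n_diagnoses / g
    if (n_groups * spec$overlap + spec$n_diagnoses <= spec$K_true &&
        g <= 4)  # cap group size so out-of-group distractors exist at defaults
      return(as.integer(g))
  }
  for (g in sort(divisors, decreasing = TRUE)) {
    n_groups <- spec$n_diagnoses / g
    if (g >= 2 && n_groups * spec$overlap + spec$n_diagnoses <= spec$K_true)
      return(as.integer(g))
  }
  stop("infeasible topic assignment: ", spec$n_diagnoses, " diagnoses with overlap ",
       spec$overlap, " do not fit into ", spec$K_true, " topics")
}

#' Generate a synthetic corpus with known differential structure
#'
#' Samples planted topics, diagnosis mixtures, and labelled records
#' according to a [synthetic_spec()]. Every record carries a primary
#' diagnosis and 1-5 true differentials drawn from the planted differential
#' map.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `corpus` (a `ddx_corpus`) and `truth` (list:
#'   `phi_true` K_true x V matrix, `dx_mixtures` named matrix of diagnosis
#'   topic mixtures, `differential_map` named list of true differential
#'   labels, `dx_topics` named list of planted topic sets).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  K <- spec$K_true; V <- spec$V
  vocab_words <- sprintf("w%03d", seq_len(V) - 1L)
  phi_true <- rdirichlet_rows(K, rep(spec$beta_topic, V))

  g <- spec$group_size
  n_groups <- spec$n_diagnoses / g
  dx_labels <- sprintf("dx%02d", seq_len(spec$n_diagnoses) - 1L)
  dx_topics <- vector("list", spec$n_diagnoses)
  names(dx_topics) <- dx_labels
  differential_map <- vector("list", spec$n_diagnoses)
  names(differential_map) <- dx_labels
  next_topic <- 1L
  for (grp in seq_len(n_groups)) {
    shared <- if (spec$overlap > 0) seq(next_topic, length.out = spec$overlap) else integer()
    next_topic <- next_topic + spec$overlap
    members <- seq((grp - 1L) * g + 1L, grp * g)
    for (m in members) {
      dx_topics[[m]] <- c(shared, next_topic)
      next_topic <- next_topic + 1L
      differential_map[[m]] <- dx_labels[setdiff(members, m)]
    }
  }

  # diagnosis mixtures: a Dirichlet draw over the diagnosis's own topics
  dx_mixtures <- matrix(0, spec$n_diagnoses, K,
                        dimnames = list(dx_labels, NULL))
  for (i in seq_len(spec$n_diagnoses)) {
    w <- as.numeric(rdirichlet_rows(1, rep(2, length(dx_topics[[i]]))))
    dx_mixtures[i, dx_topics[[i]]] <- w
  }

  docs <- vector("list", spec$n_diagnoses * spec$records_per_dx)
  r <- 0L
  for (i in seq_len(spec$n_diagnoses)) {
    avail <- differential_map[[dx_labels[i]]]
    for (j in seq_len(spec$records_per_dx)) {
      r <- r + 1L
      mix <- as.numeric(rdirichlet_rows(1, spec$alpha_doc * dx_mixtures[i, ] + 1e-8))
      m <- max(1L, stats::rpois(1, spec$doc_length))
      zs <- sample.int(K, m, replace = TRUE, prob = mix)
      tokens <- vocab_words[vapply(zs, function(t)
        sample.int(V, 1, prob = phi_true[t, ]), integer(1))]
      n_diff <- min(sample.int(5L, 1, prob = spec$diff_count_probs),
                    length(avail))
      diffs <- sample(avail, n_diff)
      docs[[r]] <- new_document(id = sprintf("rec%05d", r), tokens = tokens,
                                primary_dx = dx_labels[i],
                                differential_dx = diffs)
    }
  }
  corpus <- new_corpus(docs, provenance = sprintf("synthetic(seed=%d)", spec$seed))
  list(corpus = corpus,
       truth = list(phi_true = phi_true, dx_mixtures = dx_mixtures,
                    differential_map = differential_map,
                    dx_topics = dx_topics, vocab_words = vocab_words))
}

# Dirichlet rows via normalized gammas (uses R's RNG).
rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), n, k, byrow = TRUE)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, ] <- 1 / k  # numeric underflow guard at tiny alpha
  x / rowSums(x)
}

#' Simulate a plain LDA corpus from known parameters
#'
#' Samples documents directly from the LDA generative process with
#' well-separated planted topics — the standard setting for parameter
#' recovery checks of the Gibbs sampler (no diagnosis labels).
#'
#' @param K Number of planted topics.
#' @param V Vocabulary size.
#' @param n_docs Number of documents.
#' @param doc_length Mean token count (Poisson, at least 1).
#' @param alpha Document-topic Dirichlet concentration (per-topic).
#' @param beta_topic Topic-word Dirichlet concentration.
#' @param seed Integer seed.
#' @return A list with `corpus`, `phi_true` (K x V) and `theta_true`
#'   (n_docs x K).
#' @export
simulate_lda_corpus <- function(K = 5L, V = 200L, n_docs = 500L,
                                doc_length = 50, alpha = 0.1,
                                beta_topic = 0.05, seed = 1L) {
  set.seed(as.integer(seed))
  vocab_words <- sprintf("w%03d", seq_len(V) - 1L)
  phi_true <- rdirichlet_rows(K, rep(beta_topic, V))
  theta_true <- rdirichlet_rows(n_docs, rep(alpha, K))
  docs <- vector("list", n_docs)
  for (d in seq_len(n_docs)) {
    m <- max(1L, stats::rpois(1, doc_length))
    zs <- sample.int(K, m, replace = TRUE, prob = theta_true[d, ])
    tokens <- vocab_words[vapply(zs, function(t)
      sample.int(V, 1, prob = phi_true[t, ]), integer(1))]
    docs[[d]] <- new_document(id = sprintf("doc%05d", d), tokens = tokens)
  }
  list(corpus = new_corpus(docs, provenance = sprintf("lda-sim(seed=%d)", seed)),
       phi_true = phi_true, theta_true = theta_true)
}

#' Write the planted truth of a synthetic corpus as JSON
#'
#' @param truth The `truth` element of [generate_synthetic()].
#' @param path Output JSON path.
#' @export
write_truth <- function(truth, path) {
  obj <- list(phi_true = truth$phi_true, dx_mixtures = truth$dx_mixtures,
              differential_map = truth$differential_map,
              dx_topics = truth$dx_topics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Permutation-aligned topic recovery score
#'
#' Matches estimated topics to planted topics one-to-one (full permutation
#' search for K <= 8, greedy matching above) and returns the mean cosine
#' between matched topic-word rows — the standard summary for parameter
#' recovery on simulated corpora.
#'
#' @param phi_est Estimated K x V topic-word matrix.
#' @param phi_true Planted K x V topic-word matrix (same K and V).
#' @return A list with `mean_cosine` and `perm` (the matching, as indices
#'   into the rows of `phi_true`).
#' @export
align_topics <- function(phi_est, phi_true) {
  stopifnot(nrow(phi_est) == nrow(phi_true), ncol(phi_est) == ncol(phi_true))
  K <- nrow(phi_est)
  cs <- matrix(0, K, K)
  for (i in seq_len(K))
    for (j in seq_len(K))
      cs[i, j] <- cosine_sim(phi_est[i, ], phi_true[j, ])
  if (K <= 8) {
    perms <- permutations_of(K)
    best <- 0; best_p <- seq_len(K)
    for (p in perms) {
      v <- mean(cs[cbind(seq_len(K), p)])
      if (v > best) { best <- v; best_p <- p }
    }
    list(mean_cosine = best, perm = best_p)
  } else {
    perm <- integer(K)
    taken <- logical(K)
    for (i in order(-apply(cs, 1, max))) {
      j <- which.max(ifelse(taken, -Inf, cs[i, ]))
      perm[i] <- j; taken[j] <- TRUE
    }
    list(mean_cosine = mean(cs[cbind(seq_len(K), perm)]), perm = perm)
  }
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in permutations_of(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}
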