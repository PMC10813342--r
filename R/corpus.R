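#' Read a pre-tokenized corpus from JSON Lines
#'
#' Each line holds one record object with keys `id` (string) and `tokens`
#' (array of strings), and optionally `pos` (parallel array of
#' part-of-speech codes), `primary_dx` (string) and `differential_dx`
#' (array of strings). Input order is preserved.
#'
#' @param path Path to a UTF-8 JSON Lines file.
#' @return A `ddx_corpus`: a list with `documents` (list of `ddx_document`)
#'   and `provenance` (the source path).
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) stop("parse error on line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(rec$id) || !nzchar(as.character(rec$id)[1]))
      stop("parse error on line ", i, ": missing 'id'", call. = FALSE)
    if (is.null(rec$tokens))
      stop("parse error on line ", i, ": missing 'tokens'", call. = FALSE)
    docs[[i]] <- new_document(
      id = as.character(rec$id)[1],
      tokens = as.character(unlist(rec$tokens)),
      pos_tags = if (!is.null(rec$pos)) as.character(unlist(rec$pos)) else NULL,
      primary_dx = if (!is.null(rec$primary_dx)) as.character(rec$primary_dx)[1] else NULL,
      differential_dx = if (!is.null(rec$differential_dx))
        as.character(unlist(rec$differential_dx)) else NULL
    )
  }
  ids <- vapply(docs, function(d) d$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate document id(s): ", paste(unique(dup), collapse = ", "))
  new_corpus(docs, provenance = path)
}

new_document <- function(id, tokens, pos_tags = NULL, primary_dx = NULL,
                         differential_dx = NULL) {
  if (!is.null(pos_tags) && length(pos_tags) != length(tokens))
    stop("document '", id, "': pos_tags length differs from tokens")
  if (!is.null(primary_dx) && !is.null(differential_dx) &&
      primary_dx %in% differential_dx)
    stop("document '", id, "': differential_dx contains primary_dx")
  structure(list(id = id, tokens = tokens, pos_tags = pos_tags,
                 primary_dx = primary_dx, differential_dx = differential_dx),
            class = "ddx_document")
}

new_corpus <- function(documents, provenance = "") {
  structure(list(documents = documents, provenance = provenance),
            class = "ddx_corpus")
}

#' @export
print.ddx_corpus <- function(x, ...) {
  n <- length(x$documents)
  ntok <- sum(vapply(x$documents, function(d) length(d$tokens), integer(1)))
  ndx <- sum(vapply(x$documents, function(d) !is.null(d$primary_dx), logical(1)))
  cat("Corpus of", n, "documents,", ntok, "tokens;",
      ndx, "with a primary diagnosis\n")
  invisible(x)
}

#' @export
length.ddx_corpus <- function(x) length(x$documents)

#' Write a corpus as JSON Lines
#'
#' Inverse of [read_corpus()]: one record object per line, omitting absent
#' optional fields.
#'
#' @param corpus A `ddx_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "ddx_corpus"))
  lines <- vapply(corpus$documents, function(d) {
    rec <- list(id = jsonlite::unbox(d$id), tokens = d$tokens)
    if (!is.null(d$pos_tags)) rec$pos <- d$pos_tags
    if (!is.null(d$primary_dx)) rec$primary_dx <- jsonlite::unbox(d$primary_dx)
    if (!is.null(d$differential_dx)) rec$differential_dx <- d$differential_dx
    as.character(jsonlite::toJSON(rec))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Filter a document's tokens by part of speech and stopword list
#'
#' Clinical notes carry their condition content mostly in nouns, verbs and
#' adjectives; supplying those codes as `pos_whitelist` keeps only such
#' tokens. Token order is preserved and the operation is idempotent.
#'
#' @param doc A `ddx_document`.
#' @param pos_whitelist Character vector of POS codes to keep; empty means no
#'   POS filtering. Requires `doc$pos_tags` when non-empty.
#' @param stopwords Character vector of tokens to drop.
#' @return A filtered copy of `doc` (pos_tags subset in parallel).
#' @export
filter_tokens <- function(doc, pos_whitelist = character(), stopwords = character()) {
  stopifnot(inherits(doc, "ddx_document"))
  keep <- rep(TRUE, length(doc$tokens))
  if (length(pos_whitelist)) {
    if (is.null(doc$pos_tags))
      stop("document '", doc$id, "': POS whitelist given but no pos_tags present")
    keep <- doc$pos_tags %in% pos_whitelist
  }
  if (length(stopwords)) keep <- keep & !(doc$tokens %in% stopwords)
  doc$tokens <- doc$tokens[keep]
  if (!is.null(doc$pos_tags)) doc$pos_tags <- doc$pos_tags[keep]
  doc
}

#' Build a pruned vocabulary from a corpus
#'
#' Keeps tokens whose corpus frequency is at least `min_count`, dropping the
#' long tail of rare words that contribute little to topic estimation.
#' Ordering is deterministic: descending frequency, ties broken
#' lexicographically, so matrix columns are reproducible across runs.
#'
#' @param corpus A `ddx_corpus` with at least one document.
#' @param min_count Minimum corpus frequency for a token to be kept.
#' @return A `ddx_vocabulary`: list with `tokens` (ordered character vector),
#'   `index` (named integer vector mapping token to 1-based position) and
#'   `counts` (named integer vector, same order as `tokens`).
#' @export
build_vocabulary <- function(corpus, min_count = 2L) {
  stopifnot(inherits(corpus, "ddx_corpus"))
  if (!length(corpus$documents)) stop("cannot build a vocabulary from an empty corpus")
  min_count <- as.integer(min_count)
  stopifnot(min_count >= 1L)
  all_tokens <- unlist(lapply(corpus$documents, function(d) d$tokens),
                       use.names = FALSE)
  tab <- table(all_tokens)
  cnt <- as.integer(tab)
  tok <- names(tab)
  keep <- cnt >= min_count
  if (!any(keep)) stop("no token reaches min_count = ", min_count)
  tok <- tok[keep]; cnt <- cnt[keep]
  ord <- order(-cnt, tok, method = "radix")
  tok <- tok[ord]; cnt <- cnt[ord]
  idx <- seq_along(tok)
  names(idx) <- tok
  names(cnt) <- tok
  structure(list(tokens = tok, index = idx, counts = cnt),
            class = "ddx_vocabulary")
}

#' @export
print.ddx_vocabulary <- function(x, ...) {
  cat("Vocabulary of", length(x$tokens), "tokens; top:",
      paste(utils::head(x$tokens, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.ddx_vocabulary <- function(x) length(x$tokens)

#' Write / read a vocabulary as tab-separated text
#'
#' Two columns, token and count, in canonical order.
#' @param vocab A `ddx_vocabulary`.
#' @param path File path.
#' @return `path` invisibly, or the vocabulary for the reader.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "ddx_vocabulary"))
  writeLines(paste(vocab$tokens, vocab$counts, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tok <- vapply(parts, `[`, character(1), 1L)
  cnt <- as.integer(vapply(parts, `[`, character(1), 2L))
  idx <- seq_along(tok); names(idx) <- tok; names(cnt) <- tok
  structure(list(tokens = tok, index = idx, counts = cnt),
            class = "ddx_vocabulary")
}

# Map a token vector to 1-based vocabulary ids, dropping OOV with a warning.
tokens_to_ids <- function(tokens, vocab, warn = TRUE, context = "document") {
  ids <- unname(vocab$index[tokens])
  oov <- is.na(ids)
  if (any(oov) && warn)
    warning(sum(oov), " out-of-vocabulary token(s) skipped in ", context,
            call. = FALSE)
  ids[!oov]
}

#' Split a corpus into training and held-out parts
#'
#' Uniform random split by document, reproducible by seed.
#'
#' @param corpus A `ddx_corpus`.
#' @param test_fraction Fraction of documents held out (0 < f < 1).
#' @param seed Integer seed.
#' @return A list with `train` and `test` corpora.
#' @export
split_corpus <- function(corpus, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(corpus, "ddx_corpus"),
            test_fraction > 0, test_fraction < 1)
  n <- length(corpus$documents)
  set.seed(as.integer(seed))
  idx <- sort(sample.int(n, max(1L, round(test_fraction * n))))
  list(train = new_corpus(corpus$documents[-idx],
                          paste0(corpus$provenance, "[train]")),
       test = new_corpus(corpus$documents[idx],
                         paste0(corpus$provenance, "[test]")))
}
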