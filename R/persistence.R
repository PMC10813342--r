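#' Save a fitted topic model as a directory bundle
#'
#' Writes a JSON metadata file (K, alpha, beta, iterations, seed, vocabulary
#' checksum) plus the dense phi and theta matrices and the vocabulary as
#' plain text. The round trip through [load_topic_model()] is lossless to
#' full double precision (matrices are serialized with 17 significant
#' digits).
#'
#' @param model A `topic_model`.
#' @param dir Bundle directory (created if absent).
#' @export
save_topic_model <- function(model, dir) {
  stopifnot(inherits(model, "topic_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(K = model$K, alpha = model$alpha, beta = model$beta,
               iterations = model$iterations, seed = model$seed,
               n_docs = nrow(model$theta),
               vocab_checksum = vocab_checksum(model$vocabulary))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_matrix(model$phi, file.path(dir, "phi.tsv"))
  write_matrix(model$theta, file.path(dir, "theta.tsv"))
  write_vocabulary(model$vocabulary, file.path(dir, "vocabulary.tsv"))
  writeLines(model$doc_ids, file.path(dir, "doc_ids.txt"), useBytes = TRUE)
  invisible(dir)
}

#' @rdname save_topic_model
#' @export
load_topic_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  vocab <- read_vocabulary(file.path(dir, "vocabulary.tsv"))
  if (!identical(vocab_checksum(vocab), meta$vocab_checksum))
    stop("vocabulary checksum mismatch: bundle is corrupt or mixed")
  phi <- read_matrix(file.path(dir, "phi.tsv"))
  dimnames(phi) <- list(NULL, vocab$tokens)
  structure(list(K = as.integer(meta$K), phi = phi,
                 theta = read_matrix(file.path(dir, "theta.tsv")),
                 alpha = as.numeric(meta$alpha), beta = as.numeric(meta$beta),
                 iterations = as.integer(meta$iterations),
                 seed = as.integer(meta$seed), vocabulary = vocab,
                 doc_ids = readLines(file.path(dir, "doc_ids.txt"),
                                     encoding = "UTF-8", warn = FALSE)),
            class = "topic_model")
}

vocab_checksum <- function(vocab) {
  sprintf("%d-%d-%s", length(vocab$tokens), sum(vocab$counts),
          vocab$tokens[1])
}

write_matrix <- function(m, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d\t%d", nrow(m), ncol(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.17g", m[i, ]), collapse = "\t"), con)
  invisible(path)
}

read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dims <- as.integer(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  vals <- lapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))
  matrix(unlist(vals), nrow = dims[1], ncol = dims[2], byrow = TRUE)
}
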