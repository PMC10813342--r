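#' Group corpus records by primary diagnosis
#'
#' Concatenates the token lists of all records filed under the same primary
#' diagnosis into one large text per diagnosis — the raw material for the
#' per-diagnosis topic profiles.
#'
#' @param corpus A `ddx_corpus` in which every document carries `primary_dx`.
#' @return A named list: diagnosis label -> merged character vector of
#'   tokens, plus an `n_records` attribute (named integer vector).
#' @export
group_by_diagnosis <- function(corpus) {
  stopifnot(inherits(corpus, "ddx_corpus"))
  for (d in corpus$documents)
    if (is.null(d$primary_dx))
      stop("document '", d$id, "' has no primary_dx; cannot group")
  labels <- vapply(corpus$documents, function(d) d$primary_dx, character(1))
  groups <- split(corpus$documents, labels)
  merged <- lapply(groups, function(g)
    unlist(lapply(g, function(d) d$tokens), use.names = FALSE))
  attr(merged, "n_records") <- vapply(groups, length, integer(1))
  merged
}

#' Build the differential-diagnosis knowledge base
#'
#' For each diagnosis, the topic profile P(t|cd) is the normalized sum of
#' the word-topic posterior rows over every in-vocabulary token occurrence
#' in the diagnosis's merged text — the grouped-record generalization of
#' single-document fold-in inference.
#'
#' @param grouped Output of [group_by_diagnosis()] (or any named list of
#'   token vectors; an `n_records` attribute is honoured if present).
#' @param posterior A `word_topic_posterior`.
#' @param vocabulary The model's `ddx_vocabulary`.
#' @return A `diagnosis_kb`: list with `profiles` (named list of
#'   `label`, `probs`, `n_records`), `K`, and `model_checksum` binding the
#'   KB to the posterior that produced it.
#' @export
build_kb <- function(grouped, posterior, vocabulary) {
  stopifnot(inherits(posterior, "word_topic_posterior"),
            inherits(vocabulary, "ddx_vocabulary"))
  if (!length(grouped)) stop("no diagnosis groups")
  nrec <- attr(grouped, "n_records")
  profiles <- vector("list", length(grouped))
  names(profiles) <- names(grouped)
  for (lab in names(grouped)) {
    dist <- tryCatch(
      infer_doc_topics(posterior, grouped[[lab]], vocabulary, warn = FALSE,
                       id = paste0("diagnosis '", lab, "'")),
      error = function(e) stop("diagnosis '", lab, "': ", conditionMessage(e),
                               call. = FALSE))
    profiles[[lab]] <- list(label = lab, probs = dist$probs,
                            n_records = if (!is.null(nrec)) unname(nrec[lab]) else 1L)
  }
  structure(list(profiles = profiles, K = ncol(posterior),
                 model_checksum = posterior_checksum(posterior)),
            class = "diagnosis_kb")
}

# Cheap deterministic fingerprint binding a KB to its posterior matrix;
# weights vary over both dimensions so permuted or perturbed matrices differ.
posterior_checksum <- function(posterior) {
  m <- unclass(posterior)
  w <- outer(seq_len(nrow(m)), sqrt(seq_len(ncol(m))))
  sprintf("%dx%d-%.12e", nrow(m), ncol(m), sum(m * w))
}

#' @export
print.diagnosis_kb <- function(x, ...) {
  cat("Differential-diagnosis knowledge base:", length(x$profiles),
      "diagnoses over", x$K, "topics\n")
  nr <- vapply(x$profiles, function(p) p$n_records, numeric(1))
  cat("  records per diagnosis: min", min(nr), "median", stats::median(nr),
      "max", max(nr), "\n")
  invisible(x)
}

#' Save / load a knowledge base as JSON
#'
#' The JSON carries every profile's topic distribution and record count plus
#' the model checksum; `load_kb` can verify the checksum against a posterior.
#'
#' @param kb A `diagnosis_kb`.
#' @param path JSON file path.
#' @param posterior Optional `word_topic_posterior` to verify against.
#' @export
save_kb <- function(kb, path) {
  stopifnot(inherits(kb, "diagnosis_kb"))
  obj <- list(model_checksum = kb$model_checksum, K = kb$K,
              profiles = lapply(kb$profiles, function(p)
                list(probs = p$probs, n_records = p$n_records)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_kb
#' @export
load_kb <- function(path, posterior = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  profiles <- lapply(names(obj$profiles), function(lab)
    list(label = lab, probs = as.numeric(obj$profiles[[lab]]$probs),
         n_records = as.integer(obj$profiles[[lab]]$n_records)))
  names(profiles) <- names(obj$profiles)
  kb <- structure(list(profiles = profiles, K = as.integer(obj$K),
                       model_checksum = obj$model_checksum),
                  class = "diagnosis_kb")
  if (!is.null(posterior) &&
      !identical(posterior_checksum(posterior), kb$model_checksum))
    stop("knowledge base was built from a different model (checksum mismatch)")
  kb
}
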