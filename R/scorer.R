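#' Angle band of the diagnostic plane
#'
#' The angular region (in degrees, measured from the diagnosis axis) within
#' which a topic counts as evidence for a differential diagnosis. The
#' working default is 35-65 degrees; for rare-disease scenarios it can be
#' relaxed to 15-75 degrees. Band membership is strict: boundary angles fall
#' in the penalty branch.
#'
#' @param theta_lo,theta_hi Band edges in degrees, 0 <= lo < hi <= 90.
#' @return An `angle_band` object.
#' @export
angle_band <- function(theta_lo = 35, theta_hi = 65) {
  if (!(theta_lo >= 0 && theta_lo < theta_hi && theta_hi <= 90))
    stop("need 0 <= theta_lo < theta_hi <= 90")
  structure(list(theta_lo = theta_lo, theta_hi = theta_hi), class = "angle_band")
}

#' Place the topics of a record/diagnosis pair on the diagnostic plane
#'
#' Each topic t becomes a point with x = P(t|d_new) (the medical record) and
#' y = P(t|cd) (the candidate diagnosis), with polar descriptors
#' \deqn{distance_t = \sqrt{x^2 + y^2}, \qquad \theta_t = \arctan(x / y)}
#' (degrees, measured from the diagnosis axis). Conventions: y = 0, x > 0
#' gives 90 degrees; x = 0, y > 0 gives 0; the degenerate origin point is
#' emitted with distance 0 and 45 degrees so it contributes nothing.
#'
#' @param p_doc A `doc_topics` (or a bare probability vector) for the record.
#' @param profile A `DiagnosisProfile`-style list with `probs` (or a bare
#'   vector) for the candidate diagnosis.
#' @return A data.frame of class `topic_points` with columns topic, x, y,
#'   distance, theta_deg.
#' @export
topic_points <- function(p_doc, profile) {
  x <- if (inherits(p_doc, "doc_topics")) p_doc$probs else as.numeric(p_doc)
  y <- if (is.list(profile)) as.numeric(profile$probs) else as.numeric(profile)
  if (length(x) != length(y))
    stop("record and diagnosis distributions have different lengths (",
         length(x), " vs ", length(y), ")")
  theta <- ifelse(x == 0 & y == 0, 45, atan2(x, y) * 180 / pi)
  out <- data.frame(topic = seq_along(x), x = x, y = y,
                    distance = sqrt(x^2 + y^2), theta_deg = theta)
  class(out) <- c("topic_points", "data.frame")
  out
}

#' Bonus/penalty score of one topic point
#'
#' Inside the open band the topic is a bonus factor scaled by how close it
#' sits to the diagonal and how far from the origin:
#' `distance * sin(2 theta)`. Outside (including exactly on the band edges)
#' it is the penalty branch `-distance * cos(4 theta)`. The penalty form is
#' used verbatim; note it is positive for angles just outside the band,
#' where `cos(4 theta) < 0`, and discontinuous at the boundary.
#'
#' @param point One row of [topic_points()] (or any list with `distance`
#'   and `theta_deg`). Vectorized over rows of a `topic_points` frame.
#' @param band An [angle_band()].
#' @return Numeric score(s), each bounded by the point's distance in
#'   absolute value.
#' @export
topic_score <- function(point, band = angle_band()) {
  th <- point$theta_deg
  d <- point$distance
  rad <- th * pi / 180
  ifelse(th > band$theta_lo & th < band$theta_hi,
         d * sin(2 * rad),
         -d * cos(4 * rad))
}

#' Score one candidate differential diagnosis for a record
#'
#' Sums the per-topic bonus/penalty scores over all K topics; the per-topic
#' contributions are retained so the result can be displayed and audited on
#' the diagnostic plane.
#'
#' @inheritParams topic_points
#' @param band An [angle_band()].
#' @param label Candidate diagnosis label for the report.
#' @return A `ddx_score`: list with `label`, `total`, and `contributions`
#'   (the `topic_points` frame with a `score` column).
#' @export
ddx_score <- function(p_doc, profile, band = angle_band(),
                      label = if (is.list(profile)) profile$label else NA_character_) {
  pts <- topic_points(p_doc, profile)
  pts$score <- topic_score(pts, band)
  structure(list(label = label, total = sum(pts$score), contributions = pts),
            class = "ddx_score")
}

#' @export
print.ddx_score <- function(x, ...) {
  cat(sprintf("Differential score for %s: %.4f over %d topics\n",
              if (is.na(x$label)) "<candidate>" else x$label,
              x$total, nrow(x$contributions)))
  top <- x$contributions[order(-abs(x$contributions$score)), ][1:min(3, nrow(x$contributions)), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  t%-3d x=%.3f y=%.3f dist=%.3f theta=%.1f score=%+.4f\n",
                top$topic[i], top$x[i], top$y[i], top$distance[i],
                top$theta_deg[i], top$score[i]))
  invisible(x)
}

#' Rank candidate differential diagnoses for a record
#'
#' Scores every diagnosis in the knowledge base except the record's own
#' primary diagnosis and returns the top candidates by total score
#' (descending; ties break lexicographically by label).
#'
#' @param p_doc A `doc_topics` (or probability vector) for the record.
#' @param kb A `diagnosis_kb`.
#' @param primary_dx Label to exclude from the candidate set, or NULL.
#' @param top_n Number of candidates to return.
#' @param band An [angle_band()].
#' @return A data.frame (label, total) of class `ddx_ranking`, with the full
#'   `ddx_score` objects in attribute `scores`.
#' @export
rank_differentials <- function(p_doc, kb, primary_dx = NULL, top_n = 10L,
                               band = angle_band()) {
  stopifnot(inherits(kb, "diagnosis_kb"), top_n >= 1L)
  cand <- setdiff(names(kb$profiles), primary_dx)
  if (!length(cand)) stop("no candidate diagnosis left after excluding the primary")
  scores <- lapply(cand, function(lab)
    ddx_score(p_doc, kb$profiles[[lab]], band, label = lab))
  totals <- vapply(scores, function(s) s$total, numeric(1))
  o <- order(-totals, cand, method = "radix")
  keep <- o[seq_len(min(top_n, length(o)))]
  out <- data.frame(label = cand[keep], total = totals[keep],
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- scores[keep]
  class(out) <- c("ddx_ranking", "data.frame")
  out
}

#' Rank candidates by cosine similarity of topic distributions
#'
#' The comparison baseline: orders knowledge-base diagnoses by the cosine
#' between the record's topic distribution and each diagnosis profile,
#' instead of the bonus/penalty plane score.
#'
#' @inheritParams rank_differentials
#' @return A data.frame (label, total = cosine) of class `ddx_ranking`.
#' @export
rank_by_similarity <- function(p_doc, kb, primary_dx = NULL, top_n = 10L) {
  stopifnot(inherits(kb, "diagnosis_kb"), top_n >= 1L)
  x <- if (inherits(p_doc, "doc_topics")) p_doc$probs else as.numeric(p_doc)
  cand <- setdiff(names(kb$profiles), primary_dx)
  if (!length(cand)) stop("no candidate diagnosis left after excluding the primary")
  sims <- vapply(cand, function(lab) cosine_sim(x, kb$profiles[[lab]]$probs),
                 numeric(1))
  o <- order(-sims, cand, method = "radix")
  keep <- o[seq_len(min(top_n, length(o)))]
  out <- data.frame(label = cand[keep], total = unname(sims[keep]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ddx_ranking", "data.frame")
  out
}

#' Recall@N of recommended differentials against clinician labels
#'
#' For every test record: infer its topic distribution, rank the knowledge
#' base with the record's primary diagnosis excluded, and count each of the
#' clinician's differential diagnoses found in the top N as one hit. Recall
#' is total hits over total differentials across the corpus.
#'
#' @param test A `ddx_corpus` whose documents all carry `primary_dx` and a
#'   non-empty `differential_dx` list.
#' @param kb A `diagnosis_kb` covering every differential label.
#' @param posterior,vocabulary The model's posterior and vocabulary.
#' @param top_n Size of the recommendation list.
#' @param band An [angle_band()] (proposed ranker only).
#' @param ranker `"proposed"` (bonus/penalty score) or `"cosine"` baseline.
#' @return A `recall_report`: list with `top_n`, `hits`, `total`, `recall`,
#'   `ranker`, and `per_record` (data.frame id, n_differentials, hits).
#' @export
evaluate_recall <- function(test, kb, posterior, vocabulary, top_n = 5L,
                            band = angle_band(), ranker = c("proposed", "cosine")) {
  ranker <- match.arg(ranker)
  stopifnot(inherits(test, "ddx_corpus"), inherits(kb, "diagnosis_kb"))
  all_dx <- unique(unlist(lapply(test$documents, function(d) d$differential_dx)))
  missing <- setdiff(all_dx, names(kb$profiles))
  if (length(missing))
    stop("differential label(s) absent from the knowledge base: ",
         paste(missing, collapse = ", "))
  rows <- lapply(test$documents, function(d) {
    if (is.null(d$primary_dx) || is.null(d$differential_dx) ||
        !length(d$differential_dx))
      stop("test record '", d$id,
           "' needs a primary_dx and at least one differential_dx")
    pd <- infer_doc_topics(posterior, d$tokens, vocabulary, warn = FALSE,
                           id = paste0("document '", d$id, "'"))
    rk <- if (ranker == "proposed")
      rank_differentials(pd, kb, d$primary_dx, top_n, band)
    else rank_by_similarity(pd, kb, d$primary_dx, top_n)
    data.frame(id = d$id, n_differentials = length(d$differential_dx),
               hits = sum(d$differential_dx %in% rk$label),
               stringsAsFactors = FALSE)
  })
  per_record <- do.call(rbind, rows)
  hits <- sum(per_record$hits)
  total <- sum(per_record$n_differentials)
  structure(list(top_n = as.integer(top_n), hits = hits, total = total,
                 recall = hits / total, ranker = ranker,
                 per_record = per_record),
            class = "recall_report")
}

#' @export
print.recall_report <- function(x, ...) {
  cat(sprintf("Recall@%d (%s ranker): %d/%d = %.4f over %d records\n",
              x$top_n, x$ranker, x$hits, x$total, x$recall,
              nrow(x$per_record)))
  invisible(x)
}
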