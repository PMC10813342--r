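test_that("angle_band validates its range", {
  b <- angle_band(35, 65)
  expect_equal(c(b$theta_lo, b$theta_hi), c(35, 65))
  expect_error(angle_band(65, 35))
  expect_error(angle_band(-1, 50))
  expect_error(angle_band(10, 95))
})

test_that("topic_points computes distance and angle with axis conventions", {
  pts <- topic_points(c(0.3, 0.1, 0, 0), c(0.4, 0, 0.2, 0))
  # 3-4-5 triangle
  expect_equal(pts$distance[1], 0.5)
  expect_equal(round(pts$theta_deg[1], 4), 36.8699)
  # on the record axis (y = 0): 90 degrees
  expect_equal(pts$theta_deg[2], 90)
  # on the diagnosis axis (x = 0): 0 degrees
  expect_equal(pts$theta_deg[3], 0)
  # origin point: distance 0, display angle 45
  expect_equal(pts$distance[4], 0)
  expect_equal(pts$theta_deg[4], 45)
  # diagonal convention
  expect_equal(topic_points(0.1, 0.1)$theta_deg, 45)
  expect_error(topic_points(c(0.5, 0.5), c(1)), "length")
})

test_that("topic_score applies the bonus and penalty branches", {
  band <- angle_band(35, 65)
  p45 <- list(theta_deg = 45, distance = 0.5)
  expect_equal(topic_score(p45, band), 0.5, tolerance = 1e-12)   # sin 90 = 1
  p0 <- list(theta_deg = 0, distance = 0.3)
  expect_equal(topic_score(p0, band), -0.3, tolerance = 1e-12)   # -cos 0
  # worked point x = 0.7, y = 0.4
  pt <- topic_points(0.7, 0.4)
  expect_equal(round(pt$theta_deg, 4), 60.2551)
  expect_equal(round(pt$distance, 4), 0.8062)
  expect_equal(round(topic_score(pt, band), 4), 0.6946)
  # band membership is strict: the boundary takes the penalty branch
  edge <- list(theta_deg = 35, distance = 1)
  expect_equal(topic_score(edge, band), -cos(140 * pi / 180), tolerance = 1e-12)
  # origin contributes exactly zero
  expect_equal(topic_score(list(theta_deg = 45, distance = 0), band), 0)
})

test_that("ddx_score has the diagonal and axis closed forms", {
  band <- angle_band(35, 65)
  # identical distributions: every point on the diagonal, total = sqrt(2)
  for (s in 1:5) {
    set.seed(s)
    p <- ddxtopics:::rdirichlet_rows(1, rep(1, 6))[1, ]
    expect_equal(ddx_score(p, p, band)$total, sqrt(2), tolerance = 1e-9)
  }
  # fully disjoint: both points on axes, each scores -1
  expect_equal(ddx_score(c(1, 0), c(0, 1), band)$total, -2, tolerance = 1e-12)
  # worked example with one in-band and one out-of-band topic
  # exact contributions 0.6945966 and 0.1878297 (the in-band topic uses
  # sin 2theta = 2xy/d^2 = 0.56/0.65; the out-of-band one cos 4theta = -0.28)
  sc <- ddx_score(c(0.7, 0.3), c(0.4, 0.6), band)
  expect_equal(round(sc$total, 4), 0.8824)
  expect_equal(round(sc$contributions$score[1], 4), 0.6946)
  expect_equal(round(sc$contributions$score[2], 4), 0.1878)
  expect_equal(sc$total, sum(sc$contributions$score), tolerance = 1e-9)
})

test_that("per-topic scores are bounded by their distances", {
  band <- angle_band(35, 65)
  for (s in 1:10) {
    set.seed(s)
    x <- runif(8); y <- runif(8)
    pts <- topic_points(x, y)
    scores <- topic_score(pts, band)
    expect_true(all(abs(scores) <= pts$distance + 1e-12))
    expect_lte(abs(sum(scores)), sum(pts$distance) + 1e-12)
    expect_true(all(pts$distance <= sqrt(2) * pmax(x, y) + 1e-12))
  }
})

test_that("scores are scale-equivariant in the coordinates", {
  band <- angle_band(35, 65)
  set.seed(3)
  x <- runif(5); y <- runif(5)
  base <- ddx_score(x, y, band)$total
  for (c in c(0.1, 2, 7))
    expect_equal(ddx_score(c * x, c * y, band)$total, c * base,
                 tolerance = 1e-9)
})

test_that("a 45-degree-symmetric band makes the score swap-symmetric", {
  band <- angle_band(15, 75)
  set.seed(8)
  x <- runif(6); y <- runif(6)
  pts_xy <- topic_points(x, y)
  pts_yx <- topic_points(y, x)
  expect_equal(topic_score(pts_xy, band), topic_score(pts_yx, band),
               tolerance = 1e-12)
})

test_that("|score| grows with distance at fixed angle", {
  band <- angle_band(35, 65)
  for (th in c(10, 40, 50, 70, 88)) {
    d <- seq(0.1, 1, by = 0.1)
    s <- abs(topic_score(list(theta_deg = rep(th, 10), distance = d), band))
    expect_true(all(diff(s) > 0))
  }
})

toy_kb <- function(profiles) {
  profs <- lapply(names(profiles), function(lab)
    list(label = lab, probs = profiles[[lab]], n_records = 1L))
  names(profs) <- names(profiles)
  structure(list(profiles = profs, K = length(profiles[[1]]),
                 model_checksum = "toy"), class = "diagnosis_kb")
}

test_that("rank_differentials excludes the primary and breaks ties by label", {
  kb <- toy_kb(list(A = c(0.5, 0.5), B = c(0.5, 0.5), C = c(1, 0)))
  rk <- rank_differentials(c(0.5, 0.5), kb, primary_dx = "C", top_n = 5)
  expect_equal(nrow(rk), 2)
  expect_false("C" %in% rk$label)
  # A and B have identical profiles, hence equal totals: lexicographic order
  expect_equal(rk$label, c("A", "B"))
  expect_equal(rk$total[1], rk$total[2])
  expect_error(rank_differentials(c(1, 0), toy_kb(list(Z = c(1, 0))), "Z"),
               "candidate")
})

test_that("a topic-sharing differential outranks a disjoint distractor", {
  p_doc <- c(0.45, 0.45, 0.10, 0, 0, 0)
  kb <- toy_kb(list(
    shares2of3 = c(0.35, 0.35, 0, 0.30, 0, 0),
    disjoint = c(0, 0, 0, 0, 0.5, 0.5)))
  rk <- rank_differentials(p_doc, kb, top_n = 2)
  expect_equal(rk$label[1], "shares2of3")
  expect_gt(rk$total[1], rk$total[2])
})

test_that("rank_by_similarity orders by cosine against an explicit oracle", {
  kb <- toy_kb(list(same = c(0.6, 0.4, 0), mid = c(0.2, 0.5, 0.3),
                    orth = c(0, 0, 1)))
  p <- c(0.6, 0.4, 0)
  rk <- rank_by_similarity(p, kb, top_n = 3)
  oracle <- sort(vapply(kb$profiles, function(pr) cosv(p, pr$probs), numeric(1)),
                 decreasing = TRUE)
  expect_equal(rk$label, names(oracle))
  expect_equal(rk$total, unname(oracle), tolerance = 1e-12)
  expect_equal(rk$label[1], "same")
  expect_equal(rk$total[1], 1, tolerance = 1e-12)
  expect_equal(rk$label[3], "orth")
})

test_that("evaluate_recall counts hits over clinician differentials", {
  m <- worked_model()
  post <- word_topic_posterior(m)
  # candidate profiles engineered so the record (tokens w1,w1 -> mostly topic 1)
  # scores topic-1-heavy candidates above topic-2-heavy ones
  kb <- toy_kb(list(A = c(0.93, 0.07), B = c(0.07, 0.93), C = c(0.90, 0.10),
                    P = c(0.5, 0.5)))
  test <- make_corpus(
    make_doc("r1", c("w1", "w1"), primary = "P", diff = c("A", "B")),
    make_doc("r2", c("w1", "w2"), primary = "P", diff = "C"))
  # top-1 lists: r1 -> its best candidate only; B (topic-2-heavy) missed
  rep1 <- evaluate_recall(test, kb, post, m$vocabulary, top_n = 1)
  expect_equal(rep1$total, 3)
  expect_true(rep1$hits < rep1$total)
  # exhaustive list: everything hit
  rep_all <- evaluate_recall(test, kb, post, m$vocabulary, top_n = 3)
  expect_equal(rep_all$recall, 1)
  # recall monotone in top_n
  rep2 <- evaluate_recall(test, kb, post, m$vocabulary, top_n = 2)
  expect_gte(rep_all$recall, rep2$recall)
  expect_gte(rep2$recall, rep1$recall)
  # arithmetic contract: hits/total
  expect_equal(rep2$recall, rep2$hits / rep2$total)
  # missing KB label is a validation error listing it
  bad <- make_corpus(make_doc("r", "w1", primary = "P", diff = "nowhere"))
  expect_error(evaluate_recall(bad, kb, post, m$vocabulary, 1), "nowhere")
  # cosine ranker runs the same protocol
  repc <- evaluate_recall(test, kb, post, m$vocabulary, top_n = 3,
                          ranker = "cosine")
  expect_equal(repc$recall, 1)
})
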