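#' Plot the diagnostic Cartesian plane
#'
#' Renders the topics of a record/diagnosis pair as points on the plane
#' whose x axis is the medical record's topic weight and whose y axis is
#' the candidate diagnosis's. The bonus band is shaded as origin-anchored
#' wedges between the two band angles (measured from the diagnosis axis),
#' with the diagonal drawn through it; topics near the diagonal and far
#' from the origin argue for the differential. Optionally annotates the
#' strongest points with their top topic words.
#'
#' @param points A `topic_points` data.frame (see [topic_points()]).
#' @param band An [angle_band()].
#' @param model Optional `topic_model` supplying topic words for labels.
#' @param top_labels Number of highest-distance points to annotate with
#'   their top-3 topic words (0 = none; requires `model`).
#' @param output_path Optional PNG (or SVG, by extension) path; when NULL,
#'   draws on the current device.
#' @param main Plot title.
#' @return `output_path` (or NULL), invisibly.
#' @export
plot_plane <- function(points, band = angle_band(), model = NULL,
                       top_labels = 0L, output_path = NULL,
                       main = "Differential-diagnosis plane") {
  stopifnot(inherits(points, "topic_points"))
  if (top_labels > nrow(points))
    stop("top_labels exceeds the number of points")
  if (top_labels > 0 && is.null(model))
    stop("topic-word annotations need the fitted model")
  if (!is.null(output_path)) {
    ext <- tolower(tools::file_ext(output_path))
    if (ext == "svg") grDevices::svg(output_path, width = 6, height = 6)
    else grDevices::png(output_path, width = 720, height = 720, res = 110)
    on.exit(grDevices::dev.off())
  }
  lim <- max(points$x, points$y, 1e-3) * 1.12
  graphics::plot(NA, xlim = c(0, lim), ylim = c(0, lim), asp = 1,
                 xlab = "P(t | medical record)", ylab = "P(t | diagnosis)",
                 main = main)
  # bonus wedge between the band angles, anchored at the origin
  r <- lim * 2
  a_lo <- band$theta_lo * pi / 180; a_hi <- band$theta_hi * pi / 180
  ang <- seq(a_lo, a_hi, length.out = 60)
  # theta is measured from the y (diagnosis) axis: x = r sin, y = r cos
  graphics::polygon(c(0, r * sin(ang), 0), c(0, r * cos(ang), 0),
                    col = grDevices::adjustcolor("lightblue", 0.45),
                    border = NA)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  in_band <- points$theta_deg > band$theta_lo & points$theta_deg < band$theta_hi
  graphics::points(points$x, points$y, pch = 19,
                   col = ifelse(in_band, "darkorange", "steelblue4"))
  if (top_labels > 0) {
    tw <- top_words(model, 3L)
    o <- order(points$distance, decreasing = TRUE)[seq_len(top_labels)]
    graphics::text(points$x[o], points$y[o],
                   labels = vapply(points$topic[o], function(t)
                     paste(tw[[t]], collapse = "/"), character(1)),
                   pos = 3, cex = 0.7)
  }
  invisible(output_path)
}
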