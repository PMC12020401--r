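# Figure generation: manifold arrows, regional boxplots, displacement
# heatmaps. Every figure is regenerable from the exported CSV/JSON alone.

#' @importFrom ggplot2 ggplot aes geom_path geom_point geom_segment arrow
#'   unit labs theme_minimal geom_boxplot scale_fill_viridis_c coord_equal
NULL

## Points of the 1-SD (or `level`-SD) ellipse of a 2D Gaussian.
.ellipse_path <- function(mean2, cov2, level = 2, n = 100) {
  th <- seq(0, 2 * pi, length.out = n)
  circ <- cbind(cos(th), sin(th))
  pts <- circ %*% chol(cov2 * level^2)
  data.frame(x = pts[, 1] + mean2[1], y = pts[, 2] + mean2[2])
}

#' Manifold plot: class contours plus one pre-to-post arrow per patient
#'
#' The tail of each arrow is the patient's preoperative 2D latent
#' projection, the head the postoperative one; color encodes the
#' procedure. A patient with pre = post is drawn as a point, not an arrow.
#'
#' @param projection a fitted `manifold_projection`.
#' @param arrows data.frame with columns patient_id, procedure, pre_x,
#'   pre_y, post_x, post_y (may be empty / NULL for contours only).
#' @param level contour radius in within-class SD units (default 2).
#' @return a ggplot object.
#' @export
plot_manifold <- function(projection, arrows = NULL, level = 2) {
  cont <- do.call(rbind, lapply(projection$classes, function(cl) {
    e <- .ellipse_path(projection$class_means_2d[[cl]],
                       projection$class_cov_2d[[cl]], level)
    e$class <- cl
    e
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = cont,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$class,
                                    linetype = .data$class)) +
    ggplot2::labs(x = "LD1", y = "LD2", linetype = "class",
                  color = "procedure") +
    ggplot2::theme_minimal()
  if (!is.null(arrows) && nrow(arrows)) {
    still <- arrows[arrows$pre_x == arrows$post_x &
                    arrows$pre_y == arrows$post_y, ]
    mov <- arrows[!(arrows$pre_x == arrows$post_x &
                    arrows$pre_y == arrows$post_y), ]
    if (nrow(mov))
      p <- p + ggplot2::geom_segment(
        data = mov,
        ggplot2::aes(x = .data$pre_x, y = .data$pre_y,
                     xend = .data$post_x, yend = .data$post_y,
                     color = .data$procedure),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")))
    if (nrow(still))
      p <- p + ggplot2::geom_point(
        data = still,
        ggplot2::aes(x = .data$pre_x, y = .data$pre_y,
                     color = .data$procedure), shape = 4)
  }
  p
}

#' Regional outcome boxplots by procedure
#'
#' Boxes are drawn from the precomputed cohort summary (median, quartiles,
#' extremes), grouped by region then procedure, with n annotated.
#'
#' @param summary a [cohort_summary()] table.
#' @return a ggplot object.
#' @export
plot_regional_boxplots <- function(summary) {
  if (!nrow(summary)) .stopf("empty summary table")
  summary <- summary[order(summary$region, summary$procedure), ]
  summary$region_f <- factor(summary$region, sort(unique(summary$region)))
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$region_f, fill = .data$procedure,
                               ymin = .data$min, lower = .data$q1,
                               middle = .data$median, upper = .data$q3,
                               ymax = .data$max)) +
    ggplot2::geom_boxplot(stat = "identity",
                          position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::geom_text(ggplot2::aes(y = .data$max, label = .data$n),
                       position = ggplot2::position_dodge2(width = 0.9),
                       vjust = -0.4, size = 2.5) +
    ggplot2::labs(x = "anatomic region", y = expression(m[r]),
                  fill = "procedure") +
    ggplot2::theme_minimal()
}

#' Per-vertex displacement heatmap
#'
#' The color field is the per-vertex displacement clipped at
#' `saturation_mm` (movements greater than the saturation all map to the
#' top color, 10 mm by default); the raw values are retained in the
#' returned object.
#'
#' @param pre,post `corresponded_mesh` objects on the same template.
#' @param saturation_mm color saturation (default 10).
#' @return list with `raw` and `clipped` per-vertex fields (mm) and
#'   `figure`, a front-view ggplot rendering.
#' @export
heatmap_displacement <- function(pre, post, saturation_mm = 10) {
  raw <- vertex_displacements(pre, post)
  clipped <- pmin(raw, saturation_mm)
  df <- data.frame(x = post$vertices[, 1], z = post$vertices[, 3],
                   y = post$vertices[, 2], d = clipped)
  df <- df[order(df$y), ]   # painter's order: front-facing vertices on top
  fig <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                          color = .data$d)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_color_viridis_c(limits = c(0, saturation_mm),
                                   name = "displacement (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)") +
    ggplot2::theme_minimal()
  list(raw = raw, clipped = clipped, saturation_mm = saturation_mm,
       figure = fig)
}

#' @importFrom rlang .data
NULL
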