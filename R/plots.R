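# Published color code for the four anatomical directions:
# orange = dorsal, dark green = ventral, blue = posterior, purple = anterior
SECTOR_COLORS <- c(posterior = "#1f77b4", dorsal = "#ff7f0e",
                   anterior = "#9467bd", ventral = "#006400")

# degree bin (0..359) of a bearing in radians; the epsilon keeps bearings
# that are whole degrees up to rounding in their intended bin
degree_bin <- function(alpha) {
  floor((alpha * 180 / pi) %% 360 + 1e-7) %% 360
}

#' Per-degree sector counts for the oriented circular histogram
#'
#' The OCH sidecar table: every 0.5 um segment point contributes one dot
#' in its unit-degree bin, coloured by its sector. The sidecar makes the
#' figure testable without pixel comparison; its counts always sum to the
#' cloud size (minus soma-coincident skips).
#'
#' @param assignment A `sector_assignment`.
#' @return Data frame with columns `degree` (0-359), `sector`, `count`.
#' @export
och_sidecar <- function(assignment) {
  ok <- !is.na(assignment$angles)
  df <- data.frame(degree = degree_bin(assignment$angles[ok]),
                   sector = as.character(assignment$labels[ok]),
                   stringsAsFactors = FALSE)
  out <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          df[, c("degree", "sector")], sum)
  out[order(out$degree, out$sector), , drop = FALSE]
}

#' Per-ring, per-degree sector counts for the expansion histogram
#'
#' The ECH sidecar: each point falls in concentric 25 um distance rings
#' (half-open, ring `k` covers `[25k, 25(k+1))` micrometres from the
#' soma), binned at unit degrees and coloured by sector.
#'
#' @param cloud A `segment_cloud` (provides `dist`).
#' @param assignment The matching `sector_assignment`.
#' @param ring_width Ring width in micrometres (default 25).
#' @return Data frame with columns `ring` (0-based), `degree`, `sector`,
#'   `count`.
#' @export
ech_sidecar <- function(cloud, assignment, ring_width = 25) {
  stopifnot(ring_width > 0)
  ok <- !is.na(assignment$angles)
  df <- data.frame(ring = as.integer(floor(cloud$dist[ok] / ring_width)),
                   degree = degree_bin(assignment$angles[ok]),
                   sector = as.character(assignment$labels[ok]),
                   stringsAsFactors = FALSE)
  out <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          df[, c("ring", "degree", "sector")], sum)
  out[order(out$ring, out$degree, out$sector), , drop = FALSE]
}

# shared polar scaffold
och_theme <- function() {
  ggplot2::theme_minimal() +
    ggplot2::theme(axis.title = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' Render the oriented circular histogram (OCH) of one neuron
#'
#' Dot stacks at each of the 360 unit-degree bins (one dot per 0.5 um
#' segment), coloured by anatomical sector; a red arrow for the Fisher
#' median direction and a blue arrow for the mean direction; a light
#' green interquartile arc with quartile dots; and the neuron's DLRM
#' result as shaded sector wedges whose darkness encodes how many
#' thresholds the sector's ratio passes (1.1 < 1.2 < 1.3).
#'
#' A sidecar CSV of per-degree counts per sector is always written next
#' to the image (same path + `.csv`), so the figure's content is testable
#' without pixel comparison.
#'
#' @param cloud A `segment_cloud`.
#' @param partition The neuron's `sector_partition`.
#' @param ratios The neuron's `orientation_ratios`.
#' @param summary A `circular_summary` of the point bearings (computed if
#'   `NULL`).
#' @param out Image path (`.png`, `.svg` or `.pdf`); `NULL` to skip
#'   writing and just return the plot and sidecar.
#' @param thresholds Shading thresholds, weakest first.
#' @param dot_radius Radial increment per stacked dot (dots per unit of
#'   plot radius is its inverse); cosmetic.
#' @return Invisibly, a list with `plot` (ggplot object) and `sidecar`
#'   (data frame).
#' @export
render_och <- function(cloud, partition, ratios, summary = NULL, out = NULL,
                       thresholds = c(1.1, 1.2, 1.3), dot_radius = 1) {
  if (nrow(cloud) == 0) stop("empty segment cloud")
  assignment <- assign_sectors(cloud, partition)
  if (is.null(summary))
    summary <- circular_summary(assignment$angles[!is.na(assignment$angles)])
  side <- och_sidecar(assignment)

  # stacked dots: one point per segment, radius = position in its bin
  ok <- !is.na(assignment$angles)
  deg <- degree_bin(assignment$angles[ok])
  ordd <- order(deg)
  stack <- sequence(rle(deg[ordd])$lengths)
  dots <- data.frame(degree = deg[ordd],
                     r = stack * dot_radius,
                     sector = as.character(assignment$labels[ok])[ordd])
  rmax <- max(dots$r) * 1.15

  # wedge shading: darkness = number of thresholds passed by the ratio
  thresholds <- sort(thresholds)
  s <- partition$sectors
  shade <- data.frame(direction = s$direction,
                      lo = s$lo * 180 / pi,
                      hi = s$hi * 180 / pi,
                      level = vapply(s$direction, function(d) {
                        sum(ratios$ratio[ratios$direction == d] > thresholds)
                      }, numeric(1)))
  shade <- shade[ratios$ratio[match(shade$direction, ratios$direction)] > 1, ,
                 drop = FALSE]

  arrows <- data.frame(kind = c("median", "mean"),
                       angle = c(summary$median, summary$mean_direction),
                       col = c("red", "blue"))
  arrows <- arrows[!is.na(arrows$angle), , drop = FALSE]
  arrows$degree <- (arrows$angle * 180 / pi) %% 360

  iqr <- NULL
  if (!is.na(summary$q25)) {
    d25 <- (summary$q25 * 180 / pi) %% 360
    span <- ((summary$q75 - summary$q25) * 180 / pi) %% 360
    iqr <- data.frame(deg = seq(d25, d25 + span, length.out = 60) %% 360)
  }

  p <- ggplot2::ggplot()
  if (nrow(shade)) {
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = lo, xmax = hi, ymin = 0, ymax = rmax,
                   fill = direction, alpha = level))
  }
  p <- p +
    ggplot2::geom_point(data = dots,
                        ggplot2::aes(x = degree, y = r, colour = sector),
                        size = 0.6) +
    ggplot2::scale_colour_manual(values = SECTOR_COLORS, drop = FALSE) +
    ggplot2::scale_fill_manual(values = SECTOR_COLORS, guide = "none") +
    ggplot2::scale_alpha_continuous(range = c(0.08, 0.45), limits = c(0, 3),
                                    guide = "none") +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270),
                                labels = c("P", "D", "A", "V"),
                                oob = scales_oob_keep) +
    ggplot2::geom_segment(data = arrows,
                          ggplot2::aes(x = degree, xend = degree,
                                       y = 0, yend = 0.8 * rmax),
                          colour = arrows$col,
                          arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm")),
                          linewidth = 0.8)
  if (!is.null(iqr)) {
    p <- p + ggplot2::geom_path(
      data = data.frame(deg = iqr$deg, r = 0.9 * rmax),
      ggplot2::aes(x = deg, y = r),
      colour = "lightgreen", linewidth = 2) +
      ggplot2::geom_point(
        data = data.frame(deg = c(iqr$deg[1], iqr$deg[nrow(iqr)]),
                          r = 0.9 * rmax),
        ggplot2::aes(x = deg, y = r), colour = "lightgreen", size = 3)
  }
  p <- p + ggplot2::coord_polar(start = -pi / 2, direction = -1) + och_theme()

  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 6, height = 6, dpi = 150)
    utils::write.csv(side, paste0(out, ".csv"), row.names = FALSE)
  }
  invisible(list(plot = p, sidecar = side))
}

# keep out-of-bounds x (wedges may touch 360 exactly)
scales_oob_keep <- function(x, ...) x

#' Render the expansion circular histogram (ECH) of one neuron
#'
#' Concentric rings of dot stacks: ring `k` holds the segment points
#' lying `[25k, 25(k+1))` micrometres from the soma (planar distance by
#' default; pass a cloud resampled with the 3-D option for the
#' alternative), each point drawn at its unit-degree bearing with the
#' sector colour code. The median arrow, mean arrow and IQR arc are drawn
#' from the first ring's points only.
#'
#' A sidecar CSV (`ring`, `degree`, `sector`, `count`) is always written
#' next to the image.
#'
#' @param cloud A `segment_cloud`.
#' @param partition The neuron's `sector_partition`.
#' @param out Image path or `NULL`.
#' @param ring_width Ring width, micrometres (default 25).
#' @return Invisibly, a list with `plot` and `sidecar`.
#' @export
render_ech <- function(cloud, partition, out = NULL, ring_width = 25) {
  if (nrow(cloud) == 0) stop("empty segment cloud")
  assignment <- assign_sectors(cloud, partition)
  side <- ech_sidecar(cloud, assignment, ring_width)

  ok <- !is.na(assignment$angles)
  ring <- floor(cloud$dist[ok] / ring_width)
  deg <- degree_bin(assignment$angles[ok])
  ordd <- order(ring, deg)
  key <- paste(ring[ordd], deg[ordd])
  stack <- sequence(rle(key)$lengths)
  dots <- data.frame(degree = deg[ordd],
                     r = ring[ordd] + 0.15 + 0.08 * (stack - 1),
                     sector = as.character(assignment$labels[ok])[ordd])

  first <- assignment$angles[ok][ring == 0]
  ann <- NULL
  if (length(first)) ann <- circular_summary(first)
  rmax <- max(dots$r) + 0.5

  p <- ggplot2::ggplot(dots, ggplot2::aes(x = degree, y = r, colour = sector)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = SECTOR_COLORS, drop = FALSE) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = c(0, 90, 180, 270),
                                labels = c("P", "D", "A", "V")) +
    ggplot2::scale_y_continuous(breaks = seq(0, ceiling(rmax)),
                                labels = function(b) b * ring_width)
  if (!is.null(ann)) {
    arrows <- data.frame(kind = c("median", "mean"),
                         angle = c(ann$median, ann$mean_direction),
                         col = c("red", "blue"))
    arrows <- arrows[!is.na(arrows$angle), , drop = FALSE]
    arrows$degree <- (arrows$angle * 180 / pi) %% 360
    p <- p + ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = degree, xend = degree, y = 0, yend = 0.9),
      colour = arrows$col, inherit.aes = FALSE,
      arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm")),
      linewidth = 0.8)
    if (!is.na(ann$q25)) {
      d25 <- (ann$q25 * 180 / pi) %% 360
      span <- ((ann$q75 - ann$q25) * 180 / pi) %% 360
      arc <- data.frame(deg = seq(d25, d25 + span, length.out = 60) %% 360,
                        r = 0.95)
      p <- p + ggplot2::geom_path(data = arc,
                                  ggplot2::aes(x = deg, y = r),
                                  colour = "lightgreen", inherit.aes = FALSE,
                                  linewidth = 2)
    }
  }
  p <- p + ggplot2::coord_polar(start = -pi / 2, direction = -1) + och_theme()

  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = 6, height = 6, dpi = 150)
    utils::write.csv(side, paste0(out, ".csv"), row.names = FALSE)
  }
  invisible(list(plot = p, sidecar = side))
}

#' Map overview plot
#'
#' Somata, reference points, the section contour, and each neuron's
#' called direction (Fisher median) as an arrow — a quick per-section
#' sanity view of the group analysis.
#'
#' @param map A `map_document`.
#' @param call_angles Optional named numeric vector of map-frame arrow
#'   angles (radians, atan2 convention) keyed by neuron id — e.g. each
#'   neuron's Fisher median rotated back into the map frame.
#' @param out Image path or `NULL`.
#' @param arrow_len Arrow length, micrometres.
#' @return Invisibly, the ggplot object.
#' @export
render_map_overview <- function(map, call_angles = NULL, out = NULL,
                                arrow_len = 100) {
  rp <- do.call(rbind, map$reference_points)
  rp_df <- data.frame(x = rp[, 1], y = rp[, 2],
                      direction = rownames(rp))
  somata <- do.call(rbind, lapply(map$neurons, function(nr) {
    data.frame(id = nr$id, x = nr$soma[1], y = nr$soma[2])
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = rp_df,
                        ggplot2::aes(x = x, y = y, colour = direction),
                        size = 3, shape = 17) +
    ggplot2::scale_colour_manual(values = SECTOR_COLORS) +
    ggplot2::geom_point(data = somata, ggplot2::aes(x = x, y = y),
                        colour = "red", size = 2) +
    ggplot2::geom_text(data = somata,
                       ggplot2::aes(x = x, y = y, label = id),
                       vjust = -1, size = 3) +
    ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::ggtitle(paste("Map", map$map_id))
  if (!is.null(map$contour)) {
    cont <- rbind(map$contour, map$contour[1, ])
    p <- p + ggplot2::geom_path(
      data = data.frame(x = cont[, 1], y = cont[, 2]),
      ggplot2::aes(x = x, y = y), colour = "grey50")
  }
  if (!is.null(call_angles)) {
    arr <- do.call(rbind, lapply(names(call_angles), function(id) {
      soma <- somata[somata$id == id, ]
      ang <- call_angles[[id]]
      data.frame(x = soma$x, y = soma$y,
                 xend = soma$x + arrow_len * cos(ang),
                 yend = soma$y + arrow_len * sin(ang))
    }))
    if (!is.null(arr) && nrow(arr)) {
      p <- p + ggplot2::geom_segment(
        data = arr, ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
        colour = "red", arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")))
    }
  }
  if (!is.null(out)) ggplot2::ggsave(out, p, width = 7, height = 7, dpi = 150)
  invisible(p)
}
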