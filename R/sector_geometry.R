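DIRECTIONS <- c("posterior", "dorsal", "anterior", "ventral")
DIR_ABBREV <- c(posterior = "P", dorsal = "D", anterior = "A", ventral = "V")

#' Signed angle between two planar vectors
#'
#' The counterclockwise angle from `a` to `v`, via the two-argument
#' arctangent of the cross product \eqn{a_x v_y - a_y v_x} and the dot
#' product \eqn{a_x v_x + a_y v_y}. Result in \eqn{(-\pi, \pi]}.
#'
#' @param a Length-2 reference vector (nonzero).
#' @param v A length-2 vector or n-by-2 matrix of vectors (nonzero rows).
#' @return Signed angle(s) in radians.
#' @export
signed_angle <- function(a, v) {
  if (length(a) != 2 || all(a == 0)) stop("'a' must be a nonzero 2-D vector")
  v <- if (is.matrix(v)) v else matrix(v, ncol = 2)
  if (any(rowSums(v^2) == 0)) stop("'v' contains a zero vector")
  ang <- atan2(a[1] * v[, 2] - a[2] * v[, 1],
               a[1] * v[, 1] + a[2] * v[, 2])
  # atan2 returns [-pi, pi]; fold -pi onto +pi for the (-pi, pi] contract
  ang[ang == -pi] <- pi
  if (nrow(v) == 1) ang <- ang[1]
  ang
}

#' Build a neuron's four-sector anatomical partition
#'
#' Connects the soma to the four reference points of its map, giving four
#' direction rays at angles \eqn{\varphi_j} measured counterclockwise from
#' the posterior ray (\eqn{\varphi_{posterior} = 0}). The circle is then
#' divided into four half-open sector arcs, one per anatomical direction,
#' and each sector's arc fraction \eqn{PS_j} (its share of the full
#' circumference) is recorded.
#'
#' Two boundary constructions are available. The default, `"bisector"`,
#' places sector boundaries at the angular midpoints between circularly
#' adjacent rays, so each direction's sector is the arc closest to its own
#' ray and always contains it. The `"rays"` alternative uses the direction
#' rays themselves as boundaries, labelling the arc from ray `j`
#' counterclockwise to the next ray as sector `j`; it is provided for
#' sensitivity analysis. In both modes arcs are half-open: a boundary
#' angle belongs to the sector on its counterclockwise side.
#'
#' @param soma Length-2 soma centre, map coordinates (micrometres).
#' @param reference_points Named list/vector of the four reference points
#'   (`posterior`, `anterior`, `dorsal`, `ventral`), each length-2, or a
#'   `map_document`.
#' @param boundary_mode `"bisector"` (default) or `"rays"`.
#' @return An object of class `sector_partition`: list with `soma`,
#'   `ray_angles` (named, radians in `[0, 2*pi)`, posterior = 0),
#'   `sectors` (data frame: `direction`, `lo`, `hi` half-open arc in
#'   cyclic coordinates, `ps` arc fraction), `posterior_axis` (the
#'   reference vector `p_posterior - soma`), and `boundary_mode`.
#' @export
build_partition <- function(soma, reference_points,
                            boundary_mode = c("bisector", "rays")) {
  boundary_mode <- match.arg(boundary_mode)
  if (inherits(reference_points, "map_document"))
    reference_points <- reference_points$reference_points
  rp <- lapply(reference_points[DIRECTIONS], as.numeric)
  a <- rp$posterior - soma
  rays <- vapply(DIRECTIONS, function(j) {
    l <- rp[[j]] - soma
    if (all(abs(l) < 1e-12))
      stop("geometry error: soma coincides with the ", j, " reference point")
    signed_angle(a, l) %% (2 * pi)
  }, numeric(1))
  if (any(duplicated(round(rays, 12))))
    stop("geometry error: two reference rays are collinear from this soma")

  ord <- order(rays)                       # counterclockwise ray order
  sorted <- rays[ord]
  k <- length(sorted)
  nxt <- c(sorted[-1], sorted[1] + 2 * pi)
  if (boundary_mode == "bisector") {
    mids <- (sorted + nxt) / 2             # boundary after each ray, CCW
    lo <- c(mids[k] - 2 * pi, mids[-k])    # boundary before each ray
    hi <- mids
  } else {
    lo <- sorted
    hi <- nxt
  }
  sectors <- data.frame(direction = names(sorted),
                        lo = lo %% (2 * pi),
                        hi_width = hi - lo,
                        stringsAsFactors = FALSE)
  sectors$ps <- sectors$hi_width / (2 * pi)
  sectors$hi <- (sectors$lo + sectors$hi_width) # may exceed 2*pi (cyclic)
  sectors <- sectors[match(DIRECTIONS, sectors$direction),
                     c("direction", "lo", "hi", "ps")]
  rownames(sectors) <- NULL
  stopifnot(abs(sum(sectors$ps) - 1) < 1e-9)
  structure(list(soma = as.numeric(soma), ray_angles = rays,
                 sectors = sectors, posterior_axis = a,
                 boundary_mode = boundary_mode),
            class = "sector_partition")
}

#' @export
print.sector_partition <- function(x, ...) {
  cat(sprintf("Sector partition (%s boundaries), soma at (%.1f, %.1f)\n",
              x$boundary_mode, x$soma[1], x$soma[2]))
  with(x$sectors, for (i in seq_along(direction)) {
    cat(sprintf("  %-9s ray %7.2f deg  PS = %.3f\n", direction[i],
                x$ray_angles[direction[i]] * 180 / pi, ps[i]))
  })
  invisible(x)
}

#' Arc fractions of a partition
#'
#' @param partition A `sector_partition`.
#' @return Named numeric vector of the four `PS` arc fractions, in
#'   posterior/dorsal/anterior/ventral order.
#' @export
sector_fractions <- function(partition) {
  stats::setNames(partition$sectors$ps, partition$sectors$direction)
}

#' Angle of points about the soma, relative to the posterior ray
#'
#' The bearing \eqn{\alpha} of each sample point as seen from the soma,
#' measured counterclockwise from the soma-to-posterior-reference ray.
#'
#' @param points An n-by-2 matrix/data frame of map-plane points, or a
#'   `segment_cloud`.
#' @param partition A `sector_partition`.
#' @return Numeric vector of angles in \eqn{(-\pi, \pi]}; `NA` for points
#'   coincident with the soma.
#' @export
point_angles <- function(points, partition) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  v <- sweep(pts, 2, partition$soma)
  zero <- rowSums(v^2) == 0
  ang <- rep(NA_real_, nrow(v))
  if (any(!zero)) ang[!zero] <- signed_angle(partition$posterior_axis,
                                             v[!zero, , drop = FALSE])
  ang
}

#' Assign sample points to anatomical sectors
#'
#' Labels each sample point with the direction whose sector arc contains
#' its bearing. Arcs are half-open (`[lo, hi)` counterclockwise), so a
#' point exactly on a boundary belongs to the sector on the boundary's
#' counterclockwise side; the assignment is deterministic. Points
#' coincident with the soma cannot be given a bearing and are skipped
#' with a warning.
#'
#' @param cloud A `segment_cloud` or any data frame with `x`, `y`.
#' @param partition A `sector_partition`.
#' @return An object of class `sector_assignment`: list with `labels`
#'   (factor over the four directions, `NA` for skipped points), `angles`
#'   (bearings, radians), `counts` (named counts per direction) and
#'   `n_skipped`.
#' @export
assign_sectors <- function(cloud, partition) {
  ang <- point_angles(cloud, partition)
  n_skip <- sum(is.na(ang))
  if (n_skip > 0)
    warning(n_skip, " sample point(s) coincident with the soma were skipped")
  labels <- sector_of_angle(ang, partition)
  counts <- table(factor(labels, levels = DIRECTIONS))
  structure(list(labels = factor(labels, levels = DIRECTIONS),
                 angles = ang,
                 counts = stats::setNames(as.integer(counts), DIRECTIONS),
                 n_skipped = n_skip),
            class = "sector_assignment")
}

#' Sector containing each bearing
#'
#' @param alpha Numeric vector of bearings, radians (any range), `NA`
#'   passed through.
#' @param partition A `sector_partition`.
#' @return Character vector of direction labels.
#' @export
sector_of_angle <- function(alpha, partition) {
  s <- partition$sectors
  out <- rep(NA_character_, length(alpha))
  ok <- !is.na(alpha)
  a <- alpha[ok] %% (2 * pi)
  lab <- rep(NA_character_, length(a))
  for (i in seq_len(nrow(s))) {
    lo <- s$lo[i]; hi <- s$hi[i]
    inside <- if (hi <= 2 * pi) (a >= lo & a < hi)
              else (a >= lo | a < hi %% (2 * pi))    # arc wraps past 0
    lab[inside] <- s$direction[i]
  }
  out[ok] <- lab
  out
}

#' Distance of each bearing to its nearest sector boundary
#'
#' Used by the Fisher-median method to detect a median direction lying
#' exactly on a sector boundary (i.e. pointing at one of the reference
#' rays' limits), in which case the mean direction takes over.
#'
#' @param alpha Bearing(s), radians.
#' @param partition A `sector_partition`.
#' @return Minimum circular distance to any boundary angle.
#' @export
boundary_distance <- function(alpha, partition) {
  bounds <- partition$sectors$lo
  vapply(alpha, function(x) min(circular_distance(x, bounds)), numeric(1))
}
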