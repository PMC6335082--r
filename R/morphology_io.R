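#' Read basal-dendrite branches from an SWC reconstruction
#'
#' Parses a standard 7-column SWC file (id, type, x, y, z, radius, parent;
#' `#` comments allowed) and returns the basal dendritic tree as a set of
#' unbranched polylines ("branches") anchored at the soma. Only nodes with
#' SWC type code 3 (basal dendrite) are kept; axon (2), apical (4) and
#' other types are dropped. The soma centre is the coordinate of the root
#' type-1 node, or the centroid of the type-1 nodes when the soma is traced
#' as a multi-point contour.
#'
#' Each branch is a maximal unbranched chain of type-3 nodes, prefixed with
#' its parent's coordinate (the soma centre for primary branches, the
#' bifurcation node otherwise) so that arc length is measured from the
#' attachment point.
#'
#' @param path Path to an SWC file.
#' @return An object of class `arbor`: list with `branches` (list of
#'   n-by-3 coordinate matrices, micrometres), `soma` (length-3 soma
#'   centre) and `path`.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  if (!length(lineno)) stop("SWC parse error: no data lines in ", path)
  fields <- strsplit(trimws(lines[lineno]), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad)) {
    stop(sprintf("SWC parse error at line %d of %s: expected 7 columns, got %d",
                 lineno[bad[1]], path, lengths(fields)[bad[1]]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  nonnum <- which(apply(m, 1, function(r) any(is.na(r))))
  if (length(nonnum)) {
    stop(sprintf("SWC parse error at line %d of %s: non-numeric field",
                 lineno[nonnum[1]], path))
  }
  id <- as.integer(m[, 1]); type <- as.integer(m[, 2])
  xyz <- m[, 3:5, drop = FALSE]; parent <- as.integer(m[, 7])
  if (anyDuplicated(id)) {
    d <- which(duplicated(id))[1]
    stop(sprintf("SWC parse error at line %d of %s: duplicate node id %d",
                 lineno[d], path, id[d]))
  }
  idx <- match(parent, id)               # NA for roots (parent -1)
  orphan <- which(parent != -1L & is.na(idx))
  if (length(orphan)) {
    stop(sprintf("SWC parse error at line %d of %s: parent %d not defined",
                 lineno[orphan[1]], path, parent[orphan[1]]))
  }
  # cycle check: follow parents from every node; a forest terminates at -1
  n <- length(id)
  depth <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    seen <- integer(0)
    j <- i
    steps <- 0L
    while (!is.na(j)) {
      if (!is.na(depth[j])) break
      steps <- steps + 1L
      if (steps > n) {
        stop(sprintf("SWC parse error at line %d of %s: cyclic parent graph",
                     lineno[i], path))
      }
      seen <- c(seen, j)
      j <- idx[j]
    }
    base <- if (is.na(j)) 0L else depth[j]
    depth[rev(seen)] <- base + seq_along(seen)
  }
  soma_nodes <- which(type == 1L)
  if (!length(soma_nodes)) {
    stop("SWC parse error in ", path, ": missing soma node (type 1)")
  }
  soma <- colMeans(xyz[soma_nodes, , drop = FALSE])

  basal <- type == 3L
  # children count among basal nodes, used to cut unbranched chains
  nchild <- tabulate(idx[basal][!is.na(idx[basal])], nbins = n)
  # chain starts: basal nodes whose parent is not basal, or whose parent is
  # a basal branch point (>= 2 basal children)
  starts <- which(basal & (is.na(idx) | !basal[ifelse(is.na(idx), 1L, idx)] |
                             nchild[ifelse(is.na(idx), 1L, idx)] >= 2L))
  children <- split(seq_len(n)[basal & !is.na(idx)], idx[basal & !is.na(idx)])
  branches <- list()
  for (s in starts) {
    chain <- s
    cur <- s
    repeat {
      kids <- children[[as.character(cur)]]
      if (is.null(kids) || length(kids) != 1L) break
      if (nchild[cur] != 1L) break
      cur <- kids
      chain <- c(chain, cur)
    }
    p <- idx[s]
    anchor <- if (is.na(p)) soma
              else if (type[p] == 1L) soma
              else xyz[p, ]
    branches[[length(branches) + 1L]] <-
      unname(rbind(anchor, xyz[chain, , drop = FALSE]))
  }
  structure(list(branches = branches, soma = unname(soma), path = path),
            class = "arbor")
}

#' @export
print.arbor <- function(x, ...) {
  lens <- vapply(x$branches, branch_length, numeric(1))
  cat(sprintf("Basal arbor: %d branches, total length %.1f um\n",
              length(x$branches), sum(lens)))
  invisible(x)
}

#' Arc length of a polyline
#'
#' @param coords An n-by-2 or n-by-3 coordinate matrix.
#' @return Total arc length.
#' @export
branch_length <- function(coords) {
  if (nrow(coords) < 2) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

#' Read a horizontal-section map document
#'
#' A map is one horizontal brain section: its (optional) contour, the four
#' anatomical reference points, and the soma position of each labelled
#' neuron within the section. The on-disk format is JSON with keys
#' `map_id`, `reference_points` (object with `posterior`, `anterior`,
#' `dorsal`, `ventral`, each `[x, y]` in micrometres), optional `contour`
#' (`[[x, y], ...]`), and `neurons` (array of objects with `id`, `layer`,
#' `swc`, and optional `soma` `[x, y]`; when `soma` is present the SWC
#' coordinates are treated as soma-relative and translated into the map
#' frame).
#'
#' @param path Path to a map JSON file.
#' @return An object of class `map_document`: list with `map_id`,
#'   `reference_points` (named list of length-2 points), `contour`
#'   (matrix or NULL), `neurons` (list of records with `id`, `layer`,
#'   `swc`, `soma`), and `dir` (the map file's directory, against which
#'   relative SWC paths resolve).
#' @export
read_map <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$map_id)) stop("map validation error: missing map_id")
  rp <- doc$reference_points
  need <- c("posterior", "anterior", "dorsal", "ventral")
  missing_dir <- setdiff(need, names(rp))
  if (length(missing_dir)) {
    stop("map validation error in ", path, ": missing reference point(s) ",
         paste(missing_dir, collapse = ", "))
  }
  rp <- lapply(rp[need], function(p) {
    p <- as.numeric(unlist(p))
    if (length(p) != 2 || any(!is.finite(p)))
      stop("map validation error: reference point must be a finite [x, y]")
    p
  })
  if (is.null(doc$neurons) || !length(doc$neurons)) {
    stop("map validation error in ", path, ": a map needs at least one neuron")
  }
  layers <- c("II", "III", "IV", "Va", "Vb", "VI")
  neurons <- lapply(doc$neurons, function(nr) {
    if (is.null(nr$id)) stop("map validation error: neuron without id")
    layer <- if (is.null(nr$layer)) NA_character_ else as.character(nr$layer)
    if (!is.na(layer) && !layer %in% layers) {
      stop("map validation error: unknown layer '", layer, "' (expected ",
           paste(layers, collapse = "/"), ")")
    }
    soma <- if (is.null(nr$soma)) NULL else as.numeric(unlist(nr$soma))
    if (!is.null(soma) && length(soma) != 2)
      stop("map validation error: neuron soma must be [x, y]")
    list(id = as.character(nr$id), layer = layer,
         swc = if (is.null(nr$swc)) NA_character_ else as.character(nr$swc),
         soma = soma)
  })
  ids <- vapply(neurons, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("map validation error in ", path, ": duplicate neuron id '",
         ids[duplicated(ids)][1], "'")
  }
  contour <- NULL
  if (!is.null(doc$contour)) {
    contour <- do.call(rbind, lapply(doc$contour, function(p) as.numeric(unlist(p))))
    if (ncol(contour) != 2) stop("map validation error: contour must be [[x, y], ...]")
  }
  structure(list(map_id = as.character(doc$map_id), reference_points = rp,
                 contour = contour, neurons = neurons,
                 dir = dirname(normalizePath(path))),
            class = "map_document")
}

#' @export
print.map_document <- function(x, ...) {
  cat(sprintf("Map %s: %d neurons, reference points %s\n", x$map_id,
              length(x$neurons),
              paste(names(x$reference_points), collapse = "/")))
  invisible(x)
}

#' Resample an arbor into fixed-length segment points
#'
#' Walks every branch and emits one sample point per `step` of arc length
#' (at arc lengths `step, 2*step, ..., floor(L/step)*step` from the branch
#' anchor), so each point stands for one dendritic segment of length
#' `step`. Arc length is measured in 3-D by default and the samples are
#' then projected onto the map plane by dropping the sectioning (z) axis;
#' with `planar_arclength = TRUE` the branch is projected first and arc
#' length measured in-plane. The branch anchor itself (arc length 0, the
#' soma for primary branches) is never emitted, and a residual shorter
#' than `step` contributes no point, so the point count is exactly
#' `sum(floor(L_b / step))`.
#'
#' @param arbor An `arbor` from [read_swc()], or a list of coordinate
#'   matrices.
#' @param step Segment length in micrometres (default 0.5).
#' @param soma Optional length-2 or length-3 soma centre overriding the
#'   arbor's own (used to translate soma-relative reconstructions into map
#'   coordinates); distances are measured to its planar projection.
#' @param planar_arclength Measure arc length in the plane instead of 3-D.
#' @return An object of class `segment_cloud`: data frame with columns
#'   `x`, `y` (map plane, micrometres) and `dist` (planar distance to the
#'   soma), plus attributes `step` and `soma` (planar).
#' @export
resample_arbor <- function(arbor, step = 0.5, soma = NULL,
                           planar_arclength = FALSE) {
  if (!is.numeric(step) || length(step) != 1 || !is.finite(step) || step <= 0)
    stop("step must be a single positive number of micrometres")
  branches <- if (inherits(arbor, "arbor")) arbor$branches else arbor
  soma3 <- if (!is.null(soma)) soma
           else if (inherits(arbor, "arbor")) arbor$soma
           else c(0, 0, 0)
  shift <- if (!is.null(soma) && inherits(arbor, "arbor")) {
    # map-frame soma given: translate the reconstruction so its own soma
    # lands on the map position
    c(soma[1], soma[2], if (length(soma) > 2) soma[3] else 0) -
      c(arbor$soma[1], arbor$soma[2], arbor$soma[3])
  } else c(0, 0, 0)
  soma_xy <- c(soma3[1], soma3[2])

  pts <- lapply(branches, function(b) {
    b <- as.matrix(b)
    if (ncol(b) == 2) b <- cbind(b, 0)
    b <- sweep(b, 2, -shift)
    use <- if (planar_arclength) b[, 1:2, drop = FALSE] else b
    if (nrow(b) < 2) return(NULL)
    seglen <- sqrt(rowSums(diff(use)^2))
    cl <- c(0, cumsum(seglen))
    L <- cl[length(cl)]
    k <- floor(L / step + 1e-9)
    if (k < 1) return(NULL)
    at <- step * seq_len(k)
    cbind(stats::approx(cl, b[, 1], xout = at, ties = "ordered", rule = 2)$y,
          stats::approx(cl, b[, 2], xout = at, ties = "ordered", rule = 2)$y)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts)) pts <- matrix(numeric(0), ncol = 2)
  out <- data.frame(x = pts[, 1], y = pts[, 2])
  out$dist <- sqrt((out$x - soma_xy[1])^2 + (out$y - soma_xy[2])^2)
  structure(out, step = step, soma = soma_xy,
            class = c("segment_cloud", "data.frame"))
}
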