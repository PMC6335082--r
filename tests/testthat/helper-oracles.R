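# Independent oracles, deliberately naive: each re-derives a quantity by a
# different route than the implementation it checks.

# O(n^2) Fisher-median oracle: scan every data angle as a candidate.
brute_fisher_median <- function(theta) {
  sums <- vapply(theta, function(phi) sum(circular_distance(theta, phi)),
                 numeric(1))
  wrap_angle(theta[sums <= min(sums) + 1e-9])   # all tied minimisers
}

# circular distance by brute force over winding numbers
brute_circular_distance <- function(a, b) {
  min(abs(a - b + 2 * pi * (-3:3)))
}

# signed angle as a difference of absolute bearings, reduced to (-pi, pi]
oracle_signed_angle <- function(a, v) {
  wrap_angle(atan2(v[2], v[1]) - atan2(a[2], a[1]))
}

# cumulative-arc-length resampling oracle: walk a polyline vertex by
# vertex, dropping a point every `step` of accumulated length
oracle_resample_branch <- function(coords, step) {
  pts <- NULL
  carried <- 0
  for (i in seq_len(nrow(coords) - 1)) {
    p0 <- coords[i, ]; p1 <- coords[i + 1, ]
    seg <- sqrt(sum((p1 - p0)^2))
    if (seg == 0) next
    pos <- step - carried
    while (pos <= seg + 1e-9) {
      f <- pos / seg
      pts <- rbind(pts, p0 + f * (p1 - p0))
      pos <- pos + step
    }
    carried <- (carried + seg) %% step
  }
  pts
}

# brute-force point-in-arc membership: test each sector arc separately
oracle_sector_label <- function(alpha, partition) {
  a <- alpha %% (2 * pi)
  s <- partition$sectors
  for (i in seq_len(nrow(s))) {
    lo <- s$lo[i]; hi <- s$hi[i]
    hits <- if (hi <= 2 * pi) a >= lo && a < hi
            else a >= lo || a < (hi - 2 * pi)
    if (hits) return(s$direction[i])
  }
  NA_character_
}

# random planar polyline for resampling properties
random_polyline <- function(n_vertices = 6, scale = 20) {
  cbind(cumsum(stats::runif(n_vertices, -scale, scale)),
        cumsum(stats::runif(n_vertices, -scale, scale)),
        cumsum(stats::runif(n_vertices, -scale / 4, scale / 4)))
}

# write a minimal SWC file; rows = list of "id type x y z r parent" strings
write_swc_fixture <- function(rows, path = tempfile(fileext = ".swc")) {
  writeLines(c("# test fixture", rows), path)
  path
}

# straight three-node basal branch of total length 10 along +x
swc_straight10 <- function() {
  write_swc_fixture(c(
    "1 1 0 0 0 5 -1",
    "2 3 5 0 0 1 1",
    "3 3 10 0 0 1 2"))
}

# a small valid map JSON on disk with a symmetric frame
write_map_fixture <- function(neurons, path = tempfile(fileext = ".json"),
                              drop_point = NULL) {
  rp <- list(posterior = c(1000, 0), anterior = c(-1000, 0),
             dorsal = c(0, 1000), ventral = c(0, -1000))
  if (!is.null(drop_point)) rp[[drop_point]] <- NULL
  jsonlite::write_json(
    list(map_id = "m1", reference_points = rp, neurons = neurons),
    path, auto_unbox = TRUE, digits = NA)
  path
}
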