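#' Sample from a von Mises distribution
#'
#' Best–Fisher rejection sampler. With `kappa = 0` the draw is uniform on
#' the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, >= 0.
#' @return Angles in \eqn{(-\pi, \pi]}.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(mu + out)
}

#' Sample initial branch bearings from a von Mises mixture
#'
#' @param n Number of draws.
#' @param mixture Data frame or list with components `mu` (radians),
#'   `kappa` (>= 0) and `w` (weights summing to 1).
#' @return Angles in \eqn{(-\pi, \pi]}.
#' @export
rvonmises_mixture <- function(n, mixture) {
  mx <- as.data.frame(mixture)
  stopifnot(all(c("mu", "kappa", "w") %in% names(mx)), all(mx$kappa >= 0),
            abs(sum(mx$w) - 1) < 1e-9)
  comp <- sample.int(nrow(mx), n, replace = TRUE, prob = mx$w)
  out <- numeric(n)
  for (k in unique(comp)) {
    idx <- comp == k
    out[idx] <- rvonmises(sum(idx), mx$mu[k], mx$kappa[k])
  }
  out
}

#' Configuration for the synthetic-morphology generator
#'
#' The generator emulates the planar basal arbors of the study material:
#' horizontal-section maps holding 6 +/- 2 pyramidal neurons each, every
#' neuron growing 3-8 primary basal branches as tortuous polylines whose
#' initial bearings follow a von Mises mixture of configurable bias.
#' Branches are persistent-direction walks: each 1 um step's direction
#' reverts toward the branch's initial bearing with AR(1) memory and
#' Gaussian angular jitter, so a branch stays oriented while wiggling
#' locally.
#'
#' @param seed Integer seed; all generation is deterministic given it.
#' @param n_maps Number of maps to generate.
#' @param neurons_mean,neurons_sd Per-map neuron count distribution
#'   (rounded normal, clipped to >= 1); defaults 6 and 2.
#' @param branches_min,branches_max Range of primary branches per neuron.
#' @param length_mean,length_sd Branch length distribution, micrometres
#'   (clipped to >= 10).
#' @param step_len Walk step length, micrometres.
#' @param jitter_sd Per-step angular jitter, radians.
#' @param persistence AR(1) memory of the direction deviation (0 = white
#'   jitter about the bearing, near 1 = slow meander).
#' @param bif_min,bif_max Range of the bifurcation depth per primary
#'   branch (0-2 by default); at each bifurcation the remaining length
#'   splits evenly between two daughters.
#' @param bif_angle Mean divergence angle between the two daughters at a
#'   bifurcation, radians.
#' @param bias Default von Mises mixture for initial bearings (data frame
#'   with `mu`, `kappa`, `w`); bearings are map-frame, 0 = toward the
#'   posterior reference point.
#' @param frame_radius Distance from the map centre to each reference
#'   point, micrometres.
#' @param frame_eccentricity Relative radial perturbation of the four
#'   reference points (0 = perfectly symmetric frame).
#' @param soma_spread Standard deviation of soma placement about the map
#'   centre, micrometres.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_maps = 1L,
                             neurons_mean = 6, neurons_sd = 2,
                             branches_min = 3L, branches_max = 8L,
                             length_mean = 100, length_sd = 25,
                             step_len = 1, jitter_sd = 0.12,
                             persistence = 0.7,
                             bif_min = 0L, bif_max = 2L, bif_angle = 1.0,
                             bias = data.frame(mu = 0, kappa = 0, w = 1),
                             frame_radius = 1000,
                             frame_eccentricity = 0,
                             soma_spread = 150) {
  stopifnot(n_maps >= 1, branches_min >= 1, branches_max >= branches_min,
            length_mean > 0, step_len > 0, jitter_sd >= 0,
            persistence >= 0, persistence < 1,
            bif_min >= 0, bif_max >= bif_min, bif_angle >= 0,
            frame_radius > 0, frame_eccentricity >= 0)
  bias <- as.data.frame(bias)
  stopifnot(all(bias$kappa >= 0), abs(sum(bias$w) - 1) < 1e-9)
  structure(as.list(environment()), class = "synthetic_config")
}

# unbranched segment: persistent-direction walk in the plane from `origin`
grow_segment <- function(origin, bearing, length, cfg) {
  n_steps <- max(1L, round(length / cfg$step_len))
  dev <- numeric(n_steps)
  eps <- stats::rnorm(n_steps, 0, cfg$jitter_sd)
  for (s in seq_len(n_steps)) {
    dev[s] <- if (s == 1) eps[1] else cfg$persistence * dev[s - 1] + eps[s]
  }
  dirs <- bearing + dev
  x <- origin[1] + cumsum(cfg$step_len * cos(dirs))
  y <- origin[2] + cumsum(cfg$step_len * sin(dirs))
  cbind(c(origin[1], x), c(origin[2], y), 0)
}

# one primary branch: walk with 0-2 bifurcations; at each bifurcation the
# remaining length splits evenly between two daughters diverging about the
# parent direction. Total arc length stays equal to `length`.
grow_branch <- function(origin, bearing, len, cfg) {
  n_bif <- sample(seq(cfg$bif_min, cfg$bif_max), 1)
  segs <- list()
  recurse <- function(origin, bearing, len, bifs_left) {
    if (bifs_left == 0 || len < 4 * cfg$step_len) {
      segs[[length(segs) + 1L]] <<- grow_segment(origin, bearing, len, cfg)
      return(invisible())
    }
    # bifurcate somewhere in the middle 60% of the remaining length
    stem_len <- len * stats::runif(1, 0.2, 0.8)
    stem <- grow_segment(origin, bearing, stem_len, cfg)
    segs[[length(segs) + 1L]] <<- stem
    tip <- stem[nrow(stem), 1:2]
    # direction at the tip, then daughters diverge about it
    tip_dir <- atan2(stem[nrow(stem), 2] - stem[nrow(stem) - 1, 2],
                     stem[nrow(stem), 1] - stem[nrow(stem) - 1, 1])
    half <- abs(stats::rnorm(1, cfg$bif_angle / 2, cfg$bif_angle / 6))
    rest <- (len - stem_len) / 2
    recurse(tip, tip_dir + half, rest, bifs_left - 1L)
    recurse(tip, tip_dir - half, rest, bifs_left - 1L)
  }
  recurse(origin, bearing, len, n_bif)
  segs
}

#' Generate one synthetic neuron's basal arbor
#'
#' @param soma Length-2 soma position (map frame).
#' @param cfg A `synthetic_config`.
#' @param bias Optional von Mises mixture overriding `cfg$bias`.
#' @param n_branches Optional branch count overriding the configured
#'   range.
#' @return An `arbor` object (as from [read_swc()]), soma at `soma`.
#' @export
generate_neuron <- function(soma, cfg = synthetic_config(), bias = NULL,
                            n_branches = NULL) {
  if (is.null(bias)) bias <- cfg$bias
  if (is.null(n_branches))
    n_branches <- sample(seq(cfg$branches_min, cfg$branches_max), 1)
  bearings <- rvonmises_mixture(n_branches, bias)
  lens <- pmax(10, stats::rnorm(n_branches, cfg$length_mean, cfg$length_sd))
  branches <- do.call(c, lapply(seq_len(n_branches), function(b) {
    grow_branch(soma, bearings[b], lens[b], cfg)
  }))
  structure(list(branches = branches, soma = c(soma, 0), path = NA_character_),
            class = "arbor")
}

# serialize an arbor as SWC text (type 1 soma root + type 3 polylines).
# A branch whose anchor matches an already-written node (a parent's tip)
# is attached there, so bifurcating trees round-trip with their topology;
# coordinates are written at full double precision so arc lengths (and
# hence resampled point counts) survive the round-trip exactly.
arbor_to_swc <- function(arbor) {
  key <- function(p) sprintf("%.17g %.17g %.17g", p[1], p[2], p[3])
  rows <- list(sprintf("1 1 %.17g %.17g %.17g 5.0 -1",
                       arbor$soma[1], arbor$soma[2], arbor$soma[3]))
  seen <- new.env(parent = emptyenv())
  assign(key(arbor$soma), 1L, envir = seen)
  next_id <- 2L
  for (b in arbor$branches) {
    anchor_key <- key(b[1, ])
    parent <- if (exists(anchor_key, envir = seen))
      get(anchor_key, envir = seen) else 1L
    for (r in 2:nrow(b)) {          # row 1 is the anchor, never re-emitted
      rows[[length(rows) + 1L]] <-
        sprintf("%d 3 %.17g %.17g %.17g 0.5 %d", next_id, b[r, 1], b[r, 2],
                b[r, 3], parent)
      assign(key(b[r, ]), next_id, envir = seen)
      parent <- next_id
      next_id <- next_id + 1L
    }
  }
  unlist(rows)
}

#' Generate synthetic maps with ground-truth orientation structure
#'
#' Writes, per map, one SWC file per neuron plus a map JSON into
#' `out_dir`, together with a `ground_truth.csv` recording each neuron's
#' generating mixture and intended orientation label. Everything is
#' deterministic given `cfg$seed`.
#'
#' The four reference points sit at the configured radius from the map
#' centre toward posterior (0), dorsal (pi/2), anterior (pi) and ventral
#' (3 pi/2); `frame_eccentricity` perturbs the radii. Somata are placed
#' around the map centre inside a circular contour.
#'
#' @param cfg A `synthetic_config`.
#' @param out_dir Directory to write into (created if needed); `NULL`
#'   keeps everything in memory.
#' @return List of maps; each has `map` (a `map_document`), `arbors`
#'   (named list of `arbor`s) and `truth` (data frame with `map_id`,
#'   `neuron_id`, mixture description, `intended`).
#' @export
generate_maps <- function(cfg = synthetic_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  layers <- c("II", "III", "IV", "Va", "Vb", "VI")
  ref_dirs <- c(posterior = 0, dorsal = pi / 2, anterior = pi,
                ventral = 3 * pi / 2)
  maps <- vector("list", cfg$n_maps)
  for (m in seq_len(cfg$n_maps)) {
    map_id <- sprintf("sim%02d", m)
    n_neu <- max(1L, round(stats::rnorm(1, cfg$neurons_mean, cfg$neurons_sd)))
    radii <- cfg$frame_radius *
      (1 + cfg$frame_eccentricity * stats::runif(4, -1, 1))
    rp <- lapply(seq_along(ref_dirs), function(i) {
      radii[i] * c(cos(ref_dirs[i]), sin(ref_dirs[i]))
    })
    names(rp) <- names(ref_dirs)
    contour_t <- seq(0, 2 * pi, length.out = 73)[-73]
    contour <- 0.5 * cfg$frame_radius * cbind(cos(contour_t), sin(contour_t))
    arbors <- list()
    records <- list()
    truth <- list()
    for (i in seq_len(n_neu)) {
      nid <- sprintf("n%02d", i)
      soma <- stats::rnorm(2, 0, cfg$soma_spread)
      arbor <- generate_neuron(soma, cfg)
      arbors[[nid]] <- arbor
      layer <- layers[(m - 1) %% length(layers) + 1]
      records[[i]] <- list(id = nid, layer = layer,
                           swc = sprintf("%s_%s.swc", map_id, nid),
                           soma = soma)
      truth[[i]] <- data.frame(
        map_id = map_id, neuron_id = nid, layer = layer,
        mixture = paste(sprintf("mu=%.3f:kappa=%.2f:w=%.2f", cfg$bias$mu,
                                cfg$bias$kappa, cfg$bias$w), collapse = ";"),
        intended = intended_label(cfg$bias),
        stringsAsFactors = FALSE)
    }
    map <- structure(list(map_id = map_id,
                          reference_points = rp, contour = contour,
                          neurons = records,
                          dir = if (is.null(out_dir)) NA_character_
                                else normalizePath(out_dir)),
                     class = "map_document")
    truth <- do.call(rbind, truth)
    if (!is.null(out_dir)) {
      for (i in seq_len(n_neu)) {
        writeLines(arbor_to_swc(arbors[[i]]),
                   file.path(out_dir, records[[i]]$swc))
      }
      json <- list(map_id = map_id,
                   reference_points = rp,
                   contour = lapply(seq_len(nrow(contour)),
                                    function(r) contour[r, ]),
                   neurons = records)
      jsonlite::write_json(json, file.path(out_dir, paste0(map_id, ".json")),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(truth, file.path(out_dir, paste0(map_id, "_truth.csv")),
                       row.names = FALSE)
    }
    maps[[m]] <- list(map = map, arbors = arbors, truth = truth)
  }
  maps
}

# intended orientation label of a mixture under the symmetric frame:
# sectors are quadrants about the four cardinal bearings
intended_label <- function(bias) {
  if (all(bias$kappa == 0)) return("Und.")
  strong <- bias$kappa > 0 & bias$w > 0.2
  if (!any(strong)) return("Und.")
  sec <- c("P", "D", "A", "V")[
    (floor((wrap_angle(bias$mu[strong]) %% (2 * pi) + pi / 4) / (pi / 2)) %% 4) + 1]
  orientation_class(unique(sec))
}

#' Orientation-recovery experiment over a bias-strength grid
#'
#' For every combination of von Mises concentration `kappa` and DLRM
#' threshold `t`, generates replicate single-component neurons whose mean
#' bearing is centred in a sector of a symmetric frame, runs the full
#' pipeline (resample, partition, assign, classify), and reports the
#' fraction of replicates whose DLRM call recovers the generating label
#' (single orientation in the seeded sector; `Und.` for `kappa = 0`),
#' with binomial Monte-Carlo standard errors.
#'
#' @param kappas Numeric vector of concentrations (>= 0).
#' @param thresholds Numeric vector of DLRM thresholds (> 1).
#' @param n_rep Replicate neurons per grid cell.
#' @param n_branches,branch_len Branch count and length per neuron.
#' @param mu Mean bearing of the biased component (default centred in the
#'   anterior sector).
#' @param cfg Base `synthetic_config` (its seed orders the whole grid).
#' @param step Resampling step, micrometres.
#' @return Data frame: `kappa`, `t`, `n_rep`, `accuracy`, `se`,
#'   `modal_class`.
#' @export
recovery_experiment <- function(kappas = c(0, 2, 8),
                                thresholds = c(1.1, 1.2, 1.3),
                                n_rep = 50, n_branches = 40,
                                branch_len = 100, mu = pi,
                                cfg = synthetic_config(), step = 0.5) {
  stopifnot(length(kappas) >= 1, length(thresholds) >= 1)
  frame <- symmetric_frame()
  set.seed(cfg$seed)
  cfg$length_sd <- 0
  cfg$length_mean <- branch_len
  grid <- expand.grid(kappa = kappas, t = thresholds)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    kap <- grid$kappa[g]; t <- grid$t[g]
    target <- if (kap == 0) "Und."
              else intended_label(data.frame(mu = mu, kappa = kap, w = 1))
    classes <- vapply(seq_len(n_rep), function(r) {
      bias <- data.frame(mu = mu, kappa = kap, w = 1)
      arbor <- generate_neuron(c(0, 0), cfg, bias = bias,
                               n_branches = n_branches)
      cloud <- resample_arbor(arbor, step = step)
      part <- build_partition(c(0, 0), frame)
      classify_neuron(compute_ratios(assign_sectors(cloud, part), part),
                      t)$class
    }, character(1))
    acc <- mean(classes == target)
    data.frame(kappa = kap, t = t, n_rep = n_rep, accuracy = acc,
               se = sqrt(acc * (1 - acc) / n_rep),
               modal_class = names(sort(table(classes), decreasing = TRUE))[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' A perfectly symmetric reference frame
#'
#' Reference points at equal distance from the origin toward posterior
#' (+x), dorsal (+y), anterior (-x) and ventral (-y); with the soma at
#' the origin every sector is a quadrant and all `PS` equal 1/4.
#'
#' @param radius Distance to each reference point, micrometres.
#' @param center Frame centre.
#' @return Named list of four reference points.
#' @export
symmetric_frame <- function(radius = 1000, center = c(0, 0)) {
  list(posterior = center + c(radius, 0),
       dorsal = center + c(0, radius),
       anterior = center + c(-radius, 0),
       ventral = center + c(0, -radius))
}
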