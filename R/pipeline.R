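#' Analysis configuration
#'
#' @param step Resampling segment length, micrometres (default 0.5).
#' @param thresholds DLRM thresholds, all > 1 (default 1.1, 1.2, 1.3).
#' @param boundary_mode Sector boundary construction, `"bisector"` or
#'   `"rays"` (see [build_partition()]).
#' @param planar_arclength Measure branch arc length in-plane instead of
#'   3-D (see [resample_arbor()]).
#' @param seed Integer seed recorded in outputs (the analysis itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(step = 0.5, thresholds = c(1.1, 1.2, 1.3),
                       boundary_mode = c("bisector", "rays"),
                       planar_arclength = FALSE, seed = 1L) {
  boundary_mode <- match.arg(boundary_mode)
  stopifnot(step > 0, all(thresholds > 1))
  structure(list(step = step, thresholds = sort(thresholds),
                 boundary_mode = boundary_mode,
                 planar_arclength = planar_arclength,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Analyse all neurons of one map
#'
#' Runs the full pipeline for one horizontal-section map: read each
#' neuron's SWC reconstruction, resample into fixed-length segment
#' points, build the neuron's anatomical sector partition, assign points
#' to sectors, and call the orientation both ways — DLRM at every
#' configured threshold and the Fisher median direction.
#'
#' @param map A `map_document` (from [read_map()]) or a path to a map
#'   JSON.
#' @param config A [run_config()].
#' @param arbors Optional named list of in-memory `arbor`s keyed by
#'   neuron id, overriding the SWC paths (used by the synthetic module).
#' @return A list of class `map_analysis` with
#'   * `per_neuron`: one row per neuron per threshold (map_id, neuron_id,
#'     layer, n_points, TL/PS/ratio per direction, preferred, weak, type,
#'     class, plus the Fisher median/mean/sector);
#'   * `fisher`: per-neuron direction calls (one row per neuron);
#'   * `tendency`: the map's `map_tendency`;
#'   * `partitions`, `clouds`, `assignments`: per-neuron intermediates,
#'     keyed by id.
#' @export
analyze_map <- function(map, config = run_config(), arbors = NULL) {
  if (is.character(map)) map <- read_map(map)
  stopifnot(inherits(map, "map_document"))
  per_neuron <- list()
  fisher_rows <- list()
  partitions <- list()
  clouds <- list()
  assignments <- list()
  for (nr in map$neurons) {
    arbor <- if (!is.null(arbors) && nr$id %in% names(arbors)) {
      arbors[[nr$id]]
    } else {
      swc_path <- nr$swc
      if (is.na(swc_path)) stop("neuron ", nr$id, " in map ", map$map_id,
                                ": no SWC path and no in-memory arbor")
      if (!file.exists(swc_path) && !is.na(map$dir))
        swc_path <- file.path(map$dir, nr$swc)
      read_swc(swc_path)
    }
    soma <- if (!is.null(nr$soma)) nr$soma else arbor$soma[1:2]
    cloud <- resample_arbor(arbor, step = config$step, soma = nr$soma,
                            planar_arclength = config$planar_arclength)
    partition <- build_partition(soma, map$reference_points,
                                 boundary_mode = config$boundary_mode)
    assignment <- assign_sectors(cloud, partition)
    ratios <- compute_ratios(assignment, partition)
    fcall <- call_neuron(assignment, partition)
    partitions[[nr$id]] <- partition
    clouds[[nr$id]] <- cloud
    assignments[[nr$id]] <- assignment

    fisher_rows[[nr$id]] <- data.frame(
      map_id = map$map_id, neuron_id = nr$id, layer = nr$layer,
      median = fcall$median, mean = fcall$mean, sector = fcall$sector,
      fallback_used = fcall$fallback_used, unclear = fcall$unclear,
      stringsAsFactors = FALSE)

    for (t in config$thresholds) {
      call_t <- classify_neuron(ratios, t)
      row <- data.frame(map_id = map$map_id, neuron_id = nr$id,
                        layer = nr$layer, threshold = t,
                        n_points = sum(assignment$counts),
                        stringsAsFactors = FALSE)
      row[paste0("tl_", DIR_ABBREV[ratios$direction])] <- ratios$tl
      row[paste0("ps_", DIR_ABBREV[ratios$direction])] <- ratios$ps
      row[paste0("ratio_", DIR_ABBREV[ratios$direction])] <- ratios$ratio
      row$preferred <- paste(call_t$preferred, collapse = "+")
      row$weak <- paste(call_t$weak, collapse = "+")
      row$type <- call_t$type
      row$class <- call_t$class
      per_neuron[[paste(nr$id, t)]] <- row
    }
  }
  fisher <- do.call(rbind, fisher_rows)
  rownames(fisher) <- NULL
  counts <- vapply(c("posterior", "dorsal", "anterior", "ventral"),
                   function(d) sum(fisher$sector == d, na.rm = TRUE),
                   numeric(1))
  tendency <- map_tendency(counts, n = nrow(fisher))
  per_neuron <- do.call(rbind, per_neuron)
  rownames(per_neuron) <- NULL
  structure(list(map_id = map$map_id, per_neuron = per_neuron,
                 fisher = fisher, tendency = tendency,
                 partitions = partitions, clouds = clouds,
                 assignments = assignments),
            class = "map_analysis")
}

#' @export
print.map_analysis <- function(x, ...) {
  cat(sprintf("Analysis of map %s: %d neurons\n", x$map_id, nrow(x$fisher)))
  cat("  Fisher-median tendency:", x$tendency$label, "\n")
  invisible(x)
}

#' Analyse several maps and assemble the study-level tables
#'
#' @param maps Character vector of map JSON paths, or a list of
#'   `map_document`s / `map_analysis` inputs as accepted by
#'   [analyze_map()].
#' @param config A [run_config()].
#' @param arbors Optional list (parallel to `maps`) of named arbor lists.
#' @return A list of class `study_analysis` with `per_neuron` (all maps
#'   stacked), `per_map_dlrm` (orientation-class counts per map and
#'   threshold), `per_layer_dlrm`, `per_map_tendency` (map id, n, P/D/A/V
#'   counts, tendency label), and `analyses` (per-map results).
#' @export
analyze_maps <- function(maps, config = run_config(), arbors = NULL) {
  if (!length(maps)) stop("usage error: no maps given")
  analyses <- lapply(seq_along(maps), function(i) {
    analyze_map(maps[[i]], config,
                arbors = if (!is.null(arbors)) arbors[[i]] else NULL)
  })
  per_neuron <- do.call(rbind, lapply(analyses, `[[`, "per_neuron"))
  per_map_dlrm <- summarize_group(per_neuron, "map_id")
  per_layer_dlrm <- summarize_group(per_neuron, "layer")
  per_map_tendency <- do.call(rbind, lapply(analyses, function(a) {
    td <- a$tendency
    data.frame(map_id = a$map_id, n_cells = td$n,
               P = td$counts["P"], D = td$counts["D"],
               A = td$counts["A"], V = td$counts["V"],
               tendency = td$label, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  structure(list(per_neuron = per_neuron, per_map_dlrm = per_map_dlrm,
                 per_layer_dlrm = per_layer_dlrm,
                 per_map_tendency = per_map_tendency,
                 analyses = analyses, config = config),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf("Study analysis: %d maps, %d neurons, thresholds %s\n",
              length(x$analyses),
              length(unique(paste(x$per_neuron$map_id, x$per_neuron$neuron_id))),
              paste(x$config$thresholds, collapse = "/")))
  invisible(x)
}

#' Write the study-level CSV outputs
#'
#' Four CSVs: `per_neuron.csv` (one row per neuron per threshold with
#' TL/PS/ratio per direction and the DLRM call), `per_map_dlrm.csv` and
#' `per_layer_dlrm.csv` (orientation-class count tables), and
#' `per_map_tendency.csv` (per-map Fisher-median counts and tendency
#' label).
#'
#' @param study A `study_analysis`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_csvs <- function(study, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(per_neuron = file.path(out_dir, "per_neuron.csv"),
             per_map_dlrm = file.path(out_dir, "per_map_dlrm.csv"),
             per_layer_dlrm = file.path(out_dir, "per_layer_dlrm.csv"),
             per_map_tendency = file.path(out_dir, "per_map_tendency.csv"))
  utils::write.csv(study$per_neuron, paths["per_neuron"], row.names = FALSE)
  utils::write.csv(study$per_map_dlrm, paths["per_map_dlrm"], row.names = FALSE)
  utils::write.csv(study$per_layer_dlrm, paths["per_layer_dlrm"],
                   row.names = FALSE)
  utils::write.csv(study$per_map_tendency, paths["per_map_tendency"],
                   row.names = FALSE)
  invisible(paths)
}
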