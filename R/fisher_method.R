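#' Per-neuron orientation call by the Fisher median direction
#'
#' The Fisher circular median of all sample-point bearings is taken as the
#' neuron's main orientation direction, and the neuron is called toward
#' the anatomical sector containing it. When the median lies exactly on a
#' sector boundary (within `boundary_tol`) the call is ambiguous and the
#' circular mean direction is used instead, with `fallback_used = TRUE`.
#' If the mean is also unusable (zero resultant, or itself on a boundary)
#' the call is `"unclear"` and the sector is `NA`.
#'
#' @param angles Numeric vector of sample-point bearings (radians,
#'   relative to the posterior ray as produced by [point_angles()]), or a
#'   `sector_assignment`.
#' @param partition The neuron's `sector_partition`.
#' @param boundary_tol Angular tolerance (radians) for "median lies on a
#'   boundary".
#' @return An object of class `direction_call`: list with `median`,
#'   `mean` (NA if undefined), `sector` (direction label or NA),
#'   `fallback_used`, `unclear`.
#' @export
call_neuron <- function(angles, partition, boundary_tol = 1e-9) {
  if (inherits(angles, "sector_assignment")) angles <- angles$angles
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("no dendrite: no usable sample-point bearings")
  med <- fisher_median(angles)
  mu <- tryCatch(mean_direction(angles), error = function(e) NA_real_)
  fallback <- FALSE
  unclear <- FALSE
  use <- med
  if (boundary_distance(med, partition) <= boundary_tol) {
    fallback <- TRUE
    if (is.na(mu) || boundary_distance(mu, partition) <= boundary_tol) {
      unclear <- TRUE
      use <- NA_real_
      warning("unclear orientation call: median on a sector boundary and ",
              "mean direction unusable")
    } else {
      use <- mu
    }
  }
  sector <- if (is.na(use)) NA_character_ else sector_of_angle(use, partition)
  structure(list(median = med, mean = mu, sector = sector,
                 fallback_used = fallback, unclear = unclear),
            class = "direction_call")
}

#' @export
print.direction_call <- function(x, ...) {
  cat(sprintf("Fisher-median call: %s (median %.3f rad%s)\n",
              if (is.na(x$sector)) "unclear" else x$sector, x$median,
              if (x$fallback_used) ", mean-direction fallback" else ""))
  invisible(x)
}

#' Map-level orientation tendency from per-neuron direction calls
#'
#' Aggregates the per-neuron Fisher-median calls of one map into a group
#' label. With `f_j = count_j / n` the fraction of neurons called toward
#' direction `j`, the rules are, in precedence order (full labels outrank
#' partial ones, and a two-direction tendency outranks a one-direction
#' tendency of equal strength):
#' 1. some direction with `f_j > 0.8` — **oriented** toward `j`;
#' 2. a contiguous pair covering 100% of the neurons, with the larger
#'    member at least 50% and the smaller at least 30% — **oriented**
#'    toward the pair;
#' 3. a contiguous pair covering more than 80%, larger member >= 50%,
#'    smaller >= 30% — **partly oriented** toward the pair;
#' 4. some direction with `f_j > 0.6` — **partly oriented** toward `j`;
#' 5. otherwise **undetermined**.
#'
#' Only contiguous pairs (A-V, A-D, D-P, P-V) qualify for two-direction
#' tendencies; the opposite pairs (A-P, D-V) never do. Strict/inclusive
#' comparisons follow the rule wording: ">" strict, "at least" inclusive.
#'
#' @param counts Named or positional counts for posterior, dorsal,
#'   anterior, ventral (in that order if unnamed; names may be full
#'   direction names or abbreviations P/D/A/V).
#' @param n Total number of neurons in the map; must equal `sum(counts)`.
#' @return An object of class `map_tendency`: list with `counts`, `n`,
#'   `strength` (`"oriented"`, `"partly"` or `"undetermined"`),
#'   `directions` (character vector of 0, 1 or 2 abbreviations) and
#'   `label` (printable, e.g. `"A-V"`, `"Partly V"`, `"Undetermined"`).
#' @export
map_tendency <- function(counts, n = sum(counts)) {
  counts <- as.numeric(unlist(counts))
  if (length(counts) != 4) stop("need four per-direction counts (P, D, A, V)")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (abs(sum(counts) - n) > 1e-9) stop("counts must sum to n")
  if (n < 1) stop("n must be at least 1")
  names(counts) <- c("P", "D", "A", "V")
  f <- counts / n

  pair_frac <- function(pair) {
    m <- strsplit(pair, "-")[[1]]
    c(total = sum(f[m]), big = max(f[m]), small = min(f[m]))
  }
  pairs <- vapply(CONTIGUOUS_PAIRS, pair_frac, numeric(3))
  eligible <- pairs["big", ] >= 0.5 & pairs["small", ] >= 0.3

  result <- if (any(f > 0.8)) {
    list(strength = "oriented", dirs = names(f)[which.max(f)])
  } else if (any(eligible & pairs["total", ] >= 1 - 1e-9)) {
    best <- CONTIGUOUS_PAIRS[which(eligible & pairs["total", ] >= 1 - 1e-9)][1]
    list(strength = "oriented", dirs = strsplit(best, "-")[[1]])
  } else if (any(eligible & pairs["total", ] > 0.8)) {
    ok <- which(eligible & pairs["total", ] > 0.8)
    best <- ok[which.max(pairs["total", ok])]
    list(strength = "partly", dirs = strsplit(CONTIGUOUS_PAIRS[best], "-")[[1]])
  } else if (any(f > 0.6)) {
    list(strength = "partly", dirs = names(f)[which.max(f)])
  } else {
    list(strength = "undetermined", dirs = character(0))
  }

  dir_label <- orientation_class(result$dirs)
  label <- switch(result$strength,
                  oriented = dir_label,
                  partly = paste("Partly", dir_label),
                  undetermined = "Undetermined")
  structure(list(counts = counts, n = n, strength = result$strength,
                 directions = result$dirs, label = label),
            class = "map_tendency")
}

#' @export
print.map_tendency <- function(x, ...) {
  cat(sprintf("Map tendency (n = %d; P/D/A/V = %s): %s\n", x$n,
              paste(x$counts, collapse = "/"), x$label))
  invisible(x)
}

#' Normalise a tendency label for comparison
#'
#' Pair tendencies are order-insensitive (`"A-V"` and `"V-A"` are the
#' same tendency) and case differences in `"Partly"`/`"Undetermined"` are
#' ignored, so labels from different transcriptions compare reliably.
#'
#' @param label Character vector of tendency labels.
#' @return Canonicalised labels.
#' @export
normalize_tendency_label <- function(label) {
  vapply(label, function(l) {
    l <- trimws(l)
    if (tolower(l) == "undetermined") return("Undetermined")
    partly <- grepl("^partly\\s+", tolower(l))
    dirs <- sub("(?i)^partly\\s+", "", l, perl = TRUE)
    parts <- strsplit(dirs, "-")[[1]]
    canon <- orientation_class(toupper(trimws(parts)))
    if (is.na(canon)) return(l)
    if (partly) paste("Partly", canon) else canon
  }, character(1), USE.NAMES = FALSE)
}

#' Run the tendency rule engine over the packaged per-map count table
#'
#' The package ships (in `inst/extdata/table1_fisher_counts.csv`) the
#' per-map Fisher-median orientation counts of the original study: 44
#' horizontal-section maps of P14 rat S1HL cortex, 288 neurons, with each
#' map's published tendency label. This function feeds every row's counts
#' to [map_tendency()] and compares the computed label with the published
#' one.
#'
#' One row ("6 III") is a known discrepancy: its counts satisfy the
#' partly-pair rule for P-V exactly like three other published Partly P-V
#' maps, yet it was published as Undetermined; the engine follows the
#' stated rules and flags the mismatch rather than special-casing it.
#'
#' @param path Optional path to a counts CSV with columns `map_id`,
#'   `layer`, `n_cells`, `P`, `D`, `A`, `V`, `tendency`; defaults to the
#'   packaged table.
#' @return A data frame with the input columns plus `computed` (the
#'   engine's label) and `match` (logical, order-insensitive comparison).
#' @export
validate_table1 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_fisher_counts.csv",
                        package = "arborient", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("map_id", "layer", "n_cells", "P", "D", "A", "V", "tendency")
  stopifnot(all(need %in% names(tab)))
  tab$computed <- vapply(seq_len(nrow(tab)), function(i) {
    map_tendency(c(tab$P[i], tab$D[i], tab$A[i], tab$V[i]), tab$n_cells[i])$label
  }, character(1))
  tab$match <- normalize_tendency_label(tab$computed) ==
    normalize_tendency_label(tab$tendency)
  tab
}
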