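# Orientation-class vocabulary. Pairs: anterior-posterior and
# dorsal-ventral are opposite; the four remaining pairs are contiguous.
PAIR_CLASSES <- c("A-V", "A-D", "A-P", "D-P", "D-V", "P-V")
OPPOSITE_PAIRS <- c("A-P", "D-V")
CONTIGUOUS_PAIRS <- setdiff(PAIR_CLASSES, OPPOSITE_PAIRS)
TRIPLE_CLASSES <- c("P-V-A", "P-D-A", "P-D-V", "D-V-A")
DLRM_CLASSES <- c("P", "D", "A", "V", PAIR_CLASSES, TRIPLE_CLASSES, "Und.")

# canonical class label for a set of direction abbreviations
orientation_class <- function(abbrevs) {
  if (!length(abbrevs)) return("Und.")
  key <- paste(sort(abbrevs), collapse = "")
  lookup <- c(P = "P", D = "D", A = "A", V = "V",
              AV = "A-V", AD = "A-D", AP = "A-P", DP = "D-P", DV = "D-V",
              PV = "P-V", APV = "P-V-A", ADP = "P-D-A", DPV = "P-D-V",
              ADV = "D-V-A")
  unname(lookup[key])
}

#' Dendritic length ratios per anatomical sector
#'
#' The core DLRM quantities for one neuron: `TL`, the fraction of the
#' neuron's total dendritic length (0.5 um sample points) falling in each
#' sector; `PS`, each sector's arc fraction; and their ratio `TL/PS`. A
#' ratio above 1 means the sector holds more dendrite than its share of
#' the circle would predict under uniform growth.
#'
#' Because both `TL` and `PS` sum to 1, the `PS`-weighted ratios always
#' sum to 1, so at most three sectors can ever have a ratio above 1.
#'
#' @param assignment A `sector_assignment` from [assign_sectors()].
#' @param partition The matching `sector_partition`.
#' @return An object of class `orientation_ratios`: data frame with
#'   columns `direction`, `tl`, `ps`, `ratio` in
#'   posterior/dorsal/anterior/ventral order.
#' @export
compute_ratios <- function(assignment, partition) {
  counts <- assignment$counts[DIRECTIONS]
  total <- sum(counts)
  if (total == 0) stop("no dendrite: the segment cloud is empty")
  ps <- sector_fractions(partition)[DIRECTIONS]
  out <- data.frame(direction = DIRECTIONS,
                    tl = as.numeric(counts) / total,
                    ps = as.numeric(ps),
                    stringsAsFactors = FALSE)
  out$ratio <- out$tl / out$ps
  stopifnot(abs(sum(out$tl) - 1) < 1e-9,
            abs(sum(out$ps) - 1) < 1e-9,
            abs(sum(out$ps * out$ratio) - 1) < 1e-9,
            sum(out$ratio > 1) <= 3)
  class(out) <- c("orientation_ratios", "data.frame")
  out
}

#' Classify one neuron's growth-orientation preference (DLRM)
#'
#' A direction is *preferred* when its `TL/PS` ratio exceeds the threshold
#' `t`, and only *weakly* indicated when the ratio lies strictly between 1
#' and `t`. Both rules are strict: a ratio exactly equal to `t` is not
#' preferred and a ratio exactly 1 is not weak. The preferred set (0 to 3
#' directions) determines the orientation type:
#' * empty — `undetermined`
#' * one direction — `single`
#' * two adjacent directions (A-V, A-D, D-P, P-V) — `contiguous`
#' * two facing directions (A-P, D-V) — `opposite`
#' * three directions — `triple`
#'
#' @param ratios An `orientation_ratios` from [compute_ratios()].
#' @param t Threshold, a single number > 1 (the study grid is 1.1, 1.2,
#'   1.3).
#' @return An object of class `orientation_call`: list with `threshold`,
#'   `preferred` and `weak` (character vectors of abbreviations P/D/A/V),
#'   `type`, and `class` (canonical class label, e.g. `"A-V"` or
#'   `"Und."`).
#' @export
classify_neuron <- function(ratios, t) {
  stopifnot(is.numeric(t), length(t) == 1, t > 1)
  ab <- DIR_ABBREV[ratios$direction]
  preferred <- unname(ab[ratios$ratio > t])
  weak <- unname(ab[ratios$ratio > 1 & ratios$ratio < t])
  cls <- orientation_class(preferred)
  type <- switch(as.character(length(preferred)),
                 "0" = "undetermined",
                 "1" = "single",
                 "2" = if (cls %in% OPPOSITE_PAIRS) "opposite" else "contiguous",
                 "3" = "triple")
  structure(list(threshold = t, preferred = preferred, weak = weak,
                 type = type, class = cls),
            class = "orientation_call")
}

#' @export
print.orientation_call <- function(x, ...) {
  cat(sprintf("DLRM call at t = %.2f: %s (%s)\n", x$threshold, x$class, x$type))
  if (length(x$weak))
    cat("  weak (1 < ratio < t):", paste(x$weak, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate DLRM calls for a group of neurons
#'
#' Counts neurons per orientation class for each threshold, grouped by a
#' key (typically the map id or the cortical layer). The class columns
#' are the four single directions, the six pairs, the four triples, and
#' `Und.`; within each group and threshold they sum to the neuron count.
#'
#' @param calls A data frame with one row per neuron per threshold,
#'   holding at least columns `threshold`, `class`, and the grouping
#'   column; [analyze_map()] produces one.
#' @param group Name of the grouping column (e.g. `"map_id"` or
#'   `"layer"`).
#' @return A data frame with columns `group`, `n`, `threshold`, and one
#'   count column per orientation class.
#' @export
summarize_group <- function(calls, group = "map_id") {
  stopifnot(group %in% names(calls), all(c("threshold", "class") %in% names(calls)))
  if (anyNA(calls$class) || !all(calls$class %in% DLRM_CLASSES))
    stop("unknown orientation class in 'calls'")
  combos <- unique(calls[, c(group, "threshold")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    g <- combos[[group]][i]; t <- combos$threshold[i]
    sub <- calls[calls[[group]] == g & calls$threshold == t, ]
    cnt <- table(factor(sub$class, levels = DLRM_CLASSES))
    cbind(data.frame(group = g, n = nrow(sub), threshold = t,
                     stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(cnt))))
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- group
  out[order(out[[group]], out$threshold), , drop = FALSE]
}
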