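# a sector_assignment with prescribed counts over a symmetric frame
fake_assignment <- function(P, D, A, V) {
  structure(list(counts = c(posterior = P, dorsal = D, anterior = A,
                            ventral = V),
                 labels = NULL, angles = NULL, n_skipped = 0L),
            class = "sector_assignment")
}
sym_part <- function() build_partition(c(0, 0), symmetric_frame())

test_that("ratios follow TL/PS with the conservation identities", {
  part <- sym_part()
  r <- compute_ratios(fake_assignment(25, 25, 25, 25), part)
  expect_equal(r$ratio, rep(1, 4))

  r <- compute_ratios(fake_assignment(0, 0, 100, 0), part)
  expect_equal(r$ratio[r$direction == "anterior"], 4)
  expect_equal(sum(r$ratio == 0), 3)

  r <- compute_ratios(fake_assignment(10, 15, 45, 30), part)
  expect_equal(r$tl, c(0.10, 0.15, 0.45, 0.30))
  expect_equal(r$ratio, c(0.4, 0.6, 1.8, 1.2))
  expect_equal(sum(r$ps * r$ratio), 1, tolerance = 1e-12)

  expect_error(compute_ratios(fake_assignment(0, 0, 0, 0), part),
               "no dendrite")
})

test_that("classification applies strict thresholds and the adjacency typing", {
  part <- sym_part()
  r <- compute_ratios(fake_assignment(10, 15, 45, 30), part)
  # ratios (P, D, A, V) = (0.4, 0.6, 1.8, 1.2)
  c13 <- classify_neuron(r, 1.3)
  expect_equal(c13$preferred, "A")
  expect_equal(c13$type, "single")
  expect_equal(c13$weak, "V")
  c11 <- classify_neuron(r, 1.1)
  expect_setequal(c11$preferred, c("A", "V"))
  expect_equal(c11$type, "contiguous")
  expect_equal(c11$class, "A-V")

  flat <- compute_ratios(fake_assignment(25, 25, 25, 25), part)
  for (t in c(1.1, 1.2, 1.3)) {
    call <- classify_neuron(flat, t)
    expect_equal(call$type, "undetermined")
    expect_length(call$preferred, 0)
    expect_length(call$weak, 0)   # ratio exactly 1 is not weak
  }

  # ratio exactly t is not preferred (strict rule)
  r2 <- compute_ratios(fake_assignment(13, 9, 9, 9), part)  # ratio_P = 1.3
  expect_length(classify_neuron(r2, 1.3)$preferred, 0)
  expect_equal(classify_neuron(r2, 1.2)$preferred, "P")

  # opposite and triple types
  opp <- compute_ratios(fake_assignment(40, 5, 50, 5), part)
  expect_equal(classify_neuron(opp, 1.3)$type, "opposite")
  expect_equal(classify_neuron(opp, 1.3)$class, "A-P")
  tri <- compute_ratios(fake_assignment(30, 33, 35, 2), part)
  expect_equal(classify_neuron(tri, 1.1)$type, "triple")
  expect_equal(classify_neuron(tri, 1.1)$class, "P-D-A")

  expect_error(classify_neuron(r, 1), "t > 1")
})

test_that("preferred sets are nested across thresholds on random neurons", {
  set.seed(111)
  part <- sym_part()
  for (i in 1:300) {
    counts <- as.vector(stats::rmultinom(1, sample(50:2000, 1), runif(4, 0.1, 1)))
    if (sum(counts) == 0) next
    r <- compute_ratios(do.call(fake_assignment, as.list(counts)), part)
    p11 <- classify_neuron(r, 1.1)$preferred
    p12 <- classify_neuron(r, 1.2)$preferred
    p13 <- classify_neuron(r, 1.3)$preferred
    expect_true(all(p13 %in% p12) && all(p12 %in% p11))
    expect_lte(length(p11), 3)   # never all four directions
    expect_equal(sum(r$ps * r$ratio), 1, tolerance = 1e-9)
  }
})

test_that("group summaries partition neurons over classes per threshold", {
  calls <- data.frame(
    map_id = rep("m1", 6), threshold = rep(1.1, 6),
    class = c("A", "A", "A", "A", "A", "A"))
  tab <- summarize_group(calls, "map_id")
  expect_equal(tab$A, 6)
  cls_cols <- setdiff(names(tab), c("map_id", "n", "threshold"))
  expect_equal(sum(tab[, cls_cols]), 6)

  set.seed(112)
  part <- sym_part()
  rows <- do.call(rbind, lapply(1:30, function(i) {
    counts <- as.vector(stats::rmultinom(1, 400, runif(4, 0.2, 1)))
    r <- compute_ratios(do.call(fake_assignment, as.list(counts)), part)
    do.call(rbind, lapply(c(1.1, 1.2, 1.3), function(t) {
      data.frame(map_id = sprintf("m%d", (i - 1) %% 3 + 1), threshold = t,
                 class = classify_neuron(r, t)$class)
    }))
  }))
  tab <- summarize_group(rows, "map_id")
  class_cols <- setdiff(names(tab), c("map_id", "n", "threshold"))
  expect_true(all(rowSums(tab[, class_cols]) == tab$n))
  # undetermined counts never decrease as t rises
  for (m in unique(tab$map_id)) {
    und <- tab$Und.[tab$map_id == m][order(tab$threshold[tab$map_id == m])]
    expect_true(all(diff(und) >= 0))
  }
  expect_error(summarize_group(data.frame(map_id = "m", threshold = 1.1,
                                          class = "bogus")),
               "unknown orientation class")
})

test_that("a synthetic map with an anterior-biased majority is modally A", {
  set.seed(113)
  cfg <- synthetic_config(seed = 113)
  part <- sym_part()
  classes <- vapply(1:30, function(i) {
    bias <- if (i <= 20) data.frame(mu = pi, kappa = 4, w = 1)
            else data.frame(mu = 0, kappa = 0, w = 1)
    arb <- generate_neuron(c(0, 0), cfg, bias = bias)
    cl <- resample_arbor(arb, step = 0.5)
    classify_neuron(compute_ratios(assign_sectors(cl, part), part), 1.1)$class
  }, character(1))
  tab <- sort(table(classes), decreasing = TRUE)
  expect_identical(names(tab)[1], "A")
})
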