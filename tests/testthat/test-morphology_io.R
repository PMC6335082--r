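test_that("read_swc extracts basal polylines and filters other types", {
  arb <- read_swc(swc_straight10())
  expect_s3_class(arb, "arbor")
  expect_length(arb$branches, 1)
  expect_equal(branch_length(arb$branches[[1]]), 10)
  expect_equal(arb$soma, c(0, 0, 0))

  # axon (type 2) nodes are dropped, basal (type 3) kept
  mixed <- write_swc_fixture(c(
    "1 1 0 0 0 5 -1",
    "2 2 0 5 0 1 1",
    "3 2 0 10 0 1 2",
    "4 3 5 0 0 1 1",
    "5 3 10 0 0 1 4"))
  arb <- read_swc(mixed)
  expect_length(arb$branches, 1)
  expect_equal(arb$branches[[1]][, 1], c(0, 5, 10))
})

test_that("read_swc splits bifurcations into unbranched chains anchored at the fork", {
  y_shape <- write_swc_fixture(c(
    "1 1 0 0 0 5 -1",
    "2 3 5 0 0 1 1",
    "3 3 10 5 0 1 2",
    "4 3 10 -5 0 1 2"))
  arb <- read_swc(y_shape)
  expect_length(arb$branches, 3)
  lens <- sort(vapply(arb$branches, branch_length, numeric(1)))
  expect_equal(lens, c(5, sqrt(50), sqrt(50)))
  # daughters anchor at the fork node, not the soma
  anchors <- t(vapply(arb$branches, function(b) b[1, ], numeric(3)))
  expect_equal(sum(anchors[, 1] == 5), 2)
})

test_that("read_swc reports malformed input with line numbers", {
  cyc <- write_swc_fixture(c(
    "1 1 0 0 0 5 -1",
    "2 3 5 0 0 1 3",
    "3 3 10 0 0 1 2"))
  expect_error(read_swc(cyc), "cyclic")
  no_soma <- write_swc_fixture(c("1 3 0 0 0 1 -1", "2 3 5 0 0 1 1"))
  expect_error(read_swc(no_soma), "missing soma")
  short_row <- write_swc_fixture(c("1 1 0 0 0 5 -1", "2 3 5 0 0 1"))
  expect_error(read_swc(short_row), "line 3")
  orphan <- write_swc_fixture(c("1 1 0 0 0 5 -1", "2 3 5 0 0 1 9"))
  expect_error(read_swc(orphan), "parent 9")
  dup <- write_swc_fixture(c("1 1 0 0 0 5 -1", "1 3 5 0 0 1 1"))
  expect_error(read_swc(dup), "duplicate")
})

test_that("multi-point somata collapse to their centroid", {
  three_pt <- write_swc_fixture(c(
    "1 1 0 1 0 5 -1",
    "2 1 1 -1 0 5 1",
    "3 1 -1 -1 0 5 1",
    "4 3 5 0 0 1 1"))
  expect_equal(read_swc(three_pt)$soma, c(0, -1 / 3, 0))
})

test_that("resampling emits floor(L/step) points per branch", {
  arb <- read_swc(swc_straight10())
  cloud <- resample_arbor(arb, step = 0.5)
  expect_equal(nrow(cloud), 20)
  expect_equal(cloud$x, seq(0.5, 10, by = 0.5))
  expect_equal(cloud$dist, cloud$x)

  # residual below one step yields nothing
  stub <- list(rbind(c(0, 0, 0), c(0.3, 0, 0)))
  expect_equal(nrow(resample_arbor(stub, step = 0.5)), 0)
  expect_error(resample_arbor(arb, step = 0), "positive")
  expect_error(resample_arbor(arb, step = -1), "positive")
})

test_that("L-shaped branch resamples with the corner exactly at the bend", {
  ell <- list(rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0)))
  cloud <- resample_arbor(ell, step = 0.5)
  expect_equal(nrow(cloud), 20)
  expect_equal(sum(cloud$y == 0), 10)   # 10 samples on the +x leg
  expect_equal(sum(cloud$x == 5 & cloud$y > 0), 10)
  expect_true(any(cloud$x == 5 & cloud$y == 0))  # the corner, arc length 5.0
  # against the vertex-walk oracle
  oracle <- oracle_resample_branch(ell[[1]], 0.5)
  expect_equal(unname(as.matrix(cloud[, c("x", "y")])), unname(oracle[, 1:2]),
               tolerance = 1e-9)
})

test_that("point counts match the cumulative-arc-length oracle on random polylines", {
  set.seed(61)
  for (i in 1:40) {
    n_br <- sample(1:5, 1)
    brs <- replicate(n_br, random_polyline(sample(3:8, 1)), simplify = FALSE)
    step <- runif(1, 0.3, 2)
    cloud <- resample_arbor(brs, step = step)
    lens <- vapply(brs, branch_length, numeric(1))
    expect_equal(nrow(cloud), sum(floor(lens / step + 1e-9)))
    oracle <- do.call(rbind, lapply(brs, oracle_resample_branch, step = step))
    expect_equal(nrow(cloud), nrow(oracle))
    expect_equal(unname(as.matrix(cloud[, c("x", "y")])), unname(oracle[, 1:2]),
                 tolerance = 1e-6)
    # represented length never exceeds the true length, within one step/branch
    expect_lte(nrow(cloud) * step, sum(lens) + 1e-9)
    expect_lt(sum(lens) - nrow(cloud) * step, step * length(brs))
  }
})

test_that("projection is idempotent for planar arbors", {
  set.seed(62)
  flat <- replicate(3, {
    p <- random_polyline(5); p[, 3] <- 0; p
  }, simplify = FALSE)
  c3 <- resample_arbor(flat, step = 0.5)
  c2 <- resample_arbor(flat, step = 0.5, planar_arclength = TRUE)
  expect_equal(c3$x, c2$x)
  expect_equal(c3$y, c2$y)
})

test_that("3-D and planar arc-length modes differ for tilted branches", {
  tilted <- list(rbind(c(0, 0, 0), c(30, 0, 40)))  # 50 um in 3-D, 30 in-plane
  expect_equal(nrow(resample_arbor(tilted, step = 1)), 50)
  expect_equal(nrow(resample_arbor(tilted, step = 1, planar_arclength = TRUE)), 30)
})

test_that("read_map validates structure and rejects broken documents", {
  neurons <- list(list(id = "n1", layer = "II", swc = "n1.swc", soma = c(0, 0)),
                  list(id = "n2", layer = "Va", swc = "n2.swc", soma = c(10, 5)))
  m <- read_map(write_map_fixture(neurons))
  expect_s3_class(m, "map_document")
  expect_length(m$neurons, 2)
  expect_named(m$reference_points,
               c("posterior", "anterior", "dorsal", "ventral"))

  expect_error(read_map(write_map_fixture(neurons, drop_point = "dorsal")),
               "dorsal")
  dup <- list(list(id = "n1", layer = "II", swc = "a.swc", soma = c(0, 0)),
              list(id = "n1", layer = "II", swc = "b.swc", soma = c(1, 1)))
  expect_error(read_map(write_map_fixture(dup)), "duplicate neuron id")
  expect_error(read_map(write_map_fixture(list())), "at least one neuron")
  bad_layer <- list(list(id = "n1", layer = "VII", swc = "a.swc", soma = c(0, 0)))
  expect_error(read_map(write_map_fixture(bad_layer)), "layer")
})

test_that("soma-relative reconstructions are translated into the map frame", {
  arb <- read_swc(swc_straight10())          # soma at origin, branch along +x
  cloud <- resample_arbor(arb, step = 0.5, soma = c(100, 50))
  expect_equal(cloud$x, 100 + seq(0.5, 10, by = 0.5))
  expect_equal(unique(cloud$y), 50)
  expect_equal(max(cloud$dist), 10)
})
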