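test_that("neighbor graph follows the diagonal-scaled distance rule", {
  # two boxes of diagonal d at half the connection radius: connected
  d <- sqrt(2) * 16
  mk <- function(dist) detection_set("img", data.frame(
    cx = c(0, dist), cy = 0, w = 16, h = 16, confidence = 1,
    label = "vessel", stringsAsFactors = FALSE))
  g_near <- build_neighbor_graph(mk(0.5 * d * 1.25), radius_factor = 1.25)
  expect_equal(nrow(g_near$edges), 1)
  g_far <- build_neighbor_graph(mk(2 * d * 1.25), radius_factor = 1.25)
  expect_equal(nrow(g_far$edges), 0)

  # non-vessel and low-confidence boxes are not nodes
  ds <- detection_set("img", data.frame(
    cx = c(0, 5, 10), cy = 0, w = 16, h = 16,
    confidence = c(1, 1, 0.1), label = c("vessel", "debris", "vessel"),
    stringsAsFactors = FALSE))
  g <- build_neighbor_graph(ds, min_confidence = 0.25)
  expect_equal(nrow(g$nodes), 1)
  expect_equal(nrow(build_neighbor_graph(detection_set("img"))$nodes), 0)
})

test_that("neighbor graph equals the all-pairs brute-force rule", {
  set.seed(51)
  for (rep in 1:5) {
    n <- 50
    b <- data.frame(cx = runif(n, 0, 300), cy = runif(n, 0, 300),
                    w = runif(n, 8, 24), h = runif(n, 8, 24),
                    confidence = 1, label = "vessel",
                    stringsAsFactors = FALSE)
    rf <- 1.25
    g <- build_neighbor_graph(detection_set("img", b), rf)
    want <- list()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dist <- sqrt((b$cx[i] - b$cx[j])^2 + (b$cy[i] - b$cy[j])^2)
      lim <- rf * (sqrt(b$w[i]^2 + b$h[i]^2) + sqrt(b$w[j]^2 + b$h[j]^2)) / 2
      if (dist <= lim && dist > 0)
        want[[length(want) + 1L]] <- c(i, j, dist)
    }
    want <- do.call(rbind, want)
    expect_equal(nrow(g$edges), nrow(want))
    expect_equal(g$edges$i, want[, 1])
    expect_equal(g$edges$j, want[, 2])
    expect_equal(g$edges$weight, want[, 3])
  }
})

test_that("edge weights always equal the endpoint distances", {
  set.seed(52)
  g <- random_connected_graph(8, 4)
  xi <- g$nodes$x[g$edges$i]; yi <- g$nodes$y[g$edges$i]
  xj <- g$nodes$x[g$edges$j]; yj <- g$nodes$y[g$edges$j]
  expect_equal(g$edges$weight, sqrt((xi - xj)^2 + (yi - yj)^2))
  expect_error(vessel_graph(g$nodes, data.frame(i = 1, j = 1)), "self-loops")
})

test_that("false-connection filter keeps supported edges and drops gaps", {
  img <- two_bar_image()
  # nodes along both bars plus the vertical inter-bar edge
  nodes <- data.frame(id = 1:4, x = c(30, 60, 30, 60), y = c(22, 22, 58, 58))
  edges <- data.frame(i = c(1, 3, 1), j = c(2, 4, 3))
  g <- vessel_graph(nodes, edges)
  kept <- filter_false_connections(g, img, support_quantile = 0.8,
                                   min_support = 0.7)
  expect_equal(nrow(kept$nodes), 4)           # node set unchanged
  key <- paste(kept$edges$i, kept$edges$j)
  expect_true(all(c("1 2", "3 4") %in% key))  # intra-bar edges kept
  expect_false("1 3" %in% key)                # inter-bar gap removed

  # support fraction of the gap edge agrees with a pixel-walk oracle
  mask <- vesseltrace:::foreground_mask(img, 0.8)
  ys <- seq(22, 58); xs <- rep(30, length(ys))
  oracle <- mean(mask[cbind(ys + 1, xs + 1)])
  gap_row <- which(g$edges$i == 1 & g$edges$j == 3)
  expect_equal(vesseltrace:::edge_support(g, gap_row, mask), oracle)

  # blank image: every edge removed; edgeless graph passes through
  blank <- image2d(matrix(0, 80, 120), 1, id = "twobar")
  expect_equal(nrow(filter_false_connections(g, blank)$edges), 0)
  empty <- vessel_graph(nodes)
  expect_identical(filter_false_connections(empty, img), empty)
})

test_that("remove_cycles keeps the minimum spanning tree of a triangle", {
  nodes <- data.frame(id = 1:3, x = c(0, 3, 0), y = c(0, 0, 4))
  g <- vessel_graph(nodes, data.frame(i = c(1, 1, 2), j = c(2, 3, 3)))
  # weights: 1-2 = 3, 1-3 = 4, 2-3 = 5
  mst <- remove_cycles(g)
  expect_equal(sort(mst$edges$weight), c(3, 4))
  # already-acyclic input is a fixed point
  expect_equal(remove_cycles(mst)$edges, mst$edges)
})

test_that("remove_cycles matches exhaustive enumeration and igraph", {
  skip_if_not_installed("igraph")
  set.seed(53)
  for (rep in 1:15) {
    g <- random_connected_graph(sample(4:7, 1), sample(1:3, 1))
    mst <- remove_cycles(g)
    n <- nrow(g$nodes)
    expect_equal(nrow(mst$edges), n - 1)          # E = N - C, one component
    expect_equal(sum(mst$edges$weight), brute_force_mst_weight(g))
    ig <- igraph::graph_from_data_frame(
      g$edges[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = g$nodes$id))
    igraph::E(ig)$weight <- g$edges$weight
    expect_equal(sum(mst$edges$weight),
                 sum(igraph::E(igraph::mst(ig))$weight))
  }
})

test_that("graph_to_polylines splits at branches and conserves length", {
  # path of 4 collinear nodes spaced 10 px: one polyline of length 30
  nodes <- data.frame(id = 1:4, x = c(0, 10, 20, 30), y = 0)
  path <- vessel_graph(nodes, data.frame(i = 1:3, j = 2:4))
  polys <- graph_to_polylines(path)
  expect_length(polys, 1)
  expect_equal(polyline_length(polys[[1]]), 30)

  # Y-shaped tree: 3 polylines totaling 30
  ynodes <- data.frame(id = 1:4, x = c(0, 10, 0, -10), y = c(0, 0, 10, 0))
  yg <- vessel_graph(ynodes, data.frame(i = c(1, 1, 1), j = c(2, 3, 4)))
  ypolys <- graph_to_polylines(yg)
  expect_length(ypolys, 3)
  expect_equal(sum(vapply(ypolys, polyline_length, numeric(1))), 30)

  # cyclic input is rejected with advice
  tri <- vessel_graph(data.frame(id = 1:3, x = c(0, 3, 0), y = c(0, 0, 4)),
                      data.frame(i = c(1, 1, 2), j = c(2, 3, 3)))
  expect_error(graph_to_polylines(tri), "remove_cycles")

  # random forests: sum of polyline lengths equals total edge weight
  set.seed(54)
  for (rep in 1:30) {
    f <- random_forest_graph(sample(5:14, 1))
    polys <- graph_to_polylines(f)
    total <- sum(vapply(polys, polyline_length, numeric(1)))
    expect_equal(total, sum(f$edges$weight), tolerance = 1e-9)
    # every edge appears exactly once: edge count equals total point gaps
    expect_equal(sum(vapply(polys, function(p) nrow(p$points) - 1L,
                            integer(1))),
                 nrow(f$edges))
  }
})

test_that("reconstruct composes the stages deterministically", {
  # empty detections: empty polyline list
  blank <- image2d(matrix(0, 50, 50), 1, id = "img")
  expect_length(reconstruct(detection_set("img"), blank), 0)

  # image id mismatch is rejected
  expect_error(reconstruct(detection_set("other"), blank), "image")

  # single detection box: a point has no extent
  one <- detection_set("img", data.frame(cx = 25, cy = 25, w = 16, h = 16,
                                         confidence = 1, label = "vessel"))
  expect_length(reconstruct(one, blank), 0)

  # noise-free oracle on a single-vessel scene: one polyline within one
  # stride of the true length
  p <- scene_params(field_px = c(256, 128), n_seeds = 0, n_debris = 0,
                    n_out_of_plane = 0, noise_sd = 0.01, seed = 3)
  pl <- polyline(rbind(c(30, 64), c(230, 64)))
  truth <- annotation_set("vessel1", list(pl), 1.3)
  img <- render_scene(truth, p)
  dets <- oracle_detect(truth, 32, 16, seed = 1)
  polys <- reconstruct(dets, img)
  expect_length(polys, 1)
  expect_lt(abs(polyline_length(polys[[1]]) - 200), 16)

  # determinism
  expect_identical(polys, reconstruct(dets, img))
})

test_that("the pipeline never adds nodes or edges and ends acyclic", {
  set.seed(55)
  p <- small_scene_params(seed = 19)
  sc <- generate_scene(p, "mono")
  dets <- oracle_detect(sc$truth, 32, 16, jitter_sd = 2, miss_rate = 0.1,
                        seed = 5)
  g1 <- build_neighbor_graph(dets)
  g2 <- filter_false_connections(g1, sc$image)
  g3 <- remove_cycles(g2)
  expect_lte(nrow(g2$edges), nrow(g1$edges))
  expect_lte(nrow(g3$edges), nrow(g2$edges))
  expect_equal(nrow(g2$nodes), nrow(g1$nodes))
  expect_equal(nrow(g3$nodes), nrow(g1$nodes))
  comp <- vesseltrace:::graph_components(g3)
  expect_equal(nrow(g3$edges), nrow(g3$nodes) - length(unique(comp)))
})

test_that("jitter-kinked reconstructions stay close to the true length", {
  # center jitter of 2 px on a straight 300 px vessel: kinks lengthen each
  # link but offset on average; median recovered length within 10%
  p <- scene_params(field_px = c(360, 80), n_seeds = 0, n_debris = 0,
                    n_out_of_plane = 0, noise_sd = 0.01, seed = 4)
  pl <- polyline(rbind(c(30, 40), c(330, 40)))
  truth <- annotation_set("kink", list(pl), 1.3)
  img <- render_scene(truth, p)
  errs <- vapply(1:100, function(s) {
    dets <- oracle_detect(truth, 32, 16, jitter_sd = 2, seed = s)
    rec <- total_vessel_length(reconstruct(dets, img), 1)
    abs(rec - 300) / 300
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})
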