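# Fixture builders shared across tests; everything is generated in code.

# Straight horizontal vessel polyline of given axis length.
straight_polyline <- function(length_px = 100, y = 40, x0 = 30,
                              label = "vessel") {
  polyline(rbind(c(x0, y), c(x0 + length_px, y)), label)
}

# Image with one hard-edged bright horizontal bar.
bar_image <- function(width = 120, height = 60, bar_rows = 28:32,
                      bar_cols = 11:110, value = 1, id = "bar") {
  px <- matrix(0, height, width)
  px[bar_rows, bar_cols] <- value
  image2d(px, 1, "fluorescent", id)
}

# Two parallel bright bars separated by a dark gap (for the
# false-connection filter).
two_bar_image <- function(id = "twobar") {
  px <- matrix(0, 80, 120)
  px[20:24, 11:110] <- 1   # top bar at y ~ 21
  px[56:60, 11:110] <- 1   # bottom bar at y ~ 57
  image2d(px, 1, "fluorescent", id)
}

# Random simply-described polyline with n points (no repeats).
random_polyline <- function(n = 5, label = "vessel") {
  repeat {
    pts <- cbind(cumsum(runif(n, 0.5, 10)), cumsum(rnorm(n, 0, 4)))
    d <- diff(pts)
    if (all(rowSums(d^2) > 0)) return(polyline(pts, label))
  }
}

# Random connected vessel_graph with n nodes and a few extra edges.
random_connected_graph <- function(n = 6, extra = 2) {
  nodes <- data.frame(id = seq_len(n),
                      x = runif(n, 0, 100), y = runif(n, 0, 100))
  # random spanning tree then extra chords
  perm <- sample(n)
  edges <- data.frame(i = perm[-1],
                      j = perm[vapply(2:n, function(k) sample(k - 1, 1),
                                      integer(1))])
  all_pairs <- t(combn(n, 2))
  have <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
  avail <- which(!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have))
  if (extra > 0 && length(avail) > 0) {
    pick <- sample(avail, min(extra, length(avail)))
    edges <- rbind(edges, data.frame(i = all_pairs[pick, 1],
                                     j = all_pairs[pick, 2]))
  }
  vessel_graph(nodes, edges)
}

# Exhaustive minimum spanning tree weight by enumerating all edge subsets
# of size n - 1 (independent oracle for remove_cycles on small graphs).
brute_force_mst_weight <- function(g) {
  n <- nrow(g$nodes)
  e <- g$edges
  stopifnot(nrow(e) >= n - 1)
  combs <- combn(nrow(e), n - 1)
  best <- Inf
  for (k in seq_len(ncol(combs))) {
    sub <- e[combs[, k], ]
    # spanning + acyclic check by union-find
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    ok <- TRUE
    for (r in seq_len(nrow(sub))) {
      ra <- find(match(sub$i[r], g$nodes$id))
      rb <- find(match(sub$j[r], g$nodes$id))
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok) best <- min(best, sum(sub$weight))
  }
  best
}

# Random spanning forest over n nodes (for length-conservation checks).
random_forest_graph <- function(n = 10) {
  nodes <- data.frame(id = seq_len(n),
                      x = runif(n, 0, 200), y = runif(n, 0, 200))
  edges <- data.frame(i = integer(0), j = integer(0))
  # attach each node (after the first few roots) to a random earlier node
  roots <- max(1L, rbinom(1, 2, 0.5) + 1L)
  for (k in seq.int(roots + 1L, n)) {
    if (k > n) break
    edges <- rbind(edges, data.frame(i = sample(k - 1, 1), j = k))
  }
  vessel_graph(nodes, edges)
}

small_scene_params <- function(...) {
  scene_params(field_px = c(256, 256), n_seeds = 4, n_steps = 40,
               n_debris = 3, n_out_of_plane = 1, ...)
}
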