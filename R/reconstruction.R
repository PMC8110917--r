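#' Weighted undirected graph over detection-box centers
#'
#' Intermediate representation of polyline reconstruction: nodes are box
#' centers, edges carry the Euclidean center distance as weight. The graph
#' is simple (no self-loops, no duplicate edges) and every edge weight
#' equals the distance between its endpoints.
#'
#' @param nodes data frame with columns `id` (1..n), `x`, `y` (pixel
#'   coordinates) and optionally `box` (source box row index).
#' @param edges data frame with columns `i`, `j` (node ids) and optionally
#'   `weight`; weights are recomputed from node coordinates.
#' @return An object of class `vessel_graph`.
#' @export
vessel_graph <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes)
  if (nrow(nodes) > 0 && !all(c("id", "x", "y") %in% names(nodes)))
    stop_validation("nodes must have columns id, x, y")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(i = integer(0), j = integer(0), weight = numeric(0))
  } else {
    edges <- as.data.frame(edges)
    ii <- pmin(edges$i, edges$j)
    jj <- pmax(edges$i, edges$j)
    if (any(ii == jj)) stop_validation("self-loops are not allowed")
    edges <- data.frame(i = ii, j = jj)
    edges <- unique(edges)
    xi <- nodes$x[match(edges$i, nodes$id)]
    yi <- nodes$y[match(edges$i, nodes$id)]
    xj <- nodes$x[match(edges$j, nodes$id)]
    yj <- nodes$y[match(edges$j, nodes$id)]
    edges$weight <- sqrt((xi - xj)^2 + (yi - yj)^2)
    if (any(!is.finite(edges$weight)))
      stop_validation("edge references unknown node id")
    if (any(edges$weight <= 0))
      stop_validation("edges between coincident nodes are not allowed")
    edges <- edges[order(edges$i, edges$j), ]
    rownames(edges) <- NULL
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf("<vessel_graph> %d nodes, %d edges, total weight %.2f px\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

graph_components <- function(g) {
  n <- nrow(g$nodes)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  pos <- match(c(g$edges$i, g$edges$j), g$nodes$id)
  ei <- pos[seq_len(nrow(g$edges))]
  ej <- pos[nrow(g$edges) + seq_len(nrow(g$edges))]
  for (k in seq_len(nrow(g$edges))) {
    ra <- find(ei[k]); rb <- find(ej[k])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

#' Link detection boxes into a neighbor graph
#'
#' First stage of polyline reconstruction. Boxes labeled `vessel` whose
#' confidence reaches `min_confidence` become nodes at their centers; two
#' nodes are connected when their center distance is at most
#' `radius_factor` times the mean of the two boxes' diagonals. The rule is
#' scale-free in box size: at the default 50%-overlap region stride,
#' consecutive boxes of the same vessel always connect, while long-range
#' links are suppressed.
#'
#' @param detections a [detection_set].
#' @param radius_factor positive multiplier of the mean box diagonal.
#' @param min_confidence minimum box confidence in `[0, 1]`.
#' @return A [vessel_graph] (empty when no box is eligible).
#' @export
build_neighbor_graph <- function(detections, radius_factor = 1.25,
                                 min_confidence = 0.25) {
  stopifnot(inherits(detections, "detection_set"))
  assert_scalar_number(radius_factor, "radius_factor", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(min_confidence, "min_confidence", lower = 0, upper = 1)
  b <- detections$boxes
  keep <- which(b$label == "vessel" & b$confidence >= min_confidence)
  b <- b[keep, , drop = FALSE]
  n <- nrow(b)
  nodes <- data.frame(id = seq_len(n), x = b$cx, y = b$cy, box = keep)
  if (n < 2L) return(vessel_graph(nodes))
  diag_len <- sqrt(b$w^2 + b$h^2)
  dx <- outer(b$cx, b$cx, "-"); dy <- outer(b$cy, b$cy, "-")
  dist <- sqrt(dx^2 + dy^2)
  lim <- radius_factor * outer(diag_len, diag_len, "+") / 2
  adj <- which(dist <= lim & upper.tri(dist) & dist > 0, arr.ind = TRUE)
  vessel_graph(nodes, data.frame(i = adj[, 1], j = adj[, 2]))
}

#' Remove proximity edges without image support
#'
#' Second stage: proximity alone suggests false connections between
#' distinct vessels that happen to run close to each other. Each candidate
#' edge is tested against the image content: the straight segment between
#' its endpoints is sampled at 1 px arc steps and the edge is kept only
#' when at least `min_support` of the samples fall on foreground (pixels
#' above the `support_quantile` intensity quantile of the equalized
#' image). Edges crossing dark gaps between vessels are removed; the node
#' set is unchanged.
#'
#' @param graph a [vessel_graph].
#' @param image the [image2d] the detections came from.
#' @param support_quantile foreground intensity quantile in (0, 1).
#' @param min_support minimum supported fraction in (0, 1].
#' @return A [vessel_graph] whose edges are a subset of the input edges.
#' @export
filter_false_connections <- function(graph, image, support_quantile = 0.8,
                                     min_support = 0.7) {
  stopifnot(inherits(graph, "vessel_graph"), inherits(image, "image2d"))
  assert_scalar_number(support_quantile, "support_quantile", lower = 0,
                       upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(min_support, "min_support", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (nrow(graph$edges) == 0L) return(graph)
  mask <- foreground_mask(image, support_quantile)
  sup <- vapply(seq_len(nrow(graph$edges)), function(k)
    edge_support(graph, k, mask), numeric(1))
  vessel_graph(graph$nodes, graph$edges[sup >= min_support, , drop = FALSE])
}

# Fraction of 1 px arc samples along edge k (endpoints included) landing
# on foreground mask pixels; samples outside the image count as background.
edge_support <- function(graph, k, mask) {
  e <- graph$edges[k, ]
  a <- graph$nodes[match(e$i, graph$nodes$id), ]
  b <- graph$nodes[match(e$j, graph$nodes$id), ]
  len <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  t <- seq(0, 1, length.out = max(2L, ceiling(len) + 1L))
  xs <- round(a$x + t * (b$x - a$x)) + 1L
  ys <- round(a$y + t * (b$y - a$y)) + 1L
  inside <- xs >= 1L & xs <= ncol(mask) & ys >= 1L & ys <= nrow(mask)
  hit <- logical(length(t))
  hit[inside] <- mask[cbind(ys[inside], xs[inside])]
  mean(hit)
}

#' Remove cycles by minimum spanning forest
#'
#' Third stage: neighbor linking plus image-support filtering can still
#' retain cycles (e.g., parallel chains of overlapping boxes along one
#' vessel), which do not represent vessel topology. Per connected
#' component the minimum-weight spanning tree is kept (Kruskal's
#' algorithm, edge weight = center distance, ties broken by lexicographic
#' node-id order for determinism), so the output is an acyclic forest with
#' the node set and component partition preserved and total edge weight
#' minimal among spanning forests.
#'
#' @param graph a [vessel_graph].
#' @return A [vessel_graph] that is a spanning forest of the input.
#' @export
remove_cycles <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  e <- graph$edges
  if (nrow(e) == 0L) return(graph)
  ord <- order(e$weight, e$i, e$j)
  n <- nrow(graph$nodes)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  keep <- logical(nrow(e))
  pi <- match(e$i, graph$nodes$id)
  pj <- match(e$j, graph$nodes$id)
  for (k in ord) {
    ra <- find(pi[k]); rb <- find(pj[k])
    if (ra != rb) {
      parent[ra] <- rb
      keep[k] <- TRUE
    }
  }
  vessel_graph(graph$nodes, e[keep, , drop = FALSE])
}

#' Decompose a spanning forest into polylines
#'
#' Each tree is split into maximal simple paths at branch nodes (degree
#' >= 3); every edge appears in exactly one polyline, so the sum of
#' polyline lengths equals the total forest edge weight exactly. Total
#' vessel length — the quantity of interest — is invariant to the
#' decomposition choice; splitting at branch points additionally yields a
#' branch count for free. Isolated nodes (a single detection with no
#' neighbors has no linear extent) yield no polyline.
#'
#' @param forest an acyclic [vessel_graph], e.g. from [remove_cycles()].
#' @param label label assigned to the produced polylines.
#' @return List of [polyline] objects.
#' @export
graph_to_polylines <- function(forest, label = "vessel") {
  stopifnot(inherits(forest, "vessel_graph"))
  n <- nrow(forest$nodes)
  e <- forest$edges
  comp <- graph_components(forest)
  if (nrow(e) > n - length(unique(comp)))
    stop_validation("graph contains cycles; run remove_cycles() first")
  if (nrow(e) == 0L) return(list())
  pos_i <- match(e$i, forest$nodes$id)
  pos_j <- match(e$j, forest$nodes$id)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[pos_i[k]]] <- c(adj[[pos_i[k]]], k)
    adj[[pos_j[k]]] <- c(adj[[pos_j[k]]], k)
  }
  deg <- lengths(adj)
  used <- logical(nrow(e))
  other_end <- function(k, at) if (pos_i[k] == at) pos_j[k] else pos_i[k]
  paths <- list()
  # walk from every path terminus (degree 1) or branch node (degree >= 3)
  for (v in which(deg == 1L | deg >= 3L)) {
    for (k in adj[[v]]) {
      if (used[k]) next
      cur <- v
      edge <- k
      chain <- cur
      repeat {
        used[edge] <- TRUE
        nxt <- other_end(edge, cur)
        chain <- c(chain, nxt)
        if (deg[nxt] != 2L) break
        edge <- setdiff(adj[[nxt]], which(used))
        edge <- edge[!used[edge]][1]
        if (is.na(edge)) break
        cur <- nxt
      }
      paths[[length(paths) + 1L]] <- chain
    }
  }
  lapply(paths, function(chain)
    polyline(cbind(forest$nodes$x[chain], forest$nodes$y[chain]), label))
}

#' Reconstruct vessel polylines from detections
#'
#' Full reconstruction chain: [build_neighbor_graph()] on the vessel-class
#' boxes, [filter_false_connections()] against the image,
#' [remove_cycles()] to a spanning forest, and [graph_to_polylines()].
#' Deterministic: the same detections and image always give the same
#' polylines.
#'
#' @param detections a [detection_set].
#' @param image the matching [image2d]; `image$id` must equal
#'   `detections$image_id`.
#' @param radius_factor,min_confidence see [build_neighbor_graph()].
#' @param support_quantile,min_support see [filter_false_connections()].
#' @return List of [polyline] objects labeled `vessel`.
#' @export
reconstruct <- function(detections, image, radius_factor = 1.25,
                        min_confidence = 0.25, support_quantile = 0.8,
                        min_support = 0.7) {
  stopifnot(inherits(detections, "detection_set"), inherits(image, "image2d"))
  if (detections$image_id != image$id)
    stop_validation("detections are for image '", detections$image_id,
                    "' but image is '", image$id, "'")
  g <- build_neighbor_graph(detections, radius_factor, min_confidence)
  g <- filter_false_connections(g, image, support_quantile, min_support)
  g <- remove_cycles(g)
  graph_to_polylines(g)
}
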