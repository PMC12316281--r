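# Street network: a planar embedded undirected graph in a local metric CRS.
# Edges are straight segments between node coordinates; GeoJSON polylines are
# split at their vertices on read so this assumption always holds.

#' Construct a street network
#'
#' @param nodes tibble with columns `id` (unique), `x`, `y` (meters).
#' @param edges tibble with columns `from`, `to` (node ids); `length_m` is
#'   computed from coordinates (and validated against a supplied column).
#' @return A `street_network` object carrying the node/edge tables and a
#'   pre-built [igraph::graph_from_data_frame()] used for routing.
#' @export
street_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(
    all(c("id", "x", "y") %in% names(nodes)),
    all(c("from", "to") %in% names(edges))
  )
  nodes$id <- as.character(nodes$id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (anyDuplicated(nodes$id)) {
    abort("duplicate node ids", class = "foodscape_network_error")
  }
  if (!all(c(edges$from, edges$to) %in% nodes$id)) {
    abort("edge endpoints missing from node table", class = "foodscape_network_error")
  }
  idx <- match(edges$from, nodes$id)
  jdx <- match(edges$to, nodes$id)
  len <- sqrt((nodes$x[idx] - nodes$x[jdx])^2 + (nodes$y[idx] - nodes$y[jdx])^2)
  if ("length_m" %in% names(edges) &&
    any(abs(edges$length_m - len) > 1e-6 + 1e-6 * len)) {
    abort("edge length_m inconsistent with endpoint coordinates",
      class = "foodscape_network_error"
    )
  }
  if (any(len <= 0)) {
    abort("zero-length edge (coincident endpoints)", class = "foodscape_network_error")
  }
  edges$length_m <- len
  edges <- dplyr::mutate(edges,
    x1 = nodes$x[idx], y1 = nodes$y[idx],
    x2 = nodes$x[jdx], y2 = nodes$y[jdx]
  )
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")],
    directed = FALSE,
    vertices = nodes[, c("id", "x", "y")]
  )
  igraph::E(g)$weight <- edges$length_m
  structure(
    list(nodes = nodes, edges = edges, graph = g),
    class = "street_network"
  )
}

#' @export
print.street_network <- function(x, ...) {
  cat(
    "<street_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
    " edges, total length ", format(round(sum(x$edges$length_m) / 1000, 1)),
    " km\n",
    sep = ""
  )
  invisible(x)
}

network_bbox <- function(network) {
  c(
    min(network$nodes$x), min(network$nodes$y),
    max(network$nodes$x), max(network$nodes$y)
  )
}

#' Snap a point to the nearest position on the network
#'
#' @param network a [street_network()].
#' @param x,y point coordinates (meters).
#' @param tol_m snap tolerance; beyond it a `foodscape_snap_error` is raised
#'   (homes and anchors were geocoded to addresses, so anything further than
#'   this from a street indicates bad input).
#' @return List with `edge` (row index), `t` (position along edge in 0..1),
#'   `x`, `y` (snapped coordinates) and `dist` (snap distance).
#' @export
snap_point <- function(network, x, y, tol_m = 30) {
  e <- network$edges
  dx <- e$x2 - e$x1
  dy <- e$y2 - e$y1
  L2 <- dx * dx + dy * dy
  t <- pmin(1, pmax(0, ((x - e$x1) * dx + (y - e$y1) * dy) / L2))
  px <- e$x1 + t * dx
  py <- e$y1 + t * dy
  d <- sqrt((x - px)^2 + (y - py)^2)
  i <- which.min(d)
  if (d[i] > tol_m) {
    abort(
      sprintf("point (%.1f, %.1f) is %.1f m from the network (> %g m)", x, y, d[i], tol_m),
      class = "foodscape_snap_error"
    )
  }
  list(edge = i, t = t[i], x = px[i], y = py[i], dist = d[i])
}

# All-pairs shortest-path distances between network nodes (meters), as a
# matrix with node-id dimnames. Computed once per network and reused for
# batch buffer/routing work.
node_distances <- function(network) {
  d <- igraph::distances(network$graph, weights = igraph::E(network$graph)$weight)
  d
}

# Distances from a snapped point to every node: the point sits at arc offset
# a from edge endpoint u and b from v, so d(P, n) = min(a + d(u,n), b + d(v,n)).
snap_node_distances <- function(network, snap, node_dist = NULL) {
  e <- network$edges[snap$edge, ]
  a <- snap$t * e$length_m
  b <- (1 - snap$t) * e$length_m
  if (is.null(node_dist)) {
    d2 <- igraph::distances(network$graph,
      v = c(e$from, e$to),
      weights = igraph::E(network$graph)$weight
    )
    du <- d2[1, ]
    dv <- d2[2, ]
  } else {
    du <- node_dist[e$from, ]
    dv <- node_dist[e$to, ]
  }
  pmin(a + du, b + dv)[network$nodes$id]
}
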