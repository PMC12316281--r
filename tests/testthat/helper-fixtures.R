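# Small in-code fixtures and independent oracles shared across tests.

# straight line network along the x axis: n_nodes nodes, given spacing
line_network <- function(n_nodes = 2, spacing = 2000) {
  nodes <- tibble::tibble(
    id = paste0("n", seq_len(n_nodes)),
    x = (seq_len(n_nodes) - 1) * spacing,
    y = 0
  )
  edges <- tibble::tibble(
    from = nodes$id[-n_nodes],
    to = nodes$id[-1]
  )
  street_network(nodes, edges)
}

# star: k arms of given length from a central node
star_network <- function(k = 4, arm = 300) {
  th <- 2 * pi * (seq_len(k) - 1) / k
  nodes <- tibble::tibble(
    id = c("c", paste0("a", seq_len(k))),
    x = c(0, arm * cos(th)),
    y = c(0, arm * sin(th))
  )
  edges <- tibble::tibble(from = "c", to = paste0("a", seq_len(k)))
  street_network(nodes, edges)
}

# 3-4-5 right triangle: AB = 3, BC = 4, CA = 5
triangle_network <- function(scale = 1) {
  nodes <- tibble::tibble(
    id = c("A", "B", "C"),
    x = c(0, 3, 3) * scale,
    y = c(0, 0, 4) * scale
  )
  edges <- tibble::tibble(from = c("A", "B", "C"), to = c("B", "C", "A"))
  street_network(nodes, edges)
}

# random connected geometric graph with <= n_nodes nodes (straight edges)
random_small_network <- function(n_nodes = 8, extent = 1000) {
  repeat {
    nodes <- tibble::tibble(
      id = paste0("n", seq_len(n_nodes)),
      x = runif(n_nodes, 0, extent),
      y = runif(n_nodes, 0, extent)
    )
    pairs <- t(utils::combn(n_nodes, 2))
    d <- sqrt((nodes$x[pairs[, 1]] - nodes$x[pairs[, 2]])^2 +
      (nodes$y[pairs[, 1]] - nodes$y[pairs[, 2]])^2)
    keep <- runif(nrow(pairs)) < 0.4 & d > 1
    if (sum(keep) < n_nodes - 1) next
    edges <- tibble::tibble(
      from = nodes$id[pairs[keep, 1]],
      to = nodes$id[pairs[keep, 2]]
    )
    net <- street_network(nodes, edges)
    comp <- igraph::components(net$graph)
    if (comp$no == 1) {
      return(net)
    }
  }
}

# brute-force shortest path by exhaustive enumeration of simple paths
brute_shortest <- function(net, from_id, to_id) {
  if (from_id == to_id) {
    return(0)
  }
  adj <- list()
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    adj[[e$from]] <- rbind(adj[[e$from]], c(e$to, e$length_m))
    adj[[e$to]] <- rbind(adj[[e$to]], c(e$from, e$length_m))
  }
  best <- Inf
  recurse <- function(node, visited, len) {
    if (len >= best) {
      return()
    }
    if (node == to_id) {
      best <<- len
      return()
    }
    nb <- adj[[node]]
    if (is.null(nb)) {
      return()
    }
    for (r in seq_len(nrow(nb))) {
      nxt <- nb[r, 1]
      if (!nxt %in% visited) {
        recurse(nxt, c(visited, nxt), len + as.numeric(nb[r, 2]))
      }
    }
  }
  recurse(from_id, from_id, 0)
  best
}

# brute-force reachable network length from a node within radius: sample
# points every `step` meters along each edge and test the enumerated
# shortest distance through either endpoint
brute_reachable_length <- function(net, origin_id, radius, step = 1) {
  dn <- vapply(net$nodes$id, function(n) brute_shortest(net, origin_id, n), 0)
  names(dn) <- net$nodes$id
  total <- 0
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    s <- seq(step / 2, e$length_m, by = step)
    d <- pmin(dn[e$from] + s, dn[e$to] + (e$length_m - s))
    total <- total + step * sum(d <= radius)
  }
  total
}

# exact reachable length from the reachable_subnetwork intervals
pieces_length <- function(pieces) sum(pieces$to_m - pieces$from_m)

# independent point-in-capsule-union test (plain loop, no package geometry)
oracle_inside <- function(segs, px, py) {
  vapply(seq_along(px), function(i) {
    for (j in seq_len(nrow(segs))) {
      x1 <- segs[j, 1]; y1 <- segs[j, 2]; x2 <- segs[j, 3]; y2 <- segs[j, 4]
      r <- segs[j, 5]
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx^2 + dy^2
      t <- if (L2 < 1e-24) 0 else min(1, max(0, ((px[i] - x1) * dx + (py[i] - y1) * dy) / L2))
      d2 <- (px[i] - (x1 + t * dx))^2 + (py[i] - (y1 + t * dy))^2
      if (d2 <= r^2) {
        return(TRUE)
      }
    }
    FALSE
  }, TRUE)
}

# direct IPF iteration on a 2x2 contingency table (row/column target shares)
ipf_2x2_oracle <- function(tab, row_targets, col_targets, iters = 100) {
  w <- tab
  for (i in seq_len(iters)) {
    w <- w * (row_targets * sum(w)) / rowSums(w)
    w <- sweep(w, 2, (col_targets * sum(w)) / colSums(w), `*`)
  }
  w
}

# expand a 2x3 (or 2x2) count table to individual rows
expand_table <- function(tab, xname = "x", yname = "y") {
  rows <- expand.grid(
    x = rownames(tab), y = colnames(tab),
    stringsAsFactors = FALSE
  )
  n <- as.vector(tab)
  out <- rows[rep(seq_len(nrow(rows)), n), ]
  df <- tibble::tibble(
    x = factor(out$x, levels = rownames(tab)),
    y = factor(out$y, levels = colnames(tab))
  )
  names(df) <- c(xname, yname)
  df
}

# small fast city for pipeline-level tests; zone radii scaled down so all
# three home-location zones exist inside the reduced extent
tiny_config <- function(seed = 11, n_households = 60, ...) {
  city_config(
    seed = seed, n_households = n_households,
    grid_extent_m = 1500, node_spacing_m = 250,
    zone_radii_m = c(600, 1100), ...
  )
}
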