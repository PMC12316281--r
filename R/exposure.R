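# Exposure-area delineation: 500 m network buffers around homes and anchor
# points, fastest-path route corridors, and the household activity space
# (daily path area method).

#' Delineation parameters
#'
#' Defaults are the study constants: 500 m network buffers around home and
#' anchor points, 100 m Euclidean corridors for walking/cycling routes, 300 m
#' for car/motorcycle/scooter routes (public-transit routes contribute no
#' corridor). `edge_halfwidth_m` is the half-width used to polygonize the
#' reachable sub-network into a service area; `grid_res_m` controls the area
#' integrator (`NULL` = automatic).
#'
#' @param anchor_network_radius_m network-buffer radius around home/anchors.
#' @param walkbike_corridor_m corridor half-width for walk and bike routes.
#' @param motor_corridor_m corridor half-width for car/motorcycle/scooter.
#' @param edge_halfwidth_m service-area polygonization half-width.
#' @param snap_tolerance_m maximum allowed snap distance to the network.
#' @param grid_res_m area-integration grid resolution (meters) or `NULL`.
#' @return A list of class `buffer_params`.
#' @export
buffer_params <- function(anchor_network_radius_m = 500,
                          walkbike_corridor_m = 100,
                          motor_corridor_m = 300,
                          edge_halfwidth_m = 25,
                          snap_tolerance_m = 30,
                          grid_res_m = NULL) {
  p <- list(
    anchor_network_radius_m = anchor_network_radius_m,
    walkbike_corridor_m = walkbike_corridor_m,
    motor_corridor_m = motor_corridor_m,
    edge_halfwidth_m = edge_halfwidth_m,
    snap_tolerance_m = snap_tolerance_m,
    grid_res_m = grid_res_m
  )
  if (any(unlist(p[1:5]) <= 0)) {
    abort("buffer parameters must be positive", class = "foodscape_config_error")
  }
  class(p) <- "buffer_params"
  p
}

merge_intervals <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]
  hi <- hi[o]
  out_lo <- lo[1]
  out_hi <- hi[1]
  if (length(lo) > 1) {
    for (i in 2:length(lo)) {
      k <- length(out_lo)
      if (lo[i] <= out_hi[k] + 1e-9) {
        out_hi[k] <- max(out_hi[k], hi[i])
      } else {
        out_lo <- c(out_lo, lo[i])
        out_hi <- c(out_hi, hi[i])
      }
    }
  }
  cbind(out_lo, out_hi)
}

#' Reachable sub-network within a network distance
#'
#' Identifies, for every edge, the arc intervals whose shortest-path distance
#' from the (snapped) origin is at most `radius_m`, truncating partially
#' reachable edges at the exact residual distance.
#'
#' @inheritParams snap_point
#' @param origin length-2 numeric `c(x, y)`.
#' @param radius_m network radius in meters.
#' @param params a [buffer_params()].
#' @param node_dist optional precomputed [node_distances()] matrix for reuse
#'   across many origins.
#' @return Tibble with `edge` (row in `network$edges`), `from_m`, `to_m`
#'   (arc interval measured from the edge's `from` node).
#' @export
reachable_subnetwork <- function(network, origin, radius_m,
                                 params = buffer_params(), node_dist = NULL) {
  if (radius_m <= 0) {
    abort("radius_m must be > 0", class = "foodscape_config_error")
  }
  snap <- snap_point(network, origin[1], origin[2], tol_m = params$snap_tolerance_m)
  dP <- snap_node_distances(network, snap, node_dist)
  e <- network$edges
  L <- e$length_m
  du <- dP[e$from]
  dv <- dP[e$to]
  ru <- pmin(pmax(radius_m - du, 0), L)
  rv <- pmin(pmax(radius_m - dv, 0), L)
  full <- (ru + rv >= L - 1e-9) & (ru > 0 | rv > 0)
  part_u <- !full & ru > 0
  part_v <- !full & rv > 0
  edge_id <- c(which(full), which(part_u), which(part_v))
  lo <- c(rep(0, sum(full)), rep(0, sum(part_u)), (L - rv)[part_v])
  hi <- c(L[full], ru[part_u], L[part_v])
  # the origin's own edge is also reachable directly, without going through
  # either endpoint node (it may be unreachable via nodes entirely)
  a <- snap$t * L[snap$edge]
  edge_id <- c(edge_id, snap$edge)
  lo <- c(lo, max(0, a - radius_m))
  hi <- c(hi, min(L[snap$edge], a + radius_m))
  # merge overlapping intervals where an edge picked up several pieces
  out <- tibble::tibble(edge = edge_id, from_m = lo, to_m = hi)
  dup <- unique(edge_id[duplicated(edge_id)])
  if (length(dup) > 0) {
    merged <- purrr::map(dup, function(i) {
      o <- out[out$edge == i, ]
      m <- merge_intervals(o$from_m, o$to_m)
      tibble::tibble(edge = i, from_m = m[, 1], to_m = m[, 2])
    }) |> dplyr::bind_rows()
    out <- dplyr::bind_rows(out[!out$edge %in% dup, ], merged)
  }
  out <- out[out$to_m - out$from_m > 1e-12 | out$edge == snap$edge, ]
  out <- dplyr::arrange(out, .data$edge, .data$from_m)
  if (nrow(out) == 0) {
    abort("origin is isolated from the network", class = "foodscape_disconnected_error")
  }
  out
}

arc_to_segments <- function(network, pieces, r) {
  e <- network$edges[pieces$edge, ]
  t0 <- pieces$from_m / e$length_m
  t1 <- pieces$to_m / e$length_m
  cbind(
    x1 = e$x1 + t0 * (e$x2 - e$x1),
    y1 = e$y1 + t0 * (e$y2 - e$y1),
    x2 = e$x1 + t1 * (e$x2 - e$x1),
    y2 = e$y1 + t1 * (e$y2 - e$y1),
    r = r
  )
}

#' Network (service-area) buffer around a point
#'
#' The region within `radius_m` network distance of the snapped origin: the
#' reachable sub-network buffered by `edge_halfwidth_m` and unioned.
#'
#' @inheritParams reachable_subnetwork
#' @param kind stored on the returned area.
#' @return An [exposure_area()].
#' @export
network_buffer <- function(network, origin, radius_m = 500,
                           params = buffer_params(), node_dist = NULL,
                           kind = "home_buffer") {
  pieces <- reachable_subnetwork(network, origin, radius_m, params, node_dist)
  exposure_area(
    arc_to_segments(network, pieces, params$edge_halfwidth_m),
    kind = kind
  )
}

#' Fastest path between two points on the network
#'
#' All modes share one uniform-speed network, so the fastest path is the
#' shortest path; ties are resolved deterministically by the routing engine.
#'
#' @inheritParams reachable_subnetwork
#' @param origin,destination length-2 numeric points.
#' @return List with `coords` (polyline matrix) and `length_m`.
#' @export
fastest_path <- function(network, origin, destination,
                         params = buffer_params(), node_dist = NULL) {
  s1 <- snap_point(network, origin[1], origin[2], tol_m = params$snap_tolerance_m)
  s2 <- snap_point(network, destination[1], destination[2], tol_m = params$snap_tolerance_m)
  e1 <- network$edges[s1$edge, ]
  e2 <- network$edges[s2$edge, ]
  a1 <- s1$t * e1$length_m # P1 -> u1
  b1 <- (1 - s1$t) * e1$length_m # P1 -> v1
  a2 <- s2$t * e2$length_m
  b2 <- (1 - s2$t) * e2$length_m
  ends1 <- c(e1$from, e1$to)
  off1 <- c(a1, b1)
  ends2 <- c(e2$from, e2$to)
  off2 <- c(a2, b2)
  if (is.null(node_dist)) {
    D <- igraph::distances(network$graph,
      v = ends1, to = ends2,
      weights = igraph::E(network$graph)$weight
    )
  } else {
    D <- node_dist[ends1, ends2, drop = FALSE]
  }
  costs <- outer(off1, off2, "+") + D
  best <- which(costs == min(costs), arr.ind = TRUE)[1, ]
  best_cost <- min(costs)
  direct <- s1$edge == s2$edge
  direct_cost <- if (direct) abs(a1 - a2) else Inf
  if (!is.finite(best_cost) && !is.finite(direct_cost)) {
    abort("no path between origin and destination (different components)",
      class = "foodscape_no_path_error"
    )
  }
  p1 <- c(s1$x, s1$y)
  p2 <- c(s2$x, s2$y)
  if (direct_cost <= best_cost) {
    coords <- rbind(p1, p2)
    len <- direct_cost
  } else {
    vp <- igraph::shortest_paths(
      network$graph,
      from = ends1[best[1]], to = ends2[best[2]],
      weights = igraph::E(network$graph)$weight,
      output = "vpath"
    )$vpath[[1]]
    ids <- igraph::V(network$graph)$name[as.integer(vp)]
    idx <- match(ids, network$nodes$id)
    coords <- rbind(p1, cbind(network$nodes$x[idx], network$nodes$y[idx]), p2)
    len <- best_cost
  }
  # drop consecutive duplicate vertices (snap point coinciding with a node)
  keep <- c(TRUE, rowSums(abs(diff(coords))) > 1e-9)
  coords <- coords[keep, , drop = FALSE]
  if (nrow(coords) == 1) coords <- rbind(coords, coords)
  dimnames(coords) <- NULL
  list(coords = coords, length_m = len)
}

corridor_halfwidth <- function(mode, params) {
  if (!mode %in% fs_modes) {
    abort(paste0("unknown transport mode: ", mode),
      class = "foodscape_unknown_mode_error"
    )
  }
  if (mode %in% fs_walkbike_modes) {
    params$walkbike_corridor_m
  } else if (mode %in% fs_motor_modes) {
    params$motor_corridor_m
  } else {
    NA_real_ # public_transit: no corridor
  }
}

#' Euclidean corridor around a route
#'
#' 100 m half-width for walk/bike routes, 300 m for car/motorcycle/scooter;
#' public-transit routes yield an empty area (route data unavailable — only
#' the anchor vicinities of transit trips are retained, elsewhere).
#'
#' @param route output of [fastest_path()] (or a coordinate matrix).
#' @param mode transport mode string.
#' @param params a [buffer_params()].
#' @return An [exposure_area()] of kind `activity_space`.
#' @export
route_corridor <- function(route, mode, params = buffer_params()) {
  w <- corridor_halfwidth(mode, params)
  if (is.na(w)) {
    return(exposure_area(NULL, kind = "activity_space"))
  }
  coords <- if (is.list(route)) route$coords else route
  coords <- merge_collinear(coords)
  if (nrow(coords) < 2) coords <- rbind(coords, coords)
  n <- nrow(coords) - 1
  segs <- cbind(
    x1 = coords[seq_len(n), 1], y1 = coords[seq_len(n), 2],
    x2 = coords[seq_len(n) + 1, 1], y2 = coords[seq_len(n) + 1, 2],
    r = w
  )
  exposure_area(segs, kind = "activity_space")
}

anchor_table <- function(household) {
  a <- household$anchors
  if (is.list(a) && !is.data.frame(a)) a <- a[[1]]
  if (is.null(a) || nrow(a) == 0) {
    return(tibble::tibble(
      adult = integer(), x = numeric(), y = numeric(),
      mode = character()
    ))
  }
  tibble::as_tibble(a)
}

#' Household activity space (daily path area)
#'
#' Union of (a) the 500 m network buffer around the home, (b) a 500 m network
#' buffer around every anchor point reported by the household's adults
#' (public-transit anchors included: the visited vicinity is retained even
#' though the transit route is not), (c) the fastest-path route corridor from
#' home to every non-transit anchor, and (d) the corridor between the two
#' anchors of an adult who visits both with the same non-transit mode. The
#' result geometrically contains the home buffer by construction.
#'
#' @param household one-row household tibble (see [generate_households()]):
#'   columns `home_x`, `home_y` and a list-column `anchors` holding a tibble
#'   with `adult`, `x`, `y`, `mode`.
#' @inheritParams reachable_subnetwork
#' @return An [exposure_area()] of kind `activity_space`.
#' @export
household_activity_space <- function(household, network,
                                     params = buffer_params(),
                                     node_dist = NULL) {
  hid <- if ("household_id" %in% names(household)) household$household_id[1] else NA
  withCallingHandlers(
    {
      home <- c(household$home_x[1], household$home_y[1])
      anchors <- anchor_table(household)
      areas <- list(network_buffer(
        network, home, params$anchor_network_radius_m, params, node_dist
      ))
      for (i in seq_len(nrow(anchors))) {
        areas <- c(areas, list(network_buffer(
          network, c(anchors$x[i], anchors$y[i]),
          params$anchor_network_radius_m, params, node_dist,
          kind = "activity_space"
        )))
        if (anchors$mode[i] != "public_transit") {
          rt <- fastest_path(network, home, c(anchors$x[i], anchors$y[i]), params, node_dist)
          areas <- c(areas, list(route_corridor(rt, anchors$mode[i], params)))
        }
      }
      # inter-anchor corridors: same adult, same non-transit mode
      if (nrow(anchors) > 1) {
        for (ad in unique(anchors$adult)) {
          aa <- anchors[anchors$adult == ad, ]
          if (nrow(aa) < 2) next
          for (i in seq_len(nrow(aa) - 1)) {
            for (j in (i + 1):nrow(aa)) {
              if (aa$mode[i] == aa$mode[j] && aa$mode[i] != "public_transit") {
                rt <- fastest_path(
                  network, c(aa$x[i], aa$y[i]), c(aa$x[j], aa$y[j]),
                  params, node_dist
                )
                areas <- c(areas, list(route_corridor(rt, aa$mode[i], params)))
              }
            }
          }
        }
      }
      union_areas(areas, kind = "activity_space")
    },
    error = function(e) {
      if (!is.na(hid) && inherits(e, c("foodscape_snap_error", "foodscape_no_path_error"))) {
        abort(paste0("household ", hid, ": ", conditionMessage(e)),
          class = class(e)[1], parent = e
        )
      }
    }
  )
}

#' Delineate exposure areas for a household table
#'
#' Computes, per household, the 500 m home network buffer and/or the activity
#' space, returning a tidy tibble with the geometry in a list-column.
#'
#' @param households household tibble (one row each; see
#'   [generate_households()]).
#' @inheritParams reachable_subnetwork
#' @param kinds which exposure measures to delineate.
#' @param compute_area whether to evaluate polygon areas (set `FALSE` to skip
#'   the integration when only counts are needed).
#' @return Tibble with `household_id`, `kind`, `area` (list-column of
#'   [exposure_area()]) and `area_km2` (NA when not computed).
#' @export
delineate_exposure <- function(households, network,
                               params = buffer_params(),
                               kinds = c("home_buffer", "activity_space"),
                               compute_area = TRUE,
                               node_dist = NULL) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  if (is.null(node_dist)) node_dist <- node_distances(network)
  rows <- purrr::map(seq_len(nrow(households)), function(i) {
    hh <- households[i, ]
    purrr::map(kinds, function(k) {
      ar <- if (k == "home_buffer") {
        network_buffer(
          network, c(hh$home_x, hh$home_y),
          params$anchor_network_radius_m, params, node_dist
        )
      } else {
        household_activity_space(hh, network, params, node_dist)
      }
      tibble::tibble(
        household_id = hh$household_id,
        kind = k,
        area = list(ar),
        area_km2 = if (compute_area) area_km2(ar, params$grid_res_m) else NA_real_
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
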