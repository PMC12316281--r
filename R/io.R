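# Plain-text interchange: GeoJSON for the network, outlets and exposure
# areas; CSV for households, margins, weights and estimate tables; YAML for
# the city configuration. All geometry is in a local metric CRS.

geojson_write <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a street network as GeoJSON LineStrings
#'
#' One LineString feature per edge with a `length_m` property. On read,
#' multi-vertex LineStrings are split at their vertices (inserting nodes) so
#' the in-memory network always has straight edges; coincident endpoints are
#' merged into shared nodes.
#'
#' @param network a [street_network()].
#' @param path file path.
#' @return `write_network_geojson()` the path, invisibly;
#'   `read_network_geojson()` a [street_network()].
#' @export
write_network_geojson <- function(network, path) {
  feats <- purrr::map(seq_len(nrow(network$edges)), function(i) {
    e <- network$edges[i, ]
    list(
      type = "Feature",
      geometry = list(
        type = "LineString",
        coordinates = list(c(e$x1, e$y1), c(e$x2, e$y2))
      ),
      properties = list(from = e$from, to = e$to, length_m = e$length_m)
    )
  })
  geojson_write(feats, path)
}

#' @rdname write_network_geojson
#' @export
read_network_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  coords <- list()
  segs <- list()
  for (f in fc$features) {
    if (!identical(f$geometry$type, "LineString")) next
    cc <- f$geometry$coordinates
    for (i in seq_len(length(cc) - 1)) {
      segs[[length(segs) + 1]] <- c(
        cc[[i]][[1]], cc[[i]][[2]], cc[[i + 1]][[1]], cc[[i + 1]][[2]]
      )
    }
  }
  if (length(segs) == 0) {
    abort("no LineString features found", class = "foodscape_network_error")
  }
  m <- do.call(rbind, segs)
  pts <- rbind(m[, 1:2, drop = FALSE], m[, 3:4, drop = FALSE])
  key <- paste(round(pts[, 1], 6), round(pts[, 2], 6))
  uk <- !duplicated(key)
  nodes <- tibble::tibble(
    id = paste0("n", seq_len(sum(uk))),
    x = pts[uk, 1], y = pts[uk, 2]
  )
  idx <- match(key, key[uk])
  n <- nrow(m)
  edges <- tibble::tibble(
    from = nodes$id[idx[seq_len(n)]],
    to = nodes$id[idx[n + seq_len(n)]]
  )
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  street_network(nodes, edges)
}

#' Write / read food outlets as GeoJSON Points
#'
#' Point features carrying a `category` property; flags are re-derived on
#' read via [add_outlet_flags()].
#'
#' @param outlets outlet tibble.
#' @param path file path.
#' @return The path invisibly / an outlet tibble.
#' @export
write_outlets_geojson <- function(outlets, path) {
  feats <- purrr::map(seq_len(nrow(outlets)), function(i) {
    list(
      type = "Feature",
      geometry = list(
        type = "Point",
        coordinates = c(outlets$x[i], outlets$y[i])
      ),
      properties = list(id = outlets$id[i], category = outlets$category[i])
    )
  })
  geojson_write(feats, path)
}

#' @rdname write_outlets_geojson
#' @export
read_outlets_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- purrr::map(fc$features, function(f) {
    tibble::tibble(
      id = f$properties$id %||% NA_character_,
      x = f$geometry$coordinates[[1]],
      y = f$geometry$coordinates[[2]],
      category = f$properties$category
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      id = character(), x = numeric(), y = numeric(), category = character()
    )
  }
  add_outlet_flags(out)
}

#' Write exposure areas as GeoJSON MultiPolygons
#'
#' Each exposure area is written as one MultiPolygon feature whose parts are
#' the polygonized capsules of the union (parts may overlap; the union of
#' the parts is the area), with `household_id`, `kind` and `area_m2`
#' properties.
#'
#' @param areas tibble from [delineate_exposure()].
#' @param path file path.
#' @param n_arc arc discretisation per capsule cap.
#' @return The path, invisibly.
#' @export
write_areas_geojson <- function(areas, path, n_arc = 16) {
  feats <- purrr::map(seq_len(nrow(areas)), function(i) {
    ar <- areas$area[[i]]
    polys <- purrr::map(seq_len(nrow(ar$segments)), function(j) {
      s <- ar$segments[j, ]
      ring <- capsule_polygon(s[1], s[2], s[3], s[4], s[5], n_arc = n_arc)
      list(purrr::map(seq_len(nrow(ring)), function(k) unname(ring[k, ])))
    })
    a2 <- areas$area_km2[i]
    list(
      type = "Feature",
      geometry = list(type = "MultiPolygon", coordinates = polys),
      properties = list(
        household_id = areas$household_id[i],
        kind = areas$kind[i],
        area_m2 = if (is.na(a2)) NULL else a2 * 1e6
      )
    )
  })
  geojson_write(feats, path)
}

flatten_anchors <- function(households, max_adults = 2, max_anchors = 2) {
  out <- dplyr::select(households, -"anchors")
  for (ad in seq_len(max_adults)) {
    for (i in seq_len(max_anchors)) {
      pre <- paste0("anchor", i, "_", ad, "_")
      out[[paste0(pre, "x")]] <- NA_real_
      out[[paste0(pre, "y")]] <- NA_real_
      out[[paste0(pre, "mode")]] <- NA_character_
    }
  }
  for (r in seq_len(nrow(households))) {
    a <- households$anchors[[r]]
    if (is.null(a) || nrow(a) == 0) next
    for (ad in unique(a$adult)) {
      aa <- a[a$adult == ad, ]
      for (i in seq_len(nrow(aa))) {
        pre <- paste0("anchor", i, "_", ad, "_")
        out[[paste0(pre, "x")]][r] <- aa$x[i]
        out[[paste0(pre, "y")]][r] <- aa$y[i]
        out[[paste0(pre, "mode")]][r] <- aa$mode[i]
      }
    }
  }
  out
}

unflatten_anchors <- function(flat) {
  acols <- grep("^anchor\\d+_\\d+_x$", names(flat), value = TRUE)
  anchors <- purrr::map(seq_len(nrow(flat)), function(r) {
    rows <- purrr::map(acols, function(cx) {
      pre <- sub("x$", "", cx)
      x <- flat[[cx]][r]
      if (is.na(x)) {
        return(NULL)
      }
      ad <- as.integer(sub("^anchor\\d+_(\\d+)_$", "\\1", pre))
      tibble::tibble(
        adult = ad, x = x, y = flat[[paste0(pre, "y")]][r],
        mode = flat[[paste0(pre, "mode")]][r]
      )
    })
    rows <- purrr::compact(rows)
    if (length(rows) == 0) {
      tibble::tibble(adult = integer(), x = numeric(), y = numeric(), mode = character())
    } else {
      dplyr::arrange(dplyr::bind_rows(rows), .data$adult)
    }
  })
  out <- flat[, !grepl("^anchor\\d+_\\d+_", names(flat)), drop = FALSE]
  out$anchors <- anchors
  out
}

#' Write / read the household table as CSV
#'
#' Anchors are serialised to `anchor{i}_{adult}_x/y/mode` columns (up to two
#' anchors per adult, two adults); factors are restored on read.
#'
#' @param households household tibble (see [generate_households()]).
#' @param path file path.
#' @return The path invisibly / a household tibble.
#' @export
write_households_csv <- function(households, path) {
  readr::write_csv(flatten_anchors(households), path)
  invisible(path)
}

#' @rdname write_households_csv
#' @export
read_households_csv <- function(path) {
  flat <- readr::read_csv(path, show_col_types = FALSE)
  out <- unflatten_anchors(flat)
  for (v in names(fs_levels)) {
    if (v %in% names(out)) out[[v]] <- factor(out[[v]], levels = fs_levels[[v]])
  }
  tibble::as_tibble(out)
}

#' Write / read population margins as CSV
#'
#' @param margins tibble `variable`, `level`, `proportion` ([true_margins()]).
#' @param path file path.
#' @return The path invisibly / a margins tibble.
#' @export
write_margins_csv <- function(margins, path) {
  readr::write_csv(margins, path)
  invisible(path)
}

#' @rdname write_margins_csv
#' @export
read_margins_csv <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      variable = readr::col_character(),
      level = readr::col_character(),
      proportion = readr::col_double()
    )
  )
}

#' Write / read a city configuration as YAML
#'
#' @param config a [city_config()].
#' @param path file path.
#' @return The path invisibly / a validated [city_config()].
#' @export
write_city_yaml <- function(config, path) {
  x <- unclass(config)
  # named numeric vectors must be written as YAML maps, not bare sequences
  as_map <- function(v) {
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  }
  x$category_mix <- as_map(x$category_mix)
  x$covariate_params <- lapply(x$covariate_params, as_map)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_city_yaml
#' @export
read_city_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cp <- x$covariate_params
  for (nm in names(cp)) {
    if (is.list(cp[[nm]])) cp[[nm]] <- unlist(cp[[nm]])
  }
  city_config(
    seed = x$seed,
    grid_extent_m = x$grid_extent_m,
    node_spacing_m = x$node_spacing_m,
    node_jitter_m = x$node_jitter_m,
    center = unlist(x$center),
    outlet_intensity0 = x$outlet_intensity0,
    decay_scale_m = x$decay_scale_m,
    category_mix = unlist(x$category_mix),
    n_households = x$n_households,
    zone_radii_m = unlist(x$zone_radii_m),
    covariate_params = cp %||% list()
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
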