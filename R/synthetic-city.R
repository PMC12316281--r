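# Synthetic city generator: a perturbed street grid, food outlets whose
# intensity decays with distance from the center, and a household sample with
# anchor points, transport modes and sociodemographic covariates. Every
# downstream stage of the pipeline is testable on this world without any
# external data.

default_covariate_params <- function() {
  list(
    # population category proportions (household-head covariates)
    age = c("<35" = 0.29, "35-50" = 0.26, ">50" = 0.45),
    education = c(
      high_school_or_less = 0.24, undergraduate = 0.35, postgraduate = 0.41
    ),
    composition = c(
      one_adult = 0.43, multiple_adults = 0.26,
      one_adult_children = 0.10, multiple_adults_children = 0.21
    ),
    employment = c(employed = 0.69, unemployed = 0.22, student = 0.09),
    income = c(Q1 = 0.24, Q2 = 0.24, Q3 = 0.21, Q4 = 0.24, refused = 0.07),
    # home-zone sampling probabilities and car ownership conditional on zone
    zone_probs = c(city_center = 0.19, pericentral = 0.41, peri_urban = 0.40),
    car_by_zone = c(city_center = 0.55, pericentral = 0.80, peri_urban = 0.92),
    # per-adult anchor-count distribution (0, 1 or 2 anchors)
    anchor_counts = c(p0 = 0.20, p1 = 0.50, p2 = 0.30),
    # transport-mode probabilities conditional on household car ownership;
    # motor modes are only available to car-owning households
    mode_probs_car = c(
      walk = 0.15, bike = 0.10, car = 0.65, motorcycle = 0.03,
      scooter = 0.02, public_transit = 0.05
    ),
    mode_probs_nocar = c(
      walk = 0.45, bike = 0.25, car = 0, motorcycle = 0,
      scooter = 0, public_transit = 0.30
    ),
    # anchor locations concentrate toward the center with this decay scale
    anchor_decay_m = 2000
  )
}

#' Synthetic-city configuration
#'
#' The defaults state the emulated world: a 8 x 8 km city (half-width
#' 4000 m) on a 250 m perturbed street grid; food-outlet intensity decaying
#' exponentially from 60 outlets/km^2 at the center with scale half the city
#' extent; 699 households whose covariate distributions follow the study
#' population, with up to two anchor points per adult and mode choice linked
#' to car ownership; zone radii 1000 m (city center) and 2500 m
#' (pericentral), peri-urban beyond.
#'
#' @param seed integer master seed; each layer draws from stream
#'   `seed + offset` so layers can be regenerated independently.
#' @param grid_extent_m city half-width (meters).
#' @param node_spacing_m grid spacing; must not exceed the extent.
#' @param node_jitter_m uniform coordinate perturbation half-range.
#' @param center length-2 city-center coordinates.
#' @param outlet_intensity0 outlets per km^2 at the center.
#' @param decay_scale_m exponential distance-decay scale of outlet intensity.
#' @param category_mix named probability vector over the 10 outlet
#'   categories (sums to 1).
#' @param n_households number of households to sample.
#' @param zone_radii_m two increasing radii splitting city-center /
#'   pericentral / peri-urban.
#' @param covariate_params list of marginal/conditional covariate parameters;
#'   see `foodscape:::default_covariate_params()` for the full structure.
#' @return A validated list of class `city_config`.
#' @export
city_config <- function(seed = 20180501L,
                        grid_extent_m = 4000,
                        node_spacing_m = 250,
                        node_jitter_m = 40,
                        center = c(0, 0),
                        outlet_intensity0 = 60,
                        decay_scale_m = grid_extent_m / 2,
                        category_mix = c(
                          butcher = 0.08, bakery = 0.25,
                          drive_through_supermarket = 0.02, fish_shop = 0.02,
                          greengrocer = 0.05, grocery_store = 0.12,
                          market = 0.03, supermarket = 0.08,
                          traditional_restaurant = 0.22,
                          fast_food_restaurant = 0.13
                        ),
                        n_households = 699L,
                        zone_radii_m = c(1000, 2500),
                        covariate_params = list()) {
  cfg <- list(
    seed = as.integer(seed),
    grid_extent_m = grid_extent_m,
    node_spacing_m = node_spacing_m,
    node_jitter_m = node_jitter_m,
    center = center,
    outlet_intensity0 = outlet_intensity0,
    decay_scale_m = decay_scale_m,
    category_mix = category_mix,
    n_households = as.integer(n_households),
    zone_radii_m = zone_radii_m,
    covariate_params = modifyList(default_covariate_params(), covariate_params)
  )
  with(cfg, {
    if (grid_extent_m <= 0 || node_spacing_m <= 0 ||
      (is.finite(decay_scale_m) && decay_scale_m <= 0)) {
      abort("lengths must be positive", class = "foodscape_config_error")
    }
    if (node_spacing_m > grid_extent_m) {
      abort("node_spacing_m exceeds grid_extent_m", class = "foodscape_config_error")
    }
    if (!setequal(names(category_mix), fs_categories) ||
      abs(sum(category_mix) - 1) > 1e-9 || any(category_mix < 0)) {
      abort("category_mix must be a probability vector over the 10 categories",
        class = "foodscape_config_error"
      )
    }
    if (length(zone_radii_m) != 2 || diff(zone_radii_m) <= 0 || zone_radii_m[1] <= 0) {
      abort("zone_radii_m must be two strictly increasing positive radii",
        class = "foodscape_config_error"
      )
    }
    if (n_households < 1) {
      abort("n_households must be >= 1", class = "foodscape_config_error")
    }
  })
  for (v in c("age", "education", "composition", "employment", "income")) {
    p <- cfg$covariate_params[[v]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      abort(paste0("covariate_params$", v, " must sum to 1"),
        class = "foodscape_config_error"
      )
    }
  }
  class(cfg) <- "city_config"
  cfg
}

zone_of <- function(d, zone_radii_m) {
  factor(
    ifelse(d < zone_radii_m[1], "city_center",
      ifelse(d < zone_radii_m[2], "pericentral", "peri_urban")
    ),
    levels = fs_levels$home_location
  )
}

#' Generate the street network
#'
#' A regular grid spanning `[-extent, extent]^2` at `node_spacing_m`, each
#' node jittered uniformly by up to `node_jitter_m` per coordinate; edges
#' connect grid neighbours, so the graph is connected and planar.
#'
#' @param config a [city_config()].
#' @return A [street_network()]; deterministic given `config$seed`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "city_config"))
  withr::with_seed(config$seed + 1L, {
    ticks <- seq(-config$grid_extent_m, config$grid_extent_m,
      by = config$node_spacing_m
    )
    n <- length(ticks)
    grid <- expand.grid(col = seq_len(n), row = seq_len(n))
    nodes <- tibble::tibble(
      id = paste0("n", grid$row, "_", grid$col),
      x = config$center[1] + ticks[grid$col] +
        runif(nrow(grid), -config$node_jitter_m, config$node_jitter_m),
      y = config$center[2] + ticks[grid$row] +
        runif(nrow(grid), -config$node_jitter_m, config$node_jitter_m)
    )
    right <- grid$col < n
    up <- grid$row < n
    edges <- tibble::tibble(
      from = c(nodes$id[right], nodes$id[up]),
      to = c(
        paste0("n", grid$row[right], "_", grid$col[right] + 1),
        paste0("n", grid$row[up] + 1, "_", grid$col[up])
      )
    )
    street_network(nodes, edges)
  })
}

snap_offset_to_network <- function(network, x, y, max_offset_m = 25) {
  # move points further than 30 m from any street to a random spot within
  # max_offset_m of their nearest street point, preserving the approach side
  for (i in seq_along(x)) {
    e <- network$edges
    dx <- e$x2 - e$x1
    dy <- e$y2 - e$y1
    t <- pmin(1, pmax(0, ((x[i] - e$x1) * dx + (y[i] - e$y1) * dy) /
      (dx^2 + dy^2)))
    px <- e$x1 + t * dx
    py <- e$y1 + t * dy
    d <- sqrt((x[i] - px)^2 + (y[i] - py)^2)
    j <- which.min(d)
    if (d[j] > 30) {
      u <- c(x[i] - px[j], y[i] - py[j]) / d[j]
      off <- runif(1, 0, max_offset_m)
      x[i] <- px[j] + off * u[1]
      y[i] <- py[j] + off * u[2]
    }
  }
  list(x = x, y = y)
}

#' Generate food outlets
#'
#' Inhomogeneous Poisson process with intensity
#' `outlet_intensity0 * exp(-d / decay_scale_m)` (d = distance to center),
#' realised by thinning a homogeneous process over the city square.
#' Categories are i.i.d. draws from `category_mix`; outlets further than
#' 30 m from a street are relocated to within 25 m of the nearest street
#' point (outlets front onto streets).
#'
#' @param config a [city_config()].
#' @param network the city's [street_network()].
#' @return Outlet tibble (`id`, `x`, `y`, `category` plus derived flags);
#'   deterministic given `config$seed`.
#' @export
generate_outlets <- function(config, network) {
  stopifnot(inherits(config, "city_config"))
  withr::with_seed(config$seed + 2L, {
    area_km2 <- (2 * config$grid_extent_m / 1000)^2
    n0 <- rpois(1, config$outlet_intensity0 * area_km2)
    x <- runif(n0, -config$grid_extent_m, config$grid_extent_m) + config$center[1]
    y <- runif(n0, -config$grid_extent_m, config$grid_extent_m) + config$center[2]
    d <- sqrt((x - config$center[1])^2 + (y - config$center[2])^2)
    p_keep <- if (is.finite(config$decay_scale_m)) {
      exp(-d / config$decay_scale_m)
    } else {
      rep(1, n0)
    }
    keep <- runif(n0) <= p_keep
    x <- x[keep]
    y <- y[keep]
    if (length(x) > 0) {
      sn <- snap_offset_to_network(network, x, y)
      x <- sn$x
      y <- sn$y
    }
    cats <- if (length(x) > 0) {
      sample(names(config$category_mix), length(x),
        replace = TRUE, prob = config$category_mix
      )
    } else {
      character(0)
    }
    out <- tibble::tibble(
      id = if (length(x) > 0) sprintf("o%05d", seq_along(x)) else character(0),
      x = x, y = y, category = cats
    )
    add_outlet_flags(out)
  })
}

sample_level <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate the household sample
#'
#' Homes are placed uniformly along network edges within a zone drawn from
#' `zone_probs`; the zone label is then assigned from the home's actual
#' distance to the center. Covariates are drawn from `covariate_params`
#' (car ownership conditional on zone). Each adult (1 for single-adult
#' compositions, 2 otherwise) reports 0-2 anchor points at network nodes
#' sampled with center-decaying weight, each with a transport mode; motor
#' modes occur only in car-owning households.
#'
#' @inheritParams generate_outlets
#' @return Household tibble with one row per household and an `anchors`
#'   list-column (`adult`, `x`, `y`, `mode`); deterministic given seed.
#' @export
generate_households <- function(config, network) {
  stopifnot(inherits(config, "city_config"))
  cp <- config$covariate_params
  withr::with_seed(config$seed + 3L, {
    n <- config$n_households
    e <- network$edges
    mid_d <- sqrt(((e$x1 + e$x2) / 2 - config$center[1])^2 +
      ((e$y1 + e$y2) / 2 - config$center[2])^2)
    mid_zone <- as.character(zone_of(mid_d, config$zone_radii_m))
    zones <- sample_level(n, cp$zone_probs)
    home_edge <- integer(n)
    for (z in names(cp$zone_probs)) {
      in_z <- which(zones == z)
      cand <- which(mid_zone == z)
      if (length(cand) == 0) cand <- seq_len(nrow(e))
      home_edge[in_z] <- cand[sample.int(
        length(cand), length(in_z),
        replace = TRUE, prob = e$length_m[cand]
      )]
    }
    tt <- runif(n)
    home_x <- e$x1[home_edge] + tt * (e$x2[home_edge] - e$x1[home_edge])
    home_y <- e$y1[home_edge] + tt * (e$y2[home_edge] - e$y1[home_edge])
    dist_center <- sqrt((home_x - config$center[1])^2 + (home_y - config$center[2])^2)
    home_location <- zone_of(dist_center, config$zone_radii_m)

    composition <- factor(sample_level(n, cp$composition), fs_levels$composition)
    n_adults <- ifelse(composition %in% c("one_adult", "one_adult_children"), 1L, 2L)
    car_p <- cp$car_by_zone[as.character(home_location)]
    car <- factor(ifelse(runif(n) < car_p, "yes", "no"), fs_levels$car)

    # anchor locations: nodes weighted toward the center
    node_d <- sqrt((network$nodes$x - config$center[1])^2 +
      (network$nodes$y - config$center[2])^2)
    node_w <- exp(-node_d / cp$anchor_decay_m)
    anchors <- vector("list", n)
    for (i in seq_len(n)) {
      rows <- list()
      mode_p <- if (car[i] == "yes") cp$mode_probs_car else cp$mode_probs_nocar
      for (ad in seq_len(n_adults[i])) {
        k <- sample(0:2, 1, prob = cp$anchor_counts)
        if (k > 0) {
          nd <- sample.int(nrow(network$nodes), k, prob = node_w)
          rows[[length(rows) + 1]] <- tibble::tibble(
            adult = ad,
            x = network$nodes$x[nd],
            y = network$nodes$y[nd],
            mode = sample_level(k, mode_p[mode_p > 0])
          )
        }
      }
      anchors[[i]] <- if (length(rows)) {
        dplyr::bind_rows(rows)
      } else {
        tibble::tibble(
          adult = integer(), x = numeric(), y = numeric(), mode = character()
        )
      }
    }

    tibble::tibble(
      household_id = sprintf("h%04d", seq_len(n)),
      home_x = home_x, home_y = home_y,
      dist_center_m = dist_center,
      home_location = home_location,
      age = factor(sample_level(n, cp$age), fs_levels$age),
      education = factor(sample_level(n, cp$education), fs_levels$education),
      composition = composition,
      employment = factor(sample_level(n, cp$employment), fs_levels$employment),
      income = factor(sample_level(n, cp$income), fs_levels$income),
      car = car,
      n_adults = n_adults,
      anchors = anchors
    )
  })
}

#' Add the composition-by-age raking cell to a household table
#'
#' Calibration crosses household composition against the household head's
#' age group; this derives that 12-cell factor.
#'
#' @param households household tibble with `composition` and `age`.
#' @return The tibble with a `comp_age` factor column appended.
#' @export
add_comp_age <- function(households) {
  lv <- as.vector(outer(fs_levels$composition, fs_levels$age, paste, sep = "."))
  dplyr::mutate(
    households,
    comp_age = factor(
      paste(as.character(.data$composition), as.character(.data$age), sep = "."),
      levels = lv
    )
  )
}

#' Target population margins of the generator
#'
#' The generator's own margins for the two calibration variables — income
#' per consumption unit, and household composition crossed with the
#' household head's age group (independent in the generator, so cell
#' proportions are products of marginals). Raking a generated sample to
#' these margins must recover them exactly.
#'
#' @param config a [city_config()].
#' @return Tibble with `variable`, `level`, `proportion`; each variable's
#'   proportions sum to 1.
#' @export
true_margins <- function(config) {
  stopifnot(inherits(config, "city_config"))
  cp <- config$covariate_params
  comp_age <- as.vector(outer(cp$composition, cp$age))
  lv <- as.vector(outer(
    names(cp$composition), names(cp$age), paste,
    sep = "."
  ))
  dplyr::bind_rows(
    tibble::tibble(
      variable = "income", level = names(cp$income),
      proportion = unname(cp$income)
    ),
    tibble::tibble(
      variable = "comp_age", level = lv,
      proportion = comp_age / sum(comp_age)
    )
  )
}

#' Generate a complete synthetic city
#'
#' @param config a [city_config()].
#' @return List with `network`, `outlets`, `households`, `margins`.
#' @export
generate_city <- function(config = city_config()) {
  network <- generate_network(config)
  list(
    config = config,
    network = network,
    outlets = generate_outlets(config, network),
    households = generate_households(config, network),
    margins = true_margins(config)
  )
}
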