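test_that("unperturbed 3x3 grid: 9 nodes, 12 edges, all lengths equal spacing", {
  cfg <- city_config(seed = 1, grid_extent_m = 100, node_spacing_m = 100, node_jitter_m = 0)
  net <- generate_network(cfg)
  expect_equal(nrow(net$nodes), 9)
  expect_equal(nrow(net$edges), 12)
  expect_equal(net$edges$length_m, rep(100, 12))
})

test_that("generation is deterministic given seed and config", {
  cfg <- tiny_config(seed = 99, n_households = 30)
  a <- generate_city(cfg)
  b <- generate_city(cfg)
  expect_identical(a$network$nodes, b$network$nodes)
  expect_identical(a$outlets, b$outlets)
  expect_identical(a$households, b$households)
  # different seed changes the draw
  c2 <- generate_network(tiny_config(seed = 100))
  expect_false(identical(a$network$nodes$x, c2$nodes$x))
})

test_that("jittered grid edge lengths stay near spacing and match coordinates", {
  cfg <- city_config(seed = 5, grid_extent_m = 500, node_spacing_m = 100, node_jitter_m = 10)
  net <- generate_network(cfg)
  expect_true(all(net$edges$length_m >= 80 - 1e-9 & net$edges$length_m <= 120 + 1e-9))
  d <- sqrt((net$edges$x2 - net$edges$x1)^2 + (net$edges$y2 - net$edges$y1)^2)
  expect_equal(net$edges$length_m, d, tolerance = 1e-12)
})

test_that("config validation rejects malformed worlds", {
  expect_error(
    city_config(grid_extent_m = 100, node_spacing_m = 250),
    class = "foodscape_config_error"
  )
  expect_error(
    city_config(category_mix = c(bakery = 1)),
    class = "foodscape_config_error"
  )
  expect_error(
    city_config(zone_radii_m = c(2000, 1000)),
    class = "foodscape_config_error"
  )
  expect_error(
    city_config(n_households = 0),
    class = "foodscape_config_error"
  )
})

test_that("outlet counts follow the Poisson intensity (no decay)", {
  cfg <- tiny_config(seed = 12, decay_scale_m = Inf, outlet_intensity0 = 40)
  net <- generate_network(cfg)
  out <- generate_outlets(cfg, net)
  lambda <- 40 * (2 * cfg$grid_extent_m / 1000)^2
  expect_lt(abs(nrow(out) - lambda), 4 * sqrt(lambda))
})

test_that("degenerate category mix and zero intensity behave as stated", {
  mix <- setNames(rep(0, 10), foodscape:::fs_categories)
  mix["bakery"] <- 1
  cfg <- tiny_config(seed = 2, category_mix = mix)
  net <- generate_network(cfg)
  out <- generate_outlets(cfg, net)
  expect_true(all(out$category == "bakery"))
  ar <- network_buffer(net, c(0, 0), 500)
  expect_lte(diversity_in_area(out, ar), 1)

  cfg0 <- tiny_config(seed = 2, outlet_intensity0 = 0)
  out0 <- generate_outlets(cfg0, generate_network(cfg0))
  expect_equal(nrow(out0), 0)
})

test_that("outlets lie within 30 m of the network", {
  cfg <- tiny_config(seed = 8)
  net <- generate_network(cfg)
  out <- generate_outlets(cfg, net)
  d <- vapply(seq_len(nrow(out)), function(i) {
    snap_point(net, out$x[i], out$y[i], tol_m = Inf)$dist
  }, 0)
  expect_true(all(d <= 30 + 1e-9))
})

test_that("carless worlds produce no motorised anchors", {
  cfg <- tiny_config(
    seed = 31, n_households = 120,
    covariate_params = list(car_by_zone = c(
      city_center = 0, pericentral = 0, peri_urban = 0
    ))
  )
  net <- generate_network(cfg)
  hh <- generate_households(cfg, net)
  modes <- unlist(lapply(hh$anchors, function(a) a$mode))
  expect_false(any(modes %in% c("car", "motorcycle", "scooter")))
  expect_true(all(hh$car == "no"))
})

test_that("zone labels follow the radii and homes sit on the network", {
  cfg <- tiny_config(seed = 14, n_households = 80)
  net <- generate_network(cfg)
  hh <- generate_households(cfg, net)
  expect_identical(
    as.character(hh$home_location),
    as.character(foodscape:::zone_of(hh$dist_center_m, cfg$zone_radii_m))
  )
  expect_true(all(hh$dist_center_m[hh$home_location == "city_center"] < cfg$zone_radii_m[1]))
  d <- vapply(seq_len(nrow(hh)), function(i) {
    snap_point(net, hh$home_x[i], hh$home_y[i], tol_m = Inf)$dist
  }, 0)
  expect_true(all(d <= 30))
  # anchors inside the network bounding box
  bb <- foodscape:::network_bbox(net)
  for (a in hh$anchors) {
    if (nrow(a) > 0) {
      expect_true(all(a$x >= bb[1] & a$x <= bb[3] & a$y >= bb[2] & a$y <= bb[4]))
      expect_true(all(a$mode %in% foodscape:::fs_modes))
      expect_true(all(a$adult >= 1))
    }
  }
  # at most 2 anchors per adult
  per_adult <- unlist(lapply(hh$anchors, function(a) {
    if (nrow(a) == 0) integer(0) else table(a$adult)
  }))
  expect_true(all(per_adult <= 2))
})

test_that("car-ownership frequency matches its configured probability", {
  cfg <- tiny_config(
    seed = 77, n_households = 2000,
    covariate_params = list(car_by_zone = c(
      city_center = 0.8, pericentral = 0.8, peri_urban = 0.8
    ))
  )
  net <- generate_network(cfg)
  hh <- generate_households(cfg, net)
  phat <- mean(hh$car == "yes")
  se <- sqrt(0.8 * 0.2 / 2000)
  expect_lt(abs(phat - 0.8), 3 * se)
})

test_that("true margins are valid and configurable to uniform", {
  cfg <- tiny_config(covariate_params = list(
    income = c(Q1 = 0.2, Q2 = 0.2, Q3 = 0.2, Q4 = 0.2, refused = 0.2)
  ))
  m <- true_margins(cfg)
  inc <- m[m$variable == "income", ]
  expect_equal(inc$proportion, rep(0.2, 5))
  expect_equal(sum(m$proportion[m$variable == "comp_age"]), 1, tolerance = 1e-12)
  expect_equal(sum(inc$proportion), 1, tolerance = 1e-12)
})

test_that("margins match large-sample empirical frequencies", {
  cfg <- tiny_config(seed = 4, n_households = 50000)
  net <- generate_network(cfg)
  hh <- add_comp_age(generate_households(cfg, net))
  m <- true_margins(cfg)
  for (v in c("income", "comp_age")) {
    tgt <- m[m$variable == v, ]
    emp <- weighted_proportions(hh, v)
    emp <- emp[match(tgt$level, emp$level), ]
    # Monte-Carlo error at n = 50,000: 4 binomial SEs per category
    se <- sqrt(tgt$proportion * (1 - tgt$proportion) / 50000)
    expect_true(all(abs(emp$proportion - tgt$proportion) < 4 * se + 1e-12))
  }
})

test_that("the planted center-periphery outlet gradient is present", {
  hits <- 0
  n_seeds <- 8
  for (s in seq_len(n_seeds)) {
    cfg <- tiny_config(seed = 300 + s, n_households = 60)
    city <- generate_city(cfg)
    near <- function(x0, y0) {
      sum((city$outlets$x - x0)^2 + (city$outlets$y - y0)^2 <= 500^2)
    }
    cc <- city$households$home_location == "city_center"
    pu <- city$households$home_location == "peri_urban"
    if (sum(cc) > 0 && sum(pu) > 0) {
      m_cc <- mean(mapply(near, city$households$home_x[cc], city$households$home_y[cc]))
      m_pu <- mean(mapply(near, city$households$home_x[pu], city$households$home_y[pu]))
      if (m_cc > m_pu) hits <- hits + 1
    }
  }
  expect_gte(hits / n_seeds, 0.95)
})
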