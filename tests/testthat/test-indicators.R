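test_that("outlet labels map to categories with the stated special cases", {
  expect_equal(classify_outlet("cafeteria"), "fast_food_restaurant")
  expect_equal(classify_outlet("greengrocer"), "greengrocer")
  expect_equal(
    classify_outlet(c("bakery_pastry", "hypermarket")),
    c("bakery", "supermarket")
  )
  expect_error(classify_outlet("pharmacy"), class = "foodscape_unknown_label_error")
})

test_that("derived flags are mutually consistent", {
  out <- add_outlet_flags(tibble::tibble(
    id = as.character(1:10), x = 0, y = 0,
    category = foodscape:::fs_categories
  ))
  expect_false(any(out$is_store & out$is_restaurant))
  expect_true(all(out$is_store | out$is_restaurant))
  expect_true(all(out$category[out$sells_fv] %in% c(
    "drive_through_supermarket", "greengrocer", "grocery_store",
    "market", "supermarket"
  )))
  expect_true(all(out$is_fastfood == (out$category == "fast_food_restaurant")))
  expect_false(any(out$sells_fv & out$is_restaurant))
  expect_error(
    add_outlet_flags(tibble::tibble(id = "1", x = 0, y = 0, category = "spa")),
    class = "foodscape_unknown_label_error"
  )
})

test_that("counting respects predicates, emptiness and the boundary", {
  area <- exposure_area(cbind(0, 0, 100, 0, 25))
  out <- add_outlet_flags(tibble::tibble(
    id = as.character(1:4),
    x = c(50, 50, 50, 500), y = c(0, 10, 25, 0), # last one far outside
    category = c("bakery", "fast_food_restaurant", "supermarket", "bakery")
  ))
  expect_equal(count_in_area(out, area), 3L)
  expect_equal(count_in_area(out, area, "is_store"), 2L)
  expect_equal(count_in_area(out, area, "is_restaurant"), 1L)
  expect_equal(
    count_in_area(out, area, "is_store") + count_in_area(out, area, "is_restaurant"),
    count_in_area(out, area)
  )
  # point exactly on the boundary (y = 25 = radius) is counted
  expect_equal(count_in_area(out, area, "sells_fv"), 1L)
  empty <- exposure_area(NULL)
  expect_equal(count_in_area(out, empty), 0L)
})

test_that("counts agree with a brute-force point-in-polygon loop", {
  withr::with_seed(19, {
    segs <- cbind(
      x1 = runif(5, 0, 600), y1 = runif(5, 0, 600),
      x2 = runif(5, 0, 600), y2 = runif(5, 0, 600),
      r = runif(5, 30, 100)
    )
    area <- exposure_area(segs)
    out <- add_outlet_flags(tibble::tibble(
      id = as.character(1:1000),
      x = runif(1000, -100, 700), y = runif(1000, -100, 700),
      category = sample(foodscape:::fs_categories, 1000, replace = TRUE)
    ))
    expect_equal(
      count_in_area(out, area),
      sum(oracle_inside(segs, out$x, out$y))
    )
  })
})

test_that("diversity counts distinct store categories only", {
  area <- exposure_area(cbind(0, 0, 0, 0, 1000))
  bakeries <- add_outlet_flags(tibble::tibble(
    id = as.character(1:5), x = 1:5, y = 0, category = "bakery"
  ))
  expect_equal(diversity_in_area(bakeries, area), 1L)
  allcats <- add_outlet_flags(tibble::tibble(
    id = as.character(1:10), x = 1:10, y = 0,
    category = foodscape:::fs_categories
  ))
  expect_equal(diversity_in_area(allcats, area), 8L)
  rest <- add_outlet_flags(tibble::tibble(
    id = as.character(1:3), x = 1:3, y = 0,
    category = c("fast_food_restaurant", "traditional_restaurant", "fast_food_restaurant")
  ))
  expect_equal(diversity_in_area(rest, area), 0L)
})

test_that("relative density handles edge cases per the coding rules", {
  expect_equal(relative_density(2, 4), 0.5)
  expect_equal(relative_density(3, 3), 1.0)
  expect_true(is.na(relative_density(0, 0)))
  expect_error(relative_density(5, 4), class = "foodscape_ratio_error")
  expect_error(relative_density(-1, 4), class = "foodscape_ratio_error")
})

test_that("tertile coding matches the quantile oracle on 0..8", {
  prof <- tibble::tibble(
    household_id = sprintf("h%d", 1:9), kind = "home_buffer",
    area_km2 = 1, n_stores = 0:8, n_restaurants = 0:8, diversity = 0:8,
    fv_ratio = c(NA, seq(0, 1, length.out = 8)),
    fastfood_ratio = rep(c(0.49, 0.5, 1), 3)
  )
  coded <- code_profiles(prof)
  # independent quantile oracle: type-7 quantiles of 0..8 at 1/3 and 2/3
  q <- quantile(0:8, c(1 / 3, 2 / 3), type = 7)
  oracle <- cut(0:8, c(-Inf, q, Inf), labels = c("T1", "T2", "T3"))
  expect_equal(as.character(coded$n_stores_class), as.character(oracle))
  expect_equal(as.character(coded$n_stores_class), rep(c("T1", "T2", "T3"), each = 3))
  expect_equal(
    as.character(coded$diversity_class),
    rep(c("0-2", "3-5", "6-8"), each = 3)
  )
  # ratio cutoff: >= 0.5 is ge50, undefined ratios are lt50
  expect_equal(
    as.character(coded$fastfood_class),
    rep(c("lt50", "ge50", "ge50"), 3)
  )
  expect_equal(as.character(coded$fv_class[1]), "lt50")
})

test_that("degenerate count distributions are rejected unless strict = FALSE", {
  prof <- tibble::tibble(
    household_id = sprintf("h%d", 1:5), kind = "home_buffer",
    area_km2 = 1, n_stores = 0L, n_restaurants = 0L, diversity = 0L,
    fv_ratio = NA_real_, fastfood_ratio = NA_real_
  )
  expect_error(code_profiles(prof), class = "foodscape_degenerate_distribution_error")
  coded <- code_profiles(prof, strict = FALSE)
  expect_true(all(coded$fv_class == "lt50"))
  expect_true(all(coded$n_stores_class == "T1"))
})

test_that("tertiles partition the sample with non-empty classes per area kind", {
  cfg <- tiny_config(seed = 44, n_households = 90)
  city <- generate_city(cfg)
  areas <- delineate_exposure(city$households, city$network, compute_area = FALSE)
  coded <- code_profiles(exposure_profiles(areas, city$outlets))
  for (k in unique(coded$kind)) {
    tab <- table(coded$n_stores_class[coded$kind == k])
    expect_equal(sum(tab), sum(coded$kind == k))
    expect_true(all(tab > 0))
  }
  expect_true(all(coded$diversity >= 0 & coded$diversity <= 8))
  expect_true(all(coded$diversity <= pmin(8, coded$n_stores)))
  ok <- is.na(coded$fv_ratio) | (coded$fv_ratio >= 0 & coded$fv_ratio <= 1)
  expect_true(all(ok))
  expect_identical(is.na(coded$fv_ratio), coded$n_stores == 0)
  expect_identical(is.na(coded$fastfood_ratio), coded$n_restaurants == 0)
})
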