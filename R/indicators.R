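# Food-environment indicators: outlet classification, counts, store-type
# diversity, relative densities, and the categorical codings used in the
# regression models (tertiles for counts, 0-2/3-5/6-8 diversity bands, 50%
# cutoff for relative densities with missing treated as "less than 50%").

#' Default taxonomy mapping raw labels to outlet categories
#'
#' Maps raw business labels to the 8 food-store types and 2 restaurant
#' groups. Cafeterias are a fast-food type found in shopping centers and
#' rest areas and are mapped to `fast_food_restaurant`.
#'
#' @return Named character vector: raw label -> category.
#' @export
default_taxonomy <- function() {
  c(
    setNames(fs_categories, fs_categories),
    butcher_shop = "butcher",
    bakery_pastry = "bakery",
    fishmonger = "fish_shop",
    convenience_store = "grocery_store",
    mini_market = "grocery_store",
    hypermarket = "supermarket",
    food_market = "market",
    restaurant = "traditional_restaurant",
    cafeteria = "fast_food_restaurant",
    fast_food = "fast_food_restaurant",
    takeaway = "fast_food_restaurant"
  )
}

#' Classify a raw outlet label
#'
#' @param label raw category label(s).
#' @param taxonomy named map from raw labels to the 10 categories (see
#'   [default_taxonomy()]).
#' @return Category string(s); unknown labels raise a
#'   `foodscape_unknown_label_error` naming them.
#' @export
classify_outlet <- function(label, taxonomy = default_taxonomy()) {
  out <- unname(taxonomy[label])
  if (anyNA(out)) {
    bad <- unique(label[is.na(out)])
    abort(paste0("unknown outlet label(s): ", paste(bad, collapse = ", ")),
      class = "foodscape_unknown_label_error"
    )
  }
  if (!all(out %in% fs_categories)) {
    abort("taxonomy maps to unknown categories", class = "foodscape_unknown_label_error")
  }
  out
}

#' Derive outlet flags from categories
#'
#' Adds `is_store`, `is_restaurant`, `sells_fv` (fruit-and-vegetable
#' retailers: drive-through supermarkets, greengrocers, grocery stores,
#' markets, supermarkets) and `is_fastfood`. Store and restaurant flags are
#' mutually exclusive.
#'
#' @param outlets tibble with a `category` column.
#' @return The tibble with flag columns replaced/appended.
#' @export
add_outlet_flags <- function(outlets) {
  if (nrow(outlets) > 0 && !all(outlets$category %in% fs_categories)) {
    abort("unknown outlet categories; run classify_outlet() first",
      class = "foodscape_unknown_label_error"
    )
  }
  dplyr::mutate(
    tibble::as_tibble(outlets),
    is_store = .data$category %in% fs_store_categories,
    is_restaurant = .data$category %in% fs_restaurant_categories,
    sells_fv = .data$category %in% fs_fv_categories,
    is_fastfood = .data$category == "fast_food_restaurant"
  )
}

#' Count outlets inside an exposure area
#'
#' Boundary outlets count as inside (closed-region convention).
#'
#' @param outlets outlet tibble (`x`, `y` and flag columns).
#' @param area an [exposure_area()].
#' @param predicate optional name of a logical flag column (e.g.
#'   `"is_store"`); `NULL` counts all outlets.
#' @return Integer count.
#' @export
count_in_area <- function(outlets, area, predicate = NULL) {
  if (!is.null(predicate)) {
    outlets <- outlets[outlets[[predicate]], , drop = FALSE]
  }
  if (nrow(outlets) == 0) {
    return(0L)
  }
  sum(point_in_area(area, outlets$x, outlets$y))
}

#' Diversity of food-store types in an area
#'
#' Number of distinct store categories (0-8) present; restaurants are
#' excluded.
#'
#' @inheritParams count_in_area
#' @return Integer in 0..8.
#' @export
diversity_in_area <- function(outlets, area) {
  stores <- outlets[outlets$is_store, , drop = FALSE]
  if (nrow(stores) == 0) {
    return(0L)
  }
  inside <- point_in_area(area, stores$x, stores$y)
  length(unique(stores$category[inside]))
}

#' Relative density (ratio of a subset count to a total count)
#'
#' @param numerator,denominator non-negative counts with
#'   `numerator <= denominator`.
#' @return `numerator / denominator`, or `NA` when the denominator is 0
#'   (no stores / no restaurants in the area).
#' @export
relative_density <- function(numerator, denominator) {
  if (any(numerator < 0) || any(denominator < 0)) {
    abort("counts must be non-negative", class = "foodscape_ratio_error")
  }
  if (any(numerator > denominator)) {
    abort("numerator exceeds denominator", class = "foodscape_ratio_error")
  }
  ifelse(denominator == 0, NA_real_, numerator / denominator)
}

#' Raw exposure indicators per household and area
#'
#' Computes the five indicators for each delineated exposure area: number of
#' food stores, number of restaurants, diversity of store types, relative
#' density of fruit-and-vegetable retailers among stores, and relative
#' density of fast-food restaurants among restaurants.
#'
#' @param areas tibble from [delineate_exposure()].
#' @param outlets outlet tibble with flags (see [add_outlet_flags()]).
#' @return Tibble: `household_id`, `kind`, `area_km2`, `n_stores`,
#'   `n_restaurants`, `diversity`, `fv_ratio`, `fastfood_ratio`.
#' @export
exposure_profiles <- function(areas, outlets) {
  purrr::map(seq_len(nrow(areas)), function(i) {
    ar <- areas$area[[i]]
    inside <- point_in_area(ar, outlets$x, outlets$y)
    inb <- outlets[inside, , drop = FALSE]
    n_stores <- sum(inb$is_store)
    n_rest <- sum(inb$is_restaurant)
    tibble::tibble(
      household_id = areas$household_id[i],
      kind = areas$kind[i],
      area_km2 = areas$area_km2[i],
      n_stores = n_stores,
      n_restaurants = n_rest,
      diversity = length(unique(inb$category[inb$is_store])),
      fv_ratio = relative_density(sum(inb$sells_fv), n_stores),
      fastfood_ratio = relative_density(sum(inb$is_fastfood), n_rest)
    )
  }) |> dplyr::bind_rows()
}

tertile_breaks <- function(x) {
  quantile(x, c(1 / 3, 2 / 3), type = 7, names = FALSE)
}

tertile_class <- function(x, breaks = tertile_breaks(x), strict = TRUE) {
  # right-closed intervals, boundary ties to the lower class; written without
  # cut() so coincident breaks (degenerate distributions) still code
  cls <- factor(
    ifelse(x <= breaks[1], "T1", ifelse(x <= breaks[2], "T2", "T3")),
    levels = c("T1", "T2", "T3")
  )
  if (strict && any(table(cls) == 0)) {
    abort("degenerate distribution: an empty tertile class",
      class = "foodscape_degenerate_distribution_error"
    )
  }
  cls
}

#' Categorical coding of exposure profiles
#'
#' Codes the raw indicators the way they enter the regression models:
#' sample tertiles (per area kind, unweighted, right-closed with boundary
#' ties to the lower class) for the counts of stores and restaurants; fixed
#' bands 0-2 / 3-5 / 6-8 for diversity; and a 50% cutoff for the relative
#' densities (`ge50` iff ratio >= 0.5), with undefined ratios (no stores /
#' no restaurants) coded as `lt50`.
#'
#' @param profiles tibble from [exposure_profiles()] (>= 3 households per
#'   area kind).
#' @param strict raise `foodscape_degenerate_distribution_error` when a
#'   tertile class would be empty (e.g. a city with no outlets at all);
#'   `strict = FALSE` keeps the degenerate coding, leaving downstream models
#'   to skip outcomes with fewer than 2 observed classes.
#' @return The profiles tibble with `n_stores_class`, `n_restaurants_class`,
#'   `diversity_class`, `fv_class`, `fastfood_class` appended.
#' @export
code_profiles <- function(profiles, strict = TRUE) {
  if (min(table(profiles$kind)) < 3) {
    abort("need at least 3 households per area kind to form tertiles",
      class = "foodscape_degenerate_distribution_error"
    )
  }
  profiles |>
    dplyr::group_by(.data$kind) |>
    dplyr::mutate(
      n_stores_class = tertile_class(.data$n_stores, strict = strict),
      n_restaurants_class = tertile_class(.data$n_restaurants, strict = strict),
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      diversity_class = cut(.data$diversity, c(-1, 2, 5, 8),
        labels = c("0-2", "3-5", "6-8")
      ),
      fv_class = factor(
        ifelse(!is.na(.data$fv_ratio) & .data$fv_ratio >= 0.5, "ge50", "lt50"),
        levels = c("lt50", "ge50")
      ),
      fastfood_class = factor(
        ifelse(!is.na(.data$fastfood_ratio) & .data$fastfood_ratio >= 0.5,
          "ge50", "lt50"
        ),
        levels = c("lt50", "ge50")
      )
    )
}
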