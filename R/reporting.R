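# Descriptive summaries, end-to-end pipeline orchestration and forest-plot
# presentation of the effect estimates.

round_half_up <- function(x) floor(x + 0.5)

#' Descriptive sample summary
#'
#' Per covariate level: raw count, raw percentage (100 n / N, rounded
#' half-up to the nearest integer, matching the descriptive-table
#' presentation) and, when weights are supplied, the weighted percentage.
#'
#' @param households household tibble.
#' @param weights `NULL`, a numeric vector, or a [rake()] result.
#' @param variables covariate columns to summarise.
#' @return Tibble: `variable`, `level`, `n`, `pct`, `weighted_pct`.
#' @export
summarize_sample <- function(households, weights = NULL,
                             variables = fs_covariates) {
  stopifnot(nrow(households) >= 1)
  w <- as_weight_vector(weights, households)
  N <- nrow(households)
  purrr::map(variables, function(v) {
    f <- households[[v]]
    if (!is.factor(f)) f <- factor(f)
    n <- tapply(rep(1, N), f, sum)
    n[is.na(n)] <- 0
    ws <- tapply(w, f, sum)
    ws[is.na(ws)] <- 0
    tibble::tibble(
      variable = v,
      level = levels(f),
      n = as.integer(n),
      pct = round_half_up(100 * as.integer(n) / N),
      weighted_pct = if (is.null(weights)) {
        NA_real_
      } else {
        round_half_up(100 * as.numeric(ws) / sum(w))
      }
    )
  }) |> dplyr::bind_rows()
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
      class = "foodscape_pipeline_error", parent = e
    )
  })
}

fs_outcomes <- c(
  "n_stores_class", "n_restaurants_class", "diversity_class",
  "fv_class", "fastfood_class"
)

#' Run the full exposure pipeline on a synthetic city
#'
#' Generates the city, delineates home buffers and activity spaces for every
#' household, computes and codes the five food-environment indicators, rakes
#' the sample to the population margins, screens covariates at
#' `screen_alpha`, fits the weighted models for each coded indicator (and
#' the linear model for area size) under both exposure measures, and builds
#' the home-vs-activity comparison tables. Deterministic given the config
#' seed.
#'
#' @param config a [city_config()].
#' @param params a [buffer_params()].
#' @param out_dir optional output directory: writes network/outlets/areas
#'   GeoJSON, households/margins/weights/profiles/estimates/comparison/
#'   summary CSV and a JSON manifest (package version, seed, parameter
#'   hash). Partial outputs are removed on failure.
#' @param screen_alpha bivariate screening level (0.2).
#' @param alpha significance level for the comparison flags (0.05).
#' @param compute_area evaluate polygon areas and fit the area-size linear
#'   models (the slowest stage; disable when only indicator models matter).
#' @return List of class `foodscape_run`: city layers, `areas`, `profiles`,
#'   `weights`, `summary`, `models` (per kind x outcome), `comparison`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = city_config(), params = buffer_params(),
                         out_dir = NULL, screen_alpha = 0.2, alpha = 0.05,
                         compute_area = TRUE) {
  city <- pipeline_stage("generate", generate_city(config))
  nd <- pipeline_stage("distances", node_distances(city$network))
  areas <- pipeline_stage("delineate", delineate_exposure(
    city$households, city$network, params,
    compute_area = compute_area, node_dist = nd
  ))
  profiles <- pipeline_stage(
    "indicators",
    code_profiles(exposure_profiles(areas, city$outlets), strict = FALSE)
  )
  hh <- add_comp_age(city$households)
  wt <- pipeline_stage("rake", rake(hh, city$margins))
  summary_tbl <- summarize_sample(hh, wt)

  model_data <- dplyr::inner_join(
    profiles, dplyr::select(hh, -"anchors"),
    by = "household_id"
  )
  outcomes <- fs_outcomes
  if (compute_area) outcomes <- c(outcomes, "area_km2")
  models <- pipeline_stage("model", {
    purrr::map(c(home_buffer = "home_buffer", activity_space = "activity_space"), function(k) {
      dat <- model_data[model_data$kind == k, , drop = FALSE]
      purrr::map(setNames(outcomes, outcomes), function(oc) {
        v <- dat[[oc]]
        ok <- if (is.numeric(v)) stats::var(v) > 0 else nlevels(droplevels(factor(v))) >= 2
        if (!ok) {
          return(NULL) # degenerate coding (e.g. a city with no outlets)
        }
        fit_exposure_model(dat, oc, fs_covariates, wt, screen_alpha)
      })
    })
  })
  estimates <- purrr::map(names(models), function(k) {
    purrr::map(models[[k]], function(m) {
      if (is.null(m) || nrow(m$estimates) == 0) {
        return(NULL)
      }
      dplyr::mutate(m$estimates, area_kind = k)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  comparison <- pipeline_stage("compare", {
    purrr::map(setdiff(outcomes, "area_km2"), function(oc) {
      eh <- estimates[estimates$outcome == oc & estimates$area_kind == "home_buffer", ]
      ea <- estimates[estimates$outcome == oc & estimates$area_kind == "activity_space", ]
      cmp <- compare_measures(eh, ea, alpha = alpha)
      if (nrow(cmp) > 0 && !"outcome" %in% names(cmp)) cmp$outcome <- oc
      cmp
    }) |> dplyr::bind_rows()
  })

  manifest <- list(
    package = "foodscape",
    version = as.character(utils::packageVersion("foodscape")),
    seed = config$seed,
    n_households = config$n_households,
    param_hash = rlang::hash(list(
      config = unclass(config), params = unclass(params),
      screen_alpha = screen_alpha, alpha = alpha,
      compute_area = compute_area
    ))
  )
  run <- structure(
    list(
      config = config, network = city$network, outlets = city$outlets,
      households = hh, margins = city$margins, areas = areas,
      profiles = profiles, weights = wt, summary = summary_tbl,
      models = models, estimates = estimates, comparison = comparison,
      manifest = manifest
    ),
    class = "foodscape_run"
  )
  if (!is.null(out_dir)) {
    write_run(run, out_dir)
  }
  run
}

#' @export
print.foodscape_run <- function(x, ...) {
  cat(
    "<foodscape_run> seed ", x$config$seed, ": ",
    nrow(x$households), " households, ", nrow(x$outlets), " outlets, ",
    nrow(x$estimates), " effect estimates\n",
    sep = ""
  )
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' @param run a [run_pipeline()] result.
#' @param out_dir output directory (created if missing); on any write error
#'   the files written so far are removed.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wr <- function(fun, obj, name) {
    p <- file.path(out_dir, name)
    fun(obj, p)
    written <<- c(written, p)
  }
  tryCatch(
    {
      wr(write_network_geojson, run$network, "network.geojson")
      wr(write_outlets_geojson, run$outlets, "outlets.geojson")
      wr(write_households_csv, run$households, "households.csv")
      wr(write_margins_csv, run$margins, "margins.csv")
      wr(write_areas_geojson, run$areas, "areas.geojson")
      wr(
        function(o, p) readr::write_csv(o, p),
        dplyr::select(run$profiles, -dplyr::any_of("area")), "profiles.csv"
      )
      wr(function(o, p) readr::write_csv(o, p), tidy(run$weights), "weights.csv")
      wr(function(o, p) readr::write_csv(o, p), run$summary, "summary.csv")
      wr(function(o, p) readr::write_csv(o, p), run$estimates, "estimates.csv")
      wr(function(o, p) readr::write_csv(o, p), run$comparison, "comparison.csv")
      wr(
        function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA),
        run$manifest, "manifest.json"
      )
    },
    error = function(e) {
      unlink(written)
      abort(paste0("pipeline stage 'write' failed: ", conditionMessage(e)),
        class = "foodscape_pipeline_error", parent = e
      )
    }
  )
  invisible(out_dir)
}

#' Forest plot of effect estimates
#'
#' Paired forest plot of odds ratios with 95% CIs, home buffer vs activity
#' space side by side, facetted by outcome and contrast. Pure presentation:
#' plotted values are exactly the estimate-table values.
#'
#' @param estimates tidy estimates tibble with columns `covariate`, `level`,
#'   `or`, `ci_low`, `ci_high` and optionally `area_kind`, `outcome`,
#'   `contrast`.
#' @return A ggplot object (empty plot for an empty table).
#' @export
plot_effects <- function(estimates) {
  if (is.null(estimates) || nrow(estimates) == 0) {
    return(ggplot2::ggplot() +
      ggplot2::theme_void() +
      ggplot2::labs(title = "No estimates"))
  }
  est <- dplyr::mutate(
    estimates,
    label = paste(.data$covariate, .data$level, sep = ": ")
  )
  if (!"area_kind" %in% names(est)) est$area_kind <- "exposure"
  p <- ggplot2::ggplot(est, ggplot2::aes(
    x = .data$or, y = .data$label, colour = .data$area_kind
  )) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.6), size = 0.3
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio (95% CI, log scale)", y = NULL, colour = "Measure"
    ) +
    ggplot2::theme_minimal()
  facets <- intersect(c("outcome", "contrast"), names(est))
  if (length(facets) > 0) {
    p <- p + ggplot2::facet_grid(
      rows = if ("contrast" %in% facets) ggplot2::vars(.data$contrast) else NULL,
      cols = if ("outcome" %in% facets) ggplot2::vars(.data$outcome) else NULL,
      scales = "free_y"
    )
  }
  p
}

#' @export
autoplot.foodscape_run <- function(object, ...) {
  plot_effects(object$estimates)
}

#' @export
autoplot.street_network <- function(object, ...) {
  ggplot2::ggplot(object$edges) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2),
      linewidth = 0.2, colour = "grey30"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' @export
autoplot.exposure_area <- function(object, n_arc = 24, ...) {
  segs <- object$segments
  polys <- purrr::map(seq_len(nrow(segs)), function(j) {
    ring <- capsule_polygon(
      segs[j, 1], segs[j, 2], segs[j, 3], segs[j, 4], segs[j, 5],
      n_arc = n_arc
    )
    tibble::tibble(part = j, x = ring[, 1], y = ring[, 2])
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(polys, ggplot2::aes(
    x = .data$x, y = .data$y, group = .data$part
  )) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.4, colour = NA) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", title = object$kind)
}
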