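# Survey calibration by the raking ratio method (iterative proportional
# fitting over the margin variables), plus weighted category proportions.

#' Calibrate sample weights by raking
#'
#' Iterative proportional fitting: weights are multiplied per margin
#' category by target/current weighted proportion, cycling over the margin
#' variables until every weighted marginal proportion is within `tol` of its
#' target. Weights are normalised to mean 1 so the weighted sample size
#' equals the raw one.
#'
#' @param data sample tibble; must contain every margin `variable` as a
#'   column.
#' @param margins tibble with columns `variable`, `level`, `proportion`
#'   (each variable's proportions summing to 1), e.g. [true_margins()].
#' @param tol convergence tolerance on weighted margin proportions.
#' @param max_iter maximum IPF sweeps; non-convergence raises
#'   `foodscape_nonconvergence_error` reporting the residual error.
#' @return Object of class `foodscape_weights`: list with `weights` tibble
#'   (`household_id`, `weight`), `iterations_used`, `max_margin_error`.
#' @export
rake <- function(data, margins, tol = 1e-6, max_iter = 200) {
  margins <- tibble::as_tibble(margins)
  vars <- unique(margins$variable)
  for (v in vars) {
    if (!v %in% names(data)) {
      abort(paste0("margin variable not in data: ", v),
        class = "foodscape_margin_error"
      )
    }
    m <- margins[margins$variable == v, ]
    if (abs(sum(m$proportion) - 1) > 1e-9) {
      abort(paste0("margin proportions for ", v, " do not sum to 1"),
        class = "foodscape_margin_error"
      )
    }
    obs <- as.character(unique(data[[v]]))
    if (!all(obs %in% m$level)) {
      abort(paste0(
        "sample categories missing from margins for ", v, ": ",
        paste(setdiff(obs, m$level), collapse = ", ")
      ), class = "foodscape_margin_error")
    }
    empty <- m$level[m$proportion > 0 & !m$level %in% obs]
    if (length(empty) > 0) {
      abort(paste0(
        "margin categor", if (length(empty) > 1) "ies" else "y",
        " with positive target but no sample members in ", v, ": ",
        paste(empty, collapse = ", ")
      ), class = "foodscape_empty_cell_error")
    }
    occupied_zero <- m$level[m$proportion <= 0 & m$level %in% obs]
    if (length(occupied_zero) > 0) {
      abort(paste0(
        "sample members present in zero-target categories of ", v, ": ",
        paste(occupied_zero, collapse = ", ")
      ), class = "foodscape_margin_error")
    }
  }
  n <- nrow(data)
  w <- rep(1, n)
  margin_error <- function(w) {
    err <- 0
    for (v in vars) {
      m <- margins[margins$variable == v, ]
      cur <- tapply(w, factor(as.character(data[[v]]), levels = m$level), sum)
      cur[is.na(cur)] <- 0
      err <- max(err, max(abs(cur / sum(w) - m$proportion)))
    }
    err
  }
  it <- 0
  err <- margin_error(w)
  while (err > tol && it < max_iter) {
    it <- it + 1
    for (v in vars) {
      m <- margins[margins$variable == v, ]
      f <- factor(as.character(data[[v]]), levels = m$level)
      cur <- tapply(w, f, sum)
      cur[is.na(cur)] <- 0
      adj <- ifelse(cur > 0, m$proportion * sum(w) / cur, 1)
      w <- as.numeric(w * adj[as.integer(f)])
    }
    err <- margin_error(w)
  }
  if (err > tol) {
    abort(
      sprintf("raking did not converge in %d iterations (max margin error %.3g)", max_iter, err),
      class = "foodscape_nonconvergence_error"
    )
  }
  w <- w / mean(w)
  structure(
    list(
      weights = tibble::tibble(
        household_id = if ("household_id" %in% names(data)) {
          data$household_id
        } else {
          as.character(seq_len(n))
        },
        weight = w
      ),
      iterations_used = it,
      max_margin_error = err
    ),
    class = "foodscape_weights"
  )
}

#' @export
print.foodscape_weights <- function(x, ...) {
  cat(
    "<foodscape_weights> n = ", nrow(x$weights),
    ", iterations = ", x$iterations_used,
    ", max margin error = ", format(x$max_margin_error, digits = 3),
    ", weight range [", paste(format(range(x$weights$weight), digits = 3), collapse = ", "),
    "]\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.foodscape_weights <- function(x, ...) x$weights

#' @export
glance.foodscape_weights <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$weights),
    iterations_used = x$iterations_used,
    max_margin_error = x$max_margin_error,
    min_weight = min(x$weights$weight),
    max_weight = max(x$weights$weight)
  )
}

as_weight_vector <- function(weights, data) {
  if (is.null(weights)) {
    return(rep(1, nrow(data)))
  }
  if (inherits(weights, "foodscape_weights")) {
    w <- weights$weights$weight[match(
      data$household_id, weights$weights$household_id
    )]
    if (anyNA(w)) {
      abort("weights missing for some households", class = "foodscape_margin_error")
    }
    return(as.numeric(w))
  }
  stopifnot(is.numeric(weights), length(weights) == nrow(data))
  as.numeric(weights)
}

#' Weighted category proportions
#'
#' @param data sample tibble.
#' @param variable column name (categorical).
#' @param weights `NULL` (equal weights), a numeric vector, or a
#'   [rake()] result.
#' @return Tibble `level`, `proportion` (sums to 1).
#' @export
weighted_proportions <- function(data, variable, weights = NULL) {
  w <- as_weight_vector(weights, data)
  f <- data[[variable]]
  if (!is.factor(f)) f <- factor(f)
  s <- tapply(w, f, sum)
  s[is.na(s)] <- 0
  tibble::tibble(
    level = names(s),
    proportion = as.numeric(s) / sum(w)
  )
}
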