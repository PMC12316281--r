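# Statistical stage: bivariate screening at alpha = 0.2, weighted logistic
# and linear models alongside the multinomial fits, GVIF collinearity
# diagnostics, and the home-buffer vs activity-space comparison table.

# glm with fractional calibration weights emits a harmless "non-integer
# #successes" warning; silence only that. `dat` must carry the weights in a
# `.w` column (glm resolves the weights expression inside `data`).
quiet_glm <- function(fml, dat) {
  withCallingHandlers(
    eval(bquote(stats::glm(
      .(fml),
      family = stats::binomial(), data = dat, weights = .w,
      control = stats::glm.control(maxit = 100)
    ))),
    warning = function(wr) {
      if (grepl("non-integer", conditionMessage(wr))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Fit a weighted logistic regression
#'
#' Binomial logit for the binary relative-density codings (`lt50`/`ge50`),
#' with odds ratios and Wald 95% confidence intervals.
#'
#' @inheritParams fit_multinomial
#' @param outcome name of a binary factor column; the first level is the
#'   baseline (`lt50`).
#' @return Object of class `foodscape_logit`; use [tidy()] / [glance()].
#' @export
fit_logistic <- function(data, outcome, covariates, weights = NULL) {
  y <- data[[outcome]]
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) != 2) {
    abort("logistic outcome must have exactly 2 observed classes",
      class = "foodscape_degenerate_distribution_error"
    )
  }
  w <- as_weight_vector(weights, data)
  dat <- droplevels(data)
  dat$.y <- y
  dat$.w <- w
  fml <- as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  fit <- quiet_glm(fml, dat)
  if (!fit$converged) {
    abort("logistic fit did not converge", class = "foodscape_convergence_error")
  }
  if (max(abs(coef(fit))) > 30) {
    warn("very large coefficients: probable separation",
      class = "foodscape_separation_warning"
    )
  }
  X <- model.matrix(fit)
  structure(
    list(
      fit = fit,
      outcome = outcome,
      outcome_levels = levels(y),
      covariates = covariates,
      terms = term_map(X, stats::terms(fit)),
      n = nrow(X)
    ),
    class = "foodscape_logit"
  )
}

#' @export
print.foodscape_logit <- function(x, ...) {
  cat(
    "<foodscape_logit> ", x$outcome, " (", x$outcome_levels[2], " vs ",
    x$outcome_levels[1], "), n = ", x$n, "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname fit_logistic
#' @param x fitted model.
#' @param conf.level Wald confidence level.
#' @param include_reference include reference-level rows (OR = 1).
#' @param ... unused.
#' @export
tidy.foodscape_logit <- function(x, conf.level = 0.95,
                                 include_reference = FALSE, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  est <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  out <- tibble::tibble(
    contrast = paste(x$outcome_levels[2], "vs", x$outcome_levels[1]),
    term = names(est),
    covariate = x$terms$covariate,
    level = x$terms$level,
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = unname(2 * pnorm(-abs(est / se))),
    or = exp(unname(est)),
    ci_low = exp(unname(est - z * se)),
    ci_high = exp(unname(est + z * se))
  )
  if (include_reference) {
    out <- add_reference_rows(out, x$covariates)
  }
  out
}

#' @export
glance.foodscape_logit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    edf = length(coef(x$fit)),
    logLik = as.numeric(stats::logLik(x$fit)),
    deviance = x$fit$deviance,
    converged = x$fit$converged
  )
}

#' Fit a weighted linear model for exposure-area size
#'
#' Weighted least squares for the area (km^2) of an exposure measure, with
#' a Shapiro-Wilk statistic on the residuals standing in for the visual
#' Q-Q-plot normality check.
#'
#' @inheritParams fit_multinomial
#' @param outcome name of the numeric outcome column (default `area_km2`).
#' @return Object of class `foodscape_linear`.
#' @export
fit_linear_area <- function(data, outcome = "area_km2", covariates,
                            weights = NULL) {
  w <- as_weight_vector(weights, data)
  dat <- droplevels(data)
  dat$.w <- w
  fml <- as.formula(paste(outcome, "~", paste(covariates, collapse = " + ")))
  fit <- lm(fml, data = dat, weights = .w)
  if (anyNA(coef(fit))) {
    abort("rank-deficient design (collinear covariates)",
      class = "foodscape_rank_deficiency_error"
    )
  }
  res <- stats::residuals(fit)
  sw <- if (stats::sd(res) < 1e-12) {
    list(statistic = c(W = NA_real_), p.value = NA_real_)
  } else {
    shapiro.test(if (length(res) > 5000) sample(res, 5000) else res)
  }
  X <- model.matrix(fit)
  structure(
    list(
      fit = fit,
      outcome = outcome,
      covariates = covariates,
      terms = term_map(X, stats::terms(fit)),
      shapiro_w = unname(sw$statistic),
      shapiro_p = sw$p.value,
      n = nrow(X)
    ),
    class = "foodscape_linear"
  )
}

#' @export
print.foodscape_linear <- function(x, ...) {
  cat(
    "<foodscape_linear> ", x$outcome, ", n = ", x$n,
    ", R^2 = ", format(summary(x$fit)$r.squared, digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname fit_linear_area
#' @param x fitted model.
#' @param conf.level confidence level.
#' @param ... unused.
#' @export
tidy.foodscape_linear <- function(x, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  est <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  tibble::tibble(
    term = names(est),
    covariate = x$terms$covariate,
    level = x$terms$level,
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = unname(2 * pnorm(-abs(est / se))),
    ci_low = unname(est - z * se),
    ci_high = unname(est + z * se)
  )
}

#' @export
glance.foodscape_linear <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    n = x$n,
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    shapiro_w = x$shapiro_w,
    shapiro_p = x$shapiro_p
  )
}

#' Bivariate screening of one covariate against one outcome
#'
#' Weighted likelihood-ratio test of the single-covariate model against the
#' intercept-only model; the covariate is kept for the multivariate model
#' when p < `alpha` (0.2 in the screening stage). Empty outcome-by-covariate
#' cells trigger a `foodscape_separation_warning` and a ridge-penalised
#' fallback fit, flagged in the output.
#'
#' @inheritParams fit_multinomial
#' @param covariate single covariate name.
#' @param alpha screening significance level.
#' @return One-row tibble: `covariate`, `statistic`, `df`, `p_value`,
#'   `keep`, `flag`.
#' @export
bivariate_screen <- function(data, outcome, covariate, weights = NULL,
                             alpha = 0.2) {
  y <- droplevels(factor(data[[outcome]]))
  x <- droplevels(factor(data[[covariate]]))
  w <- as_weight_vector(weights, data)
  if (nlevels(x) < 2) {
    return(tibble::tibble(
      covariate = covariate, statistic = NA_real_, df = NA_integer_,
      p_value = NA_real_, keep = FALSE, flag = "degenerate"
    ))
  }
  flag <- ""
  ridge <- 0
  if (any(table(y, x) == 0)) {
    warn(paste0("empty cell in ", outcome, " x ", covariate,
      ": using penalised screening fit"),
    class = "foodscape_separation_warning"
    )
    ridge <- 1e-4
    flag <- "penalized"
  }
  df <- (nlevels(y) - 1) * (nlevels(x) - 1)
  dat <- tibble::tibble(.y = y, .x = x)
  if (nlevels(y) == 2 && ridge == 0) {
    dat$.w <- w
    f1 <- quiet_glm(.y ~ .x, dat)
    f0 <- quiet_glm(.y ~ 1, dat)
    stat <- f0$deviance - f1$deviance
  } else {
    X1 <- model.matrix(~.x, dat)
    X0 <- X1[, 1, drop = FALSE]
    attr(X0, "assign") <- 0L
    f1 <- multinom_engine(X1, y, w, ridge = ridge)
    f0 <- multinom_engine(X0, y, w, ridge = ridge)
    stat <- 2 * (f1$loglik - f0$loglik)
  }
  p <- pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  tibble::tibble(
    covariate = covariate, statistic = stat, df = as.integer(df),
    p_value = p, keep = p < alpha, flag = flag
  )
}

#' Screen a set of covariates
#'
#' @inheritParams bivariate_screen
#' @param covariates covariate names to screen.
#' @return Tibble with one row per covariate (see [bivariate_screen()]).
#' @export
screen_covariates <- function(data, outcome, covariates = fs_covariates,
                              weights = NULL, alpha = 0.2) {
  purrr::map(covariates, function(cv) {
    bivariate_screen(data, outcome, cv, weights = weights, alpha = alpha)
  }) |> dplyr::bind_rows()
}

#' Generalized variance inflation factors
#'
#' GVIF per covariate from the determinant-ratio of correlation submatrices
#' of the (intercept-free) design matrix; the size-adjusted value is
#' `GVIF^(1/(2 df))`, acceptable when below 5. For single-df covariates the
#' GVIF equals the classical VIF `1/(1 - R_j^2)`.
#'
#' @param data data frame holding the covariates (factors or numeric).
#' @param covariates covariate names forming the model design.
#' @return Tibble: `covariate`, `gvif`, `df`, `adjusted_gvif`, `acceptable`.
#' @export
gvif <- function(data, covariates) {
  fml <- stats::reformulate(covariates)
  mf <- droplevels(stats::model.frame(fml, data = data))
  X <- model.matrix(fml, mf)
  asg <- attr(X, "assign")
  labels <- attr(attr(mf, "terms"), "term.labels")
  X <- X[, asg != 0, drop = FALSE]
  asg <- asg[asg != 0]
  if (ncol(X) < 2) {
    # a single-column design cannot be collinear with anything
    return(tibble::tibble(
      covariate = labels, gvif = 1, df = 1L, adjusted_gvif = 1,
      acceptable = TRUE
    ))
  }
  if (any(apply(X, 2, stats::sd) < 1e-12)) {
    abort("constant design column", class = "foodscape_singular_design_error")
  }
  R <- stats::cor(X)
  ldR <- determinant(R, logarithm = TRUE)
  if (ldR$sign <= 0 || as.numeric(ldR$modulus) < log(1e-12)) {
    abort("singular design: aliased or duplicated covariates",
      class = "foodscape_singular_design_error"
    )
  }
  purrr::map(seq_along(labels), function(g) {
    cols <- which(asg == g)
    ld1 <- determinant(R[cols, cols, drop = FALSE], logarithm = TRUE)
    ld2 <- determinant(R[-cols, -cols, drop = FALSE], logarithm = TRUE)
    gv <- exp(as.numeric(ld1$modulus) + as.numeric(ld2$modulus) -
      as.numeric(ldR$modulus))
    df <- length(cols)
    adj <- gv^(1 / (2 * df))
    tibble::tibble(
      covariate = labels[g], gvif = gv, df = as.integer(df),
      adjusted_gvif = adj, acceptable = adj < 5
    )
  }) |> dplyr::bind_rows()
}

#' Screen covariates and fit the appropriate exposure model
#'
#' Runs the bivariate screening at `screen_alpha`, then fits the weighted
#' model matching the outcome coding: multinomial logit for 3-class codings
#' (count tertiles, diversity bands), binomial logit for the binary
#' relative-density codings, and weighted least squares for the numeric
#' area outcome. Returns the screening table, the fitted model, its GVIF
#' report and tidy effect estimates.
#'
#' @inheritParams fit_multinomial
#' @param screen_alpha screening significance level (0.2).
#' @return List of class `foodscape_model_run`: `outcome`, `screen`,
#'   `covariates_used`, `fit`, `collinearity`, `estimates`.
#' @export
fit_exposure_model <- function(data, outcome, covariates = fs_covariates,
                               weights = NULL, screen_alpha = 0.2) {
  numeric_outcome <- is.numeric(data[[outcome]])
  scr <- if (numeric_outcome) {
    # LR screening needs a categorical outcome; for the area outcome the
    # bivariate stage is a weighted single-covariate F test
    purrr::map(covariates, function(cv) {
      v <- data[[cv]]
      degenerate <- if (is.numeric(v)) {
        stats::var(v) == 0
      } else {
        nlevels(droplevels(factor(v))) < 2
      }
      if (degenerate) {
        return(tibble::tibble(
          covariate = cv, statistic = NA_real_, df = NA_integer_,
          p_value = NA_real_, keep = FALSE, flag = "degenerate"
        ))
      }
      f1 <- fit_linear_area(data, outcome, cv, weights)
      a <- stats::anova(f1$fit)
      tibble::tibble(
        covariate = cv, statistic = a$`F value`[1],
        df = as.integer(a$Df[1]), p_value = a$`Pr(>F)`[1],
        keep = a$`Pr(>F)`[1] < screen_alpha, flag = ""
      )
    }) |> dplyr::bind_rows()
  } else {
    screen_covariates(data, outcome, covariates, weights, screen_alpha)
  }
  used <- scr$covariate[scr$keep]
  if (length(used) == 0) {
    return(structure(
      list(
        outcome = outcome, screen = scr, covariates_used = character(0),
        fit = NULL, collinearity = NULL,
        estimates = tibble::tibble()
      ),
      class = "foodscape_model_run"
    ))
  }
  fit <- if (numeric_outcome) {
    fit_linear_area(data, outcome, used, weights)
  } else if (nlevels(droplevels(factor(data[[outcome]]))) == 2) {
    tryCatch(
      fit_logistic(data, outcome, used, weights),
      foodscape_convergence_error = function(e) {
        # same binomial likelihood via the penalised multinomial engine
        warn(
          paste0(outcome, ": logistic non-convergence; using ridge fallback"),
          class = "foodscape_separation_warning"
        )
        fit_multinomial(data, outcome, used, weights, ridge = 1e-3)
      }
    )
  } else {
    # fall back to a lightly penalised fit under separation (sparse cells
    # are common with tertile outcomes crossed with many covariate levels)
    tryCatch(
      fit_multinomial(data, outcome, used, weights),
      foodscape_separation_error = function(e) {
        warn(
          paste0(outcome, ": separation in multinomial fit; using ridge fallback"),
          class = "foodscape_separation_warning"
        )
        fit_multinomial(data, outcome, used, weights, ridge = 1e-3)
      },
      foodscape_convergence_error = function(e) {
        warn(
          paste0(outcome, ": non-convergence; using ridge fallback"),
          class = "foodscape_separation_warning"
        )
        fit_multinomial(data, outcome, used, weights, ridge = 1e-3)
      }
    )
  }
  coll <- if (length(used) >= 2) gvif(data, used) else NULL
  est <- tidy(fit)
  est <- est[est$covariate != "(Intercept)", , drop = FALSE]
  est$outcome <- outcome
  structure(
    list(
      outcome = outcome, screen = scr, covariates_used = used, fit = fit,
      collinearity = coll, estimates = est
    ),
    class = "foodscape_model_run"
  )
}

#' @export
print.foodscape_model_run <- function(x, ...) {
  cat(
    "<foodscape_model_run> ", x$outcome, ": ",
    length(x$covariates_used), "/", nrow(x$screen),
    " covariates retained (", paste(x$covariates_used, collapse = ", "),
    ")\n",
    sep = ""
  )
  invisible(x)
}

#' Compare effect estimates between exposure measures
#'
#' Joins the tidy estimates fitted on the home-buffer and activity-space
#' measures and flags significance flips: covariate levels significant (at
#' `alpha`) for one measure but not the other.
#'
#' @param est_home,est_activity tidy estimate tibbles (from
#'   [fit_exposure_model()]`$estimates` or [tidy()]).
#' @param alpha significance threshold (0.05).
#' @return Tibble with ORs/CIs side by side, `sig_home`, `sig_activity`,
#'   `flip`.
#' @export
compare_measures <- function(est_home, est_activity, alpha = 0.05) {
  keys <- intersect(
    c("outcome", "contrast", "covariate", "level"),
    intersect(names(est_home), names(est_activity))
  )
  if (nrow(est_home) == 0 || nrow(est_activity) == 0) {
    return(tibble::tibble())
  }
  ci_cols <- c("or", "ci_low", "ci_high", "p.value")
  h <- est_home[, c(keys, ci_cols)]
  a <- est_activity[, c(keys, ci_cols)]
  dplyr::inner_join(h, a, by = keys, suffix = c("_home", "_activity")) |>
    dplyr::mutate(
      sig_home = .data$p.value_home < alpha,
      sig_activity = .data$p.value_activity < alpha,
      flip = xor(.data$sig_home, .data$sig_activity)
    )
}
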