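# Weighted multinomial logit, fitted by Newton-Raphson maximum likelihood.
# Baseline class = first factor level; coefficients are log-odds of each
# non-baseline class against the baseline, as in a standard multinomial
# logistic regression.

multinom_engine <- function(X, y, w, ridge = 0, max_iter = 100, tol = 1e-9) {
  K <- nlevels(y)
  p <- ncol(X)
  n <- nrow(X)
  Y <- matrix(0, n, K - 1)
  for (k in 2:K) Y[, k - 1] <- as.numeric(as.integer(y) == k)
  B <- matrix(0, p, K - 1)
  loglik <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
    sum(w * (rowSums(Y * eta) - lse)) - 0.5 * ridge * sum(B^2)
  }
  probs <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    e <- exp(eta - m)
    denom <- exp(-m) + rowSums(e)
    e / denom # n x (K-1), probabilities of non-baseline classes
  }
  ll <- loglik(B)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    P <- probs(B)
    G <- t(X) %*% (w * (Y - P)) - ridge * B # p x (K-1)
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (k in seq_len(K - 1)) {
      for (l in seq_len(k)) {
        wt <- w * P[, k] * ((k == l) - P[, l])
        blk <- -t(X) %*% (wt * X)
        ri <- (k - 1) * p + seq_len(p)
        ci <- (l - 1) * p + seq_len(p)
        H[ri, ci] <- blk
        H[ci, ri] <- t(blk)
      }
    }
    diag(H) <- diag(H) - ridge
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) NULL)
    if (is.null(step)) {
      abort("singular Hessian in multinomial fit (separation or collinear design)",
        class = "foodscape_separation_error"
      )
    }
    # Newton step with halving
    shrink <- 1
    repeat {
      Bn <- B - shrink * matrix(step, p, K - 1)
      lln <- loglik(Bn)
      if (is.finite(lln) && lln >= ll - 1e-12) break
      shrink <- shrink / 2
      if (shrink < 1e-8) break
    }
    delta <- max(abs(Bn - B))
    B <- Bn
    ll_old <- ll
    ll <- lln
    if (max(abs(G)) < 1e-6 || delta < tol) {
      converged <- TRUE
      break
    }
  }
  P <- probs(B)
  H <- matrix(0, p * (K - 1), p * (K - 1))
  for (k in seq_len(K - 1)) {
    for (l in seq_len(k)) {
      wt <- w * P[, k] * ((k == l) - P[, l])
      blk <- -t(X) %*% (wt * X)
      ri <- (k - 1) * p + seq_len(p)
      ci <- (l - 1) * p + seq_len(p)
      H[ri, ci] <- blk
      H[ci, ri] <- t(blk)
    }
  }
  diag(H) <- diag(H) - ridge
  V <- tryCatch(solve(-H), error = function(e) {
    matrix(NA_real_, nrow(H), ncol(H))
  })
  list(
    coefficients = B, vcov = V, loglik = ll, converged = converged,
    iter = iter, fitted = cbind(1 - rowSums(P), P)
  )
}

term_map <- function(X, terms_obj) {
  asg <- attr(X, "assign")
  labels <- attr(terms_obj, "term.labels")
  covariate <- character(length(asg))
  covariate[asg == 0] <- "(Intercept)"
  covariate[asg > 0] <- labels[asg[asg > 0]]
  level <- mapply(function(cn, cv) {
    if (cv == "(Intercept)") "" else sub(cv, "", cn, fixed = TRUE)
  }, colnames(X), covariate)
  tibble::tibble(term = colnames(X), covariate = covariate, level = unname(level))
}

#' Fit a weighted multinomial logistic regression
#'
#' Maximum-likelihood multinomial logit with case weights; odds ratios are
#' exponentiated coefficients against the baseline outcome class (the first
#' factor level, i.e. the lowest tertile/band), with Wald 95% confidence
#' intervals from the observed information.
#'
#' @param data tibble holding outcome and covariates as factors.
#' @param outcome name of the outcome column (>= 2 classes; 3 in the
#'   exposure codings).
#' @param covariates character vector of covariate column names.
#' @param weights `NULL`, numeric vector, or a [rake()] result. Estimates
#'   are invariant to rescaling all weights by a constant.
#' @param ridge optional L2 penalty used as a fallback under separation.
#' @return Object of class `foodscape_multinom`; use [tidy()] for effect
#'   estimates and [glance()] for fit summaries.
#' @export
fit_multinomial <- function(data, outcome, covariates, weights = NULL,
                            ridge = 0) {
  y <- data[[outcome]]
  if (!is.factor(y)) y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2) {
    abort("outcome has fewer than 2 observed classes",
      class = "foodscape_degenerate_distribution_error"
    )
  }
  w <- as_weight_vector(weights, data)
  fml <- stats::reformulate(covariates)
  mf <- droplevels(stats::model.frame(fml, data = data))
  X <- model.matrix(fml, mf)
  fit <- multinom_engine(X, y, w, ridge = ridge)
  if (!fit$converged) {
    abort("multinomial fit did not converge", class = "foodscape_convergence_error")
  }
  if (max(abs(fit$coefficients)) > 30) {
    warn("very large coefficients: probable separation",
      class = "foodscape_separation_warning"
    )
  }
  structure(
    list(
      coefficients = fit$coefficients,
      vcov = fit$vcov,
      loglik = fit$loglik,
      converged = fit$converged,
      n = nrow(X),
      edf = length(fit$coefficients),
      outcome = outcome,
      outcome_levels = levels(y),
      covariates = covariates,
      terms = term_map(X, attr(mf, "terms")),
      weights_total = sum(w)
    ),
    class = "foodscape_multinom"
  )
}

#' @export
print.foodscape_multinom <- function(x, ...) {
  cat(
    "<foodscape_multinom> ", x$outcome, " (", length(x$outcome_levels),
    " classes, baseline ", x$outcome_levels[1], "), n = ", x$n,
    ", logLik = ", format(x$loglik, digits = 6), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname fit_multinomial
#' @param x fitted model.
#' @param conf.level Wald confidence level.
#' @param include_reference include rows for reference covariate levels
#'   (OR fixed at 1 with degenerate CI).
#' @param ... unused.
#' @export
tidy.foodscape_multinom <- function(x, conf.level = 0.95,
                                    include_reference = FALSE, ...) {
  p <- nrow(x$coefficients)
  K1 <- ncol(x$coefficients)
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- purrr::map(seq_len(K1), function(k) {
    idx <- (k - 1) * p + seq_len(p)
    est <- x$coefficients[, k]
    se <- sqrt(pmax(diag(x$vcov)[idx], 0))
    tibble::tibble(
      contrast = paste(x$outcome_levels[k + 1], "vs", x$outcome_levels[1]),
      term = x$terms$term,
      covariate = x$terms$covariate,
      level = x$terms$level,
      estimate = est,
      std.error = se,
      statistic = est / se,
      p.value = 2 * pnorm(-abs(est / se)),
      or = exp(est),
      ci_low = exp(est - z * se),
      ci_high = exp(est + z * se)
    )
  }) |> dplyr::bind_rows()
  if (include_reference) {
    out <- add_reference_rows(out, x$covariates)
  }
  out
}

#' @export
glance.foodscape_multinom <- function(x, ...) {
  tibble::tibble(
    n = x$n, edf = x$edf, logLik = x$loglik, converged = x$converged,
    n_classes = length(x$outcome_levels)
  )
}

add_reference_rows <- function(est, covariates) {
  # reference level rows carry OR = 1 with a degenerate CI
  refs <- est |>
    dplyr::distinct(.data$contrast) |>
    dplyr::mutate(ref = list(covariates)) |>
    tidyr::unnest("ref") |>
    dplyr::transmute(
      contrast = .data$contrast,
      term = paste0(.data$ref, "(ref)"),
      covariate = .data$ref,
      level = "(reference)",
      estimate = 0, std.error = 0, statistic = NA_real_, p.value = NA_real_,
      or = 1, ci_low = 1, ci_high = 1
    )
  dplyr::bind_rows(est, refs) |>
    dplyr::arrange(.data$contrast, .data$covariate)
}
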