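test_that("logistic OR on an all-positive 2x2 table equals ad/bc", {
  tab <- matrix(c(30, 14, 18, 42), 2, 2,
    dimnames = list(c("x0", "x1"), c("lt50", "ge50"))
  )
  df <- expand_table(tab, "g", "y")
  df$household_id <- as.character(seq_len(nrow(df)))
  fit <- fit_logistic(df, "y", "g")
  est <- tidy(fit)
  row <- est[est$covariate == "g", ]
  or_closed <- (tab["x0", 1] * tab["x1", 2]) / (tab["x0", 2] * tab["x1", 1])
  expect_equal(log(row$or), log(or_closed), tolerance = 1e-6)
  expect_true(row$ci_low <= row$or && row$or <= row$ci_high)
  # reference rows pin OR = 1
  full <- tidy(fit, include_reference = TRUE)
  ref <- full[full$level == "(reference)", ]
  expect_equal(ref$or, 1)
})

test_that("multinomial ORs on a 2x3 table equal the cross-product ratios", {
  tab <- matrix(c(40, 25, 30, 35, 20, 50), 2, 3,
    dimnames = list(c("x0", "x1"), c("T1", "T2", "T3"))
  )
  df <- expand_table(tab, "g", "y")
  df$household_id <- as.character(seq_len(nrow(df)))
  fit <- fit_multinomial(df, "y", "g")
  est <- tidy(fit)
  for (k in c("T2", "T3")) {
    closed <- (tab["x1", k] / tab["x1", "T1"]) / (tab["x0", k] / tab["x0", "T1"])
    got <- est$or[est$contrast == paste(k, "vs T1") & est$covariate == "g"]
    expect_equal(log(got), log(closed), tolerance = 1e-6)
  }
})

test_that("the in-package multinomial agrees with glm on 2-class outcomes", {
  withr::with_seed(88, {
    n <- 400
    df <- tibble::tibble(
      household_id = as.character(1:n),
      g = factor(sample(c("a", "b", "c"), n, TRUE)),
      z = factor(sample(c("u", "v"), n, TRUE))
    )
    eta <- -0.3 + 0.8 * (df$g == "b") - 0.5 * (df$z == "v")
    df$y <- factor(ifelse(runif(n) < plogis(eta), "pos", "neg"), c("neg", "pos"))
    w <- runif(n, 0.3, 2.5)
    fm <- fit_multinomial(df, "y", c("g", "z"), weights = w)
    fl <- fit_logistic(df, "y", c("g", "z"), weights = w)
    expect_equal(
      as.numeric(fm$coefficients),
      unname(coef(fl$fit)),
      tolerance = 1e-5
    )
    expect_equal(
      sqrt(diag(fm$vcov)),
      unname(sqrt(diag(vcov(fl$fit)))),
      tolerance = 1e-4
    )
  })
})

test_that("estimates are invariant to rescaling all weights", {
  withr::with_seed(12, {
    n <- 300
    df <- tibble::tibble(
      household_id = as.character(1:n),
      g = factor(sample(c("a", "b"), n, TRUE)),
      y3 = factor(sample(c("T1", "T2", "T3"), n, TRUE)),
      y2 = factor(sample(c("lt50", "ge50"), n, TRUE), c("lt50", "ge50"))
    )
    w <- runif(n, 0.5, 2)
    m1 <- fit_multinomial(df, "y3", "g", weights = w)
    m2 <- fit_multinomial(df, "y3", "g", weights = 2 * w)
    expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-8)
    l1 <- fit_logistic(df, "y2", "g", weights = w)
    l2 <- fit_logistic(df, "y2", "g", weights = 2 * w)
    expect_equal(coef(l1$fit), coef(l2$fit), tolerance = 1e-8)
  })
})

test_that("a planted log-OR of 0.7 is recovered within 3 SE at n = 5000", {
  withr::with_seed(5, {
    n <- 5000
    g <- factor(sample(c("ref", "exp"), n, TRUE), c("ref", "exp"))
    eta <- -0.4 + 0.7 * (g == "exp")
    y <- factor(ifelse(runif(n) < plogis(eta), "ge50", "lt50"), c("lt50", "ge50"))
    df <- tibble::tibble(household_id = as.character(1:n), g = g, y = y)
    est <- tidy(fit_logistic(df, "y", "g"))
    row <- est[est$covariate == "g", ]
    expect_lt(abs(row$estimate - 0.7), 3 * row$std.error)
  })
})

test_that("bivariate screening keeps strong predictors and drops constants", {
  withr::with_seed(42, {
    n <- 200
    y <- factor(sample(c("T1", "T2", "T3"), n, TRUE))
    df <- tibble::tibble(
      household_id = as.character(1:n),
      y = y,
      same = y, # deterministic predictor
      const = factor(rep("only", n))
    )
    s1 <- suppressWarnings(bivariate_screen(df, "y", "same"))
    expect_true(s1$keep)
    expect_lt(s1$p_value, 1e-10)
    s2 <- bivariate_screen(df, "y", "const")
    expect_false(s2$keep)
    expect_equal(s2$flag, "degenerate")
  })
})

test_that("screening flags empty cells and falls back to a penalised fit", {
  df <- tibble::tibble(
    household_id = as.character(1:60),
    y = factor(rep(c("T1", "T2", "T3"), each = 20)),
    g = factor(c(rep("a", 40), rep("b", 20))) # no b in T1/T2? -> a cell is empty
  )
  # y T1,T2 only have g = a; cell (T3, a) is 0 as well? construct precisely:
  df$g <- factor(c(rep("a", 20), rep("a", 20), rep("b", 20)))
  expect_warning(
    s <- bivariate_screen(df, "y", "g"),
    class = "foodscape_separation_warning"
  )
  expect_equal(s$flag, "penalized")
  expect_true(is.finite(s$p_value))
})

test_that("screening holds its nominal type-I rate at alpha = 0.2", {
  withr::with_seed(2024, {
    reps <- 500
    n <- 400
    rejections <- 0
    for (r in seq_len(reps)) {
      df <- tibble::tibble(
        household_id = as.character(1:n),
        y = factor(sample(c("lt50", "ge50"), n, TRUE), c("lt50", "ge50")),
        g = factor(sample(c("a", "b", "c"), n, TRUE))
      )
      if (bivariate_screen(df, "y", "g")$keep) rejections <- rejections + 1
    }
    expect_lt(abs(rejections / reps - 0.2), 0.04)
  })
})

test_that("weighted linear model recovers structure and checks residuals", {
  withr::with_seed(9, {
    n <- 699
    zone <- factor(
      sample(c("city_center", "pericentral", "peri_urban"), n, TRUE),
      c("city_center", "pericentral", "peri_urban")
    )
    # noiseless linear outcome -> R^2 = 1
    df0 <- tibble::tibble(
      household_id = as.character(1:n), zone = zone,
      area_km2 = 2 + 1.5 * (zone == "peri_urban")
    )
    f0 <- fit_linear_area(df0, "area_km2", "zone")
    expect_equal(suppressWarnings(glance(f0)$r.squared), 1, tolerance = 1e-9)
    # planted peri-urban effect recovered within 3 SE under noise
    beta <- 1.2
    df1 <- dplyr::mutate(df0,
      area_km2 = 2 + beta * (zone == "peri_urban") + rnorm(n, 0, 1)
    )
    f1 <- fit_linear_area(df1, "area_km2", "zone")
    est <- tidy(f1)
    row <- est[est$level == "peri_urban", ]
    expect_lt(abs(row$estimate - beta), 3 * row$std.error)
    expect_true(is.finite(glance(f1)$shapiro_w))
    # duplicated covariate -> rank deficiency
    df1$zone2 <- df1$zone
    expect_error(
      fit_linear_area(df1, "area_km2", c("zone", "zone2")),
      class = "foodscape_rank_deficiency_error"
    )
  })
})

test_that("null linear models cover zero in >= 90% of replicates", {
  withr::with_seed(31, {
    reps <- 200
    n <- 150
    covered <- 0
    g <- factor(rep(c("a", "b"), each = n / 2))
    for (r in seq_len(reps)) {
      df <- tibble::tibble(
        household_id = as.character(1:n), g = g,
        area_km2 = rnorm(n)
      )
      est <- tidy(fit_linear_area(df, "area_km2", "g"))
      row <- est[est$covariate == "g", ]
      if (row$ci_low <= 0 && row$ci_high >= 0) covered <- covered + 1
    }
    expect_gte(covered / reps, 0.9)
  })
})

test_that("GVIF is 1 on orthogonal designs and matches auxiliary-regression VIF", {
  # perfectly balanced 2x2 factorial: orthogonal dummies
  df <- tidyr::expand_grid(
    a = factor(c("a1", "a2")), b = factor(c("b1", "b2")),
    rep = 1:25
  )
  rep_gvif <- gvif(df, c("a", "b"))
  expect_equal(rep_gvif$gvif, c(1, 1), tolerance = 1e-9)
  expect_true(all(rep_gvif$acceptable))

  withr::with_seed(7, {
    n <- 500
    x1 <- rnorm(n)
    x2 <- 0.6 * x1 + rnorm(n, 0, 0.8)
    x3 <- rnorm(n)
    dfn <- tibble::tibble(x1 = x1, x2 = x2, x3 = x3)
    got <- gvif(dfn, c("x1", "x2", "x3"))
    # oracle: classical VIF via auxiliary regressions
    for (v in c("x1", "x2", "x3")) {
      r2 <- summary(lm(stats::reformulate(setdiff(c("x1", "x2", "x3"), v), v),
        data = dfn
      ))$r.squared
      expect_equal(got$gvif[got$covariate == v], 1 / (1 - r2), tolerance = 1e-9)
    }
    expect_equal(got$adjusted_gvif, sqrt(got$gvif), tolerance = 1e-12)
    expect_true(all(got$gvif >= 1 - 1e-9))
  })

  # duplicated covariate -> singular design
  df$a2 <- df$a
  expect_error(gvif(df, c("a", "a2")), class = "foodscape_singular_design_error")
})

test_that("multi-df GVIF detects planted association between factors", {
  withr::with_seed(15, {
    n <- 600
    a <- factor(sample(c("a1", "a2", "a3"), n, TRUE))
    # b strongly depends on a
    b <- factor(ifelse(runif(n) < 0.8, as.character(a), sample(c("a1", "a2", "a3"), n, TRUE)))
    levels(b) <- c("b1", "b2", "b3")
    z <- factor(sample(c("z1", "z2"), n, TRUE))
    df <- tibble::tibble(a = a, b = b, z = z)
    rep <- gvif(df, c("a", "b", "z"))
    expect_gt(rep$gvif[rep$covariate == "a"], 2)
    expect_equal(rep$df[rep$covariate == "a"], 2L)
    expect_equal(
      rep$adjusted_gvif,
      rep$gvif^(1 / (2 * rep$df)),
      tolerance = 1e-12
    )
    expect_lt(abs(rep$gvif[rep$covariate == "z"] - 1), 0.1)
  })
})

test_that("compare_measures flags significance flips and handles edge cases", {
  est <- tibble::tibble(
    outcome = "n_stores_class",
    contrast = "T3 vs T1",
    covariate = c("car", "education"),
    level = c("yes", "postgraduate"),
    or = c(0.5, 1.4),
    ci_low = c(0.3, 0.9),
    ci_high = c(0.9, 2.1),
    p.value = c(0.01, 0.2)
  )
  same <- compare_measures(est, est)
  expect_true(all(!same$flip))
  est2 <- est
  est2$p.value <- c(0.5, 0.001)
  both <- compare_measures(est, est2)
  expect_true(all(both$flip))
  expect_equal(nrow(compare_measures(est[0, ], est)), 0)
})

test_that("fit_exposure_model picks the model family from the outcome", {
  withr::with_seed(3, {
    n <- 400
    df <- tibble::tibble(
      household_id = as.character(1:n),
      age = factor(sample(foodscape:::fs_levels$age, n, TRUE), foodscape:::fs_levels$age),
      car = factor(sample(c("no", "yes"), n, TRUE), c("no", "yes"))
    )
    eta <- 0.9 * (df$car == "yes")
    df$fv_class <- factor(
      ifelse(runif(n) < plogis(eta - 0.4), "ge50", "lt50"), c("lt50", "ge50")
    )
    df$n_stores_class <- factor(
      sample(c("T1", "T2", "T3"), n, TRUE, prob = c(0.4, 0.35, 0.25))
    )
    run2 <- fit_exposure_model(df, "fv_class", c("age", "car"))
    expect_s3_class(run2$fit, "foodscape_logit")
    expect_true("car" %in% run2$covariates_used)
    run3 <- fit_exposure_model(df, "n_stores_class", c("age", "car"),
      screen_alpha = 1
    )
    expect_s3_class(run3$fit, "foodscape_multinom")
    expect_equal(sort(run3$covariates_used), c("age", "car"))
    expect_true(all(run3$collinearity$acceptable))
  })
})
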