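test_that("pearson correlation matches the textbook formula and t-transform", {
  x <- c(1, 2, 3, 4)
  res <- pearson_corr(x, c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)               # hand-computed product-moment r
  expect_equal(res$df, 2)
  tval <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(-tval, 2))

  expect_equal(pearson_corr(x, x)$r, 1)
  expect_error(pearson_corr(x, rep(1, 4)), "zero variance")
  expect_error(pearson_corr(1:2, 2:1), "at least 3")

  # pairwise deletion
  res2 <- pearson_corr(c(x, NA), c(1, 3, 2, 4, 99))
  expect_equal(res2$n, 4)
  expect_equal(res2$r, 0.8)
})

test_that("partial correlation equals residualized correlation and reduces to pearson", {
  set.seed(401)
  x <- rnorm(8); y <- rnorm(8); z1 <- rnorm(8); z2 <- rnorm(8)
  res <- partial_corr(x, y, data.frame(z1, z2))
  # brute-force normal-equations residualization
  X <- cbind(1, z1, z2)
  bx <- solve(t(X) %*% X, t(X) %*% x)
  by <- solve(t(X) %*% X, t(X) %*% y)
  r_oracle <- cor(x - X %*% bx, y - X %*% by)[1]
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$df, 8 - 2 - 2)

  expect_identical(partial_corr(x, y, NULL), pearson_corr(x, y))
  expect_error(partial_corr(x, y, data.frame(z1, z1b = z1)), "collinear")
  expect_error(partial_corr(x, y, data.frame(x)), "zero residual")
})

test_that("partialling out the true driver of y leaves no association with x", {
  set.seed(402)
  rs <- replicate(200, {
    z <- rnorm(50)
    x <- rnorm(50)
    y <- z + rnorm(50)
    partial_corr(x, y, data.frame(z))$r
  })
  expect_lt(abs(mean(rs)), 2 * sd(rs) / sqrt(length(rs)))
})

test_that("extreme-value screening removes only |z| beyond the cut-off", {
  expect_length(exclude_extremes(rep(5, 20))$excluded, 0)

  set.seed(403)
  v <- c(rnorm(100), 10)
  ex <- exclude_extremes(v, 3.29)
  expect_equal(ex$excluded, 101L)
  expect_length(ex$kept, 100)
  expect_true(is.na(ex$values[101]))

  # 114 -> 113, the screening a cohort's time-lag column goes through
  set.seed(404)
  lags <- c(rnorm(113, 2.5, 0.1), 1.2)
  expect_length(exclude_extremes(lags)$kept, 113)
})

test_that("hierarchical regression recovers planted standardized effects", {
  set.seed(405)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- 0.5 * x1 + 0.3 * x2 + rnorm(n)
  d <- data.frame(y, x1, x2, x3)
  hr <- hierarchical_regression(d, "y", list(c("x1", "x2"), "x3"))
  expect_equal(hr$n, n)
  m1 <- hr$models[[1]]
  sd_y <- sqrt(0.25 + 0.09 + 1)
  beta_true <- c(0.5, 0.3) / sd_y        # standardized planted betas
  se <- summary(lm(scale(y) ~ scale(x1) + scale(x2)))$coefficients[2:3, 2]
  expect_true(all(abs(m1$coefficients$beta - beta_true) < 2 * se))
  # R2 never decreases across blocks; adjusted R2 never exceeds R2
  r2s <- vapply(hr$models, `[[`, 0, "r2")
  expect_true(all(diff(r2s) >= 0))
  expect_true(all(vapply(hr$models, `[[`, 0, "adj_r2") <= r2s))
  # block 1 F-change is the model-1 F
  expect_equal(m1$F_change, m1$F)
})

test_that("a perfectly determined criterion gives R2 = 1 and no later improvement", {
  set.seed(406)
  x1 <- rnorm(60); x2 <- rnorm(60); z <- rnorm(60)
  y <- 2 * x1 - x2
  hr <- suppressWarnings(  # summary.lm warns on an essentially perfect fit
    hierarchical_regression(data.frame(y, x1, x2, z), "y",
                            list(c("x1", "x2"), "z")))
  expect_equal(hr$models[[1]]$r2, 1, tolerance = 1e-10)
  expect_equal(hr$models[[2]]$r2 - hr$models[[1]]$r2, 0, tolerance = 1e-8)

  expect_error(hierarchical_regression(data.frame(y, x1), "y",
                                       list("nope")), "missing columns")
  expect_error(
    hierarchical_regression(data.frame(y = rnorm(3), x1 = rnorm(3),
                                       x2 = rnorm(3), x3 = rnorm(3)),
                            "y", list(c("x1", "x2"), "x3")),
    "too few")
})

test_that("the cohort report builds both grids and the block regression", {
  set.seed(407)
  n <- 80
  tab <- data.frame(
    hamd = rnorm(n, 14, 8), bdi = rnorm(n, 20, 13),
    iip = rnorm(n, 1.5, .5), tdeq_dep = rnorm(n, 4, 1.5),
    tdeq_selfcrit = rnorm(n, 4, 1.4),
    ms_total = runif(n, .4, .6), ms_patient_led = runif(n, .2, .35),
    ms_clinician_led = runif(n, .2, .35),
    leading = rnorm(n, 0, .05),
    lag_mean = rnorm(n, 2.5, .1),
    lag_mean_patient_led = rnorm(n, 2.5, .15),
    lag_mean_clinician_led = rnorm(n, 2.5, .15),
    age = round(runif(n, 20, 60)), gender = rbinom(n, 1, .7),
    medication = rbinom(n, 1, .4), gross_move_patient = runif(n, .3, .8))
  rep <- analysis_report(tab)
  expect_s3_class(rep, "cohort_report")
  expect_equal(dim(rep$zero_order$r), c(5, 7))
  # null cohort: grid entries centered on zero
  expect_lt(max(abs(as.matrix(rep$zero_order$r))), 0.5)
  expect_lt(abs(mean(as.matrix(rep$zero_order$r))), 0.1)
  expect_s3_class(rep$regression, "hier_reg")
  expect_match(rep$note, "uncorrected")

  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("correlations.csv", "partial_correlations.csv", "regression.csv",
      "report.txt")))))
  back <- utils::read.csv(file.path(dir, "correlations.csv"))
  expect_equal(back$ms_total[back$stat == "r" & back$scale == "hamd"],
               rep$zero_order$r["hamd", "ms_total"])

  expect_error(analysis_report(tab[, 1:5]), "lacks")
  expect_error(analysis_report(tab[, setdiff(names(tab), "age")]),
               "missing control")
})
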