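#' Two-sided Pearson correlation with pairwise deletion
#'
#' @param x,y numeric vectors of equal length; `NA` pairs are dropped.
#' @return A `corr_result`: list with `r`, `n` (complete pairs), `df`, `p`
#'   (two-sided).
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, alternative = "two.sided", method = "pearson")
  structure(list(r = unname(ct$estimate), n = n,
                 df = unname(ct$parameter), p = ct$p.value,
                 covariates = 0L),
            class = "corr_result")
}

#' Partial correlation by residualization
#'
#' Correlates the least-squares residuals of `x` and `y` on the covariates
#' (intercept always included), over the complete cases of all variables
#' involved. With an empty covariate set this is exactly [pearson_corr()].
#' The two-sided p-value uses the t transform with `n - 2 - k` degrees of
#' freedom, `k` the number of covariate columns.
#'
#' @param x,y numeric vectors.
#' @param covariates data frame / matrix of covariate columns, or `NULL`.
#' @return A `corr_result` with `covariates = k`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L) return(pearson_corr(x, y))
  C <- as.matrix(as.data.frame(covariates))
  storage.mode(C) <- "double"
  ok <- stats::complete.cases(x, y, C)
  x <- x[ok]; y <- y[ok]; C <- C[ok, , drop = FALSE]
  k <- ncol(C)
  n <- length(x)
  if (n < k + 4L) stop("too few complete cases for partial correlation",
                       call. = FALSE)
  X <- cbind(1, C)
  if (qr(X)$rank < ncol(X))
    stop("covariates are collinear (rank-deficient design)", call. = FALSE)
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) < 1e-10 * max(stats::sd(x), 1) ||
      stats::sd(ry) < 1e-10 * max(stats::sd(y), 1))
    stop("zero residual variance: a covariate duplicates x or y",
         call. = FALSE)
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  structure(list(r = r, n = n, df = df,
                 p = 2 * stats::pt(-abs(tval), df), covariates = k),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  lab <- if (x$covariates > 0)
    sprintf("partial r (k = %d)", x$covariates) else "r"
  cat(sprintf("%s = %.3f, n = %d, df = %d, p = %.4g%s\n",
              lab, x$r, x$n, x$df, x$p, sig_mark(x$p)))
  invisible(x)
}

sig_mark <- function(p) {
  if (p < .01) " **" else if (p < .05) " *" else if (p < .10) " +" else ""
}

#' Exclude extreme values by z-score
#'
#' Single-pass two-sided screening: entries with
#' `|value - mean| / sd > z_threshold` are removed (default 3.29, i.e.
#' p < .001 under normality). With zero standard deviation nothing is
#' excluded; `NA` entries are never excluded.
#'
#' @param values numeric vector.
#' @param z_threshold positive cut-off on |z| (default 3.29).
#' @return List with `values` (extremes replaced by `NA`), `kept`
#'   (the non-extreme finite values), `excluded` (indices removed).
#' @export
exclude_extremes <- function(values, z_threshold = 3.29) {
  stopifnot(z_threshold > 0)
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0)
    return(list(values = values, kept = values[!is.na(values)],
                excluded = integer()))
  z <- (values - m) / s
  excl <- which(!is.na(z) & abs(z) > z_threshold)
  out <- values
  out[excl] <- NA_real_
  list(values = out, kept = out[!is.na(out)], excluded = excl)
}

#' Block-wise (hierarchical) multiple regression
#'
#' Fits ordinary least squares on cumulative predictor blocks against one
#' criterion, on the listwise-complete cases across *all* blocks (a single
#' analysis sample, so every model shares one N). All variables are z-scored
#' first, so the coefficients are standardized betas. Each block k is
#' compared against block k-1 by the F-change statistic
#' `((R2_k - R2_{k-1}) / dp) / ((1 - R2_k) / (n - p_k - 1))`; the first
#' block's F-change is its overall model F.
#'
#' @param data data frame holding criterion and predictors.
#' @param criterion name of the criterion column.
#' @param blocks ordered list of character vectors of predictor names; block
#'   1 is conventionally the control variables.
#' @return An object of class `hier_reg`: list of per-block results
#'   (`coefficients` data frame with beta/t/p, `r2`, `adj_r2`, `F`, `F_p`,
#'   `F_change`, `F_change_p`, `df1`, `df2`) plus `n`.
#' @export
hierarchical_regression <- function(data, criterion, blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  vars <- c(criterion, unlist(blocks))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  d <- data[stats::complete.cases(data[, vars]), vars, drop = FALSE]
  n <- nrow(d)
  p_max <- length(unlist(blocks))
  if (n <= p_max + 1L)
    stop("too few complete cases for the requested predictors", call. = FALSE)
  dz <- as.data.frame(lapply(d, function(v) as.numeric(scale(v))))
  results <- vector("list", length(blocks))
  r2_prev <- 0
  preds <- character()
  for (k in seq_along(blocks)) {
    preds <- c(preds, blocks[[k]])
    fml <- stats::reformulate(preds, response = criterion)
    fit <- stats::lm(fml, data = dz)
    sm <- summary(fit)
    r2 <- sm$r.squared
    p_k <- length(preds)
    dp <- length(blocks[[k]])
    df2 <- n - p_k - 1L
    denom <- (1 - r2) / df2
    f_change <- if (denom > 0) ((r2 - r2_prev) / dp) / denom else Inf
    f_change <- max(0, f_change)
    f_change_p <- if (is.finite(f_change))
      stats::pf(f_change, dp, df2, lower.tail = FALSE) else 0
    co <- sm$coefficients[-1L, , drop = FALSE]   # drop intercept
    results[[k]] <- list(
      block = k, predictors = preds,
      coefficients = data.frame(
        predictor = rownames(co),
        beta = co[, "Estimate"], t = co[, "t value"],
        p = co[, "Pr(>|t|)"], row.names = NULL),
      r2 = r2, adj_r2 = sm$adj.r.squared,
      F = unname(sm$fstatistic["value"]),
      F_p = stats::pf(sm$fstatistic["value"], sm$fstatistic["numdf"],
                      sm$fstatistic["dendf"], lower.tail = FALSE),
      F_change = f_change, F_change_p = unname(f_change_p),
      df1 = dp, df2 = df2)
    r2_prev <- r2
  }
  structure(list(models = results, n = n, criterion = criterion),
            class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, ...) {
  cat(sprintf("Block-wise regression, criterion: %s (N = %d)\n",
              x$criterion, x$n))
  for (m in x$models) {
    cat(sprintf("\nModel %d (%s)\n", m$block,
                paste(m$predictors, collapse = ", ")))
    co <- m$coefficients
    co$beta <- sprintf("%+.3f", co$beta)
    co$t <- sprintf("%.3f", co$t)
    co$p <- sprintf("%.3f%s", co$p, vapply(co$p, sig_mark, ""))
    print(co, row.names = FALSE)
    cat(sprintf("  F = %.3f (p = %.4g), F change = %.3f (p = %.4g), adj R2 = %.3f\n",
                m$F, m$F_p, m$F_change, m$F_change_p, m$adj_r2))
  }
  invisible(x)
}

# measures analyzed against the clinical scales
ms_measures <- c("ms_total", "ms_patient_led", "ms_clinician_led", "leading",
                 "lag_mean", "lag_mean_patient_led", "lag_mean_clinician_led")
clinical_scales <- c("hamd", "bdi", "iip", "tdeq_dep", "tdeq_selfcrit")

#' Cohort analysis report: correlation grids and block regression
#'
#' Reproduces the cohort-level analysis plan on a table of dyad records:
#' (1) zero-order two-sided Pearson correlations between each clinical scale
#' (HAMD, BDI-II, IIP-32, TDEQ-12 dependency and self-criticism) and each
#' synchrony measure, with pairwise deletion; (2) the same grid as partial
#' correlations controlling for age, gender, medication and patient gross
#' body movement; (3) a block-wise regression of patient-led MS on the
#' control block, then HAMD, then TDEQ dependency (listwise-complete cases).
#' Mean time-lag columns are screened for extremes (|z| > 3.29) first.
#' No multiple-testing correction is applied, and the report says so.
#'
#' @param table cohort data frame with the synchrony measure columns, the
#'   clinical scales present among `hamd, bdi, iip, tdeq_dep, tdeq_selfcrit`,
#'   and `age, gender, medication, gross_move_patient`.
#' @param controls character vector of control-variable columns.
#' @param z_threshold extreme-value cut-off for the time-lag screening.
#' @return An object of class `cohort_report`: list with `zero_order` and
#'   `partial` (data frames of r and p per scale x measure), `ns`,
#'   `regression` (a [hierarchical_regression()] result or `NULL` when the
#'   required columns are absent), `excluded` (per-column excluded indices),
#'   `note`.
#' @export
analysis_report <- function(table,
                            controls = c("age", "gender", "medication",
                                         "gross_move_patient"),
                            z_threshold = 3.29) {
  scales <- intersect(clinical_scales, names(table))
  meas <- intersect(ms_measures, names(table))
  if (!length(scales) || !length(meas))
    stop("cohort table lacks clinical scale or synchrony measure columns",
         call. = FALSE)
  missing_ctrl <- setdiff(controls, names(table))
  if (length(missing_ctrl))
    stop("missing control columns: ", paste(missing_ctrl, collapse = ", "),
         call. = FALSE)
  excluded <- list()
  for (cl in intersect(c("lag_mean", "lag_mean_patient_led",
                         "lag_mean_clinician_led"), meas)) {
    ex <- exclude_extremes(table[[cl]], z_threshold)
    table[[cl]] <- ex$values
    excluded[[cl]] <- ex$excluded
  }
  grid <- function(partial) {
    r <- matrix(NA_real_, length(scales), length(meas),
                dimnames = list(scales, meas))
    p <- r; nn <- r
    for (s in scales) for (m in meas) {
      res <- tryCatch(
        if (partial) partial_corr(table[[s]], table[[m]],
                                  table[, controls, drop = FALSE])
        else pearson_corr(table[[s]], table[[m]]),
        error = function(e) NULL)
      if (!is.null(res)) {
        r[s, m] <- res$r; p[s, m] <- res$p; nn[s, m] <- res$n
      }
    }
    list(r = as.data.frame(r), p = as.data.frame(p), n = as.data.frame(nn))
  }
  zo <- grid(FALSE)
  pc <- grid(TRUE)
  reg <- NULL
  reg_blocks <- list(controls = controls, severity = "hamd",
                     dependency = "tdeq_dep")
  if (all(c("hamd", "tdeq_dep", "ms_patient_led") %in% names(table)))
    reg <- tryCatch(
      hierarchical_regression(table, "ms_patient_led", reg_blocks),
      error = function(e) NULL)
  structure(list(
    zero_order = zo, partial = pc, controls = controls,
    regression = reg, excluded = excluded,
    note = paste("p-values are two-sided and uncorrected for multiple",
                 "comparisons; interpret the grids accordingly.")),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort synchrony report\n\nZero-order Pearson correlations (r):\n")
  print(round(x$zero_order$r, 3))
  cat(sprintf("\nPartial correlations (controls: %s):\n",
              paste(x$controls, collapse = ", ")))
  print(round(x$partial$r, 3))
  if (!is.null(x$regression)) {
    cat("\n")
    print(x$regression)
  }
  if (length(x$excluded) && any(lengths(x$excluded) > 0)) {
    cat("\nExtreme values excluded (|z| > 3.29):\n")
    for (nm in names(x$excluded))
      if (length(x$excluded[[nm]]))
        cat(sprintf("  %s: rows %s\n", nm,
                    paste(x$excluded[[nm]], collapse = ", ")))
  }
  cat("\nNote:", x$note, "\n")
  invisible(x)
}

#' Write a cohort report to CSV files
#'
#' Writes `correlations.csv`, `partial_correlations.csv`, `regression.csv`
#' and a plain-text `report.txt` into `dir`.
#'
#' @param report a [analysis_report()] result.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(g, which) {
    df <- g[[which]]
    cbind(scale = rownames(df), stat = which, df, row.names = NULL)
  }
  utils::write.csv(rbind(flat(report$zero_order, "r"),
                         flat(report$zero_order, "p"),
                         flat(report$zero_order, "n")),
                   file.path(dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(rbind(flat(report$partial, "r"),
                         flat(report$partial, "p"),
                         flat(report$partial, "n")),
                   file.path(dir, "partial_correlations.csv"),
                   row.names = FALSE)
  if (!is.null(report$regression)) {
    rows <- do.call(rbind, lapply(report$regression$models, function(m)
      cbind(model = m$block, m$coefficients,
            F = m$F, F_change = m$F_change, F_change_p = m$F_change_p,
            adj_r2 = m$adj_r2, n = report$regression$n)))
    utils::write.csv(rows, file.path(dir, "regression.csv"),
                     row.names = FALSE)
  }
  txt <- file.path(dir, "report.txt")
  sink(txt); on.exit(sink())
  print(report)
  invisible(dir)
}
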