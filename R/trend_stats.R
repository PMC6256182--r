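# normalise grade -> values input: named list of numeric vectors, or a
# data.frame with columns grade, value (and optionally participant)
.grade_data <- function(values) {
  if (is.data.frame(values)) {
    stopifnot(all(c("grade", "value") %in% names(values)))
    df <- data.frame(grade = as.character(values$grade),
                     value = as.numeric(values$value),
                     stringsAsFactors = FALSE)
    if ("participant" %in% names(values)) df$participant <- values$participant
    df$grade <- factor(df$grade, levels = unique(df$grade))
    return(df)
  }
  if (is.list(values) && !is.null(names(values))) {
    df <- data.frame(
      grade = factor(rep(names(values), lengths(values)),
                     levels = names(values)),
      value = as.numeric(unlist(values, use.names = FALSE)))
    return(df)
  }
  stop("values must be a named list (grade -> numeric) or a data.frame ",
       "with columns grade and value")
}

.check_groups <- function(df) {
  sizes <- table(df$grade)
  if (length(sizes) < 2L)
    stop("need at least 2 grades")
  if (any(sizes < 2L))
    stop("every grade needs at least 2 values")
}

#' One-way ANOVA over grades
#'
#' Classical one-way between-groups decomposition of a network measure over
#' grade: `F = (SSB/df1) / (SSW/df2)` with `df1 = k - 1` and
#' `df2 = N - k`.  With `repeated = TRUE` (requires a `participant` column) a
#' within-participant ANOVA (`value ~ grade + Error(participant)`) is fitted
#' instead, for comparison.
#'
#' @param values named list mapping grade to per-participant values, or a
#'   data.frame with columns `grade`, `value` (and `participant` for the
#'   repeated-measures variant).
#' @param repeated fit the within-participant layout instead.
#' @return list with `F`, `df1`, `df2`, `p_value` (class `anova_result`).
#' @export
oneway_anova <- function(values, repeated = FALSE) {
  df <- .grade_data(values)
  .check_groups(df)
  if (repeated) {
    if (is.null(df$participant))
      stop("repeated-measures ANOVA needs a participant column")
    df$participant <- factor(df$participant)
    fit <- stats::aov(value ~ grade + Error(participant), data = df)
    tab <- summary(fit)[["Error: Within"]][[1L]]
    res <- list(F = tab["grade", "F value"],
                df1 = as.integer(tab["grade", "Df"]),
                df2 = as.integer(tab["Residuals", "Df"]),
                p_value = tab["grade", "Pr(>F)"], repeated = TRUE)
    return(structure(res, class = "anova_result"))
  }
  a <- stats::anova(stats::lm(value ~ grade, data = df))
  F <- a[["F value"]][1L]
  if (!is.finite(F))
    stop("F is undefined: no variance between or within grades")
  structure(list(F = F, df1 = a[["Df"]][1L], df2 = a[["Df"]][2L],
                 p_value = a[["Pr(>F)"]][1L], repeated = FALSE),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%sone-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              if (isTRUE(x$repeated)) "repeated-measures " else "",
              x$df1, x$df2, x$F, x$p_value))
  invisible(x)
}

#' Tukey HSD pairwise comparisons between grades
#'
#' Adjusted p-values from the studentized-range distribution
#' (Tukey-Kramer for unequal group sizes), computed over all grade pairs as
#' in standard HSD practice and reported for the requested pairs — by
#' default the consecutive grades in schedule order.
#'
#' @inheritParams oneway_anova
#' @param pairs two-column matrix (or list of length-2 vectors) of grade
#'   labels to report; `NULL` reports consecutive pairs.
#' @return data.frame with `grade_a`, `grade_b`, `diff` (mean difference
#'   b - a) and `adjusted_p`.
#' @export
tukey_pairwise <- function(values, pairs = NULL) {
  df <- .grade_data(values)
  .check_groups(df)
  lev <- levels(df$grade)
  k <- length(lev)
  means <- tapply(df$value, df$grade, mean)
  ns <- tapply(df$value, df$grade, length)
  df2 <- nrow(df) - k
  msw <- sum(tapply(df$value, df$grade,
                    function(v) sum((v - mean(v))^2))) / df2
  if (is.null(pairs))
    pairs <- cbind(lev[-k], lev[-1L])
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  stopifnot(is.matrix(pairs), ncol(pairs) == 2L,
            all(pairs %in% lev))
  out <- data.frame(grade_a = pairs[, 1L], grade_b = pairs[, 2L],
                    diff = NA_real_, adjusted_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    a <- out$grade_a[i]
    b <- out$grade_b[i]
    se <- sqrt(msw / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
    q <- abs(means[[b]] - means[[a]]) / se
    out$diff[i] <- means[[b]] - means[[a]]
    out$adjusted_p[i] <- stats::ptukey(q, nmeans = k, df = df2,
                                       lower.tail = FALSE)
  }
  out
}

#' Orthogonal polynomial trend fit over grade
#'
#' Regresses a measure on orthogonal polynomial contrasts of the numeric
#' grade variable, respecting the actual (possibly unequal) spacing of the
#' grade labels — e.g. 1, 2, 3, 4, 5, 6, 8 with grade 7 absent.  Reports
#' per-order coefficients with t-values, the intercept, and the R-squared of
#' the full polynomial model.
#'
#' @param grade numeric grade per observation.
#' @param value measure value per observation.
#' @param max_order highest polynomial order (must be below the number of
#'   distinct grades).
#' @return a `trend_fit`: list with `coefficients` (data.frame `order`,
#'   `coefficient`, `t_value`), `intercept` (named vector `coefficient`,
#'   `t_value`), `r_squared`, `max_order`.
#' @export
polynomial_trend_fit <- function(grade, value, max_order = 4L) {
  grade <- as.numeric(grade)
  value <- as.numeric(value)
  stopifnot(length(grade) == length(value))
  max_order <- as.integer(max_order)
  n_distinct <- length(unique(grade))
  if (max_order >= n_distinct)
    stop("max_order must be below the number of distinct grades (",
         n_distinct, ")")
  if (max_order < 1L)
    stop("max_order must be at least 1")
  fit <- stats::lm(value ~ poly(grade, max_order))
  s <- summary(fit)
  co <- stats::coef(s)
  structure(list(
    coefficients = data.frame(order = seq_len(max_order),
                              coefficient = co[-1L, "Estimate"],
                              t_value = co[-1L, "t value"],
                              row.names = NULL),
    intercept = c(coefficient = co[1L, "Estimate"],
                  t_value = co[1L, "t value"]),
    r_squared = s$r.squared,
    max_order = max_order), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("polynomial trend fit (order", x$max_order, "), R^2 =",
      format(x$r_squared, digits = 3), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Log-log power-law fit of a degree distribution
#'
#' Ordinary least squares of `log10 P(k)` on `log10 k` over the observed
#' degrees (zero-frequency degrees never appear).  A linear log-log
#' relationship indicates a power-law (scale-free) degree distribution; the
#' slope is the negated power-law exponent.  This is the descriptive OLS
#' convention, not a maximum-likelihood tail fit.
#'
#' @param distribution named numeric vector `k -> P(k)` as returned by
#'   [degree_distribution()].
#' @return a `powerlaw_fit`: list with `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
loglog_degree_fit <- function(distribution) {
  k <- as.numeric(names(distribution))
  p <- as.numeric(distribution)
  keep <- p > 0 & k > 0
  k <- k[keep]
  p <- p[keep]
  if (length(k) < 2L)
    stop("need at least 2 degrees with positive frequency")
  fit <- stats::lm(log10(p) ~ log10(k))
  rss <- sum(stats::residuals(fit)^2)
  r2 <- if (rss < 1e-20) 1 else summary(fit)$r.squared
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n_points = length(k)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("log-log degree fit: slope = %.3f, R^2 = %.3f (%d degrees)\n",
              x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Power of the two-sided zero-correlation test
#'
#' Fisher z approximation: with `z = atanh(|r|) sqrt(n - 3)` and critical
#' value `z_c = qnorm(1 - alpha/2)`, power is
#' `pnorm(z - z_c) + pnorm(-z - z_c)` (the second term is the negligible
#' opposite tail).  At `r = 0` this reduces to the test's size `alpha`.
#'
#' @param n sample size (>= 4).
#' @param r true correlation, `|r| < 1`.
#' @param alpha two-sided significance level.
#' @return power in `[0, 1]`.
#' @export
correlation_power <- function(n, r, alpha = 0.05) {
  if (n < 4) stop("n must be at least 4")
  if (abs(r) >= 1) stop("|r| must be below 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  z <- abs(atanh(r)) * sqrt(n - 3)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(z - zc) + stats::pnorm(-z - zc)
}

#' Trend statistics for every network measure in a measures table
#'
#' For each measure column, runs the one-way ANOVA over grades, Tukey HSD
#' comparisons between consecutive grades, and the orthogonal polynomial
#' trend fit with grade treated as numeric (unequal spacing respected).
#'
#' @param measures a long-form measures `data.frame` as produced by
#'   [run_pipeline()] / [write_measures_table()], with columns `participant`,
#'   `grade` and the measure columns.
#' @param measure_cols measure columns to analyse.
#' @param max_order maximum polynomial order; truncated to the number of
#'   distinct grades minus 1.
#' @return list with `trends` (one row per measure: F, dfs, p, R-squared and
#'   polynomial coefficients/t-values) and `pairwise` (Tukey-adjusted
#'   consecutive-grade p-values per measure).
#' @export
trend_statistics <- function(measures,
                             measure_cols = c("n", "mean_degree", "L", "D",
                                              "C", "hermit_proportion"),
                             max_order = 4L) {
  stopifnot(all(c("grade", measure_cols) %in% names(measures)))
  grade_num <- suppressWarnings(as.numeric(measures$grade))
  if (anyNA(grade_num))
    grade_num <- match(measures$grade, unique(measures$grade))
  max_order <- min(as.integer(max_order), length(unique(grade_num)) - 1L)
  order_names <- c("linear", "quadratic", "cubic", "quartic")
  trends <- NULL
  pairwise <- NULL
  for (m in measure_cols) {
    df <- data.frame(grade = measures$grade, value = measures[[m]])
    an <- oneway_anova(df)
    tk <- tukey_pairwise(df)
    pf <- polynomial_trend_fit(grade_num, measures[[m]], max_order)
    row <- data.frame(measure = m, F = an$F, df1 = an$df1, df2 = an$df2,
                      p_value = an$p_value, r_squared = pf$r_squared,
                      stringsAsFactors = FALSE)
    for (o in seq_len(max_order)) {
      row[[paste0(order_names[o], "_coef")]] <- pf$coefficients$coefficient[o]
      row[[paste0(order_names[o], "_t")]] <- pf$coefficients$t_value[o]
    }
    row$intercept_coef <- pf$intercept[["coefficient"]]
    row$intercept_t <- pf$intercept[["t_value"]]
    trends <- rbind(trends, row)
    tk$measure <- m
    pairwise <- rbind(pairwise, tk[, c("measure", "grade_a", "grade_b",
                                       "diff", "adjusted_p")])
  }
  rownames(trends) <- NULL
  rownames(pairwise) <- NULL
  list(trends = trends, pairwise = pairwise)
}
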