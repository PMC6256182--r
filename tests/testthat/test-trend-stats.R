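# balanced 7-grade x 50-participant fixture with a smooth grade effect
grade_fixture <- function(seed = 101, k = 7, n = 50) {
  set.seed(seed)
  grades <- c(1:6, 8)[seq_len(k)]
  df <- expand.grid(participant = seq_len(n), grade = grades)
  df$value <- 6.7 + 0.03 * df$grade - 0.002 * (df$grade - 4)^2 +
    stats::rnorm(nrow(df), 0, 0.05)
  df
}

test_that("one-way ANOVA reproduces the between-groups decomposition", {
  df <- grade_fixture()
  res <- oneway_anova(df)
  expect_identical(res$df1, 6L)
  expect_identical(res$df2, 343L)
  # two-group hand computation: SSB = 13.5, MSW = 1
  hand <- oneway_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(hand$F, 13.5)
  expect_identical(hand$df1, 1L)
  expect_identical(hand$df2, 4L)
  # equal group means with spread: F = 0, p = 1
  null <- oneway_anova(list(a = c(1, 2, 3), b = c(3, 2, 1)))
  expect_equal(null$F, 0)
  expect_equal(null$p_value, 1)
  expect_error(oneway_anova(list(a = 1, b = c(1, 2))), "at least 2 values")
  expect_error(oneway_anova(list(a = c(1, 2))), "at least 2 grades")
  expect_error(oneway_anova(list(a = c(1, 1), b = c(1, 1))), "undefined")
})

test_that("F is invariant under affine transformations of the data", {
  df <- grade_fixture(seed = 7)
  f0 <- oneway_anova(df)$F
  df_shift <- df
  df_shift$value <- df$value + 100
  df_scale <- df
  df_scale$value <- df$value * 3.7
  expect_equal(oneway_anova(df_shift)$F, f0)
  expect_equal(oneway_anova(df_scale)$F, f0)
})

test_that("the repeated-measures variant uses within-participant error terms", {
  df <- grade_fixture(seed = 8)
  rm <- oneway_anova(df, repeated = TRUE)
  expect_identical(rm$df1, 6L)
  expect_identical(rm$df2, 294L)   # (k-1)(n-1)
  expect_true(rm$F > 0)
})

test_that("Tukey HSD agrees with the stats reference implementation", {
  df <- grade_fixture(seed = 9)
  grades <- unique(df$grade)
  all_pairs <- t(utils::combn(as.character(grades), 2))
  ours <- tukey_pairwise(df, pairs = all_pairs)
  ref <- stats::TukeyHSD(stats::aov(value ~ factor(grade), data = df))[[1]]
  ref_key <- rownames(ref)
  for (i in seq_len(nrow(ours))) {
    key <- paste0(ours$grade_b[i], "-", ours$grade_a[i])
    expect_true(key %in% ref_key)
    expect_equal(ours$adjusted_p[i], ref[key, "p adj"], tolerance = 1e-6)
    expect_equal(ours$diff[i], ref[key, "diff"], tolerance = 1e-9)
  }
  # default reporting: consecutive grades in order
  cons <- tukey_pairwise(df)
  expect_identical(cons$grade_a, as.character(grades[-length(grades)]))
  expect_identical(cons$grade_b, as.character(grades[-1]))
})

test_that("two groups reduce Tukey to the ordinary pooled t-test", {
  set.seed(10)
  a <- rnorm(20)
  b <- rnorm(20, 0.5)
  tk <- tukey_pairwise(list(g1 = a, g2 = b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tk$adjusted_p, tt$p.value, tolerance = 1e-10)
})

test_that("perfectly separated grades drive adjusted p to zero", {
  tk <- tukey_pairwise(list(a = c(1, 1, 1), b = c(2, 2, 2), c = c(5, 5, 5)))
  expect_true(all(tk$adjusted_p < 1e-12))
})

test_that("polynomial trends recover exact generating polynomials", {
  grades <- rep(c(1:6, 8), each = 10)
  quad <- 2 + 0.5 * grades - 0.1 * grades^2
  fit <- polynomial_trend_fit(grades, quad, max_order = 4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$coefficients$coefficient[3:4])), 1e-8)
  lin <- 1 + 0.25 * grades
  fit_lin <- polynomial_trend_fit(grades, lin, max_order = 3)
  expect_equal(fit_lin$r_squared, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit_lin$coefficients$coefficient[2:3])), 1e-8)
  expect_error(polynomial_trend_fit(c(1, 2, 1, 2), c(1, 2, 3, 4), 2),
               "max_order")
})

test_that("orthogonal contrasts are uncorrelated on the unequal grade spacing", {
  grades <- rep(c(1:6, 8), each = 50)
  x <- stats::poly(grades, 4)
  gram <- crossprod(x)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-10)
})

test_that("noisy quadratic trends are recovered with the right sign", {
  grades <- rep(c(1:6, 8), each = 50)
  hits <- vapply(1:100, function(s) {
    set.seed(3000 + s)
    y <- 10 + 0.8 * grades - 0.12 * grades^2 + stats::rnorm(length(grades), 0, 0.5)
    fit <- polynomial_trend_fit(grades, y, max_order = 2)
    # orthogonal quadratic contrast of x^2 has a positive leading weight,
    # so a concave trend must show a negative quadratic coefficient
    fit$coefficients$coefficient[2] < 0 &&
      abs(fit$coefficients$t_value[2]) > 2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("log-log fits identify exact power laws and flat distributions", {
  k <- 1:10
  pk <- stats::setNames(k^(-2) / sum(k^(-2)), k)
  fit <- loglog_degree_fit(pk)
  expect_equal(fit$slope, -2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_identical(fit$n_points, 10L)
  flat <- stats::setNames(rep(0.1, 10), 1:10)
  expect_equal(loglog_degree_fit(flat)$slope, 0, tolerance = 1e-12)
  expect_error(loglog_degree_fit(stats::setNames(1, 3)), "at least 2")
})

test_that("preferential-attachment degree distributions fit a descending line", {
  set.seed(12)
  ig <- igraph::sample_pa(500, power = 1, m = 2, directed = FALSE)
  fit <- loglog_degree_fit(degree_distribution(ig))
  expect_lt(fit$slope, 0)
  expect_gte(fit$r_squared, 0.8)
})

test_that("correlation power behaves like a power function should", {
  expect_equal(correlation_power(50, 0, 0.05), 0.05, tolerance = 1e-12)
  expect_gte(correlation_power(50, 0.4, 0.05), 0.80)
  powers_n <- vapply(c(10, 20, 50, 100), correlation_power, numeric(1),
                     r = 0.3, alpha = 0.05)
  expect_true(all(diff(powers_n) > 0))
  powers_r <- vapply(c(0.1, 0.2, 0.3, 0.5), function(r)
    correlation_power(50, r, 0.05), numeric(1))
  expect_true(all(diff(powers_r) > 0))
  expect_error(correlation_power(3, 0.3), "at least 4")
  expect_error(correlation_power(50, 1), "below 1")
  expect_error(correlation_power(50, 0.3, 0), "alpha")
})

test_that("trend_statistics summarises every measure with consecutive pairs", {
  d <- small_demo_cohort(seed = 13, n_types = 1200, n_participants = 4)
  recs <- list()
  for (p in 1:4) for (g in 1:3) {
    lex <- d$cohort$lexicons[[p]][[g]]
    recs[[length(recs) + 1]] <- compute_all_measures(lex)
  }
  tmp <- withr::local_tempfile(fileext = ".tsv")
  measures <- write_measures_table(recs, tmp)
  ts <- trend_statistics(measures, measure_cols = c("mean_degree", "C"),
                         max_order = 4)
  expect_identical(ts$trends$measure, c("mean_degree", "C"))
  # order truncated to distinct grades - 1
  expect_true("quadratic_coef" %in% names(ts$trends))
  expect_false("cubic_coef" %in% names(ts$trends))
  expect_identical(nrow(ts$pairwise), 4L)   # 2 consecutive pairs x 2 measures
  expect_true(all(ts$pairwise$adjusted_p >= 0 & ts$pairwise$adjusted_p <= 1))
})
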