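test_that("pearson_matrix matches the direct-formula oracle on fuzzed tables", {
  set.seed(501)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    tab <- as.data.frame(matrix(rnorm(n * 6), n, 6,
                                dimnames = list(NULL, letters[1:6])))
    cm <- pearson_matrix(tab)
    for (a in 1:5) for (b in (a + 1):6) {
      o <- oracle_pearson(tab[[a]], tab[[b]])
      expect_equal(cm$r[a, b], o$r, tolerance = 1e-10)
      expect_equal(cm$p[a, b], o$p, tolerance = 1e-10)
    }
    expect_equal(cm$df[1, 2], n - 2)
  }
})

test_that("pearson_matrix handles exact linearity, nulls and degenerate columns", {
  x <- seq_len(50)
  cm <- pearson_matrix(data.frame(x = x, y = 2 * x + 1))
  expect_equal(cm$r[1, 2], 1)
  expect_lt(cm$p[1, 2], 1e-12)

  set.seed(502)
  big <- data.frame(x = rnorm(10000), y = rnorm(10000))
  expect_lt(abs(pearson_matrix(big)$r[1, 2]), 0.05)

  dg <- pearson_matrix(data.frame(x = rnorm(20), z = rep(1, 20)))
  expect_true(is.na(dg$r[1, 2]))
  expect_equal(dg$r[1, 1], 1)
})

test_that("welch_t matches its oracle and degenerates sensibly", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  w <- welch_t(a, b)
  o <- oracle_welch(a, b)
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)

  same <- c(2, 4, 6, 8)
  w0 <- welch_t(same, same)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)

  # equal variances, large n: Welch converges to the pooled t
  set.seed(503)
  ga <- rnorm(4000); gb <- rnorm(4000, 0.05)
  wp <- welch_t(ga, gb)
  pooled <- t.test(ga, gb, var.equal = TRUE)
  expect_equal(wp$t, unname(pooled$statistic), tolerance = 1e-3)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("sobel arithmetic and mediation regressions are exact", {
  expect_equal(oracle_sobel_z(1, 0.1, 1, 0.1), 1 / sqrt(0.02), tolerance = 1e-12)

  set.seed(504)
  n <- 200
  x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.6 * m + 0.2 * x + rnorm(n)
  res <- mediation(x, m, y, boot = 200, seed = 1)
  fa <- summary(lm(m ~ x))$coefficients
  fb <- summary(lm(y ~ x + m))$coefficients
  expect_equal(res$a, fa["x", 1], tolerance = 1e-12)
  expect_equal(res$b, fb["m", 1], tolerance = 1e-12)
  expect_equal(res$c_prime, fb["x", 1], tolerance = 1e-12)
  expect_equal(res$indirect, res$a * res$b, tolerance = 1e-12)
  expect_equal(res$sobel_z,
               oracle_sobel_z(res$a, res$se_a, res$b, res$se_b),
               tolerance = 1e-12)
  expect_true(res$ci[1] <= res$indirect && res$indirect <= res$ci[2])
  # bootstrap is seed-deterministic
  res2 <- mediation(x, m, y, boot = 200, seed = 1)
  expect_identical(res$ci, res2$ci)
  expect_error(mediation(x, x, y), "collinear")
})

test_that("full-mediation cohorts show indirect but no direct effect", {
  set.seed(505)
  n <- 5000
  x <- rnorm(n); m <- 0.7 * x + rnorm(n, 0, sqrt(1 - 0.49))
  y <- 0.6 * m + rnorm(n, 0, sqrt(1 - 0.36))
  res <- mediation(x, m, y, boot = 0)
  expect_lt(res$sobel_p, 1e-6)
  expect_gt(res$p_direct, 0.05)
  expect_equal(res$a, 0.7, tolerance = 0.05)
  expect_equal(res$b, 0.6, tolerance = 0.05)
})

test_that("random-intercept fit recovers parameters and the design df", {
  set.seed(506)
  d <- sim_lmm_data(46, 18, beta1 = 0.5, u0_var = 1, resid_var = 1)
  fit <- fit_random_intercept(d, "y", "x")
  expect_equal(unname(fit$beta["x"]), 0.5, tolerance = 0.5)  # ~3 SE at this n
  expect_equal(fit$f_tests$df2, 44, tolerance = 0.01)
  expect_equal(fit$n_subjects, 46)
  expect_gt(fit$u0_var, 0.4); expect_lt(fit$u0_var, 1.8)
  expect_gt(fit$r2_marginal, 0); expect_lt(fit$r2_marginal, 1)

  # F and p agree with the t-test equivalence F = t^2 at df = q - 2
  se <- sqrt(diag(as.matrix(vcov(fit$fit))))[2]
  expect_equal(fit$f_tests$F, unname((fit$beta["x"] / se)^2), tolerance = 1e-6)
})

test_that("u0_var = 0 data reduce to the pooled OLS slope", {
  set.seed(507)
  d <- sim_lmm_data(30, 10, beta1 = 0.4, u0_var = 0, resid_var = 1)
  fit <- fit_random_intercept(d, "y", "x")
  ols <- unname(coef(lm(y ~ x, d))["x"])
  expect_equal(unname(fit$beta["x"]), ols, tolerance = 0.01)
})

test_that("type-interaction model nests, tests per-term effects, and errors on empty levels", {
  set.seed(508)
  d <- sim_lmm_data(40, 18, beta1 = 0.3)
  d$condition <- rep(rep(c("fear", "sad", "disgust", "amusement", "tender",
                           "neutral"), each = 3), 40)
  # single level present -> identical to the random-intercept fit
  d1 <- d; d1$condition <- "neutral"
  f1 <- fit_type_interaction(d1, "y", "x")
  f0 <- fit_random_intercept(d, "y", "x")
  expect_equal(unname(f1$beta["x"]), unname(f0$beta["x"]), tolerance = 1e-9)

  # a genuine type offset is detected; reference level is neutral
  d$y <- d$y + ifelse(d$condition == "fear", 1.0, 0)
  ft <- fit_type_interaction(d, "y", "x")
  expect_identical(levels(model.frame(ft$fit)$condition)[1], "neutral")
  ftt <- ft$f_tests
  expect_equal(ftt$df1[ftt$term == "condition"], 5)
  expect_lt(ftt$p[ftt$term == "condition"], 1e-6)
  expect_gt(ftt$p[ftt$term == "x:condition"], 0.01)

  d_bad <- d
  d_bad$condition <- factor(d_bad$condition,
                            levels = c(unique(d$condition), "erotic"))
  expect_error(fit_type_interaction(d_bad, "y", "x"), "erotic")
})

test_that("type main-effect power at a configured offset is high", {
  set.seed(509)
  hits <- 0L
  for (r in 1:40) {
    d <- sim_lmm_data(46, 18, beta1 = 0)
    d$condition <- rep(rep(c("fear", "sad", "disgust", "amusement", "tender",
                             "neutral"), each = 3), 46)
    d$y <- d$y + 0.5 * (d$condition %in% c("fear", "sad", "disgust"))
    ft <- fit_type_interaction(d, "y", "x")$f_tests
    hits <- hits + (ft$p[ft$term == "condition"] < 0.05)
  }
  expect_gte(hits / 40, 0.9)
})
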