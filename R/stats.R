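#' Pairwise Pearson correlation matrix with p-values
#'
#' Pearson coefficients with two-sided p-values from the t-transform
#' `t = r * sqrt(df / (1 - r^2))`, `df = n - 2`, computed per pair on
#' pairwise-complete observations. Zero-variance columns yield `NA` for
#' their pairs.
#'
#' @param table data frame holding the variables (e.g. per-subject blink
#'   indices and STAI scores).
#' @param vars columns to correlate; default: all numeric columns.
#' @return An object of class `correlation_matrix`: list with matrices `r`,
#'   `p`, `n` (pairwise n) and `df` (`n - 2`).
#' @export
pearson_matrix <- function(table, vars = NULL) {
  if (is.null(vars)) vars <- names(table)[vapply(table, is.numeric, logical(1))]
  x <- as.matrix(table[, vars, drop = FALSE])
  k <- ncol(x)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(i)) {
    ok <- stats::complete.cases(x[, c(i, j)])
    nij <- sum(ok)
    n[i, j] <- n[j, i] <- nij
    if (nij < 3L) next
    vi <- x[ok, i]; vj <- x[ok, j]
    if (stats::sd(vi) == 0 || stats::sd(vj) == 0) next
    rij <- stats::cor(vi, vj)
    r[i, j] <- r[j, i] <- rij
    if (i == j) { p[i, j] <- NA_real_; next }
    tt <- rij * sqrt((nij - 2) / max(1 - rij^2, .Machine$double.eps))
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = nij - 2)
  }
  structure(list(r = r, p = p, n = n, df = n - 2, variables = vars),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<correlation_matrix> %d variables, pairwise df %s\n",
              length(x$variables),
              paste(range(x$df[upper.tri(x$df)]), collapse = "-")))
  r <- format(round(x$r, digits))
  r[upper.tri(r, diag = TRUE)] <- ""
  diag(r) <- "-"
  print(noquote(r))
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' Two-sample t statistic with the Welch-Satterthwaite degrees of freedom;
#' a thin wrapper around [stats::t.test()] returning the triple the
#' reporting layer needs.
#'
#' @param group_a,group_b numeric score vectors (each n >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    stop("degenerate input: zero variance in both groups", call. = FALSE)
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Simple mediation analysis (X -> M -> Y)
#'
#' The two-regression mediation model: the a-path from `m ~ x`, the b-path
#' and direct effect c' from `y ~ x + m`. Inference on the indirect effect
#' `a * b` uses the Sobel delta-method z,
#' `z = a*b / sqrt(a^2 se_b^2 + b^2 se_a^2)`, with a seeded percentile
#' bootstrap confidence interval as robustness companion.
#'
#' @param x,m,y numeric vectors: predictor (e.g. STAI-T), mediator (e.g.
#'   STAI-S) and outcome (e.g. blink amplitude). Complete triples only,
#'   n >= 10.
#' @param boot bootstrap replicates for the percentile CI (0 = skip).
#' @param seed integer seed for the bootstrap.
#' @param conf CI level.
#' @return An object of class `mediation_result` with `a`, `se_a`, `b`,
#'   `se_b`, `c_prime`, `se_c_prime`, `p_direct`, `indirect`, `sobel_z`,
#'   `sobel_p`, and `ci` (bootstrap percentile bounds) when `boot > 0`.
#' @export
mediation <- function(x, m, y, boot = 5000, seed = NULL, conf = 0.95) {
  ok <- stats::complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("mediation needs at least 10 complete triples", call. = FALSE)
  if (abs(stats::cor(x, m)) > 1 - 1e-10)
    stop("degeneracy: predictor and mediator are collinear", call. = FALSE)
  fit_paths <- function(x, m, y) {
    fa <- stats::lm(m ~ x)
    fb <- stats::lm(y ~ x + m)
    sa <- summary(fa)$coefficients
    sb <- summary(fb)$coefficients
    c(a = sa["x", 1], se_a = sa["x", 2],
      b = sb["m", 1], se_b = sb["m", 2],
      c_prime = sb["x", 1], se_c = sb["x", 2], p_c = sb["x", 4])
  }
  est <- fit_paths(x, m, y)
  ab <- est[["a"]] * est[["b"]]
  se_ab <- sqrt(est[["a"]]^2 * est[["se_b"]]^2 + est[["b"]]^2 * est[["se_a"]]^2)
  z <- ab / se_ab
  out <- list(a = est[["a"]], se_a = est[["se_a"]],
              b = est[["b"]], se_b = est[["se_b"]],
              c_prime = est[["c_prime"]], se_c_prime = est[["se_c"]],
              p_direct = est[["p_c"]],
              indirect = ab, sobel_z = z,
              sobel_p = 2 * stats::pnorm(-abs(z)),
              n = n, boot = boot, conf = conf, ci = NULL)
  if (boot > 0) {
    out$ci <- with_seed(seed, {
      ab_b <- numeric(boot)
      for (r in seq_len(boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        e <- fit_paths(x[idx], m[idx], y[idx])
        ab_b[r] <- e[["a"]] * e[["b"]]
      }
      unname(stats::quantile(ab_b, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
    })
  }
  structure(out, class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n = %d\n", x$n))
  cat(sprintf("  a = %.4f (se %.4f), b = %.4f (se %.4f)\n",
              x$a, x$se_a, x$b, x$se_b))
  cat(sprintf("  indirect a*b = %.4f, Sobel Z = %.3f, p = %.4g\n",
              x$indirect, x$sobel_z, x$sobel_p))
  cat(sprintf("  direct c' = %.4f (se %.4f), p = %.4g\n",
              x$c_prime, x$se_c_prime, x$p_direct))
  if (!is.null(x$ci))
    cat(sprintf("  %g%% bootstrap CI for a*b: [%.4f, %.4f] (%d reps)\n",
                100 * x$conf, x$ci[1], x$ci[2], x$boot))
  invisible(x)
}
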