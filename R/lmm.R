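# Random-intercept linear mixed models with Satterthwaite denominator
# degrees of freedom.
#
# lme4 supplies the REML fit; the inference layer here re-expresses the
# REML criterion and the fixed-effect covariance as closed-form functions
# of the variance parameters (theta, sigma) using the Woodbury identity for
# the single-grouping-factor random-intercept structure, then obtains
# Satterthwaite df from the delta method: df = 2 g^2 / (g' A g'), with g
# the contrast variance, g' its gradient in (theta, sigma), and A twice the
# inverse Hessian of the REML criterion. Multi-df terms use the
# Fai-Cornelius eigen-combination. This matches the usual Satterthwaite
# machinery for lmer fits without requiring packages beyond lme4.

# Sufficient statistics for the Woodbury-based REML computations.
ri_suffstats <- function(X, y, group) {
  j <- as.integer(group)
  q <- max(j)
  list(X = X, y = y, j = j, q = q,
       n = length(y), p = ncol(X),
       nj = tabulate(j, q),
       XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y * y),
       ZtX = rowsum(X, j), Zty = rowsum(y, j))
}

# Fixed-effect covariance (response units) at variance parameters vp.
ri_vcov_beta <- function(ss, vp) {
  th <- vp[1]; sg <- vp[2]
  d <- th^2 / (1 + th^2 * ss$nj)
  XtViX <- (ss$XtX - crossprod(ss$ZtX, d * ss$ZtX)) / sg^2
  solve(XtViX)
}

# -2 restricted log-likelihood at vp (same criterion lme4 minimizes).
ri_reml_dev <- function(ss, vp) {
  th <- vp[1]; sg <- vp[2]
  d <- th^2 / (1 + th^2 * ss$nj)
  XtViX <- (ss$XtX - crossprod(ss$ZtX, d * ss$ZtX)) / sg^2
  XtViy <- (ss$Xty - crossprod(ss$ZtX, d * ss$Zty)) / sg^2
  ytViy <- (ss$yty - sum(d * ss$Zty^2)) / sg^2
  beta <- solve(XtViX, XtViy)
  quad <- ytViy - sum(beta * XtViy)
  logdetV <- 2 * ss$n * log(sg) + sum(log1p(th^2 * ss$nj))
  logdetX <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  logdetV + logdetX + quad + (ss$n - ss$p) * log(2 * pi)
}

# Asymptotic covariance of (theta, sigma): 2 * H^{-1} of the REML criterion.
ri_varpar_vcov <- function(ss, vp) {
  h <- 1e-3 * (abs(vp) + 1e-2)
  f <- function(v) ri_reml_dev(ss, v)
  H <- matrix(0, 2, 2)
  f0 <- f(vp)
  for (i in 1:2) {
    e <- c(0, 0); e[i] <- h[i]
    H[i, i] <- (f(vp + e) - 2 * f0 + f(vp - e)) / h[i]^2
  }
  e1 <- c(h[1], 0); e2 <- c(0, h[2])
  H[1, 2] <- H[2, 1] <-
    (f(vp + e1 + e2) - f(vp + e1 - e2) - f(vp - e1 + e2) + f(vp - e1 - e2)) /
    (4 * h[1] * h[2])
  A <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(A) || any(!is.finite(A)) || any(diag(A) < 0))
    A <- 2 * solve(H + diag(1e-6 * (abs(diag(H)) + 1), 2))
  A
}

# Satterthwaite df for a single contrast vector L.
ri_satterthwaite_df <- function(ss, vp, L, A) {
  g <- function(v) drop(crossprod(L, ri_vcov_beta(ss, v) %*% L))
  h <- 1e-4 * (abs(vp) + 1e-2)
  grad <- c(
    (g(vp + c(h[1], 0)) - g(vp - c(h[1], 0))) / (2 * h[1]),
    (g(vp + c(0, h[2])) - g(vp - c(0, h[2]))) / (2 * h[2]))
  denom <- drop(crossprod(grad, A %*% grad))
  if (denom <= 0) return(ss$n - ss$p)
  df <- 2 * g(vp)^2 / denom
  min(df, ss$n - ss$p)  # cap at the residual-df upper bound
}

# Per-term F test with Satterthwaite (Fai-Cornelius for multi-df terms).
ri_term_ftest <- function(ss, vp, beta, cols, A) {
  C <- ri_vcov_beta(ss, vp)
  c_ <- length(cols)
  L <- diag(ss$p)[cols, , drop = FALSE]
  M <- L %*% C %*% t(L)
  Lb <- beta[cols]
  Fval <- drop(crossprod(Lb, solve(M, Lb))) / c_
  if (c_ == 1L) {
    df2 <- ri_satterthwaite_df(ss, vp, L[1, ], A)
  } else {
    eig <- eigen(M, symmetric = TRUE)
    nus <- vapply(seq_len(c_), function(i)
      ri_satterthwaite_df(ss, vp, drop(t(L) %*% eig$vectors[, i]), A),
      numeric(1))
    keep <- nus > 2
    E <- sum(nus[keep] / (nus[keep] - 2))
    df2 <- if (E > c_) 2 * E / (E - c_) else ss$n - ss$p
    df2 <- min(df2, ss$n - ss$p)
  }
  c(F = Fval, df1 = c_, df2 = df2,
    p = stats::pf(Fval, c_, df2, lower.tail = FALSE))
}

ri_fit_core <- function(formula, data, terms_of_interest) {
  fit <- lme4::lmer(formula, data = data, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  X <- lme4::getME(fit, "X")
  y <- lme4::getME(fit, "y")
  grp <- lme4::getME(fit, "flist")[[1L]]
  ss <- ri_suffstats(X, y, grp)
  theta <- lme4::getME(fit, "theta")
  sigma <- stats::sigma(fit)
  vp <- c(unname(theta), sigma)
  beta <- lme4::fixef(fit)
  A <- ri_varpar_vcov(ss, vp)
  assign_ <- attr(X, "assign")
  ftests <- do.call(rbind, lapply(names(terms_of_interest), function(tn) {
    cols <- which(assign_ == terms_of_interest[[tn]])
    data.frame(term = tn, t(ri_term_ftest(ss, vp, beta, cols, A)))
  }))
  rownames(ftests) <- NULL
  fitted_fixed <- drop(X %*% beta)
  u0_var <- (vp[1] * vp[2])^2
  resid_var <- vp[2]^2
  var_fixed <- stats::var(fitted_fixed)
  structure(list(
    beta = beta, u0_var = u0_var, resid_var = resid_var,
    f_tests = ftests,
    r2_marginal = var_fixed / (var_fixed + u0_var + resid_var),
    n_obs = ss$n, n_subjects = ss$q, formula = formula, fit = fit),
    class = "mixed_model_fit")
}

#' Random-intercept mixed model for repeated blink measurements
#'
#' Fits `bm ~ stai + (1 | subject)` by REML: a per-subject random intercept
#' absorbs the dependence among a participant's repeated film-clip
#' observations while the anxiety score enters as a fixed slope. Reports
#' the fixed effects, variance components, a Satterthwaite-F test for the
#' slope, and the marginal R-squared (fixed-effect variance share,
#' Nakagawa-Schielzeth form). In the balanced design with a purely
#' between-subject predictor, the Satterthwaite denominator df equals the
#' between-subject df, `n_subjects - 2`.
#'
#' @param data long data frame, one row per subject x clip.
#' @param response column name of the blink measurement.
#' @param predictor column name of the (between-subject) anxiety score.
#' @param subject column name of the subject identifier.
#' @return An object of class `mixed_model_fit`.
#' @export
fit_random_intercept <- function(data, response, predictor,
                                 subject = "subject") {
  f <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)",
                                 response, predictor, subject))
  fit <- ri_fit_core(f, data, stats::setNames(list(1L), predictor))
  fit
}

#' Mixed model with film-type main effect and type-by-anxiety interaction
#'
#' Extends [fit_random_intercept()] with a categorical film-type main
#' effect and its interaction with the anxiety score:
#' `bm ~ stai * type + (1 | subject)`. The neutral category (label
#' `"neutral"`, when present) is the reference level. Per-term F tests use
#' Satterthwaite denominator df (Fai-Cornelius combination for the
#' multi-df type and interaction terms). With a single type level the
#' model reduces to the random-intercept fit.
#'
#' @inheritParams fit_random_intercept
#' @param type column name of the film-type category.
#' @return An object of class `mixed_model_fit`.
#' @export
fit_type_interaction <- function(data, response, predictor,
                                 type = "condition", subject = "subject") {
  tv <- data[[type]]
  if (is.null(tv)) stop(sprintf("column '%s' not found", type), call. = FALSE)
  if (!is.factor(tv)) tv <- factor(tv)
  empty <- levels(tv)[tabulate(tv, nlevels(tv)) == 0L]
  if (length(empty))
    stop(sprintf("design error: film-type level(s) with no observations: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  if (nlevels(tv) == 1L)
    return(fit_random_intercept(data, response, predictor, subject))
  if ("neutral" %in% levels(tv)) tv <- stats::relevel(tv, "neutral")
  data[[type]] <- tv
  f <- stats::as.formula(sprintf("%s ~ %s * %s + (1 | %s)",
                                 response, predictor, type, subject))
  terms <- stats::setNames(list(1L, 2L, 3L),
                           c(predictor, type, paste0(predictor, ":", type)))
  ri_fit_core(f, data, terms)
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("<mixed_model_fit> ")
  cat(sprintf("%d obs, %d subjects | u0_var %.4g, resid_var %.4g, R2m %.3f\n",
              x$n_obs, x$n_subjects, x$u0_var, x$resid_var, x$r2_marginal))
  ft <- x$f_tests
  for (i in seq_len(nrow(ft)))
    cat(sprintf("  %s: F(%d, %.1f) = %.3f, p = %.4g\n",
                ft$term[i], ft$df1[i], ft$df2[i], ft$F[i], ft$p[i]))
  invisible(x)
}
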