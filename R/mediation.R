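#' Ordinary least squares fit with standard errors
#'
#' Thin estimator backing the path model: solves the least-squares
#' problem for a response and a predictor matrix (intercept added
#' automatically), returning coefficients and their standard errors from
#' the residual variance. Rank-deficient designs are an error, never
#' silently dropped.
#'
#' @param y numeric response vector.
#' @param x numeric predictor matrix (without intercept column).
#' @return list: \code{coefficients} (named, intercept first),
#'   \code{se}, \code{sigma2} (residual variance), \code{df_residual}.
#' @export
fit_ols <- function(y, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(length(y) == nrow(x))
  X <- cbind("(intercept)" = 1, x)
  if (nrow(X) <= ncol(X)) stop("need n > number of predictors")
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) stop("rank-deficient design matrix")
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(X)
  list(coefficients = fit$coefficients, se = se,
       sigma2 = sigma2, df_residual = df)
}

# Path coefficients for one sample. With covariates the three regressions
# are fitted by QR; without, closed-form centered cross-products (the hot
# path inside the bootstrap loop). Returns c(a, b, cprime, c).
.paths_fast <- function(x, m, y) {
  n <- length(x)
  cx <- x - sum(x) / n
  cm <- m - sum(m) / n
  cy <- y - sum(y) / n
  sxx <- sum(cx * cx); sxm <- sum(cx * cm); smm <- sum(cm * cm)
  sxy <- sum(cx * cy); smy <- sum(cm * cy)
  a <- sxm / sxx
  det <- sxx * smm - sxm * sxm
  cprime <- (smm * sxy - sxm * smy) / det
  b <- (sxx * smy - sxm * sxy) / det
  c(a = a, b = b, cprime = cprime, c = sxy / sxx)
}

.paths_cov <- function(x, m, y, cov) {
  Xa <- cbind(1, x, cov)
  a <- .lm.fit(Xa, m)$coefficients[2]
  cf <- .lm.fit(cbind(1, x, m, cov), y)$coefficients
  c(a = a, b = cf[3], cprime = cf[2], c = .lm.fit(Xa, y)$coefficients[2])
}

#' Simple mediation analysis with percentile bootstrap
#'
#' Fits the three-regression single-mediator model: \code{a} from
#' \code{m ~ x (+ covariates)}, \code{b} and \code{c'} from
#' \code{y ~ x + m (+ covariates)}, and the total effect \code{c} from
#' \code{y ~ x (+ covariates)}. The indirect effect is \code{a * b}; by
#' the OLS decomposition \code{c = c' + a * b} holds exactly on every
#' sample. Confidence bounds for the indirect effect come from a
#' percentile case bootstrap: subjects are resampled with replacement and
#' all paths refitted. The proportion mediated is
#' \code{100 * a * b / c}, reported as \code{NA} (flagged) when the total
#' effect is numerically zero.
#'
#' @param x,m,y numeric vectors: predictor, mediator, outcome.
#' @param covariates optional numeric matrix/data.frame of covariates
#'   entered in every regression.
#' @param n_boot bootstrap resamples for the CI (default 5000).
#' @param ci_level confidence level (default 0.95, percentile bounds).
#' @param seed optional integer; fixing it makes the bootstrap
#'   reproducible.
#' @return list of class \code{"mediation_result"}: paths \code{a, b,
#'   c, cprime}, \code{indirect}, \code{ci_low}, \code{ci_high},
#'   \code{prop_mediated}, \code{n}, \code{n_boot}, \code{ci_level},
#'   \code{seed}, \code{covariate_names}, and the bootstrap indirect
#'   draws in \code{boot_indirect}.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); m <- 0.5 * x + rnorm(200); y <- 0.4 * m + rnorm(200)
#' mediate(x, m, y, n_boot = 500, seed = 42)
#' @export
mediate <- function(x, m, y, covariates = NULL,
                    n_boot = 5000, ci_level = 0.95, seed = NULL) {
  stopifnot(length(m) == length(x), length(y) == length(x),
            ci_level > 0, ci_level < 1, n_boot >= 1)
  cov <- NULL
  if (!is.null(covariates)) {
    cov <- as.matrix(covariates)
    stopifnot(nrow(cov) == length(x))
  }
  ok <- stats::complete.cases(if (is.null(cov)) cbind(x, m, y)
                              else cbind(x, m, y, cov))
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  if (!is.null(cov)) cov <- cov[ok, , drop = FALSE]
  n <- length(x)
  if (n < 10) stop("need at least 10 complete cases, got ", n)

  est <- if (is.null(cov)) .paths_fast(x, m, y) else .paths_cov(x, m, y, cov)

  if (!is.null(seed)) set.seed(seed)
  boot <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    p <- if (is.null(cov)) .paths_fast(x[idx], m[idx], y[idx])
         else .paths_cov(x[idx], m[idx], y[idx], cov[idx, , drop = FALSE])
    boot[i] <- p[["a"]] * p[["b"]]
  }
  alpha <- 1 - ci_level
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 6))

  indirect <- est[["a"]] * est[["b"]]
  prop <- if (abs(est[["c"]]) > 1e-12) 100 * indirect / est[["c"]] else NA_real_
  structure(list(a = est[["a"]], b = est[["b"]], c = est[["c"]],
                 cprime = est[["cprime"]], indirect = indirect,
                 ci_low = ci[1], ci_high = ci[2],
                 prop_mediated = prop, n = n, n_boot = n_boot,
                 ci_level = ci_level, seed = seed,
                 covariate_names = colnames(cov),
                 boot_indirect = boot),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Simple mediation (percentile bootstrap, n =", x$n,
      ", boots =", x$n_boot, ")\n")
  cat(sprintf("  a = %.4f  b = %.4f  c' = %.4f  c = %.4f\n",
              x$a, x$b, x$cprime, x$c))
  cat(sprintf("  indirect a*b = %.4f, %d%% CI [%.4f, %.4f]\n",
              x$indirect, round(100 * x$ci_level), x$ci_low, x$ci_high))
  if (is.na(x$prop_mediated))
    cat("  proportion mediated: undefined (total effect ~ 0)\n")
  else cat(sprintf("  proportion mediated = %.2f%%\n", x$prop_mediated))
  invisible(x)
}

#' Mediation path algebra on a printed correlation matrix
#'
#' Computes the standardized single-mediator paths implied by the three
#' pairwise correlations alone (no covariates): \code{a = r_xm},
#' \code{b = (r_my - r_xy r_xm) / (1 - r_xm^2)}, \code{c' = (r_xy -
#' r_my r_xm) / (1 - r_xm^2)}, \code{c = r_xy}, indirect \code{a b} and
#' proportion mediated \code{100 a b / c}. Useful as a closed-form
#' consistency check against results published only as a correlation
#' table.
#'
#' @param r_xm,r_my,r_xy Pearson correlations among predictor, mediator
#'   and outcome.
#' @return list: \code{a, b, cprime, c, indirect, prop_mediated}.
#' @examples
#' mediate_from_correlations(r_xm = 0.400, r_my = 0.373, r_xy = 0.294)
#' @export
mediate_from_correlations <- function(r_xm, r_my, r_xy) {
  stopifnot(abs(r_xm) < 1, abs(r_my) <= 1, abs(r_xy) <= 1)
  a <- r_xm
  b <- (r_my - r_xy * r_xm) / (1 - r_xm^2)
  cprime <- (r_xy - r_my * r_xm) / (1 - r_xm^2)
  list(a = a, b = b, cprime = cprime, c = r_xy,
       indirect = a * b,
       prop_mediated = if (abs(r_xy) > 1e-12) 100 * a * b / r_xy else NA_real_)
}

#' Mediation analysis within addiction subgroups
#'
#' Splits a scored cohort by a grouping column (by default the
#' addicted/non-addicted classification), runs \code{\link{mediate}}
#' within each subgroup, and additionally reports the predictor-outcome
#' and mediator-outcome correlations per subgroup, so patterns like
#' "bullying-addiction association absent while affect-addiction
#' association persists" are directly checkable. Subgroups below
#' \code{min_n} complete cases are skipped with a warning.
#'
#' @param data data.frame (e.g. a scored cohort).
#' @param x,m,y column names of predictor, mediator, outcome.
#' @param group column name of the subgroup label, default
#'   \code{"addiction_class"}.
#' @param covariates optional character vector of covariate columns.
#' @param min_n minimum complete cases per subgroup (default 30).
#' @param ... passed to \code{\link{mediate}} (\code{n_boot},
#'   \code{ci_level}, \code{seed}).
#' @return named list per subgroup: \code{mediation} (a
#'   \code{mediation_result}) and \code{screen} (data.frame of r and p
#'   for x-y and m-y).
#' @export
subgroup_mediate <- function(data, x, m, y, group = "addiction_class",
                             covariates = NULL, min_n = 30, ...) {
  stopifnot(all(c(x, m, y, group, covariates) %in% names(data)))
  out <- list()
  for (g in unique(stats::na.omit(data[[group]]))) {
    d <- data[!is.na(data[[group]]) & data[[group]] == g, , drop = FALSE]
    cc <- stats::complete.cases(d[, c(x, m, y, covariates), drop = FALSE])
    if (sum(cc) < min_n) {
      warning("subgroup '", g, "' has ", sum(cc), " complete cases (< ",
              min_n, "); skipped")
      next
    }
    d <- d[cc, , drop = FALSE]
    med <- mediate(d[[x]], d[[m]], d[[y]],
                   covariates = if (is.null(covariates)) NULL
                                else d[, covariates, drop = FALSE], ...)
    r_xy <- stats::cor.test(d[[x]], d[[y]])
    r_my <- stats::cor.test(d[[m]], d[[y]])
    out[[g]] <- list(
      mediation = med,
      screen = data.frame(pair = c(paste(x, y, sep = "-"),
                                   paste(m, y, sep = "-")),
                          r = c(unname(r_xy$estimate), unname(r_my$estimate)),
                          p = c(r_xy$p.value, r_my$p.value),
                          n = nrow(d)))
  }
  out
}
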