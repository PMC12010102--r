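test_that("fit_ols matches exact lines, orthogonality and the normal equations", {
  x <- 1:20
  f <- fit_ols(2 * x, cbind(x = x))
  expect_equal(unname(f$coefficients), c(0, 2), tolerance = 1e-12)
  # mutually orthogonal, centered predictors: multiple = simple slopes
  set.seed(1)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(60 * 2), 60, 2))))[, 2:3]
  y <- rnorm(60)
  f2 <- fit_ols(y, X)
  expect_equal(unname(f2$coefficients[2]),
               unname(fit_ols(y, X[, 1, drop = FALSE])$coefficients[2]),
               tolerance = 1e-10)
  # brute-force normal-equations oracle on random 50 x 3 data
  set.seed(2)
  X3 <- matrix(rnorm(150), 50, 3); y3 <- rnorm(50)
  D <- cbind(1, X3)
  beta <- solve(t(D) %*% D, t(D) %*% y3)
  expect_equal(unname(fit_ols(y3, X3)$coefficients), as.numeric(beta),
               tolerance = 1e-10)
  expect_error(fit_ols(y3, cbind(X3, X3[, 1])), "rank")
})

test_that("OLS decomposition c = c' + a*b holds exactly, with and without covariates", {
  set.seed(3)
  for (i in 1:5) {
    n <- 120
    x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.3 * x + 0.4 * m + rnorm(n)
    cov <- if (i %% 2) cbind(rnorm(n), rbinom(n, 1, .5)) else NULL
    r <- mediate(x, m, y, covariates = cov, n_boot = 50, seed = i)
    expect_equal(r$c, r$cprime + r$a * r$b, tolerance = 1e-10)
  }
})

test_that("path estimates agree with the closed-form correlation algebra", {
  # sample correlations imposed exactly; standardized regression on that
  # sample must equal the printed-matrix path algebra
  R <- matrix(c(1, .400, .294,
                .400, 1, .373,
                .294, .373, 1), 3, 3)
  X <- make_exact_cor(600, R, seed = 4)
  med <- mediate(X[, 1], X[, 2], X[, 3], n_boot = 50, seed = 1)
  alg <- mediate_from_correlations(r_xm = .400, r_my = .373, r_xy = .294)
  expect_equal(med$a, alg$a, tolerance = 1e-8)
  expect_equal(med$b, alg$b, tolerance = 1e-8)
  expect_equal(med$cprime, alg$cprime, tolerance = 1e-8)
  expect_equal(med$indirect, alg$indirect, tolerance = 1e-8)
  expect_equal(med$prop_mediated, alg$prop_mediated, tolerance = 1e-6)
  # frozen closed-form values for this correlation matrix
  expect_equal(alg$b, 0.3040476, tolerance = 1e-6)
  expect_equal(alg$indirect, 0.1216190, tolerance = 1e-6)
  expect_equal(alg$prop_mediated, 41.36702, tolerance = 1e-4)
})

test_that("covariate-adjusted paths equal lm coefficients", {
  set.seed(5)
  n <- 150
  cov <- cbind(age = rnorm(n), fd = rnorm(n))
  x <- rnorm(n); m <- 0.5 * x + 0.2 * cov[, 1] + rnorm(n)
  y <- 0.3 * x + 0.4 * m - 0.1 * cov[, 2] + rnorm(n)
  r <- mediate(x, m, y, covariates = cov, n_boot = 50, seed = 2)
  expect_equal(r$a, unname(coef(lm(m ~ x + cov))["x"]), tolerance = 1e-10)
  fit_y <- lm(y ~ x + m + cov)
  expect_equal(r$b, unname(coef(fit_y)["m"]), tolerance = 1e-10)
  expect_equal(r$cprime, unname(coef(fit_y)["x"]), tolerance = 1e-10)
  expect_equal(r$c, unname(coef(lm(y ~ x + cov))["x"]), tolerance = 1e-10)
})

test_that("bootstrap is seed-deterministic and its CI shrinks ~ 1/sqrt(n)", {
  set.seed(6)
  n <- 3200
  x <- rnorm(n); m <- 0.4 * x + rnorm(n); y <- 0.3 * m + 0.2 * x + rnorm(n)
  r1 <- mediate(x, m, y, n_boot = 400, seed = 99)
  r2 <- mediate(x, m, y, n_boot = 400, seed = 99)
  expect_identical(r1$boot_indirect, r2$boot_indirect)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  widths <- sapply(c(200, 800, 3200), function(k) {
    r <- mediate(x[1:k], m[1:k], y[1:k], n_boot = 400, seed = 7)
    r$ci_high - r$ci_low
  })
  # width ratio between n and 4n should be ~2 (allow 1.5..3)
  expect_gt(widths[1] / widths[2], 1.5); expect_lt(widths[1] / widths[2], 3)
  expect_gt(widths[2] / widths[3], 1.5); expect_lt(widths[2] / widths[3], 3)
})

test_that("null mediator path yields a CI covering zero", {
  p <- gen_params(n_subjects = 2000, a_true = 0.4, b_true = 0,
                  cprime_true = 0.2, seed = 15)
  lat <- gen_questionnaire_cohort(p)$truth$latents
  r <- mediate(lat$bv, lat$na, lat$sva, n_boot = 1000, seed = 8)
  expect_true(r$ci_low <= 0 && r$ci_high >= 0)
  expect_lt(abs(r$indirect), 0.05)
})

test_that("proportion mediated is flagged undefined when the total effect vanishes", {
  set.seed(9)
  x <- rnorm(500)
  m <- 0.5 * x + rnorm(500)
  y <- rnorm(500)
  y <- residuals(lm(y ~ x))   # force sample c to 0 exactly
  r <- mediate(x, m, y, n_boot = 50, seed = 1)
  expect_true(is.na(r$prop_mediated))
})

test_that("subgroup mediation is consistent with the pooled analysis", {
  coh <- fixture_cohort(600, seed = 31)
  sc <- as.data.frame(score_cohort(coh$items))
  sub <- subgroup_mediate(sc, "bv", "na", "sva", n_boot = 200, seed = 3)
  expect_setequal(names(sub), c("addicted", "nonaddicted"))
  for (g in names(sub)) {
    m <- sub[[g]]$mediation
    expect_equal(m$c, m$cprime + m$a * m$b, tolerance = 1e-10)
    expect_equal(sub[[g]]$screen$n, rep(m$n, 2))
  }
  # identical strata give identical results
  sc$fake <- rep(c("g1", "g2"), each = 300)
  sc2 <- sc; sc2[301:600, c("bv", "na", "sva")] <- sc[1:300, c("bv", "na", "sva")]
  sub2 <- subgroup_mediate(sc2, "bv", "na", "sva", group = "fake",
                           n_boot = 200, seed = 4)
  expect_equal(sub2$g1$mediation$indirect, sub2$g2$mediation$indirect)
  # ignoring the split reproduces mediate() on the union
  whole <- mediate(sc$bv, sc$na, sc$sva, n_boot = 200, seed = 5)
  sc$one <- "all"
  sub3 <- subgroup_mediate(sc, "bv", "na", "sva", group = "one",
                           n_boot = 200, seed = 5)
  expect_equal(sub3$all$mediation$indirect, whole$indirect, tolerance = 1e-12)
  expect_equal(c(sub3$all$mediation$ci_low, sub3$all$mediation$ci_high),
               c(whole$ci_low, whole$ci_high), tolerance = 1e-12)
  # undersized subgroups are skipped with a warning
  sc$tiny <- c(rep("a", 5), rep("b", 595))
  expect_warning(subgroup_mediate(sc, "bv", "na", "sva", group = "tiny",
                                  n_boot = 50, seed = 1), "skipped")
})
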