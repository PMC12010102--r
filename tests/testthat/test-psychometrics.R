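test_that("scale scoring sums items, respects range and is additive over subscales", {
  defs <- default_scales()
  n <- 6
  items <- as.data.frame(matrix(1L, n, 10))
  names(items) <- sprintf("sva_item%02d", 1:10)
  expect_equal(score_scale(items, defs$sva)$sva, rep(10, n))   # floor 10
  items[] <- 6L
  expect_equal(score_scale(items, defs$sva)$sva, rep(60, n))   # ceiling 60
  items[1, 1] <- 7L
  expect_error(score_scale(items, defs$sva), "range")

  coh <- fixture_cohort(200)
  sc <- score_cohort(coh$items)
  expect_equal(sc$bv, sc$vb + sc$pb + sc$rb)
  expect_true(all(sc$sva >= 10 & sc$sva <= 60))
  # one missing item drops the subject from that scale's totals only
  it2 <- coh$items
  it2$sva_item03[5] <- NA
  sc2 <- score_cohort(it2)
  expect_true(is.na(sc2$sva[5]))
  expect_false(is.na(sc2$bv[5]))
  expect_equal(attr(sc2, "incomplete"), 5L)
})

test_that("addiction classification uses inclusive gender-specific cutoffs", {
  expect_equal(classify_addiction(33, "F"), "addicted")
  expect_equal(classify_addiction(30, "M"), "nonaddicted")
  expect_equal(classify_addiction(c(31, 31), c("M", "F")),
               c("addicted", "nonaddicted"))
  expect_error(classify_addiction(30, NA_character_), "gender")
  expect_error(classify_addiction(30, "X"), "gender")
})

test_that("cronbach alpha matches its formula oracle and known cases", {
  set.seed(1)
  x <- rnorm(100)
  dup <- cbind(x, x, x)
  expect_equal(cronbach_alpha(dup), 1)
  # population covariance [[1,.5],[.5,1]] imposed exactly on the sample:
  # alpha = 2*(1 - 2/3) = 2/3 by the formula
  two <- make_exact_cor(400, matrix(c(1, .5, .5, 1), 2), seed = 2)
  expect_equal(cronbach_alpha(two), 2 / 3, tolerance = 1e-10)
  # independent items -> alpha near 0
  set.seed(3)
  ind <- matrix(rnorm(2000 * 10), 2000, 10)
  expect_lt(abs(cronbach_alpha(ind)), 0.1)
  # invariance to item order; adding a parallel item raises alpha
  cs <- make_exact_cor(300, diag(4) * 0.5 + 0.5, seed = 4)
  expect_equal(cronbach_alpha(cs), cronbach_alpha(cs[, c(3, 1, 4, 2)]))
  cs5 <- make_exact_cor(300, diag(5) * 0.5 + 0.5, seed = 4)
  expect_gt(cronbach_alpha(cs5), cronbach_alpha(cs))
  expect_error(cronbach_alpha(matrix(1, 10, 3)), "variance")
  expect_error(cronbach_alpha(matrix(rnorm(10), 10, 1)), "2 items")
})

test_that("harman single-factor extraction flags a dominant common factor", {
  # one factor, loading .9 on 20 items: lambda1 = 1 + 19*.81 -> 81.95%
  R <- diag(20) * (1 - 0.81) + 0.81
  x <- make_exact_cor(500, R, seed = 5)
  h <- harman_single_factor(x)
  expect_equal(h$first_factor_pct, 100 * (1 + 19 * 0.81) / 20,
               tolerance = 1e-8)
  expect_true(h$bias_flagged)
  expect_equal(h$n_factors, 1)
  # independent items: first factor near 100/p, many factors, no flag
  set.seed(6)
  ind <- matrix(rnorm(3000 * 25), 3000, 25)
  h2 <- harman_single_factor(ind)
  expect_lt(h2$first_factor_pct, 40)
  expect_equal(h2$first_factor_pct, 100 / 25, tolerance = 0.35)
  expect_false(h2$bias_flagged)
  # invariance to item permutation
  h3 <- harman_single_factor(ind[, sample(25)])
  expect_equal(h3$first_factor_pct, h2$first_factor_pct)
  expect_equal(h3$n_factors, h2$n_factors)
})

test_that("correlation matrix reproduces trivial and attenuated cases", {
  d <- data.frame(x = rnorm(50))
  d$y <- d$x; d$z <- -d$x
  ct <- pearson_corr_matrix(d, c("x", "y", "z"))
  expect_equal(unname(ct$r["x", "y"]), 1)
  expect_equal(unname(ct$r["x", "z"]), -1)
  expect_error(pearson_corr_matrix(data.frame(a = rnorm(9), b = 1),
                                   c("a", "b")), "constant")

  # scored-scale correlation equals the latent correlation attenuated by
  # item loading and discretization; oracle = independent re-simulation
  # of the item model at large n
  p <- gen_params(n_subjects = 5000, a_true = 0.4, seed = 21)
  sc <- score_cohort(gen_questionnaire_cohort(p)$items)
  r_obs <- cor(sc$bv, sc$na)
  set.seed(77)
  n <- 2e5
  bv <- rnorm(n); na_l <- 0.4 * bv + sqrt(1 - 0.16) * rnorm(n)
  cutpts <- qnorm((1:5) / 6)
  sum_items <- function(lat, k, lam) {
    s <- 0
    for (j in seq_len(k))
      s <- s + findInterval(lam * lat + sqrt(1 - lam^2) * rnorm(n), cutpts) + 1
    s
  }
  bv_s <- sum_items(0.9 * bv + sqrt(1 - 0.81) * rnorm(n), 4, 0.8) +
    sum_items(0.9 * bv + sqrt(1 - 0.81) * rnorm(n), 4, 0.8) +
    sum_items(0.9 * bv + sqrt(1 - 0.81) * rnorm(n), 4, 0.8)
  na_s <- sum_items(na_l, 10, 0.8)
  expect_equal(r_obs, cor(bv_s, na_s), tolerance = 0.03)
})

test_that("pooled t from summaries equals the raw-data pooled t and printed values", {
  expect_equal(pooled_t_test(5, 2, 30, 5, 2, 40)$t, 0)
  set.seed(8)
  g1 <- rnorm(40, 1); g2 <- rnorm(55, 0.5, 1.3)
  ours <- pooled_t_test(mean(g1), sd(g1), 40, mean(g2), sd(g2), 55)
  oracle <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(ours$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(ours$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(ours$df, unname(oracle$parameter))
  # published group contrasts recomputed from their summary rows
  expect_equal(pooled_t_test(25.35, 12.15, 1269, 18.21, 7.87, 1615)$t,
               19.06, tolerance = 0.02)
  expect_equal(pooled_t_test(27.63, 8.33, 1269, 23.90, 7.02, 1615)$t,
               13.03, tolerance = 0.02)
  expect_error(pooled_t_test(1, 0, 10, 1, 0, 10), "pooled variance")
})

test_that("2x2 chi-square matches the expected-counts oracle and is swap-invariant", {
  m <- matrix(c(620, 558, 649, 1057), 2)
  res <- chi_square_2x2(m)
  # brute-force Pearson statistic from expected counts
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(res$chi2, sum((m - e)^2 / e), tolerance = 1e-9)
  expect_equal(res$df, 1)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$chi2, 0)
  expect_equal(chi_square_2x2(m[2:1, ])$chi2, res$chi2)
  expect_equal(chi_square_2x2(m[, 2:1])$chi2, res$chi2)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "marginal")
})
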