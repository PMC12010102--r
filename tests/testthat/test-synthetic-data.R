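test_that("generator parameters are validated against the implied model", {
  expect_error(gen_params(a_true = 0.9, b_true = 0.9, cprime_true = 0.5),
               "positive-definite|\\(-1, 1\\)")
  expect_error(gen_params(likert_levels = 1), "likert_levels")
  expect_error(gen_params(a_true = 1.2), "positive-definite")
  p <- gen_params(a_true = 0.4, b_true = 0.3, cprime_true = 0.18)
  expect_equal(p$c_true, 0.18 + 0.4 * 0.3)
})

test_that("identical seeds give byte-identical cohorts; streams are local", {
  p <- gen_params(n_subjects = 50, seed = 42)
  set.seed(7); before <- rnorm(1)
  c1 <- gen_questionnaire_cohort(p)
  c2 <- gen_questionnaire_cohort(p)
  expect_identical(c1, c2)
  # the generator restores the caller's RNG state
  set.seed(7); expect_identical(rnorm(1), before)
  c3 <- gen_questionnaire_cohort(gen_params(n_subjects = 50, seed = 43))
  expect_false(identical(c1$items, c3$items))
})

test_that("sample latent correlations converge to the closed-form implied matrix", {
  p <- gen_params(n_subjects = 5000, a_true = 0.4, b_true = 0.3,
                  cprime_true = 0.18, seed = 11)
  coh <- gen_questionnaire_cohort(p)
  emp <- cor(coh$truth$latents[, c("bv", "na", "sva")])
  expect_lt(max(abs(emp - implied_latent_cor(p))), 0.03)
})

test_that("null paths give uncorrelated scale scores", {
  p <- gen_params(n_subjects = 3000, a_true = 0, b_true = 0,
                  cprime_true = 0, seed = 5)
  sc <- score_cohort(gen_questionnaire_cohort(p)$items)
  r <- cor(as.data.frame(sc)[, c("sva", "bv", "na")])
  off <- abs(r[upper.tri(r)])
  expect_lt(max(off), 3 / sqrt(p$n_subjects))
})

test_that("likert discretization is uniform on 1..L and monotone in the latent", {
  z <- seq(-4, 4, length.out = 2001)
  cut6 <- svapath:::.likert_cut(z, 6L)
  expect_true(all(diff(cut6) >= 0))            # monotone
  expect_setequal(unique(cut6), 1:6)
  set.seed(1)
  u <- svapath:::.likert_cut(rnorm(60000), 6L) # equiprobable thresholds
  expect_lt(max(abs(tabulate(u, 6) / 60000 - 1 / 6)), 0.01)
  # stochastic ordering of items given higher latent
  p <- gen_params(n_subjects = 4000, seed = 13)
  coh <- gen_questionnaire_cohort(p)
  hi <- coh$truth$latents$sva > 1
  lo <- coh$truth$latents$sva < -1
  expect_gt(mean(as.matrix(coh$items[hi, grep("^sva_item", names(coh$items))])),
            mean(as.matrix(coh$items[lo, grep("^sva_item", names(coh$items))])))
})

test_that("resting generator validates its grid and inputs", {
  expect_error(neuro_gen_params(n_subjects = 5, n_timepoints = 40,
                                tr_seconds = 0.5),
               "frequency bins")
  p <- neuro_gen_params(n_subjects = 5, n_parcels = 4, n_timepoints = 150)
  expect_error(gen_resting_parcels(p, trait = rnorm(3)), "per subject")
  p2 <- neuro_gen_params(n_subjects = 5, n_parcels = 4, n_timepoints = 150,
                         pattern_coupling_parcels = 2L)
  expect_error(gen_resting_parcels(p2, trait = rnorm(5)), "item profiles")
  expect_error(neuro_gen_params(n_subjects = 5, n_parcels = 4,
                                coupling_parcels = 9L), "coupling_parcels")
})

test_that("resting generator is seed-deterministic and matches its streaming form", {
  p <- neuro_gen_params(n_subjects = 6, n_parcels = 5,
                        n_voxels_per_parcel = 8, n_timepoints = 150,
                        coupling_parcels = 2L, pattern_coupling_parcels = 4L,
                        seed = 31)
  trait <- seq_len(6)
  items <- matrix(sample(1:6, 60, TRUE), 6, 10)
  s1 <- gen_resting_parcels(p, trait, items)
  s2 <- gen_resting_parcels(p, trait, items)
  expect_identical(s1, s2)
  m_full <- alff_maps(s1)
  m_stream <- simulate_alff_maps(p, trait, items)
  expect_equal(m_full$values, m_stream$values, tolerance = 1e-12)
})

test_that("zero coupling leaves parcel-mean ALFF unrelated to the trait", {
  set.seed(9)
  n <- 100
  trait <- rnorm(n)
  p <- neuro_gen_params(n_subjects = n, n_parcels = 8,
                        n_voxels_per_parcel = 6, n_timepoints = 150,
                        coupling_parcels = seq_len(8), coupling_strength = 0,
                        seed = 17)
  pm <- parcel_means(simulate_alff_maps(p, trait))
  r <- as.numeric(cor(trait, pm))
  expect_lt(max(abs(r)), 3 / sqrt(n))
})

test_that("ALFF of pure-noise voxels is linear in noise sd with the Parseval mean", {
  # white noise of sd s has expected in-band mean amplitude s*sqrt(pi/N)
  tpts <- 300
  noise_alff <- function(s, seed) {
    set.seed(seed)
    m <- matrix(rnorm(tpts * 200, sd = s), tpts, 200)
    mean(svapath:::.alff_matrix(m, 2, c(0.01, 0.1)))
  }
  a1 <- noise_alff(1, 23); a2 <- noise_alff(2, 23)
  expect_equal(a2 / a1, 2, tolerance = 1e-10)  # identical draws, scaled
  expect_equal(a1, sqrt(pi / tpts), tolerance = 0.05)
})
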