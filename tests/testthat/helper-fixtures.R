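# Shared fixtures, built in code at load time.

# Small scored cohort reused across psychometric/mediation tests.
fixture_cohort <- function(n = 400, seed = 101, a = 0.4, b = 0.3,
                           cprime = 0.18) {
  gen_questionnaire_cohort(gen_params(n_subjects = n, a_true = a, b_true = b,
                                      cprime_true = cprime, seed = seed))
}

# Small neural fixture: 10 parcels, planted amplitude coupling in parcel 3
# and pattern coupling in parcel 5.
fixture_maps <- function(n = 24, seed = 202) {
  coh <- fixture_cohort(n, seed = seed)
  sva_items <- as.matrix(coh$items[, grep("^sva_item", names(coh$items))])
  trait <- rowSums(sva_items)
  p <- neuro_gen_params(n_subjects = n, n_parcels = 10,
                        n_voxels_per_parcel = 12, n_timepoints = 150,
                        tr_seconds = 2, coupling_parcels = 3L,
                        coupling_strength = 0.5,
                        pattern_coupling_parcels = 5L, seed = seed)
  list(params = p, trait = trait, items = sva_items,
       maps = simulate_alff_maps(p, trait, sva_items))
}

# Transform columns of a random matrix so the sample correlation matrix
# (and each sample variance) is exactly R; used to build data with known
# sample moments for closed-form oracles.
make_exact_cor <- function(n, R, seed = 1) {
  set.seed(seed)
  k <- ncol(R)
  X <- matrix(rnorm(n * k), n, k)
  X <- scale(X, scale = FALSE)
  X <- X %*% solve(chol(crossprod(X) / (n - 1)))
  X %*% chol(R)
}
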