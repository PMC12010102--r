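#' Parameters for the synthetic questionnaire generator
#'
#' Bundles and validates the generating model for a synthetic cohort of
#' Likert questionnaire responses. The cohort follows a single-mediator
#' path model on standardized latent variables: bullying victimization
#' (BV) is standard normal, negative affect is \code{a_true * BV} plus
#' noise, and the latent addiction score is
#' \code{cprime_true * BV + b_true * NA} plus noise. Error variances are
#' solved so that all latent variables have unit variance, which makes the
#' path coefficients equal to (partial) correlations and gives closed-form
#' implied moments for testing. The implied total effect is
#' \code{c = cprime_true + a_true * b_true}.
#'
#' @param n_subjects number of subjects to simulate.
#' @param a_true standardized path from bullying victimization to
#'   negative affect.
#' @param b_true standardized path from negative affect to the latent
#'   addiction score, given bullying victimization.
#' @param cprime_true standardized direct path from bullying victimization
#'   to the latent addiction score.
#' @param item_loading common factor loading of every item on its own
#'   latent variable, in \[0, 1\]. Items are unit-variance before
#'   discretization.
#' @param n_items named item counts per scale; defaults are 10 addiction
#'   items, 4 items per bullying subdimension (verbal, physical,
#'   relational), and 10 items each for negative and positive affect.
#' @param subdim_loading loading of each bullying subdimension latent on
#'   the common bullying factor.
#' @param likert_levels number of ordered response options (>= 2).
#' @param female_prop expected proportion of female subjects; gender is
#'   Bernoulli and independent of the latent variables.
#' @param seed integer seed for the generator's RNG stream.
#' @return A validated list of class \code{"gen_params"}; the element
#'   \code{c_true} holds the implied total effect.
#' @export
gen_params <- function(n_subjects = 1000,
                       a_true = 0.4, b_true = 0.3, cprime_true = 0.18,
                       item_loading = 0.8,
                       n_items = c(sva = 10, vb = 4, pb = 4, rb = 4,
                                   na = 10, pa = 10),
                       subdim_loading = 0.9,
                       likert_levels = 6,
                       female_prop = 0.5915,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, likert_levels >= 2,
            item_loading >= 0, item_loading <= 1,
            subdim_loading > 0, subdim_loading <= 1,
            female_prop >= 0, female_prop <= 1)
  required <- c("sva", "vb", "pb", "rb", "na", "pa")
  if (!all(required %in% names(n_items)))
    stop("n_items must name counts for: ", paste(required, collapse = ", "))
  c_true <- cprime_true + a_true * b_true
  if (abs(c_true) >= 1)
    stop("implied total effect c = cprime + a*b must lie in (-1, 1)")
  # residual variances keeping every latent at unit variance
  var_e1 <- 1 - a_true^2
  var_e2 <- 1 - (cprime_true^2 + b_true^2 + 2 * a_true * b_true * cprime_true)
  if (var_e1 <= 0 || var_e2 <= 0)
    stop("paths (a, b, cprime) do not give a positive-definite implied ",
         "covariance: residual variances are ", signif(var_e1, 4), ", ",
         signif(var_e2, 4))
  structure(list(n_subjects = as.integer(n_subjects),
                 a_true = a_true, b_true = b_true, cprime_true = cprime_true,
                 c_true = c_true, var_e1 = var_e1, var_e2 = var_e2,
                 item_loading = item_loading, n_items = n_items,
                 subdim_loading = subdim_loading,
                 likert_levels = as.integer(likert_levels),
                 female_prop = female_prop, seed = as.integer(seed)),
            class = "gen_params")
}

#' Closed-form latent correlation matrix implied by the path model
#'
#' Returns the population correlation matrix of the latent variables
#' (bullying victimization, negative affect, addiction score) implied by
#' the standardized paths, for use as an oracle against sample moments.
#'
#' @param p a \code{\link{gen_params}} object.
#' @return 3 x 3 correlation matrix with dimnames \code{bv, na, sva}.
#' @export
implied_latent_cor <- function(p) {
  stopifnot(inherits(p, "gen_params"))
  r_bn <- p$a_true
  r_bs <- p$c_true
  r_ns <- p$b_true + p$a_true * p$cprime_true
  m <- matrix(c(1, r_bn, r_bs,
                r_bn, 1, r_ns,
                r_bs, r_ns, 1), 3, 3,
              dimnames = list(c("bv", "na", "sva"), c("bv", "na", "sva")))
  m
}

# Discretize a standard-normal item into 1..L by equiprobable thresholds,
# so item marginals are uniform on 1..L and higher latent values give
# stochastically higher responses.
.likert_cut <- function(z, levels) {
  thresholds <- stats::qnorm(seq_len(levels - 1) / levels)
  findInterval(z, thresholds) + 1L
}

# Draw item columns for one scale: loading * latent + sqrt(1-loading^2) * noise
# keeps each pre-cut item standard normal.
.gen_scale_items <- function(latent, k, loading, levels, prefix) {
  n <- length(latent)
  resid <- sqrt(1 - loading^2)
  out <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    z <- loading * latent + resid * stats::rnorm(n)
    out[, j] <- .likert_cut(z, levels)
  }
  colnames(out) <- sprintf("%s_item%02d", prefix, seq_len(k))
  out
}

#' Generate a synthetic questionnaire cohort with known mediation structure
#'
#' Simulates a cohort of Likert item responses in which negative affect
#' mediates the association between bullying victimization and the latent
#' short-video addiction score, with generating paths recorded in a truth
#' record. Bullying subdimension latents (verbal, physical, relational)
#' load on a common bullying factor; each item loads on its own scale's
#' latent and is discretized to \code{1..likert_levels} by equiprobable
#' normal thresholds. Demographics (age, gender, group label, parental
#' education, mean framewise displacement) are attached; gender is
#' independent of the latent variables.
#'
#' @param p a \code{\link{gen_params}} object.
#' @return A list of class \code{"sva_cohort"} with elements
#'   \describe{
#'     \item{items}{data.frame: \code{id, age, gender, group, mother_edu,
#'       father_edu, fd} plus item columns named \code{<scale>_item##}.}
#'     \item{truth}{list with the latent scores (\code{bv, na, sva, vb,
#'       pb, rb, pa}), the generating parameters and the seed.}
#'   }
#' @examples
#' coh <- gen_questionnaire_cohort(gen_params(n_subjects = 200, seed = 7))
#' head(coh$items[, 1:9])
#' @export
gen_questionnaire_cohort <- function(p) {
  stopifnot(inherits(p, "gen_params"))
  rng <- .local_rng(p$seed, offset = 0L)
  on.exit(rng(), add = TRUE)
  n <- p$n_subjects

  bv <- stats::rnorm(n)
  na_l <- p$a_true * bv + sqrt(p$var_e1) * stats::rnorm(n)
  sva_l <- p$cprime_true * bv + p$b_true * na_l + sqrt(p$var_e2) * stats::rnorm(n)
  sub_resid <- sqrt(1 - p$subdim_loading^2)
  vb_l <- p$subdim_loading * bv + sub_resid * stats::rnorm(n)
  pb_l <- p$subdim_loading * bv + sub_resid * stats::rnorm(n)
  rb_l <- p$subdim_loading * bv + sub_resid * stats::rnorm(n)
  pa_l <- stats::rnorm(n)  # positive affect: scored but unrelated by design

  k <- p$n_items
  items <- cbind(
    .gen_scale_items(sva_l, k[["sva"]], p$item_loading, p$likert_levels, "sva"),
    .gen_scale_items(vb_l,  k[["vb"]],  p$item_loading, p$likert_levels, "vb"),
    .gen_scale_items(pb_l,  k[["pb"]],  p$item_loading, p$likert_levels, "pb"),
    .gen_scale_items(rb_l,  k[["rb"]],  p$item_loading, p$likert_levels, "rb"),
    .gen_scale_items(na_l,  k[["na"]],  p$item_loading, p$likert_levels, "na"),
    .gen_scale_items(pa_l,  k[["pa"]],  p$item_loading, p$likert_levels, "pa"))

  demo <- data.frame(
    id = sprintf("sub%04d", seq_len(n)),
    age = sample(12:24, n, replace = TRUE),
    gender = ifelse(stats::runif(n) < p$female_prop, "F", "M"),
    group = "CS",
    mother_edu = sample(1:5, n, replace = TRUE),
    father_edu = sample(1:5, n, replace = TRUE),
    fd = round(exp(stats::rnorm(n, log(0.12), 0.3)), 4),
    stringsAsFactors = FALSE)

  structure(list(
    items = cbind(demo, as.data.frame(items)),
    truth = list(latents = data.frame(bv = bv, na = na_l, sva = sva_l,
                                      vb = vb_l, pb = pb_l, rb = rb_l,
                                      pa = pa_l),
                 params = p, seed = p$seed)),
    class = "sva_cohort")
}

#' Parameters for the synthetic resting-state parcel generator
#'
#' Describes the acquisition grid and the planted structure for simulated
#' parcel-wise BOLD-like signals: each voxel's series is a sum of
#' sinusoids with frequencies inside the low-frequency band (0.01-0.1 Hz)
#' plus white noise. In \code{coupling_parcels} the sinusoid amplitudes
#' scale with \code{1 + coupling_strength * zscore(trait)}, planting a
#' trait-amplitude association. In \code{pattern_coupling_parcels} each
#' subject's voxel-amplitude pattern mixes a shared template with a
#' projection of the subject's item profile, so behaviorally similar
#' subjects receive similar spatial patterns (the IS-RSA target).
#'
#' @param n_subjects number of subjects.
#' @param n_parcels number of parcels (default 200).
#' @param n_voxels_per_parcel voxels simulated per parcel.
#' @param n_timepoints volumes per series (default 300).
#' @param tr_seconds repetition time in seconds (default 2).
#' @param coupling_parcels integer parcel indices with planted
#'   trait-amplitude coupling.
#' @param coupling_strength unitless slope of the planted couplings; also
#'   weights the item-profile component in pattern-coupled parcels.
#' @param pattern_coupling_parcels parcel indices whose inter-subject
#'   amplitude-pattern similarity tracks behavioral similarity.
#' @param noise_sd standard deviation of the additive white noise.
#' @param n_components sinusoids summed per parcel.
#' @param seed integer seed for the generator's RNG stream.
#' @return A validated list of class \code{"neuro_gen_params"}.
#' @export
neuro_gen_params <- function(n_subjects,
                             n_parcels = 200,
                             n_voxels_per_parcel = 12,
                             n_timepoints = 300,
                             tr_seconds = 2.0,
                             coupling_parcels = integer(0),
                             coupling_strength = 0.5,
                             pattern_coupling_parcels = integer(0),
                             noise_sd = 1,
                             n_components = 4,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_parcels >= 1, n_voxels_per_parcel >= 1,
            tr_seconds > 0, noise_sd >= 0, n_components >= 1)
  if (length(coupling_parcels))
    stopifnot(all(coupling_parcels >= 1), all(coupling_parcels <= n_parcels))
  if (length(pattern_coupling_parcels))
    stopifnot(all(pattern_coupling_parcels >= 1),
              all(pattern_coupling_parcels <= n_parcels))
  n_bins <- length(.band_bins(n_timepoints, tr_seconds, c(0.01, 0.1)))
  if (n_bins < 3)
    stop("acquisition grid too coarse: the 0.01-0.1 Hz band contains ",
         n_bins, " frequency bins (need >= 3); increase n_timepoints or ",
         "tr_seconds")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_parcels = as.integer(n_parcels),
                 n_voxels_per_parcel = as.integer(n_voxels_per_parcel),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 coupling_parcels = as.integer(coupling_parcels),
                 coupling_strength = coupling_strength,
                 pattern_coupling_parcels = as.integer(pattern_coupling_parcels),
                 noise_sd = noise_sd,
                 n_components = as.integer(n_components),
                 seed = as.integer(seed)),
            class = "neuro_gen_params")
}

# Parcel-level shared structure drawn once per simulation: component
# frequencies/phases, the voxel-amplitude template, and the item-profile
# projection used in pattern-coupled parcels.
.neuro_shared <- function(p, n_items) {
  lapply(seq_len(p$n_parcels), function(q) {
    list(freqs = stats::runif(p$n_components, 0.01, 0.1),
         template = matrix(stats::runif(p$n_voxels_per_parcel * p$n_components,
                                        0.5, 1.5),
                           p$n_voxels_per_parcel, p$n_components),
         proj = if (q %in% p$pattern_coupling_parcels)
           matrix(stats::rnorm(p$n_voxels_per_parcel * n_items),
                  p$n_voxels_per_parcel, n_items) / sqrt(n_items)
         else NULL)
  })
}

# Core generator: draws shared structure, then streams one subject at a
# time through `consume(s, array[parcels, voxels, timepoints])`. Both
# gen_resting_parcels() and simulate_alff_maps() use this path, so their
# RNG consumption (hence their outputs) is identical.
.gen_resting_core <- function(p, trait, items, consume) {
  n <- p$n_subjects
  if (length(trait) != n)
    stop("trait must have one value per subject (", n, ")")
  if (length(p$pattern_coupling_parcels) && is.null(items))
    stop("pattern_coupling_parcels requested but no item profiles supplied")
  z_trait <- if (stats::sd(trait) > 0) as.numeric(scale(trait)) else rep(0, n)
  z_items <- NULL
  if (!is.null(items)) {
    items <- as.matrix(items)
    if (nrow(items) != n) stop("items must have one row per subject")
    z_items <- scale(items)
    z_items[!is.finite(z_items)] <- 0
  }

  rng <- .local_rng(p$seed, offset = 101L)
  on.exit(rng(), add = TRUE)
  shared <- .neuro_shared(p, if (is.null(z_items)) 1L else ncol(z_items))

  tp <- seq_len(p$n_timepoints) * p$tr_seconds
  nv <- p$n_voxels_per_parcel
  nc <- p$n_components
  nt <- p$n_timepoints
  # sin(2 pi f t + phi) = sin(phi) cos(2 pi f t) + cos(phi) sin(2 pi f t):
  # the time-dependent factors are shared across subjects and voxels
  sin_t <- lapply(shared, function(sh) sin(2 * pi * outer(sh$freqs, tp)))
  cos_t <- lapply(shared, function(sh) cos(2 * pi * outer(sh$freqs, tp)))
  for (s in seq_len(n)) {
    phase <- matrix(stats::runif(p$n_parcels * nv * nc, 0, 2 * pi),
                    p$n_parcels * nv, nc)
    sig <- vector("list", p$n_parcels)
    for (q in seq_len(p$n_parcels)) {
      sh <- shared[[q]]
      ph <- phase[(q - 1L) * nv + seq_len(nv), , drop = FALSE]
      gain <- if (q %in% p$coupling_parcels)
        max(0.05, 1 + p$coupling_strength * z_trait[s]) else 1
      amp <- sh$template * gain
      if (!is.null(sh$proj)) {
        mod <- pmax(0.1, 1 + p$coupling_strength *
                      as.numeric(sh$proj %*% z_items[s, ]))
        amp <- amp * mod
      }
      sig[[q]] <- (amp * sin(ph)) %*% cos_t[[q]] + (amp * cos(ph)) %*% sin_t[[q]]
    }
    # rows of the stacked matrix vary voxel-fastest within parcel, so the
    # [voxel, parcel, time] reshape then a transpose gives [parcel, voxel, time]
    m <- do.call(rbind, sig) +
      stats::rnorm(p$n_parcels * nv * nt, sd = p$noise_sd)
    consume(s, aperm(array(m, c(nv, p$n_parcels, nt)), c(2, 1, 3)))
  }
  invisible(NULL)
}

#' Generate synthetic parcel-wise resting-state time series
#'
#' Simulates per-subject parcel x voxel x timepoint BOLD-like signals
#' with the planted trait and pattern couplings described in
#' \code{\link{neuro_gen_params}}, plus a truth record of what was
#' planted. For large simulations where only band-limited amplitudes are
#' needed, \code{\link{simulate_alff_maps}} produces identical amplitude
#' maps without materializing the series.
#'
#' @param p a \code{\link{neuro_gen_params}} object.
#' @param trait numeric vector, one behavioral score per subject, driving
#'   amplitude coupling.
#' @param items optional subjects x items matrix of responses driving
#'   pattern coupling; required when \code{pattern_coupling_parcels} is
#'   non-empty.
#' @return A list of class \code{"parcel_ts_set"}: \code{series} (list of
#'   per-subject 3-d arrays \code{[parcel, voxel, timepoint]}),
#'   \code{subjects}, \code{tr_seconds}, and \code{truth} (planted
#'   parcels, strengths, seed).
#' @export
gen_resting_parcels <- function(p, trait, items = NULL) {
  stopifnot(inherits(p, "neuro_gen_params"))
  series <- vector("list", p$n_subjects)
  .gen_resting_core(p, trait, items, function(s, arr) series[[s]] <<- arr)
  structure(list(series = series,
                 subjects = sprintf("sub%04d", seq_len(p$n_subjects)),
                 tr_seconds = p$tr_seconds,
                 truth = list(coupling_parcels = p$coupling_parcels,
                              pattern_coupling_parcels = p$pattern_coupling_parcels,
                              coupling_strength = p$coupling_strength,
                              noise_sd = p$noise_sd, seed = p$seed)),
            class = "parcel_ts_set")
}

#' Simulate amplitude maps directly from the resting-state generator
#'
#' Streams the generator of \code{\link{gen_resting_parcels}} one subject
#' at a time and reduces each subject's series to band-limited amplitude
#' (ALFF) immediately, so simulations with many subjects and parcels do
#' not hold all time series in memory. The result is identical to
#' \code{alff_maps(gen_resting_parcels(p, ...), band)} for the same
#' parameters and seed.
#'
#' @inheritParams gen_resting_parcels
#' @param band frequency band in Hz, default \code{c(0.01, 0.1)}.
#' @param normalize \code{"raw"} or \code{"zscore"} (per-subject z-scoring
#'   across all voxels).
#' @return An \code{\link{alff_maps}} object.
#' @export
simulate_alff_maps <- function(p, trait, items = NULL,
                               band = c(0.01, 0.1), normalize = "raw") {
  stopifnot(inherits(p, "neuro_gen_params"))
  vals <- array(0, c(p$n_subjects, p$n_parcels, p$n_voxels_per_parcel))
  .gen_resting_core(p, trait, items, function(s, arr) {
    vals[s, , ] <<- .alff_subject(arr, p$tr_seconds, band)
  })
  values <- lapply(seq_len(p$n_parcels), function(q)
    matrix(vals[, q, ], nrow = p$n_subjects))
  .new_alff_maps(values, band, normalize,
                 subjects = sprintf("sub%04d", seq_len(p$n_subjects)),
                 tr_seconds = p$tr_seconds)
}

# Run code under a temporary RNG state seeded at seed + offset (one
# documented stream per generator: questionnaire 0, resting-state 101),
# restoring the caller's state afterwards. Returns the restore function.
.local_rng <- function(seed, offset) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed + offset)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
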