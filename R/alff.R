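#' Amplitude of low-frequency fluctuations of a single time series
#'
#' Computes ALFF as the mean single-sided amplitude spectrum within a
#' frequency band: the series is linearly detrended, its periodogram is
#' taken by discrete Fourier transform (no tapering), and ALFF is the
#' mean over band bins of the square root of power, i.e. of the amplitude
#' \code{2 |X_k| / N} at frequencies \code{k / (N * tr)}. Averaging
#' (rather than summing) over bins keeps the value invariant to the
#' number of bins the band happens to contain. Band edges are inclusive.
#'
#' A pure sinusoid of amplitude A at an in-band bin frequency contributes
#' amplitude A at its bin, so ALFF is linear in signal amplitude; a
#' constant series gives 0.
#'
#' @param series numeric vector of at least 32 timepoints.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param band numeric length-2, band in Hz within (0, Nyquist\].
#' @return ALFF in the units of the input signal.
#' @examples
#' t <- seq_len(300) * 2
#' compute_alff(sin(2 * pi * 0.05 * t), tr_seconds = 2)
#' @export
compute_alff <- function(series, tr_seconds, band = c(0.01, 0.1)) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 32) stop("need at least 32 timepoints, got ", n)
  if (anyNA(series)) stop("series contains missing values")
  stopifnot(tr_seconds > 0, length(band) == 2, band[1] < band[2])
  nyquist <- 1 / (2 * tr_seconds)
  if (band[1] <= 0 || band[2] > nyquist + 1e-12)
    stop("band must lie within (0, Nyquist = ", signif(nyquist, 4), " Hz]")
  bins <- .band_bins(n, tr_seconds, band)
  if (!length(bins))
    stop("band [", band[1], ", ", band[2], "] Hz contains no frequency bins ",
         "at N = ", n, ", TR = ", tr_seconds, " s")
  x <- .detrend_linear(matrix(series, ncol = 1))
  amp <- 2 * Mod(stats::fft(x[, 1])[bins + 1L]) / n
  mean(amp)
}

# Indices k (1-based frequency index, frequency k/(N*tr)) whose
# frequencies fall inside the closed band. Excludes DC; caps at Nyquist.
.band_bins <- function(n, tr_seconds, band) {
  k <- seq_len(floor(n / 2))
  f <- k / (n * tr_seconds)
  k[f >= band[1] - 1e-12 & f <= band[2] + 1e-12]
}

# Remove per-column linear trend (intercept + slope) by projection onto
# the orthonormalized [1, t] basis; idempotent.
.detrend_linear <- function(mat) {
  n <- nrow(mat)
  q <- qr.Q(qr(cbind(1, seq_len(n))))
  mat - q %*% crossprod(q, mat)
}

# ALFF for a timepoints x series matrix, vectorized through one matrix FFT.
.alff_matrix <- function(m, tr_seconds, band) {
  n <- nrow(m)
  if (n < 32) stop("need at least 32 timepoints, got ", n)
  bins <- .band_bins(n, tr_seconds, band)
  if (!length(bins))
    stop("band contains no frequency bins at N = ", n, ", TR = ", tr_seconds)
  m <- .detrend_linear(m)
  amp <- 2 * Mod(stats::mvfft(m)[bins + 1L, , drop = FALSE]) / n
  colMeans(amp)
}

# ALFF for one subject's [parcel, voxel, timepoint] array -> parcel x voxel.
.alff_subject <- function(arr, tr_seconds, band) {
  d <- dim(arr)
  v <- .alff_matrix(t(matrix(arr, d[1] * d[2], d[3])), tr_seconds, band)
  matrix(v, d[1], d[2])
}

# values: list (one element per parcel) of subject x voxel matrices.
.new_alff_maps <- function(values, band, normalize, subjects, tr_seconds) {
  normalize <- match.arg(normalize, c("raw", "zscore"))
  if (normalize == "zscore") {
    all_vox <- do.call(cbind, values)
    mu <- rowMeans(all_vox)
    sd_s <- apply(all_vox, 1, stats::sd)
    values <- lapply(values, function(v) (v - mu) / sd_s)
  }
  structure(list(values = values, band = band, normalization = normalize,
                 subjects = subjects, tr_seconds = tr_seconds,
                 n_parcels = length(values)),
            class = "alff_maps")
}

#' Voxel-wise ALFF maps for a set of subjects
#'
#' Applies \code{\link{compute_alff}} to every voxel of every subject of
#' a parcel time-series set, producing per-subject parcel-by-voxel
#' amplitude maps. Maps can optionally be z-scored per subject across
#' all voxels; the default keeps raw amplitudes. Voxel counts must agree
#' across subjects within each parcel, since downstream inter-subject
#' analyses compare patterns voxel by voxel.
#'
#' @param data a \code{\link{gen_resting_parcels}} result, a
#'   \code{\link{read_parcel_set}} result, or a NIfTI-derived set from
#'   \code{\link{parcel_set_from_nifti}}.
#' @param band frequency band in Hz, default \code{c(0.01, 0.1)}.
#' @param normalize \code{"raw"} (default) or \code{"zscore"}
#'   (per-subject, across all voxels).
#' @return An object of class \code{"alff_maps"}: \code{values} is a
#'   list with one subjects x voxels matrix per parcel, plus
#'   \code{band}, \code{normalization}, \code{subjects},
#'   \code{tr_seconds}, \code{n_parcels}.
#' @export
alff_maps <- function(data, band = c(0.01, 0.1), normalize = "raw") {
  stopifnot(is.list(data), !is.null(data$series), length(data$series) >= 1)
  ns <- length(data$series)
  subjects <- data$subjects %||% sprintf("sub%04d", seq_len(ns))
  if (isTRUE(data$ragged)) {
    np <- length(data$series[[1]])
    nv <- vapply(data$series[[1]], nrow, 0L)
    values <- lapply(seq_len(np), function(q) matrix(0, ns, nv[q]))
    for (s in seq_len(ns)) {
      sub <- data$series[[s]]
      if (length(sub) != np || !all(vapply(sub, nrow, 0L) == nv))
        stop("subjects have inconsistent parcel/voxel grids; ",
             "inter-subject analyses require aligned voxels")
      for (q in seq_len(np))
        values[[q]][s, ] <- .alff_matrix(t(sub[[q]]), data$tr_seconds, band)
    }
  } else {
    dims <- lapply(data$series, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
      stop("subjects have inconsistent parcel/voxel/timepoint grids; ",
           "inter-subject analyses require aligned voxels")
    d <- dims[[1]]
    vals <- array(0, c(ns, d[1], d[2]))
    for (s in seq_len(ns))
      vals[s, , ] <- .alff_subject(data$series[[s]], data$tr_seconds, band)
    values <- lapply(seq_len(d[1]), function(q) matrix(vals[, q, ], nrow = ns))
  }
  .new_alff_maps(values, band, normalize, subjects, data$tr_seconds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean ALFF over a region of interest
#'
#' Averages a subject's ALFF over all voxels of the selected parcels,
#' returning one scalar per subject. The mean is taken over voxels (so a
#' union of parcels is the voxel-count-weighted mean of the per-parcel
#' means) and is invariant to voxel ordering.
#'
#' @param maps an \code{\link{alff_maps}} object.
#' @param parcels integer vector of parcel indices forming the ROI.
#' @return Named numeric vector, one value per subject.
#' @export
roi_mean <- function(maps, parcels) {
  stopifnot(inherits(maps, "alff_maps"))
  if (!length(parcels)) stop("empty parcel selection")
  if (any(parcels < 1 | parcels > maps$n_parcels))
    stop("parcel indices must lie in 1..", maps$n_parcels)
  out <- rowMeans(do.call(cbind, maps$values[parcels]))
  names(out) <- maps$subjects
  out
}

#' Per-subject parcel-mean ALFF matrix
#'
#' Collapses voxel-wise maps to a subjects x parcels matrix of mean
#' amplitudes, the unit of analysis for parcel-level association tests.
#'
#' @param maps an \code{\link{alff_maps}} object.
#' @return numeric matrix \code{[subject, parcel]} with subject rownames.
#' @export
parcel_means <- function(maps) {
  stopifnot(inherits(maps, "alff_maps"))
  out <- vapply(maps$values, rowMeans, numeric(length(maps$subjects)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  rownames(out) <- maps$subjects
  out
}
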