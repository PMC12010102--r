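#' Behavioral representational dissimilarity matrix
#'
#' Builds the subject-by-subject dissimilarity matrix of item response
#' profiles using Euclidean distance across the scale's items (e.g. the
#' 10 addiction items). Subjects with missing responses are excluded
#' with a warning.
#'
#' @param items subjects x items numeric matrix or data.frame.
#' @param subjects optional subject ids; defaults to the rownames, or
#'   \code{sub0001...} when absent.
#' @return symmetric matrix of class \code{"rdm"} with zero diagonal,
#'   attribute \code{metric = "euclidean"}.
#' @export
behavioral_rdm <- function(items, subjects = NULL) {
  m <- as.matrix(items)
  if (!is.null(subjects)) {
    stopifnot(length(subjects) == nrow(m))
    rownames(m) <- subjects
  }
  if (is.null(rownames(m))) rownames(m) <- sprintf("sub%04d", seq_len(nrow(m)))
  bad <- !stats::complete.cases(m)
  if (any(bad)) {
    warning(sum(bad), " subject(s) with missing responses excluded from RDM")
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) < 3) stop("need at least 3 complete subjects")
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  .new_rdm(d, "euclidean", rownames(m))
}

#' Neural representational dissimilarity matrix for one parcel
#'
#' Dissimilarity between two subjects is \code{1 - r}, the complement of
#' the Pearson correlation between their voxel-wise ALFF patterns within
#' the parcel; entries lie in \[0, 2\] with zero diagonal.
#'
#' @param maps an \code{\link{alff_maps}} object (unsmoothed maps are
#'   the intended input).
#' @param parcel single parcel index.
#' @return matrix of class \code{"rdm"}, metric
#'   \code{"one_minus_pearson"}.
#' @export
neural_rdm <- function(maps, parcel) {
  stopifnot(inherits(maps, "alff_maps"), length(parcel) == 1)
  if (parcel < 1 || parcel > maps$n_parcels)
    stop("parcel must lie in 1..", maps$n_parcels)
  x <- maps$values[[parcel]]             # subjects x voxels
  if (ncol(x) < 3) stop("need at least 3 voxels in the parcel")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ALFF pattern for subject(s): ",
         paste(maps$subjects[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(t(x))
  diag(d) <- 0
  .new_rdm(d, "one_minus_pearson", maps$subjects)
}

.new_rdm <- function(d, metric, subjects) {
  dimnames(d) <- list(subjects, subjects)
  structure(d, metric = metric, class = c("rdm", class(d)))
}

#' Strictly-lower-triangle vectorization of an RDM
#'
#' Extracts the strictly lower triangle (diagonal excluded) in
#' column-major order — the fixed enumeration used for all RDM-to-RDM
#' correlations, so reported r values are reproducible bit for bit. The
#' result has length \code{n(n-1)/2}.
#'
#' @param m square matrix.
#' @return numeric vector.
#' @export
lower_triangle <- function(m) {
  m <- unclass(as.matrix(m))
  m[lower.tri(m)]
}

#' Inter-subject representational similarity map across parcels
#'
#' For every parcel, correlates (Pearson) the strictly-lower-triangle
#' vector of the behavioral RDM with that of the parcel's neural RDM
#' (\code{1 - r} of ALFF patterns). Raw p-values come from the usual t
#' transform with \code{n(n-1)/2} pairs; because pair distances sharing
#' a subject are dependent, this parametric p is optimistic — the
#' Bonferroni-corrected version over parcels is reported for fidelity
#' with common practice, and \code{\link{mantel_permutation}} offers a
#' calibrated alternative. Subject order must match exactly between the
#' behavioral RDM and the maps; a mismatch is a hard error, never a
#' silent reindexing.
#'
#' @param behav an \code{"rdm"} from \code{\link{behavioral_rdm}}.
#' @param maps an \code{\link{alff_maps}} object.
#' @param alpha significance level applied to corrected p-values.
#' @param parcels parcel indices to map (default all).
#' @return data.frame of class \code{"isrsa_result"}: \code{parcel, r,
#'   p_raw, p_bonferroni, significant}; correction count m = number of
#'   parcels tested.
#' @export
isrsa_map <- function(behav, maps, alpha = 0.05, parcels = NULL) {
  stopifnot(inherits(behav, "rdm"), inherits(maps, "alff_maps"))
  if (!identical(rownames(behav), maps$subjects))
    stop("subject order differs between behavioral RDM and ALFF maps; ",
         "align inputs explicitly")
  if (is.null(parcels)) parcels <- seq_len(maps$n_parcels)
  bv <- lower_triangle(behav)
  npairs <- length(bv)
  m <- length(parcels)
  r <- vapply(parcels, function(q) {
    stats::cor(bv, lower_triangle(neural_rdm(maps, q)))
  }, 0)
  tval <- r * sqrt((npairs - 2) / pmax(1 - r^2, .Machine$double.eps))
  p_raw <- 2 * stats::pt(abs(tval), df = npairs - 2, lower.tail = FALSE)
  p_bonf <- pmin(1, m * p_raw)
  structure(data.frame(parcel = parcels, r = r, p_raw = p_raw,
                       p_bonferroni = p_bonf,
                       significant = p_bonf < alpha),
            class = c("isrsa_result", "data.frame"),
            n_subjects = length(maps$subjects), n_pairs = npairs,
            alpha = alpha)
}

#' Mantel permutation test for RDM-to-RDM correlation
#'
#' Permutation inference that respects the dependence among pairwise
#' distances: subject labels of the second RDM are permuted (rows and
#' columns jointly) and the lower-triangle Pearson correlation is
#' recomputed for each permutation. The one-sided p-value is
#' \code{(1 + #\{r_perm >= r_obs\}) / (1 + n_perm)}.
#'
#' @param rdm_a,rdm_b square dissimilarity matrices with identical
#'   subject order.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer for reproducibility.
#' @return list: \code{r} observed, \code{p} permutation p-value,
#'   \code{n_perm}.
#' @export
mantel_permutation <- function(rdm_a, rdm_b, n_perm = 999, seed = NULL) {
  a <- unclass(as.matrix(rdm_a)); b <- unclass(as.matrix(rdm_b))
  stopifnot(nrow(a) == ncol(a), all(dim(a) == dim(b)))
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("subject order differs between the two RDMs")
  if (n_perm < 99) stop("need at least 99 permutations")
  n <- nrow(a)
  if (lfactorial(n) < log(n_perm))
    warning("only ", factorial(n), " distinct permutations exist for n = ",
            n, "; p-value resolution is limited")
  av <- lower_triangle(a)
  r_obs <- stats::cor(av, lower_triangle(b))
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n)
    r_perm <- stats::cor(av, lower_triangle(b[idx, idx]))
    if (r_perm >= r_obs) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}
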