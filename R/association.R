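#' Parcel-level association between ALFF and a behavioral trait
#'
#' Parcel-level stand-in for a voxel-wise group GLM: for each parcel the
#' subjects' mean ALFF is related to the trait, partialling out
#' covariates (parental education, age, gender, head motion in the
#' intended use). The statistic is the partial Pearson correlation
#' computed by residualizing both parcel ALFF and trait on the
#' covariates, which is numerically identical to the t test of the trait
#' coefficient in the regression \code{ALFF ~ trait + covariates}.
#' P-values are corrected across parcels by Bonferroni (default) or
#' Benjamini-Hochberg FDR. A covariate collinear with the trait (or with
#' other covariates) is an error, never silently dropped.
#'
#' @param maps an \code{\link{alff_maps}} object.
#' @param trait numeric vector, one behavioral score per subject.
#' @param covariates optional numeric matrix/data.frame of per-subject
#'   covariates.
#' @param correction \code{"bonferroni"} (default) or \code{"bh_fdr"}.
#' @param alpha significance level for the \code{significant} flag.
#' @return data.frame of class \code{"association_result"}:
#'   \code{parcel, beta, partial_r, t, p_raw, p_corrected, significant};
#'   \code{beta} is the trait coefficient in the ALFF regression.
#' @export
parcel_association <- function(maps, trait, covariates = NULL,
                               correction = c("bonferroni", "bh_fdr"),
                               alpha = 0.05) {
  stopifnot(inherits(maps, "alff_maps"))
  correction <- match.arg(correction)
  pm <- parcel_means(maps)
  n <- nrow(pm)
  stopifnot(length(trait) == n)
  q <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    if (anyNA(covariates) || anyNA(trait))
      stop("complete covariates and trait required (listwise-clean input)")
    q <- ncol(covariates)
    design <- cbind(1, covariates, trait)
    if (qr(design)$rank < ncol(design))
      stop("covariates are collinear with each other or with the trait")
  }
  if (n <= q + 2) stop("need n > number of covariates + 2")

  if (q > 0) {
    Z <- cbind(1, covariates)
    qz <- qr(Z)
    trait_r <- stats::residuals(stats::lm.fit(Z, trait))
    alff_r <- qr.resid(qz, pm)
  } else {
    trait_r <- trait - mean(trait)
    alff_r <- sweep(pm, 2, colMeans(pm))
  }
  sds <- apply(alff_r, 2, stats::sd)
  if (any(sds == 0)) stop("constant parcel-mean ALFF in parcel(s): ",
                          paste(which(sds == 0), collapse = ", "))
  r <- as.numeric(stats::cor(trait_r, alff_r))
  beta <- as.numeric(crossprod(alff_r, trait_r)) / sum(trait_r^2)
  df <- n - 2 - q
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p_raw <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  p_corr <- switch(correction,
                   bonferroni = stats::p.adjust(p_raw, "bonferroni"),
                   bh_fdr = stats::p.adjust(p_raw, "BH"))
  structure(data.frame(parcel = seq_len(ncol(pm)), beta = beta,
                       partial_r = r, t = tval, p_raw = p_raw,
                       p_corrected = p_corr,
                       significant = p_corr < alpha),
            class = c("association_result", "data.frame"),
            correction = correction, alpha = alpha, n = n, df = df)
}

#' Correlation between a region-of-interest summary and a trait
#'
#' Pearson correlation (with two-sided p) between per-subject ROI values
#' (e.g. \code{\link{roi_mean}} output) and a behavioral score. When
#' covariates are supplied, the covariate-adjusted (partial) correlation
#' is reported alongside the raw one.
#'
#' @param roi numeric vector of per-subject ROI summaries.
#' @param trait numeric vector of behavioral scores.
#' @param covariates optional numeric matrix/data.frame.
#' @return list: \code{r}, \code{p}, \code{n}, and if covariates were
#'   given \code{r_adjusted}, \code{p_adjusted}.
#' @export
roi_correlation <- function(roi, trait, covariates = NULL) {
  stopifnot(length(roi) == length(trait))
  ok <- stats::complete.cases(if (is.null(covariates)) cbind(roi, trait)
                              else cbind(roi, trait, as.matrix(covariates)))
  roi <- roi[ok]; trait <- trait[ok]
  n <- length(roi)
  if (n < 3) stop("need at least 3 subjects")
  if (stats::sd(roi) == 0 || stats::sd(trait) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(roi, trait)
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = n)
  if (!is.null(covariates)) {
    Z <- cbind(1, as.matrix(covariates)[ok, , drop = FALSE])
    q <- ncol(Z) - 1
    rr <- stats::residuals(stats::lm.fit(Z, roi))
    tr <- stats::residuals(stats::lm.fit(Z, trait))
    r_adj <- stats::cor(rr, tr)
    df <- n - 2 - q
    tv <- r_adj * sqrt(df / max(1 - r_adj^2, .Machine$double.eps))
    out$r_adjusted <- r_adj
    out$p_adjusted <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
  }
  out
}
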