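#' Define a Likert scale and its subscales
#'
#' A scale definition names the item columns, the admissible response
#' range, an optional partition of items into subscales (e.g. bullying
#' victimization into verbal, physical and relational subdimensions), and
#' optional gender-specific cutoff scores used for classification.
#'
#' @param name scale label used for the total-score column.
#' @param items character vector of item column names (unique).
#' @param range length-2 integer, admissible responses (default 1..6).
#' @param subscales optional named list of item-name vectors; every
#'   subscale item must belong to \code{items}.
#' @param cutoffs optional named numeric, e.g. \code{c(F = 33, M = 31)}.
#' @return list of class \code{"scale_definition"}.
#' @export
scale_definition <- function(name, items, range = c(1L, 6L),
                             subscales = NULL, cutoffs = NULL) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(items), length(items) >= 1,
            length(range) == 2, range[1] < range[2])
  if (anyDuplicated(items)) stop("duplicate item ids in scale '", name, "'")
  if (!is.null(subscales)) {
    stopifnot(is.list(subscales), !is.null(names(subscales)))
    bad <- setdiff(unlist(subscales), items)
    if (length(bad))
      stop("subscale items not in parent scale '", name, "': ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(cutoffs) && is.null(names(cutoffs)))
    stop("cutoffs must be named by gender code")
  structure(list(name = name, items = items, range = range,
                 subscales = subscales, cutoffs = cutoffs),
            class = "scale_definition")
}

#' Default study scale definitions
#'
#' The instrument battery used throughout the package: a 10-item
#' short-video addiction scale (6-point, gender-specific cutoffs 33 for
#' females and 31 for males), a bullying-victimization scale with verbal,
#' physical and relational subdimensions (cyberbullying excluded;
#' configurable item counts, default 4 each), and 10-item negative and
#' positive affect scales. Item names follow the generator convention
#' \code{<scale>_item##}.
#'
#' @param n_sva,n_na,n_pa item counts of the addiction and affect scales.
#' @param n_sub named item counts of the bullying subdimensions.
#' @return named list of \code{\link{scale_definition}} objects
#'   (\code{sva, bv, na, pa}).
#' @export
default_scales <- function(n_sva = 10, n_na = 10, n_pa = 10,
                           n_sub = c(vb = 4, pb = 4, rb = 4)) {
  nm <- function(prefix, k) sprintf("%s_item%02d", prefix, seq_len(k))
  sub_items <- lapply(names(n_sub), function(s) nm(s, n_sub[[s]]))
  names(sub_items) <- names(n_sub)
  list(
    sva = scale_definition("sva", nm("sva", n_sva),
                           cutoffs = c(F = 33, M = 31)),
    bv = scale_definition("bv", unlist(sub_items), subscales = sub_items),
    na = scale_definition("na", nm("na", n_na)),
    pa = scale_definition("pa", nm("pa", n_pa)))
}

#' Sum-score one scale (and its subscales) for a cohort
#'
#' Totals are plain sums of item responses; subscale totals are sums over
#' the subscale's items, so the parent total equals the sum of subscale
#' totals. Subjects missing any item of the scale are flagged and receive
#' \code{NA} totals (listwise within the scale).
#'
#' @param items data.frame containing the scale's item columns (plus
#'   anything else, ignored).
#' @param def a \code{\link{scale_definition}}.
#' @return data.frame of totals (one column per scale/subscale), with
#'   attribute \code{"incomplete"} holding the row indices that were
#'   flagged.
#' @export
score_scale <- function(items, def) {
  stopifnot(inherits(def, "scale_definition"))
  missing_cols <- setdiff(def$items, names(items))
  if (length(missing_cols))
    stop("unknown item id(s) for scale '", def$name, "': ",
         paste(missing_cols, collapse = ", "))
  m <- as.matrix(items[, def$items, drop = FALSE])
  if (any(m < def$range[1] | m > def$range[2], na.rm = TRUE))
    stop("responses outside declared range [", def$range[1], ", ",
         def$range[2], "] in scale '", def$name, "'")
  incomplete <- which(rowSums(is.na(m)) > 0)
  total <- rowSums(m)
  out <- data.frame(total)
  names(out) <- def$name
  for (s in names(def$subscales))
    out[[s]] <- rowSums(m[, def$subscales[[s]], drop = FALSE])
  attr(out, "incomplete") <- incomplete
  out
}

#' Classify addiction risk by gender-specific cutoff
#'
#' A subject is classified as addicted when the scale total reaches the
#' cutoff for their gender (inclusive: score >= cutoff), the convention
#' of the source instrument. Defaults: 33 for females, 31 for males.
#'
#' @param score numeric vector of scale totals.
#' @param gender character vector of gender codes matching the cutoff
#'   names (\code{"F"}/\code{"M"} by default).
#' @param cutoffs named numeric cutoffs per gender.
#' @return character vector, \code{"addicted"} / \code{"nonaddicted"}
#'   (\code{NA} score gives \code{NA}).
#' @examples
#' classify_addiction(c(33, 31, 31), c("F", "M", "F"))
#' @export
classify_addiction <- function(score, gender, cutoffs = c(F = 33, M = 31)) {
  if (length(gender) == 1) gender <- rep(gender, length(score))
  stopifnot(length(score) == length(gender))
  if (anyNA(gender) || !all(gender %in% names(cutoffs)))
    stop("gender must be one of: ", paste(names(cutoffs), collapse = ", "))
  unname(ifelse(score >= cutoffs[gender], "addicted", "nonaddicted"))
}

#' Score a full cohort against the study battery
#'
#' Applies \code{\link{score_scale}} for every definition, carries the
#' demographic columns through, and classifies addiction from the
#' addiction-scale total and gender. Subjects missing items on a scale
#' get \code{NA} on that scale's totals.
#'
#' @param items cohort data.frame (demographics + item columns), e.g.
#'   \code{gen_questionnaire_cohort(...)$items}.
#' @param defs list of scale definitions, default \code{\link{default_scales}()}.
#' @param demographics columns copied through if present.
#' @return data.frame of class \code{"scored_cohort"}: demographics,
#'   one column per scale/subscale total, and \code{addiction_class}.
#' @export
score_cohort <- function(items, defs = default_scales(),
                         demographics = c("id", "age", "gender", "group",
                                          "mother_edu", "father_edu", "fd")) {
  if ("id" %in% names(items) && anyDuplicated(items$id))
    stop("duplicate subject ids")
  keep <- intersect(demographics, names(items))
  out <- items[, keep, drop = FALSE]
  flagged <- integer(0)
  for (def in defs) {
    sc <- score_scale(items, def)
    flagged <- union(flagged, attr(sc, "incomplete"))
    for (col in names(sc)) out[[col]] <- sc[[col]]
    if (length(attr(sc, "incomplete")))
      out[attr(sc, "incomplete"), names(sc)] <- NA
  }
  if (!is.null(defs$sva$cutoffs) && "gender" %in% names(out))
    out$addiction_class <- classify_addiction(out$sva, out$gender,
                                              defs$sva$cutoffs)
  attr(out, "incomplete") <- flagged
  class(out) <- c("scored_cohort", class(out))
  out
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' \code{alpha = k/(k-1) * (1 - sum of item variances / variance of the
#' total)}, with sample variances (n-1 denominator). Rows with any
#' missing item are dropped listwise.
#'
#' @param items matrix or data.frame, columns = items of one scale.
#' @return alpha (unitless; 1 for perfectly parallel items).
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2) stop("need at least 2 items")
  if (nrow(m) < 3) stop("need at least 3 complete cases")
  vt <- stats::var(rowSums(m))
  if (vt == 0) stop("zero total-score variance: alpha undefined")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
}

#' Harman's single-factor test for common method bias
#'
#' Performs an unrotated principal-component extraction over all items
#' (eigendecomposition of the item correlation matrix on complete cases)
#' and reports the number of factors with eigenvalue above 1 and the
#' percentage of total variance carried by the first factor,
#' \code{100 * lambda_1 / p}. Common-method bias is conventionally
#' flagged when the first factor exceeds 40\%.
#'
#' @param items matrix or data.frame of all study items.
#' @param threshold_pct flag threshold, default 40.
#' @return list: \code{n_factors} (eigenvalues > 1),
#'   \code{first_factor_pct}, \code{bias_flagged}, \code{eigenvalues}.
#' @export
harman_single_factor <- function(items, threshold_pct = 40) {
  m <- as.matrix(items)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) <= ncol(m))
    stop("need more complete cases than items")
  r <- stats::cor(m)
  if (anyNA(r)) stop("correlation matrix undefined (constant item?)")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("singular item correlation matrix")
  pct <- 100 * ev[1] / ncol(m)
  list(n_factors = sum(ev > 1), first_factor_pct = pct,
       bias_flagged = pct > threshold_pct, eigenvalues = ev)
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations among the selected variables on
#' listwise-complete rows, with two-sided p-values from the t transform
#' \code{t = r * sqrt((n-2)/(1-r^2))}.
#'
#' @param data data.frame (e.g. a scored cohort).
#' @param vars character vector of numeric column names.
#' @return list of class \code{"corr_table"}: \code{r}, \code{p}
#'   matrices and \code{n} complete cases.
#' @export
pearson_corr_matrix <- function(data, vars) {
  stopifnot(all(vars %in% names(data)))
  m <- as.matrix(data[, vars, drop = FALSE])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3) stop("need at least 3 complete cases")
  if (any(apply(m, 2, stats::sd) == 0))
    stop("constant variable: correlation undefined")
  r <- stats::cor(m)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  structure(list(r = r, p = p, n = n), class = "corr_table")
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's t test with pooled variance computed from group means,
#' standard deviations and sizes (the form recoverable from published
#' summary tables), with \code{df = n1 + n2 - 2} and a two-sided p-value.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return list: \code{t}, \code{df}, \code{p}.
#' @examples
#' pooled_t_test(25.35, 12.15, 1269, 18.21, 7.87, 1615)
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) stop("zero pooled variance: t undefined")
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Pearson chi-square test on a 2 x 2 contingency table
#'
#' Pearson's chi-square without continuity correction (df = 1), the form
#' that reproduces published group-by-gender comparisons exactly.
#' Invariant to row and column swaps.
#'
#' @param counts 2 x 2 matrix of non-negative counts.
#' @return list: \code{chi2}, \code{df}, \code{p}.
#' @examples
#' chi_square_2x2(matrix(c(620, 558, 649, 1057), 2))
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal: chi-square undefined")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop("non-positive expected count")
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
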