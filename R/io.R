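#' Read and write questionnaire and result tables
#'
#' All tabular artifacts are plain tab-delimited text with a header row;
#' writer functions optionally embed provenance comment lines (prefixed
#' \code{#}) that readers skip.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @param meta optional named character vector written as \code{# key: value}
#'   header lines.
#' @return \code{read_table_tsv} returns a data.frame;
#'   writers return \code{path} invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_table_tsv <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a questionnaire cohort
#'
#' One row per subject: id, demographics, covariates and item columns
#' named \code{<scale>_item##}.
#'
#' @param cohort an \code{"sva_cohort"} (or its \code{items} data.frame).
#' @param path file path for the delimited table.
#' @param meta optional provenance header entries.
#' @return the path (writer) / data.frame (reader), invisibly for the
#'   writer.
#' @export
write_questionnaire <- function(cohort, path, meta = NULL) {
  items <- if (inherits(cohort, "sva_cohort")) cohort$items else cohort
  write_table_tsv(items, path, meta)
}

#' @rdname write_questionnaire
#' @export
read_questionnaire <- function(path) read_table_tsv(path)

#' Write a truth record as key-value text
#'
#' Flattens a (possibly nested) list of scalar generator settings into
#' \code{key = value} lines so planted parameters travel with the data.
#'
#' @param truth named list.
#' @param path file path.
#' @export
write_truth_record <- function(truth, path) {
  flat <- unlist(truth)
  writeLines(sprintf("%s = %s", names(flat), as.character(flat)), path)
  invisible(path)
}

#' Write / read a parcel time-series set as delimited files
#'
#' Stores one tab-delimited matrix per subject (rows = parcel-voxel
#' series in parcel-major order, columns = timepoints) under a
#' directory, plus a \code{manifest.tsv} mapping subject id to file and
#' grid dimensions (\code{n_parcels, n_voxels, n_timepoints, tr}).
#'
#' @param data a \code{"parcel_ts_set"}.
#' @param dir output directory (created if needed).
#' @return the directory (writer) / a \code{"parcel_ts_set"} (reader).
#' @export
write_parcel_set <- function(data, dir) {
  stopifnot(inherits(data, "parcel_ts_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(data$series[[1]])
  files <- sprintf("%s_timeseries.tsv", data$subjects)
  for (s in seq_along(data$series)) {
    m <- matrix(data$series[[s]], d[1] * d[2], d[3])
    utils::write.table(format(m, digits = 10, trim = TRUE),
                       file.path(dir, files[s]),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(subject = data$subjects, file = files,
                         n_parcels = d[1], n_voxels = d[2],
                         n_timepoints = d[3], tr = data$tr_seconds)
  write_table_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname write_parcel_set
#' @export
read_parcel_set <- function(dir) {
  manifest <- read_table_tsv(file.path(dir, "manifest.tsv"))
  series <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- as.matrix(utils::read.table(file.path(dir, manifest$file[i]),
                                     sep = "\t"))
    array(m, c(manifest$n_parcels[i], manifest$n_voxels[i],
               manifest$n_timepoints[i]))
  })
  structure(list(series = series, subjects = manifest$subject,
                 tr_seconds = manifest$tr[1], truth = NULL),
            class = "parcel_ts_set")
}

#' Build a parcel time-series set from NIfTI volumes
#'
#' Converts per-subject 4D BOLD NIfTI volumes plus an integer-label
#' parcellation NIfTI on the same grid (label 0 = background) into a
#' parcel time-series set. Because inter-subject pattern analyses need
#' voxel correspondence, every parcel keeps its voxels in the same
#' (label-mask) order for all subjects. Requires the \pkg{RNifti}
#' package.
#'
#' @param bold_files character vector of 4D NIfTI paths, one per subject.
#' @param label_file parcellation NIfTI path (integer labels).
#' @param tr_seconds repetition time; taken from the first header when
#'   \code{NULL}.
#' @param subjects optional subject ids (default file base names).
#' @return a \code{"parcel_ts_set"}. Parcels are ordered by ascending
#'   label; voxel counts differ across parcels, so the per-subject
#'   element is a list of voxel x timepoint matrices rather than a
#'   single array.
#' @export
parcel_set_from_nifti <- function(bold_files, label_file,
                                  tr_seconds = NULL, subjects = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("parcel_set_from_nifti requires the RNifti package")
  labels <- round(as.array(RNifti::readNifti(label_file)))
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) stop("parcellation contains no nonzero labels")
  masks <- lapply(ids, function(l) which(labels == l))
  if (is.null(subjects))
    subjects <- sub("\\.nii(\\.gz)?$", "", basename(bold_files))
  series <- lapply(seq_along(bold_files), function(i) {
    img <- RNifti::readNifti(bold_files[i])
    arr <- as.array(img)
    if (length(dim(arr)) != 4) stop("expected 4D volume: ", bold_files[i])
    if (!all(dim(arr)[1:3] == dim(labels)))
      stop("grid mismatch between BOLD and parcellation: ", bold_files[i])
    nt <- dim(arr)[4]
    flat <- matrix(arr, ncol = nt)
    if (i == 1 && is.null(tr_seconds)) {
      pd <- attr(img, "pixdim")
      tr_seconds <<- if (!is.null(pd) && length(pd) >= 4) pd[4] else
        stop("tr_seconds not supplied and absent from the NIfTI header")
    }
    lapply(masks, function(mk) flat[mk, , drop = FALSE])
  })
  structure(list(series = series, subjects = subjects,
                 tr_seconds = tr_seconds, parcel_labels = ids,
                 truth = NULL, ragged = TRUE),
            class = "parcel_ts_set")
}
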