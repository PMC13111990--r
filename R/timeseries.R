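#' ROI time-series matrix
#'
#' Container for one subject's parcellated BOLD signal: a T x R numeric matrix
#' with unique ROI labels, the repetition time in seconds, and a subject id.
#'
#' @param values T x R numeric matrix (timepoints x regions).
#' @param roi_labels character vector of R unique region labels; defaults to
#'   the matrix column names.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param subject_id subject identifier.
#' @return an object of class `roi_ts`.
#' @export
roi_ts <- function(values, roi_labels = colnames(values), tr_seconds = 2,
                   subject_id = "subject") {
  values <- as.matrix(values)
  .assert(is.numeric(values) && !anyNA(values) && all(is.finite(values)),
          "`values` must be a finite numeric matrix with no missing entries")
  .assert(nrow(values) >= 2, "need at least 2 timepoints")
  .assert(ncol(values) >= 1, "need at least 1 ROI")
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI_%03d", seq_len(ncol(values)))
  roi_labels <- as.character(roi_labels)
  .assert(length(roi_labels) == ncol(values), "one label per column required")
  .assert(!anyDuplicated(roi_labels), "ROI labels must be unique")
  tr_seconds <- .check_positive(tr_seconds, "tr_seconds")
  colnames(values) <- roi_labels
  structure(list(values = values, roi_labels = roi_labels,
                 tr_seconds = tr_seconds, subject_id = subject_id),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("ROI time series '%s': %d timepoints x %d ROIs, TR = %gs\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

# coerce RNifti image / array input to a plain array
.as_volume <- function(x) {
  if (is.character(x)) x <- RNifti::readNifti(x)
  a <- as.array(x)
  storage.mode(a) <- if (all(a == round(a))) storage.mode(a) else "double"
  a
}

#' Merge subcortical and cortical label volumes into one parcellation
#'
#' Keeps subcortical labels as-is and offsets cortical labels by
#' `offset` (label c becomes `offset + c`). Voxels labelled in both volumes
#' take the subcortical label: the subcortical atlas is the finer,
#' anatomically specific parcellation, so it wins on overlap. With the default
#' 54-region subcortical atlas and 17-network cortical atlas this yields up to
#' 71 distinct ROI labels.
#'
#' @param subcortical integer-labelled 3D volume (array, NIfTI image or path);
#'   0 is background.
#' @param cortical integer-labelled 3D volume on the same grid.
#' @param offset added to nonzero cortical labels; defaults to the maximum
#'   subcortical label (54 for the default atlas).
#' @return list with `volume` (merged integer 3D array) and `n_rois`
#'   (count of distinct nonzero labels).
#' @export
merge_atlases <- function(subcortical, cortical, offset = NULL) {
  sub <- .as_volume(subcortical)
  cor <- .as_volume(cortical)
  if (!identical(dim(sub), dim(cor))) {
    stop(errorCondition("atlas grids do not match",
                        class = c("boldhmm_shape_error", "boldhmm_error")))
  }
  if (is.null(offset)) offset <- max(sub)
  merged <- sub
  take_cortical <- sub == 0 & cor > 0
  merged[take_cortical] <- cor[take_cortical] + offset
  labs <- sort(unique(as.vector(merged)))
  labs <- labs[labs != 0]
  list(volume = merged, n_rois = length(labs))
}

#' Extract mean ROI time courses from a 4D BOLD volume
#'
#' Column j at time t is the arithmetic mean of the voxel values carrying
#' label j at volume t. Columns are ordered by ascending label. Labels in
#' `expected_labels` with no voxels in the atlas are dropped with a warning.
#'
#' @param bold 4D array (x, y, z, t), NIfTI image or path.
#' @param atlas integer-labelled 3D volume on the same spatial grid (or the
#'   list returned by [merge_atlases()]).
#' @param tr_seconds repetition time in seconds.
#' @param subject_id subject identifier.
#' @param expected_labels labels the parcellation is supposed to contain;
#'   defaults to `1:max(atlas)`.
#' @return a [roi_ts()] with labels `"roi_<label>"`.
#' @export
extract_roi_series <- function(bold, atlas, tr_seconds = 2,
                               subject_id = "subject",
                               expected_labels = NULL) {
  if (is.list(atlas) && !is.null(atlas$volume)) atlas <- atlas$volume
  bold <- .as_volume(bold)
  atlas <- .as_volume(atlas)
  .assert(length(dim(bold)) == 4L, "`bold` must be a 4D volume")
  if (!identical(dim(bold)[1:3], dim(atlas))) {
    stop(errorCondition("BOLD and atlas spatial grids do not match",
                        class = c("boldhmm_shape_error", "boldhmm_error")))
  }
  lab_vec <- as.integer(as.vector(atlas))
  if (all(lab_vec <= 0)) {
    stop(errorCondition("atlas contains no nonzero labels",
                        class = c("boldhmm_empty_atlas", "boldhmm_error")))
  }
  if (is.null(expected_labels)) expected_labels <- seq_len(max(lab_vec))
  present <- sort(unique(lab_vec[lab_vec > 0]))
  missing <- setdiff(expected_labels, present)
  if (length(missing)) {
    warning(sprintf("dropping %d atlas label(s) with no voxels: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }

  Tn <- dim(bold)[4]
  vox <- matrix(bold, ncol = Tn)        # voxels x time
  keep <- lab_vec > 0
  sums <- rowsum(vox[keep, , drop = FALSE], group = lab_vec[keep])
  counts <- as.vector(table(lab_vec[keep]))
  values <- t(sums / counts)            # time x ROI, ascending label
  roi_ts(values, roi_labels = sprintf("roi_%d", present),
         tr_seconds = tr_seconds, subject_id = subject_id)
}

#' Mean signal over all atlas-labelled voxels
#'
#' The global nuisance signal: per timepoint, the mean BOLD value across every
#' voxel with a nonzero atlas label.
#'
#' @inheritParams extract_roi_series
#' @return length-T numeric vector.
#' @export
global_signal <- function(bold, atlas) {
  if (is.list(atlas) && !is.null(atlas$volume)) atlas <- atlas$volume
  bold <- .as_volume(bold)
  atlas <- .as_volume(atlas)
  if (!identical(dim(bold)[1:3], dim(atlas))) {
    stop(errorCondition("BOLD and atlas spatial grids do not match",
                        class = c("boldhmm_shape_error", "boldhmm_error")))
  }
  keep <- as.vector(atlas) > 0
  .assert(any(keep), "atlas contains no nonzero labels",
          class = "boldhmm_empty_atlas")
  colMeans(matrix(bold, ncol = dim(bold)[4])[keep, , drop = FALSE])
}

#' Drop initial volumes for signal stabilization
#'
#' Removes the first `n_drop` timepoints (e.g. 240 acquired volumes minus the
#' first 10 gives the 230 analysed timepoints).
#'
#' @param series a [roi_ts()].
#' @param n_drop number of leading timepoints to remove (`0 <= n_drop < T`).
#' @return the truncated [roi_ts()].
#' @export
truncate_volumes <- function(series, n_drop = 10L) {
  .assert(inherits(series, "roi_ts"), "`series` must be a roi_ts")
  n_drop <- .check_count(n_drop, "n_drop", min = 0L)
  Tn <- nrow(series$values)
  if (n_drop >= Tn) {
    stop(errorCondition(sprintf("n_drop (%d) must be < T (%d)", n_drop, Tn),
                        class = c("boldhmm_range_error", "boldhmm_error")))
  }
  if (n_drop == 0L) return(series)
  roi_ts(series$values[(n_drop + 1):Tn, , drop = FALSE],
         series$roi_labels, series$tr_seconds, series$subject_id)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`, zero phase) independently to each column. Columns are
#' demeaned before filtering and any residual mean (finite-length edge
#' effects) is removed afterwards, so output columns are mean-zero.
#'
#' @param series a [roi_ts()].
#' @param low_hz,high_hz passband edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_seconds)` (the Nyquist frequency).
#' @param order filter order (default 4).
#' @return the filtered [roi_ts()].
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1, order = 4L) {
  .assert(inherits(series, "roi_ts"), "`series` must be a roi_ts")
  nyquist <- 1 / (2 * series$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist)) {
    stop(errorCondition(
      sprintf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz",
              low_hz, high_hz, nyquist),
      class = c("boldhmm_band_error", "boldhmm_error")))
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  filtered <- apply(series$values, 2, function(x) {
    y <- signal::filtfilt(bf, x - mean(x))
    y - mean(y)
  })
  roi_ts(filtered, series$roi_labels, series$tr_seconds, series$subject_id)
}

#' Regress nuisance signals out of every ROI column
#'
#' Returns per-column residuals of the least-squares projection onto an
#' intercept plus the nuisance columns (typically 6 motion parameters and the
#' global signal). Collinear nuisance columns are dropped with a warning
#' rather than failing. Residuals are orthogonal to every retained regressor.
#'
#' @param series a [roi_ts()].
#' @param nuisance T x p numeric matrix, or a list with elements `motion`
#'   (T x 6) and `global_signal` (length T), either optional.
#' @return the residual [roi_ts()]; attribute `"regressors_used"` records the
#'   retained design columns.
#' @export
regress_nuisance <- function(series, nuisance) {
  .assert(inherits(series, "roi_ts"), "`series` must be a roi_ts")
  X <- .as_nuisance_matrix(nuisance)
  Tn <- nrow(series$values)
  .assert(nrow(X) == Tn,
          sprintf("nuisance rows (%d) must equal timepoints (%d)",
                  nrow(X), Tn))
  design <- cbind(intercept = 1, X)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop_idx <- qrd$pivot[(qrd$rank + 1):ncol(design)]
    warning(sprintf("dropping %d collinear nuisance column(s): %s",
                    length(drop_idx),
                    paste(colnames(design)[drop_idx], collapse = ", ")))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  resid <- qr.resid(qrd, series$values)
  out <- roi_ts(resid, series$roi_labels, series$tr_seconds, series$subject_id)
  attr(out, "regressors_used") <- colnames(design)
  out
}

.as_nuisance_matrix <- function(nuisance) {
  if (is.list(nuisance) && !is.matrix(nuisance)) {
    parts <- list()
    if (!is.null(nuisance$motion)) {
      m <- as.matrix(nuisance$motion)
      colnames(m) <- sprintf("motion_%d", seq_len(ncol(m)))
      parts <- c(parts, list(m))
    }
    if (!is.null(nuisance$global_signal)) {
      parts <- c(parts, list(matrix(nuisance$global_signal,
                                    ncol = 1,
                                    dimnames = list(NULL, "global_signal"))))
    }
    .assert(length(parts) > 0, "empty nuisance set")
    X <- do.call(cbind, parts)
  } else {
    X <- as.matrix(nuisance)
    if (is.null(colnames(X))) colnames(X) <- sprintf("nuis_%d", seq_len(ncol(X)))
  }
  .assert(is.numeric(X) && !anyNA(X), "nuisance regressors must be numeric")
  X
}

#' Standardize each ROI column to mean 0 and unit standard deviation
#'
#' Uses the sample standard deviation (denominator n - 1), the single
#' convention used throughout the package.
#'
#' @param series a [roi_ts()].
#' @return the standardized [roi_ts()].
#' @export
standardize <- function(series) {
  .assert(inherits(series, "roi_ts"), "`series` must be a roi_ts")
  sds <- apply(series$values, 2, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    stop(errorCondition(
      sprintf("constant (zero-variance) ROI column(s): %s",
              paste(series$roi_labels[zero], collapse = ", ")),
      class = c("boldhmm_constant_column", "boldhmm_error")))
  }
  z <- scale(series$values, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  roi_ts(z, series$roi_labels, series$tr_seconds, series$subject_id)
}

#' Full preprocessing chain for one subject
#'
#' Applies, in this fixed order: truncation of initial volumes, zero-phase
#' band-pass filtering, nuisance regression, and column standardization.
#' Nuisance regressors (supplied at full acquisition length) are truncated and
#' band-passed with the same filter before regression, so the regression
#' cannot reintroduce stop-band energy.
#'
#' @param series a [roi_ts()] at acquisition length.
#' @param nuisance optional nuisance input as in [regress_nuisance()], with
#'   rows matching the *untruncated* series.
#' @param n_drop initial volumes to drop (default 10).
#' @param band passband in Hz (default `c(0.01, 0.1)`).
#' @return the preprocessed [roi_ts()]; attribute `"preprocess_log"` records
#'   each step applied.
#' @export
preprocess_series <- function(series, nuisance = NULL, n_drop = 10L,
                              band = c(0.01, 0.1)) {
  log <- character(0)
  out <- truncate_volumes(series, n_drop)
  log <- c(log, sprintf("truncate: dropped %d initial volumes", n_drop))
  out <- bandpass(out, band[1], band[2])
  log <- c(log, sprintf("bandpass: %g-%g Hz zero-phase Butterworth order 4",
                        band[1], band[2]))
  if (!is.null(nuisance)) {
    X <- .as_nuisance_matrix(nuisance)
    .assert(nrow(X) == nrow(series$values),
            "nuisance rows must match the untruncated series")
    X <- X[(n_drop + 1):nrow(X), , drop = FALSE]
    Xf <- bandpass(roi_ts(X, tr_seconds = series$tr_seconds),
                   band[1], band[2])
    out <- regress_nuisance(out, Xf$values)
    log <- c(log, sprintf("regress: %d nuisance regressors (band-passed first)",
                          ncol(X)))
  }
  out <- standardize(out)
  log <- c(log, "standardize: per-column mean 0, sd 1 (n-1 denominator)")
  attr(out, "preprocess_log") <- log
  out
}

#' Write an ROI matrix as a full-precision TSV
#'
#' Header row holds the ROI labels; values are written with 17 significant
#' digits so a write/read round trip is lossless.
#'
#' @param x a [roi_ts()] or T x R matrix with column names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi_tsv <- function(x, path) {
  m <- if (inherits(x, "roi_ts")) x$values else as.matrix(x)
  .assert(!is.null(colnames(m)), "matrix must carry ROI labels as column names")
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(paste(colnames(m), collapse = "\t"), txt), path)
  invisible(path)
}

#' Read an ROI matrix written by [write_roi_tsv()]
#'
#' @param path TSV file with a header row of ROI labels.
#' @param as_roi_ts if `TRUE`, wrap the matrix in a [roi_ts()].
#' @param tr_seconds,subject_id metadata used when `as_roi_ts = TRUE`.
#' @return a numeric matrix with column names, or a [roi_ts()].
#' @export
read_roi_tsv <- function(path, as_roi_ts = FALSE, tr_seconds = 2,
                         subject_id = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df)
  if (as_roi_ts) {
    roi_ts(m, tr_seconds = tr_seconds,
           subject_id = subject_id %||% sub("\\.tsv$", "", basename(path)))
  } else {
    m
  }
}

#' Read a 6-column motion-parameter text file
#'
#' Whitespace-delimited realignment parameters (3 translations, 3 rotations)
#' in the SPM `rp_*.txt` dialect.
#'
#' @param path text file with 6 numeric columns and no header.
#' @return T x 6 numeric matrix with columns `trans_x..z`, `rot_x..z`.
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  .assert(ncol(m) == 6, "motion file must have exactly 6 columns")
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}
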