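#' TaqMan array CT preprocessing
#'
#' Raw TaqMan low-density-array data arrive as a miRNA x sample matrix of
#' threshold-cycle (CT) values in which failed/undetected wells are flagged
#' (here, `NA`). Preprocessing follows the standard ddCT workflow:
#' censoring, normalization against the U6 small nuclear RNA carried on every
#' card, and a detection filter on the normalized values. Higher CT (and
#' higher dCT) means lower expression.
#'
#' @name qpcr
NULL

#' Censor CT values at the detection limit
#'
#' Every undetected well (`NA`) and every CT above `max_ct` cycles is set to
#' exactly `max_ct`; all other entries are unchanged. The operation is
#' idempotent.
#'
#' @param ct Numeric miRNA x sample matrix of raw CT values; `NA` marks an
#'   undetected well.
#' @param max_ct Detection limit in cycles (default 35).
#' @return Matrix of the same shape with all values in `(0, max_ct]`.
#' @export
censor_ct <- function(ct, max_ct = 35) {
  stopifnot(is.matrix(ct), is.numeric(ct))
  if (any(ct <= 0, na.rm = TRUE)) {
    stop("CT values must be positive; found value(s) <= 0")
  }
  ct[is.na(ct) | ct > max_ct] <- max_ct
  ct
}

#' Normalize CT against the U6 internal control
#'
#' Computes per-sample dCT = CT(miRNA, sample) - CT(control, sample). The
#' control row is dropped from the output.
#'
#' @param ct Censored CT matrix (rownames are miRNA ids, one of which is the
#'   control).
#' @param control_id Row id of the internal control (default `"U6"`).
#' @return dCT matrix without the control row.
#' @export
normalize_delta_ct <- function(ct, control_id = "U6") {
  stopifnot(is.matrix(ct), !is.null(rownames(ct)))
  if (!control_id %in% rownames(ct)) {
    stop("control row '", control_id, "' not found in CT matrix")
  }
  ctrl <- ct[control_id, ]
  bad <- is.na(ctrl)
  if (any(bad)) {
    stop("control '", control_id, "' is missing in sample(s): ",
         paste(colnames(ct)[bad], collapse = ", "))
  }
  dct <- sweep(ct[setdiff(rownames(ct), control_id), , drop = FALSE], 2, ctrl)
  dct
}

#' Detection filter on normalized CT
#'
#' Retains the miRNAs whose minimum dCT across samples is strictly below
#' `cutoff` (the "Min < 10" rule): a miRNA counts as detected if it is well
#' expressed relative to U6 in at least one sample. Optionally the minimum
#' can be taken within each group, requiring at least one group to pass.
#'
#' @param dct dCT matrix.
#' @param cutoff Detection cutoff in dCT cycles (default 10, strict `<`).
#' @param groups Optional sample -> group labels (aligned with columns). When
#'   given, a miRNA is retained if its within-group minimum passes in any
#'   group; with the default `NULL` the minimum is over all samples. The two
#'   readings coincide, and are kept both available because the choice is a
#'   convention, not a result.
#' @return Filtered dCT matrix; the number of retained miRNAs is attached as
#'   attribute `"n_detected"`.
#' @export
detection_filter <- function(dct, cutoff = 10, groups = NULL) {
  stopifnot(is.matrix(dct))
  if (is.null(groups)) {
    keep <- apply(dct, 1, min) < cutoff
  } else {
    stopifnot(length(groups) == ncol(dct))
    keep <- apply(dct, 1, function(v) {
      any(tapply(v, groups, min) < cutoff)
    })
  }
  out <- dct[keep, , drop = FALSE]
  attr(out, "n_detected") <- sum(keep)
  out
}

#' Per-cell miRNA copy number from raw CT
#'
#' Copies per cell are estimated from the calibration
#' `10^((40 - CT) / 3.34) / 22`, obtained from a synthetic miRNA dilution
#' series under the assumption of 30 pg total RNA per cell. One PCR cycle
#' corresponds to a factor ~2 in template, hence 3.34 cycles per decade.
#' Applied to censored raw CT, not dCT: the calibration is against absolute
#' template amounts.
#'
#' @param ct Raw (censored) CT value(s), cycles, in `(0, 40]`.
#' @return Estimated copies per cell, same length as `ct`; strictly
#'   decreasing in `ct`.
#' @export
copy_number <- function(ct) {
  if (any(ct <= 0, na.rm = TRUE)) {
    stop("CT must be positive")
  }
  10^((40 - ct) / 3.34) / 22
}
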