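#' Bundle the six weighted volumes of one ihMT scan
#'
#' One scan acquires five saturation-weighted volumes (no saturation, the two
#' single-sided offsets and the two alternating dual-sided schemes) plus a
#' T1-prepared volume. All six must share one grid and affine: motion
#' correction between volumes is assumed to have been applied upstream, and
#' the constructor refuses mismatched grids rather than resampling.
#'
#' @param S0 unsaturated reference volume.
#' @param Splus,Sminus single-sided saturation at positive / negative offset.
#' @param Spm,Smp dual-sided alternating saturation starting positive / negative.
#' @param ST1 T1-prepared volume.
#' @return An object of class \code{weighted_volume_set}.
#' @export
weighted_volume_set <- function(S0, Splus, Sminus, Spm, Smp, ST1) {
  vols <- list(S0 = S0, Splus = Splus, Sminus = Sminus,
               Spm = Spm, Smp = Smp, ST1 = ST1)
  for (nm in names(vols)) {
    if (!inherits(vols[[nm]], "volume3d")) stop(nm, " must be a volume3d")
    if (!same_grid(vols[[nm]], S0))
      stop("grid mismatch: ", nm, " is not on the S0 grid")
    if (any(vols[[nm]]$data < 0, na.rm = TRUE))
      stop(nm, " contains negative signal values")
  }
  structure(vols, class = "weighted_volume_set")
}

#' @export
print.weighted_volume_set <- function(x, ...) {
  cat("weighted_volume_set:", paste(dim(x$S0$data), collapse = " x "),
      "voxels (S0, S+, S-, S+/-, S-/+, ST1)\n")
  invisible(x)
}

ratio_volume <- function(values, template, mask = NULL) {
  v <- values
  if (!is.null(mask)) v[!mask] <- NaN
  v[is.infinite(v)] <- NaN
  volume3d(array(v, dim = dim(template$data)), template$voxel_to_mm)
}

default_mask <- function(ws, s0_threshold) {
  ws$S0$data > s0_threshold * max(ws$S0$data, na.rm = TRUE)
}

#' Magnetization transfer ratio (single-sided)
#'
#' MTR = 1 - (S+ + S-) / (2 S0), voxelwise. Voxels where S0 falls at or
#' below \code{s0_threshold} times its maximum are masked to NaN, as are
#' voxels with a non-positive denominator.
#'
#' @param ws a \code{\link{weighted_volume_set}}.
#' @param s0_threshold background mask threshold as a fraction of max(S0).
#' @return A \code{\link{volume3d}} of dimensionless fractions.
#' @export
compute_mtr <- function(ws, s0_threshold = 0.05) {
  stopifnot(inherits(ws, "weighted_volume_set"))
  m <- default_mask(ws, s0_threshold) & ws$S0$data > 0
  ratio_volume(1 - (ws$Splus$data + ws$Sminus$data) / (2 * ws$S0$data), ws$S0, m)
}

#' Enhanced magnetization transfer ratio (dual-sided)
#'
#' eMTR = 1 - (S+/- + S-/+) / (2 S0).
#'
#' @inheritParams compute_mtr
#' @return A \code{\link{volume3d}}.
#' @export
compute_emtr <- function(ws, s0_threshold = 0.05) {
  stopifnot(inherits(ws, "weighted_volume_set"))
  m <- default_mask(ws, s0_threshold) & ws$S0$data > 0
  ratio_volume(1 - (ws$Spm$data + ws$Smp$data) / (2 * ws$S0$data), ws$S0, m)
}

#' MT asymmetry
#'
#' MTasym = (S+ - S-) / S0: nonzero when the absorption lineshape differs
#' between positive and negative offsets.
#'
#' @inheritParams compute_mtr
#' @return A \code{\link{volume3d}}.
#' @export
compute_mtasym <- function(ws, s0_threshold = 0.05) {
  stopifnot(inherits(ws, "weighted_volume_set"))
  m <- default_mask(ws, s0_threshold) & ws$S0$data > 0
  ratio_volume((ws$Splus$data - ws$Sminus$data) / ws$S0$data, ws$S0, m)
}

#' Inhomogeneous magnetization transfer ratio
#'
#' ihMTR = 2 (eMTR - MTR), which algebraically equals
#' (S+ + S- - S+/- - S-/+) / S0. Sensitive to dipolar order in myelin
#' lipids; near zero outside the brain and slightly negative in CSF.
#'
#' @inheritParams compute_mtr
#' @return A \code{\link{volume3d}}.
#' @export
compute_ihmtr <- function(ws, s0_threshold = 0.05) {
  e <- compute_emtr(ws, s0_threshold)
  m <- compute_mtr(ws, s0_threshold)
  ratio_volume(2 * (e$data - m$data), ws$S0)
}

#' Inverse inhomogeneous magnetization transfer ratio
#'
#' ihMTRinv = 2 ST1 (1/S+/- + 1/S-/+ - 1/S+ - 1/S-), a reciprocal-signal
#' reformulation scaled by the T1-prepared image, designed to reduce T1 and
#' B1 confounds. Voxels where any saturated signal falls at or below
#' \code{s0_threshold} times max(S0) are masked (reciprocals blow up at low
#' signal).
#'
#' @inheritParams compute_mtr
#' @return A \code{\link{volume3d}}.
#' @export
compute_ihmtr_inv <- function(ws, s0_threshold = 0.05) {
  stopifnot(inherits(ws, "weighted_volume_set"))
  thr <- s0_threshold * max(ws$S0$data, na.rm = TRUE)
  m <- default_mask(ws, s0_threshold) &
    ws$Splus$data > thr & ws$Sminus$data > thr &
    ws$Spm$data > thr & ws$Smp$data > thr
  vals <- 2 * ws$ST1$data *
    (1 / ws$Spm$data + 1 / ws$Smp$data - 1 / ws$Splus$data - 1 / ws$Sminus$data)
  ratio_volume(vals, ws$S0, m)
}

#' Compute all five MT ratio maps in one pass
#'
#' Produces MTR, eMTR, MT asymmetry, ihMTR and inverse ihMTR plus the brain
#' mask used. The default mask keeps voxels with S0 above a fraction of its
#' maximum; an explicit mask volume overrides it. Ratios are stored as
#' fractions (multiply by 100 for the percent scale used in reports).
#' Negative values are not clipped.
#'
#' @param ws a \code{\link{weighted_volume_set}}.
#' @param s0_threshold background threshold as a fraction of max(S0); default 0.05.
#' @param mask optional \code{\link{volume3d}} of 1/0 (or logical array)
#'   overriding the S0 threshold mask.
#' @return An object of class \code{ratio_maps}: list with elements
#'   \code{mtr}, \code{emtr}, \code{mtasym}, \code{ihmtr}, \code{ihmtr_inv}
#'   (each a \code{\link{volume3d}}) and \code{mask}.
#' @export
compute_ratio_maps <- function(ws, s0_threshold = 0.05, mask = NULL) {
  stopifnot(inherits(ws, "weighted_volume_set"))
  if (!is.null(mask)) {
    mk <- if (inherits(mask, "volume3d")) mask$data else mask
    if (!identical(dim(mk), dim(ws$S0$data))) stop("grid mismatch: mask")
    mk <- mk > 0 & !is.na(mk)
  } else {
    mk <- default_mask(ws, s0_threshold)
  }
  if (!any(mk)) warning("all voxels masked: maps are entirely NaN")
  apply_mask <- function(v) { v$data[!mk] <- NaN; v }
  out <- list(
    mtr = apply_mask(compute_mtr(ws, s0_threshold)),
    emtr = apply_mask(compute_emtr(ws, s0_threshold)),
    mtasym = apply_mask(compute_mtasym(ws, s0_threshold)),
    ihmtr = apply_mask(compute_ihmtr(ws, s0_threshold)),
    ihmtr_inv = apply_mask(compute_ihmtr_inv(ws, s0_threshold)),
    mask = volume3d(array(as.numeric(mk), dim = dim(ws$S0$data)), ws$S0$voxel_to_mm)
  )
  structure(out, class = "ratio_maps")
}

#' @export
print.ratio_maps <- function(x, ...) {
  cat("ratio_maps:", paste(dim(x$mtr$data), collapse = " x "), "voxels;",
      sum(x$mask$data > 0), "voxels in mask\n")
  invisible(x)
}

#' Write a set of ratio maps to a directory
#'
#' Writes \code{mtr.nii.gz}, \code{emtr.nii.gz}, \code{mtasym.nii.gz},
#' \code{ihmtr.nii.gz}, \code{ihmtr_inv.nii.gz} and \code{mask.nii.gz}.
#'
#' @param maps a \code{ratio_maps} object from \code{\link{compute_ratio_maps}}.
#' @param dir output directory (created if absent).
#' @param percent write ratios multiplied by 100.
#' @return \code{dir}, invisibly.
#' @export
write_ratio_maps <- function(maps, dir, percent = FALSE) {
  stopifnot(inherits(maps, "ratio_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("mtr", "emtr", "mtasym", "ihmtr", "ihmtr_inv")) {
    v <- maps[[nm]]
    if (percent) v$data <- v$data * 100
    write_volume(v, file.path(dir, paste0(nm, ".nii.gz")))
  }
  write_volume(maps$mask, file.path(dir, "mask.nii.gz"))
  invisible(dir)
}
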