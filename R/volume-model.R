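#' Construct a 3D scalar volume
#'
#' A \code{volume3d} is the carrier for every image in the pipeline: a 3D
#' numeric array plus the voxel-to-world affine. World coordinates are RAS+
#' millimetres, voxel indices are 0-based, and affines act on column vectors,
#' following the NIfTI convention. \code{NaN} marks masked voxels.
#'
#' @param data 3D numeric array. Values must be finite or \code{NaN}.
#' @param voxel_to_mm 4x4 affine mapping 0-based voxel indices to RAS+ mm.
#'   Defaults to identity (1 mm isotropic).
#' @return An object of class \code{volume3d} with elements \code{data},
#'   \code{voxel_to_mm} and \code{voxel_size} (mm per voxel along each axis).
#' @export
volume3d <- function(data, voxel_to_mm = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("non-3D image: 'data' must be a 3D array, got ", length(dim(data)), " dimensions")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  storage.mode(data) <- "double"
  voxel_to_mm <- check_affine_matrix(voxel_to_mm)
  if (any(is.infinite(data))) stop("data values must be finite or NaN")
  structure(list(
    data = data,
    voxel_to_mm = voxel_to_mm,
    voxel_size = sqrt(colSums(voxel_to_mm[1:3, 1:3]^2))
  ), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("volume3d:", paste(dim(x$data), collapse = " x "),
      "voxels;", paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

check_affine_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  storage.mode(m) <- "double"
  if (!isTRUE(all.equal(m[4, ], c(0, 0, 0, 1), tolerance = 1e-9)))
    stop("last row of affine must be (0, 0, 0, 1)")
  if (abs(det(m[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("affine linear part is singular")
  m
}

#' Construct an affine transform between named spaces
#'
#' Carrier for registration outputs, e.g. the transform from the eMTR image
#' to the subject's T1-weighted image. Homogeneous 4x4 matrix, column-vector
#' convention: \code{y = matrix \%*\% c(x, 1)}.
#'
#' @param matrix 4x4 homogeneous matrix with last row (0,0,0,1) and a
#'   non-singular linear part.
#' @param from_space,to_space names of the source and destination spaces.
#' @return An object of class \code{affine_transform}.
#' @export
affine_transform <- function(matrix, from_space = "native", to_space = "native") {
  structure(list(matrix = check_affine_matrix(matrix),
                 from_space = from_space, to_space = to_space),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine_transform:", x$from_space, "->", x$to_space, "\n")
  print(x$matrix)
  invisible(x)
}

#' Construct a labelled ROI volume
#'
#' Integer atlas labels on a regular grid; 0 is background and every nonzero
#' label must be named.
#'
#' @param labels 3D integer array; 0 = background.
#' @param voxel_to_mm 4x4 voxel-to-world affine.
#' @param label_names named character vector or list mapping label value
#'   (as character) to ROI name. If \code{NULL}, names \code{"roi<k>"} are
#'   generated for the labels present.
#' @return An object of class \code{label_volume}.
#' @export
label_volume <- function(labels, voxel_to_mm = diag(4), label_names = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("non-3D image: labels must be a 3D array")
  storage.mode(labels) <- "integer"
  voxel_to_mm <- check_affine_matrix(voxel_to_mm)
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0L]
  if (is.null(label_names)) {
    label_names <- stats::setNames(paste0("roi", present), as.character(present))
  } else {
    label_names <- unlist(label_names)
    missing <- setdiff(as.character(present), names(label_names))
    if (length(missing))
      stop("labels present without names: ", paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, voxel_to_mm = voxel_to_mm,
                 label_names = label_names), class = "label_volume")
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return A \code{\link{volume3d}}; data promoted to double, affine taken
#'   from the file's xform.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("non-3D image: ", path, " has ", length(d), " dimensions")
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  volume3d(array(as.numeric(img), dim = d), voxel_to_mm = aff)
}

#' Write a 3D volume as NIfTI-1
#'
#' Data are stored as 64-bit float so NaN-masked voxels and exact values
#' survive the round trip.
#'
#' @param v a \code{\link{volume3d}}.
#' @param path output path (\code{.nii} or \code{.nii.gz}); parent directory
#'   must exist.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume3d"))
  if (!dir.exists(dirname(path))) stop("unwritable path (no such directory): ", dirname(path))
  img <- RNifti::asNifti(v$data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(v$voxel_to_mm, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a labelled atlas volume from NIfTI
#'
#' @inheritParams read_volume
#' @param label_names optional named vector mapping label value to ROI name.
#' @return A \code{\link{label_volume}}.
#' @export
read_labels <- function(path, label_names = NULL) {
  v <- read_volume(path)
  lab <- round(v$data)
  if (max(abs(lab - v$data), na.rm = TRUE) > 1e-6)
    stop("label image contains non-integer values: ", path)
  storage.mode(lab) <- "integer"
  label_volume(lab, v$voxel_to_mm, label_names)
}

#' Write a labelled volume as NIfTI
#' @param lv a \code{\link{label_volume}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(lv, path) {
  stopifnot(inherits(lv, "label_volume"))
  write_volume(volume3d(array(as.numeric(lv$labels), dim = dim(lv$labels)),
                        lv$voxel_to_mm), path)
}

#' Read a plain-text 4x4 affine transform
#'
#' Expects four lines of four whitespace-delimited numbers, row-major; the
#' last row must be (0, 0, 0, 1) and the linear part non-singular.
#'
#' @param path path to the text file.
#' @param from_space,to_space space names attached to the transform.
#' @return An \code{\link{affine_transform}}.
#' @export
read_affine <- function(path, from_space = "native", to_space = "native") {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vals <- lapply(lines, function(l) suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (length(vals) != 4L || any(vapply(vals, length, 1L) != 4L) ||
      any(vapply(vals, anyNA, TRUE)))
    stop("affine file must have 4 rows of 4 numbers: ", path)
  m <- do.call(rbind, vals)
  affine_transform(m, from_space = from_space, to_space = to_space)
}

#' Write an affine transform as plain text
#' @param t an \code{\link{affine_transform}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_affine <- function(t, path) {
  stopifnot(inherits(t, "affine_transform"))
  writeLines(apply(t$matrix, 1, function(r) paste(format(r, digits = 17), collapse = " ")),
             path)
  invisible(path)
}

#' Resample an atlas into a target grid by nearest neighbour
#'
#' Pulls labels into the target grid: for each target voxel the transform
#' \code{t} maps target-space mm to label-space mm (the pull direction), the
#' result is converted to a label voxel index and sampled with nearest
#' neighbour. Labels are categorical, so no other interpolation is offered.
#' Target voxels that map outside the source extent become background (0).
#'
#' @param lv source \code{\link{label_volume}}.
#' @param t \code{\link{affine_transform}} from target-space mm to label-space mm.
#' @param target a \code{\link{volume3d}} defining the output grid.
#' @return A \code{\link{label_volume}} on the target grid.
#' @export
resample_labels <- function(lv, t, target) {
  stopifnot(inherits(lv, "label_volume"), inherits(t, "affine_transform"),
            inherits(target, "volume3d"))
  dims <- dim(target$data)
  # target voxel -> target mm -> label mm -> label voxel, one matrix product
  full <- solve(lv$voxel_to_mm) %*% t$matrix %*% target$voxel_to_mm
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1L), j = 0:(dims[2] - 1L),
                               k = 0:(dims[3] - 1L)))
  src <- t(full[1:3, 1:3] %*% t(idx)) +
    matrix(full[1:3, 4], nrow(idx), 3, byrow = TRUE)
  src <- round(src)
  sdim <- dim(lv$labels)
  inside <- src[, 1] >= 0 & src[, 1] <= sdim[1] - 1 &
    src[, 2] >= 0 & src[, 2] <= sdim[2] - 1 &
    src[, 3] >= 0 & src[, 3] <= sdim[3] - 1
  out <- integer(nrow(idx))
  if (any(inside)) {
    lin <- 1L + src[inside, 1] + sdim[1] * (src[inside, 2] + sdim[2] * src[inside, 3])
    out[inside] <- lv$labels[lin]
  }
  label_volume(array(out, dim = dims), target$voxel_to_mm,
               label_names = lv$label_names[as.character(sort(unique(out[out != 0L])))])
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data %||% a$labels), dim(b$data %||% b$labels)) &&
    max(abs((a$voxel_to_mm) - (b$voxel_to_mm))) <= tol
}

`%||%` <- function(x, y) if (is.null(x)) y else x
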