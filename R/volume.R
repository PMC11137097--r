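# Lightweight image container used throughout the package. Axis semantics
# are fixed: x = left-right, y = anterior-posterior, z = inferior-superior
# in the scanner frame, frame axis (if any) last. The ALPS index is defined
# on diffusivities along these fixed axes, so every volume is brought to
# this canonical (RAS) orientation at load time.

#' Create an image volume
#'
#' A `volume` is the package's container for 3-D scalar images and 4-D
#' image series (frame axis last): a numeric array plus voxel spacing in
#' mm, a 4x4 voxel-index-to-world-mm affine, and a free-text unit label.
#'
#' @param data Numeric 3-D array, or 4-D array with the frame axis last.
#' @param spacing Voxel size in mm along x, y, z; strictly positive.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(c(spacing, 1))`.
#'   Must be invertible.
#' @param units Free-text unit label (e.g. `"mm^2/s"`, `"kBq/mL"`).
#' @return An object of class `volume`.
#' @seealso [read_volume()], [write_volume()]
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                   units = "unitless") {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("'data' must be a 3-D or 4-D array (frame axis last)", call. = FALSE)
  if (any(dim(data)[1:3] < 1L))
    stop("spatial dimensions must all be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive voxel sizes in mm",
         call. = FALSE)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)) ||
      abs(det(affine)) < 1e-12)
    stop("'affine' must be an invertible 4x4 voxel-to-world matrix",
         call. = FALSE)
  structure(list(data = data, spacing = spacing, affine = affine,
                 units = units),
            class = "volume")
}

#' @export
dim.volume <- function(x) dim(x$data)

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %s voxels, spacing %s mm, units '%s'\n",
              paste(d, collapse = " x "),
              paste(format(x$spacing, digits = 3), collapse = " x "),
              x$units))
  invisible(x)
}

#' Number of frames in a 4-D volume
#' @param vol A [volume()].
#' @return Integer frame count (1 for a 3-D volume).
#' @export
n_frames <- function(vol) {
  stopifnot(inherits(vol, "volume"))
  d <- dim(vol$data)
  if (length(d) == 4L) d[4L] else 1L
}

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [volume()]. The image is reoriented
#' to canonical RAS axes if stored otherwise, so that array axis 1 runs
#' left-to-right, axis 2 posterior-to-anterior, axis 3 inferior-to-superior;
#' voxel spacing is taken from the affine column norms.
#'
#' @param path Path to a NIfTI-1 file.
#' @param units Unit label to attach (NIfTI headers do not carry the unit
#'   semantics this package needs).
#' @param allow_nan If `FALSE` (default), any NaN in the payload is an error.
#' @return A [volume()].
#' @export
read_volume <- function(path, units = "unitless", allow_nan = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path, internal = FALSE),
                  error = function(e)
                    stop("not a readable NIfTI-1 file: ", path,
                         " (", conditionMessage(e), ")", call. = FALSE))
  if (!identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  if (abs(det(aff)) < 1e-12)
    stop("non-invertible affine in ", path, call. = FALSE)
  arr <- array(as.vector(img), dim = dim(img))
  if (!allow_nan && anyNA(arr))
    stop("volume contains NaN/NA values: ", path, call. = FALSE)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  volume(arr, spacing = spacing, affine = aff, units = units)
}

#' Write a volume as NIfTI-1
#'
#' Data are stored as 64-bit floats so that a write/read round trip is
#' bit-exact; the affine is stored in the sform (code 2).
#'
#' @param vol A [volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume"))
  img <- RNifti::asNifti(vol$data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Gradient tables ----------------------------------------------------------

#' Create a diffusion gradient table
#'
#' Holds per-frame b-values (s/mm^2) and unit direction vectors for a DWI
#' series. Directions with nonzero b are normalised to unit length; a zero
#' direction vector is only legal on b = 0 frames.
#'
#' @param bvals Numeric vector of non-negative b-values, one per frame.
#' @param bvecs 3 x n matrix of direction vectors (columns per frame).
#' @return An object of class `gradient_table` with elements `bvals` and
#'   `bvecs` (unit columns).
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L)
    stop("'bvecs' must be a 3 x n matrix (one column per frame)",
         call. = FALSE)
  if (length(bvals) != ncol(bvecs))
    stop("gradient table mismatch: ", length(bvals), " b-values vs ",
         ncol(bvecs), " direction vectors", call. = FALSE)
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(bvecs)))
    stop("non-numeric or non-finite gradient directions", call. = FALSE)
  nrm <- sqrt(colSums(bvecs^2))
  weighted <- bvals > 0
  if (any(weighted & nrm < 1e-8))
    stop("zero direction vector on a diffusion-weighted (b > 0) frame",
         call. = FALSE)
  bvecs[, weighted] <- sweep(bvecs[, weighted, drop = FALSE], 2L,
                             nrm[weighted], `/`)
  bvecs[, !weighted] <- 0
  structure(list(bvals = bvals, bvecs = unname(bvecs)),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  tab <- table(round(x$bvals))
  cat("<gradient_table>", length(x$bvals), "frames:",
      paste(sprintf("%s frame(s) at b=%s", tab, names(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname n_frames
#' @param x A `gradient_table`.
#' @export
n_frames_table <- function(x) length(x$bvals)

#' Read an FSL-style gradient table
#'
#' `.bval` is one whitespace-separated row of b-values; `.bvec` is three
#' rows (x, y, z components), one column per frame.
#'
#' @param bval_path,bvec_path Paths to the text files.
#' @return A [gradient_table()].
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  bvals <- tryCatch(scan(bval_path, what = numeric(), quiet = TRUE),
                    error = function(e)
                      stop("non-numeric token in ", bval_path, call. = FALSE))
  rows <- readLines(bvec_path, warn = FALSE)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3L)
    stop("'", bvec_path, "' must have exactly 3 rows, found ",
         length(rows), call. = FALSE)
  comp <- lapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
    if (anyNA(v)) stop("non-numeric token in ", bvec_path, call. = FALSE)
    v
  })
  if (length(unique(lengths(comp))) != 1L)
    stop("ragged rows in ", bvec_path, call. = FALSE)
  gradient_table(bvals, do.call(rbind, comp))
}

#' Write an FSL-style gradient table
#' @param table A [gradient_table()].
#' @param bval_path,bvec_path Output paths.
#' @return `c(bval_path, bvec_path)`, invisibly.
#' @export
write_gradient_table <- function(table, bval_path, bvec_path) {
  stopifnot(inherits(table, "gradient_table"))
  writeLines(paste(format(table$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(table$bvecs, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Group DWI frames into b-value shells
#'
#' Frames are assigned to a shell when their b-value is within `tol` of the
#' shell centre (scanner-reported b-values jitter); b-values below `tol`
#' count as b = 0.
#'
#' @param bvals Numeric b-values.
#' @param tol Shell assignment tolerance in s/mm^2.
#' @return A list with `b0` (integer frame indices) and `shells`, a named
#'   list (`"b1000"`, ...) of frame indices, ordered by shell centre.
#' @export
shell_membership <- function(bvals, tol = 50) {
  bvals <- as.numeric(bvals)
  b0 <- which(bvals <= tol)
  shells <- list()
  remaining <- setdiff(seq_along(bvals), b0)
  while (length(remaining)) {
    centre <- min(bvals[remaining])
    members <- remaining[abs(bvals[remaining] - centre) <= tol]
    shells[[sprintf("b%d", round(mean(bvals[members])))]] <- members
    remaining <- setdiff(remaining, members)
  }
  list(b0 = b0, shells = shells)
}

# ROI masks ----------------------------------------------------------------

#' Create a labelled region-of-interest mask
#'
#' @param labels Integer 3-D array of region labels (0 = unlabelled),
#'   aligned to the volumes it will be applied to.
#' @param legend Named integer vector mapping ROI names (e.g. `proj_L`,
#'   `assoc_R`, `cerebellum`) to label values. Every named ROI must be
#'   nonempty in `labels`.
#' @param spacing,affine Grid geometry, as in [volume()].
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, legend, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3-D array", call. = FALSE)
  if (is.null(names(legend)) || any(!nzchar(names(legend))))
    stop("'legend' must be a named integer vector", call. = FALSE)
  legend <- stats::setNames(as.integer(legend), names(legend))
  present <- unique(as.vector(labels))
  missing <- names(legend)[!legend %in% present]
  if (length(missing))
    stop("empty ROI(s): ", paste(missing, collapse = ", "), call. = FALSE)
  spacing <- as.numeric(spacing)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(labels = labels, legend = legend, spacing = spacing,
                 affine = unname(as.matrix(affine))),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask>", paste(dim(x$labels), collapse = " x "), "voxels;",
      length(x$legend), "ROIs:", paste(names(x$legend), collapse = ", "),
      "\n")
  invisible(x)
}

#' Resolve an ROI name to voxel indices
#'
#' @param mask A [roi_mask()].
#' @param name ROI name, present in the mask legend.
#' @return Integer vector of linear (1-based, column-major) voxel indices.
#' @export
resolve_roi <- function(mask, name) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!name %in% names(mask$legend))
    stop("unknown ROI '", name, "'; legend has: ",
         paste(names(mask$legend), collapse = ", "), call. = FALSE)
  idx <- which(mask$labels == mask$legend[[name]])
  if (!length(idx)) stop("ROI '", name, "' is empty", call. = FALSE)
  idx
}

#' ROI names available in a mask
#' @param mask A [roi_mask()].
#' @return Character vector of ROI names.
#' @export
roi_names <- function(mask) names(mask$legend)

#' Write / read a labelled ROI mask
#'
#' The label volume is stored as NIfTI and the legend as a JSON object
#' mapping ROI names to label values.
#'
#' @param mask A [roi_mask()].
#' @param labels_path NIfTI path for the label volume.
#' @param legend_path JSON path for the legend.
#' @return Paths, invisibly.
#' @export
write_roi_mask <- function(mask, labels_path, legend_path) {
  stopifnot(inherits(mask, "roi_mask"))
  write_volume(volume(array(as.numeric(mask$labels), dim = dim(mask$labels)),
                      spacing = mask$spacing, affine = mask$affine,
                      units = "label"),
               labels_path)
  jsonlite::write_json(as.list(mask$legend), legend_path, auto_unbox = TRUE)
  invisible(c(labels_path, legend_path))
}

#' @rdname write_roi_mask
#' @export
read_roi_mask <- function(labels_path, legend_path) {
  vol <- read_volume(labels_path, units = "label")
  legend <- unlist(jsonlite::read_json(legend_path))
  roi_mask(array(as.integer(round(vol$data)), dim = dim(vol$data)[1:3]),
           legend = legend, spacing = vol$spacing, affine = vol$affine)
}
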