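# Per-voxel diffusion tensor fitting, one shell at a time.
#
# The ALPS method reads the tensor's *diagonal* elements in the fixed
# scanner frame (diffusivity along x, y, z), not eigenvalues, so this
# module never eigen-decomposes. The fit is log-linear weighted least
# squares with a single reweighting pass (weights = squared predicted
# signal), the standard deterministic DTI estimator.

#' Tensor field container
#'
#' @param components 4-D array `(x, y, z, 6)` of symmetric tensor
#'   components in mm^2/s, ordered `Dxx, Dyy, Dzz, Dxy, Dxz, Dyz`.
#' @param s0 3-D array: fitted (or true) unweighted signal.
#' @param valid Logical 3-D array of voxels with a usable fit; defaults to
#'   all finite voxels.
#' @param flagged Logical 3-D array of voxels where a negative diagonal
#'   was clamped to zero.
#' @param shell Nominal shell b-value (s/mm^2) the field was fitted from,
#'   or `NA` for ground-truth fields.
#' @param spacing,affine Grid geometry, as in [volume()].
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(components, s0, valid = NULL, flagged = NULL,
                         shell = NA_real_, spacing = c(1, 1, 1),
                         affine = NULL) {
  stopifnot(is.array(components), length(dim(components)) == 4L,
            dim(components)[4L] == 6L)
  shape <- dim(components)[1:3]
  stopifnot(all(dim(s0) == shape))
  if (is.null(valid))
    valid <- array(apply(is.finite(components), c(1, 2, 3), all), shape)
  if (is.null(flagged)) flagged <- array(FALSE, shape)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(components = components, s0 = s0, valid = valid,
                 flagged = flagged, shell = shell,
                 spacing = as.numeric(spacing),
                 affine = unname(as.matrix(affine))),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s voxels (%d valid), shell %s\n",
              paste(dim(x$components)[1:3], collapse = " x "),
              sum(x$valid),
              if (is.na(x$shell)) "ground truth" else paste0("b=", x$shell)))
  invisible(x)
}

#' Split a multi-shell DWI series into per-shell datasets
#'
#' Each output dataset contains all b = 0 frames plus the weighted frames
#' of one shell, so shells are fitted separately against a shared b0.
#'
#' @param dwi 4-D [volume()] of DWI signals.
#' @param table Matching [gradient_table()].
#' @param tol Shell-assignment tolerance in s/mm^2 (see
#'   [shell_membership()]).
#' @return Named list (`"b1000"`, ...) of lists with elements `dwi`
#'   (4-D volume), `table` (gradient table) and `b` (nominal shell value).
#' @export
split_shells <- function(dwi, table, tol = 50) {
  stopifnot(inherits(dwi, "volume"), inherits(table, "gradient_table"))
  if (n_frames(dwi) != length(table$bvals))
    stop("DWI has ", n_frames(dwi), " frames but gradient table has ",
         length(table$bvals), call. = FALSE)
  mem <- shell_membership(table$bvals, tol = tol)
  if (!length(mem$b0)) stop("no b = 0 frame in the series", call. = FALSE)
  if (!length(mem$shells))
    stop("no diffusion-weighted frames in the series", call. = FALSE)
  lapply(stats::setNames(names(mem$shells), names(mem$shells)), function(nm) {
    idx <- c(mem$b0, mem$shells[[nm]])
    if (length(mem$shells[[nm]]) < 6L)
      stop("shell ", nm, " has fewer than 6 directions", call. = FALSE)
    list(dwi = volume(dwi$data[, , , idx, drop = FALSE],
                      spacing = dwi$spacing, affine = dwi$affine,
                      units = dwi$units),
         table = gradient_table(table$bvals[idx],
                                table$bvecs[, idx, drop = FALSE]),
         b = round(mean(table$bvals[mem$shells[[nm]]])))
  })
}

# Design matrix for log-linear tensor regression:
# log S = log S0 - b g' D g, parameters (log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor_design <- function(table) {
  g <- table$bvecs; b <- table$bvals
  cbind(1,
        -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}

#' Fit diffusion tensors voxelwise
#'
#' Solves `log S = log S0 - b g' D g` by ordinary least squares followed
#' by one reweighting pass with weights equal to the squared predicted
#' signal (log-linear WLS). Signals are floored at `1e-6 * S0` before the
#' log to keep noisy background finite; negative fitted diagonal
#' diffusivities are clamped to 0 and the voxel flagged. Voxels whose
#' weighted system is numerically singular are marked invalid rather than
#' aborting the fit.
#'
#' @param dwi 4-D [volume()] for one shell (b0 frames plus weighted
#'   frames, e.g. from [split_shells()]).
#' @param table Matching [gradient_table()].
#' @param mask Optional logical array or voxel index vector restricting
#'   the fit (e.g. to labelled ROIs); other voxels come back invalid.
#' @param shell Nominal shell label stored on the result; inferred from
#'   the table when missing.
#' @return A [tensor_field()].
#' @export
fit_tensor <- function(dwi, table, mask = NULL, shell = NULL) {
  stopifnot(inherits(dwi, "volume"), inherits(table, "gradient_table"))
  n <- length(table$bvals)
  if (n_frames(dwi) != n)
    stop("DWI frame count does not match gradient table", call. = FALSE)
  if (n < 7L)
    stop("tensor fit needs at least 7 frames, got ", n, call. = FALSE)
  X <- tensor_design(table)
  if (qr(X)$rank < 7L)
    stop("rank-deficient direction set: cannot identify 6 tensor ",
         "components + S0", call. = FALSE)
  if (is.null(shell)) {
    wb <- table$bvals[table$bvals > 50]
    shell <- if (length(wb)) round(mean(wb)) else NA_real_
  }
  shape <- dim(dwi$data)[1:3]
  nvox <- prod(shape)
  vox <- if (is.null(mask)) seq_len(nvox)
         else if (is.logical(mask)) which(mask)
         else as.integer(mask)
  S <- matrix(dwi$data, nvox, n)[vox, , drop = FALSE]
  b0f <- table$bvals <= 50
  s0_est <- if (any(b0f)) rowMeans(S[, b0f, drop = FALSE])
            else apply(S, 1L, max)
  Y <- t(log(pmax(S, 1e-6 * pmax(s0_est, .Machine$double.eps))))  # n x V
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, Y))                             # 7 x V
  W <- exp(2 * (X %*% beta))                                      # n x V
  ZZ <- X[, rep(1:7, times = 7)] * X[, rep(1:7, each = 7)]        # n x 49
  M <- crossprod(ZZ, W)                                           # 49 x V
  R <- crossprod(X, W * Y)                                        # 7 x V
  ok <- rep(TRUE, length(vox))
  for (v in seq_along(vox)) {
    bv <- tryCatch(solve(matrix(M[, v], 7L, 7L), R[, v]),
                   error = function(e) NULL)
    if (is.null(bv)) ok[v] <- FALSE else beta[, v] <- bv
  }
  diag_comp <- beta[2:4, , drop = FALSE]
  clamped <- colSums(diag_comp < 0) > 0L
  beta[2:4, ] <- pmax(diag_comp, 0)
  comp <- array(NA_real_, c(shape, 6L))
  compm <- matrix(comp, nvox, 6L)
  compm[vox, ] <- t(beta[2:7, , drop = FALSE])
  compm[vox[!ok], ] <- NA_real_
  s0 <- array(NA_real_, shape)
  s0[vox] <- exp(beta[1L, ])
  s0[vox[!ok]] <- NA_real_
  valid <- array(FALSE, shape); valid[vox[ok]] <- TRUE
  flagged <- array(FALSE, shape); flagged[vox[clamped & ok]] <- TRUE
  tensor_field(array(compm, c(shape, 6L)), s0 = s0, valid = valid,
               flagged = flagged, shell = shell, spacing = dwi$spacing,
               affine = dwi$affine)
}

#' Axis-aligned diffusivity maps
#'
#' Returns the tensor's diagonal elements `Dxx`, `Dyy`, `Dzz` in the
#' canonical image/scanner frame. These are *not* eigenvalues: the ALPS
#' method is defined on diffusivity along fixed anatomical axes, and for
#' any tensor with nonzero off-diagonal terms the two differ.
#'
#' @param field A fitted [tensor_field()].
#' @return Named list of three 3-D [volume()]s (`Dxx`, `Dyy`, `Dzz`) in
#'   mm^2/s, `NA` outside the valid-fit mask.
#' @export
axis_diffusivities <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  out <- lapply(1:3, function(k) {
    m <- field$components[, , , k, drop = TRUE]
    m <- array(m, dim(field$components)[1:3])
    m[!field$valid] <- NA_real_
    volume(m, spacing = field$spacing, affine = field$affine,
           units = "mm^2/s")
  })
  names(out) <- c("Dxx", "Dyy", "Dzz")
  out
}

#' Mean diffusivity map (convenience)
#'
#' Trace/3 of the fitted tensor; exposed for completeness, not used by the
#' ALPS analysis.
#'
#' @param field A [tensor_field()].
#' @return A 3-D [volume()] in mm^2/s.
#' @export
mean_diffusivity <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  m <- (field$components[, , , 1L] + field$components[, , , 2L] +
          field$components[, , , 3L]) / 3
  m <- array(m, dim(field$components)[1:3])
  m[!field$valid] <- NA_real_
  volume(m, spacing = field$spacing, affine = field$affine,
         units = "mm^2/s")
}
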