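# Three-zone white-matter tensor phantom.
#
# At the level of the lateral-ventricle body, the tracts relevant to the
# ALPS method run along three orthogonal axes: projection fibres along z,
# association fibres along y, subcortical fibres along x, while the
# perivascular spaces run along x. The phantom places one band per tract
# per hemisphere on a regular grid, assigns each a diagonal diffusion
# tensor with the matching dominant axis, and adds a "perivascular" gain g
# to Dxx in the projection and association bands. g is the single disease
# knob: the analytic ALPS index of the phantom is
# (Dxx_base + g) / mean(Dyy_proj, Dzz_assoc).

#' Specify a white-matter tensor phantom
#'
#' Defaults give a CN-like phantom: with `pv_gain = 1e-4` mm^2/s the
#' analytic ALPS index is (0.8e-3 + 1e-4)/0.625e-3 = 1.44.
#'
#' @param shape Grid size (x, y, z) in voxels.
#' @param spacing Voxel size in mm; defaults to the 1.9 x 1.9 x 3.0 mm DWI
#'   grid of the emulated protocol.
#' @param diffusivities Named list of per-zone `(Dxx, Dyy, Dzz)` triples in
#'   mm^2/s for `proj`, `assoc`, `subc`, `background`, `cerebellum`,
#'   `cortex`. Projection must be z-dominant, association y-dominant and
#'   subcortical x-dominant (after adding `pv_gain` where it applies).
#' @param pv_gain Perivascular gain g >= 0: additive Dxx enhancement in the
#'   projection and association zones (mm^2/s).
#' @param S0 Unweighted (b = 0) signal level, arbitrary units.
#' @param snr Default signal-to-noise ratio `S0 / sigma` for DWI synthesis
#'   (`Inf` = noiseless).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40, 40, 18),
                         spacing = c(1.9, 1.9, 3.0),
                         diffusivities = list(
                           proj       = c(0.80e-3, 0.625e-3, 1.60e-3),
                           assoc      = c(0.80e-3, 1.60e-3, 0.625e-3),
                           subc       = c(1.60e-3, 0.70e-3, 0.70e-3),
                           background = c(0.80e-3, 0.80e-3, 0.80e-3),
                           cerebellum = c(0.80e-3, 0.80e-3, 0.80e-3),
                           cortex     = c(0.80e-3, 0.80e-3, 0.80e-3)),
                         pv_gain = 1.0e-4, S0 = 500, snr = 30) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  need <- c("proj", "assoc", "subc", "background", "cerebellum", "cortex")
  if (!all(need %in% names(diffusivities)))
    stop("'diffusivities' must name zones: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (z in need) {
    d <- diffusivities[[z]]
    if (length(d) != 3L || any(!is.finite(d)) || any(d < 0))
      stop("zone '", z, "' needs three non-negative diffusivities",
           call. = FALSE)
  }
  if (!is.finite(pv_gain) || pv_gain < 0)
    stop("'pv_gain' must be >= 0", call. = FALSE)
  if (S0 <= 0) stop("'S0' must be positive", call. = FALSE)
  if (!(is.infinite(snr) || snr > 0)) stop("'snr' must be positive or Inf",
                                           call. = FALSE)
  phantom_zones(shape)   # fail early if any zone is empty at this size
  # axis-dominance invariants, after applying the perivascular gain
  dp <- diffusivities$proj + c(pv_gain, 0, 0)
  da <- diffusivities$assoc + c(pv_gain, 0, 0)
  ds <- diffusivities$subc
  if (which.max(dp) != 3L)
    stop("projection zone must be z-dominant (Dzz largest)", call. = FALSE)
  if (which.max(da) != 2L)
    stop("association zone must be y-dominant (Dyy largest)", call. = FALSE)
  if (which.max(ds) != 1L)
    stop("subcortical zone must be x-dominant (Dxx largest)", call. = FALSE)
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 diffusivities = diffusivities, pv_gain = pv_gain,
                 S0 = S0, snr = snr),
            class = "phantom_spec")
}

# Zone voxel sets as linear indices. Bands are placed by grid fraction so
# the geometry scales with the grid: fibre bands sit at three lateral
# offsets from the midline within a central y band and a "ventricle-body"
# z slab; the cerebellum is an inferior central block and the cortical
# (PET target) zone an anterior band, all mutually disjoint.
phantom_zones <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  ix <- slice.index(array(0, shape), 1L)
  iy <- slice.index(array(0, shape), 2L)
  iz <- slice.index(array(0, shape), 3L)
  mx <- (nx + 1) / 2
  dx <- abs(ix - mx) / nx
  fy <- iy / ny; fz <- iz / nz
  in_band <- fy > 0.30 & fy <= 0.70 & fz > 0.45 & fz <= 0.70
  zones <- list()
  offs <- list(proj = c(0.100, 0.175), assoc = c(0.225, 0.300),
               subc = c(0.350, 0.425))
  for (zn in names(offs)) {
    lat <- dx > offs[[zn]][1] & dx <= offs[[zn]][2] & in_band
    zones[[paste0(zn, "_L")]] <- which(lat & ix < mx)
    zones[[paste0(zn, "_R")]] <- which(lat & ix > mx)
  }
  zones$cerebellum <- which(fz <= 0.15 & dx <= 0.20 &
                              fy > 0.30 & fy <= 0.70)
  zones$cortex <- which(fy > 0.78 & fy <= 0.95 & dx <= 0.30 &
                          fz > 0.45 & fz <= 0.70)
  empty <- names(zones)[lengths(zones) == 0L]
  if (length(empty))
    stop("zone(s) empty at grid size ", paste(shape, collapse = "x"), ": ",
         paste(empty, collapse = ", "), call. = FALSE)
  zones
}

#' Build the tensor phantom
#'
#' Instantiates the zone geometry and per-zone diagonal tensors of a
#' [phantom_spec()], returning the ground-truth tensor field, an ROI mask
#' naming the zones, and the analytic ALPS index implied by the zone
#' tensors (the oracle against which the fitted pipeline is validated).
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `tensor_phantom`: `field` (ground-truth
#'   [tensor_field()]), `mask` ([roi_mask()] with ROIs `proj_L/R`,
#'   `assoc_L/R`, `subc_L/R`, `cerebellum`, `cortex`), `alps` (analytic
#'   index), `spec`.
#' @export
make_tensor_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  zones <- phantom_zones(spec$shape)
  nvox <- prod(spec$shape)
  comp <- matrix(0, nvox, 6L)   # Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
  comp[, 1:3] <- matrix(spec$diffusivities$background, nvox, 3L,
                        byrow = TRUE)
  labels <- array(0L, spec$shape)
  legend <- c(proj_L = 1L, assoc_L = 2L, subc_L = 3L, proj_R = 4L,
              assoc_R = 5L, subc_R = 6L, cerebellum = 7L, cortex = 8L)
  for (nm in names(legend)) {
    zone <- sub("_[LR]$", "", nm)
    d <- spec$diffusivities[[zone]]
    if (zone %in% c("proj", "assoc")) d <- d + c(spec$pv_gain, 0, 0)
    idx <- zones[[nm]]
    comp[idx, 1:3] <- matrix(d, length(idx), 3L, byrow = TRUE)
    labels[idx] <- legend[[nm]]
  }
  field <- tensor_field(array(comp, c(spec$shape, 6L)),
                        s0 = array(spec$S0, spec$shape),
                        shell = NA_real_, spacing = spec$spacing)
  mask <- roi_mask(labels, legend, spacing = spec$spacing)
  dp <- spec$diffusivities$proj; da <- spec$diffusivities$assoc
  alps <- mean(c(dp[1] + spec$pv_gain, da[1] + spec$pv_gain)) /
    mean(c(dp[2], da[3]))
  structure(list(field = field, mask = mask, alps = alps, spec = spec),
            class = "tensor_phantom")
}

#' @export
print.tensor_phantom <- function(x, ...) {
  cat(sprintf(
    "<tensor_phantom> %s grid, perivascular gain %.3g mm^2/s, analytic ALPS %.4f\n",
    paste(x$spec$shape, collapse = "x"), x$spec$pv_gain, x$alps))
  invisible(x)
}

#' Multi-shell acquisition scheme
#'
#' Builds the emulated DWI protocol: `n_b0` unweighted frames followed by
#' `n_dirs` distributed isotropic directions repeated at each shell.
#' Directions come from a deterministic spherical Fibonacci lattice, a
#' standard near-uniform sampling of the sphere.
#'
#' @param n_dirs Directions per shell.
#' @param bvalues Nonzero shell b-values in s/mm^2.
#' @param n_b0 Number of b = 0 frames.
#' @return A [gradient_table()] with `n_b0 + n_dirs * length(bvalues)`
#'   frames.
#' @export
make_gradient_scheme <- function(n_dirs = 30, bvalues = c(1000, 2000),
                                 n_b0 = 1) {
  stopifnot(n_dirs >= 6, n_b0 >= 1, all(bvalues > 0))
  i <- seq_len(n_dirs) - 0.5
  z <- 1 - 2 * i / n_dirs
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n_dirs) - 1)
  dirs <- rbind(r * cos(phi), r * sin(phi), z)
  bvals <- c(rep(0, n_b0), rep(bvalues, each = n_dirs))
  bvecs <- cbind(matrix(0, 3L, n_b0),
                 dirs[, rep(seq_len(n_dirs), times = length(bvalues))])
  gradient_table(bvals, bvecs)
}

#' Mean of the Rician distribution
#'
#' Closed form `sigma * sqrt(pi/2) * L_{1/2}(-nu^2 / (2 sigma^2))` via
#' scaled Bessel functions; used as the oracle for noise-level checks.
#'
#' @param nu Underlying noiseless signal magnitude(s).
#' @param sigma Gaussian channel noise SD.
#' @return Expected magnitude signal, same shape as `nu`.
#' @export
rician_mean <- function(nu, sigma) {
  if (sigma == 0) return(nu)
  t <- nu^2 / (2 * sigma^2)
  # exp(-t/2) I_k(t/2) computed as scaled Bessel to avoid overflow
  s0 <- besselI(t / 2, 0, expon.scaled = TRUE)
  s1 <- besselI(t / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * ((1 + t) * s0 + t * s1)
}

#' Simulate a diffusion-weighted series from a tensor field
#'
#' Monoexponential tensor forward model: frame i has noiseless signal
#' `S_i = S0 * exp(-b_i * g_i' D g_i)` per voxel. With finite `snr`,
#' single-coil magnitude (Rician) noise is applied as
#' `|S_i + N(0, sigma) + i N(0, sigma)|` with `sigma = S0 / snr`.
#'
#' @param field A [tensor_field()] (e.g. from [make_tensor_phantom()]).
#' @param table A [gradient_table()].
#' @param S0 Unweighted signal level; defaults to the field's S0 map.
#' @param snr Signal-to-noise ratio on the b = 0 signal; `Inf` bypasses
#'   noise exactly.
#' @param seed Integer seed; required whenever noise is drawn. No global
#'   RNG state is consumed or altered.
#' @return A 4-D [volume()] of signals, frame axis last.
#' @export
simulate_dwi <- function(field, table, S0 = NULL, snr = Inf, seed = NULL) {
  stopifnot(inherits(field, "tensor_field"),
            inherits(table, "gradient_table"))
  if (!is.null(S0) && any(S0 < 0)) stop("'S0' must be non-negative",
                                        call. = FALSE)
  if (!(is.infinite(snr) || snr > 0))
    stop("'snr' must be positive or Inf", call. = FALSE)
  shape <- dim(field$components)[1:3]
  nvox <- prod(shape)
  D <- matrix(field$components, nvox, 6L)
  s0 <- if (is.null(S0)) as.vector(field$s0) else rep_len(S0, nvox)
  g <- table$bvecs
  q <- t(rbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
               2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ],
               2 * g[2, ] * g[3, ])) * table$bvals   # n x 6
  signal <- s0 * exp(-tcrossprod(D, q))              # nvox x n
  if (is.finite(snr)) {
    if (is.null(seed))
      stop("'seed' is required when snr is finite", call. = FALSE)
    sigma <- mean(s0) / snr
    signal <- withr::with_seed(as.integer(seed), {
      n <- length(signal)
      sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
             stats::rnorm(n, 0, sigma)^2)
    })
  }
  volume(array(signal, c(shape, length(table$bvals))),
         spacing = field$spacing, units = "a.u.")
}

#' Simulate an amyloid-PET SUVR map
#'
#' Builds a noiseless SUVR image over an ROI mask: the cerebellar
#' reference region is set to 1 exactly and the cortical target zone to
#' the SUVR that maps to `target_centiloid` under the linear centiloid
#' transform, so the simulate-then-quantify round trip is exact.
#'
#' @param mask A [roi_mask()] with the reference and cortical ROIs.
#' @param target_centiloid Desired global centiloid value (may lie outside
#'   `[0, 100]`; the scale is open-ended).
#' @param anchors A [centiloid_anchors()] calibration pair.
#' @param cortical_roi,reference_roi ROI names in the mask legend.
#' @param background Intensity outside both ROIs (nonspecific uptake).
#' @return A 3-D [volume()] with units `"SUVR"`.
#' @export
simulate_pet_suvr <- function(mask, target_centiloid, anchors,
                              cortical_roi = "cortex",
                              reference_roi = "cerebellum",
                              background = 0.25) {
  stopifnot(inherits(mask, "roi_mask"), inherits(anchors, "centiloid_anchors"))
  target_suvr <- anchors$suvr_yc +
    target_centiloid / 100 * (anchors$suvr_ad100 - anchors$suvr_yc)
  arr <- array(background, dim(mask$labels))
  arr[resolve_roi(mask, reference_roi)] <- 1
  arr[resolve_roi(mask, cortical_roi)] <- target_suvr
  volume(arr, spacing = mask$spacing, affine = mask$affine, units = "SUVR")
}
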