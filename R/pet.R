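# Amyloid-PET quantification: SUV, SUVR against a cerebellar reference,
# and the linear centiloid transform. Decay correction, frame averaging
# and reconstruction are assumed done upstream; the input is one static
# activity volume.

#' PET acquisition metadata
#'
#' @param injected_dose Injected tracer dose in MBq; positive.
#' @param body_weight Subject body weight in kg; positive.
#' @param frame_window Acquisition window label, e.g. `"50-70min"`.
#' @return An object of class `pet_meta`.
#' @export
pet_meta <- function(injected_dose, body_weight, frame_window = "50-70min") {
  if (!is.finite(injected_dose) || injected_dose <= 0)
    stop("'injected_dose' must be positive (MBq)", call. = FALSE)
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("'body_weight' must be positive (kg)", call. = FALSE)
  structure(list(injected_dose = injected_dose, body_weight = body_weight,
                 frame_window = frame_window),
            class = "pet_meta")
}

#' Centiloid calibration anchors
#'
#' The centiloid scale is a linear rescaling of global SUVR anchoring a
#' young-control mean at 0 and a typical-AD level at 100. The anchors are
#' calibration inputs, not constants: they depend on tracer, analysis
#' VOIs and software. Defaults are standard PiB global-cortical values
#' and are also recorded in the shipped cohort configuration.
#'
#' @param suvr_yc Young-control anchor SUVR (centiloid 0).
#' @param suvr_ad100 Typical-AD anchor SUVR (centiloid 100); must exceed
#'   `suvr_yc`.
#' @return An object of class `centiloid_anchors`.
#' @export
centiloid_anchors <- function(suvr_yc = 1.009, suvr_ad100 = 2.076) {
  if (!is.finite(suvr_yc) || !is.finite(suvr_ad100) ||
      suvr_yc <= 0 || suvr_ad100 <= suvr_yc)
    stop("anchors must satisfy suvr_ad100 > suvr_yc > 0", call. = FALSE)
  structure(list(suvr_yc = suvr_yc, suvr_ad100 = suvr_ad100),
            class = "centiloid_anchors")
}

#' Standardized uptake value image
#'
#' `SUV = activity concentration [kBq/mL] / (injected dose [MBq] /
#' body weight [kg])`, voxelwise.
#'
#' @param activity 3-D [volume()] of activity concentration in kBq/mL;
#'   non-negative.
#' @param meta A [pet_meta()].
#' @return A [volume()] of SUV (unitless).
#' @export
suv_image <- function(activity, meta) {
  stopifnot(inherits(activity, "volume"), inherits(meta, "pet_meta"))
  if (any(activity$data < 0, na.rm = TRUE))
    stop("activity must be non-negative", call. = FALSE)
  out <- activity
  out$data <- activity$data / (meta$injected_dose / meta$body_weight)
  out$units <- "SUV"
  out
}

#' SUV ratio image against the cerebellar reference
#'
#' Divides the SUV image by its mean over the reference ROI, so the
#' reference ROI mean of the output is 1 by construction.
#'
#' @param suv A [volume()] from [suv_image()] (any intensity image works;
#'   the operation is a pure normalisation).
#' @param mask A [roi_mask()] containing the reference ROI.
#' @param reference_roi Reference ROI name, default `"cerebellum"`.
#' @return A [volume()] with units `"SUVR"`.
#' @export
suvr_image <- function(suv, mask, reference_roi = "cerebellum") {
  stopifnot(inherits(suv, "volume"), inherits(mask, "roi_mask"))
  ref <- mean(suv$data[resolve_roi(mask, reference_roi)], na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0)
    stop("reference ('", reference_roi, "') mean must be positive",
         call. = FALSE)
  out <- suv
  out$data <- suv$data / ref
  out$units <- "SUVR"
  out
}

#' Global cortical SUVR
#'
#' Mean SUVR over the designated global cortical ROI — the scalar fed to
#' the centiloid transform.
#'
#' @param suvr A [volume()] from [suvr_image()].
#' @param mask A [roi_mask()].
#' @param cortical_roi Cortical target ROI name, default `"cortex"`.
#' @return Scalar mean SUVR.
#' @export
global_cortical_suvr <- function(suvr, mask, cortical_roi = "cortex") {
  stopifnot(inherits(suvr, "volume"), inherits(mask, "roi_mask"))
  vals <- suvr$data[resolve_roi(mask, cortical_roi)]
  vals <- vals[is.finite(vals)]
  if (!length(vals))
    stop("cortical ROI '", cortical_roi, "' has no valid voxels",
         call. = FALSE)
  mean(vals)
}

#' Centiloid transform
#'
#' `CL = 100 * (SUVR - SUVR_yc) / (SUVR_ad100 - SUVR_yc)`. The transform
#' is affine in SUVR and open-ended: values outside `[0, 100]` are legal.
#'
#' @param global_suvr Scalar global cortical SUVR.
#' @param anchors A [centiloid_anchors()].
#' @return Scalar centiloid value.
#' @export
centiloid <- function(global_suvr, anchors) {
  stopifnot(inherits(anchors, "centiloid_anchors"))
  100 * (global_suvr - anchors$suvr_yc) /
    (anchors$suvr_ad100 - anchors$suvr_yc)
}

#' PET quantification driver
#'
#' Activity volume to one summary row: cortical mean SUV, cerebellar mean
#' SUV, global cortical SUVR, centiloid.
#'
#' @param activity 3-D [volume()] in kBq/mL.
#' @param meta A [pet_meta()].
#' @param mask A [roi_mask()] with reference and cortical ROIs.
#' @param anchors A [centiloid_anchors()].
#' @param cortical_roi,reference_roi ROI names.
#' @param subject Optional subject id.
#' @return One-row data frame: `subject`, `suv_cortex`, `suv_cerebellum`,
#'   `global_suvr`, `centiloid`.
#' @export
quantify_pet <- function(activity, meta, mask, anchors,
                         cortical_roi = "cortex",
                         reference_roi = "cerebellum",
                         subject = NA_character_) {
  suv <- suv_image(activity, meta)
  suvr <- suvr_image(suv, mask, reference_roi)
  gs <- global_cortical_suvr(suvr, mask, cortical_roi)
  data.frame(subject = subject,
             suv_cortex = mean(suv$data[resolve_roi(mask, cortical_roi)]),
             suv_cerebellum = mean(suv$data[resolve_roi(mask,
                                                        reference_roi)]),
             global_suvr = gs,
             centiloid = centiloid(gs, anchors))
}
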