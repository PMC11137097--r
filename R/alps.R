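# The DTI-ALPS index.
#
# At the lateral-ventricle-body level the perivascular spaces run along x,
# projection fibres along z and association fibres along y. Diffusivity
# along x in the projection and association areas therefore reflects
# perivascular water movement unobstructed by the dominant fibres, and the
# index is the ratio of those x diffusivities to the diffusivities
# perpendicular to both fibres and perivascular spaces:
#
#   ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
#
# An index near 1 indicates minimal perivascular diffusion; it rises as
# perivascular diffusivity increases. The subcortical ROI is extracted for
# completeness but never enters the index, because subcortical fibres run
# parallel to the perivascular spaces and their diffusivity does not
# isolate perivascular water.

#' ROI-mean axis diffusivities for one hemisphere
#'
#' Averages each axis diffusivity map over the projection, association
#' and (when present) subcortical ROIs of one hemisphere, excluding
#' invalid (`NA`) voxels.
#'
#' @param maps Named list of `Dxx`, `Dyy`, `Dzz` [volume()]s, as returned
#'   by [axis_diffusivities()].
#' @param mask A [roi_mask()] with ROIs named `proj_L`, `assoc_L`,
#'   `subc_L` (and `_R` counterparts); `subc` is optional.
#' @param hemisphere `"L"` or `"R"`.
#' @param shell Nominal shell b-value to record.
#' @return An object of class `alps_roi_diffusivities`: the nine ROI-mean
#'   diffusivities (`Dxx/Dyy/Dzz` x `proj/assoc/subc`, subcortical `NA`
#'   when the ROI is absent), plus `hemisphere` and `b`.
#' @export
roi_mean_diffusivities <- function(maps, mask, hemisphere = c("L", "R"),
                                   shell = NA_real_) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(mask, "roi_mask"),
            all(c("Dxx", "Dyy", "Dzz") %in% names(maps)))
  out <- list()
  for (zone in c("proj", "assoc", "subc")) {
    nm <- paste0(zone, "_", hemisphere)
    if (zone == "subc" && !nm %in% roi_names(mask)) {
      out[paste0(c("Dxx_", "Dyy_", "Dzz_"), zone)] <- NA_real_
      next
    }
    idx <- resolve_roi(mask, nm)
    for (ax in c("Dxx", "Dyy", "Dzz")) {
      vals <- maps[[ax]]$data[idx]
      vals <- vals[is.finite(vals)]
      if (!length(vals))
        stop("ROI '", nm, "' has no valid voxels after masking",
             call. = FALSE)
      out[[paste0(ax, "_", zone)]] <- mean(vals)
    }
  }
  structure(c(out, list(hemisphere = hemisphere, b = shell)),
            class = "alps_roi_diffusivities")
}

#' The ALPS index
#'
#' `mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`. The carried
#' subcortical means and `Dyy_assoc`/`Dzz_proj` do not enter the ratio.
#' The index is invariant under uniform positive scaling of all
#' diffusivities and equals 1 when the four inputs are equal.
#'
#' @param d An [roi_mean_diffusivities()] result (or any list with the
#'   four required fields).
#' @return The scalar index.
#' @export
alps_index <- function(d) {
  num <- c(d$Dxx_proj, d$Dxx_assoc)
  den <- c(d$Dyy_proj, d$Dzz_assoc)
  if (any(!is.finite(c(num, den))) || any(c(num, den) < 0))
    stop("ALPS inputs must be finite and non-negative", call. = FALSE)
  if (mean(den) <= 0)
    stop("ALPS denominator mean(Dyy_proj, Dzz_assoc) must be positive",
         call. = FALSE)
  mean(num) / mean(den)
}

#' Hemispheric ALPS computation
#'
#' @inheritParams roi_mean_diffusivities
#' @return A list of class `alps_hemisphere`: `diffusivities`, `index`,
#'   `hemisphere`, `b`.
#' @export
hemisphere_alps <- function(maps, mask, hemisphere = c("L", "R"),
                            shell = NA_real_) {
  d <- roi_mean_diffusivities(maps, mask, hemisphere, shell)
  structure(list(diffusivities = d, index = alps_index(d),
                 hemisphere = d$hemisphere, b = shell),
            class = "alps_hemisphere")
}

#' Subject-level ALPS index
#'
#' The hemispheric indexes are computed first and then averaged (one
#' index per hemisphere, arithmetic mean per participant) — not pooled
#' ROI means followed by a single ratio.
#'
#' @param left,right [hemisphere_alps()] results on the same shell.
#' @return A list of class `alps_result`: `left`, `right` (hemispheric
#'   indexes), `index` (their mean), `b`.
#' @export
subject_alps <- function(left, right) {
  stopifnot(inherits(left, "alps_hemisphere"),
            inherits(right, "alps_hemisphere"))
  if (!identical(left$b, right$b))
    stop("shell mismatch between hemispheres: ", left$b, " vs ", right$b,
         call. = FALSE)
  structure(list(left = left$index, right = right$index,
                 index = mean(c(left$index, right$index)), b = left$b),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result> b=%s: L %.4f, R %.4f, subject %.4f\n",
              format(x$b), x$left, x$right, x$index))
  invisible(x)
}

#' End-to-end ALPS computation from a DWI series
#'
#' Splits the series into shells, fits tensors per shell (b0 + one shell
#' at a time), derives the axis diffusivity maps and computes hemispheric
#' and subject ALPS indexes per shell.
#'
#' @param dwi 4-D [volume()].
#' @param table Matching [gradient_table()].
#' @param mask [roi_mask()] with the bilateral `proj`/`assoc` (and
#'   optionally `subc`) ROIs.
#' @param fit_mask Optional mask passed to [fit_tensor()]; defaults to
#'   the labelled voxels of `mask` (the index only reads ROI voxels).
#' @param subject Optional subject id recorded in the output.
#' @return A data frame, one row per shell: subject, shell `b`, left /
#'   right / subject index, and the nine hemisphere-averaged ROI
#'   diffusivities. Attribute `"results"` holds the underlying
#'   [subject_alps()] objects.
#' @export
compute_alps <- function(dwi, table, mask, fit_mask = NULL,
                         subject = NA_character_) {
  stopifnot(inherits(mask, "roi_mask"))
  if (is.null(fit_mask)) fit_mask <- mask$labels > 0L
  shells <- split_shells(dwi, table)
  rows <- list(); results <- list()
  for (nm in names(shells)) {
    sh <- shells[[nm]]
    field <- fit_tensor(sh$dwi, sh$table, mask = fit_mask, shell = sh$b)
    maps <- axis_diffusivities(field)
    hl <- hemisphere_alps(maps, mask, "L", shell = sh$b)
    hr <- hemisphere_alps(maps, mask, "R", shell = sh$b)
    res <- subject_alps(hl, hr)
    results[[nm]] <- res
    dmean <- function(fld) mean(c(hl$diffusivities[[fld]],
                                  hr$diffusivities[[fld]]))
    fields <- as.vector(outer(c("Dxx_", "Dyy_", "Dzz_"),
                              c("proj", "assoc", "subc"), paste0))
    rows[[nm]] <- data.frame(subject = subject, b = sh$b,
                             alps_L = res$left, alps_R = res$right,
                             alps = res$index,
                             as.list(stats::setNames(vapply(fields, dmean,
                                                            numeric(1)),
                                                     fields)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
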