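# End-to-end orchestration: simulate -> fit -> ALPS -> PET quant -> stats,
# driven by a YAML scenario, with a manifest of output hashes for
# reproducibility checks. Outputs use uncompressed .nii so that file
# hashes are identical across reruns with the same seed.

#' Validate a pipeline scenario configuration
#'
#' Reads a YAML scenario (or takes a list), checks keys and ranges, and
#' fills unstated entries from the shipped default scenario
#' (`system.file("extdata", "default_scenario.yaml", package =
#' "glymalps")`). Unknown top-level keys are an error, named in the
#' message.
#'
#' @param config Path to a YAML file, or a list; `NULL` uses the shipped
#'   defaults unchanged.
#' @return An object of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  # modifyList-style merge that *replaces* unnamed lists (e.g. the
  # imaging_subjects array) instead of ignoring them
  merge_config <- function(base, override) {
    for (nm in names(override)) {
      b <- base[[nm]]; o <- override[[nm]]
      base[[nm]] <- if (is.list(b) && is.list(o) &&
                        !is.null(names(o)) && all(nzchar(names(o))))
        merge_config(b, o) else o
    }
    base
  }
  defaults <- yaml::read_yaml(system.file("extdata",
                                          "default_scenario.yaml",
                                          package = "glymalps"))
  cfg <- if (is.null(config)) defaults
         else if (is.character(config)) {
           if (!file.exists(config)) stop("config file not found: ", config,
                                          call. = FALSE)
           merge_config(defaults, yaml::read_yaml(config))
         } else merge_config(defaults, config)
  known <- names(defaults)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) ||
      cfg$seed != round(cfg$seed))
    stop("config key 'seed' must be an integer", call. = FALSE)
  if (!is.numeric(cfg$dwi$snr) || cfg$dwi$snr <= 0)
    stop("config key 'dwi.snr' must be positive", call. = FALSE)
  if (!is.numeric(cfg$dwi$S0) || cfg$dwi$S0 <= 0)
    stop("config key 'dwi.S0' must be positive", call. = FALSE)
  if (cfg$protocol$n_dirs < 6)
    stop("config key 'protocol.n_dirs' must be >= 6", call. = FALSE)
  if (any(unlist(cfg$protocol$bvalues) <= 0))
    stop("config key 'protocol.bvalues' must be positive", call. = FALSE)
  for (s in cfg$imaging_subjects)
    if (is.null(s$id) || is.null(s$pv_gain) || s$pv_gain < 0)
      stop("each imaging subject needs an 'id' and a 'pv_gain' >= 0",
           call. = FALSE)
  structure(cfg, class = "run_config")
}

stage_seed <- function(base, offset) as.integer((base + offset) %% .Machine$integer.max)

#' Run the full pipeline
#'
#' Executes the stages in dependency order — `simulate` (phantom DWI per
#' imaging subject, ROI mask, cohort table), `fit_alps` (per-shell tensor
#' fits and ALPS indexes), `pet_quant` (SUVR simulation and centiloid
#' quantification), `stats` (group summary, regression and
#' normalized-slope tables) — and writes a `manifest.json` recording the
#' seed, package version and an MD5 hash of every output file. Identical
#' config and seed reproduce identical hashes. A stage failure leaves a
#' `FAILED` marker naming the stage and rethrows the error.
#'
#' @param config A [validate_config()] result, a YAML path, a list, or
#'   `NULL` for the shipped default scenario.
#' @param output_dir Overrides the config's output directory.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out_dir <- if (is.null(output_dir)) cfg$output_dir else output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(path) files[[basename(path)]] <<- path
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      writeLines(paste0("stage '", name, "': ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- as.integer(cfg$seed)
  scheme <- make_gradient_scheme(cfg$protocol$n_dirs,
                                 unlist(cfg$protocol$bvalues),
                                 cfg$protocol$n_b0)
  anchors <- centiloid_anchors(cfg$anchors$suvr_yc, cfg$anchors$suvr_ad100)
  phantoms <- list()

  run_stage("simulate", function() {
    bv <- file.path(out_dir, "protocol.bval")
    bc <- file.path(out_dir, "protocol.bvec")
    write_gradient_table(scheme, bv, bc); emit(bv); emit(bc)
    for (i in seq_along(cfg$imaging_subjects)) {
      subj <- cfg$imaging_subjects[[i]]
      spec <- phantom_spec(shape = unlist(cfg$phantom$shape),
                           spacing = unlist(cfg$phantom$spacing),
                           pv_gain = subj$pv_gain, S0 = cfg$dwi$S0,
                           snr = cfg$dwi$snr)
      ph <- make_tensor_phantom(spec)
      phantoms[[subj$id]] <<- ph
      dwi <- simulate_dwi(ph$field, scheme, snr = cfg$dwi$snr,
                          seed = stage_seed(seed, 1000L * i))
      p <- file.path(out_dir, paste0("dwi_", subj$id, ".nii"))
      write_volume(dwi, p); emit(p)
      if (i == 1L) {
        lp <- file.path(out_dir, "roi_labels.nii")
        gp <- file.path(out_dir, "roi_legend.json")
        write_roi_mask(ph$mask, lp, gp); emit(lp); emit(gp)
      }
    }
    cohort <- simulate_cohort(cohort_spec(cfg$cohort),
                              seed = stage_seed(seed, 1L),
                              verbose = FALSE)
    cp <- file.path(out_dir, "cohort.tsv")
    utils::write.table(cohort, cp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(cp)
  })

  run_stage("fit_alps", function() {
    mask <- phantoms[[1L]]$mask
    rows <- lapply(names(phantoms), function(id) {
      dwi <- read_volume(file.path(out_dir, paste0("dwi_", id, ".nii")))
      compute_alps(dwi, scheme, mask, subject = id)
    })
    ap <- file.path(out_dir, "alps.tsv")
    utils::write.table(do.call(rbind, rows), ap, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(ap)
  })

  run_stage("pet_quant", function() {
    mask <- phantoms[[1L]]$mask
    meta <- pet_meta(cfg$pet$injected_dose, cfg$pet$body_weight)
    rows <- lapply(cfg$imaging_subjects, function(subj) {
      suvr <- simulate_pet_suvr(mask, subj$target_centiloid, anchors,
                                background = cfg$pet$background)
      sp <- file.path(out_dir, paste0("suvr_", subj$id, ".nii"))
      write_volume(suvr, sp); emit(sp)
      # activity consistent with the SUVR map and the metadata, so the
      # quantification path (SUV -> SUVR -> centiloid) is exercised fully
      act <- suvr
      act$data <- suvr$data * (meta$injected_dose / meta$body_weight)
      act$units <- "kBq/mL"
      quantify_pet(act, meta, mask, anchors, subject = subj$id)
    })
    pp <- file.path(out_dir, "pet.tsv")
    utils::write.table(do.call(rbind, rows), pp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(pp)
  })

  run_stage("stats", function() {
    cohort <- utils::read.table(file.path(out_dir, "cohort.tsv"),
                                header = TRUE, sep = "\t")
    cohort$group <- factor(cohort$group, levels = c("CN", "AD"))
    t1 <- group_summary_table(cohort)
    t2 <- regression_table(cohort)
    t4 <- normalized_slope_analysis(
      cohort, vsrad_denominator = cfg$stats$vsrad_denominator)
    for (nm in c("group_summary", "regressions",
                 "normalized_slopes")) {
      obj <- switch(nm, group_summary = t1,
                    regressions = t2,
                    normalized_slopes = t4)
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      utils::write.table(obj, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit(p)
    }
    kp <- file.path(out_dir, "normalization_constants.json")
    jsonlite::write_json(attr(t4, "constants"), kp, auto_unbox = TRUE,
                         digits = NA)
    emit(kp)
  })

  files <- files[order(names(files))]
  manifest <- list(
    package = "glymalps",
    version = as.character(utils::packageVersion("glymalps")),
    seed = seed,
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
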