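# Synthetic CN/AD biomarker cohorts.
#
# Generative direction: amyloid burden (centiloid) is the exogenous stage
# variable, drawn per group from a normal distribution; the ALPS indexes
# are generated from centiloid through the configured linear links; MMSE
# and VSRAD are then generated from ALPS(b=1000) by inverting their links.
# Residual SDs are chosen so that the *all-subject* Pearson correlation of
# each pair matches the configured r:
#
#   sigma_res = |slope| * SD(x over all subjects) * sqrt(1/r^2 - 1)
#
# where SD(x) is the analytic two-group mixture SD. What the generator
# reproduces is the correlation structure, not any causal claim.

#' Cohort simulation specification
#'
#' Defaults are loaded from the shipped configuration
#' (`system.file("extdata", "cohort_defaults.yaml", package =
#' "glymalps")`); any top-level entry can be overridden.
#'
#' @param config Path to a YAML file with the same structure as the
#'   shipped defaults, or a list; `NULL` uses the shipped file.
#' @param ... Named top-level overrides (e.g. `groups =
#'   list(n_cn = 10, n_ad = 20)`), merged recursively over the config.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(config = NULL, ...) {
  spec <- yaml::read_yaml(system.file("extdata", "cohort_defaults.yaml",
                                      package = "glymalps"))
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config) && length(config))
    spec <- utils::modifyList(spec, config)
  dots <- list(...)
  if (length(dots)) spec <- utils::modifyList(spec, dots)
  with(spec, {
    stopifnot(groups$n_cn >= 2, groups$n_ad >= 2)
    for (g in c("cn", "ad")) {
      if (centiloid[[g]]$sd <= 0) stop("centiloid SDs must be > 0",
                                       call. = FALSE)
      if (sex_m[[g]] < 0 || sex_m[[g]] > groups[[paste0("n_", g)]])
        stop("male count out of range for group ", g, call. = FALSE)
    }
    for (sh in names(links)) for (l in links[[sh]]) {
      if (abs(l$r) >= 1 || l$r == 0) stop("links need 0 < |r| < 1",
                                          call. = FALSE)
      if (l$slope == 0) stop("link slopes must be nonzero", call. = FALSE)
    }
  })
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d CN + %d AD; centiloid CN %.1f+-%.1f, AD %.1f+-%.1f\n",
              x$groups$n_cn, x$groups$n_ad,
              x$centiloid$cn$mean, x$centiloid$cn$sd,
              x$centiloid$ad$mean, x$centiloid$ad$sd))
  invisible(x)
}

# exact mean of round(clip(X, lo, hi)) for X ~ N(m, s), integer endpoints
clipped_rounded_normal_mean <- function(m, s, lo, hi) {
  k <- seq.int(lo, hi)
  upper <- stats::pnorm((k + 0.5 - m) / s)
  upper[length(k)] <- 1
  lower <- c(0, upper[-length(k)])
  sum(k * (upper - lower))
}

#' Analytic moments implied by a cohort specification
#'
#' Closed-form means/SDs the generator targets: the centiloid mixture
#' moments, residual SDs for every link, per-group ALPS means/SDs, the
#' all-subject ALPS SD, raw (pre-clipping) MMSE and VSRAD group moments,
#' and the exact expectation of the clipped-and-rounded MMSE per group.
#' Used by
#' the recovery tests and the acceptance analysis as the independent
#' oracle for what simulated cohorts should average to.
#'
#' @param spec A [cohort_spec()].
#' @return A nested list of moments.
#' @export
cohort_moments <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- c(cn = spec$groups$n_cn, ad = spec$groups$n_ad)
  w <- n / sum(n)
  mu <- c(cn = spec$centiloid$cn$mean, ad = spec$centiloid$ad$mean)
  sd <- c(cn = spec$centiloid$cn$sd, ad = spec$centiloid$ad$sd)
  mix_mean <- sum(w * mu)
  mix_var <- sum(w * (sd^2 + mu^2)) - mix_mean^2
  out <- list(centiloid = list(group_mean = mu, group_sd = sd,
                               mix_mean = mix_mean,
                               mix_sd = sqrt(mix_var)))
  for (sh in names(spec$links)) {
    lcl <- spec$links[[sh]]$centiloid
    s_res <- abs(lcl$slope) * sqrt(mix_var) * sqrt(1 / lcl$r^2 - 1)
    a_mean <- lcl$intercept + lcl$slope * mu
    a_sd <- sqrt(lcl$slope^2 * sd^2 + s_res^2)
    a_mix_var <- lcl$slope^2 * mix_var + s_res^2
    out[[sh]] <- list(sigma_res = s_res, group_mean = a_mean,
                      group_sd = a_sd, mix_sd = sqrt(a_mix_var))
  }
  # MMSE / VSRAD are generated from ALPS(b1000); their residual SDs make
  # the all-subject correlation with ALPS equal the configured r
  a <- out$alps_b1000
  for (bm in c("mmse", "vsrad")) {
    l <- spec$links$alps_b1000[[bm]]
    s_eps <- (a$mix_sd / abs(l$slope)) * sqrt(1 / l$r^2 - 1)
    raw_mean <- (a$group_mean - l$intercept) / l$slope
    raw_sd <- sqrt(a$group_sd^2 / l$slope^2 + s_eps^2)
    out[[bm]] <- list(sigma = s_eps, raw_group_mean = raw_mean,
                      raw_group_sd = raw_sd)
  }
  out$mmse$clipped_group_mean <- vapply(c("cn", "ad"), function(g)
    clipped_rounded_normal_mean(out$mmse$raw_group_mean[[g]],
                                out$mmse$raw_group_sd[[g]], 0, 30),
    numeric(1))
  out
}

#' Simulate a biomarker cohort
#'
#' Draws one CN/AD cohort with the spec's group sizes: per-group
#' centiloid, ALPS at both shells from the centiloid links, MMSE and
#' VSRAD from the ALPS(b=1000) links (see the generator notes in the
#' package vignette). MMSE is clipped to `[0, 30]` and rounded to
#' integers; the clipped fraction per group is reported in the
#' `"mmse_clip"` attribute (and via a message when `verbose = TRUE`)
#' because clipping attenuates the configured MMSE correlation rather
#' than being silently absorbed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the generator touches no global RNG state
#'   and is bit-reproducible for a fixed seed.
#' @param verbose Report the MMSE clipped fraction with a message.
#' @return A data frame of class `cohort_table` with columns `id`,
#'   `group` (factor CN/AD), `sex`, `age`, `MMSE`, `VSRAD`, `centiloid`,
#'   `ALPS_b1000`, `ALPS_b2000`. Attributes: `spec`, `moments`,
#'   `mmse_clip`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed,
                            verbose = interactive()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed) || is.null(seed))
    stop("'seed' is required: cohort simulation is stochastic",
         call. = FALSE)
  mom <- cohort_moments(spec)
  n_cn <- spec$groups$n_cn; n_ad <- spec$groups$n_ad
  n <- n_cn + n_ad
  group <- factor(rep(c("CN", "AD"), c(n_cn, n_ad)),
                  levels = c("CN", "AD"))
  tab <- withr::with_seed(as.integer(seed), {
    sex <- c(sample(rep(c("M", "F"), c(spec$sex_m$cn, n_cn - spec$sex_m$cn))),
             sample(rep(c("M", "F"), c(spec$sex_m$ad, n_ad - spec$sex_m$ad))))
    age <- c(stats::rnorm(n_cn, spec$age$cn$mean, spec$age$cn$sd),
             stats::rnorm(n_ad, spec$age$ad$mean, spec$age$ad$sd))
    cl <- c(stats::rnorm(n_cn, spec$centiloid$cn$mean, spec$centiloid$cn$sd),
            stats::rnorm(n_ad, spec$centiloid$ad$mean, spec$centiloid$ad$sd))
    l1 <- spec$links$alps_b1000$centiloid
    l2 <- spec$links$alps_b2000$centiloid
    alps1 <- l1$intercept + l1$slope * cl +
      stats::rnorm(n, 0, mom$alps_b1000$sigma_res)
    alps2 <- l2$intercept + l2$slope * cl +
      stats::rnorm(n, 0, mom$alps_b2000$sigma_res)
    lm_ <- spec$links$alps_b1000$mmse
    lv_ <- spec$links$alps_b1000$vsrad
    mmse_raw <- (alps1 - lm_$intercept) / lm_$slope +
      stats::rnorm(n, 0, mom$mmse$sigma)
    vsrad <- (alps1 - lv_$intercept) / lv_$slope +
      stats::rnorm(n, 0, mom$vsrad$sigma)
    list(sex = sex, age = age, cl = cl, alps1 = alps1, alps2 = alps2,
         mmse_raw = mmse_raw, vsrad = vsrad)
  })
  mmse <- as.integer(round(pmin(30, pmax(0, tab$mmse_raw))))
  clip <- tapply(tab$mmse_raw < 0 | tab$mmse_raw > 30, group, mean)
  if (verbose)
    message(sprintf(
      "MMSE clipped to [0, 30]: %.0f%% of CN and %.0f%% of AD values",
      100 * clip[["CN"]], 100 * clip[["AD"]]))
  out <- data.frame(id = sprintf("S%03d", seq_len(n)), group = group,
                    sex = tab$sex, age = tab$age, MMSE = mmse,
                    VSRAD = tab$vsrad, centiloid = tab$cl,
                    ALPS_b1000 = tab$alps1, ALPS_b2000 = tab$alps2)
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "spec") <- spec
  attr(out, "moments") <- mom
  attr(out, "mmse_clip") <- clip
  out
}
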