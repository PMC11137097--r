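# Biomarker statistics: VSRAD Z-score, 0-100 normalization of the
# biomarkers onto the centiloid-like scale, one-way ANOVA with Fisher's
# LSD post-hoc, and Pearson regression with confidence bands.

#' VSRAD atrophy Z-score
#'
#' `Z = (control mean - individual value) / control SD` for a
#' gray-matter ROI summary, so *larger* Z means more atrophy relative to
#' the normal database.
#'
#' @param individual_gm Individual gray-matter ROI summary value(s).
#' @param control_mean,control_sd Normal-database mean and SD;
#'   `control_sd` must be positive.
#' @return Z-score(s), same length as `individual_gm`.
#' @export
vsrad_z <- function(individual_gm, control_mean, control_sd) {
  if (!is.finite(control_sd) || control_sd <= 0)
    stop("'control_sd' must be positive", call. = FALSE)
  (control_mean - individual_gm) / control_sd
}

#' Normalize biomarkers onto a 0-100 scale
#'
#' Applies the three normalization equations, with cohort constants taken
#' over *all* subjects:
#' \deqn{nDTI\text{-}ALPS = (ALPS_{MAX} - ALPS)/(ALPS_{MAX} - 1) \times 100}
#' \deqn{nMMSE = (30 - MMSE)/30 \times 100}
#' \deqn{nVSRAD = (VSRAD - VSRAD_{MIN})/VSRAD_{MAX} \times 100}
#' All three increase with disease severity, like centiloid. The nVSRAD
#' denominator is `VSRAD_MAX` by default; note that this form only
#' reaches 100 at `VSRAD_MAX` when `VSRAD_MIN = 0` — set
#' `vsrad_denominator = "range"` for the `(VSRAD_MAX - VSRAD_MIN)`
#' variant.
#'
#' @param cohort A [simulate_cohort()] table or any data frame with
#'   `MMSE`, `VSRAD` and the ALPS column.
#' @param alps_col Which ALPS column to normalize, default
#'   `"ALPS_b1000"`.
#' @param vsrad_denominator `"max"` (as defined above) or `"range"`.
#' @return Data frame with `id`, `group`, `centiloid`, `nDTI_ALPS`,
#'   `nMMSE`, `nVSRAD`; attribute `"constants"` records `ALPS_MAX`,
#'   `VSRAD_MIN`, `VSRAD_MAX` and the denominator convention.
#' @export
normalize_biomarkers <- function(cohort, alps_col = "ALPS_b1000",
                                 vsrad_denominator = c("max", "range")) {
  vsrad_denominator <- match.arg(vsrad_denominator)
  need <- c("MMSE", "VSRAD", alps_col)
  if (!all(need %in% names(cohort)))
    stop("cohort lacks column(s): ",
         paste(setdiff(need, names(cohort)), collapse = ", "),
         call. = FALSE)
  alps <- cohort[[alps_col]]
  if (anyNA(alps) || anyNA(cohort$MMSE) || anyNA(cohort$VSRAD))
    stop("missing values in analyzed columns", call. = FALSE)
  alps_max <- max(alps)
  if (alps_max <= 1)
    stop("ALPS_MAX <= 1: nDTI-ALPS is undefined for this cohort",
         call. = FALSE)
  vmin <- min(cohort$VSRAD); vmax <- max(cohort$VSRAD)
  den <- if (vsrad_denominator == "max") vmax else vmax - vmin
  if (den == 0) stop("degenerate VSRAD denominator", call. = FALSE)
  out <- data.frame(
    id = if ("id" %in% names(cohort)) cohort$id else seq_len(nrow(cohort)),
    group = if ("group" %in% names(cohort)) cohort$group else NA,
    centiloid = if ("centiloid" %in% names(cohort)) cohort$centiloid else NA,
    nDTI_ALPS = (alps_max - alps) / (alps_max - 1) * 100,
    nMMSE = (30 - cohort$MMSE) / 30 * 100,
    nVSRAD = (cohort$VSRAD - vmin) / den * 100)
  attr(out, "constants") <- list(ALPS_MAX = alps_max, VSRAD_MIN = vmin,
                                 VSRAD_MAX = vmax,
                                 vsrad_denominator = vsrad_denominator)
  out
}

#' Group comparison: one-way ANOVA with Fisher's LSD post-hoc
#'
#' One-way ANOVA across groups followed by Fisher's LSD: pairwise t-tests
#' using the pooled ANOVA mean-square error on its residual degrees of
#' freedom, two-sided, with no multiplicity correction (that is what LSD
#' is). A fully degenerate column (zero total variance, i.e. identical
#' values everywhere) is reported as `F = 0, p = 1`.
#'
#' @param cohort Data frame.
#' @param column Name of the numeric column to compare.
#' @param group_col Grouping column (factor or character), default
#'   `"group"`.
#' @return An object of class `group_comparison`: per-group `summary`
#'   (n, mean, sd), `F`, `df`, `p`, and `lsd`, a data frame of pairwise
#'   differences with `t` and `p`.
#' @export
group_compare <- function(cohort, column, group_col = "group") {
  val <- cohort[[column]]
  grp <- factor(cohort[[group_col]])
  if (anyNA(val)) stop("missing values in '", column, "'", call. = FALSE)
  counts <- table(grp)
  if (any(counts < 2L))
    stop("each group needs at least 2 subjects", call. = FALSE)
  summ <- data.frame(group = levels(grp), n = as.integer(counts),
                     mean = as.numeric(tapply(val, grp, mean)),
                     sd = as.numeric(tapply(val, grp, sd)))
  k <- nlevels(grp); N <- length(val)
  if (stats::var(val) == 0) {
    fstat <- 0; p <- 1; mse <- 0; dfr <- N - k
  } else {
    fit <- stats::aov(val ~ grp)
    tab <- stats::anova(fit)
    fstat <- tab$`F value`[1L]; p <- tab$`Pr(>F)`[1L]
    mse <- tab$`Mean Sq`[2L]; dfr <- tab$Df[2L]
    if (!is.finite(fstat)) { fstat <- 0; p <- 1 }
  }
  pairs <- utils::combn(levels(grp), 2L)
  lsd <- do.call(rbind, apply(pairs, 2L, function(pr) {
    i <- summ$group == pr[1]; j <- summ$group == pr[2]
    d <- summ$mean[i] - summ$mean[j]
    se <- sqrt(mse * (1 / summ$n[i] + 1 / summ$n[j]))
    tt <- if (se > 0) d / se else if (d == 0) 0 else Inf * sign(d)
    pp <- if (se > 0) 2 * stats::pt(-abs(tt), dfr)
          else if (d == 0) 1 else 0
    data.frame(pair = paste(pr, collapse = " - "), diff = d, se = se,
               t = tt, p = pp)
  }))
  structure(list(column = column, summary = summ, F = fstat,
                 df = c(k - 1L, dfr), p = p, lsd = lsd, alpha = 0.05),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison of", x$column, "\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("ANOVA F(%d, %d) = %.4g, p = %.3g\n", x$df[1], x$df[2],
              x$F, x$p))
  invisible(x)
}

#' Group comparison for a categorical variable
#'
#' Pearson chi-square test of the group-by-category contingency table
#' (no continuity correction), as used for sex ratios.
#'
#' @inheritParams group_compare
#' @return List with `table`, `statistic`, `df`, `p`.
#' @export
group_compare_categorical <- function(cohort, column, group_col = "group") {
  tab <- table(cohort[[group_col]], cohort[[column]])
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson regression
#'
#' Ordinary least-squares line plus the Pearson correlation, with the
#' two-sided p-value from `t = r * sqrt((n - 2)/(1 - r^2))` on `n - 2`
#' degrees of freedom, and the ingredients of the pointwise confidence
#' band for the mean response.
#'
#' @param x Predictor vector (must have nonzero variance).
#' @param y Response vector, same length, `n >= 3`, all finite.
#' @param conf_level Confidence level for bands, default 0.95.
#' @return An object of class `pearson_regression`: `slope`, `intercept`,
#'   `r`, `p`, `n`, `se_slope`, `sigma` (residual SD), `x_mean`, `ssx`,
#'   `df`, `conf_level`.
#' @seealso [confidence_band()]
#' @export
pearson_regression <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in 'x' or 'y'", call. = FALSE)
  if (stats::var(x) == 0) stop("'x' has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- max(2 * stats::pt(-abs(tstat), n - 2), .Machine$double.xmin)
  sm <- suppressWarnings(summary(fit))  # exact fits are legitimate here
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 r = r, p = p, n = n,
                 se_slope = sm$coefficients[2L, 2L],
                 sigma = sm$sigma, x_mean = mean(x),
                 ssx = sum((x - mean(x))^2), df = n - 2L,
                 conf_level = conf_level),
            class = "pearson_regression")
}

#' @export
print.pearson_regression <- function(x, ...) {
  cat(sprintf(
    "Pearson regression (n = %d): y = %.4g + %.4g x, r = %.3f, p = %.3g\n",
    x$n, x$intercept, x$slope, x$r, x$p))
  invisible(x)
}

#' Pointwise confidence band for the mean response
#'
#' @param fit A [pearson_regression()] result.
#' @param newx Predictor values at which to evaluate the band.
#' @return Data frame `x`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(fit, newx) {
  stopifnot(inherits(fit, "pearson_regression"))
  yhat <- fit$intercept + fit$slope * newx
  se <- fit$sigma * sqrt(1 / fit$n + (newx - fit$x_mean)^2 / fit$ssx)
  tc <- stats::qt(1 - (1 - fit$conf_level) / 2, fit$df)
  data.frame(x = newx, fit = yhat, lwr = yhat - tc * se,
             upr = yhat + tc * se)
}

#' Regression summary across biomarker pairs
#'
#' Regresses each ALPS column on each clinical/imaging predictor
#' (ALPS as the response) and tabulates slope, intercept, r and p — the
#' per-shell regression summary of the analysis.
#'
#' @param cohort Cohort data frame.
#' @param predictors Predictor column names.
#' @param responses Response (ALPS) column names.
#' @return Data frame with one row per predictor-response pair.
#' @export
regression_table <- function(cohort,
                             predictors = c("MMSE", "centiloid", "VSRAD"),
                             responses = c("ALPS_b1000", "ALPS_b2000")) {
  rows <- list()
  for (resp in responses) for (pred in predictors) {
    f <- pearson_regression(cohort[[pred]], cohort[[resp]])
    rows[[paste(pred, resp)]] <- data.frame(
      predictor = pred, response = resp, slope = f$slope,
      intercept = f$intercept, r = f$r, p = f$p, n = f$n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Demographics and biomarker group summary
#'
#' Per-group mean +- SD with the ANOVA p-value for each continuous
#' variable and a chi-square p for the sex ratio — the cohort
#' characteristics table of the analysis.
#'
#' @param cohort Cohort data frame with `group` and `sex` columns.
#' @param variables Continuous columns to summarise.
#' @return Data frame `variable`, `CN`, `AD`, `p`; attribute `"tests"`
#'   holds the underlying [group_compare()] objects.
#' @export
group_summary_table <- function(cohort,
                                variables = c("age", "MMSE", "VSRAD",
                                              "centiloid", "ALPS_b1000",
                                              "ALPS_b2000")) {
  fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
  tests <- list()
  rows <- lapply(variables, function(v) {
    gc <- group_compare(cohort, v)
    tests[[v]] <<- gc
    s <- gc$summary
    data.frame(variable = v,
               CN = fmt(s$mean[s$group == "CN"], s$sd[s$group == "CN"]),
               AD = fmt(s$mean[s$group == "AD"], s$sd[s$group == "AD"]),
               p = gc$p)
  })
  sexes <- table(cohort$group, cohort$sex)
  sex_test <- group_compare_categorical(cohort, "sex")
  sex_row <- data.frame(
    variable = "M:F",
    CN = paste(sexes["CN", "M"], sexes["CN", "F"], sep = ":"),
    AD = paste(sexes["AD", "M"], sexes["AD", "F"], sep = ":"),
    p = sex_test$p)
  out <- rbind(rows[[1L]], sex_row, do.call(rbind, rows[-1L]))
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  attr(out, "sex_test") <- sex_test
  out
}

#' Normalized-slope comparison against centiloid
#'
#' Normalizes the three non-PET biomarkers with
#' [normalize_biomarkers()] and regresses each on centiloid, so their
#' rates of change per centiloid unit can be compared on a common 0-100
#' scale. Because the normalizations are affine, each |r| equals that of
#' the corresponding raw regression; only the slopes are rescaled (e.g.
#' the nDTI-ALPS slope is the raw ALPS-on-centiloid slope times
#' `-100/(ALPS_MAX - 1)`).
#'
#' @inheritParams normalize_biomarkers
#' @return Data frame with one row per normalized biomarker
#'   (`nDTI_ALPS`, `nVSRAD`, `nMMSE`): slope, intercept, r, p.
#'   Attributes `"constants"` (normalization constants) and `"fits"`
#'   (the [pearson_regression()] objects).
#' @export
normalized_slope_analysis <- function(cohort, alps_col = "ALPS_b1000",
                                      vsrad_denominator = c("max",
                                                            "range")) {
  norm <- normalize_biomarkers(cohort, alps_col = alps_col,
                               vsrad_denominator = vsrad_denominator)
  fits <- lapply(c(nDTI_ALPS = "nDTI_ALPS", nVSRAD = "nVSRAD",
                   nMMSE = "nMMSE"),
                 function(v) pearson_regression(norm$centiloid, norm[[v]]))
  out <- data.frame(biomarker = names(fits),
                    slope = vapply(fits, `[[`, numeric(1), "slope"),
                    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
                    r = vapply(fits, `[[`, numeric(1), "r"),
                    p = vapply(fits, `[[`, numeric(1), "p"))
  rownames(out) <- NULL
  attr(out, "constants") <- attr(norm, "constants")
  attr(out, "fits") <- fits
  out
}
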