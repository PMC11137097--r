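# Independent oracles and small fixtures used across the suite.

# Closed-form simple-regression statistics from covariance/variance
# ratios; deliberately independent of pearson_regression()'s lm() path.
closed_form_regression <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- sxy / sqrt(sxx * syy)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(slope = slope, intercept = intercept, r = r,
       p = 2 * pt(-abs(tstat), n - 2))
}

# Pooled-variance two-sample t statistic (for the F = t^2 identity).
pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Random symmetric positive-definite tensor with physiological
# diffusivities (eigenvalues in [0.3, 2.0] x 1e-3 mm^2/s).
random_spd_tensor <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  ev <- runif(3, 0.3e-3, 2.0e-3)
  d <- q %*% diag(ev) %*% t(q)
  c(d[1, 1], d[2, 2], d[3, 3], d[1, 2], d[1, 3], d[2, 3])
}

# Single-voxel tensor field from the 6-vector (Dxx,Dyy,Dzz,Dxy,Dxz,Dyz).
voxel_field <- function(comp, s0 = 100) {
  tensor_field(array(rep(comp, each = 1), c(1, 1, 1, 6)),
               s0 = array(s0, c(1, 1, 1)))
}

# Multi-voxel field from a matrix of 6-vectors (one row per voxel).
row_field <- function(comp_mat, s0 = 100) {
  n <- nrow(comp_mat)
  tensor_field(array(comp_mat, c(n, 1, 1, 6)),
               s0 = array(s0, c(n, 1, 1)))
}

# Small phantom for fast pipeline tests.
small_phantom_spec <- function(...) phantom_spec(shape = c(24, 24, 12), ...)

# Noncentral-F power oracle for the two-group ANOVA under the cohort
# generator's analytic group moments.
anova_power_oracle <- function(spec, alpha = 1e-5) {
  mom <- cohort_moments(spec)
  n1 <- spec$groups$n_cn; n2 <- spec$groups$n_ad
  m <- mom$alps_b1000$group_mean; s <- mom$alps_b1000$group_sd
  sp2 <- ((n1 - 1) * s[1]^2 + (n2 - 1) * s[2]^2) / (n1 + n2 - 2)
  ncp <- (m[1] - m[2])^2 / (sp2 * (1 / n1 + 1 / n2))
  1 - pf(qf(1 - alpha, 1, n1 + n2 - 2), 1, n1 + n2 - 2, ncp = ncp)
}
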