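test_that("shell splitting pairs each shell with the shared b0 frames", {
  ph <- make_tensor_phantom(small_phantom_spec())
  scheme <- make_gradient_scheme(n_dirs = 30, bvalues = c(1000, 2000))
  dwi <- simulate_dwi(ph$field, scheme)
  shells <- split_shells(dwi, scheme)
  expect_named(shells, c("b1000", "b2000"))
  for (sh in shells) {
    expect_equal(n_frames(sh$dwi), 31L)
    expect_equal(sum(sh$table$bvals == 0), 1L)
  }
  # single-shell input passes through as one dataset
  one <- make_gradient_scheme(n_dirs = 8, bvalues = 1000)
  d1 <- simulate_dwi(ph$field, one)
  expect_length(split_shells(d1, one), 1L)
  # all-b0 input cannot be split
  b0 <- gradient_table(c(0, 0), matrix(0, 3, 2))
  d0 <- simulate_dwi(ph$field, b0)
  expect_error(split_shells(d0, b0), "no diffusion-weighted")
  expect_error(split_shells(dwi, one), "frames")
})

test_that("noiseless tensor fit inverts the forward model exactly", {
  withr::with_seed(101, {
    comp <- t(replicate(50, random_spd_tensor()))
  })
  field <- row_field(comp, s0 = 150)
  scheme <- make_gradient_scheme(n_dirs = 30, bvalues = 1000)
  dwi <- simulate_dwi(field, scheme)
  fit <- fit_tensor(dwi, scheme)
  est <- matrix(fit$components, 50, 6)
  scale <- max(abs(comp))
  expect_lt(max(abs(est - comp)) / scale, 1e-10)
  expect_equal(as.vector(fit$s0), rep(150, 50), tolerance = 1e-10)
  expect_true(all(fit$valid))
  expect_false(any(fit$flagged))
})

test_that("isotropic voxels fit to vanishing off-diagonal terms", {
  field <- voxel_field(c(1e-3, 1e-3, 1e-3, 0, 0, 0))
  scheme <- make_gradient_scheme(n_dirs = 12, bvalues = 1000)
  fit <- fit_tensor(simulate_dwi(field, scheme), scheme)
  expect_lt(max(abs(fit$components[1, 1, 1, 4:6])), 1e-10 * 1e-3)
})

test_that("a 90-degree rotation about z swaps the Dxx and Dyy maps", {
  withr::with_seed(55, d6 <- random_spd_tensor())
  D <- matrix(c(d6[1], d6[4], d6[5],
                d6[4], d6[2], d6[6],
                d6[5], d6[6], d6[3]), 3, 3)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Dr <- Rz %*% D %*% t(Rz)
  scheme <- make_gradient_scheme(n_dirs = 15, bvalues = 1000)
  fit_of <- function(M) {
    f <- voxel_field(c(M[1, 1], M[2, 2], M[3, 3],
                       M[1, 2], M[1, 3], M[2, 3]))
    fit_tensor(simulate_dwi(f, scheme), scheme)
  }
  maps <- axis_diffusivities(fit_of(D))
  maps_r <- axis_diffusivities(fit_of(Dr))
  expect_equal(maps_r$Dxx$data[1], maps$Dyy$data[1], tolerance = 1e-8)
  expect_equal(maps_r$Dyy$data[1], maps$Dxx$data[1], tolerance = 1e-8)
  expect_equal(maps_r$Dzz$data[1], maps$Dzz$data[1], tolerance = 1e-8)
})

test_that("axis diffusivities are frame diagonals, not eigenvalues", {
  comp <- c(1.0e-3, 1.0e-3, 0.5e-3, 0.4e-3, 0, 0)  # strong Dxy coupling
  scheme <- make_gradient_scheme(n_dirs = 15, bvalues = 1000)
  fit <- fit_tensor(simulate_dwi(voxel_field(comp), scheme), scheme)
  maps <- axis_diffusivities(fit)
  expect_equal(maps$Dxx$data[1], 1.0e-3, tolerance = 1e-8)
  D <- matrix(c(comp[1], comp[4], comp[5],
                comp[4], comp[2], comp[6],
                comp[5], comp[6], comp[3]), 3, 3)
  ev <- eigen(D, symmetric = TRUE)$values
  expect_gt(min(abs(maps$Dxx$data[1] - ev)), 1e-5)
})

test_that("rank-deficient and short designs are rejected", {
  field <- voxel_field(c(1e-3, 1e-3, 1e-3, 0, 0, 0))
  # seven frames but only one distinct direction: rank < 7
  gt <- gradient_table(c(0, rep(1000, 6)),
                       cbind(c(0, 0, 0),
                             matrix(rep(c(1, 0, 0), 6), 3)))
  expect_error(fit_tensor(simulate_dwi(field, gt), gt), "rank-deficient")
  gt5 <- gradient_table(c(0, rep(1000, 4)),
                        cbind(c(0, 0, 0), diag(3), c(1, 1, 1) / sqrt(3)))
  expect_error(fit_tensor(simulate_dwi(field, gt5), gt5), "at least 7")
})

test_that("noisy fits recover projection-zone Dxx within a few percent", {
  spec <- phantom_spec()
  ph <- make_tensor_phantom(spec)
  scheme <- make_gradient_scheme(n_dirs = 30, bvalues = 1000)
  proj <- c(resolve_roi(ph$mask, "proj_L"), resolve_roi(ph$mask, "proj_R"))
  true_dxx <- spec$diffusivities$proj[1] + spec$pv_gain
  med_err <- vapply(1:3, function(s) {
    dwi <- simulate_dwi(ph$field, scheme, snr = 30, seed = 300 + s)
    fit <- fit_tensor(dwi, scheme, mask = proj)
    dxx <- matrix(fit$components, prod(dim(ph$mask$labels)), 6)[proj, 1]
    median(abs(dxx - true_dxx) / true_dxx)
  }, numeric(1))
  expect_lt(mean(med_err), 0.05)
})

test_that("fitted projection Dxx rises with the perivascular gain", {
  gains <- c(0, 1e-4, 2e-4)
  scheme <- make_gradient_scheme(n_dirs = 30, bvalues = 1000)
  mean_dxx <- vapply(gains, function(g) {
    ph <- make_tensor_phantom(small_phantom_spec(pv_gain = g))
    proj <- c(resolve_roi(ph$mask, "proj_L"),
              resolve_roi(ph$mask, "proj_R"))
    mean(vapply(1:5, function(s) {
      dwi <- simulate_dwi(ph$field, scheme, snr = 30, seed = 900 + s)
      fit <- fit_tensor(dwi, scheme, mask = proj)
      mean(matrix(fit$components,
                  prod(dim(ph$mask$labels)), 6)[proj, 1])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dxx) > 0))
})
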