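test_that("phantom analytic ALPS follows the zone tensors", {
  # isotropic everywhere: the ratio degenerates to 1
  iso <- rep(0.8e-3, 3)
  spec_iso <- small_phantom_spec(
    diffusivities = list(proj = c(0.8e-3, 0.8e-3, 0.81e-3),
                         assoc = c(0.8e-3, 0.81e-3, 0.8e-3),
                         subc = c(0.81e-3, 0.8e-3, 0.8e-3),
                         background = iso, cerebellum = iso, cortex = iso),
    pv_gain = 0)
  expect_equal(make_tensor_phantom(spec_iso)$alps,
               0.8e-3 / 0.8e-3, tolerance = 1e-12)
  # direct arithmetic of the index from the zone tensors
  spec2 <- small_phantom_spec(
    diffusivities = list(proj = c(1.2e-3, 0.6e-3, 1.8e-3),
                         assoc = c(1.2e-3, 1.8e-3, 0.6e-3),
                         subc = c(1.6e-3, 0.7e-3, 0.7e-3),
                         background = iso, cerebellum = iso, cortex = iso),
    pv_gain = 0)
  expect_equal(make_tensor_phantom(spec2)$alps, 2.0, tolerance = 1e-12)
  # default CN-like setting
  expect_equal(make_tensor_phantom(phantom_spec())$alps, 1.44,
               tolerance = 1e-12)
})

test_that("analytic ALPS increases strictly with the perivascular gain", {
  gains <- c(0, 5e-5, 1e-4, 2e-4)
  alps <- vapply(gains, function(g)
    make_tensor_phantom(small_phantom_spec(pv_gain = g))$alps, numeric(1))
  expect_true(all(diff(alps) > 0))
})

test_that("phantom zones are disjoint, nonempty and axis-dominant", {
  ph <- make_tensor_phantom(phantom_spec())
  legend <- ph$mask$legend
  idx <- lapply(names(legend), resolve_roi, mask = ph$mask)
  expect_true(all(lengths(idx) > 0))
  expect_equal(length(unlist(idx)), length(unique(unlist(idx))))
  comp <- matrix(ph$field$components, prod(dim(ph$mask$labels)), 6)
  proj <- comp[resolve_roi(ph$mask, "proj_L"), 1:3, drop = FALSE]
  assoc <- comp[resolve_roi(ph$mask, "assoc_R"), 1:3, drop = FALSE]
  subc <- comp[resolve_roi(ph$mask, "subc_L"), 1:3, drop = FALSE]
  expect_true(all(max.col(proj) == 3))   # projection: z-dominant
  expect_true(all(max.col(assoc) == 2))  # association: y-dominant
  expect_true(all(max.col(subc) == 1))   # subcortical: x-dominant
  expect_error(phantom_spec(diffusivities = list(
    proj = c(1.8e-3, 0.6e-3, 1.2e-3),   # x-dominant projection: invalid
    assoc = c(1.2e-3, 1.8e-3, 0.6e-3), subc = c(1.6e-3, 0.7e-3, 0.7e-3),
    background = rep(0.8e-3, 3), cerebellum = rep(0.8e-3, 3),
    cortex = rep(0.8e-3, 3))), "z-dominant")
  expect_error(phantom_spec(shape = c(8, 8, 8)), "empty")
})

test_that("noiseless DWI matches the monoexponential forward model", {
  ph <- make_tensor_phantom(small_phantom_spec(S0 = 200))
  # b = 0 frame is constant S0
  gt0 <- gradient_table(0, cbind(c(0, 0, 0)))
  s <- simulate_dwi(ph$field, gt0)
  expect_equal(unique(as.vector(s$data)), 200)
  # isotropic D = 1e-3 at b = 1000 along any direction: S = S0 exp(-1)
  iso <- voxel_field(c(1e-3, 1e-3, 1e-3, 0, 0, 0), s0 = 200)
  dir <- c(1, 2, -1) / sqrt(6)
  s1 <- simulate_dwi(iso, gradient_table(1000, cbind(dir)))
  expect_equal(as.vector(s1$data), 200 * exp(-1), tolerance = 1e-12)
})

test_that("Rician noise is non-negative and matches the analytic mean", {
  comp <- array(rep(c(0.8e-3, 0.8e-3, 0.8e-3, 0, 0, 0),
                    each = 25 * 25 * 20), c(25, 25, 20, 6))
  field <- tensor_field(comp, s0 = array(100, c(25, 25, 20)))
  gt <- gradient_table(0, cbind(c(0, 0, 0)))
  noisy <- simulate_dwi(field, gt, snr = 30, seed = 11)
  expect_true(all(noisy$data >= 0))
  # >= 1e4 voxels: sample mean within 2% of the closed-form Rician mean
  expect_equal(mean(noisy$data), rician_mean(100, 100 / 30),
               tolerance = 0.02)
  # low-signal regime where the Rician mean departs strongly from nu
  expect_gt(rician_mean(1, 10), 10)  # noise floor dominates
  expect_equal(rician_mean(500, 0), 500)
})

test_that("DWI simulation is seed-reproducible and demands a seed", {
  ph <- make_tensor_phantom(small_phantom_spec())
  gt <- make_gradient_scheme(n_dirs = 6, bvalues = 1000)
  a <- simulate_dwi(ph$field, gt, snr = 20, seed = 42)
  b <- simulate_dwi(ph$field, gt, snr = 20, seed = 42)
  c_ <- simulate_dwi(ph$field, gt, snr = 20, seed = 43)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c_$data))
  expect_error(simulate_dwi(ph$field, gt, snr = 20), "seed")
})

test_that("cohort simulation is deterministic under a fixed seed", {
  spec <- cohort_spec()
  a <- simulate_cohort(spec, seed = 5, verbose = FALSE)
  b <- simulate_cohort(spec, seed = 5, verbose = FALSE)
  expect_identical(a, b)
  expect_false(identical(
    a$centiloid,
    simulate_cohort(spec, seed = 6, verbose = FALSE)$centiloid))
})

test_that("cohort tables honour the specified design", {
  coh <- simulate_cohort(cohort_spec(), seed = 3, verbose = FALSE)
  expect_equal(table(coh$group), table(factor(rep(c("CN", "AD"),
                                                  c(27, 56)),
                                              levels = c("CN", "AD"))))
  expect_equal(unname(table(coh$group, coh$sex)["CN", c("M", "F")]),
               c(11L, 16L))
  expect_equal(unname(table(coh$group, coh$sex)["AD", c("M", "F")]),
               c(28L, 28L))
  expect_true(all(coh$MMSE >= 0 & coh$MMSE <= 30))
  expect_true(all(coh$MMSE == round(coh$MMSE)))
  expect_named(attr(coh, "mmse_clip"), c("CN", "AD"))
  expect_error(simulate_cohort(cohort_spec()), "seed")
})

test_that("near-unit correlation collapses the residual scatter", {
  spec <- cohort_spec(links = list(alps_b1000 = list(
    centiloid = list(slope = -0.0018, intercept = 1.436, r = 0.999999))))
  coh <- simulate_cohort(spec, seed = 8, verbose = FALSE)
  resid <- coh$ALPS_b1000 - (1.436 - 0.0018 * coh$centiloid)
  expect_lt(max(abs(resid)), 1e-3)
})

test_that("the generator reproduces its configured AD-group ALPS mean", {
  spec <- cohort_spec()
  mom <- cohort_moments(spec)
  ad_means <- vapply(1:1000, function(s) {
    coh <- simulate_cohort(spec, seed = s, verbose = FALSE)
    mean(coh$ALPS_b1000[coh$group == "AD"])
  }, numeric(1))
  expect_equal(mean(ad_means), 1.29, tolerance = 0.01)
  expect_equal(mean(ad_means), unname(mom$alps_b1000$group_mean["ad"]),
               tolerance = 0.005)
})

test_that("simulated cohorts recover the configured correlation", {
  spec <- cohort_spec()
  rs <- vapply(1:200, function(s) {
    coh <- simulate_cohort(spec, seed = s, verbose = FALSE)
    abs(cor(coh$centiloid, coh$ALPS_b1000))
  }, numeric(1))
  expect_equal(mean(rs), 0.65, tolerance = 0.05)
})

test_that("simulated PET SUVR maps hit their centiloid target exactly", {
  ph <- make_tensor_phantom(small_phantom_spec())
  anchors <- centiloid_anchors()
  for (target in c(0, 50, 100, 78.5)) {
    suvr <- simulate_pet_suvr(ph$mask, target, anchors)
    expect_equal(mean(suvr$data[resolve_roi(ph$mask, "cerebellum")]), 1)
    got <- centiloid(global_cortical_suvr(suvr, ph$mask), anchors)
    expect_equal(got, target, tolerance = 1e-9)
  }
  # anchor endpoints map to the anchor SUVRs themselves
  s0 <- simulate_pet_suvr(ph$mask, 0, anchors)
  expect_equal(mean(s0$data[resolve_roi(ph$mask, "cortex")]),
               anchors$suvr_yc)
  s100 <- simulate_pet_suvr(ph$mask, 100, anchors)
  expect_equal(mean(s100$data[resolve_roi(ph$mask, "cortex")]),
               anchors$suvr_ad100)
})
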