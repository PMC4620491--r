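# the expressed Met- plus 40-residue amyloid-beta construct (41 residues)
AB40_SEQ <- "MDAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV"

test_that("sequence mass uses average residue masses plus one water", {
  expect_equal(sequence_mass("G"), 75.07, tolerance = 1e-4)
  expect_error(sequence_mass(""), "empty")
  expect_error(sequence_mass("AXZ"), "unknown residue")
  expect_equal(sequence_mass(AB40_SEQ), 4461, tolerance = 1 / 4461)
})

test_that("empirical Rh relations reproduce the reference predictions", {
  expect_equal(round(rh_empirical(N = 41, state = "F", basis = "length"), 1),
               13.9)
  expect_equal(round(rh_empirical(N = 41, state = "U", basis = "length"), 1),
               18.4)
  expect_equal(round(rh_empirical(M = 4461, state = "PMG")), 17)
  expect_equal(round(rh_empirical(M = 4461, state = "F"), 1), 12.6)
  expect_error(rh_empirical(N = 41, state = "PMG", basis = "length"),
               "not calibrated")
})

test_that("Rh relations are increasing in size with U > PMG > F", {
  M <- seq(3000, 100000, length.out = 40)
  f <- rh_empirical(M = M, state = "F")
  u <- rh_empirical(M = M, state = "U")
  p <- rh_empirical(M = M, state = "PMG")
  expect_true(all(diff(f) > 0) && all(diff(u) > 0) && all(diff(p) > 0))
  expect_true(all(u > p) && all(p > f))
  ## the length-basis power laws cross near N ~ 15; above that the
  ## unfolded chain is always larger
  N <- 20:400
  expect_true(all(rh_empirical(N = N, state = "U", basis = "length") >
                  rh_empirical(N = N, state = "F", basis = "length")))
})

test_that("SEC apparent-mass conversion gives ~16 A at 8.8 kDa and scales
           as a power law", {
  expect_equal(round(sec_rh_from_mmapp(8800)), 16)
  expect_gte(sec_rh_from_mmapp(4400), 12.4)
  expect_lte(sec_rh_from_mmapp(4400), 13.9)
  expect_equal(sec_rh_from_mmapp(2 * 5000) / sec_rh_from_mmapp(5000),
               2^0.357, tolerance = 1e-9)
})

test_that("compaction index is the affine map with CI(U)=0, CI(F)=1", {
  expect_equal(as.numeric(compaction_index(18.0, 18.0, 12.4)), 0)
  expect_equal(as.numeric(compaction_index(12.4, 18.0, 12.4)), 1)
  expect_equal(round(as.numeric(compaction_index(15.5, 18.0, 12.4)), 2),
               0.45)
  ci <- compaction_index(19.0, 18.0, 12.4)
  expect_true(attr(ci, "outside_range"))
  expect_error(compaction_index(15, 12, 14), "Rh_U > Rh_F")
  ## affine in Rh: constant slope
  rh <- seq(12.4, 18, by = 0.4)
  ci_v <- as.numeric(compaction_index(rh, 18.0, 12.4))
  expect_lt(max(abs(diff(diff(ci_v)))), 1e-12)
})

test_that("diffusion decay generation and fitting invert each other", {
  d0 <- make_diffusion_decay(D = 1.5e-10, I0 = 2, noise_sd = 0, seed = 1)
  expect_equal(d0$intensities[1] / 2,
               exp(-1.5e-10 * d0$gamma^2 * d0$gradients[1]^2 * d0$delta^2 *
                     (d0$Delta - d0$delta / 3)))
  ## zero gradient means intensity exactly I0
  dg0 <- make_diffusion_decay(D = 1.5e-10, I0 = 3, gradients = c(0, 0.1, 0.2, 0.3),
                              noise_sd = 0, seed = 1)
  expect_equal(dg0$intensities[1], 3)
  ## ln(I/I0) linear in g^2
  lin <- lm(log(d0$intensities / 2) ~ I(d0$gradients^2))
  expect_equal(unname(coef(lin)[2]),
               -1.5e-10 * d0$gamma^2 * d0$delta^2 * (d0$Delta - d0$delta / 3),
               tolerance = 1e-9)
  fit <- fit_diffusion(d0)
  expect_equal(fit$D, 1.5e-10, tolerance = 1e-6)
  expect_error(make_diffusion_decay(1e-10, noise_sd = -0.1), "non-negative")
  expect_error(fit_diffusion(list(gradients = c(0.1, 0.1),
                                  intensities = c(1, 1),
                                  delta = 4e-3, Delta = 0.1)),
               "at least 4")
})

test_that("noisy decays recover D within 2% across 100 seeds", {
  rel_err <- vapply(1:100, function(s) {
    dec <- make_diffusion_decay(D = 1.5e-10, noise_sd = 0.01, seed = s)
    abs(fit_diffusion(dec)$D - 1.5e-10) / 1.5e-10
  }, numeric(1))
  expect_lt(stats::quantile(rel_err, 0.95), 0.02)
})

test_that("Stokes-Einstein and internal-standard radii are consistent", {
  expect_equal(stokes_einstein_rh(1.545e-10, 298.15, 8.902e-4), 15.9,
               tolerance = 1e-2)
  expect_equal(stokes_einstein_rh(2 * 1e-10, 298.15, 8.902e-4),
               stokes_einstein_rh(1e-10, 298.15, 8.902e-4) / 2)
  expect_equal(internal_standard_rh(1e-10, 1e-10, 3.4), 3.4)
  expect_equal(internal_standard_rh(2e-10, 1e-10, 3.4), 6.8)
  ## closure: fitted sample and reference decays reproduce the ratio
  dr <- make_diffusion_decay(D = 8e-10, noise_sd = 0, seed = 1)
  ds <- make_diffusion_decay(D = 1.6e-10, noise_sd = 0, seed = 2)
  Dr <- fit_diffusion(dr)$D; Ds <- fit_diffusion(ds)$D
  expect_equal(internal_standard_rh(Dr, Ds, 3.0), 3.0 * 5, tolerance = 1e-4)
  ## and equals the Stokes-Einstein route when the reference radius is the
  ## Stokes-Einstein radius of the reference compound
  T <- 298.15; eta <- water_viscosity(25)
  rh_ref <- stokes_einstein_rh(Dr, T, eta)
  expect_equal(internal_standard_rh(Dr, Ds, rh_ref),
               stokes_einstein_rh(Ds, T, eta), tolerance = 1e-9)
})

test_that("mean residue ellipticity follows the MRW/(10 l C) formula", {
  expect_equal(mean_residue_ellipticity(0, 0.1, 0.0892, 4461, 41), 0)
  m1 <- mean_residue_ellipticity(-10, 0.1, 0.0892, 4461, 41)
  expect_equal(m1, -10 * (4461 / 40) / (10 * 0.1 * 0.0892),
               tolerance = 1e-12)
  expect_equal(m1, -1.25e4, tolerance = 0.01)
  expect_equal(mean_residue_ellipticity(-10, 0.1, 2 * 0.0892, 4461, 41),
               m1 / 2)
  expect_error(mean_residue_ellipticity(-10, 0.1, 0, 4461, 41), "positive")
})

test_that("percent change reports signed changes against the reference", {
  expect_equal(round(percent_change(c(16.9, 15.5), ref = 1)[2]), -8)
  expect_equal(percent_change(c(100, 100))[2], 0)
  expect_equal(percent_change(c(100, 65))[2], -35)
  expect_error(percent_change(c(0, 5)), "nonzero")
})

test_that("reversibility check compares heating and cooling curves", {
  h <- c(100, 80, 60, 40)
  expect_true(reversibility_check(h, h)$reversible)
  expect_equal(reversibility_check(h, h)$deviation, rep(0, 4))
  expect_false(reversibility_check(h, h * 0.5)$reversible)
  set.seed(9)
  noisy <- h * (1 + rnorm(4, 0, 0.02))
  expect_true(reversibility_check(h, noisy, tol = 0.1)$reversible)
  expect_error(reversibility_check(h, h[1:3]), "length")
})

test_that("water viscosity interpolates the handbook table", {
  expect_equal(water_viscosity(25), 8.902e-4, tolerance = 1e-6)
  expect_equal(water_viscosity(20), 1.002e-3, tolerance = 1e-6)
  expect_true(all(diff(water_viscosity(seq(0, 100, by = 2.5))) < 0))
  expect_error(water_viscosity(-5), "0-100")
})
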