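test_that("binning arithmetic assigns frames to the right hypercubes", {
  run <- manual_run(1, list(cv1 = c(0.1, 0.9, 1.1)))
  occ <- assign_microstates(list(run), binning_spec("cv1", 1.0))
  expect_equal(nrow(occ$bins), 2)
  expect_equal(sort(unname(rowSums(occ$counts))), c(1, 2))
  expect_equal(occ$dropped, 0)
})

test_that("t_eq discards exactly the pre-equilibration frames", {
  run <- manual_run(1, list(cv1 = runif(100, 0, 2)))
  occ0 <- assign_microstates(list(run), binning_spec("cv1", 0.5, t_eq = 0))
  occ50 <- assign_microstates(list(run), binning_spec("cv1", 0.5, t_eq = 50))
  expect_equal(sum(occ0$counts) - sum(occ50$counts), 50)
})

test_that("duplicated input doubles every occupancy, same microstates", {
  set.seed(2)
  run <- manual_run(1, list(cv1 = runif(200, 0, 3)))
  spec <- binning_spec("cv1", 0.5, ranges = list(c(0, 3)))
  occ1 <- assign_microstates(list(run), spec)
  occ2 <- assign_microstates(list(run, run), spec)
  expect_identical(occ1$bins$id, occ2$bins$id)
  expect_equal(rowSums(occ2$counts), 2 * rowSums(occ1$counts))
})

test_that("out-of-range frames are dropped and counted", {
  run <- manual_run(1, list(cv1 = c(0.5, 1.5, 2.5, 7.0)))
  occ <- assign_microstates(list(run),
                            binning_spec("cv1", 1, ranges = list(c(0, 3))))
  expect_equal(occ$dropped, 1)
  expect_equal(occ$n_retained, 3)
})

test_that("binning errors name the problem", {
  run <- manual_run(1, list(cv1 = 1:5 / 2))
  expect_error(assign_microstates(list(run), binning_spec("cv9", 1)), "cv9")
  expect_error(assign_microstates(list(run), binning_spec("cv1", 1, t_eq = 10)),
               "pre-t_eq")
})

test_that("single replica with zero bias reduces WHAM to the histogram
           estimator", {
  set.seed(5)
  x <- c(rnorm(4000, 1, 0.2), rnorm(1000, 2, 0.2))
  run <- manual_run(1, list(cv1 = x))
  spec <- binning_spec("cv1", 0.25, ranges = list(c(0, 3)))
  occ <- assign_microstates(list(run), spec)
  fes <- reconstruct_fes(occ, list(run), spec, kT = 2.9)
  n <- unname(rowSums(occ$counts))
  F_hist <- -2.9 * log(n); F_hist <- F_hist - min(F_hist)
  expect_equal(fes$microstates$F, F_hist, tolerance = 1e-6)
})

test_that("single replica with a bias matches the closed-form reweighting
           oracle at machine precision", {
  set.seed(6)
  x <- c(rnorm(4000, 1, 0.25), rnorm(2000, 2.2, 0.25))
  bias_fun <- function(s) 3 * sin(s) + 0.5 * s^2
  run <- manual_run(1, list(cv1 = x), bias_fun = bias_fun)
  spec <- binning_spec("cv1", 0.25, ranges = list(c(0, 3)))
  occ <- assign_microstates(list(run), spec)
  fes <- reconstruct_fes(occ, list(run), spec, kT = 2.9, tol = 1e-10)
  centers <- occ$bins$center_cv1
  oracle <- -2.9 * log(unname(rowSums(occ$counts))) - bias_fun(centers)
  oracle <- oracle - min(oracle)
  ## bias interpolation on a 0.05 grid vs analytic evaluation
  expect_equal(fes$microstates$F, oracle, tolerance = 1e-3)
})

test_that("adding a constant to every bias leaves the free energies
           unchanged (gauge invariance)", {
  L <- two_well_landscape(depths = c(8, 4))
  sch <- metad_schedule(t_eq = 1000)
  runs <- sample_biased_replicas(L, sch, 1, 6000, seed = 3)
  spec <- binning_spec("cv1", 0.3, t_eq = 1000)
  occ <- assign_microstates(runs, spec)
  fes1 <- reconstruct_fes(occ, runs, spec)
  runs2 <- runs
  runs2[[1]]$bias_grid$bias <- runs2[[1]]$bias_grid$bias + 37
  fes2 <- reconstruct_fes(occ, runs2, spec)
  expect_equal(fes1$microstates$F, fes2$microstates$F, tolerance = 1e-6)
})

test_that("two biased replicas recover a 5 kJ/mol basin difference", {
  L <- make_landscape(
    c("cv1", "cv2"),
    wells = list(list(center = c(1.5, 1.5), depth = 10, width = 0.4),
                 list(center = c(4.0, 4.0), depth = 5, width = 0.4)),
    domain = list(c(0, 5.5), c(0, 5.5)))
  sch <- metad_schedule(t_eq = 15000)
  runs <- sample_biased_replicas(L, sch, 2, 30000, seed = 1)
  spec <- binning_spec(c("cv1", "cv2"), 0.25, t_eq = 15000)
  occ <- assign_microstates(runs, spec)
  fes <- reconstruct_fes(occ, runs, spec)
  ms <- fes$microstates
  near <- function(cx, cy) which.min((ms$center_cv1 - cx)^2 +
                                     (ms$center_cv2 - cy)^2)
  dF <- ms$F[near(4, 4)] - ms$F[near(1.5, 1.5)]
  expect_equal(dF, 5, tolerance = 1)
})

test_that("frame conservation: retained + dropped = post-t_eq total", {
  run <- manual_run(1, list(cv1 = c(0.5, 1.5, 2.5, 7.0, 8.0)))
  occ <- assign_microstates(list(run),
                            binning_spec("cv1", 1, ranges = list(c(0, 3)),
                                         t_eq = 1))
  expect_equal(occ$n_retained + occ$dropped, 4)
})

test_that("block errors: duplicated blocks give zero, all errors are
           non-negative or unavailable", {
  set.seed(8)
  x <- rep(c(rnorm(500, 1, 0.3), rnorm(200, 2, 0.3)), 4)  # 4 identical blocks
  run <- manual_run(1, list(cv1 = x))
  spec <- binning_spec("cv1", 0.5, ranges = list(c(0, 3)))
  occ <- assign_microstates(list(run), spec)
  err <- estimate_errors(occ, list(run), spec, n_blocks = 4)
  expect_true(all(err[!is.na(err)] >= 0))
  expect_true(all(abs(err[!is.na(err)]) < 1e-8))
})

test_that("converged synthetic runs have small median block error below
           40 kJ/mol", {
  L <- two_well_landscape(depths = c(8, 4))
  sch <- metad_schedule(t_eq = 6000)
  runs <- sample_biased_replicas(L, sch, 1, 18000, seed = 2)
  spec <- binning_spec("cv1", 0.3, t_eq = 6000)
  occ <- assign_microstates(runs, spec)
  fes <- reconstruct_fes(occ, runs, spec)
  err <- estimate_errors(occ, runs, spec)
  sel <- fes$microstates$F < 40 & !is.na(err)
  expect_lte(median(err[sel]), 3)
})

test_that("refinement leaves homogeneous bins alone and splits bins that
           mix clusters in a non-binned CV", {
  ## cv2 bimodal within the single cv1 bin
  cv1 <- runif(400, 0.4, 0.6)
  cv2 <- c(rnorm(200, 0, 0.05), rnorm(200, 5, 0.05))
  run <- manual_run(1, list(cv1 = cv1, cv2 = cv2))
  spec <- binning_spec("cv1", 1, ranges = list(c(0, 1)))
  occ <- assign_microstates(list(run), spec)
  expect_equal(nrow(occ$bins), 1)
  ref <- refine_bins(occ, list(run), spec, spread_threshold = 1)
  expect_gte(nrow(ref$bins), 2)
  expect_equal(sum(ref$counts), sum(occ$counts))  # frames conserved
  ## homogeneous case: nothing splits
  run2 <- manual_run(1, list(cv1 = cv1, cv2 = rnorm(400, 1, 0.05)))
  occ2 <- assign_microstates(list(run2), spec)
  ref2 <- refine_bins(occ2, list(run2), spec, spread_threshold = 1)
  expect_equal(nrow(ref2$bins), 1)
})

test_that("reconstruction refuses replicas without retained frames", {
  r1 <- manual_run(1, list(cv1 = runif(50, 0, 2)))
  r2 <- manual_run(2, list(cv1 = runif(50, 4, 5)))
  spec <- binning_spec("cv1", 0.5, ranges = list(c(0, 2)))
  occ <- assign_microstates(list(r1, r2), spec)
  expect_error(reconstruct_fes(occ, list(r1, r2), spec),
               "at least one retained frame")
})
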