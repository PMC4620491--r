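#' Bias-exchange metadynamics schedule
#'
#' Bundles the deposition and exchange parameters of a bias-exchange
#' metadynamics run. Defaults mirror a standard peptide setup: Gaussians of
#' height 0.30 kJ/mol deposited every 5 steps, bias exchanges attempted
#' every 20 steps (one sampler step plays the role of 1 ps, so the strides
#' keep their familiar 5 ps / 20 ps values), with optional loose upper
#' walls implemented as half-harmonic potentials.
#'
#' @param gaussian_height Gaussian height w, kJ/mol.
#' @param gaussian_width Per-CV Gaussian width sigma (recycled).
#' @param deposition_stride Steps between depositions.
#' @param exchange_stride Steps between exchange attempts (multiple of the
#'   deposition stride).
#' @param wall_positions Per-CV upper bounds, or `NULL` for no walls.
#' @param wall_kappa Wall spring constant, kJ/mol per CV-unit^2.
#' @param t_eq Equilibration steps discarded from analysis.
#' @return An object of class `metad_schedule`.
#' @export
metad_schedule <- function(gaussian_height = 0.30, gaussian_width = 0.2,
                           deposition_stride = 5, exchange_stride = 20,
                           wall_positions = NULL, wall_kappa = 500,
                           t_eq = 0) {
  if (gaussian_height < 0) stop("gaussian_height must be >= 0")
  if (deposition_stride <= 0 || exchange_stride <= 0)
    stop("strides must be positive")
  if (exchange_stride %% deposition_stride != 0)
    stop("exchange_stride must be a multiple of deposition_stride")
  if (any(gaussian_width <= 0)) stop("gaussian_width must be positive")
  structure(
    list(gaussian_height = gaussian_height, gaussian_width = gaussian_width,
         deposition_stride = as.integer(deposition_stride),
         exchange_stride = as.integer(exchange_stride),
         wall_positions = wall_positions, wall_kappa = wall_kappa,
         t_eq = as.integer(t_eq)),
    class = "metad_schedule")
}

#' One replica of a bias-exchange run
#'
#' Container for a replica's CV time series and its one-dimensional bias
#' potential on a grid along its biased CV.
#'
#' @param id Replica identifier.
#' @param biased_cv Name of the CV this replica biases.
#' @param cv_table Data.frame with a `time` column plus one column per CV.
#' @param bias_grid Data.frame with columns `cv_value` (strictly
#'   increasing) and `bias` (kJ/mol).
#' @return An object of class `replica_run`.
#' @export
replica_run <- function(id, biased_cv, cv_table, bias_grid) {
  stopifnot(is.data.frame(cv_table), "time" %in% names(cv_table))
  stopifnot(is.data.frame(bias_grid),
            all(c("cv_value", "bias") %in% names(bias_grid)))
  if (any(diff(bias_grid$cv_value) <= 0))
    stop("bias grid must be strictly increasing in cv_value")
  structure(list(id = id, biased_cv = biased_cv, cv_table = cv_table,
                 bias_grid = bias_grid, frame_times = cv_table$time),
            class = "replica_run")
}

## linear interpolation on a uniform grid with linear extrapolation
.interp_grid <- function(gx, gy, x) {
  n <- length(gx)
  dg <- gx[2] - gx[1]
  pos <- (x - gx[1]) / dg
  i <- pmin(pmax(floor(pos), 0), n - 2)
  frac <- pos - i
  gy[i + 1] + frac * (gy[i + 2] - gy[i + 1])
}

## one deposited Gaussian, reflected at the CV domain boundaries so that
## the kernel mass falling outside the sampled interval is folded back in
## (prevents a self-reinforcing bias dip at the grid edges)
.deposit_kernel <- function(grid, center, sigma, lo, hi, height) {
  k <- function(c0) exp(-0.5 * ((grid - c0) / sigma)^2)
  height * (k(center) + k(2 * lo - center) + k(2 * hi - center))
}

.wall_energy <- function(s, walls, kappa) {
  if (is.null(walls)) return(0)
  over <- pmax(s - walls, 0)
  0.5 * kappa * sum(over^2)
}

#' Sample biased replicas on a toy landscape
#'
#' Runs a Metropolis random walk in CV space for `n_replicas` replicas,
#' replica k biased along CV k by a history-dependent metadynamics
#' potential (Gaussians deposited every `deposition_stride` steps on a
#' dense 1-D grid), with configuration swaps attempted between a random
#' replica pair every `exchange_stride` steps. The proposal step size is
#' tuned to a 30-50% acceptance rate during burn-in. Each returned
#' [replica_run()] carries, as its working bias, the time average of the
#' accumulated bias over the post-`t_eq` portion of the run (the final
#' instantaneous grid and the deposition log are kept as attributes
#' `final_bias` and `deposits`; swap records as `swaps`).
#'
#' @param landscape A [make_landscape()] object.
#' @param schedule A [metad_schedule()].
#' @param n_replicas Number of replicas (at most the number of CVs).
#' @param n_steps Number of sampler steps (must exceed `schedule$t_eq`).
#' @param seed Integer seed; identical seeds give identical output.
#' @param grid_points Number of points in each 1-D bias grid.
#' @return List of [replica_run()] objects.
#' @export
sample_biased_replicas <- function(landscape, schedule, n_replicas,
                                   n_steps, seed = 1, grid_points = 201) {
  stopifnot(inherits(landscape, "toy_landscape"),
            inherits(schedule, "metad_schedule"))
  d <- length(landscape$cv_names)
  if (n_replicas > d) stop("n_replicas must not exceed the number of CVs")
  if (n_steps <= schedule$t_eq) stop("no post-equilibration frames")
  set.seed(as.integer(seed))
  kT <- landscape$kT
  dom <- landscape$domain
  sig <- rep_len(schedule$gaussian_width, d)
  walls <- schedule$wall_positions
  if (!is.null(walls)) walls <- rep_len(walls, d)

  ## per-replica bias grids along the replica's own CV
  grids <- lapply(seq_len(n_replicas), function(k)
    seq(dom[1, k], dom[2, k], length.out = grid_points))
  bias <- lapply(seq_len(n_replicas), function(k) numeric(grid_points))
  bias_sum <- lapply(seq_len(n_replicas), function(k) numeric(grid_points))
  bias_n <- 0L
  n_dep <- n_steps %/% schedule$deposition_stride
  deposits <- lapply(seq_len(n_replicas), function(k)
    list(step = integer(n_dep), center = numeric(n_dep)))
  dep_i <- 0L

  ## state: one CV-space point per replica
  S <- matrix(stats::runif(n_replicas * d, dom[1, ], dom[2, ]),
              nrow = n_replicas, ncol = d, byrow = TRUE)
  Fcur <- landscape$F(S)
  Wcur <- vapply(seq_len(n_replicas), function(k)
    .wall_energy(S[k, ], walls, schedule$wall_kappa), numeric(1))
  Bcur <- vapply(seq_len(n_replicas), function(k)
    .interp_grid(grids[[k]], bias[[k]], S[k, k]), numeric(1))

  traj <- lapply(seq_len(n_replicas), function(k)
    matrix(NA_real_, nrow = n_steps, ncol = d))
  step_size <- rep(mean(sig), n_replicas)
  acc_win <- int_win <- rep(0L, n_replicas)
  acc_tot <- rep(0L, n_replicas)
  burn_in <- min(schedule$t_eq, n_steps)
  if (burn_in == 0L) burn_in <- min(2000L, n_steps)
  swaps <- list(step = integer(0), i = integer(0), j = integer(0),
                accepted = logical(0))

  for (t in seq_len(n_steps)) {
    for (k in seq_len(n_replicas)) {
      prop <- S[k, ] + stats::rnorm(d, 0, step_size[k])
      int_win[k] <- int_win[k] + 1L
      if (all(prop >= dom[1, ] & prop <= dom[2, ])) {
        Fp <- landscape$F(prop)
        Wp <- .wall_energy(prop, walls, schedule$wall_kappa)
        Bp <- .interp_grid(grids[[k]], bias[[k]], prop[k])
        dE <- (Fp + Wp + Bp) - (Fcur[k] + Wcur[k] + Bcur[k])
        if (dE <= 0 || stats::runif(1) < exp(-dE / kT)) {
          S[k, ] <- prop
          Fcur[k] <- Fp; Wcur[k] <- Wp; Bcur[k] <- Bp
          acc_win[k] <- acc_win[k] + 1L
          acc_tot[k] <- acc_tot[k] + 1L
        }
      }
      traj[[k]][t, ] <- S[k, ]
    }
    ## step-size tuning during burn-in
    if (t <= burn_in && t %% 200L == 0L) {
      rate <- acc_win / pmax(int_win, 1L)
      step_size <- step_size * ifelse(rate > 0.5, 1.25,
                                      ifelse(rate < 0.3, 0.8, 1))
      acc_win[] <- 0L; int_win[] <- 0L
    }
    ## deposition
    if (t %% schedule$deposition_stride == 0L) {
      dep_i <- dep_i + 1L
      for (k in seq_len(n_replicas)) {
        if (schedule$gaussian_height > 0) {
          ctr <- S[k, k]
          bias[[k]] <- bias[[k]] + .deposit_kernel(grids[[k]], ctr, sig[k],
                                                  dom[1, k], dom[2, k],
                                                  schedule$gaussian_height)
          deposits[[k]]$step[dep_i] <- t
          deposits[[k]]$center[dep_i] <- ctr
          Bcur[k] <- .interp_grid(grids[[k]], bias[[k]], S[k, k])
        }
      }
      if (t > schedule$t_eq) {
        for (k in seq_len(n_replicas)) bias_sum[[k]] <- bias_sum[[k]] + bias[[k]]
        bias_n <- bias_n + 1L
      }
    }
    ## bias exchange: swap configurations between a random pair
    if (n_replicas > 1 && t %% schedule$exchange_stride == 0L) {
      pair <- sample.int(n_replicas, 2L)
      i <- pair[1]; j <- pair[2]
      Bij <- .interp_grid(grids[[i]], bias[[i]], S[j, i])
      Bji <- .interp_grid(grids[[j]], bias[[j]], S[i, j])
      dE <- (Bij + Bji) - (Bcur[i] + Bcur[j])
      ok <- dE <= 0 || stats::runif(1) < exp(-dE / kT)
      if (ok) {
        tmp <- S[i, ]; S[i, ] <- S[j, ]; S[j, ] <- tmp
        tmpF <- Fcur[i]; Fcur[i] <- Fcur[j]; Fcur[j] <- tmpF
        tmpW <- Wcur[i]; Wcur[i] <- Wcur[j]; Wcur[j] <- tmpW
        Bcur[i] <- Bij; Bcur[j] <- Bji
      }
      swaps$step <- c(swaps$step, t)
      swaps$i <- c(swaps$i, i); swaps$j <- c(swaps$j, j)
      swaps$accepted <- c(swaps$accepted, ok)
    }
  }

  lapply(seq_len(n_replicas), function(k) {
    avg <- if (bias_n > 0) bias_sum[[k]] / bias_n else bias[[k]]
    tab <- data.frame(time = seq_len(n_steps), traj[[k]])
    names(tab) <- c("time", landscape$cv_names)
    run <- replica_run(
      id = k, biased_cv = landscape$cv_names[k], cv_table = tab,
      bias_grid = data.frame(cv_value = grids[[k]], bias = avg))
    attr(run, "final_bias") <- data.frame(cv_value = grids[[k]],
                                          bias = bias[[k]])
    dep <- as.data.frame(deposits[[k]])
    attr(run, "deposits") <- dep[dep$step > 0L, , drop = FALSE]
    attr(run, "swaps") <- as.data.frame(swaps)
    attr(run, "acceptance") <- acc_tot[k] / n_steps
    attr(run, "step_size") <- step_size[k]
    run
  })
}
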