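#' Microstate binning specification
#'
#' Defines the hypercube discretization of CV space: which CVs to bin on,
#' the per-CV bin width, optional explicit per-CV ranges (frames outside
#' are dropped and counted) and the equilibration time before which frames
#' are discarded. Default widths follow the per-CV Gaussian widths of the
#' biasing schedule.
#'
#' @param cvs Character vector of CV names used for binning.
#' @param widths Per-CV bin widths (recycled).
#' @param ranges Optional list of c(lo, hi) per CV; default: the observed
#'   data range.
#' @param t_eq Equilibration time (same units as the `time` column).
#' @return An object of class `binning_spec`.
#' @export
binning_spec <- function(cvs, widths, ranges = NULL, t_eq = 0) {
  stopifnot(length(cvs) >= 1, all(widths > 0), t_eq >= 0)
  widths <- rep_len(widths, length(cvs))
  if (!is.null(ranges)) {
    stopifnot(length(ranges) == length(cvs))
    for (r in ranges) stopifnot(length(r) == 2, r[2] > r[1])
  }
  structure(list(cvs = cvs, widths = widths, ranges = ranges, t_eq = t_eq),
            class = "binning_spec")
}

## membership of frame CV rows in a box (half-open on every axis)
.in_box <- function(X, lo, hi) {
  ok <- rep(TRUE, nrow(X))
  for (j in seq_along(lo)) ok <- ok & X[, j] >= lo[j] & X[, j] < hi[j]
  ok
}

#' Assign post-equilibration frames to CV-space microstates
#'
#' Discards frames with time <= `t_eq`, then maps every retained frame of
#' every replica to the hypercube containing its CV values. Only occupied
#' hypercubes are kept. Frames outside the binning ranges are dropped and
#' counted.
#'
#' @param runs List of [replica_run()] objects.
#' @param spec A [binning_spec()].
#' @return An object of class `microstate_occupancy`: `bins` (one row per
#'   occupied hypercube with per-CV `lo_`/`hi_`/`center_` columns),
#'   `counts` (microstates x replicas matrix n_k-alpha), `frames` (per
#'   replica, the retained in-range frames), `assign` (per replica, the
#'   bin row index of each such frame), `dropped` (out-of-range count).
#' @export
assign_microstates <- function(runs, spec) {
  stopifnot(length(runs) >= 1, inherits(spec, "binning_spec"))
  for (run in runs) {
    miss <- setdiff(spec$cvs, names(run$cv_table))
    if (length(miss))
      stop("replica ", run$id, " is missing CV column(s): ",
           paste(miss, collapse = ", "))
  }
  tmax <- max(vapply(runs, function(r) max(r$cv_table$time), numeric(1)))
  if (spec$t_eq >= tmax)
    stop("all frames are pre-t_eq: t_eq = ", spec$t_eq,
         " but the latest frame is at ", tmax)
  kept <- lapply(runs, function(r)
    r$cv_table[r$cv_table$time > spec$t_eq, , drop = FALSE])
  if (all(vapply(kept, nrow, integer(1)) == 0L))
    stop("all frames are pre-t_eq")

  d <- length(spec$cvs)
  ## binning origin and extent
  if (is.null(spec$ranges)) {
    lo <- vapply(seq_len(d), function(j)
      min(vapply(kept, function(k) min(k[[spec$cvs[j]]]), numeric(1))),
      numeric(1))
    hi <- vapply(seq_len(d), function(j)
      max(vapply(kept, function(k) max(k[[spec$cvs[j]]]), numeric(1))),
      numeric(1))
    hi <- hi + spec$widths * 1e-9  # make the max value fall inside
  } else {
    lo <- vapply(spec$ranges, `[`, numeric(1), 1)
    hi <- vapply(spec$ranges, `[`, numeric(1), 2)
  }

  frames <- vector("list", length(runs))
  keys <- vector("list", length(runs))
  dropped <- 0L
  for (k in seq_along(runs)) {
    X <- as.matrix(kept[[k]][, spec$cvs, drop = FALSE])
    idx <- matrix(0L, nrow(X), d)
    inside <- rep(TRUE, nrow(X))
    for (j in seq_len(d)) {
      idx[, j] <- as.integer(floor((X[, j] - lo[j]) / spec$widths[j]))
      inside <- inside & X[, j] >= lo[j] & X[, j] < hi[j]
    }
    dropped <- dropped + sum(!inside)
    frames[[k]] <- kept[[k]][inside, , drop = FALSE]
    keys[[k]] <- apply(idx[inside, , drop = FALSE], 1, paste, collapse = "_")
  }
  all_keys <- sort(unique(unlist(keys)))
  if (length(all_keys) == 0L) stop("no frames inside the binning ranges")
  counts <- vapply(seq_along(runs), function(k) {
    tab <- table(factor(keys[[k]], levels = all_keys))
    as.integer(tab)
  }, integer(length(all_keys)))
  counts <- matrix(counts, nrow = length(all_keys),
                   dimnames = list(all_keys, vapply(runs, function(r)
                     as.character(r$id), character(1))))
  idx_mat <- do.call(rbind, lapply(strsplit(all_keys, "_"), as.integer))
  bins <- data.frame(id = all_keys, stringsAsFactors = FALSE)
  for (j in seq_len(d)) {
    bins[[paste0("lo_", spec$cvs[j])]] <- lo[j] + idx_mat[, j] * spec$widths[j]
    bins[[paste0("hi_", spec$cvs[j])]] <- lo[j] + (idx_mat[, j] + 1) * spec$widths[j]
    bins[[paste0("center_", spec$cvs[j])]] <-
      lo[j] + (idx_mat[, j] + 0.5) * spec$widths[j]
  }
  assign <- lapply(keys, function(kk) match(kk, all_keys))
  structure(
    list(bins = bins, counts = counts, frames = frames, assign = assign,
         dropped = dropped, n_retained = sum(counts), spec = spec,
         origin = lo, extent = hi),
    class = "microstate_occupancy")
}

#' @export
print.microstate_occupancy <- function(x, ...) {
  cat(sprintf(
    "microstate_occupancy: %d microstates over (%s), %d frames retained, %d dropped\n",
    nrow(x$bins), paste(x$spec$cvs, collapse = ", "), x$n_retained, x$dropped))
  invisible(x)
}

## per-replica bias evaluated at every bin center along the replica's
## biased CV; warns when extrapolating beyond the supplied grid
.bias_at_bins <- function(occ, runs) {
  vapply(runs, function(run) {
    cv <- run$biased_cv
    col <- paste0("center_", cv)
    if (!col %in% names(occ$bins))
      stop("replica ", run$id, " is biased on '", cv,
           "', which is not a binning CV")
    x <- occ$bins[[col]]
    g <- run$bias_grid
    if (any(x < min(g$cv_value) | x > max(g$cv_value)))
      warning("bias grid of replica ", run$id,
              " does not cover all microstate centers; extrapolating")
    .interp_grid(g$cv_value, g$bias, x)
  }, numeric(nrow(occ$bins)))
}

## core self-consistent iteration of the multi-histogram equations
.wham_iterate <- function(counts, V, kT, tol, max_iter) {
  n_alpha <- rowSums(counts)
  N_k <- colSums(counts)
  occupied <- n_alpha > 0
  f_k <- rep(0, ncol(counts))
  F_a <- rep(0, nrow(counts))
  for (it in seq_len(max_iter)) {
    ## F_alpha = -kT ln[ n_alpha / sum_k N_k exp((f_k - V_k(alpha))/kT) ]
    logdenom <- vapply(seq_len(nrow(counts)), function(a)
      .logsumexp(log(N_k) + (f_k - V[a, ]) / kT), numeric(1))
    F_new <- ifelse(occupied, -kT * (log(n_alpha) - logdenom), Inf)
    F_new <- F_new - min(F_new)
    resid <- max(abs(F_new[occupied] - F_a[occupied]))
    F_a <- F_new
    ## f_k = -kT ln sum_alpha exp(-(F_alpha + V_k(alpha))/kT)
    f_k <- vapply(seq_len(ncol(counts)), function(k)
      -kT * .logsumexp(-(F_a[occupied] + V[occupied, k]) / kT), numeric(1))
    if (it > 1 && resid < tol)
      return(list(F = F_a, f = f_k, iterations = it, residual = resid,
                  converged = TRUE))
  }
  list(F = F_a, f = f_k, iterations = max_iter, residual = resid,
       converged = FALSE)
}

#' Reconstruct microstate free energies by the weighted-histogram method
#'
#' Solves the self-consistent multi-histogram (WHAM) equations over the
#' replicas' one-dimensional bias potentials:
#' \deqn{F_\alpha = -kT \ln\frac{\sum_k n_{k\alpha}}
#'   {\sum_k N_k e^{(f_k - V_k(s_\alpha))/kT}}, \qquad
#'   f_k = -kT \ln \sum_\alpha e^{-(F_\alpha + V_k(s_\alpha))/kT},}
#' where V_k is replica k's bias interpolated at the microstate center
#' along its biased CV. Output free energies are shifted so the global
#' minimum is 0. Iteration stops when the maximum absolute change of any
#' F_alpha falls below `tol`.
#'
#' @param occupancy A [assign_microstates()] result.
#' @param runs The same list of [replica_run()] objects.
#' @param spec The [binning_spec()] used.
#' @param kT Thermal energy, kJ/mol.
#' @param tol Convergence tolerance on F, kJ/mol.
#' @param max_iter Maximum iterations (error if exceeded).
#' @return An object of class `microstate_fes`: `microstates` (the bin
#'   table plus counts, `n`, `F` and `error` columns), `kT`, `iterations`,
#'   `residual`, plus the occupancy embedded for downstream slicing.
#' @export
reconstruct_fes <- function(occupancy, runs, spec, kT = 2.9, tol = 1e-4,
                            max_iter = 10000) {
  stopifnot(inherits(occupancy, "microstate_occupancy"))
  if (any(colSums(occupancy$counts) == 0))
    stop("every replica must contribute at least one retained frame")
  V <- .bias_at_bins(occupancy, runs)
  sol <- .wham_iterate(occupancy$counts, V, kT, tol, max_iter)
  if (!sol$converged)
    stop("WHAM did not converge in ", max_iter,
         " iterations (residual ", format(sol$residual), " kJ/mol)")
  ms <- occupancy$bins
  ms <- cbind(ms, occupancy$counts)
  ms$n <- rowSums(occupancy$counts)
  ms$F <- sol$F
  ms$error <- NA_real_
  structure(
    list(microstates = ms, kT = kT, iterations = sol$iterations,
         residual = sol$residual, f_k = sol$f, bias_at_bins = V,
         occupancy = occupancy),
    class = "microstate_fes")
}

#' @export
print.microstate_fes <- function(x, ...) {
  cat(sprintf(
    "microstate_fes: %d microstates, kT = %g kJ/mol, F in [0, %.1f], %d WHAM iterations\n",
    nrow(x$microstates), x$kT, max(x$microstates$F), x$iterations))
  invisible(x)
}

#' Block-analysis errors of microstate free energies
#'
#' Splits the post-equilibration time span into `n_blocks` contiguous
#' blocks, recomputes the WHAM free energies per block (with the same
#' biases), aligns each block at the full-estimate global-minimum
#' microstate, and reports the standard deviation over blocks divided by
#' sqrt(n_blocks). A microstate empty in any block gets `NA` (error
#' unavailable), never a spurious 0.
#'
#' @param occupancy A [assign_microstates()] result.
#' @param runs List of [replica_run()] objects.
#' @param spec The [binning_spec()] used.
#' @param n_blocks Number of time blocks.
#' @param kT,tol,max_iter As in [reconstruct_fes()].
#' @return Numeric per-microstate error vector (kJ/mol), `NA` where
#'   unavailable.
#' @export
estimate_errors <- function(occupancy, runs, spec, n_blocks = 4, kT = 2.9,
                            tol = 1e-4, max_iter = 10000) {
  stopifnot(inherits(occupancy, "microstate_occupancy"), n_blocks >= 2)
  V <- .bias_at_bins(occupancy, runs)
  times <- unlist(lapply(occupancy$frames, function(f) f$time))
  t0 <- min(times); t1 <- max(times)
  edges <- seq(t0, t1, length.out = n_blocks + 1)
  edges[n_blocks + 1] <- t1 + 1
  n_bins <- nrow(occupancy$bins)
  ## reference gauge: the full-data minimum bin
  full <- .wham_iterate(occupancy$counts, V, kT, tol, max_iter)
  ref_bin <- which.min(full$F)
  Fb <- matrix(NA_real_, n_bins, n_blocks)
  for (b in seq_len(n_blocks)) {
    counts_b <- vapply(seq_along(runs), function(k) {
      tt <- occupancy$frames[[k]]$time
      sel <- tt >= edges[b] & tt < edges[b + 1]
      tabulate(occupancy$assign[[k]][sel], nbins = n_bins)
    }, integer(n_bins))
    counts_b <- matrix(counts_b, nrow = n_bins)
    if (sum(counts_b) == 0) next
    sol <- .wham_iterate(counts_b, V, kT, tol, max_iter)
    Fv <- sol$F
    Fv[rowSums(counts_b) == 0] <- NA
    shift <- if (!is.na(Fv[ref_bin])) Fv[ref_bin] else min(Fv, na.rm = TRUE)
    Fb[, b] <- Fv - shift
  }
  err <- apply(Fb, 1, function(v)
    if (anyNA(v)) NA_real_ else stats::sd(v) / sqrt(n_blocks))
  err
}

#' Refine inconsistent microstates
#'
#' A hypercube is a proper microstate only if its member frames are
#' structurally consistent; here consistency is measured as the standard
#' deviation, over member frames, of every CV present in the trajectories
#' but not used for binning. Bins exceeding `spread_threshold` in any such
#' CV are split in half along their widest binned axis, recursively, until
#' consistent or until an axis would fall below 1/8 of its original width.
#'
#' @param occupancy A [assign_microstates()] result.
#' @param runs List of [replica_run()] objects (unused beyond interface
#'   symmetry; member frames are already stored in the occupancy).
#' @param spec The [binning_spec()] used.
#' @param spread_threshold Maximum allowed member standard deviation in
#'   any non-binned CV.
#' @return A new `microstate_occupancy` with refined bins.
#' @export
refine_bins <- function(occupancy, runs, spec, spread_threshold) {
  stopifnot(inherits(occupancy, "microstate_occupancy"),
            spread_threshold > 0)
  cvs <- spec$cvs
  other <- setdiff(
    Reduce(intersect, lapply(occupancy$frames, names)),
    c("time", cvs))
  if (length(other) == 0L) return(occupancy)
  d <- length(cvs)
  min_width <- spec$widths / 8

  ## pool member frames (run, row) per bin
  pooled <- do.call(rbind, lapply(seq_along(occupancy$frames), function(k) {
    f <- occupancy$frames[[k]]
    f$.run <- k
    f$.bin <- occupancy$assign[[k]]
    f
  }))
  lo0 <- as.matrix(occupancy$bins[, paste0("lo_", cvs), drop = FALSE])
  hi0 <- as.matrix(occupancy$bins[, paste0("hi_", cvs), drop = FALSE])
  queue <- lapply(seq_len(nrow(lo0)), function(i)
    list(lo = lo0[i, ], hi = hi0[i, ],
         rows = which(pooled$.bin == i)))
  final <- list()
  while (length(queue)) {
    box <- queue[[1]]; queue <- queue[-1]
    if (length(box$rows) == 0L) next
    spread <- vapply(other, function(cv)
      if (length(box$rows) > 1) stats::sd(pooled[[cv]][box$rows]) else 0,
      numeric(1))
    widths <- box$hi - box$lo
    splittable <- which(widths / 2 >= min_width - 1e-12)
    if (max(spread) > spread_threshold && length(splittable)) {
      j <- splittable[which.max(widths[splittable])]
      mid <- (box$lo[j] + box$hi[j]) / 2
      left <- right <- box
      left$hi[j] <- mid; right$lo[j] <- mid
      x <- pooled[[cvs[j]]][box$rows]
      left$rows <- box$rows[x < mid]
      right$rows <- box$rows[x >= mid]
      queue <- c(queue, list(left), list(right))
    } else {
      final[[length(final) + 1]] <- box
    }
  }
  ## rebuild the occupancy container from the final boxes
  bins <- data.frame(id = vapply(final, function(b)
    paste(signif(b$lo, 10), collapse = "_"), character(1)),
    stringsAsFactors = FALSE)
  for (j in seq_len(d)) {
    bins[[paste0("lo_", cvs[j])]] <- vapply(final, function(b) b$lo[j], numeric(1))
    bins[[paste0("hi_", cvs[j])]] <- vapply(final, function(b) b$hi[j], numeric(1))
    bins[[paste0("center_", cvs[j])]] <-
      (bins[[paste0("lo_", cvs[j])]] + bins[[paste0("hi_", cvs[j])]]) / 2
  }
  newbin <- integer(nrow(pooled))
  for (i in seq_along(final)) newbin[final[[i]]$rows] <- i
  counts <- vapply(seq_along(occupancy$frames), function(k)
    tabulate(newbin[pooled$.run == k], nbins = nrow(bins)),
    integer(nrow(bins)))
  counts <- matrix(counts, nrow = nrow(bins),
                   dimnames = list(bins$id, colnames(occupancy$counts)))
  assign <- lapply(seq_along(occupancy$frames), function(k)
    newbin[pooled$.run == k])
  structure(
    list(bins = bins, counts = counts, frames = occupancy$frames,
         assign = assign, dropped = occupancy$dropped,
         n_retained = sum(counts), spec = spec,
         origin = occupancy$origin, extent = occupancy$extent),
    class = "microstate_occupancy")
}
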