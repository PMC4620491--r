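#' Multi-basin toy free-energy landscape in CV space
#'
#' Builds a smooth landscape over 1-4 collective variables as a Boltzmann
#' softmin of parabolic basins,
#' \deqn{F(s) = -kT \ln \sum_w \exp(-G_w(s)/kT), \quad
#'       G_w(s) = -d_w + \sum_j ((s_j - c_{wj})/\sigma_{wj})^2,}
#' normalized so the global minimum is 0. Each well is given as a list with
#' `center` (CV-space vector), `depth` (kJ/mol, > 0) and `width` (per-CV
#' scale). The returned object exposes the exact free energy and, via
#' [landscape_marginal()], its quadrature marginal along any CV.
#'
#' @param cv_names Character vector naming the CVs.
#' @param wells List of wells (`center`, `depth`, `width`).
#' @param domain Matrix 2 x n_cv (rows lo, hi) or list of c(lo, hi) per CV.
#' @param temperature Temperature in K; sets kT = R*T.
#' @param seed Integer seed (kept for interface symmetry; the construction
#'   is deterministic).
#' @return An object of class `toy_landscape` with elements `F` (vectorized
#'   function of a CV vector or matrix), `cv_names`, `domain`, `kT`,
#'   `wells`.
#' @export
#' @examples
#' L <- make_landscape("cv1", wells = list(list(center = 1, depth = 10,
#'                     width = 0.3)), domain = list(c(0, 3)))
#' L$F(1) # 0 at the global minimum
make_landscape <- function(cv_names, wells, domain, temperature = 350,
                           seed = 1) {
  if (length(wells) == 0L) stop("at least one well is required")
  d <- length(cv_names)
  if (is.list(domain)) domain <- vapply(domain, function(x) x[1:2], numeric(2))
  domain <- matrix(as.numeric(domain), nrow = 2)
  if (ncol(domain) != d) stop("domain must give one interval per CV")
  if (any(domain[2, ] <= domain[1, ])) stop("empty domain")
  C <- do.call(rbind, lapply(wells, function(w) rep_len(as.numeric(w$center), d)))
  D <- vapply(wells, function(w) as.numeric(w$depth), numeric(1))
  W <- do.call(rbind, lapply(wells, function(w) rep_len(as.numeric(w$width), d)))
  if (any(D <= 0)) stop("well depths must be positive")
  if (any(W <= 0)) stop("well widths must be positive")
  for (j in seq_len(d))
    if (any(C[, j] < domain[1, j] | C[, j] > domain[2, j]))
      stop("well center outside domain")
  kT <- kT_at(temperature)

  raw <- function(S) {
    S <- if (is.matrix(S)) S else matrix(S, ncol = d, byrow = length(S) > d)
    vapply(seq_len(nrow(S)), function(i) {
      q <- rowSums(((rep(S[i, ], each = nrow(C)) - C) / W)^2)
      -kT * .logsumexp((D - q) / kT)
    }, numeric(1))
  }
  ## normalize: global minimum to 0 (refine from every well center)
  f0 <- min(vapply(seq_along(wells), function(w) {
    if (d == 1) {
      stats::optimize(function(x) raw(matrix(x, ncol = 1)),
                      interval = domain[, 1])$objective
    } else {
      stats::optim(C[w, ], function(x) raw(matrix(x, nrow = 1)),
                   method = "Nelder-Mead")$value
    }
  }, numeric(1)))
  Ffun <- function(s) raw(s) - f0

  structure(
    list(F = Ffun, cv_names = cv_names, domain = domain, kT = kT,
         temperature = temperature, wells = wells, seed = seed),
    class = "toy_landscape")
}

#' Exact marginal free energy along one CV
#'
#' Dense-grid quadrature of the Boltzmann weight over all other CVs:
#' F_j(s_j) = -kT ln Int exp(-F(s)/kT) ds_-j, shifted to min 0.
#'
#' @param landscape A [make_landscape()] object.
#' @param cv CV name or index to keep.
#' @param at Values of the kept CV at which to evaluate (default: a grid of
#'   `n_grid` points over its domain).
#' @param n_grid Quadrature points per integrated dimension.
#' @return Data.frame with columns `s` and `F`.
#' @export
landscape_marginal <- function(landscape, cv, at = NULL, n_grid = 101) {
  stopifnot(inherits(landscape, "toy_landscape"))
  d <- length(landscape$cv_names)
  j <- if (is.character(cv)) match(cv, landscape$cv_names) else as.integer(cv)
  if (is.na(j) || j < 1 || j > d) stop("unknown CV: ", cv)
  dom <- landscape$domain
  if (is.null(at)) at <- seq(dom[1, j], dom[2, j], length.out = n_grid)
  kT <- landscape$kT
  others <- setdiff(seq_len(d), j)
  if (length(others) == 0L) {
    Fm <- landscape$F(matrix(at, ncol = 1))
  } else {
    grids <- lapply(others, function(k) seq(dom[1, k], dom[2, k],
                                            length.out = n_grid))
    rest <- as.matrix(expand.grid(grids))
    Fm <- vapply(at, function(sj) {
      S <- matrix(0, nrow = nrow(rest), ncol = d)
      S[, j] <- sj
      S[, others] <- rest
      -kT * .logsumexp(-landscape$F(S) / kT)
    }, numeric(1))
  }
  data.frame(s = at, F = Fm - min(Fm))
}
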