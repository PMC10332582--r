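#' Inverse-distance spatial weights
#'
#' Pairwise distances (haversine meters for lon/lat coordinates, Euclidean
#' for planar) converted to row-standardized inverse-distance weights with a
#' zero diagonal. Duplicate coordinates are rejected (infinite weight).
#'
#' @param x,y coordinate vectors.
#' @param coord_system `"planar"` (meters) or `"lonlat"` (degrees; x =
#'   longitude).
#' @return object of class `spatial_weights`: `w` (row-standardized weight
#'   matrix), `dist` (meters), `coord_system`.
#' @export
spatial_weights <- function(x, y, coord_system = c("planar", "lonlat")) {
  coord_system <- match.arg(coord_system)
  n <- length(x)
  if (n < 3) stop("need at least 3 sites")
  d <- if (coord_system == "lonlat")
    geosphere::distm(cbind(x, y), fun = geosphere::distHaversine)
  else as.matrix(dist(cbind(x, y)))
  if (any(d[upper.tri(d)] == 0))
    stop("duplicate coordinates: inverse-distance weights undefined")
  w <- 1 / d
  diag(w) <- 0
  w <- w / rowSums(w)
  structure(list(w = w, dist = d, coord_system = coord_system),
            class = "spatial_weights")
}

#' Occupancy residuals of a fitted model
#'
#' Per-site residuals of the occupancy (ecological) component: the
#' conditional occupancy given the detection history minus the fitted
#' unconditional occupancy. For Bayesian fits the residual is averaged over
#' posterior draws, using the analytic conditional Pr(z_i = 1 | y_i, theta)
#' in place of sampled latent states (same expectation, no extra Monte Carlo
#' noise).
#'
#' @param fit an `occu_fit_ml` or `occu_fit_bayes`.
#' @param data optional `detection_history`.
#' @param max_draws posterior draws used for Bayesian fits (default 1000).
#' @return numeric vector of per-site residuals in [-1, 1].
#' @export
occupancy_residuals <- function(fit, data = NULL, max_draws = 1000) {
  y <- if (is.null(data)) fit$y else data$y
  X <- fit$designs$X; W <- fit$designs$W
  resid_at <- function(th) {
    sf <- occu_surfaces(th, X, W)
    p <- sf$p
    if (ncol(p) == 1L && ncol(y) > 1L) p <- matrix(p, nrow(y), ncol(y))
    obs <- !is.na(y)
    lq <- log1p(-p); lq[!obs] <- 0
    log_q <- rowSums(lq)
    detected <- rowSums(obs & y == 1L, na.rm = TRUE) > 0
    cond <- rep(1, nrow(y))
    nd <- !detected
    num <- log(sf$psi[nd]) + log_q[nd]
    cond[nd] <- exp(num - log_sum_exp(num, log1p(-sf$psi[nd])))
    cond - sf$psi
  }
  if (inherits(fit, "occu_fit_bayes")) {
    dm <- fit$draws_matrix
    keep <- unique(round(seq(1, nrow(dm), length.out = min(max_draws, nrow(dm)))))
    rs <- vapply(keep, function(s) resid_at(dm[s, ]), numeric(nrow(y)))
    return(rowMeans(rs))
  }
  resid_at(fit$estimates)
}

#' Global Moran's I
#'
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2
#' with expectation -1/(n-1) and the normal-approximation variance, z score
#' and two-sided p-value under spatial independence.
#'
#' @param residuals numeric vector (non-constant).
#' @param weights a `spatial_weights` object or a bare weight matrix with
#'   zero diagonal.
#' @return object of class `moran_result`: `I`, `expectation`, `variance`,
#'   `z`, `p_value`, `n`.
#' @export
morans_i <- function(residuals, weights) {
  w <- if (inherits(weights, "spatial_weights")) weights$w else weights
  n <- length(residuals)
  if (n < 3) stop("need at least 3 sites")
  if (sd(residuals) == 0) stop("constant residuals: Moran's I undefined")
  if (!all(dim(w) == n)) stop("weight matrix does not match residual length")
  xc <- residuals - mean(residuals)
  S0 <- sum(w)
  I <- (n / S0) * sum(w * outer(xc, xc)) / sum(xc^2)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((w + t(w))^2)
  S2 <- sum((rowSums(w) + colSums(w))^2)
  # variance under the normality assumption
  VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  z <- (I - EI) / sqrt(VI)
  structure(list(I = I, expectation = EI, variance = VI, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)), n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f, z = %.3f, p = %.4f, n = %d)\n",
              x$I, x$expectation, x$z, x$p_value, x$n))
  invisible(x)
}

#' Distance-binned Moran correlogram with permutation envelope
#'
#' Moran's I computed per distance class (equal-count bins of the pairwise
#' distances, binary in-bin weights) with a pointwise 2.5/97.5% envelope
#' from permuting the residuals over sites. Bins with fewer than 20 pairs
#' are flagged unreliable.
#'
#' @param residuals numeric vector, length >= 10.
#' @param x,y site coordinates.
#' @param coord_system `"planar"` or `"lonlat"`.
#' @param n_bins number of distance classes (default 8).
#' @param n_perms permutations for the envelope (default 999).
#' @param seed integer seed.
#' @return data.frame of class `correlogram`: `bin_center, lo_edge, hi_edge,
#'   I, lo, hi, n_pairs, reliable`.
#' @export
distance_correlogram <- function(residuals, x, y,
                                 coord_system = c("planar", "lonlat"),
                                 n_bins = 8, n_perms = 999, seed) {
  if (missing(seed)) stop("seed is required")
  coord_system <- match.arg(coord_system)
  n <- length(residuals)
  if (n < 10) stop("need at least 10 sites")
  d <- if (coord_system == "lonlat")
    geosphere::distm(cbind(x, y), fun = geosphere::distHaversine)
  else as.matrix(dist(cbind(x, y)))
  dv <- d[upper.tri(d)]
  if (max(dv) == 0) stop("all sites at one location")
  edges <- quantile(dv, probs = seq(0, 1, length.out = n_bins + 1))
  edges[1] <- 0; edges[n_bins + 1] <- max(dv)
  edges <- unique(edges)
  nb <- length(edges) - 1
  bin_of <- function(dd) pmin(pmax(findInterval(dd, edges, left.open = TRUE,
                                                rightmost.closed = TRUE), 1), nb)
  moran_bins <- function(res) {
    xc <- res - mean(res)
    denom <- sum(xc^2) / n
    cp <- outer(xc, xc)
    vapply(seq_len(nb), function(k) {
      wk <- d > edges[k] & d <= edges[k + 1]
      diag(wk) <- FALSE
      s0 <- sum(wk)
      if (s0 == 0) return(NA_real_)
      sum(cp[wk]) / s0 / denom
    }, numeric(1))
  }
  I_obs <- moran_bins(residuals)
  set.seed(seed)
  perm <- matrix(NA_real_, n_perms, nb)
  for (b in seq_len(n_perms))
    perm[b, ] <- moran_bins(sample(residuals))
  n_pairs <- vapply(seq_len(nb), function(k)
    sum(dv > edges[k] & dv <= edges[k + 1]), numeric(1))
  out <- data.frame(
    bin_center = (edges[-(nb + 1)] + edges[-1]) / 2,
    lo_edge = edges[-(nb + 1)], hi_edge = edges[-1],
    I = I_obs,
    lo = apply(perm, 2, quantile, 0.025, na.rm = TRUE),
    hi = apply(perm, 2, quantile, 0.975, na.rm = TRUE),
    n_pairs = n_pairs, reliable = n_pairs >= 20)
  class(out) <- c("correlogram", "data.frame")
  attr(out, "seed") <- seed
  out
}

#' Plot a correlogram
#'
#' @param x a `correlogram`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.correlogram <- function(x, ...) {
  graphics::plot(x$bin_center, x$I, type = "b", pch = 16,
                 xlab = "distance (m)", ylab = "Moran's I",
                 ylim = range(c(x$I, x$lo, x$hi), na.rm = TRUE), ...)
  graphics::lines(x$bin_center, x$lo, lty = 2)
  graphics::lines(x$bin_center, x$hi, lty = 2)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
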