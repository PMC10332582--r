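#' Single-season occupancy model specification
#'
#' @param psi_terms,p_terms term lists resolvable against a covariate table
#'   (see [build_design()]).
#' @param label model label, default the `p(...)psi(...)` convention.
#' @return object of class `occu_model_spec`.
#' @export
occu_spec <- function(psi_terms = character(), p_terms = character(),
                      label = NULL) {
  if (is.null(label))
    label <- sprintf("p(%s)psi(%s)",
                     if (length(p_terms)) paste(p_terms, collapse = "+") else ".",
                     if (length(psi_terms)) paste(psi_terms, collapse = "+") else ".")
  structure(list(psi_terms = psi_terms, p_terms = p_terms, label = label),
            class = "occu_model_spec")
}

# psi_i and p_ij surfaces from designs and a parameter vector
occu_surfaces <- function(theta, X, W) {
  kpsi <- ncol(X)
  beta <- theta[seq_len(kpsi)]
  alpha <- theta[-seq_len(kpsi)]
  psi <- inv_logit(drop(X %*% beta))
  n <- dim(W)[1]; J <- dim(W)[2]; kp <- dim(W)[3]
  eta <- matrix(0, n, J)
  for (k in seq_len(kp)) eta <- eta + W[, , k, drop = TRUE] * alpha[k]
  list(psi = psi, p = inv_logit(eta))
}

# vectorized pointwise site log-likelihoods; y is n x J in {0,1,NA}
occu_pointwise_ll <- function(theta, y, X, W) {
  sf <- occu_surfaces(theta, X, W)
  psi <- sf$psi; p <- sf$p
  if (ncol(p) == 1L && ncol(y) > 1L) p <- matrix(p, nrow(y), ncol(y))
  obs <- !is.na(y)
  yy <- ifelse(obs, y, 0L)
  lp <- yy * log(p) + (1 - yy) * log1p(-p)
  lp[!obs] <- 0
  log_det <- rowSums(lp)
  detected <- rowSums(obs & yy == 1L) > 0
  ll <- numeric(length(psi))
  ll[detected] <- log(psi[detected]) + log_det[detected]
  nd <- !detected
  ll[nd] <- log_sum_exp(log(psi[nd]) + log_det[nd], log1p(-psi[nd]))
  ll
}

#' Site likelihood of a detection history row
#'
#' Probability of one site's detection history under the zero-inflated
#' Bernoulli occupancy model: psi * prod_j p^y (1-p)^(1-y) over observed
#' occasions, plus (1-psi) when no detection was observed. Missing occasions
#' contribute nothing; the all-zero branch is evaluated in log space.
#'
#' @param y vector of 0/1/NA over occasions.
#' @param psi occupancy probability of the site.
#' @param p detection probability, scalar or per-occasion vector.
#' @return the probability.
#' @export
site_likelihood <- function(y, psi, p) {
  obs <- !is.na(y)
  if (!any(obs)) stop("all occasions missing: site likelihood undefined")
  p <- rep_len(p, length(y))
  yo <- y[obs]; po <- p[obs]
  log_det <- sum(yo * log(po) + (1 - yo) * log1p(-po))
  if (any(yo == 1)) return(exp(log(psi) + log_det))
  exp(log_sum_exp(log(psi) + log_det, log1p(-psi)))
}

# deterministic multistart list around naive rates
occu_starts <- function(y, kpsi, kp) {
  det_site <- rowSums(y == 1, na.rm = TRUE) > 0
  naive_psi <- min(max(mean(det_site), 0.05), 0.95)
  nobs <- sum(!is.na(y[det_site, , drop = FALSE]))
  naive_p <- if (nobs > 0)
    min(max(sum(y[det_site, , drop = FALSE] == 1, na.rm = TRUE) / nobs, 0.05),
        0.95) else 0.5
  offs <- list(c(0, 0), c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  lapply(offs, function(o) {
    th <- numeric(kpsi + kp)
    th[1] <- logit(naive_psi) + o[1]
    th[kpsi + 1] <- logit(naive_p) + o[2]
    th
  })
}

#' Fit a single-season occupancy model by maximum likelihood
#'
#' Maximizes the summed site log-likelihood by quasi-Newton iteration from
#' five deterministic starts (intercepts at the logit of the naive rates
#' offset by 0/+1/-1, slopes at zero), followed by Newton polishing of the
#' gradient. Standard errors come from the inverse observed information.
#'
#' @param data a `detection_history`.
#' @param designs a `design_matrices` object on the same station order.
#' @param spec optional `occu_model_spec` label carried into reports.
#' @return object of class `occu_fit_ml` with elements `spec`, `beta`,
#'   `alpha`, `se`, `vcov`, `loglik`, `pointwise` (per-site log-likelihoods),
#'   `aicc`, `n_sites`, `n_params`, `converged`, `boundary`.
#' @export
fit_ml <- function(data, designs, spec = NULL) {
  y <- data$y
  if (!any(y == 1, na.rm = TRUE))
    stop("no detections: occupancy and detection are not jointly identifiable")
  if (any(rowSums(!is.na(y)) == 0))
    stop("site with no observed occasion")
  X <- designs$X; W <- designs$W
  kpsi <- ncol(X); kp <- dim(W)[3]
  nll <- function(th) {
    v <- -sum(occu_pointwise_ll(th, y, X, W))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- optimize_ml(nll, occu_starts(y, kpsi, kp))
  th <- opt$par
  vc <- tryCatch(solve(opt$hessian), error = function(e)
    matrix(NA_real_, length(th), length(th)))
  se <- suppressWarnings(sqrt(diag(vc)))
  sf <- occu_surfaces(th, X, W)
  boundary <- any(sf$psi > 0.9999) || any(sf$p > 0.9999)
  if (boundary)
    warning("fitted probabilities at the boundary (psi or p > 0.9999)")
  pw <- occu_pointwise_ll(th, y, X, W)
  n <- nrow(y); k <- kpsi + kp
  ll <- sum(pw)
  aicc <- if (n > k + 1) -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  nm <- c(paste0("psi_", colnames(X)), paste0("p_", dimnames(W)[[3]]))
  names(th) <- names(se) <- nm
  structure(list(spec = spec %||% occu_spec(designs$psi_terms, designs$p_terms),
                 beta = th[seq_len(kpsi)], alpha = th[-seq_len(kpsi)],
                 estimates = th, se = se, vcov = vc,
                 loglik = ll, pointwise = pw, aicc = aicc,
                 n_sites = n, n_params = k,
                 converged = opt$converged, gnorm = opt$gnorm,
                 boundary = boundary,
                 designs = designs, y = y),
            class = "occu_fit_ml")
}

#' @export
print.occu_fit_ml <- function(x, ...) {
  cat("Occupancy model (ML):", x$spec$label, "\n")
  cat("Estimates interpreted as habitat use (psi) and intensity of use (p)\n")
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(round(tab, 4))
  cat(sprintf("logLik %.3f  AICc %.3f  n_sites %d  k %d  converged %s\n",
              x$loglik, x$aicc, x$n_sites, x$n_params, x$converged))
  invisible(x)
}

#' Conditional occupancy given the detection history
#'
#' Pr(z_i = 1 | history): exactly 1 for sites with at least one detection;
#' for all-zero sites, psi * prod(1-p) divided by the site likelihood.
#'
#' @param fit an `occu_fit_ml`.
#' @param data optional `detection_history` (defaults to the fitted data).
#' @return per-site probability vector.
#' @export
conditional_occupancy <- function(fit, data = NULL) {
  y <- if (is.null(data)) fit$y else data$y
  sf <- occu_surfaces(fit$estimates, fit$designs$X, fit$designs$W)
  psi <- sf$psi
  p <- sf$p
  if (ncol(p) == 1L && ncol(y) > 1L) p <- matrix(p, nrow(y), ncol(y))
  obs <- !is.na(y)
  lq <- log1p(-p); lq[!obs] <- 0
  log_q <- rowSums(lq)          # log prod (1 - p_ij) over observed occasions
  detected <- rowSums(obs & y == 1L, na.rm = TRUE) > 0
  out <- rep(1, nrow(y))
  nd <- !detected
  num <- log(psi[nd]) + log_q[nd]
  den <- log_sum_exp(num, log1p(-psi[nd]))
  out[nd] <- exp(num - den)
  out
}

#' Predicted occupancy or detection response curve
#'
#' Inverse-logit prediction over a covariate grid with other model terms held
#' at 0 (the scaled mean) or at the reference level. ML fits get delta-method
#' 95% intervals formed on the link scale and back-transformed; Bayesian fits
#' get equal-tailed 2.5/97.5% posterior quantiles.
#'
#' @param fit an `occu_fit_ml` or `occu_fit_bayes`.
#' @param target `"psi"` or `"p"`.
#' @param grid data.frame of covariate values on the scaled axis; quadratic
#'   companions of gridded terms are filled in automatically.
#' @return data.frame with the grid, `estimate`, `lower`, `upper`.
#' @export
predict_response <- function(fit, target = c("psi", "p"), grid) {
  target <- match.arg(target)
  designs <- fit$designs
  cn <- if (target == "psi") colnames(designs$X) else dimnames(designs$W)[[3]]
  M <- matrix(0, nrow(grid), length(cn), dimnames = list(NULL, cn))
  M[, 1] <- 1
  for (g in names(grid)) {
    matched <- FALSE
    if (g %in% cn) { M[, g] <- grid[[g]]; matched <- TRUE }
    sq <- paste0(g, "^2")
    if (sq %in% cn) { M[, sq] <- grid[[g]]^2; matched <- TRUE }
    # categorical level: dummy columns named term + level
    hits <- cn[startsWith(cn, g) & cn != g & !grepl("\\^2$", cn)]
    if (!matched && length(hits)) {
      for (h in hits) M[, h] <- as.numeric(paste0(g, grid[[g]]) == h)
      matched <- TRUE
    }
    if (!matched) stop("term absent from the fitted ", target, " model: ", g)
  }
  if (inherits(fit, "occu_fit_bayes")) {
    draws <- fit$draws_matrix
    idx <- if (target == "psi") seq_len(ncol(designs$X)) else
      ncol(designs$X) + seq_len(length(cn))
    eta <- M %*% t(draws[, idx, drop = FALSE])
    pr <- inv_logit(eta)
    return(data.frame(grid, estimate = rowMeans(pr),
                      lower = apply(pr, 1, quantile, 0.025),
                      upper = apply(pr, 1, quantile, 0.975)))
  }
  idx <- if (target == "psi") seq_len(ncol(designs$X)) else
    ncol(designs$X) + seq_len(length(cn))
  co <- fit$estimates[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  eta <- drop(M %*% co)
  se <- sqrt(pmax(0, rowSums((M %*% V) * M)))
  data.frame(grid, estimate = inv_logit(eta),
             lower = inv_logit(eta - 1.96 * se),
             upper = inv_logit(eta + 1.96 * se))
}
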