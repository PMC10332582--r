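#' AICc ranking of maximum-likelihood fits
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1), ranked ascending, with Akaike
#' weights exp(-delta/2) renormalized. Models within the conventional
#' parsimony threshold (delta AICc < 2) are flagged as retained.
#'
#' @param fits named list of fits carrying `loglik`, and either
#'   `n_params`/`n_sites` (single-species) or `k`/`n_sites` (co-occurrence);
#'   all must share the dataset.
#' @param labels optional labels; default from each fit's spec.
#' @return data.frame of class `selection_table`, AICc ascending, columns
#'   `model, k, loglik, aicc, delta, weight, retained`.
#' @export
aicc_table <- function(fits, labels = NULL) {
  if (is.null(labels))
    labels <- names(fits) %||%
      vapply(fits, function(f) f$spec$label, character(1))
  k <- vapply(fits, function(f) f$n_params %||% f$k, numeric(1))
  n <- vapply(fits, function(f) f$n_sites, numeric(1))
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  if (length(unique(n)) != 1) stop("fits do not share a dataset (n differs)")
  if (any(n <= k + 1))
    stop("AICc correction undefined: n <= k + 1 for some model")
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  ord <- order(aicc)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2); w <- w / sum(w)
  out <- data.frame(model = labels, k = k, loglik = ll, aicc = aicc,
                    delta = delta, weight = w, retained = delta < 2,
                    stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  class(out) <- c("selection_table", "data.frame")
  attr(out, "score") <- "aicc"
  out
}

#' elpd (PSIS-LOO) comparison of Bayesian fits
#'
#' Ranks fits by leave-one-out expected log pointwise predictive density.
#' The difference to the best model is reported with its standard error
#' SE(delta) = sqrt(n * var(pointwise differences)); a model is flagged
#' `less_support` when |delta elpd| exceeds that SE. Weights are
#' exp-renormalized (pseudo-BMA).
#'
#' @param fits named list of `occu_fit_bayes` sharing the site set.
#' @param labels optional labels.
#' @return data.frame of class `selection_table`, elpd descending, columns
#'   `model, k_eff, elpd, delta, se_delta, weight, less_support, max_pareto_k`.
#' @export
elpd_compare <- function(fits, labels = NULL) {
  if (is.null(labels))
    labels <- names(fits) %||%
      vapply(fits, function(f) f$spec$label, character(1))
  n <- unique(vapply(fits, function(f) length(f$elpd_pointwise), numeric(1)))
  if (length(n) != 1) stop("fits do not share the site set")
  pw <- vapply(fits, function(f) f$elpd_pointwise, numeric(n))
  elpd <- colSums(pw)
  p_loo <- vapply(fits, function(f) {
    lpd_i <- apply(f$pointwise_ll, 2, function(ll) {
      m <- max(ll); m + log(mean(exp(ll - m)))
    })
    sum(lpd_i) - sum(f$elpd_pointwise)
  }, numeric(1))
  best <- which.max(elpd)
  delta <- elpd - elpd[best]
  se_delta <- vapply(seq_along(fits), function(i) {
    d <- pw[, i] - pw[, best]
    sqrt(n * var(d))
  }, numeric(1))
  w <- exp(elpd - max(elpd)); w <- w / sum(w)
  out <- data.frame(model = labels, k_eff = p_loo, elpd = elpd, delta = delta,
                    se_delta = se_delta, weight = w,
                    less_support = abs(delta) > se_delta,
                    max_pareto_k = vapply(fits, function(f) max(f$pareto_k),
                                          numeric(1)),
                    stringsAsFactors = FALSE)[order(-elpd), ]
  rownames(out) <- NULL
  class(out) <- c("selection_table", "data.frame")
  attr(out, "score") <- "elpd"
  out
}

#' p-first sequential model selection
#'
#' Stage 1 ranks `p(term) psi(.)` models (plus the null) over the detection
#' candidates while occupancy is held constant; stage 2 fixes the winning
#' detection structure and ranks `psi(term)` models (plus `psi(.)`) over the
#' occupancy candidates. Ranking uses AICc for the ML engine and PSIS-LOO
#' elpd for the Bayesian engine. The pipeline is a pure function of
#' (data, candidates, seed).
#'
#' @param data a `detection_history`.
#' @param covariates covariate table in station order (numerics already
#'   scaled).
#' @param p_candidates,psi_candidates character vectors of candidate terms
#'   (each fitted singly, matching the one-covariate-at-a-time roster).
#' @param engine `"ml"` or `"bayes"`.
#' @param seed seed for the Bayesian engine.
#' @param ... further arguments to [fit_bayes()] (chains, iterations, ...).
#' @return list with `stage_p` and `stage_psi` selection tables, `final_spec`
#'   (an `occu_model_spec`), and `final_fit`.
#' @export
p_first_selection <- function(data, covariates, p_candidates = character(),
                              psi_candidates = character(),
                              engine = c("ml", "bayes"), seed = 1, ...) {
  engine <- match.arg(engine)
  if (!length(p_candidates) && !length(psi_candidates))
    warning("no candidate terms: degenerate run with the null model only")
  fit_one <- function(psi_terms, p_terms, sd_off = 0) {
    d <- build_design(covariates, psi_terms, p_terms, effort = data$effort)
    sp <- occu_spec(psi_terms, p_terms)
    if (engine == "ml") fit_ml(data, d, sp)
    else fit_bayes(data, d, sp, seed = seed + sd_off, ...)
  }
  rank_fits <- function(fits) {
    if (engine == "ml") aicc_table(fits) else elpd_compare(fits)
  }
  p_specs <- c(list(character(0)), as.list(p_candidates))
  fits1 <- lapply(seq_along(p_specs), function(i)
    fit_one(character(0), unlist(p_specs[[i]]) %||% character(0), sd_off = i))
  names(fits1) <- vapply(fits1, function(f) f$spec$label, character(1))
  tab1 <- rank_fits(fits1)
  best_p <- fits1[[match(tab1$model[1], names(fits1))]]$spec$p_terms
  psi_specs <- c(list(character(0)), as.list(psi_candidates))
  fits2 <- lapply(seq_along(psi_specs), function(i)
    fit_one(unlist(psi_specs[[i]]) %||% character(0), best_p,
            sd_off = 100 + i))
  names(fits2) <- vapply(fits2, function(f) f$spec$label, character(1))
  tab2 <- rank_fits(fits2)
  winner <- fits2[[match(tab2$model[1], names(fits2))]]
  list(stage_p = tab1, stage_psi = tab2, final_spec = winner$spec,
       final_fit = winner)
}

#' MacKenzie-Bailey goodness-of-fit statistic
#'
#' Chi-squared comparison of observed vs expected detection-history
#' frequencies. Sites are grouped into cohorts sharing a missingness
#' pattern; within each cohort the expected count of each observed unique
#' history is E_h = sum_i Pr(h | theta, x_i), and one pooled never-observed
#' cell per cohort carries O = 0 and E = N_cohort - sum E_h, so no full
#' 2^J enumeration is needed.
#'
#' @param fit an `occu_fit_ml` (or any object exposing `estimates` and
#'   `designs`), or a bare parameter vector paired with `designs`.
#' @param data a `detection_history`; defaults to the fitted data.
#' @param theta optional parameter vector overriding the fit's estimates
#'   (used per-draw by the posterior predictive check).
#' @return the chi-squared statistic.
#' @export
mb_statistic <- function(fit, data = NULL, theta = NULL) {
  y <- if (is.null(data)) fit$y else data$y
  th <- theta %||% fit$estimates
  X <- fit$designs$X; W <- fit$designs$W
  sf <- occu_surfaces(th, X, W)
  psi <- sf$psi; p <- sf$p
  if (ncol(p) == 1L && ncol(y) > 1L) p <- matrix(p, nrow(y), ncol(y))
  obs <- !is.na(y)
  pat <- apply(obs, 1, paste, collapse = "")
  chisq <- 0
  for (cohort in split(seq_len(nrow(y)), pat)) {
    oc <- obs[cohort[1], ]
    if (!any(oc)) next
    hist_str <- apply(y[cohort, oc, drop = FALSE], 1, paste, collapse = "")
    counts <- table(hist_str)
    Eh_total <- 0
    for (h in names(counts)) {
      hv <- as.integer(strsplit(h, "")[[1]])
      # Pr(history h) for each site in the cohort at its own psi/p
      prh <- vapply(cohort, function(i) {
        pi <- p[i, oc]
        ld <- sum(hv * log(pi) + (1 - hv) * log1p(-pi))
        if (any(hv == 1)) exp(log(psi[i]) + ld)
        else exp(log_sum_exp(log(psi[i]) + ld, log1p(-psi[i])))
      }, numeric(1))
      Eh <- sum(prh)
      Oh <- as.numeric(counts[[h]])
      if (Eh > 0) chisq <- chisq + (Oh - Eh)^2 / Eh
      Eh_total <- Eh_total + Eh
    }
    E0 <- length(cohort) - Eh_total
    if (E0 > 1e-12) chisq <- chisq + E0    # (0 - E0)^2 / E0
  }
  chisq
}

# proportion-of-zeros discrepancy: |observed zero fraction - expected|
zero_prop_statistic <- function(fit, data = NULL, theta = NULL) {
  y <- if (is.null(data)) fit$y else data$y
  th <- theta %||% fit$estimates
  sf <- occu_surfaces(th, fit$designs$X, fit$designs$W)
  p <- sf$p
  if (ncol(p) == 1L && ncol(y) > 1L) p <- matrix(p, nrow(y), ncol(y))
  obs <- !is.na(y)
  expected <- sum((1 - sf$psi * p)[obs])
  observed <- sum(y[obs] == 0)
  abs(observed - expected) / sum(obs)
}

# simulate a detection history at fixed theta with an observed missingness mask
simulate_history_at <- function(theta, designs, miss) {
  sf <- occu_surfaces(theta, designs$X, designs$W)
  n <- nrow(miss); J <- ncol(miss)
  p <- sf$p
  if (ncol(p) == 1L && J > 1L) p <- matrix(p, n, J)
  z <- rbinom(n, 1, sf$psi)
  yv <- rbinom(n * J, 1, as.vector(p) * rep(z, J))
  y <- matrix(as.integer(yv), n, J)
  y[miss] <- NA_integer_
  eff <- matrix(7L, n, J); eff[miss] <- 0L
  structure(list(species = "sim", stations = paste0("st", seq_len(n)),
                 y = y, effort = eff, occasion_days = 7),
            class = "detection_history")
}

#' Parametric-bootstrap goodness of fit
#'
#' Frequentist MacKenzie-Bailey check for ML fits: simulate `n_sims`
#' datasets at the fitted parameters with the observed missingness pattern,
#' refit (starting at the observed fit, for speed and stability) and
#' recompute the statistic; the p-value is the proportion of simulated
#' statistics at least as large as the observed one. The lower-tail
#' proportion is also reported so that underdispersion is visible.
#'
#' @param fit a converged `occu_fit_ml`.
#' @param data a `detection_history`; defaults to the fitted data.
#' @param n_sims bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return object of class `gof_result`: `statistic`, `p_value`,
#'   `p_lower`, `n_replicates`, `seed`, `mode = "bootstrap"`.
#' @export
gof_bootstrap <- function(fit, data = NULL, n_sims = 1000, seed) {
  if (missing(seed)) stop("seed is required")
  if (is.null(data))
    data <- structure(list(y = fit$y, effort = (!is.na(fit$y)) * 7L),
                      class = "detection_history")
  set.seed(seed)
  obs_stat <- mb_statistic(fit, data)
  miss <- is.na(data$y)
  sims <- rep(NA_real_, n_sims)
  nll_refit <- function(th, y) {
    v <- -sum(occu_pointwise_ll(th, y, fit$designs$X, fit$designs$W))
    if (!is.finite(v)) 1e10 else v
  }
  fails <- 0L
  for (b in seq_len(n_sims)) {
    sim <- simulate_history_at(fit$estimates, fit$designs, miss)
    refit <- tryCatch(
      optim(fit$estimates, nll_refit, y = sim$y, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(refit)) { fails <- fails + 1L; next }
    sims[b] <- mb_statistic(list(estimates = refit$par,
                                 designs = fit$designs, y = sim$y))
  }
  if (fails > 0.1 * n_sims)
    stop("bootstrap refit failure rate above 10% (", fails, "/", n_sims, ")")
  ok <- is.finite(sims)
  structure(list(statistic = obs_stat,
                 p_value = mean(sims[ok] >= obs_stat),
                 p_lower = mean(sims[ok] <= obs_stat),
                 simulated = sims, n_replicates = sum(ok), seed = seed,
                 mode = "bootstrap"),
            class = "gof_result")
}

#' Posterior predictive goodness of fit
#'
#' Bayesian MacKenzie-Bailey check: for each retained posterior draw (thinned
#' to `n_draws_used`), a replicate dataset is simulated at that draw's
#' parameters and the discrepancy statistic is computed for both the
#' replicate and the observed data at the same parameters. The Bayesian P
#' value is the proportion of draws in which the replicate statistic exceeds
#' the observed one; values above 0.05 indicate acceptable fit, and the
#' two-sided tail proportion is reported so that underdispersion
#' (P near 1) is also visible.
#'
#' @param fit an `occu_fit_bayes`.
#' @param data a `detection_history`; defaults to the fitted data.
#' @param n_draws_used posterior draws used (default 1000).
#' @param seed integer seed.
#' @param statistic `"chisq"` (MacKenzie-Bailey) or `"zero_prop"`
#'   (proportion-of-zeros discrepancy).
#' @return object of class `gof_result`: `statistic` (posterior mean of the
#'   observed-data statistic), `p_value` (Bayesian P), `p_two_sided`,
#'   `n_replicates`, `seed`, `mode = "posterior"`.
#' @export
gof_posterior_predictive <- function(fit, data = NULL, n_draws_used = 1000,
                                     seed, statistic = c("chisq", "zero_prop")) {
  if (missing(seed)) stop("seed is required")
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "chisq") mb_statistic else zero_prop_statistic
  y <- if (is.null(data)) fit$y else data$y
  set.seed(seed)
  dm <- fit$draws_matrix
  keep <- unique(round(seq(1, nrow(dm), length.out = min(n_draws_used, nrow(dm)))))
  miss <- is.na(y)
  obs_s <- rep_s <- numeric(length(keep))
  shell <- list(designs = fit$designs, y = y)
  for (s in seq_along(keep)) {
    th <- dm[keep[s], ]
    obs_s[s] <- stat_fun(shell, theta = th)
    sim <- simulate_history_at(th, fit$designs, miss)
    rep_s[s] <- stat_fun(list(designs = fit$designs, y = sim$y), theta = th)
  }
  structure(list(statistic = mean(obs_s),
                 p_value = mean(rep_s > obs_s),
                 p_two_sided = 2 * min(mean(rep_s > obs_s), mean(rep_s <= obs_s)),
                 n_replicates = length(keep), seed = seed,
                 mode = "posterior", discrepancy = statistic),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("MacKenzie-Bailey GOF (%s): statistic %.3f, p = %.3f (%d replicates)\n",
              x$mode, x$statistic, x$p_value, x$n_replicates))
  invisible(x)
}
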