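#' Paired detection histories for two-species co-occurrence
#'
#' Binds the dominant (A) and subordinate (B) species' detection histories,
#' checking that they share station order, occasion grid and missingness
#' pattern (the two species are observed by the same cameras).
#'
#' @param history_A,history_B `detection_history` objects.
#' @return object of class `cooc_data` with elements `yA`, `yB`, `effort`,
#'   `stations`, `species`.
#' @export
cooc_data <- function(history_A, history_B) {
  if (!identical(dim(history_A$y), dim(history_B$y)))
    stop("histories differ in shape")
  if (!identical(as.character(history_A$stations),
                 as.character(history_B$stations)))
    stop("histories differ in station order")
  if (!identical(is.na(history_A$y), is.na(history_B$y)))
    stop("histories differ in missingness pattern")
  structure(list(yA = history_A$y, yB = history_B$y,
                 effort = history_A$effort,
                 stations = history_A$stations,
                 species = c(A = history_A$species, B = history_B$species)),
            class = "cooc_data")
}

#' Specify a conditional co-occurrence model variant
#'
#' The psiBa parameterization has eight parameters (psiA, psiBA, psiBa, pA,
#' pB, rA, rBA, rBa); the nested variants alias them. `psi_conditional`
#' separates psiBA from psiBa (B's occupancy depends on A's presence);
#' `det_conditional` separates pA from rA and pB from rBA/rBa (detection
#' depends on the co-occurrence state). Parameter counts over the 2x2 grid
#' are 4, 5, 7 and 8 (plus any covariate slopes on the psiB side).
#'
#' @param psi_conditional logical, psiBA != psiBa.
#' @param det_conditional logical, pA != rA and pB != rBA != rBa.
#' @param psi_b_terms optional covariate term names entering the linear
#'   predictors of psiBA/psiBa (shared slopes, separate intercepts).
#' @param label optional model label.
#' @return object of class `cooc_model_spec` with the implied parameter
#'   count `k`.
#' @export
cooc_spec <- function(psi_conditional = TRUE, det_conditional = TRUE,
                      psi_b_terms = character(), label = NULL) {
  k <- 1 + (if (psi_conditional) 2 else 1) +
    (if (det_conditional) 5 else 2) + length(psi_b_terms)
  if (is.null(label))
    label <- sprintf("psiBA%spsiBa_%s%s",
                     if (psi_conditional) "!=" else "=",
                     if (det_conditional) "detDep" else "detInd",
                     if (length(psi_b_terms))
                       paste0("_psiB(", paste(psi_b_terms, collapse = "+"), ")")
                     else "")
  structure(list(psi_conditional = psi_conditional,
                 det_conditional = det_conditional,
                 psi_b_terms = psi_b_terms, k = k, label = label),
            class = "cooc_model_spec")
}

#' Enumerate the nested co-occurrence variants
#'
#' The 2x2 grid of occupancy conditioning x detection conditioning, with
#' parameter counts 4, 5, 7, 8; covariate-augmented copies are appended when
#' psiB-side terms are supplied.
#'
#' @param psi_b_terms optional covariate terms on the psiB parameters.
#' @return list of `cooc_model_spec`.
#' @export
enumerate_variants <- function(psi_b_terms = character()) {
  base <- list(cooc_spec(FALSE, FALSE), cooc_spec(TRUE, FALSE),
               cooc_spec(FALSE, TRUE), cooc_spec(TRUE, TRUE))
  if (!length(psi_b_terms)) return(base)
  c(base, lapply(base, function(s)
    cooc_spec(s$psi_conditional, s$det_conditional, psi_b_terms)))
}

# map the free logit-scale vector to the 8 probability parameters
# order of free params: psiA, psiBA, [psiBa], pA, pB, [rA, rBA, rBa], [slopes]
cooc_unpack <- function(theta, spec, XB = NULL) {
  i <- 1
  psiA <- inv_logit(theta[i]); i <- i + 1
  eta_BA <- theta[i]; i <- i + 1
  eta_Ba <- if (spec$psi_conditional) { v <- theta[i]; i <- i + 1; v } else eta_BA
  pA <- inv_logit(theta[i]); i <- i + 1
  pB <- inv_logit(theta[i]); i <- i + 1
  if (spec$det_conditional) {
    rA <- inv_logit(theta[i]); i <- i + 1
    rBA <- inv_logit(theta[i]); i <- i + 1
    rBa <- inv_logit(theta[i]); i <- i + 1
  } else {
    rA <- pA; rBA <- pB; rBa <- pB
  }
  nslope <- length(spec$psi_b_terms)
  if (nslope > 0) {
    gam <- theta[i:(i + nslope - 1)]
    shift <- drop(XB %*% gam)
  } else shift <- 0
  list(psiA = psiA,
       psiBA = inv_logit(eta_BA + shift), psiBa = inv_logit(eta_Ba + shift),
       pA = pA, pB = pB, rA = rA, rBA = rBA, rBa = rBa)
}

# vectorized pointwise log-likelihood over sites
cooc_pointwise_ll <- function(theta, yA, yB, spec, XB = NULL) {
  pr <- cooc_unpack(theta, spec, XB)
  obs <- !is.na(yA)
  a <- ifelse(obs, yA, 0L); b <- ifelse(obs, yB, 0L)
  n <- nrow(yA)
  psiBA <- rep_len(pr$psiBA, n); psiBa <- rep_len(pr$psiBa, n)
  sum_obs <- function(m) rowSums(ifelse(obs, m, 0))
  # state 11: A ~ rA, B ~ rBA where A detected that occasion, rBa otherwise
  llA11 <- sum_obs(a * log(pr$rA) + (1 - a) * log1p(-pr$rA))
  rB <- ifelse(a == 1L, pr$rBA, pr$rBa)
  llB11 <- sum_obs(b * log(rB) + (1 - b) * log1p(-rB))
  anyA <- rowSums(obs & a == 1L) > 0
  anyB <- rowSums(obs & b == 1L) > 0
  l11 <- log(pr$psiA) + log(psiBA) + llA11 + llB11
  # state 10: A present alone ~ pA; B must be undetected
  llA10 <- sum_obs(a * log(pr$pA) + (1 - a) * log1p(-pr$pA))
  l10 <- log(pr$psiA) + log1p(-psiBA) + llA10 + ifelse(anyB, -Inf, 0)
  # state 01: B present alone ~ pB; A must be undetected
  llB01 <- sum_obs(b * log(pr$pB) + (1 - b) * log1p(-pr$pB))
  l01 <- log1p(-pr$psiA) + log(psiBa) + llB01 + ifelse(anyA, -Inf, 0)
  # state 00: nothing present; nothing may be detected
  l00 <- log1p(-pr$psiA) + log1p(-psiBa) + ifelse(anyA | anyB, -Inf, 0)
  m <- pmax(l11, l10, l01, l00)
  m[!is.finite(m)] <- 0
  m + log(exp(l11 - m) + exp(l10 - m) + exp(l01 - m) + exp(l00 - m))
}

#' Site likelihood of a paired detection history row
#'
#' Probability of one site's joint (A, B) history under the psiBa
#' parameterization: a sum over the four latent co-occurrence states, each
#' weighted by its occasion-wise detection product. In the both-present
#' state, B's detection probability on occasion j is rBA when A was detected
#' on that same occasion and rBa when it was not.
#'
#' @param yA,yB vectors of 0/1/NA over occasions with identical missingness.
#' @param params list or named vector with `psiA, psiBA, psiBa, pA, pB, rA,
#'   rBA, rBa`.
#' @return the probability.
#' @export
cooc_site_likelihood <- function(yA, yB, params) {
  if (!identical(is.na(yA), is.na(yB))) stop("mismatched missingness")
  if (all(is.na(yA))) stop("all occasions missing")
  p <- as.list(params)
  th <- logit(c(p$psiA, p$psiBA, p$psiBa, p$pA, p$pB, p$rA, p$rBA, p$rBa))
  ll <- cooc_pointwise_ll(th, matrix(yA, 1), matrix(yB, 1),
                          cooc_spec(TRUE, TRUE))
  exp(ll)
}

#' Species interaction factor
#'
#' Phi = psi_AB / (psi_A psi_B) = psiBA / (psiA psiBA + (1 - psiA) psiBa):
#' the ratio of the joint occupancy to its value under independence. Phi > 1
#' indicates aggregation, Phi < 1 avoidance, Phi = 1 independence (and
#' whenever psiBA = psiBa, Phi is exactly 1 for any psiA).
#'
#' @param psiA dominant-species occupancy, in (0, 1].
#' @param psiBA,psiBa subordinate occupancy given dominant presence/absence.
#' @return Phi.
#' @export
species_interaction_factor <- function(psiA, psiBA, psiBa) {
  if (any(psiA <= 0)) stop("undefined for psiA = 0")
  marg_B <- psiA * psiBA + (1 - psiA) * psiBa
  if (any(marg_B <= 0)) stop("subordinate marginal occupancy is zero")
  psiBA / marg_B
}

#' Detection interaction factor
#'
#' delta = rBA / (rA * rBa), the codetectability ratio; delta != 1 indicates
#' that the two species' detections are conditionally dependent.
#'
#' @param rA dominant detection given both present.
#' @param rBA,rBa subordinate detection given both present and the dominant
#'   detected / not detected.
#' @return delta.
#' @export
detection_interaction_factor <- function(rA, rBA, rBa) {
  if (any(rA * rBa <= 0)) stop("undefined: zero denominator")
  rBA / (rA * rBa)
}

cooc_starts <- function(yA, yB, spec) {
  naiveA <- min(max(mean(rowSums(yA == 1, na.rm = TRUE) > 0), 0.05), 0.95)
  naiveB <- min(max(mean(rowSums(yB == 1, na.rm = TRUE) > 0), 0.05), 0.95)
  pA0 <- min(max(mean(yA == 1, na.rm = TRUE) / naiveA, 0.05), 0.95)
  pB0 <- min(max(mean(yB == 1, na.rm = TRUE) / naiveB, 0.05), 0.95)
  base <- c(logit(naiveA), logit(naiveB),
            if (spec$psi_conditional) logit(naiveB),
            logit(pA0), logit(pB0),
            if (spec$det_conditional) c(logit(pA0), logit(pB0), logit(pB0)),
            rep(0, length(spec$psi_b_terms)))
  offs <- c(0, 1, -1, 0.5, -0.5)
  lapply(offs, function(o) { th <- base; th[1:2] <- th[1:2] + o; th })
}

#' Fit a two-species conditional co-occurrence model
#'
#' Maximum likelihood on logit-transformed parameters with the same
#' deterministic multistart and Newton-polish scheme as [fit_ml()]. AICc
#' uses the number of sites as the sample size. The species interaction
#' factor Phi is derived from the occupancy estimates, and the detection
#' interaction factor delta from the conditional detection estimates (only
#' when the variant separates them). With psiB-side covariates, Phi is
#' evaluated at covariate zero (the scaled mean).
#'
#' @param data a `cooc_data`.
#' @param spec a `cooc_model_spec`.
#' @param covariates optional covariate table (rows in station order) from
#'   which `spec$psi_b_terms` are drawn.
#' @return object of class `cooc_fit`: `params` (the eight probabilities,
#'   aliased parameters exactly equal), `se` (delta-method, probability
#'   scale), `loglik`, `pointwise`, `aicc`, `k`, `n_sites`, `phi`, `delta`,
#'   `converged`, `spec`.
#' @export
fit_cooc <- function(data, spec = cooc_spec(), covariates = NULL) {
  yA <- data$yA; yB <- data$yB
  if (!any(yA == 1, na.rm = TRUE))
    stop("species with zero detections: ", data$species[["A"]])
  if (!any(yB == 1, na.rm = TRUE))
    stop("species with zero detections: ", data$species[["B"]])
  XB <- NULL
  if (length(spec$psi_b_terms)) {
    if (is.null(covariates)) stop("spec has psi_b_terms but no covariates given")
    XB <- as.matrix(covariates[, spec$psi_b_terms, drop = FALSE])
  }
  nll <- function(th) {
    v <- -sum(cooc_pointwise_ll(th, yA, yB, spec, XB))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- optimize_ml(nll, cooc_starts(yA, yB, spec))
  th <- opt$par
  pr <- cooc_unpack(th, spec, XB)
  pr_scalar <- cooc_unpack(th, spec, if (is.null(XB)) NULL else XB * 0)
  est <- vapply(pr_scalar, function(v) v[1], numeric(1))
  # delta-method SEs on the probability scale via the free-parameter vcov
  vc <- tryCatch(solve(opt$hessian),
                 error = function(e) matrix(NA_real_, length(th), length(th)))
  se_free <- suppressWarnings(sqrt(diag(vc)))
  idx <- cooc_param_index(spec)
  se <- vapply(names(est), function(nmp) {
    j <- idx[[nmp]]
    if (is.na(j)) return(NA_real_)
    est[nmp] * (1 - est[nmp]) * se_free[j]
  }, numeric(1))
  pw <- cooc_pointwise_ll(th, yA, yB, spec, XB)
  ll <- sum(pw)
  n <- nrow(yA); k <- length(th)
  aicc <- if (n > k + 1) -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  phi <- species_interaction_factor(est["psiA"], est["psiBA"], est["psiBa"])
  delta <- if (spec$det_conditional)
    detection_interaction_factor(est["rA"], est["rBA"], est["rBa"]) else NA_real_
  structure(list(spec = spec, params = est, se = se, free = th, vcov = vc,
                 loglik = ll, pointwise = pw, aicc = aicc, k = k,
                 n_sites = n, phi = unname(phi), delta = unname(delta),
                 converged = opt$converged, gnorm = opt$gnorm,
                 XB = XB, data = data),
            class = "cooc_fit")
}

# which free-parameter slot feeds each probability (NA when shifted by covariates)
cooc_param_index <- function(spec) {
  i <- 1; idx <- list()
  idx$psiA <- i; i <- i + 1
  idx$psiBA <- i; i <- i + 1
  idx$psiBa <- if (spec$psi_conditional) { v <- i; i <- i + 1; v } else idx$psiBA
  idx$pA <- i; i <- i + 1
  idx$pB <- i; i <- i + 1
  if (spec$det_conditional) {
    idx$rA <- i; i <- i + 1
    idx$rBA <- i; i <- i + 1
    idx$rBa <- i; i <- i + 1
  } else {
    idx$rA <- idx$pA; idx$rBA <- idx$pB; idx$rBa <- idx$pB
  }
  idx
}

#' @export
print.cooc_fit <- function(x, ...) {
  cat("Conditional co-occurrence model (psiBa parameterization):",
      x$spec$label, "\n")
  print(round(data.frame(estimate = x$params, se = x$se), 4))
  cat(sprintf("logLik %.3f  AICc %.3f  k %d  n_sites %d  SIF %.3f%s\n",
              x$loglik, x$aicc, x$k, x$n_sites, x$phi,
              if (is.na(x$delta)) "" else sprintf("  DIF %.3f", x$delta)))
  invisible(x)
}

#' Parametric-bootstrap intervals for the interaction factors
#'
#' Phi and delta are ratio statistics with skewed sampling distributions, so
#' their uncertainty is assessed by a seeded parametric bootstrap: simulate
#' from the fitted model with the observed missingness pattern, refit, and
#' take percentile intervals of the resampled factors.
#'
#' @param fit a `cooc_fit`.
#' @param n_boot bootstrap replicates (default 500).
#' @param seed integer seed.
#' @return list with `phi` and `delta` data.frames (estimate, lower, upper)
#'   and the replicate draws.
#' @export
sif_dif_bootstrap <- function(fit, n_boot = 500, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  miss <- is.na(fit$data$yA)
  # bootstrap at the covariate-zero parameter point with the covariate-free
  # variant of the fitted structure
  bspec <- cooc_spec(fit$spec$psi_conditional, fit$spec$det_conditional)
  phis <- deltas <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    sim <- simulate_cooc_at(fit$params, miss)
    bf <- tryCatch(fit_cooc(sim, bspec), error = function(e) NULL)
    if (is.null(bf)) next
    phis[b] <- bf$phi
    deltas[b] <- bf$delta
  }
  qs <- function(v, est) {
    v <- v[is.finite(v)]
    data.frame(estimate = est,
               lower = if (length(v)) quantile(v, 0.025) else NA,
               upper = if (length(v)) quantile(v, 0.975) else NA,
               row.names = NULL)
  }
  list(phi = qs(phis, fit$phi), delta = qs(deltas, fit$delta),
       draws = data.frame(phi = phis, delta = deltas), seed = seed)
}

# simulate a cooc_data at fixed probability parameters with a missingness mask
simulate_cooc_at <- function(params, miss) {
  p <- as.list(params)
  n <- nrow(miss); J <- ncol(miss)
  zA <- rbinom(n, 1, p$psiA)
  zB <- rbinom(n, 1, ifelse(zA == 1, p$psiBA, p$psiBa))
  yA <- matrix(0L, n, J); yB <- matrix(0L, n, J)
  both <- zA == 1 & zB == 1
  yA[zA == 1, ] <- rbinom(sum(zA == 1) * J, 1,
                          ifelse(both[zA == 1], p$rA, p$pA))
  pb <- matrix(0, n, J)
  pb[both, ] <- ifelse(yA[both, , drop = FALSE] == 1, p$rBA, p$rBa)
  pb[zB == 1 & !both, ] <- p$pB
  yB[zB == 1, ] <- rbinom(sum(zB == 1) * J, 1, pb[zB == 1, ])
  yA[miss] <- NA_integer_; yB[miss] <- NA_integer_
  eff <- matrix(7L, n, J); eff[miss] <- 0L
  structure(list(yA = yA, yB = yB, effort = eff,
                 stations = paste0("st", seq_len(n)),
                 species = c(A = "A", B = "B")),
            class = "cooc_data")
}
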