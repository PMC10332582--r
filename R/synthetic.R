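#' Define a simulation scenario
#'
#' Generative truth for parameter-recovery testing: single-species occupancy
#' and detection on the logit scale (or as scalar probabilities), covariate
#' generators, missingness, and optionally the eight-parameter co-occurrence
#' truth.
#'
#' @param n_sites,n_occasions design dimensions.
#' @param occasion_days days per occasion (default 7).
#' @param psi,p scalar probabilities for intercept-only truth (ignored when
#'   `beta`/`alpha` are given).
#' @param beta,alpha named logit-scale coefficient vectors; names must be
#'   `"(Intercept)"` plus covariate names (`"name^2"` for the quadratic
#'   companion of a generated numeric, `"nameLEVEL"` for a factor dummy).
#' @param covariates named list describing generators, each element
#'   `list(type = "normal")` (standard normal) or
#'   `list(type = "factor", levels = c(...), prob = NULL)`.
#' @param missingness probability a site-occasion cell is blanked at random
#'   (theft/failure gaps) in addition to trailing truncation.
#' @param deployment_days either `NULL` (all sites run the full grid) or
#'   `list(mean =, sd =, min =)` for truncated-normal deployment lengths
#'   converted to trailing missingness.
#' @param cooc optional named vector/list with `psiA, psiBA, psiBa, pA, pB,
#'   rA, rBA, rBa` for paired-species simulation.
#' @param seed mandatory integer seed.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_sites, n_occasions, occasion_days = 7,
                         psi = NULL, p = NULL, beta = NULL, alpha = NULL,
                         covariates = list(), missingness = 0,
                         deployment_days = NULL, cooc = NULL, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_occasions >= 1)
  if (is.null(beta)) {
    stopifnot(psi >= 0, psi <= 1)
    beta <- c("(Intercept)" = logit(min(max(psi, 1e-12), 1 - 1e-12)))
  }
  if (is.null(alpha)) {
    stopifnot(p >= 0, p <= 1)
    alpha <- c("(Intercept)" = logit(min(max(p, 1e-12), 1 - 1e-12)))
  }
  if (!is.null(cooc)) {
    cooc <- as.list(cooc)
    stopifnot(all(c("psiA", "psiBA", "psiBa", "pA", "pB", "rA", "rBA", "rBa")
                  %in% names(cooc)))
    stopifnot(all(unlist(cooc) >= 0 & unlist(cooc) <= 1))
  }
  structure(list(n_sites = n_sites, n_occasions = n_occasions,
                 occasion_days = occasion_days, beta = beta, alpha = alpha,
                 covariates = covariates, missingness = missingness,
                 deployment_days = deployment_days, cooc = cooc, seed = seed),
            class = "sim_scenario")
}

# draw the covariate table described by a scenario
sim_covariates <- function(scn) {
  n <- scn$n_sites
  tab <- data.frame(station_id = sprintf("st%03d", seq_len(n)))
  for (nm in names(scn$covariates)) {
    g <- scn$covariates[[nm]]
    tab[[nm]] <- switch(g$type,
      normal = rnorm(n),
      factor = sample(g$levels, n, replace = TRUE,
                      prob = g$prob %||% NULL),
      stop("unknown covariate generator type: ", g$type))
  }
  tab
}

# linear predictor from a named coefficient vector against the covariate table
sim_eta <- function(coefs, tab) {
  eta <- rep(0, nrow(tab))
  for (nm in names(coefs)) {
    if (nm == "(Intercept)") { eta <- eta + coefs[[nm]]; next }
    if (grepl("\\^2$", nm)) {
      base <- sub("\\^2$", "", nm)
      eta <- eta + coefs[[nm]] * tab[[base]]^2
      next
    }
    if (nm %in% names(tab)) { eta <- eta + coefs[[nm]] * tab[[nm]]; next }
    # factor dummy "nameLEVEL"
    hit <- FALSE
    for (cn in names(tab)) {
      if (startsWith(nm, cn) && !is.numeric(tab[[cn]])) {
        lev <- substring(nm, nchar(cn) + 1)
        eta <- eta + coefs[[nm]] * (as.character(tab[[cn]]) == lev)
        hit <- TRUE; break
      }
    }
    if (!hit) stop("coefficient names unknown covariate: ", nm)
  }
  eta
}

# missingness mask: trailing truncation from deployment lengths + random gaps
sim_missingness <- function(scn) {
  n <- scn$n_sites; J <- scn$n_occasions
  miss <- matrix(FALSE, n, J)
  eff <- matrix(as.integer(scn$occasion_days), n, J)
  if (!is.null(scn$deployment_days)) {
    dd <- scn$deployment_days
    len <- round(rnorm(n, dd$mean, dd$sd))
    len <- pmax(len, dd$min %||% scn$occasion_days)
    len <- pmin(len, J * scn$occasion_days)
    for (i in seq_len(n)) {
      full <- len[i] %/% scn$occasion_days
      rem <- len[i] - full * scn$occasion_days
      if (full < J) {
        eff[i, ] <- 0L
        if (full > 0) eff[i, seq_len(full)] <- scn$occasion_days
        if (rem > 0) eff[i, full + 1L] <- as.integer(rem)
      }
    }
  }
  if (scn$missingness > 0) {
    gaps <- matrix(runif(n * J) < scn$missingness, n, J)
    eff[gaps] <- 0L
  }
  miss <- eff == 0L
  list(miss = miss, effort = eff)
}

#' Simulate a single-species camera-trap dataset
#'
#' Draws site covariates, latent occupancy states z_i ~ Bernoulli(psi_i) and
#' detections y_ij ~ Bernoulli(z_i p_ij), then applies missingness by
#' blanking cells and zeroing effort. Returns the generating truth for
#' recovery tests.
#'
#' @param scenario a `sim_scenario`.
#' @param seed optional override of the scenario seed.
#' @return list with `history` (`detection_history`), `covariates`
#'   (data.frame), and `truth` (z, psi, p, beta, alpha, seed).
#' @export
simulate_single <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  scn <- scenario
  n <- scn$n_sites; J <- scn$n_occasions
  tab <- sim_covariates(scn)
  psi <- inv_logit(sim_eta(scn$beta, tab))
  eta_p <- sim_eta(scn$alpha, tab)
  p <- matrix(inv_logit(eta_p), n, J)
  z <- rbinom(n, 1, psi)
  y <- matrix(as.integer(rbinom(n * J, 1, as.vector(p) * rep(z, J))), n, J)
  mm <- sim_missingness(scn)
  y[mm$miss] <- NA_integer_
  colnames(y) <- colnames(mm$effort) <- paste0("occ_", seq_len(J))
  rownames(y) <- rownames(mm$effort) <- tab$station_id
  hist <- structure(list(species = "focal", stations = tab$station_id,
                         y = y, effort = mm$effort,
                         occasion_days = scn$occasion_days),
                    class = "detection_history")
  list(history = hist, covariates = tab,
       truth = list(z = z, psi = psi, p = p[, 1], beta = scn$beta,
                    alpha = scn$alpha, seed = seed))
}

#' Simulate a paired-species dataset under the psiBa parameterization
#'
#' Draws the joint latent state from the four-cell distribution
#' (psiA psiBA, psiA (1-psiBA), (1-psiA) psiBa, (1-psiA)(1-psiBa)), then
#' occasion-wise detections: A at rA (both present) or pA (A alone); B at
#' rBA/rBa conditioned on whether A was detected on that same occasion, or
#' pB when B is alone. Missingness is shared between the two species.
#'
#' @param scenario a `sim_scenario` with the `cooc` truth set.
#' @param seed optional override of the scenario seed.
#' @return list with `data` (a `cooc_data`) and `truth`.
#' @export
simulate_cooc <- function(scenario, seed = scenario$seed) {
  if (is.null(scenario$cooc)) stop("scenario has no co-occurrence truth")
  set.seed(seed)
  scn <- scenario
  mm <- sim_missingness(scn)
  sim <- simulate_cooc_at(scn$cooc, mm$miss)
  sim$effort <- mm$effort
  list(data = sim, truth = c(scn$cooc, list(seed = seed)))
}

#' Preset scenario: a Middle Cauca style cloud-forest survey
#'
#' The design constants of a three-reserve camera grid: 58 stations, weekly
#' occasions capped at 19, intercept-only truth psi = 0.68 and p = 0.15 (the
#' null-model estimates typical of a small montane felid), per-site
#' deployment lengths drawn Normal(130, 24) days truncated at >= 30 and
#' converted to trailing missingness.
#'
#' @param seed integer seed.
#' @return a `sim_scenario`.
#' @export
scenario_middle_cauca <- function(seed) {
  sim_scenario(n_sites = 58, n_occasions = 19, occasion_days = 7,
               psi = 0.68, p = 0.15,
               deployment_days = list(mean = 130, sd = 24, min = 30),
               seed = seed)
}

#' Write a simulated dataset in the ingestion CSV dialects
#'
#' Round-trip helper: emits the stations CSV, a records CSV with one record
#' per detected site-occasion (time-stamped at the first day of the
#' occasion), and the covariates CSV, so a simulated dataset can be pushed
#' through the same readers as field data.
#'
#' @param sim result of [simulate_single()].
#' @param dir output directory.
#' @param origin calendar date of every station's activation.
#' @return named list of written paths.
#' @export
write_simulated <- function(sim, dir, origin = as.Date("2021-01-01")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- sim$history
  ndays <- rowSums(h$effort)
  st <- data.frame(station_id = h$stations,
                   x = seq_along(h$stations) * 1000, y = 0,
                   coord_system = "planar",
                   activation_date = origin,
                   retrieval_date = origin + ndays - 1,
                   pir_delay_class = "fast", block_id = "sim")
  stations_path <- file.path(dir, "stations.csv")
  write.csv(st, stations_path, row.names = FALSE)
  idx <- which(h$y == 1, arr.ind = TRUE)
  rec <- data.frame(
    station_id = h$stations[idx[, 1]],
    species = h$species,
    timestamp = format(as.POSIXct(origin, tz = "UTC") +
                         ((idx[, 2] - 1) * h$occasion_days) * 86400 + 12 * 3600,
                       "%Y-%m-%dT%H:%M"))
  records_path <- file.path(dir, "records.csv")
  write.csv(rec, records_path, row.names = FALSE)
  cov_path <- file.path(dir, "covariates.csv")
  write.csv(sim$covariates, cov_path, row.names = FALSE)
  list(stations = stations_path, records = records_path,
       covariates = cov_path)
}
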