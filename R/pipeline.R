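#' Read a pipeline run configuration
#'
#' @param path YAML file; see [run_pipeline()] for the recognized keys.
#' @return a named list of class `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_config
#' @param cfg a named list of configuration values.
#' @export
as_run_config <- function(cfg) {
  need <- c("records", "stations", "output_dir", "focal_species", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("missing config key: ", paste(miss, collapse = ", "))
  for (k in c("records", "stations", "covariates")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("config path does not exist: ", k, " = ", cfg[[k]])
  }
  cfg$engine <- cfg$engine %||% "ml"
  cfg$occasion_days <- cfg$occasion_days %||% 7
  cfg$p_candidates <- unlist(cfg$p_candidates) %||% character(0)
  cfg$psi_candidates <- unlist(cfg$psi_candidates) %||% character(0)
  cfg$gof_sims <- cfg$gof_sims %||% 200
  cfg$mcmc <- modifyList(list(chains = 3, iterations = 4000), cfg$mcmc %||% list())
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full occupancy workflow
#'
#' Config-driven end-to-end run mirroring the analysis order of a
#' camera-trap occupancy study: detection histories from records, covariate
#' standardization and collinearity screen (with optional landscape PCA),
#' p-first sequential single-species selection, goodness of fit, spatial
#' residual diagnostics, and an optional conditional co-occurrence stage
#' whose psiB-side covariates come from the winning single-species model.
#' Every output file is recorded in a manifest with its MD5 hash so reruns
#' can be verified; all randomness is controlled by the config seed.
#'
#' Recognized config keys: `records`, `stations`, `covariates` (CSV paths),
#' `output_dir`, `focal_species`, `guild_map` (named list old->pooled),
#' `p_candidates`, `psi_candidates`, `engine` ("ml"/"bayes"),
#' `landscape_metrics` (columns to PCA), `cooc_pairs` (list of lists with
#' `A`, `B`), `seed`, `occasion_days`, `gof_sims`, `mcmc`
#' (`chains`, `iterations`).
#'
#' @param config a `run_config`, a list, or a YAML path.
#' @return invisible list of stage outputs, including the `manifest`
#'   data.frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  cfg <- config
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("camoccu %s | R %s",
                         as.character(utils::packageVersion("camoccu")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("seed: %d", cfg$seed),
                 sprintf("engine: %s", cfg$engine))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out, name)
    write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  stations <- stage("ingest", read_stations(cfg$stations))
  records <- stage("ingest", read_records(cfg$records, stations))
  if (!is.null(cfg$guild_map))
    records <- pool_guild(records, cfg$guild_map)
  records <- filter_independent(records)

  species_needed <- unique(c(cfg$focal_species,
                             unlist(lapply(cfg$cooc_pairs, function(p)
                               c(p$A, p$B)))))
  histories <- stage("histories", {
    hs <- lapply(species_needed, function(sp)
      build_history(records, stations, sp, cfg$occasion_days))
    names(hs) <- species_needed
    hs
  })
  for (sp in species_needed)
    stage("histories", {
      write_history(histories[[sp]],
                    file.path(out, paste0("history_", sp, ".csv")),
                    file.path(out, paste0("effort_", sp, ".csv")))
      written <<- c(written, file.path(out, paste0("history_", sp, ".csv")),
                    file.path(out, paste0("effort_", sp, ".csv")))
    })
  summ <- summarize_survey(histories, stations, records)
  emit(summ$blocks, "survey_blocks.csv")
  emit(summ$species, "survey_species.csv")

  covs <- NULL
  if (!is.null(cfg$covariates)) {
    covs <- stage("covariates", {
      cv <- read.csv(cfg$covariates, stringsAsFactors = FALSE)
      cv <- cv[match(stations$station_id, cv$station_id), , drop = FALSE]
      if (anyNA(cv$station_id)) stop("covariate table missing stations")
      cv
    })
    if (!is.null(cfg$landscape_metrics)) {
      pca <- stage("covariates",
                   pca_landscape(covs[, unlist(cfg$landscape_metrics),
                                      drop = FALSE]))
      emit(data.frame(component = seq_along(pca$eigenvalues),
                      eigenvalue = pca$eigenvalues), "pca_eigenvalues.csv")
      emit(data.frame(metric = rownames(pca$loadings), pca$loadings),
           "pca_loadings.csv")
      emit(data.frame(station_id = covs$station_id,
                      LS = pca$scores[, 1]), "pca_scores.csv")
      covs$LS <- as.numeric(scale(pca$scores[, 1]))
    }
    num <- setdiff(names(covs)[vapply(covs, is.numeric, logical(1))],
                   "station_id")
    if (length(num) >= 2)
      emit(as.data.frame(correlation_screen(covs, columns = num)),
           "correlation_screen.csv")
    covs <- zscore(covs, setdiff(num, "LS"))
  } else {
    covs <- data.frame(station_id = stations$station_id)
  }
  covs$pir_delay_class <- as.character(stations$pir_delay_class)
  covs$block_id <- as.character(stations$block_id)

  focal <- histories[[cfg$focal_species]]
  sel <- stage("selection", p_first_selection(
    focal, covs, cfg$p_candidates, cfg$psi_candidates,
    engine = cfg$engine, seed = cfg$seed,
    chains = if (cfg$engine == "bayes") cfg$mcmc$chains else 3,
    iterations = if (cfg$engine == "bayes") cfg$mcmc$iterations else 4000))
  emit(sel$stage_p, "selection_stage_p.csv")
  emit(sel$stage_psi, "selection_stage_psi.csv")
  fit <- sel$final_fit
  report <- fit_report(fit)
  report_path <- file.path(out, "final_fit.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  written <- c(written, report_path)

  gof <- stage("gof", {
    if (cfg$engine == "ml")
      gof_bootstrap(fit, focal, n_sims = cfg$gof_sims, seed = cfg$seed + 17)
    else
      gof_posterior_predictive(fit, focal, n_draws_used = cfg$gof_sims,
                               seed = cfg$seed + 17)
  })
  emit(data.frame(mode = gof$mode, statistic = gof$statistic,
                  p_value = gof$p_value, n_replicates = gof$n_replicates),
       "gof.csv")

  spat <- stage("spatial", {
    res <- occupancy_residuals(fit, focal)
    sw <- spatial_weights(stations$x, stations$y, stations$coord_system[1])
    mi <- morans_i(res, sw)
    cg <- distance_correlogram(res, stations$x, stations$y,
                               stations$coord_system[1],
                               seed = cfg$seed + 31)
    list(moran = mi, correlogram = cg, residuals = res)
  })
  emit(data.frame(I = spat$moran$I, expectation = spat$moran$expectation,
                  z = spat$moran$z, p_value = spat$moran$p_value),
       "moran.csv")
  emit(as.data.frame(spat$correlogram), "correlogram.csv")
  plot_path <- file.path(out, "correlogram.pdf")
  grDevices::pdf(plot_path, width = 6, height = 4)
  plot(spat$correlogram)
  grDevices::dev.off()
  written <- c(written, plot_path)

  cooc_fits <- NULL
  if (length(cfg$cooc_pairs %||% list()) > 0) {
    cooc_fits <- stage("cooccurrence", {
      lapply(cfg$cooc_pairs, function(pair) {
        cd <- cooc_data(histories[[pair$A]], histories[[pair$B]])
        fits <- lapply(enumerate_variants(), function(sp2)
          fit_cooc(cd, sp2))
        names(fits) <- vapply(fits, function(f) f$spec$label, character(1))
        tab <- aicc_table(fits)
        best <- fits[[match(tab$model[1], names(fits))]]
        list(pair = pair, table = tab, best = best)
      })
    })
    for (i in seq_along(cooc_fits)) {
      cf <- cooc_fits[[i]]
      nm <- paste0("cooc_", cf$pair$A, "_", cf$pair$B)
      emit(cf$table, paste0(nm, "_selection.csv"))
      emit(cooc_report(cf$best), paste0(nm, "_best.csv"))
    }
  } else {
    log_lines <- c(log_lines, "co-occurrence stage skipped: no pairs configured")
  }

  log_lines <- c(log_lines, paste("stage complete:",
                                  c("ingest", "histories", "covariates",
                                    "selection", "gof", "spatial",
                                    if (!is.null(cooc_fits)) "cooccurrence")))
  log_path <- file.path(out, "run_log.txt")
  writeLines(log_lines, log_path)
  written <- c(written, log_path)
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  invisible(list(summary = summ, selection = sel, fit = fit, gof = gof,
                 spatial = spat, cooc = cooc_fits, manifest = manifest))
}

# JSON-ready report of a single-species fit
fit_report <- function(fit) {
  if (inherits(fit, "occu_fit_bayes")) {
    list(label = fit$spec$label,
         interpretation = "habitat use (psi) / intensity of use (p)",
         engine = "bayes",
         coefficients = data.frame(parameter = rownames(fit$summary),
                                   fit$summary),
         elpd_loo = fit$elpd_loo, elpd_loo_se = fit$elpd_loo_se,
         max_rhat = max(fit$rhat), seed = fit$seed)
  } else {
    list(label = fit$spec$label,
         interpretation = "habitat use (psi) / intensity of use (p)",
         engine = "ml",
         coefficients = data.frame(parameter = names(fit$estimates),
                                   estimate = unname(fit$estimates),
                                   se = unname(fit$se),
                                   lower = unname(fit$estimates - 1.96 * fit$se),
                                   upper = unname(fit$estimates + 1.96 * fit$se)),
         loglik = fit$loglik, aicc = fit$aicc, converged = fit$converged)
  }
}

# flat data.frame report of a co-occurrence fit keyed by the canonical
# psiBa parameter names
cooc_report <- function(fit) {
  data.frame(parameter = names(fit$params),
             estimate = unname(fit$params), se = unname(fit$se),
             sif = fit$phi, dif = fit$delta, aicc = fit$aicc, k = fit$k)
}
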