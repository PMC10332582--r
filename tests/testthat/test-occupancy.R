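test_that("site likelihood matches hand-computed cases and skips missing occasions", {
  expect_equal(site_likelihood(c(1, 0, 1), 0.5, 0.5), 0.0625)
  expect_equal(site_likelihood(c(0, 0, 0), 0.5, 0.5), 0.5625)
  expect_equal(site_likelihood(c(1, NA, 0), 0.5, 0.5), 0.125)
  expect_error(site_likelihood(c(NA, NA), 0.5, 0.5), "missing")
})

test_that("site likelihood normalizes over all histories (enumeration)", {
  set.seed(1)
  for (J in 2:4) {
    H <- enum_histories(J)
    for (r in 1:5) {
      psi <- runif(1, 0.05, 0.95)
      p <- runif(J, 0.05, 0.95)
      tot <- sum(apply(H, 1, site_likelihood, psi = psi, p = p))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("ML fit recovers an intercept-only truth and flags degenerate data", {
  scn <- sim_scenario(n_sites = 200, n_occasions = 8, psi = 0.6, p = 0.35,
                      seed = 21)
  sim <- simulate_single(scn)
  f <- fit_ml(sim$history, null_design(sim$history))
  expect_true(f$converged)
  expect_equal(f$loglik, sum(f$pointwise), tolerance = 1e-8)
  expect_equal(f$n_params, 2)
  expect_lt(abs(plogis(f$estimates[1]) - 0.6), 0.12)
  expect_lt(abs(plogis(f$estimates[2]) - 0.35), 0.08)

  # all-ones data: boundary MLE with a warning
  ones <- as_history(matrix(1L, 10, 4))
  expect_warning(fb <- fit_ml(ones, null_design(ones)), "boundary")
  expect_gt(plogis(fb$estimates[1]), 0.999)
  expect_gt(plogis(fb$estimates[2]), 0.999)

  # no detections at all: psi and p not jointly identifiable
  zeros <- as_history(matrix(0L, 10, 4))
  expect_error(fit_ml(zeros, null_design(zeros)), "identifiable")
})

test_that("reports label estimates as habitat use / intensity of use", {
  scn <- sim_scenario(n_sites = 60, n_occasions = 5, psi = 0.6, p = 0.4,
                      seed = 3)
  sim <- simulate_single(scn)
  f <- fit_ml(sim$history, null_design(sim$history))
  expect_match(paste(capture.output(print(f)), collapse = " "),
               "habitat use")
  expect_match(paste(capture.output(print(f)), collapse = " "),
               "intensity of use")
})

test_that("conditional occupancy is 1 for detected sites and Bayes-rule otherwise", {
  y <- rbind(c(1L, 0L, 0L), c(0L, 0L, 0L))
  h <- as_history(y)
  d <- null_design(h)
  # force psi = p = 0.5 through a fixed parameter vector
  f <- list(estimates = c(0, 0), designs = d, y = y)
  class(f) <- "occu_fit_ml"
  co <- conditional_occupancy(f)
  expect_equal(co[1], 1)
  expect_equal(co[2], 0.0625 / 0.5625, tolerance = 1e-10)
  # p -> 1 limit drives the all-zero conditional to 0
  f2 <- list(estimates = c(0, 20), designs = d, y = y)
  class(f2) <- "occu_fit_ml"
  expect_lt(conditional_occupancy(f2)[2], 1e-8)
})

test_that("response curves respect the link and quadratic turning point", {
  set.seed(4)
  scn <- sim_scenario(
    n_sites = 600, n_occasions = 10,
    beta = c("(Intercept)" = 0.5, elev = 0.8, "elev^2" = -0.7),
    alpha = c("(Intercept)" = -0.6),
    covariates = list(elev = list(type = "normal")), seed = 31)
  sim <- simulate_single(scn)
  d <- build_design(sim$covariates, psi_terms = c("elev", "elev^2"),
                    effort = sim$history$effort)
  f <- fit_ml(sim$history, d)
  grid <- data.frame(elev = seq(-2, 2, length.out = 201))
  pr <- predict_response(f, "psi", grid)
  expect_true(all(pr$estimate > 0 & pr$estimate < 1))
  expect_true(all(pr$lower <= pr$estimate & pr$estimate <= pr$upper))
  b <- f$estimates
  xstar <- -b["psi_elev"] / (2 * b["psi_elev^2"])
  expect_equal(grid$elev[which.max(pr$estimate)], unname(xstar),
               tolerance = 0.03)
  # a positive single slope gives a strictly increasing curve
  f1 <- list(estimates = c(0, 1, -1), designs =
               build_design(sim$covariates, psi_terms = "elev",
                            effort = sim$history$effort),
             vcov = diag(3), y = sim$history$y)
  class(f1) <- "occu_fit_ml"
  pr1 <- predict_response(f1, "psi", grid)
  expect_true(all(diff(pr1$estimate) > 0))
  expect_error(predict_response(f, "psi", data.frame(slope = 0)), "slope")
})

test_that("Wald intervals achieve near-nominal coverage over replicates", {
  # moderate check here (deeper 50-replicate sweep in the acceptance suite)
  truth <- c(0.3, 0.8)
  hits <- 0
  for (r in 1:12) {
    scn <- sim_scenario(n_sites = 200, n_occasions = 10,
                        beta = c("(Intercept)" = truth[1], x = truth[2]),
                        alpha = c("(Intercept)" = -0.4),
                        covariates = list(x = list(type = "normal")),
                        seed = 500 + r)
    sim <- simulate_single(scn)
    d <- build_design(sim$covariates, psi_terms = "x",
                      effort = sim$history$effort)
    f <- fit_ml(sim$history, d)
    ci <- cbind(f$estimates - 1.96 * f$se, f$estimates + 1.96 * f$se)
    hits <- hits + (ci[2, 1] <= truth[2] && truth[2] <= ci[2, 2])
  }
  expect_gte(hits, 9)
})
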