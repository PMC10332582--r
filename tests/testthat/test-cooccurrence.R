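all_half <- list(psiA = .5, psiBA = .5, psiBa = .5, pA = .5, pB = .5,
                 rA = .5, rBA = .5, rBa = .5)

test_that("joint site likelihood matches the four-state hand sums", {
  expect_equal(cooc_site_likelihood(1, 1, all_half), 0.0625)
  expect_equal(cooc_site_likelihood(0, 0, all_half), 0.5625)
  s <- cooc_site_likelihood(1, 1, all_half) +
    cooc_site_likelihood(1, 0, all_half) +
    cooc_site_likelihood(0, 1, all_half) +
    cooc_site_likelihood(0, 0, all_half)
  expect_equal(s, 1)
  expect_error(cooc_site_likelihood(c(1, NA), c(1, 0), all_half),
               "missingness")
})

test_that("joint likelihood normalizes over 4^J histories at random parameters", {
  set.seed(2)
  for (r in 1:8) {
    J <- sample(1:3, 1)
    pars <- as.list(setNames(runif(8, 0.05, 0.95),
                             c("psiA", "psiBA", "psiBa", "pA", "pB",
                               "rA", "rBA", "rBa")))
    grids <- expand.grid(rep(list(0:1), 2 * J))
    tot <- sum(apply(grids, 1, function(g)
      cooc_site_likelihood(as.numeric(g[1:J]),
                           as.numeric(g[(J + 1):(2 * J)]), pars)))
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("marginalizing species B reproduces species A's mixture likelihood", {
  set.seed(3)
  J <- 2
  pars <- as.list(setNames(runif(8, 0.1, 0.9),
                           c("psiA", "psiBA", "psiBa", "pA", "pB",
                             "rA", "rBA", "rBa")))
  yB_all <- expand.grid(rep(list(0:1), J))
  for (yA in list(c(0, 0), c(1, 0), c(1, 1))) {
    marg <- sum(apply(yB_all, 1, function(yb)
      cooc_site_likelihood(yA, as.numeric(yb), pars)))
    # A alone: occupancy psiA, detection a psiBA-weighted mixture of rA / pA
    lik_r <- prod(pars$rA^yA * (1 - pars$rA)^(1 - yA))
    lik_p <- prod(pars$pA^yA * (1 - pars$pA)^(1 - yA))
    direct <- pars$psiA * (pars$psiBA * lik_r + (1 - pars$psiBA) * lik_p) +
      (1 - pars$psiA) * all(yA == 0)
    expect_equal(marg, direct, tolerance = 1e-12)
  }
})

test_that("variant enumeration spans the 2x2 grid with counts 4/5/7/8", {
  vs <- enumerate_variants()
  expect_length(vs, 4)
  expect_setequal(vapply(vs, function(v) v$k, numeric(1)), c(4, 5, 7, 8))
  va <- enumerate_variants(psi_b_terms = "leaf_litter")
  expect_length(va, 8)
  aug <- va[[8]]
  expect_equal(aug$k, 9)
  expect_equal(aug$psi_b_terms, "leaf_litter")
})

test_that("interaction factors follow their closed forms and error cases", {
  expect_equal(species_interaction_factor(0.5, 0.8, 0.2), 1.6)
  expect_equal(species_interaction_factor(0.5, 0.4, 0), 2)   # 1/psiA limit
  for (psiA in c(0.2, 0.5, 0.73, 0.9))
    expect_equal(species_interaction_factor(psiA, 0.73, 0.73), 1)
  expect_error(species_interaction_factor(0, 0.5, 0.5), "psiA")
  expect_equal(detection_interaction_factor(0.5, 0.3, 0.2), 3)
  expect_equal(detection_interaction_factor(0.9, 0.09, 0.1), 1)
  r <- c(0.4, 0.4 * 0.25, 0.25)
  expect_equal(detection_interaction_factor(r[1], r[2], r[3]), 1)
  expect_error(detection_interaction_factor(0, 0.1, 0.1), "denominator")
})

test_that("the independent variant factorizes into two single-species fits", {
  scn <- sim_scenario(n_sites = 250, n_occasions = 6, psi = .5, p = .5,
                      cooc = all_half, seed = 41)
  sim <- simulate_cooc(scn)
  fc <- fit_cooc(sim$data, cooc_spec(FALSE, FALSE))
  expect_equal(fc$k, 4)
  hA <- as_history(sim$data$yA); hB <- as_history(sim$data$yB)
  fA <- fit_ml(hA, null_design(hA))
  fB <- fit_ml(hB, null_design(hB))
  expect_equal(fc$loglik, fA$loglik + fB$loglik, tolerance = 1e-6)
  # aliased parameters are exactly equal
  expect_identical(unname(fc$params["pA"]), unname(fc$params["rA"]))
  expect_identical(unname(fc$params["pB"]), unname(fc$params["rBA"]))
  expect_equal(fc$phi, 1, tolerance = 1e-10)
  expect_true(is.na(fc$delta))
})

test_that("maximized loglik is monotone across the nested variants", {
  truth <- list(psiA = .6, psiBA = .75, psiBa = .35, pA = .4, pB = .3,
                rA = .45, rBA = .5, rBa = .2)
  scn <- sim_scenario(n_sites = 300, n_occasions = 8, psi = .5, p = .5,
                      cooc = truth, seed = 13)
  sim <- simulate_cooc(scn)
  lls <- vapply(enumerate_variants(), function(v)
    fit_cooc(sim$data, v)$loglik, numeric(1))
  ord <- order(vapply(enumerate_variants(), function(v) v$k, numeric(1)))
  expect_true(all(diff(lls[ord]) >= -1e-6))
  full <- fit_cooc(sim$data, cooc_spec(TRUE, TRUE))
  expect_equal(full$k, 8)
  expect_true(all(full$params >= 0 & full$params <= 1))
})

test_that("fit_cooc names the species that lacks detections", {
  scn <- sim_scenario(n_sites = 40, n_occasions = 5, psi = .5, p = .5,
                      cooc = all_half, seed = 19)
  sim <- simulate_cooc(scn)
  sim$data$yB[sim$data$yB == 1L] <- 0L
  sim$data$species[["B"]] <- "tiger_cat"
  expect_error(fit_cooc(sim$data), "tiger_cat")
})

test_that("SIF recovery is near 1 when occupancy is unconditional", {
  truth <- list(psiA = .6, psiBA = .5, psiBa = .5, pA = .4, pB = .3,
                rA = .4, rBA = .35, rBa = .25)
  scn <- sim_scenario(n_sites = 2000, n_occasions = 8, psi = .5, p = .5,
                      cooc = truth, seed = 23)
  sim <- simulate_cooc(scn)
  fc <- fit_cooc(sim$data, cooc_spec(TRUE, TRUE))
  expect_gt(fc$phi, 0.9)
  expect_lt(fc$phi, 1.1)
})

test_that("parametric bootstrap intervals bracket the interaction factors", {
  truth <- list(psiA = .6, psiBA = .8, psiBa = .3, pA = .45, pB = .35,
                rA = .45, rBA = .5, rBa = .25)
  scn <- sim_scenario(n_sites = 400, n_occasions = 8, psi = .5, p = .5,
                      cooc = truth, seed = 29)
  sim <- simulate_cooc(scn)
  fc <- fit_cooc(sim$data, cooc_spec(TRUE, TRUE))
  bs <- sif_dif_bootstrap(fc, n_boot = 30, seed = 8)
  expect_true(bs$phi$lower <= fc$phi && fc$phi <= bs$phi$upper)
  expect_true(is.finite(bs$delta$lower))
  bs2 <- sif_dif_bootstrap(fc, n_boot = 30, seed = 8)
  expect_identical(bs$draws, bs2$draws)
})
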