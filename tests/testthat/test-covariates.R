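test_that("zscore standardizes to sample SD 1, is idempotent, rejects constants", {
  tab <- data.frame(station_id = c("a", "b", "c"), v = c(1, 2, 3),
                    k = c(5, 5, 5))
  out <- zscore(tab, "v")
  expect_equal(out$v, c(-1, 0, 1))
  expect_equal(zscore(out, "v")$v, out$v, tolerance = 1e-12)
  expect_error(zscore(tab, "k"), "k")
  expect_error(zscore(tab, "ghost"), "ghost")
  # missing cells propagate
  tab$w <- c(1, NA, 3)
  expect_true(is.na(zscore(tab, "w")$w[2]))
})

test_that("correlation screen flags |r| above the strict 0.65 threshold", {
  set.seed(42)
  n <- 120
  z <- rnorm(n)
  tab <- data.frame(a = z, dup = z)
  # construct a pair with r ~ 0.83 (the cohesion-vs-amount structure)
  tab$b <- 0.83 * scale(z)[, 1] + sqrt(1 - 0.83^2) * scale(rnorm(n))[, 1]
  tab$c <- 0.50 * scale(z)[, 1] + sqrt(1 - 0.50^2) * scale(rnorm(n))[, 1]
  scr <- correlation_screen(tab, threshold = 0.65)
  row <- function(v1, v2) scr[(scr$var1 == v1 & scr$var2 == v2) |
                                (scr$var1 == v2 & scr$var2 == v1), ]
  expect_equal(row("a", "dup")$r_2dp, 1.00)
  expect_true(row("a", "dup")$flagged)
  expect_true(abs(row("a", "b")$r) > 0.75)   # near the built 0.83
  expect_true(row("a", "b")$flagged)
  expect_false(row("a", "c")$flagged)
  # symmetric in column order and invariant to affine rescaling
  scr2 <- correlation_screen(tab[, c("c", "b", "dup", "a")])
  expect_equal(sort(scr2$r), sort(scr$r))
  tab2 <- tab; tab2$a <- 100 - 3 * tab2$a
  scr3 <- correlation_screen(tab2)
  expect_equal(abs(row("a", "b")$r),
               abs(scr3[(scr3$var1 == "a" & scr3$var2 == "b"), ]$r),
               tolerance = 1e-12)
  # fewer than 3 complete rows -> not evaluable
  small <- data.frame(x = c(1, 2, NA, NA), y = c(NA, 3, 4, 5))
  expect_false(correlation_screen(small)$evaluable)
})

test_that("landscape PCA uses the correlation matrix, Kaiser rule and sign anchor", {
  # two perfectly correlated metrics: eigenvalues [2, 0], one retained
  z <- rnorm(50)
  p2 <- pca_landscape(data.frame(amount = z, cohesion = 2 * z + 1))
  expect_equal(p2$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(p2$n_retained, 1)

  # four metrics with the field's sign structure: amount/cohesion move
  # together, heterogeneity and edge density against them
  set.seed(7)
  n <- 200
  g <- rnorm(n)
  mx <- data.frame(forest_amount = g + 0.3 * rnorm(n),
                   cohesion = 0.9 * g + 0.4 * rnorm(n),
                   heterogeneity = -0.9 * g + 0.4 * rnorm(n),
                   edge_density = -0.85 * g + 0.4 * rnorm(n))
  ps <- pca_landscape(mx)
  expect_gte(ps$n_retained, 1)
  expect_lt(ps$loadings["forest_amount", 1], 0)   # sign convention
  # negative PC1 scores align with high forest amount
  expect_lt(cor(ps$scores[, 1], mx$forest_amount), 0)
  # eigenvalues sum to the number of metrics; scores centered;
  # reconstruction from all components returns the scaled matrix
  expect_equal(sum(ps$eigenvalues), 4, tolerance = 1e-9)
  expect_equal(max(abs(colMeans(ps$scores))), 0, tolerance = 1e-9)
  rec <- ps$scores %*% t(ps$loadings)
  expect_equal(unname(rec), unname(scale(as.matrix(mx))),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pca_landscape(data.frame(a = rep(1, 10), b = rnorm(10))),
               "constant")
})

test_that("independent metrics give near-unit eigenvalues at large n", {
  set.seed(99)
  m <- as.data.frame(matrix(rnorm(4e4), ncol = 4))
  ev <- pca_landscape(m)$eigenvalues
  expect_true(all(abs(ev - 1) < 0.1))
})

test_that("design matrices carry intercepts, dummies, squares and effort", {
  tab <- data.frame(station_id = c("a", "b", "c", "d"),
                    elevation = c(-1.2, 0, 0.5, 0.7),
                    pir_delay_class = c("slow", "fast", "fast", "slow"))
  eff <- matrix(c(7L, 7L, 7L, 7L, 3L, 7L, 0L, 7L), 4, 2)
  d0 <- build_design(tab)
  expect_equal(d0$X, matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)")))
  d1 <- build_design(tab, psi_terms = c("elevation", "elevation^2"),
                     p_terms = "pir_delay_class", effort = eff)
  expect_equal(unname(d1$X[, 3]), unname(d1$X[, 2])^2)
  expect_equal(dim(d1$W), c(4, 2, 2))            # intercept + 1 dummy
  expect_equal(dimnames(d1$W)[[3]], c("(Intercept)", "pir_delay_classslow"))
  expect_equal(d1$reference_levels$pir_delay_class, "fast")  # alphabetical
  d2 <- build_design(tab, p_terms = "effort", effort = eff)
  expect_equal(mean(d2$W[, , 2]), 0, tolerance = 1e-12)
  expect_error(build_design(tab, psi_terms = "slope"), "slope")
  expect_error(build_design(tab, psi_terms = "pir_delay_class^2"),
               "categorical")
  expect_error(build_design(tab, p_terms = "effort"), "effort")
  # deterministic: identical inputs, identical term ordering
  expect_identical(build_design(tab, psi_terms = c("elevation", "elevation^2"),
                                p_terms = "pir_delay_class", effort = eff)$X,
                   d1$X)
})
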