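test_that("polychoric estimation recovers the latent correlation", {
  # comonotonic limit: an item paired with itself pushes rho to the bound
  set.seed(101)
  x <- sample.int(5, 500, replace = TRUE, prob = c(.1, .2, .3, .25, .15))
  same <- polychoric_pair(x, x)
  expect_equal(same$rho, 0.999)
  expect_false(same$converged)

  # independent items: rho near zero
  z1 <- findInterval(rnorm(20000), c(-1, 0, 1)) + 1L
  z2 <- findInterval(rnorm(20000), c(-0.5, 0.5, 1.5)) + 1L
  ind <- polychoric_pair(z1, z2)
  expect_lt(abs(ind$rho), 0.02)

  # generative oracle: discretized bivariate normal with rho = 0.6
  n <- 50000
  u <- rnorm(n); v <- 0.6 * u + sqrt(1 - 0.36) * rnorm(n)
  cuts <- c(-1.2, -0.3, 0.5, 1.4)
  y1 <- findInterval(u, cuts) + 1L
  y2 <- findInterval(v, cuts) + 1L
  est <- polychoric_pair(y1, y2)
  expect_gte(est$rho, 0.58)
  expect_lte(est$rho, 0.62)
})

test_that("polychoric matrices are symmetric with unit diagonal", {
  sim <- ability_like_sim(n_persons = 300, n_items = 5, seed = 19)
  pc <- polychoric_matrix(sim$rm)
  expect_equal(pc$rho, t(pc$rho))
  expect_equal(diag(pc$rho), setNames(rep(1, 5), sim$rm$item_ids))
  expect_true(all(abs(pc$rho) <= 1))

  # invariant to relabeling persons
  shuf <- sim$rm
  ord <- rev(seq_len(nrow(shuf$responses)))
  shuf$responses <- shuf$responses[ord, ]
  shuf$person_ids <- shuf$person_ids[ord]
  expect_equal(polychoric_matrix(shuf)$rho, pc$rho)

  const <- response_matrix(cbind(rep(2L, 10), c(1L, rep(2L, 9))))
  expect_error(polychoric_matrix(const), "single observed category")
})

test_that("a rank-one correlation structure is fitted perfectly", {
  lam <- c(0.8, 0.7, 0.85, 0.6, 0.75)
  R <- tcrossprod(lam); diag(R) <- 1
  fit <- one_factor_fit(R, n = 500)
  expect_equal(unname(fit$loadings), lam, tolerance = 1e-4)
  expect_equal(fit$fit_indices$cfi, 1)
  expect_equal(fit$fit_indices$rmsea, 0)
  expect_lt(fit$fit_indices$srmr, 1e-6)
})

test_that("an identity matrix triggers the degenerate-baseline clamp", {
  fit <- one_factor_fit(diag(6), n = 200)
  expect_true(fit$degenerate_baseline)
  expect_equal(fit$fit_indices$cfi, 1)
})

test_that("unidimensional synthetic data meet the conventional fit criteria", {
  sim <- ability_like_sim(n_persons = 1000, n_items = 35, seed = 11)
  pc <- polychoric_matrix(sim$rm)
  fit <- one_factor_fit(pc, nrow(sim$rm$responses))
  expect_gt(fit$fit_indices$cfi, 0.95)
  expect_lt(fit$fit_indices$srmr, 0.08)

  efa <- efa_eigen_ratio(pc)
  expect_gt(efa$ratio, 4)
  expect_gt(efa$pct_first, 0.20)
  # trace preservation
  expect_equal(sum(efa$eigenvalues), 35, tolerance = 1e-8)

  # identity: all eigenvalues one, ratio one
  id <- efa_eigen_ratio(diag(7))
  expect_equal(id$eigenvalues, rep(1, 7))
  expect_equal(id$ratio, 1)
})

test_that("self-consistency: a model-implied matrix returns its loadings", {
  set.seed(23)
  lam <- runif(10, 0.5, 0.9)
  R <- tcrossprod(lam); diag(R) <- 1
  fit <- one_factor_fit(R, n = 1000)
  expect_equal(unname(fit$loadings), lam, tolerance = 1e-4)
})

test_that("local dependence flags exactly the constructed pairs", {
  res <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  none <- local_dependence(res)
  expect_equal(nrow(none$flagged_pairs), 0L)

  res["b", "c"] <- res["c", "b"] <- 0.25
  one <- local_dependence(res, 0.20)
  expect_equal(nrow(one$flagged_pairs), 1L)
  expect_setequal(c(one$flagged_pairs$item_i, one$flagged_pairs$item_j),
                  c("b", "c"))
})

test_that("a shared nuisance factor shows up as a residual-correlation flag", {
  # 8 unidimensional items plus a doublet loading on an extra factor
  set.seed(31)
  n <- 1500
  theta <- rnorm(n)
  nuis <- rnorm(n)
  d <- simulation_design(n_items = 8, seed = 31)
  bank <- sample_bank(d)
  X <- matrix(0L, n, 8)
  for (i in 1:8) {
    eff <- theta
    if (i %in% c(3, 4)) eff <- (theta + 1.2 * nuis) / sqrt(1 + 1.2^2)
    pr <- prob_categories(bank$slope[i], bank$thresholds[[i]], eff)
    u <- runif(n)
    X[, i] <- 1L + rowSums(u > t(apply(pr, 1, cumsum)))
  }
  rm <- response_matrix(pmin(X, 5L))
  fit <- one_factor_fit(polychoric_matrix(rm), n)
  ld <- local_dependence(fit, 0.20)
  expect_gte(nrow(ld$flagged_pairs), 1L)
  expect_true(any(ld$flagged_pairs$item_i == "item3" &
                    ld$flagged_pairs$item_j == "item4"))
})
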