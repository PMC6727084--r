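test_that("lambda_max is the zero-solution threshold", {
  # single informative column: weighted score equals the constructed value
  set.seed(110)
  n <- 30
  mk <- function(seed, b) make_cohort(n, 1, seed = seed, beta = b,
                                      censor = 0.2)
  dA <- mk(111, 1)
  dB <- mk(112, 0)
  md <- multi_cancer_data(list(dA, dB))
  w <- compute_km_weights_all(md)
  prep <- aftfuse:::prepare_problem(md, w)
  scores <- abs(c(prep$cohorts[[1]]$sxy, prep$cohorts[[2]]$sxy))
  expect_equal(lambda_max(md, w), max(scores))
  # homogeneity: scaling y scales lambda_max (times enter on the log scale,
  # so scale the canonical log-times directly)
  md2 <- md
  for (k in 1:2) md2$datasets[[k]]$y <- 2 * md2$datasets[[k]]$y
  expect_equal(lambda_max(md2, w), 2 * lambda_max(md, w), tolerance = 1e-12)
  # y orthogonal to X under the weights: threshold collapses to 0
  md0 <- md
  for (k in 1:2) {
    co <- prep$cohorts[[k]]
    d <- md0$datasets[[k]]
    # remove the weighted projection of (centered) y on the column
    num <- sum(w[[k]]$w * co$Xs[, 1] * co$yc)
    den <- sum(w[[k]]$w * co$Xs[, 1]^2)
    md0$datasets[[k]]$y <- d$y - num / den * co$Xs[, 1]
  }
  # re-sorting may break: keep the same order, weights unchanged
  expect_lt(lambda_max(md0, w), 1e-12)
})

test_that("CV selection is deterministic and respects single-point grids", {
  md <- make_multi(2, 40, 3, seed = 120, beta = c(1.5, 0, 0))
  w <- compute_km_weights_all(md)
  template <- penalty_spec("magnitude")
  t1 <- select_lambdas_cv(md, w, template, V = 3, seed = 9,
                          n_sparsity = 3, fusion_multipliers = c(0, 1))
  t2 <- select_lambdas_cv(md, w, template, V = 3, seed = 9,
                          n_sparsity = 3, fusion_multipliers = c(0, 1))
  expect_identical(t1$folds, t2$folds)
  expect_equal(t1$grid$cv_mean, t2$grid$cv_mean)
  expect_equal(t1$selected$lambda_sparsity, t2$selected$lambda_sparsity)
  # one candidate pair: that pair is selected
  single <- select_lambdas_cv(md, w, template, V = 3, seed = 9,
                              n_sparsity = 1, fusion_multipliers = 1)
  expect_equal(single$selected$lambda_sparsity, lambda_max(md, w))
  expect_equal(single$selected$lambda_fusion, lambda_max(md, w))
})

test_that("CV loss at the null model equals the intercept-only loss", {
  md <- make_multi(2, 45, 3, seed = 125, beta = c(1, 0, 0))
  w <- compute_km_weights_all(md)
  template <- penalty_spec("none")
  # a sparsity level above every training fold's own threshold guarantees
  # the null (intercept-only) fit on every fold
  res <- select_lambdas_cv(md, w, template, V = 3, seed = 4,
                           sparsity_values = 10 * lambda_max(md, w),
                           fusion_multipliers = 0)
  # recompute the intercept-only weighted holdout loss with the same folds
  losses <- c()
  for (v in 1:3) {
    for (k in 1:2) {
      tr <- aftfuse:::subset_rows(md$datasets[[k]], which(res$folds[[k]] != v))
      te <- aftfuse:::subset_rows(md$datasets[[k]], which(res$folds[[k]] == v))
      wt <- compute_km_weights(tr)$w
      mu <- sum(wt * tr$y) / sum(wt)
      wte <- compute_km_weights(te)$w
      losses <- c(losses, sum(wte * (te$y - mu)^2) / sum(wte))
    }
  }
  expect_equal(res$grid$cv_mean[1], mean(losses), tolerance = 1e-10)
})

test_that("stratification demands enough events and folds are stratified", {
  d_few <- canonicalize(cancer_dataset(
    matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("g001", "g002"))),
    1:6, c(1, 0, 0, 0, 0, 0)))
  md <- multi_cancer_data(list(d_few, make_cohort(30, 2, seed = 6)))
  w <- compute_km_weights_all(md)
  expect_error(select_lambdas_cv(md, w, penalty_spec("none"), V = 3,
                                 n_sparsity = 1),
               "too few events")
  folds <- aftfuse:::stratified_folds(rep(c(1, 0), each = 10), V = 5,
                                      seed = 3)
  for (v in 1:5) {
    expect_equal(sum(folds == v & rep(c(1, 0), each = 10) == 1), 2)
  }
})

test_that("pure-noise data selects a large sparsity level", {
  top <- 0
  for (s in 1:8) {
    md <- make_multi(2, 40, 5, seed = 300 + s, beta = rep(0, 5))
    w <- compute_km_weights_all(md)
    res <- select_lambdas_cv(md, w, penalty_spec("none"), V = 3,
                             seed = s, n_sparsity = 8,
                             fusion_multipliers = 0)
    if (res$selected$lambda_sparsity >= 0.5 * res$lambda_max) top <- top + 1
  }
  expect_gte(top, 6)   # >= 75% of seeds near the top of the path
})

test_that("BIC tuning returns the minimizing pair and its fit", {
  md <- make_multi(2, 60, 6, seed = 130, beta = c(2, -1.5, rep(0, 4)))
  w <- compute_km_weights_all(md)
  res <- select_lambdas_bic(md, w, penalty_spec("magnitude"),
                            method = "joint", n_sparsity = 8,
                            fusion_multipliers = c(0, 1))
  best <- aftfuse:::pick_best(res$grid, res$grid$bic)
  expect_equal(res$selected$lambda_sparsity,
               res$grid$lambda_sparsity[best])
  expect_s3_class(res$fit, "joint_fit")
  # the strong signal should survive BIC selection
  expect_true(all(res$fit$selected[1:2, ]))
})

test_that("selection is invariant to cohort order", {
  md <- make_multi(3, 40, 4, seed = 140, beta = c(1.5, 0, 0, 0))
  w <- compute_km_weights_all(md)
  r1 <- select_lambdas_bic(md, w, penalty_spec("none"), method = "joint",
                           n_sparsity = 6)
  perm <- c(3, 1, 2)
  md_p <- multi_cancer_data(md$datasets[perm])
  r2 <- select_lambdas_bic(md_p, compute_km_weights_all(md_p),
                           penalty_spec("none"), method = "joint",
                           n_sparsity = 6)
  expect_equal(r1$selected$lambda_sparsity, r2$selected$lambda_sparsity)
})
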