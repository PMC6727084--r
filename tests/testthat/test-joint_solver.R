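# Direct (loop-based) re-evaluation of the joint objective, independent of
# the implementation's matrix algebra.
joint_objective_oracle <- function(beta, alpha, data, weights, spec) {
  total <- 0
  for (k in seq_len(data$K)) {
    d <- data$datasets[[k]]
    for (i in seq_len(d$n)) {
      pred <- alpha[k] + sum(d$X[i, ] * beta[, k])
      total <- total + weights[[k]]$w[i] * (d$y[i] - pred)^2 / (2 * d$n)
    }
    for (j in seq_len(nrow(beta))) {
      total <- total + mcp_value(beta[j, k], spec$lambda_sparsity,
                                 spec$gamma)
    }
  }
  if (spec$fusion_type != "none" && spec$lambda_fusion > 0) {
    for (j in seq_len(nrow(beta))) {
      v <- if (spec$fusion_type == "magnitude") {
        magnitude_fusion_value(beta[j, ])
      } else {
        sign_fusion_value(beta[j, ])
      }
      total <- total + spec$lambda_fusion / 2 * v
    }
  }
  total
}

# multi_cancer_data on the standardized scale of `prep` (y centered,
# columns weight-standardized), so the solver's internal objective can be
# evaluated through the public joint_objective.
standardized_multi <- function(md, w) {
  prep <- aftfuse:::prepare_problem(md, w)
  datasets <- lapply(seq_along(prep$cohorts), function(k) {
    co <- prep$cohorts[[k]]
    d <- md$datasets[[k]]
    d$X <- co$Xs
    d$y <- co$yc
    d
  })
  multi_cancer_data(datasets)
}

test_that("joint_objective matches direct evaluation", {
  md <- make_multi(2, 15, 4, seed = 70, beta = c(1, -1, 0, 0))
  w <- compute_km_weights_all(md)
  set.seed(2)
  for (ft in c("magnitude", "sign", "none")) {
    spec <- penalty_spec(ft, 0.2, 0.3)
    beta <- matrix(rnorm(8, sd = 0.5), 4, 2)
    alpha <- rnorm(2)
    expect_equal(joint_objective(beta, alpha, md, w, spec),
                 joint_objective_oracle(beta, alpha, md, w, spec),
                 tolerance = 1e-12)
  }
  # beta = 0, alpha = 0: weighted RSS of y only
  spec <- penalty_spec("magnitude", 0.2, 0.3)
  rss <- sum(sapply(seq_len(md$K), function(k) {
    d <- md$datasets[[k]]
    sum(w[[k]]$w * d$y^2) / (2 * d$n)
  }))
  expect_equal(joint_objective(matrix(0, 4, 2), c(0, 0), md, w, spec), rss)
})

test_that("no fusion makes each cohort's fit independent of the others", {
  dA <- make_cohort(40, 5, seed = 81, beta = c(1.5, -1, 0, 0, 0),
                    cancer_id = "A")
  dB <- make_cohort(45, 5, seed = 82, beta = c(0, 1, 0, 0, 0),
                    cancer_id = "B")
  dC <- make_cohort(50, 5, seed = 83, beta = c(0, 0, 2, 0, 0),
                    cancer_id = "C")
  spec <- penalty_spec("none", lambda_sparsity = 0.08)
  mdAB <- multi_cancer_data(list(dA, dB))
  mdAC <- multi_cancer_data(list(dA, dC))
  fAB <- fit_joint(mdAB, compute_km_weights_all(mdAB), spec, tol = 1e-8)
  fAC <- fit_joint(mdAC, compute_km_weights_all(mdAC), spec, tol = 1e-8)
  expect_equal(fAB$beta[, "A"], fAC$beta[, "A"], tolerance = 1e-6)
  expect_equal(fAB$alpha[["A"]], fAC$alpha[["A"]], tolerance = 1e-6)
})

test_that("orthonormal weighted design gives the analytic prox solution", {
  set.seed(90)
  n <- 40
  p <- 4
  mk_orth <- function(seed, id) {
    d <- make_cohort(n, p, seed = seed, beta = c(1, -1, 0.5, 0),
                     cancer_id = id)
    w <- compute_km_weights(d)
    # weighted Gram-Schmidt on the centered columns so that the
    # standardized Gram matrix is exactly the identity
    wv <- w$w
    Xc <- sweep(d$X, 2, colSums(d$X * wv) / sum(wv), "-")
    for (j in seq_len(p)) {
      if (j > 1) {
        for (l in seq_len(j - 1)) {
          Xc[, j] <- Xc[, j] -
            sum(wv * Xc[, j] * Xc[, l]) / sum(wv * Xc[, l]^2) * Xc[, l]
        }
      }
    }
    d$X <- Xc
    list(d = d, w = w)
  }
  a <- mk_orth(91, "A")
  b <- mk_orth(92, "B")
  md <- multi_cancer_data(list(a$d, b$d))
  w <- list(a$w, b$w)
  spec <- penalty_spec("none", lambda_sparsity = 0.12)
  fit <- fit_joint(md, w, spec, tol = 1e-10, max_iter = 1000)
  prep <- aftfuse:::prepare_problem(md, w)
  for (k in 1:2) {
    expected <- mcp_prox(prep$cohorts[[k]]$sxy, 1, spec$lambda_sparsity,
                         spec$gamma)
    expect_equal(unname(fit$beta_std[, k]), expected, tolerance = 1e-7)
  }
})

test_that("solution survives random perturbations (objective optimality)", {
  md <- make_multi(2, 30, 3, seed = 95, beta = c(1, -0.8, 0))
  w <- compute_km_weights_all(md)
  spec <- penalty_spec("magnitude", 0.1, 0.15)
  fit <- fit_joint(md, w, spec, tol = 1e-9, max_iter = 2000)
  smd <- standardized_multi(md, w)
  base <- joint_objective(fit$beta_std, c(0, 0), smd, w, spec)
  set.seed(7)
  pert <- matrix(runif(10000 * 6, -0.05, 0.05), ncol = 6)
  worse <- vapply(seq_len(nrow(pert)), function(i) {
    joint_objective(fit$beta_std + matrix(pert[i, ], 3, 2), c(0, 0),
                    smd, w, spec)
  }, numeric(1))
  expect_true(all(worse >= base - 1e-10))
})

test_that("every coordinate satisfies its scalar optimality condition", {
  md <- make_multi(3, 50, 8, seed = 99, beta = c(1.5, -1, rep(0, 6)))
  w <- compute_km_weights_all(md)
  for (ft in c("magnitude", "sign", "none")) {
    fit <- fit_joint(md, w, penalty_spec(ft, 0.08, 0.1), tol = 1e-6,
                     max_iter = 1000)
    expect_true(fit$converged)
    expect_lt(aftfuse:::joint_kkt_max_move(fit, md, w), 10 * 1e-6)
  }
})

test_that("objective trace is finite and surrogate sweeps decrease", {
  md <- make_multi(2, 40, 5, seed = 101, beta = c(2, 0, 0, -1, 0))
  w <- compute_km_weights_all(md)
  fit <- fit_joint(md, w, penalty_spec("magnitude", 0.05, 0.2))
  expect_true(all(is.finite(fit$objective_trace)))
  expect_true(all(fit$surrogate_end <= fit$surrogate_start + 1e-12))
})

test_that("cohort permutation permutes the joint solution", {
  md <- make_multi(3, 35, 4, seed = 103, beta = c(1, -1, 0, 0))
  w <- compute_km_weights_all(md)
  spec <- penalty_spec("sign", 0.06, 0.1)
  fit <- fit_joint(md, w, spec, tol = 1e-8)
  perm <- c(2, 3, 1)
  md_p <- multi_cancer_data(md$datasets[perm])
  fit_p <- fit_joint(md_p, compute_km_weights_all(md_p), spec, tol = 1e-8)
  expect_equal(unname(fit_p$beta), unname(fit$beta[, perm]),
               tolerance = 1e-5)
})

test_that("predictions are the fitted affine map", {
  md <- make_multi(2, 30, 3, seed = 105, beta = c(1, 0, 0))
  w <- compute_km_weights_all(md)
  fit <- fit_joint(md, w, penalty_spec("none", 0.05))
  new <- md$datasets[[2]]
  sc <- predict_survival_scores(fit, new, "C2")
  expect_equal(sc, fit$alpha[["C2"]] + as.numeric(new$X %*% fit$beta[, "C2"]))
  # zero model predicts the intercept
  fit0 <- fit_joint(md, w, penalty_spec("none", 100))
  expect_equal(predict_survival_scores(fit0, new, "C1"),
               rep(unname(fit0$alpha["C1"]), new$n))
  # gene mismatch detected
  bad <- new
  bad$gene_ids <- rev(bad$gene_ids)
  expect_error(predict_survival_scores(fit, bad, "C2"), "gene order")
  expect_error(predict_survival_scores(fit, new, "NOPE"), "unknown cohort")
})
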