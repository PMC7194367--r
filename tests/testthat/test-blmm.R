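test_that("diagonalized likelihood and posterior equal the dense oracles", {
  dims <- list(c(2, 3, 2), c(3, 4, 2), c(4, 5, 3))  # (C, G, T)
  withr::with_seed(101, {
    for (d in dims) {
      C <- d[1]; G <- d[2]; T_ <- d[3]
      for (rep in 1:10) {
        V <- random_pd(C)
        S <- random_pd(C)
        Mv <- matrix(rnorm(T_ * G), T_, G)
        Yv <- matrix(rnorm(G * C), G, C)
        y <- expression_matrix(Yv, centered = TRUE)
        m <- motif_score_matrix(Mv)
        gs <- gene_similarity(m)
        vc <- freeform_components(V, S)
        expect_equal(marginal_log_likelihood(y, gs, vc),
                     dense_loglik(Yv, gs$Pi, V, S), tolerance = 1e-8)
        expect_lt(max(abs(posterior_mean(y, m, vc, pi = gs)$values -
                          dense_posterior(Yv, Mv, V, S))), 1e-8)
      }
    }
  })
})

test_that("degenerate one-cell model reduces to a standard normal", {
  y <- expression_matrix(matrix(0, 1, 1), centered = TRUE)
  m <- motif_score_matrix(matrix(0, 1, 1))
  gs <- gene_similarity(m)
  vc <- ridge_components(1, 1, 1)
  expect_equal(marginal_log_likelihood(y, gs, vc), -0.5 * log(2 * pi))
})

test_that("diagonal components factorize over conditions", {
  withr::with_seed(21, {
    C <- 4; G <- 6; T_ <- 3
    v_d <- diag(runif(C, 0.5, 2))
    s_d <- diag(runif(C, 0.5, 2))
    Mv <- matrix(rnorm(T_ * G), T_, G)
    Yv <- matrix(rnorm(G * C), G, C)
    gs <- gene_similarity(motif_score_matrix(Mv))
    ll <- marginal_log_likelihood(expression_matrix(Yv, centered = TRUE),
                                  gs, freeform_components(v_d, s_d))
    per_cond <- vapply(seq_len(C), function(c) {
      K <- v_d[c, c] * gs$Pi + s_d[c, c] * diag(G)
      ld <- determinant(K)$modulus[1]
      -0.5 * (G * log(2 * pi) + ld +
              drop(crossprod(Yv[, c], solve(K, Yv[, c]))))
    }, numeric(1))
    expect_equal(ll, sum(per_cond), tolerance = 1e-8)
  })
})

test_that("posterior mean is linear in Y and matches the ridge identity", {
  withr::with_seed(31, {
    y0 <- expression_matrix(matrix(0, 5, 3), centered = TRUE)
    m <- motif_score_matrix(matrix(rnorm(10), 2, 5))
    vc <- freeform_components(random_pd(3), random_pd(3))
    expect_equal(unname(posterior_mean(y0, m, vc)$values), matrix(0, 2, 3))
    # M = I, sigma2 = delta = 1: omega_hat = Y / 2
    yi <- expression_matrix(matrix(rnorm(16), 4, 4), centered = TRUE)
    mi <- motif_score_matrix(diag(4))
    got <- posterior_mean(yi, mi, ridge_components(1, 1, 4))
    expect_equal(unname(got$values), unname(yi$values) / 2)
  })
})

test_that("posterior is invariant to a common scaling and cancels
           proportional covariances", {
  withr::with_seed(41, {
    p <- small_problem(G = 12, C = 4, T_ = 3)
    V <- random_pd(4)
    S <- random_pd(4)
    a <- posterior_mean(p$y, p$m, freeform_components(V, S))
    b <- posterior_mean(p$y, p$m, freeform_components(2.7 * V, 2.7 * S))
    expect_lt(max(abs(a$values - b$values)), 1e-8)
    for (gam in c(0.5, 1, 3)) {
      blmm <- posterior_mean(p$y, p$m, freeform_components(V, gam * V))
      iso <- posterior_mean(p$y, p$m,
                            freeform_components(diag(4), gam * diag(4)))
      expect_lt(max(abs(blmm$values - iso$values)), 1e-8)
    }
  })
})

test_that("ridge fit recovers the isotropic variance ratio and equals the
           closed-form ridge solution", {
  ratios <- vapply(1:10, function(s) {
    sim <- simulate_isotropic(G = 978, C = 10, T_ = 623, sigma2 = 2,
                              delta = 1, seed = 1000L + s)
    fit <- fit_ridge(sim$y, sim$m)
    # closed-form ridge oracle via the push-through identity
    Mv <- sim$m$values
    closed <- solve(tcrossprod(Mv) + diag(fit$lambda, nrow(Mv)),
                    Mv %*% sim$y$values)
    expect_lt(max(abs(fit$omega_hat$values - closed)), 1e-8)
    fit$components$sigma2 / fit$components$delta
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.5)
})

test_that("fitted ridge likelihood dominates the truth", {
  sim <- simulate_isotropic(G = 400, C = 6, T_ = 50, sigma2 = 2, delta = 1,
                            seed = 7)
  fit <- fit_ridge(sim$y, sim$m)
  gs <- gene_similarity(sim$m)
  ll_true <- marginal_log_likelihood(sim$y, gs, ridge_components(2, 1, 6))
  expect_gte(fit$loglik, ll_true - 1e-6)
})

test_that("freeform fit recovers block structure and improves on its
           isotropic start", {
  n_rep <- 20
  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(G = 978, C = 10, T_motifs = 623,
                             v_kind = "blocks_two", seed = 3000L + r)
    ds <- simulate_dataset(cfg)
    gs <- gene_similarity(ds$M)
    fit <- fit_freeform(ds$Y, ds$M, pi = gs, max_iter = 400)
    Vc <- cov2cor(fit$components$V)
    blocks <- ds$V$blocks
    within <- c()
    between <- c()
    for (i in seq_along(blocks)) {
      bi <- blocks[[i]]
      if (length(bi) > 1) within <- c(within, Vc[bi, bi][!diag(length(bi))])
      for (j in seq_along(blocks)) {
        if (i < j) between <- c(between, Vc[bi, blocks[[j]]])
      }
    }
    hits[r] <- mean(within) > mean(between)
    if (r <= 3) {
      # penalized objective at the optimum must not be worse than at the
      # isotropic initialization (penalty there is zero)
      iso <- fit_freeform(ds$Y, ds$M, pi = gs, constraint = "isotropic")
      expect_gte(fit$loglik, iso$loglik - 1e-6)
    }
  }
  expect_gte(sum(hits), 18)
})

test_that("freeform fit on independent-V data stays near-diagonal", {
  offs <- vapply(1:20, function(r) {
    cfg <- simulation_config(G = 978, C = 10, T_motifs = 623,
                             v_kind = "independent", seed = 4000L + r)
    ds <- simulate_dataset(cfg)
    fit <- fit_freeform(ds$Y, ds$M, max_iter = 400)
    Vc <- cov2cor(fit$components$V)
    mean(abs(Vc[!diag(10)]))
  }, numeric(1))
  expect_lt(mean(offs), 0.2)
})

test_that("isotropic-constrained freeform reproduces the ridge fit", {
  sim <- simulate_isotropic(G = 300, C = 8, T_ = 40, sigma2 = 1.5,
                            delta = 1, seed = 99)
  fi <- fit_freeform(sim$y, sim$m, constraint = "isotropic")
  fr <- fit_ridge(sim$y, sim$m)
  expect_lt(max(abs(fi$omega_hat$values - fr$omega_hat$values)), 1e-6)
  expect_identical(fi$model, "blmm_isotropic")
})

test_that("expression prediction is the forward linear map", {
  withr::with_seed(55, {
    m <- motif_score_matrix(matrix(rnorm(12), 3, 4))
    om <- motif_activity_matrix(matrix(rnorm(6), 3, 2))
    expect_equal(predict_expression(m, om)$values,
                 crossprod(m$values, om$values), ignore_attr = TRUE)
    om0 <- motif_activity_matrix(matrix(0, 3, 2))
    expect_true(all(predict_expression(m, om0)$values == 0))
    mi <- motif_score_matrix(diag(3))
    expect_equal(unname(predict_expression(mi, om)$values),
                 unname(om$values))
  })
})
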