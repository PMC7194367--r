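test_that("motif activity draws follow N(0, sigma2 V) row-wise", {
  v <- make_identity_cov(5)
  om <- draw_motif_activity(v, sigma2 = 1, T_motifs = 2000, seed = 8)
  expect_identical(om$kind, "simulated_prior")
  emp <- crossprod(om$values) / nrow(om$values)
  expect_lt(max(abs(emp - diag(5))), 0.15)
  expect_error(draw_motif_activity(v, 0, 10, seed = 1), "> 0")

  # degenerate two-block covariance forces identical columns within blocks
  vb <- make_block_cov(6, k = 2, within = 1, between = 0, seed = 2)
  omb <- draw_motif_activity(vb, sigma2 = 2, T_motifs = 50, seed = 3)
  for (b in vb$blocks) {
    ref <- omb$values[, b[1]]
    for (j in b[-1]) expect_equal(omb$values[, j], ref, tolerance = 1e-6)
  }
})

test_that("noise draws have per-column variance delta (Sigma = I)", {
  eps <- draw_noise(make_identity_cov(3), delta = 4, G = 5000, seed = 12)
  expect_lt(max(abs(apply(eps, 2, var) / 4 - 1)), 0.05)
  expect_identical(eps, draw_noise(make_identity_cov(3), 4, 5000, seed = 12))
  tiny <- draw_noise(make_identity_cov(3), 1e-12, 100, seed = 1)
  expect_lt(max(abs(tiny)), 1e-4)
})

test_that("expression composition is the exact linear model", {
  m <- motif_score_matrix(diag(2))
  om <- motif_activity_matrix(matrix(c(1, 3, 2, 4), 2, 2),
                              kind = "simulated_prior")
  noise <- matrix(c(0.5, 0, 0, 0), 2, 2)
  y <- compose_expression(m, om, noise)
  expect_equal(unname(y$values), matrix(c(1.5, 3, 2, 4), 2, 2))
  expect_equal(unname(compose_expression(m, om)$values), unname(om$values))
  om0 <- motif_activity_matrix(matrix(0, 2, 2), kind = "simulated_prior")
  expect_equal(unname(compose_expression(m, om0, noise)$values), noise)
  bad <- motif_score_matrix(matrix(1, 3, 2))
  expect_error(compose_expression(bad, om), "motifs")
})

test_that("sigma2 calibration matches its closed form and hits the target", {
  withr::with_seed(4, {
    m <- motif_score_matrix(matrix(rnorm(40 * 200), 40, 200))
  })
  v <- make_block_cov(8, k = 2, within = 1, between = 0, seed = 1)
  sig <- normalize_by_trace(make_wishart_noise(8, seed = 2))
  for (f in c(0.2, 0.5)) {
    s2 <- calibrate_sigma2(m, v, sig, delta = 1.3, target_fraction = f,
                           tol = 1e-10)
    signal_unit <- (sum(diag(v$values)) / 8) * (sum(m$values^2) / 200)
    noise_var <- 1.3 * sum(diag(sig$values)) / 8
    closed <- (f / (1 - f)) * noise_var / signal_unit
    expect_equal(s2, closed, tolerance = 1e-8)
  }
  # symmetric case: unit signal and noise scales => sigma2 = 1 at f = 0.5
  mu <- motif_score_matrix(matrix(sqrt(1 / 2), 2, 2))  # tr(Pi)/G = 1
  vi <- make_identity_cov(2)
  expect_equal(calibrate_sigma2(mu, vi, vi, delta = 1, target_fraction = 0.5),
               1, tolerance = 1e-8)
  expect_error(calibrate_sigma2(m, v, sig, target_fraction = 1.2), "0, 1")
})

test_that("simulated datasets are reproducible and hit the signal target", {
  cfg <- simulation_config(G = 600, C = 10, T_motifs = 40,
                           v_kind = "blocks_two", seed = 17)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$Y$values, d2$Y$values)
  expect_identical(d1$omega_true$values, d2$omega_true$values)
  expect_true(d1$Y$centered)
  expect_lt(max(abs(rowMeans(d1$Y$values))), 1e-10)
  expect_gt(d1$signal_fraction, 0.1)
  expect_lt(d1$signal_fraction, 0.3)
  # changing the draw seed keeps the V structure when structure_seed fixed
  cfg2 <- simulation_config(G = 600, C = 10, T_motifs = 40,
                            v_kind = "blocks_two", seed = 18,
                            structure_seed = 17)
  d3 <- simulate_dataset(cfg2)
  expect_identical(d3$V$values, d1$V$values)
  expect_false(identical(d3$omega_true$values, d1$omega_true$values))
})

test_that("many-groups config at C=50 carries 25 blocks", {
  cfg <- simulation_config(G = 100, C = 50, T_motifs = 10,
                           v_kind = "blocks_many", seed = 2)
  ds <- simulate_dataset(cfg)
  expect_length(ds$V$blocks, 25)
})

test_that("prior draw covariance converges to sigma2 V", {
  v <- make_full_positive_cov(6, seed = 9)
  s2 <- 1.7
  om <- draw_motif_activity(v, s2, T_motifs = 5000, seed = 10)
  emp <- crossprod(om$values) / nrow(om$values)
  rel <- norm(emp - s2 * v$values, "F") / norm(s2 * v$values, "F")
  expect_lt(rel, 0.1)
})

test_that("dataset writer produces a readable directory", {
  cfg <- simulation_config(G = 30, C = 4, T_motifs = 5, seed = 3)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_simulated_dataset(ds, dir)
  back <- read_labeled_matrix(file.path(dir, "Y.tsv"), "rows_are_genes")
  expect_identical(back$values, ds$Y$values)
  params <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(params$sigma2, ds$sigma2)
})
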