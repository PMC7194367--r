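test_that("recovery scores behave as correlation/MSE identities", {
  withr::with_seed(61, {
    v <- matrix(rnorm(40), 8, 5)
  })
  a <- motif_activity_matrix(v, kind = "simulated_prior")
  b <- motif_activity_matrix(v)
  sc <- recovery_scores(a, b)
  expect_equal(sc$pearson, 1)
  expect_equal(sc$spearman, 1)
  expect_equal(sc$mse, 0)
  neg <- motif_activity_matrix(-v)
  expect_equal(recovery_scores(a, neg)$pearson, -1)
  twice <- motif_activity_matrix(2 * v)
  sc2 <- recovery_scores(a, twice)
  expect_equal(sc2$pearson, 1)
  expect_equal(sc2$mse, mean(v^2))
  expect_equal(nrow(sc$per_condition), 5)
  bad <- motif_activity_matrix(v[, 1:4])
  expect_error(recovery_scores(a, bad), "identical shape")
})

test_that("pooled pearson is invariant under a common reordering", {
  withr::with_seed(62, {
    a <- matrix(rnorm(30), 6, 5)
    b <- a + matrix(rnorm(30, sd = 0.3), 6, 5)
    perm_r <- sample(6)
    perm_c <- sample(5)
  })
  s1 <- recovery_scores(motif_activity_matrix(a), motif_activity_matrix(b))
  ids_r <- paste0("m", perm_r)
  ids_c <- paste0("c", perm_c)
  s2 <- recovery_scores(
    motif_activity_matrix(a[perm_r, perm_c], motif_ids = ids_r,
                          condition_ids = ids_c),
    motif_activity_matrix(b[perm_r, perm_c], motif_ids = ids_r,
                          condition_ids = ids_c))
  expect_equal(s1$pearson, s2$pearson)
  expect_equal(s1$mse, s2$mse)
})

test_that("cross-validation folds partition the genes", {
  cfg <- simulation_config(G = 978, C = 6, T_motifs = 30, seed = 5)
  ds <- simulate_dataset(cfg)
  cv <- kfold_crossval(ds$Y, ds$M, k = 10, model = "ridge", seed = 4)
  folds <- attr(cv, "folds")
  expect_length(folds, 10)
  expect_true(all(lengths(folds) %in% c(97, 98)))
  expect_setequal(unlist(folds), 1:978)
  expect_equal(sum(duplicated(unlist(folds))), 0)
  cv2 <- kfold_crossval(ds$Y, ds$M, k = 10, model = "ridge", seed = 4)
  expect_identical(cv, cv2)
  expect_true(all(cv$train_pearson >= cv$test_pearson - 0.1))
})

test_that("near-noiseless data cross-validates almost perfectly", {
  # compose a dataset with vanishing noise directly
  withr::with_seed(71, {
    m <- motifBLMM:::synthetic_motif_scores(20, 400, seed = 71)
    om <- draw_motif_activity(make_identity_cov(5), 1, 20, seed = 72)
    eps <- draw_noise(make_identity_cov(5), 1e-10, 400, seed = 73)
    y <- double_center(compose_expression(m, om, eps))
  })
  cv <- kfold_crossval(y, m, k = 5, model = "ridge", seed = 2)
  expect_gt(min(cv$test_pearson), 0.99)
})

test_that("permuting motif scores flattens test performance", {
  cfg <- simulation_config(G = 500, C = 10, T_motifs = 80,
                           v_kind = "independent", seed = 31)
  ds <- simulate_dataset(cfg)
  pr <- permutation_null(ds$Y, ds$M, n_perm = 20, model = "ridge",
                         seed = 9)
  expect_length(pr$null_test_pearsons, 20)
  expect_lt(abs(mean(pr$null_test_pearsons)), 0.05)
  expect_gt(pr$observed, quantile(pr$null_test_pearsons, 0.95))
  pr2 <- permutation_null(ds$Y, ds$M, n_perm = 20, model = "ridge",
                          seed = 9)
  expect_identical(pr$null_test_pearsons, pr2$null_test_pearsons)
  expect_error(permutation_null(ds$Y, ds$M, n_perm = 0), ">= 1")
})

test_that("group-difference ranking follows the mean-gap score", {
  om <- motif_activity_matrix(rbind(mA = c(1, 1, 0, 0),
                                    mB = c(0, 0, 0, 0)),
                              condition_ids = paste0("c", 1:4))
  groups <- c(c1 = "g1", c2 = "g1", c3 = "g2", c4 = "g2")
  rk <- rank_motifs_by_group_difference(om, groups)
  expect_equal(rk$motif, c("mA", "mB"))
  expect_equal(rk$score, c(1, 0))
  expect_equal(rk$rank, c(1, 2))
  # ties broken by label
  om2 <- motif_activity_matrix(rbind(z = c(1, 1, 1, 1), a = c(2, 2, 2, 2)),
                               condition_ids = paste0("c", 1:4))
  rk2 <- rank_motifs_by_group_difference(om2, groups)
  expect_equal(rk2$motif, c("a", "z"))
  expect_equal(rk2$score, c(0, 0))
  single <- motif_activity_matrix(matrix(1:4, 1, 4,
                                         dimnames = list("m1", paste0("c", 1:4))))
  expect_equal(rank_motifs_by_group_difference(single, groups)$rank, 1)
  expect_error(rank_motifs_by_group_difference(om, c(c1 = "g1", c2 = "g1",
                                                     c3 = "g1", c4 = "g1")),
               "two")
})

test_that("IQR outlier selection matches direct interval evaluation", {
  vals <- c(0, 0, 0, 0, 100)
  om <- motif_activity_matrix(matrix(vals, 5, 2,
                                     dimnames = list(paste0("m", 1:5),
                                                     c("c1", "c2"))))
  grp <- c(c1 = "t1", c2 = "t1")
  sel <- select_outlier_motifs_iqr(om, grp)
  expect_identical(as.character(sel), "m5")
  # all equal: nothing selected
  om2 <- motif_activity_matrix(matrix(3, 5, 2,
                                      dimnames = list(paste0("m", 1:5),
                                                      c("c1", "c2"))))
  expect_length(select_outlier_motifs_iqr(om2, grp), 0)
  # 1..100 against brute-force interval
  v <- matrix(1:100, 100, 1, dimnames = list(sprintf("m%03d", 1:100), "c1"))
  om3 <- motif_activity_matrix(v)
  sel3 <- select_outlier_motifs_iqr(om3, c(c1 = "t1"), factor = 2.5)
  med <- median(1:100)
  iqr <- IQR(1:100, type = 7)
  manual <- rownames(v)[1:100 < med - 2.5 * iqr | 1:100 > med + 2.5 * iqr]
  expect_identical(as.character(sel3), sort(manual))
  sel4 <- select_outlier_motifs_iqr(om3, c(c1 = "t1"), factor = 0.5)
  manual4 <- rownames(v)[1:100 < med - 0.5 * iqr | 1:100 > med + 0.5 * iqr]
  expect_identical(as.character(sel4), sort(manual4))
})
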