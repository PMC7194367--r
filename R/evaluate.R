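#' Recovery of simulated motif activities
#'
#' Compares an estimated activity matrix against the simulated truth with
#' the Pearson correlation, Spearman rank correlation and mean squared
#' error, pooled over all T x C entries (one score per dataset), plus the
#' same three scores per condition column.
#'
#' @param omega_true,omega_hat [motif_activity_matrix()] objects with
#'   identical shape and labels.
#' @return A list of class `"recovery_score"`: `pearson`, `spearman`,
#'   `mse` (pooled) and `per_condition` (data frame with one row per
#'   condition).
#' @export
recovery_scores <- function(omega_true, omega_hat) {
  stopifnot(inherits(omega_true, "motif_activity_matrix"),
            inherits(omega_hat, "motif_activity_matrix"))
  a <- omega_true$values
  b <- omega_hat$values
  if (!identical(dim(a), dim(b)) || !identical(dimnames(a), dimnames(b))) {
    stop("omega_true and omega_hat must have identical shape and labels",
         call. = FALSE)
  }
  per_cond <- data.frame(
    condition = colnames(a),
    pearson = vapply(seq_len(ncol(a)),
                     function(j) stats::cor(a[, j], b[, j]), numeric(1)),
    spearman = vapply(seq_len(ncol(a)),
                      function(j) stats::cor(a[, j], b[, j],
                                             method = "spearman"), numeric(1)),
    mse = vapply(seq_len(ncol(a)),
                 function(j) mean((a[, j] - b[, j])^2), numeric(1)),
    row.names = NULL)
  structure(list(pearson = stats::cor(as.vector(a), as.vector(b)),
                 spearman = stats::cor(as.vector(a), as.vector(b),
                                       method = "spearman"),
                 mse = mean((a - b)^2),
                 per_condition = per_cond),
            class = "recovery_score")
}

#' @export
print.recovery_score <- function(x, ...) {
  cat(sprintf("recovery: pearson=%.4f spearman=%.4f mse=%.4g\n",
              x$pearson, x$spearman, x$mse))
  invisible(x)
}

make_folds <- function(G, k, seed) {
  if (k > G) stop("more folds than genes", call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(G))
  fold_of <- rep(seq_len(k), length.out = G)   # sizes differ by at most one
  split(idx, fold_of)
}

pooled_pearson <- function(a, b) stats::cor(as.vector(a), as.vector(b))

#' k-fold cross-validation over genes
#'
#' Shuffles genes into `k` near-equal folds; for each fold the model is fit
#' on the remaining genes, the posterior activities are used to predict the
#' held-out expression `Yhat_test = M_test' omega_hat`, and the pooled
#' Pearson correlation between predicted and observed entries is recorded
#' for both the training and the test genes.
#'
#' @param y a centered [expression_matrix()].
#' @param m the [motif_score_matrix()].
#' @param k number of folds (default 10).
#' @param model `"ridge"` or `"blmm"`.
#' @param seed integer seed for the fold assignment.
#' @param fit_opts list of extra arguments for the fitter.
#' @return A data frame with columns `fold`, `n_test`, `train_pearson`,
#'   `test_pearson`, `model`, `seed`; attribute `"folds"` carries the gene
#'   partition.
#' @export
kfold_crossval <- function(y, m, k = 10, model = c("ridge", "blmm"),
                           seed = 1L, fit_opts = list()) {
  model <- match.arg(model)
  stopifnot(inherits(y, "expression_matrix"),
            inherits(m, "motif_score_matrix"))
  G <- nrow(y$values)
  folds <- make_folds(G, k, seed)
  T_ <- nrow(m$values)
  res <- lapply(seq_along(folds), function(i) {
    test <- folds[[i]]
    train <- setdiff(seq_len(G), test)
    if (length(train) < T_) {
      warning(sprintf("fold %d: fewer training genes (%d) than motifs (%d)",
                      i, length(train), T_), call. = FALSE)
    }
    y_tr <- expression_matrix(y$values[train, , drop = FALSE],
                              centered = y$centered)
    m_tr <- motif_score_matrix(m$values[, train, drop = FALSE],
                               normalized = m$normalized)
    fit <- do.call(fit_motif_activity,
                   c(list(y = y_tr, m = m_tr, model = model), fit_opts))
    yhat_tr <- crossprod(m_tr$values, fit$omega_hat$values)
    yhat_te <- crossprod(m$values[, test, drop = FALSE],
                         fit$omega_hat$values)
    data.frame(fold = i, n_test = length(test),
               train_pearson = pooled_pearson(y$values[train, ], yhat_tr),
               test_pearson = pooled_pearson(y$values[test, ], yhat_te),
               model = model, seed = seed)
  })
  out <- do.call(rbind, res)
  attr(out, "folds") <- folds
  out
}

#' Permutation null for motif-score informativeness
#'
#' Destroys the gene-to-motif-score link by permuting the gene axis of `M`
#' (all motif rows moved together, a permutation without replacement),
#' refits the model on a training split and records the pooled test-set
#' Pearson correlation, repeated `n_perm` times. The observed (unpermuted)
#' score is returned alongside the null distribution; randomizing the
#' scores is expected to flatten predictive performance to about zero.
#'
#' @param y a centered [expression_matrix()].
#' @param m the [motif_score_matrix()].
#' @param n_perm number of permutations (>= 1).
#' @param model `"ridge"` or `"blmm"`.
#' @param seed integer seed (controls the train/test split and all
#'   permutations).
#' @param test_fraction fraction of genes held out for evaluation
#'   (default 0.1, mirroring one fold of a ten-fold split).
#' @param fit_opts list of extra arguments for the fitter.
#' @return A list of class `"permutation_result"`: `observed`,
#'   `null_test_pearsons` (length `n_perm`), `n_perm`, `model`, `seed`.
#' @export
permutation_null <- function(y, m, n_perm, model = c("ridge", "blmm"),
                             seed = 1L, test_fraction = 0.1,
                             fit_opts = list()) {
  model <- match.arg(model)
  stopifnot(inherits(y, "expression_matrix"),
            inherits(m, "motif_score_matrix"))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  G <- nrow(y$values)
  seeds <- derive_seeds(seed, c("split", paste0("perm", seq_len(n_perm))))
  test <- withr::with_seed(seeds[["split"]],
                           sort(sample.int(G, max(1, round(test_fraction * G)))))
  train <- setdiff(seq_len(G), test)
  score_with <- function(mvals) {
    y_tr <- expression_matrix(y$values[train, , drop = FALSE],
                              centered = y$centered)
    m_tr <- motif_score_matrix(mvals[, train, drop = FALSE],
                               normalized = m$normalized)
    fit <- do.call(fit_motif_activity,
                   c(list(y = y_tr, m = m_tr, model = model), fit_opts))
    yhat_te <- crossprod(mvals[, test, drop = FALSE], fit$omega_hat$values)
    pooled_pearson(y$values[test, ], yhat_te)
  }
  observed <- score_with(m$values)
  nulls <- vapply(seq_len(n_perm), function(i) {
    perm <- withr::with_seed(seeds[[paste0("perm", i)]], sample.int(G))
    mv <- m$values[, perm, drop = FALSE]
    colnames(mv) <- colnames(m$values)   # gene g gets the scores of perm(g)
    score_with(mv)
  }, numeric(1))
  structure(list(observed = observed, null_test_pearsons = nulls,
                 n_perm = n_perm, model = model, seed = seed,
                 test_genes = test),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("permutation_result [%s]: observed test r=%.4f, ",
                     "null mean=%.4f (sd %.4f, n=%d)\n"),
              x$model, x$observed, mean(x$null_test_pearsons),
              stats::sd(x$null_test_pearsons), x$n_perm))
  invisible(x)
}

#' Rank motifs by two-group mean activity difference
#'
#' Scores each motif by the absolute difference between its mean activity
#' in the two condition groups,
#' `score_t = |mean(omega[t, group1]) - mean(omega[t, group2])|`, and sorts
#' in decreasing order (rank 1 = most group-discriminating motif). Ties are
#' broken by motif label.
#'
#' @param omega_hat a [motif_activity_matrix()].
#' @param groups factor/character of length C with exactly two levels,
#'   named by (or ordered as) the condition labels.
#' @return A data frame `motif`, `score`, `rank`, sorted by rank.
#' @export
rank_motifs_by_group_difference <- function(omega_hat, groups) {
  stopifnot(inherits(omega_hat, "motif_activity_matrix"))
  v <- omega_hat$values
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), colnames(v))) {
      stop("names of 'groups' must match the condition labels", call. = FALSE)
    }
    groups <- groups[colnames(v)]
  }
  if (length(groups) != ncol(v)) {
    stop("'groups' must assign every condition", call. = FALSE)
  }
  g <- factor(as.character(groups))
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop("'groups' must define exactly two non-empty classes", call. = FALSE)
  }
  m1 <- rowMeans(v[, g == levels(g)[1], drop = FALSE])
  m2 <- rowMeans(v[, g == levels(g)[2], drop = FALSE])
  score <- abs(m1 - m2)
  ord <- order(-score, rownames(v))
  data.frame(motif = rownames(v)[ord], score = score[ord],
             rank = seq_along(ord), row.names = NULL)
}

#' Select outlier motifs by the IQR rule
#'
#' Summarizes each motif's activity per replicate group by the median over
#' that group's conditions, then, within each group, flags motifs whose
#' summarized activity falls outside
#' `[median - factor * IQR, median + factor * IQR]`, where the median and
#' inter-quartile range are taken over all motifs of that group (quartiles
#' by linear interpolation, `stats::quantile` type 7). The union of flagged
#' motifs over groups is returned. The default multiplier 2.5 selects the
#' strongly tissue-specific tail of the activity distribution.
#'
#' @param omega_hat a [motif_activity_matrix()].
#' @param replicate_groups factor/character of length C assigning each
#'   condition to a replicate group (named by condition labels or in column
#'   order).
#' @param factor positive IQR multiplier (default 2.5).
#' @return Character vector of selected motif labels; attribute
#'   `"per_group"` lists the selection per group.
#' @export
select_outlier_motifs_iqr <- function(omega_hat, replicate_groups,
                                      factor = 2.5) {
  stopifnot(inherits(omega_hat, "motif_activity_matrix"))
  if (factor <= 0) stop("factor must be > 0", call. = FALSE)
  v <- omega_hat$values
  if (!is.null(names(replicate_groups))) {
    if (!setequal(names(replicate_groups), colnames(v))) {
      stop("names of 'replicate_groups' must match condition labels",
           call. = FALSE)
    }
    replicate_groups <- replicate_groups[colnames(v)]
  }
  if (length(replicate_groups) != ncol(v)) {
    stop("'replicate_groups' must assign every condition", call. = FALSE)
  }
  g <- factor(as.character(replicate_groups))
  if (any(table(g) == 0)) stop("empty replicate group", call. = FALSE)
  per_group <- lapply(levels(g), function(lev) {
    summarized <- apply(v[, g == lev, drop = FALSE], 1, stats::median)
    med <- stats::median(summarized)
    iqr <- stats::IQR(summarized, type = 7)
    rownames(v)[summarized < med - factor * iqr |
                summarized > med + factor * iqr]
  })
  names(per_group) <- levels(g)
  out <- sort(unique(unlist(per_group)))
  attr(out, "per_group") <- per_group
  out
}
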