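#' Gene similarity matrix with cached eigendecomposition
#'
#' Computes `Pi = M' M`, the G x G gene-gene similarity induced by shared
#' motif content, together with its eigendecomposition. `Pi` drives the
#' covariance between genes in the marginal model, and its eigenbasis is
#' what lets the GC x GC covariance `V (x) Pi + Sigma (x) I` be handled in
#' O(G^3 + C^3) once instead of O((GC)^3): the decomposition is computed a
#' single time and reused across all likelihood evaluations of a fit.
#'
#' @param m a [motif_score_matrix()].
#' @return An object of class `"gene_similarity"`: list with `Pi`,
#'   eigenvalues `lambda` (clipped at 0) and eigenvectors `P`.
#' @export
gene_similarity <- function(m) {
  stopifnot(inherits(m, "motif_score_matrix"))
  Pi <- crossprod(m$values)
  ed <- eigen(Pi, symmetric = TRUE)
  structure(list(Pi = Pi, lambda = pmax(ed$values, 0), P = ed$vectors),
            class = "gene_similarity")
}

#' Variance components of the two-Kronecker-term model
#'
#' In `"freeform"` mode the components are unrestricted symmetric positive
#' definite matrices `V` (signal covariance across conditions) and `Sigma`
#' (noise covariance), with the scalar scales absorbed into the matrices.
#' In `"ridge"` mode both are isotropic, `V = sigma2 * I` and
#' `Sigma = delta * I`, which reduces the posterior to ridge regression
#' with penalty `lambda = delta / sigma2`.
#'
#' @param V,Sigma [condition_covariance()] objects or plain matrices
#'   (freeform mode).
#' @param sigma2,delta positive scalars (ridge mode).
#' @param C condition count (ridge mode, to build the identity matrices).
#' @return An object of class `"variance_components"` with elements `V`,
#'   `Sigma` (plain matrices), `mode`, and in ridge mode `sigma2`, `delta`.
#' @name variance-components
NULL

#' @rdname variance-components
#' @export
freeform_components <- function(V, Sigma) {
  V <- if (inherits(V, "condition_covariance")) V$values else V
  Sigma <- if (inherits(Sigma, "condition_covariance")) Sigma$values else Sigma
  stopifnot(is.matrix(V), is.matrix(Sigma), all(dim(V) == dim(Sigma)))
  structure(list(V = V, Sigma = Sigma, mode = "freeform"),
            class = "variance_components")
}

#' @rdname variance-components
#' @export
ridge_components <- function(sigma2, delta, C) {
  stopifnot(sigma2 > 0, delta > 0, C >= 1)
  structure(list(V = diag(sigma2, C), Sigma = diag(delta, C),
                 mode = "ridge", sigma2 = sigma2, delta = delta),
            class = "variance_components")
}

# Shared diagonalization of the marginal covariance V (x) Pi + Sigma (x) I_G.
# With Sigma = L L' (Cholesky), Vbar = L^-1 V L^-T = U diag(d) U', and
# Pi = P diag(lambda) P', the covariance factors as
#   (L (x) I) (U (x) P) diag(lambda_g d_c + 1) (U (x) P)' (L' (x) I),
# so everything reduces to the C x C map Q = L^-T U and the eigenvalue grid
# e[g, c] = lambda_g * d_c + 1.
whiten_components <- function(vc, pi, jitter_warn = TRUE) {
  Sigma <- vc$Sigma
  C <- ncol(Sigma)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    jit <- 1e-9 * sum(diag(Sigma)) / C
    if (jit <= 0 || ev_min < -1e-6 * sum(diag(Sigma)) / C) {
      stop(sprintf("Sigma is not positive definite (min eigenvalue %g)",
                   ev_min), call. = FALSE)
    }
    if (jitter_warn) {
      warning(sprintf(
        "Sigma nearly singular (min eigenvalue %g); adding jitter %g",
        ev_min, jit), call. = FALSE)
    }
    R <- chol(Sigma + diag(jit, C))
  }
  Linv_V <- forwardsolve(t(R), vc$V)
  Vbar <- t(forwardsolve(t(R), t(Linv_V)))
  Vbar <- (Vbar + t(Vbar)) / 2
  ed <- eigen(Vbar, symmetric = TRUE)
  Q <- backsolve(R, ed$vectors)          # Q = L^-T U = R^-1 U
  list(R = R, d = ed$values, Q = Q,
       logdet_sigma = 2 * sum(log(diag(R))))
}

#' Marginal log-likelihood of the expression matrix
#'
#' Evaluates the log density of `vec(Y)` under
#' `N(0, V (x) Pi + Sigma (x) I_G)` without ever materializing the GC x GC
#' covariance: the noise covariance is Cholesky-whitened, the whitened
#' signal covariance jointly diagonalized with the cached eigendecomposition
#' of `Pi`, and the likelihood evaluated on the eigenvalue grid
#' `lambda_g * d_c + 1`.
#'
#' @param y a centered [expression_matrix()].
#' @param pi a [gene_similarity()] for the paired motif scores.
#' @param vc a [variance_components()] object.
#' @return The scalar log-likelihood.
#' @export
marginal_log_likelihood <- function(y, pi, vc) {
  stopifnot(inherits(y, "expression_matrix"), inherits(pi, "gene_similarity"),
            inherits(vc, "variance_components"))
  Y <- y$values
  G <- nrow(Y)
  C <- ncol(Y)
  if (ncol(vc$V) != C || nrow(pi$Pi) != G) {
    stop("dimension mismatch between y, pi and vc", call. = FALSE)
  }
  w <- whiten_components(vc, pi)
  Z1 <- crossprod(pi$P, Y) %*% w$Q
  e <- outer(pi$lambda, w$d) + 1
  if (min(e) <= 0) stop("total covariance is not positive definite",
                        call. = FALSE)
  quad <- sum(Z1^2 / e)
  logdet <- G * w$logdet_sigma + sum(log(e))
  -0.5 * (G * C * log(2 * base::pi) + logdet + quad)
}

#' Posterior mean motif activities
#'
#' Computes the posterior mean of the motif activity matrix given the
#' expression data,
#' `vec(omega_hat) = (V (x) M) [V (x) Pi + Sigma (x) I_G]^-1 vec(Y)`,
#' through the same joint diagonalization as the likelihood (never forming
#' GC x GC matrices). With isotropic components this is exactly the ridge
#' estimator `M (Pi + lambda I)^-1 Y` with `lambda = delta / sigma2`; when
#' `Sigma` is proportional to `V` the condition covariance cancels and the
#' posterior coincides with that identity-covariance case.
#'
#' @param y a centered [expression_matrix()].
#' @param m the [motif_score_matrix()].
#' @param vc a [variance_components()] object.
#' @param pi optional precomputed [gene_similarity()] (recomputed if `NULL`).
#' @return A [motif_activity_matrix()] of kind `"posterior"`.
#' @export
posterior_mean <- function(y, m, vc, pi = NULL) {
  stopifnot(inherits(y, "expression_matrix"),
            inherits(m, "motif_score_matrix"),
            inherits(vc, "variance_components"))
  if (!identical(rownames(y$values), colnames(m$values))) {
    stop("gene labels of y and m must match in order", call. = FALSE)
  }
  if (is.null(pi)) pi <- gene_similarity(m)
  Y <- y$values
  w <- whiten_components(vc, pi)
  Z1 <- crossprod(pi$P, Y) %*% w$Q
  e <- outer(pi$lambda, w$d) + 1
  if (min(e) <= 0) stop("total covariance is singular", call. = FALSE)
  W <- pi$P %*% ((Z1 / e) %*% t(w$Q))    # K^-1 vec(Y) in matrix form
  omega <- m$values %*% W %*% vc$V
  motif_activity_matrix(omega, motif_ids = rownames(m$values),
                        condition_ids = colnames(Y), kind = "posterior")
}

#' Predict expression from posterior activities
#'
#' Evaluates the linear model forward: `Yhat = M' omega_hat`.
#'
#' @param m a [motif_score_matrix()] (T x G).
#' @param omega_hat a [motif_activity_matrix()] (T x C).
#' @return An [expression_matrix()] of fitted values.
#' @export
predict_expression <- function(m, omega_hat) {
  stopifnot(inherits(m, "motif_score_matrix"),
            inherits(omega_hat, "motif_activity_matrix"))
  if (nrow(m$values) != nrow(omega_hat$values)) {
    stop("M and omega_hat must have the same number of motifs", call. = FALSE)
  }
  expression_matrix(crossprod(m$values, omega_hat$values),
                    gene_ids = colnames(m$values),
                    condition_ids = colnames(omega_hat$values))
}

#' Fit the identity-covariance (ridge) model
#'
#' Maximizes the marginal likelihood of the model with `V = sigma2 * I` and
#' `Sigma = delta * I` over the two scalars, using the eigenbasis of
#' `Pi = M'M` so each evaluation is O(G). The posterior activities at the
#' optimum equal the closed-form ridge solution
#' `(M M' + lambda I)^-1 M Y` with `lambda = delta / sigma2`.
#'
#' @param y a centered [expression_matrix()].
#' @param m the [motif_score_matrix()].
#' @param pi optional precomputed [gene_similarity()].
#' @return An object of class `"fitted_blmm"` with elements `components`
#'   (ridge [variance-components]), `omega_hat`, `loglik`, `lambda`
#'   (`delta / sigma2`), `n_iter`, `converged`, `model = "ridge"`.
#' @export
fit_ridge <- function(y, m, pi = NULL) {
  stopifnot(inherits(y, "expression_matrix"),
            inherits(m, "motif_score_matrix"))
  if (!isTRUE(y$centered)) {
    warning("fitting on an uncentered expression matrix", call. = FALSE)
  }
  Y <- y$values
  if (all(Y == 0)) stop("expression matrix is all zero", call. = FALSE)
  if (is.null(pi)) pi <- gene_similarity(m)
  G <- nrow(Y)
  C <- ncol(Y)
  Yt <- crossprod(pi$P, Y)               # G x C in the Pi eigenbasis
  s_g <- rowSums(Yt^2)
  lambda_g <- pi$lambda
  # negative log-likelihood and gradient in log(sigma2), log(delta)
  nll <- function(theta) {
    s2 <- exp(theta[1]); de <- exp(theta[2])
    w <- s2 * lambda_g + de
    0.5 * (G * C * log(2 * base::pi) + C * sum(log(w)) + sum(s_g / w))
  }
  grad <- function(theta) {
    s2 <- exp(theta[1]); de <- exp(theta[2])
    w <- s2 * lambda_g + de
    common <- C / w - s_g / w^2
    0.5 * c(s2 * sum(common * lambda_g), de * sum(common))
  }
  v0 <- stats::var(as.vector(Y))
  mean_l <- mean(lambda_g)
  theta0 <- log(c(max(v0 / max(mean_l, 1e-12), 1e-8), v0))
  opt <- stats::optim(theta0, nll, grad, method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 10,
                                     pgtol = 1e-10))
  sigma2 <- exp(opt$par[1]); delta <- exp(opt$par[2])
  vc <- ridge_components(sigma2, delta, C)
  omega_hat <- posterior_mean(y, m, vc, pi = pi)
  structure(list(components = vc, omega_hat = omega_hat,
                 loglik = -opt$value, lambda = delta / sigma2,
                 n_iter = opt$counts[["function"]],
                 converged = opt$convergence == 0, reg_lambda = 0,
                 model = "ridge"),
            class = "fitted_blmm")
}

# Pack/unpack a lower-triangular Cholesky factor with log-diagonal into a
# parameter vector (column-major over the lower triangle).
chol_pack <- function(A) {
  idx <- lower.tri(A, diag = TRUE)
  theta <- A[idx]
  di <- which(diag(nrow(A))[idx] == 1)
  theta[di] <- log(diag(A))
  list(theta = theta, di = di, idx = idx)
}

chol_unpack <- function(theta, C, di, idx) {
  A <- matrix(0, C, C)
  A[idx] <- theta
  diag(A) <- exp(theta[di])
  A
}

#' Fit the freeform Bayesian linear mixed model
#'
#' Maximizes the penalized marginal log-likelihood over unrestricted
#' symmetric positive definite condition covariances `V` and `Sigma`
#' (scales absorbed), parameterized by their lower-triangular Cholesky
#' factors with log-transformed diagonals — `C (C + 1)` free parameters in
#' total — using L-BFGS with an analytic gradient. An L2 penalty
#' `reg_lambda * sum(Sigma[i != j]^2)` shrinks the off-diagonal noise
#' covariance (an isotropic Gaussian prior with zero mean on those
#' entries).
#'
#' Initialization: the default `init = "ridge"` first solves the
#' two-parameter isotropic problem and starts the freeform search at
#' `V = sigma2_hat I`, `Sigma = delta_hat I`, a well-conditioned point from
#' which the off-diagonal structure is grown. `init = "sample_cov"` starts
#' both factors at half the sample covariance of the condition profiles,
#' `cov(Y) / 2` (jittered to positive definiteness). Because
#' double-centered data carry exactly zero variance along the all-ones
#' condition direction, the sample covariance start is nearly singular and
#' the likelihood surface extremely stiff there, which stalls
#' quasi-Newton line searches; `"ridge"` avoids this and is the default.
#'
#' Note the marginal likelihood of doubly centered data is unbounded along
#' the degenerate all-ones direction (its observed variance is exactly
#' zero), so the optimizer may report `converged = FALSE` while the
#' posterior activities have long stabilized; `max_iter` bounds the work
#' spent on that drift.
#'
#' With `constraint = "isotropic"` the same machinery is restricted to
#' `V = sigma2 * I`, `Sigma = delta * I` (two parameters); this
#' reproduces [fit_ridge()] and is the internal consistency check that the
#' identity-constrained mixed model and closed-form ridge regression agree.
#'
#' @param y a centered [expression_matrix()].
#' @param m the [motif_score_matrix()].
#' @param reg_lambda penalty weight on off-diagonal `Sigma` entries
#'   (default `1e-4`).
#' @param constraint `"freeform"` or `"isotropic"`.
#' @param max_iter maximum L-BFGS iterations (default 2000).
#' @param factr L-BFGS relative-reduction stopping factor (in units of
#'   machine epsilon, as in [stats::optim()]; smaller is stricter).
#' @param pgtol projected-gradient tolerance.
#' @param init `"ridge"` or `"sample_cov"` (see Details).
#' @param pi optional precomputed [gene_similarity()].
#' @return An object of class `"fitted_blmm"`: `components` (freeform
#'   [variance-components]), `omega_hat`, `loglik` (penalized, at the
#'   optimum), `loglik_unpenalized`, `n_iter`, `converged`, `reg_lambda`,
#'   `model = "blmm"` (or `"blmm_isotropic"`).
#' @export
fit_freeform <- function(y, m, reg_lambda = 1e-4,
                         constraint = c("freeform", "isotropic"),
                         max_iter = 2000, factr = 1e7, pgtol = 1e-5,
                         init = c("ridge", "sample_cov"), pi = NULL) {
  constraint <- match.arg(constraint)
  init <- match.arg(init)
  stopifnot(inherits(y, "expression_matrix"),
            inherits(m, "motif_score_matrix"))
  if (!isTRUE(y$centered)) {
    warning("fitting on an uncentered expression matrix", call. = FALSE)
  }
  Y <- y$values
  if (all(Y == 0)) stop("expression matrix is all zero", call. = FALSE)
  if (is.null(pi)) pi <- gene_similarity(m)
  G <- nrow(Y)
  C <- ncol(Y)
  lambda_g <- pi$lambda
  Yt <- crossprod(pi$P, Y)               # G x C, fixed across iterations
  big <- sqrt(.Machine$double.xmax)

  # objective: 0.5 (GC log 2pi + logdet + quad) + penalty, with analytic
  # gradients mapped back through V = A A', Sigma = B B'
  eval_point <- function(V, Sigma, want_grad = TRUE) {
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Linv_V <- forwardsolve(t(R), V)
    Vbar <- t(forwardsolve(t(R), t(Linv_V)))
    Vbar <- (Vbar + t(Vbar)) / 2
    ed <- eigen(Vbar, symmetric = TRUE)
    Q <- backsolve(R, ed$vectors)
    e <- outer(lambda_g, ed$values) + 1
    if (min(e) <= 0) return(NULL)
    Z1 <- Yt %*% Q
    Z2 <- Z1 / e
    quad <- sum(Z1 * Z2)
    logdet <- G * 2 * sum(log(diag(R))) + sum(log(e))
    nll <- 0.5 * (G * C * log(2 * base::pi) + logdet + quad)
    if (!is.finite(nll)) return(NULL)
    out <- list(nll = nll)
    if (want_grad) {
      s_c <- colSums(lambda_g / e)
      r_c <- colSums(1 / e)
      GV_inner <- diag(s_c, C) - crossprod(Z2, lambda_g * Z2)
      GS_inner <- diag(r_c, C) - crossprod(Z2)
      out$grad_V <- 0.5 * Q %*% GV_inner %*% t(Q)
      out$grad_Sigma <- 0.5 * Q %*% GS_inner %*% t(Q)
    }
    out
  }

  if (constraint == "isotropic") {
    fn <- function(theta) {
      p <- eval_point(diag(exp(theta[1]), C), diag(exp(theta[2]), C),
                      want_grad = FALSE)
      if (is.null(p)) return(big)
      p$nll
    }
    gr <- function(theta) {
      p <- eval_point(diag(exp(theta[1]), C), diag(exp(theta[2]), C))
      if (is.null(p)) return(c(0, 0))
      c(exp(theta[1]) * sum(diag(p$grad_V)),
        exp(theta[2]) * sum(diag(p$grad_Sigma)))
    }
    v0 <- stats::var(as.vector(Y))
    theta0 <- log(c(max(v0 / max(mean(lambda_g), 1e-12), 1e-8), v0))
    # two smooth parameters: always solve to tight tolerance
    opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 10,
                                       pgtol = 1e-10))
    V_hat <- diag(exp(opt$par[1]), C)
    Sigma_hat <- diag(exp(opt$par[2]), C)
    penalty_hat <- 0
  } else {
    if (init == "ridge") {
      iso <- fit_ridge(y, m, pi = pi)
      A0 <- diag(sqrt(iso$components$sigma2), C)
      B0 <- diag(sqrt(iso$components$delta), C)
    } else {
      S0 <- stats::cov(Y)                # C x C condition covariance
      S0 <- S0 + diag(1e-6 * max(mean(diag(S0)), 1e-12), C)
      A0 <- B0 <- t(chol(S0 / 2))
    }
    pk <- chol_pack(A0)
    np <- length(pk$theta)
    off <- !diag(C)
    unpack2 <- function(theta) {
      list(A = chol_unpack(theta[seq_len(np)], C, pk$di, pk$idx),
           B = chol_unpack(theta[np + seq_len(np)], C, pk$di, pk$idx))
    }
    fn <- function(theta) {
      ab <- unpack2(theta)
      Sigma <- tcrossprod(ab$B)
      p <- eval_point(tcrossprod(ab$A), Sigma, want_grad = FALSE)
      if (is.null(p)) return(big)
      p$nll + reg_lambda * sum(Sigma[off]^2)
    }
    gr <- function(theta) {
      ab <- unpack2(theta)
      Sigma <- tcrossprod(ab$B)
      p <- eval_point(tcrossprod(ab$A), Sigma)
      if (is.null(p)) return(numeric(2 * np))
      gS <- p$grad_Sigma
      gS[off] <- gS[off] + 2 * reg_lambda * Sigma[off]
      gA <- 2 * (p$grad_V %*% ab$A)
      gB <- 2 * (gS %*% ab$B)
      tA <- gA[pk$idx]; tA[pk$di] <- tA[pk$di] * diag(ab$A)
      tB <- gB[pk$idx]; tB[pk$di] <- tB[pk$di] * diag(ab$B)
      c(tA, tB)
    }
    pkB <- chol_pack(B0)
    theta0 <- c(pk$theta, pkB$theta)
    opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = factr,
                                       pgtol = pgtol))
    ab <- unpack2(opt$par)
    V_hat <- tcrossprod(ab$A)
    Sigma_hat <- tcrossprod(ab$B)
    penalty_hat <- reg_lambda * sum(Sigma_hat[off]^2)
  }
  vc <- freeform_components(V_hat, Sigma_hat)
  omega_hat <- posterior_mean(y, m, vc, pi = pi)
  structure(list(components = vc, omega_hat = omega_hat,
                 loglik = -opt$value,
                 loglik_unpenalized = -(opt$value - penalty_hat),
                 n_iter = opt$counts[["function"]],
                 converged = opt$convergence == 0,
                 reg_lambda = if (constraint == "freeform") reg_lambda else 0,
                 model = if (constraint == "freeform") "blmm"
                         else "blmm_isotropic"),
            class = "fitted_blmm")
}

#' @export
print.fitted_blmm <- function(x, ...) {
  cat(sprintf(paste0("fitted_blmm [%s]: loglik=%.4f, iterations=%d, ",
                     "converged=%s\n"),
              x$model, x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Fit a motif activity model
#'
#' Front-end dispatching to [fit_freeform()] (`model = "blmm"`) or
#' [fit_ridge()] (`model = "ridge"`).
#'
#' @param y a centered [expression_matrix()].
#' @param m the [motif_score_matrix()].
#' @param model `"blmm"` or `"ridge"`.
#' @param ... passed to the underlying fitter.
#' @return A `"fitted_blmm"` object.
#' @export
fit_motif_activity <- function(y, m, model = c("blmm", "ridge"), ...) {
  model <- match.arg(model)
  if (model == "ridge") fit_ridge(y, m, ...) else fit_freeform(y, m, ...)
}
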