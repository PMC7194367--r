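# Independent dense oracles and small fixture builders. The oracles build
# the full GC x GC Kronecker covariance with base R and never touch the
# package's diagonalized code path.

random_pd <- function(C, jitter = 0.5) {
  A <- matrix(rnorm(C * C), C, C)
  tcrossprod(A) + diag(jitter, C)
}

# log N(vec(Y); 0, V (x) Pi + Sigma (x) I_G) via explicit dense matrices
dense_loglik <- function(Yv, Piv, V, Sigma) {
  G <- nrow(Yv)
  C <- ncol(Yv)
  K <- kronecker(V, Piv) + kronecker(Sigma, diag(G))
  z <- as.vector(Yv)
  ld <- determinant(K, logarithm = TRUE)$modulus[1]
  -0.5 * (G * C * log(2 * pi) + ld + drop(crossprod(z, solve(K, z))))
}

# posterior mean (V (x) M) K^-1 vec(Y) via explicit dense matrices
dense_posterior <- function(Yv, Mv, V, Sigma) {
  G <- nrow(Yv)
  C <- ncol(Yv)
  K <- kronecker(V, crossprod(Mv)) + kronecker(Sigma, diag(G))
  matrix(kronecker(V, Mv) %*% solve(K, as.vector(Yv)), nrow(Mv), C)
}

# small random problem: returns y (centered flag set), m, and plain values
small_problem <- function(G, C, T_, seed = 1) {
  withr::with_seed(seed, {
    Mv <- matrix(rnorm(T_ * G), T_, G)
    Yv <- matrix(rnorm(G * C), G, C)
    list(y = expression_matrix(Yv, centered = TRUE),
         m = motif_score_matrix(Mv), Yv = Yv, Mv = Mv)
  })
}

# simulate directly from V = sigma2*I, Sigma = delta*I without the
# trace-normalized pipeline (for ridge parameter-recovery tests)
simulate_isotropic <- function(G, C, T_, sigma2, delta, seed) {
  m <- motifBLMM:::synthetic_motif_scores(T_, G, seed = seed)
  omega <- draw_motif_activity(make_identity_cov(C), sigma2, T_,
                               seed = seed + 1L)
  eps <- draw_noise(make_identity_cov(C), delta, G, seed = seed + 2L)
  y <- double_center(compose_expression(m, omega, eps))
  list(y = y, m = m, omega = omega)
}
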