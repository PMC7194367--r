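#' Condition covariance container
#'
#' A `condition_covariance` wraps a C x C symmetric positive semi-definite
#' matrix over conditions, used both for the signal covariance `V_C` (the
#' covariance of motif activities across conditions) and for the noise
#' covariance `Sigma_C`. The `kind` tag records which generator produced it;
#' for block covariances the partition of conditions into groups is kept in
#' `blocks`.
#'
#' @param values symmetric numeric matrix.
#' @param kind one of `"independent"`, `"full_positive"`, `"blocks_many"`,
#'   `"blocks_two"`, `"wishart"`, `"structured"`, `"custom"`.
#' @param blocks optional list of integer vectors partitioning `1:C`.
#' @param trace_normalized logical; has the matrix been scaled to unit trace?
#' @param condition_ids optional condition labels.
#' @return An object of class `"condition_covariance"`.
#' @export
condition_covariance <- function(values,
                                 kind = c("custom", "independent",
                                          "full_positive", "blocks_many",
                                          "blocks_two", "wishart",
                                          "structured"),
                                 blocks = NULL, trace_normalized = FALSE,
                                 condition_ids = colnames(values)) {
  kind <- match.arg(kind)
  check_finite(values, "condition_covariance")
  if (nrow(values) != ncol(values)) {
    stop("covariance must be square", call. = FALSE)
  }
  if (max(abs(values - t(values))) > 1e-10 * max(1, max(abs(values)))) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(sprintf("covariance is not positive semi-definite (min eigenvalue %g)",
                 min(ev)), call. = FALSE)
  }
  if (!is.null(blocks)) {
    members <- sort(unlist(blocks))
    if (!identical(members, seq_len(nrow(values)))) {
      stop("blocks must partition 1..C exactly", call. = FALSE)
    }
  }
  if (is.null(condition_ids)) {
    condition_ids <- default_labels(nrow(values), "c")
  }
  condition_ids <- check_labels(condition_ids, nrow(values), "condition_ids")
  dimnames(values) <- list(condition_ids, condition_ids)
  structure(list(values = values, kind = kind, blocks = blocks,
                 trace_normalized = isTRUE(trace_normalized)),
            class = "condition_covariance")
}

#' @export
print.condition_covariance <- function(x, ...) {
  cat(sprintf("condition_covariance [%s]: %d x %d%s%s\n", x$kind,
              nrow(x$values), ncol(x$values),
              if (!is.null(x$blocks)) sprintf(", %d blocks", length(x$blocks)) else "",
              if (x$trace_normalized) ", unit trace" else ""))
  invisible(x)
}

#' Condition covariance generators
#'
#' Generators for the condition covariance regimes of the simulation study:
#'
#' * `make_identity_cov()` — isotropic, independent conditions (the implicit
#'   assumption of ridge regression);
#' * `make_full_positive_cov()` — a correlation matrix with all off-diagonal
#'   entries strictly positive and no block structure, built as `B B'` for
#'   `B` with i.i.d. Uniform(0.2, 1) entries, rescaled to unit diagonal;
#' * `make_block_cov()` — a block-partitioned correlation matrix modeling
#'   groups of biological replicates: `within` correlation inside a block,
#'   `between` across blocks, 1 on the diagonal. Each of the `k` blocks gets
#'   one member, the remaining conditions are assigned uniformly at random,
#'   so block sizes vary around `C / k`;
#' * `make_wishart_noise()` — an unstructured random covariance `A A'` with
#'   `A` a C x C matrix of i.i.d. standard normals (a Wishart draw with C
#'   degrees of freedom).
#'
#' All generators are deterministic given `(C, parameters, seed)`.
#'
#' @param C number of conditions.
#' @param k number of blocks, `1 <= k <= C`.
#' @param within,between correlations inside / across blocks,
#'   `0 <= between < within <= 1`.
#' @param seed integer seed; the draw does not disturb the global RNG state.
#' @return A [condition_covariance()] of the corresponding `kind`.
#' @examples
#' make_block_cov(4, k = 2, within = 1, between = 0, seed = 1)$values
#' @name covariance-generators
NULL

#' @rdname covariance-generators
#' @export
make_identity_cov <- function(C) {
  if (C < 1) stop("C must be >= 1", call. = FALSE)
  condition_covariance(diag(C), kind = "independent")
}

#' @rdname covariance-generators
#' @export
make_full_positive_cov <- function(C, seed) {
  if (C < 2) stop("C must be >= 2 for a correlated covariance", call. = FALSE)
  B <- withr::with_seed(seed, matrix(stats::runif(C * C, 0.2, 1), C, C))
  W <- tcrossprod(B)
  d <- 1 / sqrt(diag(W))
  condition_covariance(W * outer(d, d), kind = "full_positive")
}

#' @rdname covariance-generators
#' @export
make_block_cov <- function(C, k, within = 0.95, between = 0.05, seed = 1) {
  if (k < 1 || k > C) stop("need 1 <= k <= C blocks", call. = FALSE)
  if (!(between >= 0 && between < within && within <= 1) && k > 1) {
    stop("need 0 <= between < within <= 1", call. = FALSE)
  }
  # every block gets one member; the rest are assigned uniformly at random,
  # so sizes vary around C / k; conditions are ordered by block for a
  # readable partition
  assignment <- withr::with_seed(seed, {
    sort(c(seq_len(k), if (C > k) sample.int(k, C - k, replace = TRUE)))
  })
  V <- matrix(between, C, C)
  for (b in seq_len(k)) {
    idx <- which(assignment == b)
    V[idx, idx] <- within
  }
  diag(V) <- 1
  blocks <- split(seq_len(C), assignment)
  names(blocks) <- NULL
  condition_covariance(V, kind = if (k == 2) "blocks_two" else "blocks_many",
                       blocks = blocks)
}

#' @rdname covariance-generators
#' @export
make_wishart_noise <- function(C, seed) {
  if (C < 1) stop("C must be >= 1", call. = FALSE)
  A <- withr::with_seed(seed, matrix(stats::rnorm(C * C), C, C))
  condition_covariance(tcrossprod(A), kind = "wishart")
}

#' Noise structuredness specification
#'
#' Records the degree `rho` with which the noise covariance is pulled toward
#' the signal covariance `V_C`. `rho = 0` leaves the noise purely
#' unstructured (Wishart); `rho = 1` makes it proportional to `V_C`. The
#' implied mixing weight on the V-shaped component relative to the
#' unstructured one, `eta_rho = rho / (1 - rho)` (infinite at `rho = 1`), is
#' recorded for transparency.
#'
#' @param rho structuredness degree in `[0, 1]`.
#' @param base_seed integer seed used for the unstructured component.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(rho, base_seed = 1L) {
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho > 1) {
    stop("rho must be a single value in [0, 1]", call. = FALSE)
  }
  structure(list(rho = rho,
                 eta_rho = if (rho < 1) rho / (1 - rho) else Inf,
                 base_seed = as.integer(base_seed)),
            class = "noise_spec")
}

#' Structured noise covariance
#'
#' Mixes an unstructured (Wishart) noise covariance toward the signal
#' covariance `V_C`:
#' \deqn{\Sigma_\rho \propto (1-\rho)\,\Sigma_{random}/tr(\Sigma_{random})
#'   + \rho\, V_C / tr(V_C),}
#' normalized to unit trace. At `rho = 0` this is the trace-normalized
#' Wishart draw unchanged; at `rho = 1` it is the trace-normalized `V_C`,
#' the regime where the condition covariance cancels from the posterior and
#' the mixed model collapses onto ridge regression.
#'
#' @param base a [condition_covariance()], typically from
#'   [make_wishart_noise()].
#' @param v the signal covariance `V_C`.
#' @param spec a [noise_spec()].
#' @return A trace-normalized `condition_covariance` of kind `"structured"`,
#'   with the `rho` used stored in attribute `"rho"`.
#' @export
make_structured_noise <- function(base, v, spec) {
  stopifnot(inherits(base, "condition_covariance"),
            inherits(v, "condition_covariance"),
            inherits(spec, "noise_spec"))
  if (!identical(dim(base$values), dim(v$values))) {
    stop("base and v must have the same dimension", call. = FALSE)
  }
  b <- base$values / sum(diag(base$values))
  vv <- v$values / sum(diag(v$values))
  mix <- (1 - spec$rho) * b + spec$rho * vv
  mix <- mix / sum(diag(mix))
  out <- condition_covariance(mix, kind = "structured",
                              trace_normalized = TRUE,
                              condition_ids = colnames(v$values))
  attr(out, "rho") <- spec$rho
  out
}

#' Scale a covariance to unit trace
#'
#' @param m a [condition_covariance()].
#' @return `m / tr(m)`, with the `trace_normalized` flag set.
#' @export
normalize_by_trace <- function(m) {
  stopifnot(inherits(m, "condition_covariance"))
  tr <- sum(diag(m$values))
  if (tr <= 0) stop("trace must be positive", call. = FALSE)
  condition_covariance(m$values / tr, kind = m$kind, blocks = m$blocks,
                       trace_normalized = TRUE,
                       condition_ids = colnames(m$values))
}
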