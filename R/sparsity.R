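#' Analysis operator with unit-norm rows
#'
#' A k x n matrix whose rows are analysis filters on vectorized patches
#' (n = patch_size^2, k > n over-complete). Rows are constrained to the
#' oblique manifold (unit Euclidean norm), and the operator must have full
#' column rank so that the analyzed vector determines the signal subspace.
#'
#' @param omega numeric k x n matrix.
#' @param modality modality tag.
#' @param normalize if \code{TRUE}, rows are rescaled to unit norm rather than
#'   validated.
#' @return An object of class \code{analysis_operator} (the matrix with
#'   attributes; usable directly in matrix products).
#' @export
analysis_operator <- function(omega, modality = "OTHER", normalize = FALSE) {
  if (!is.matrix(omega) || !is.numeric(omega))
    stop("'omega' must be a numeric matrix")
  if (any(!is.finite(omega))) stop("'omega' must be finite")
  rn <- sqrt(rowSums(omega^2))
  if (normalize) {
    if (any(rn == 0)) stop("cannot normalize a zero row")
    omega <- omega / rn
  } else if (any(abs(rn - 1) > 1e-8)) {
    stop("rows must have unit Euclidean norm (max deviation ",
         format(max(abs(rn - 1))), "); use normalize = TRUE to rescale")
  }
  sv <- svd(omega, nu = 0, nv = 0)$d
  if (min(sv) <= 1e-12 * max(sv))
    warning("operator is (numerically) column rank deficient")
  structure(omega, class = c("analysis_operator", "matrix", "array"),
            modality = match.arg(modality, MODALITIES))
}

#' @export
print.analysis_operator <- function(x, ...) {
  cat(sprintf("<analysis_operator> %d x %d, modality %s\n",
              nrow(x), ncol(x), attr(x, "modality")))
  invisible(x)
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

#' Log-square co-sparsity surrogate
#'
#' Smooth approximation of the number of non-zero entries of an analyzed
#' vector: \code{g(alpha) = sum_k log(1 + nu * alpha_k^2)}, tight for large
#' \code{nu}. Zero iff \code{alpha} is zero.
#'
#' @param alpha numeric vector (or matrix: summed over all entries).
#' @param nu positive weight; larger values approximate the zero-norm more
#'   closely.
#' @return Non-negative scalar.
#' @examples
#' sparsity_g(0, 1)          # 0
#' sparsity_g(1, 1)          # log(2)
#' @export
sparsity_g <- function(alpha, nu) {
  if (nu <= 0) stop("'nu' must be positive")
  sum(log1p(nu * alpha^2))
}

#' Joint co-sparsity of a pair of analyzed vectors
#'
#' Couples the two modalities row-by-row:
#' \code{sum_k log(1 + nu * (a_k^2 + b_k^2))}. It is symmetric in its
#' arguments, reduces to \code{\link{sparsity_g}} when one argument is zero,
#' and — because the two responses share one saturating term — favours
#' configurations in which the two modalities are sparse on a common
#' co-support.
#'
#' @param alpha_a,alpha_b numeric vectors of equal length (one response per
#'   operator row).
#' @param nu positive weight.
#' @return Non-negative scalar.
#' @export
joint_sparsity_g <- function(alpha_a, alpha_b, nu) {
  if (length(alpha_a) != length(alpha_b))
    stop("analyzed vectors must have equal length (paired operator rows); got ",
         length(alpha_a), " vs ", length(alpha_b))
  if (nu <= 0) stop("'nu' must be positive")
  sum(log1p(nu * (alpha_a^2 + alpha_b^2)))
}

#' Co-support of a signal under an analysis operator
#'
#' The index set of (near-)zero entries of \code{omega \%*\% x}; these zero
#' responses encode the low-dimensional subspace containing the signal.
#' Indices are 1-based, following R convention.
#'
#' @param omega analysis operator (k x n matrix).
#' @param x signal vector of length n.
#' @param zero_tol entries with absolute response \code{<= zero_tol} count as
#'   zero.
#' @return Integer vector of row indices.
#' @export
cosupport <- function(omega, x, zero_tol = 1e-8) {
  if (ncol(omega) != length(x))
    stop("dim mismatch: operator has ", ncol(omega), " columns, signal length ",
         length(x))
  which(abs(as.vector(omega %*% x)) <= zero_tol)
}

#' Full-rank (log-determinant) penalty
#'
#' \code{h(omega) = -(1 / (n log n)) log det((1/m) t(omega) \%*\% omega)},
#' computed through a Cholesky log-determinant. Finite for full column rank;
#' rank-deficient operators return \code{Inf} with a warning. For the n x n
#' identity with \code{m = n} the value is exactly 1.
#'
#' @param omega analysis operator (k x n, n >= 2).
#' @param m normalizer of the Gram matrix; defaults to the row count, making
#'   \code{(1/m) t(omega) omega} a row-averaged Gram matrix.
#' @return Scalar penalty (large when the operator is close to column rank
#'   deficiency).
#' @export
rank_penalty_h <- function(omega, m = nrow(omega)) {
  n <- ncol(omega)
  if (n < 2) stop("operator must have at least 2 columns")
  G <- crossprod(omega) / m
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R) || any(diag(R) <= 0)) {
    warning("rank-deficient operator: log det <= 0; returning Inf")
    return(Inf)
  }
  logdet <- 2 * sum(log(diag(R)))
  -logdet / (n * log(n))
}

#' Row-coherence penalty
#'
#' \code{r(omega) = -sum_{k<l} log(1 - (omega_k . omega_l)^2)} over all
#' unordered row pairs of a unit-row operator. Zero for mutually orthogonal
#' rows; infinite (with the offending pair reported) when two rows are
#' parallel or antiparallel, i.e. trivially linearly dependent.
#'
#' @param omega analysis operator with unit-norm rows.
#' @return Non-negative scalar penalty.
#' @export
coherence_penalty_r <- function(omega) {
  C <- tcrossprod(omega)
  cij <- C[upper.tri(C)]
  bad <- 1 - cij^2 <= 1e-12
  if (any(bad)) {
    pairs <- which(upper.tri(C), arr.ind = TRUE)[bad, , drop = FALSE]
    warning("parallel/antiparallel rows: ",
            paste(apply(pairs, 1, paste, collapse = "-"), collapse = ", "),
            "; returning Inf")
    return(Inf)
  }
  -sum(log1p(-cij^2))
}

#' Configuration of the co-sparse learning objective
#'
#' @param nu positive weight of the log-square surrogate (large values make
#'   the surrogate a tighter zero-norm approximation).
#' @param kappa weight of the full-rank penalty \code{\link{rank_penalty_h}}.
#' @param mu weight of the coherence penalty
#'   \code{\link{coherence_penalty_r}}.
#' @param k_rows operator row count; \code{NULL} resolves to twice the patch
#'   dimension (k = 2n) at learning time.
#' @param m_norm Gram normalizer of \code{rank_penalty_h}; \code{NULL}
#'   resolves to \code{k_rows}.
#' @param zero_tol co-support threshold.
#' @return A list of class \code{sparsity_config}.
#' @export
sparsity_config <- function(nu = 1000, kappa = 10, mu = 0.01, k_rows = NULL,
                            m_norm = NULL, zero_tol = 1e-8) {
  if (nu <= 0 || kappa <= 0 || mu <= 0 || zero_tol <= 0)
    stop("nu, kappa, mu and zero_tol must be positive")
  structure(list(nu = nu, kappa = kappa, mu = mu, k_rows = k_rows,
                 m_norm = m_norm, zero_tol = zero_tol),
            class = "sparsity_config")
}

#' Joint learning objective for an operator pair
#'
#' Mean joint co-sparsity of the analyzed training ensembles plus the
#' constraint penalties:
#' \deqn{(1/N) \sum_i g(\Omega_a x_{a,i}, \Omega_b x_{b,i}) +
#'       \kappa [h(\Omega_a) + h(\Omega_b)] + \mu [r(\Omega_a) + r(\Omega_b)]}
#' The penalties are added (not subtracted): h and r blow up for degenerate
#' operators, so adding them steers the minimization away from rank-deficient
#' and trivially redundant solutions.
#'
#' @param ops list of two \code{\link{analysis_operator}}s (modality a, b).
#' @param ensemble a \code{\link{patch_ensemble_pair}}.
#' @param cfg a \code{\link{sparsity_config}}.
#' @return Scalar objective (\code{Inf} if either operator is degenerate).
#' @export
learning_objective <- function(ops, ensemble, cfg) {
  O_a <- ops[[1]]; O_b <- ops[[2]]
  if (ncol(O_a) != nrow(ensemble$X_a) || ncol(O_b) != nrow(ensemble$X_b))
    stop("operator width must equal patch dimension")
  if (nrow(O_a) != nrow(O_b))
    stop("operators must have equal row count (rows are paired by index)")
  m <- if (is.null(cfg$m_norm)) nrow(O_a) else cfg$m_norm
  A <- O_a %*% ensemble$X_a
  B <- O_b %*% ensemble$X_b
  g_mean <- mean(colSums(log1p(cfg$nu * (A^2 + B^2))))
  g_mean + cfg$kappa * (rank_penalty_h(O_a, m) + rank_penalty_h(O_b, m)) +
    cfg$mu * (coherence_penalty_r(O_a) + coherence_penalty_r(O_b))
}

#' Mean joint co-sparsity of an ensemble under an operator pair
#'
#' The data term of \code{\link{learning_objective}} alone — useful for
#' held-out evaluation of learned operators.
#'
#' @inheritParams learning_objective
#' @return Scalar mean joint co-sparsity per patch.
#' @export
mean_joint_sparsity <- function(ops, ensemble, cfg) {
  A <- ops[[1]] %*% ensemble$X_a
  B <- ops[[2]] %*% ensemble$X_b
  mean(colSums(log1p(cfg$nu * (A^2 + B^2))))
}
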