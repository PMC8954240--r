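# Proximal operator of r -> w * log(1 + nu r^2) + (rho/2)(r - s)^2 over r >= 0,
# vectorized over s. Stationary points solve the cubic
#   r^3 - s r^2 + ((rho + 2 w nu) / (rho nu)) r - s / nu = 0;
# all real roots are found in closed form (Cardano / trigonometric case),
# the objective is evaluated at each, and the winner is polished by a few
# guarded Newton steps to tolerance 1e-10.
prox_logsq <- function(s, w, nu, rho) {
  r <- numeric(length(s))
  pos <- s > 0
  if (!any(pos)) return(r)
  sv <- s[pos]
  a2 <- -sv
  a1 <- (rho + 2 * w * nu) / (rho * nu)
  a0 <- -sv / nu
  # depressed cubic t^3 + p t + q, r = t - a2/3
  p <- a1 - a2^2 / 3
  q <- 2 * a2^3 / 27 - a2 * a1 / 3 + a0
  disc <- (q / 2)^2 + (p / 3)^3
  phi <- function(r) w * log1p(nu * r^2) + (rho / 2) * (r - sv)^2
  best <- rep(Inf, length(sv)); rbest <- numeric(length(sv))
  one <- disc > 0
  if (any(one)) {
    cbrt <- function(z) sign(z) * abs(z)^(1 / 3)
    sq <- sqrt(disc[one])
    t1 <- rep(NA_real_, length(sv))
    t1[one] <- cbrt(-q[one] / 2 + sq) + cbrt(-q[one] / 2 - sq)
    tt <- t1; tt[!one] <- 0; vv <- rep(FALSE, length(sv)); vv[one] <- TRUE
    cand <- pmin(pmax(tt - a2 / 3, 0), sv); val <- phi(cand)
    better <- vv & is.finite(val) & val < best
    rbest[better] <- cand[better]; best[better] <- val[better]
  }
  three <- !one
  if (any(three)) {
    pp <- p[three]; qq <- q[three]
    mp <- sqrt(pmax(-pp / 3, 0))
    arg <- ifelse(mp > 0, pmin(pmax(3 * qq / (2 * pp) / mp, -1), 1), 0)
    theta <- acos(arg)
    for (k in 0:2) {
      tk <- rep(0, length(sv))
      tk[three] <- 2 * mp * cos(theta / 3 - 2 * pi * k / 3)
      cand <- pmin(pmax(tk - a2 / 3, 0), sv); val <- phi(cand)
      better <- three & is.finite(val) & val < best
      rbest[better] <- cand[better]; best[better] <- val[better]
    }
  }
  # guarded Newton polish on phi'(r)
  for (it in 1:8) {
    g1 <- 2 * w * nu * rbest / (1 + nu * rbest^2) + rho * (rbest - sv)
    g2 <- 2 * w * nu * (1 - nu * rbest^2) / (1 + nu * rbest^2)^2 + rho
    ok <- g2 > 0
    step <- ifelse(ok, g1 / g2, 0)
    rn <- pmin(pmax(rbest - step, 0), sv)
    keep <- phi(rn) <= best
    rbest[keep] <- rn[keep]; best[keep] <- phi(rn)[keep]
    if (max(abs(step)) < 1e-10) break
  }
  r[pos] <- rbest
  r
}

#' ADMM solver settings
#'
#' @param rho augmented-Lagrangian penalty (> 0).
#' @param max_iter maximum ADMM sweeps.
#' @param tol_primal,tol_dual relative residual tolerances for early stopping.
#' @param n_inner projected-gradient steps in each operator sub-problem.
#' @return A list of class \code{admm_control}.
#' @export
admm_control <- function(rho = 1, max_iter = 200, tol_primal = 1e-6,
                         tol_dual = 1e-6, n_inner = 5) {
  if (rho <= 0) stop("'rho' must be positive")
  structure(list(rho = rho, max_iter = as.integer(max_iter),
                 tol_primal = tol_primal, tol_dual = tol_dual,
                 n_inner = as.integer(n_inner)),
            class = "admm_control")
}

# gradient of kappa*h + mu*r at a unit-row operator
penalty_gradient <- function(O, kappa, mu, n) {
  Ginv <- tryCatch(chol2inv(chol(crossprod(O))), error = function(e) NULL)
  gh <- if (is.null(Ginv)) 0 else -(2 / (n * log(n))) * (O %*% Ginv)
  C <- tcrossprod(O)
  M <- C / pmax(1 - C^2, 1e-12)
  diag(M) <- 0
  gr <- 2 * (M %*% O)
  kappa * gh + mu * gr
}

# penalty value kappa*h + mu*r (Inf-safe)
penalty_value <- function(O, kappa, mu, m) {
  kappa * rank_penalty_h(O, m) + mu * suppressWarnings(coherence_penalty_r(O))
}

# One operator sub-problem: a few projected-gradient steps with backtracking
# on  (rho/2)||O X - V||_F^2 + kappa h(O) + mu r(O),  rows retracted to unit
# norm after every step.
update_operator <- function(O, XXt, VXt, Vss, rho, kappa, mu, m, n_inner,
                            step) {
  n <- ncol(O)
  fval <- function(O) {
    rho / 2 * (sum(O * (O %*% XXt)) - 2 * sum(O * VXt) + Vss) +
      penalty_value(O, kappa, mu, m)
  }
  f0 <- fval(O)
  for (inner in seq_len(n_inner)) {
    g <- rho * (O %*% XXt - VXt) + penalty_gradient(O, kappa, mu, n)
    accepted <- FALSE
    for (bt in 1:20) {
      On <- normalize_rows(O - step * g)
      fn <- fval(On)
      if (is.finite(fn) && fn < f0) {
        O <- On; f0 <- fn; step <- step * 2; accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  list(O = O, f = f0, step = step)
}

#' Learn a pair of analysis operators by ADMM
#'
#' Minimizes the joint co-sparse learning objective
#' (\code{\link{learning_objective}}) over a pair of unit-row operators by the
#' alternating direction method of multipliers, with the splitting
#' \code{Y = [Omega_a X_a; Omega_b X_b]}: the Y block is the separable
#' proximal step of the joint log-square surrogate (closed-form cubic roots
#' plus Newton polish); the operator block is a penalized least-squares
#' descent followed by retraction of every row to the oblique manifold; the
#' scaled dual variable is updated with the constraint residual. Both
#' operators start from one shared seeded random unit-row draw, so the
#' procedure is deterministic and exactly symmetric when both modalities
#' carry the same data.
#'
#' @param ensemble a \code{\link{patch_ensemble_pair}} from an aligned
#'   (pre-deformation) image pair.
#' @param cfg a \code{\link{sparsity_config}}.
#' @param admm an \code{\link{admm_control}}.
#' @param seed integer seed for the operator initialization.
#' @param modalities length-2 character, modality tags for the returned
#'   operators.
#' @return A list with \code{op_a}, \code{op_b}
#'   (\code{\link{analysis_operator}}s) and \code{state} (iteration count,
#'   objective trace, primal/dual residual traces, convergence flag).
#' @export
learn_operators <- function(ensemble, cfg = sparsity_config(),
                            admm = admm_control(), seed = 1L,
                            modalities = c("OTHER", "OTHER")) {
  X_a <- ensemble$X_a; X_b <- ensemble$X_b
  n <- nrow(X_a); N <- ncol(X_a)
  k <- if (is.null(cfg$k_rows)) 2L * n else cfg$k_rows
  if (k <= n) stop("k_rows must exceed the patch dimension n = ", n)
  m <- if (is.null(cfg$m_norm)) k else cfg$m_norm
  rho <- admm$rho; w <- 1 / N
  set.seed(seed)
  O0 <- normalize_rows(matrix(stats::rnorm(k * n), k, n))
  O_a <- O0; O_b <- O0
  XXt_a <- tcrossprod(X_a); XXt_b <- tcrossprod(X_b)
  Y_a <- O_a %*% X_a; Y_b <- O_b %*% X_b
  U_a <- matrix(0, k, N); U_b <- matrix(0, k, N)
  obj <- function() {
    mean(colSums(log1p(cfg$nu * ((O_a %*% X_a)^2 + (O_b %*% X_b)^2)))) +
      penalty_value(O_a, cfg$kappa, cfg$mu, m) +
      penalty_value(O_b, cfg$kappa, cfg$mu, m)
  }
  obj_trace <- numeric(0); pri_trace <- numeric(0); dual_trace <- numeric(0)
  step_a <- 1e-2; step_b <- 1e-2
  converged <- FALSE
  for (it in seq_len(admm$max_iter)) {
    # Y block: joint radial prox, entrywise over (a, b) response pairs
    P_a <- O_a %*% X_a + U_a
    P_b <- O_b %*% X_b + U_b
    s <- sqrt(P_a^2 + P_b^2)
    r <- prox_logsq(as.vector(s), w, cfg$nu, rho)
    sc <- ifelse(s > 0, matrix(r, k, N) / s, 0)
    Y_a_old <- Y_a; Y_b_old <- Y_b
    Y_a <- sc * P_a; Y_b <- sc * P_b
    # operator block
    V_a <- Y_a - U_a; V_b <- Y_b - U_b
    ua <- update_operator(O_a, XXt_a, V_a %*% t(X_a), sum(V_a^2), rho,
                          cfg$kappa, cfg$mu, m, admm$n_inner, step_a)
    O_a <- ua$O; step_a <- ua$step
    ub <- update_operator(O_b, XXt_b, V_b %*% t(X_b), sum(V_b^2), rho,
                          cfg$kappa, cfg$mu, m, admm$n_inner, step_b)
    O_b <- ub$O; step_b <- ub$step
    # dual update (scaled)
    R_a <- O_a %*% X_a - Y_a; R_b <- O_b %*% X_b - Y_b
    U_a <- U_a + R_a; U_b <- U_b + R_b
    pri <- sqrt(sum(R_a^2) + sum(R_b^2))
    dua <- rho * sqrt(sum((Y_a - Y_a_old)^2) + sum((Y_b - Y_b_old)^2))
    obj_trace <- c(obj_trace, obj())
    pri_trace <- c(pri_trace, pri)
    dual_trace <- c(dual_trace, dua)
    if (it > 20 && pri > 10 * min(pri_trace[(it - 20):(it - 1)])) {
      cond <- simpleError(paste0("ADMM diverged at iteration ", it,
                                 ": primal residual grew 10-fold"))
      cond$trace <- list(objective = obj_trace, primal = pri_trace,
                         dual = dual_trace)
      stop(cond)
    }
    scale_pri <- max(sqrt(sum((O_a %*% X_a)^2) + sum((O_b %*% X_b)^2)),
                     sqrt(sum(Y_a^2) + sum(Y_b^2)), 1e-12)
    scale_dua <- max(rho * sqrt(sum(U_a^2) + sum(U_b^2)), 1e-12)
    if (pri < admm$tol_primal * scale_pri &&
        dua < admm$tol_dual * scale_dua) { converged <- TRUE; break }
  }
  list(op_a = analysis_operator(O_a, modalities[1], normalize = TRUE),
       op_b = analysis_operator(O_b, modalities[2], normalize = TRUE),
       state = list(iterations = length(obj_trace), objective = obj_trace,
                    primal = pri_trace, dual = dual_trace, rho = rho,
                    converged = converged))
}

#' Write / read a learned operator pair (JSON)
#'
#' Plain-text persistence of the two operators plus the learning settings.
#'
#' @param ops result of \code{\link{learn_operators}} (or a list with
#'   \code{op_a}, \code{op_b}).
#' @param path output JSON path.
#' @param cfg optional \code{\link{sparsity_config}} echoed into the file.
#' @return \code{read_operators}: a list with \code{op_a}, \code{op_b}.
#' @export
write_operators <- function(ops, path, cfg = NULL) {
  strip <- function(m) {
    m <- unclass(m)
    attr(m, "modality") <- NULL
    m
  }
  payload <- list(
    op_a = list(omega = strip(ops$op_a), modality = attr(ops$op_a,
                                                         "modality")),
    op_b = list(omega = strip(ops$op_b), modality = attr(ops$op_b,
                                                         "modality")),
    config = if (is.null(cfg)) NULL else unclass(cfg))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_operators
#' @export
read_operators <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(op_a = analysis_operator(p$op_a$omega, p$op_a$modality,
                                normalize = TRUE),
       op_b = analysis_operator(p$op_b$omega, p$op_b$modality,
                                normalize = TRUE),
       config = p$config)
}
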