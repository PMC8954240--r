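test_that("log-square sparsity surrogate matches closed forms and oracle", {
  expect_identical(sparsity_g(0, 1), 0)
  expect_equal(sparsity_g(1, 1), log(2))
  set.seed(1)
  alpha <- rnorm(20)
  brute <- 0
  for (a in alpha) brute <- brute + log(1 + 100 * a^2)
  expect_equal(sparsity_g(alpha, 100), brute, tolerance = 1e-12)
})

test_that("joint surrogate is symmetric and reduces to the marginal", {
  set.seed(2)
  a <- rnorm(15); b <- rnorm(15)
  expect_identical(joint_sparsity_g(numeric(3), numeric(3), 10), 0)
  expect_equal(joint_sparsity_g(a, numeric(15), 50), sparsity_g(a, 50))
  expect_equal(joint_sparsity_g(a, b, 50), joint_sparsity_g(b, a, 50))
  brute <- sum(log(1 + 50 * (a^2 + b^2)))
  expect_equal(joint_sparsity_g(a, b, 50), brute, tolerance = 1e-12)
  expect_error(joint_sparsity_g(a, b[1:3], 50), "length")
})

test_that("cosupport returns the near-zero response rows", {
  omega <- diag(3)
  expect_identical(cosupport(omega, c(0, 0.5, 0)), c(1L, 3L))
  om <- random_unit_rows(8, 4, seed = 3)
  expect_identical(cosupport(om, numeric(4)), 1:8)
  x <- rnorm(4)
  naive <- which(sapply(1:8, function(k) abs(sum(om[k, ] * x)) <= 0.1))
  expect_identical(cosupport(om, x, zero_tol = 0.1), naive)
})

test_that("rank penalty has the identity closed form and Inf sentinel", {
  n <- 6
  expect_equal(rank_penalty_h(diag(n), m = n), 1, tolerance = 1e-12)
  deficient <- random_unit_rows(8, 4, seed = 4)
  deficient[, 4] <- 0
  expect_warning(h <- rank_penalty_h(deficient), "rank")
  expect_identical(h, Inf)
  om <- random_unit_rows(16, 8, seed = 5)
  ev <- eigen(crossprod(om) / 16, symmetric = TRUE, only.values = TRUE)$values
  oracle <- -sum(log(ev)) / (8 * log(8))
  expect_equal(rank_penalty_h(om), oracle, tolerance = 1e-9)
})

test_that("coherence penalty is zero for orthogonal rows, Inf for parallel", {
  expect_identical(coherence_penalty_r(diag(5)), 0)
  dup <- random_unit_rows(6, 4, seed = 6)
  dup[2, ] <- dup[5, ]
  expect_warning(r <- coherence_penalty_r(dup), "parallel")
  expect_identical(r, Inf)
  om <- random_unit_rows(12, 6, seed = 7)
  brute <- 0
  for (k in 1:11) for (l in (k + 1):12)
    brute <- brute - log(1 - sum(om[k, ] * om[l, ])^2)
  expect_equal(coherence_penalty_r(om), brute, tolerance = 1e-9)
})

test_that("learning objective composes its three ingredients", {
  set.seed(8)
  n <- 9
  ens <- list(X_a = matrix(rnorm(n * 30), n, 30),
              X_b = matrix(rnorm(n * 30), n, 30))
  ops <- list(analysis_operator(random_unit_rows(2 * n, n, 9)),
              analysis_operator(random_unit_rows(2 * n, n, 10)))
  cfg <- sparsity_config(nu = 200, kappa = 3, mu = 0.05)
  got <- learning_objective(ops, ens, cfg)
  gsum <- mean(sapply(1:30, function(i)
    joint_sparsity_g(as.vector(ops[[1]] %*% ens$X_a[, i]),
                     as.vector(ops[[2]] %*% ens$X_b[, i]), 200)))
  oracle <- gsum +
    3 * (rank_penalty_h(ops[[1]], 2 * n) + rank_penalty_h(ops[[2]], 2 * n)) +
    0.05 * (coherence_penalty_r(ops[[1]]) + coherence_penalty_r(ops[[2]]))
  expect_equal(got, oracle, tolerance = 1e-10)
  # penalties survive when the data term vanishes
  zero_ens <- list(X_a = ens$X_a * 0, X_b = ens$X_b * 0)
  expect_equal(learning_objective(ops, zero_ens, cfg), oracle - gsum,
               tolerance = 1e-10)
})

test_that("the joint prox solves its 1-D subproblem to high accuracy", {
  set.seed(11)
  s <- c(0, runif(100, 0, 4))
  for (pars in list(c(w = 5e-4, nu = 1000, rho = 1),
                    c(w = 0.05, nu = 50, rho = 0.3))) {
    r <- cosreg:::prox_logsq(s, pars["w"], pars["nu"], pars["rho"])
    phi <- function(r, s) pars["w"] * log1p(pars["nu"] * r^2) +
      pars["rho"] / 2 * (r - s)^2
    for (i in seq_along(s)) {
      best <- if (s[i] == 0) 0 else
        optimize(phi, c(0, s[i]), s = s[i], tol = 1e-12)$objective
      expect_lte(phi(r[i], s[i]), best + 1e-10)
    }
  }
})

test_that("ADMM learning is deterministic with unit rows at checkpoints", {
  ph <- small_phantom()
  ens <- extract_patch_pairs(ph$pa, ph$mr, 5, 400, seed = 13)
  cfg <- sparsity_config()
  a <- learn_operators(ens, cfg, admm_control(max_iter = 12), seed = 2)
  b <- learn_operators(ens, cfg, admm_control(max_iter = 12), seed = 2)
  expect_identical(unclass(a$op_a), unclass(b$op_a))
  expect_identical(a$state$objective, b$state$objective)
  # deterministic prefixes expose the operators after every earlier sweep:
  # the oblique-manifold constraint holds at each one
  for (it in c(1, 4, 8)) {
    chk <- learn_operators(ens, cfg, admm_control(max_iter = it), seed = 2)
    expect_lt(max(abs(sqrt(rowSums(unclass(chk$op_a)^2)) - 1)), 1e-8)
    expect_lt(max(abs(sqrt(rowSums(unclass(chk$op_b)^2)) - 1)), 1e-8)
    expect_identical(chk$state$objective,
                     a$state$objective[seq_len(chk$state$iterations)])
  }
})

test_that("degenerate single-modality learning is exactly symmetric", {
  ph <- small_phantom()
  ens <- extract_patch_pairs(ph$mr, ph$mr, 5, 300, seed = 17)
  res <- learn_operators(ens, sparsity_config(),
                         admm_control(max_iter = 15), seed = 4)
  expect_equal(unclass(res$op_a), unclass(res$op_b), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("learned operators sparsify held-out patches better than random", {
  ph <- small_phantom()
  train <- extract_patch_pairs(ph$pa, ph$mr, 7, 800, seed = 21)
  held <- extract_patch_pairs(ph$pa, ph$mr, 7, 400, seed = 22)
  cfg <- sparsity_config()
  res <- small_operators()
  init <- random_unit_rows(98, 49, seed = 5)
  g_rand <- mean_joint_sparsity(list(init, init), held, cfg)
  g_learn <- mean_joint_sparsity(list(res$op_a, res$op_b), held, cfg)
  expect_lt(g_learn, g_rand)
  # objective trace settles into (near-)monotone decrease
  tr <- res$state$objective
  later <- tr[-(1:5)]
  expect_true(all(diff(later) <= 1e-6 * abs(later[-length(later)])))
})
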