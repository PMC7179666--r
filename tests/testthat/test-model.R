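# Objective, augmented Lagrangian, CG coefficient solver, primal/dual
# updates, and the full ADMM fit.

small_problem <- function(m = 6, n = 5, k = 2, seed = 1) {
  set.seed(seed)
  A_p <- matrix(rbinom(m * n, 1, 0.3), m, n)
  A_n <- matrix(rbinom(m * n, 1, 0.3), m, n) * (1 - A_p)
  W_r <- random_similarity(m, seed = seed + 1)
  W_d <- random_similarity(n, seed = seed + 2)
  list(A_p = A_p, A_n = A_n, W_r = W_r, W_d = W_d,
       L_U = graph_laplacian(W_r), L_V = graph_laplacian(W_d))
}

test_that("objective matches the scalar-loop oracle in every mode", {
  pb <- small_problem()
  for (mode in c("multi_task", "single_task_p", "single_task_n")) {
    ctl <- cmf_control(k = 2, alpha = 0.7, beta = 1.3, lambda = 0.4,
                       seed = 1, mode = mode)
    for (s in 1:5) {
      st <- random_state(6, 5, 2, seed = s)
      expect_equal(cmf_objective(st, pb$A_p, pb$A_n, pb$L_U, pb$L_V, ctl),
                   oracle_objective(st, pb$A_p, pb$A_n, pb$L_U, pb$L_V, ctl),
                   tolerance = 1e-10)
    }
  }
})

test_that("objective degenerate cases", {
  pb <- small_problem()
  ctl <- cmf_control(k = 2, alpha = 2, beta = 3, lambda = 1, seed = 1)
  zero <- list(U = matrix(0, 6, 2), V = matrix(0, 5, 2),
               R_p = matrix(0, 2, 2), R_n = matrix(0, 2, 2))
  expect_equal(cmf_objective(zero, pb$A_p, pb$A_n, pb$L_U, pb$L_V, ctl),
               (sum(pb$A_p^2) + sum(pb$A_n^2)) / 2)

  # exact factorization with all regularization off
  set.seed(9)
  U <- matrix(runif(12), 6, 2); V <- matrix(runif(10), 5, 2)
  Rp <- matrix(runif(4), 2, 2); Rn <- matrix(runif(4), 2, 2)
  ctl0 <- cmf_control(k = 2, alpha = 0, beta = 0, lambda = 0, seed = 1)
  st <- list(U = U, V = V, R_p = Rp, R_n = Rn)
  expect_equal(cmf_objective(st, U %*% Rp %*% t(V), U %*% Rn %*% t(V),
                             pb$L_U, pb$L_V, ctl0), 0, tolerance = 1e-20)
})

test_that("augmented Lagrangian reduces to the objective on the constraint set", {
  pb <- small_problem()
  ctl <- cmf_control(k = 2, alpha = 0.7, beta = 1.3, lambda = 0.4, seed = 1)
  st <- random_state(6, 5, 2, seed = 3)
  st$J <- st$V; st$W <- st$U
  st$Y <- matrix(0, 5, 2); st$Z <- matrix(0, 6, 2)
  expect_equal(cmf_lagrangian(st, pb$A_p, pb$A_n, pb$L_U, pb$L_V, ctl),
               cmf_objective(st, pb$A_p, pb$A_n, pb$L_U, pb$L_V, ctl),
               tolerance = 1e-12)

  # perturbing J with Y = 0 adds the Laplacian difference plus the penalty
  set.seed(4)
  E <- matrix(rnorm(10, sd = 0.1), 5, 2)
  st2 <- st; st2$J <- st$V + E
  lhs <- cmf_lagrangian(st2, pb$A_p, pb$A_n, pb$L_U, pb$L_V, ctl) -
    cmf_lagrangian(st, pb$A_p, pb$A_n, pb$L_U, pb$L_V, ctl)
  rhs <- ctl$beta / 2 * (sum(st2$J * (pb$L_V %*% st2$J)) -
                           sum(st$J * (pb$L_V %*% st$J))) +
    st$rho2 / 2 * sum(E^2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("solve_coefficient closed-form special cases", {
  set.seed(7)
  A <- matrix(rnorm(80), 10, 8)
  U <- qr.Q(qr(matrix(rnorm(30), 10, 3)))   # orthonormal columns
  V <- qr.Q(qr(matrix(rnorm(24), 8, 3)))
  R0 <- solve_coefficient(A, U, V, lambda = 0)
  expect_equal(unclass(R0), t(U) %*% A %*% V, tolerance = 1e-8,
               ignore_attr = TRUE)
  Rbig <- solve_coefficient(A, U, V, lambda = 1e12)
  expect_lte(sqrt(sum(Rbig^2)), 1e-6 * sqrt(sum((t(U) %*% A %*% V)^2)))
})

test_that("solve_coefficient agrees with the dense Kronecker oracle", {
  set.seed(11)
  for (rep in 1:25) {
    m <- sample(4:12, 1); n <- sample(4:12, 1); k <- sample(2:4, 1)
    A <- matrix(rnorm(m * n), m, n)
    U <- matrix(rnorm(m * k), m, k)
    V <- matrix(rnorm(n * k), n, k)
    lam <- runif(1, 0.1, 2)
    R <- solve_coefficient(A, U, V, lam)
    expect_equal(unclass(R), oracle_kron_solve(A, U, V, lam),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("CG warns and returns best iterate when capped", {
  set.seed(3)
  A <- matrix(rnorm(50), 10, 5)
  U <- matrix(rnorm(30), 10, 3); V <- matrix(rnorm(15), 5, 3)
  expect_warning(solve_coefficient(A, U, V, 0.5, max_iter = 1L), "converge")
})

test_that("primal update trivial identities", {
  pb <- small_problem()
  st <- random_state(6, 5, 2, seed = 5)
  st$Y <- matrix(0, 5, 2)
  ctl <- cmf_control(k = 2, alpha = 1, beta = 0, lambda = 0.3, seed = 1)
  up <- cmf_update_primal(st, pb$A_p, pb$A_n, pb$L_U, pb$L_V, ctl)
  expect_equal(up$J, st$V, tolerance = 1e-12)   # beta = 0, Y = 0

  st2 <- random_state(6, 5, 2, seed = 6)
  st2$Z <- matrix(0, 6, 2)
  ctl2 <- cmf_control(k = 2, alpha = 0, beta = 1, lambda = 0.3, seed = 1)
  up2 <- cmf_update_primal(st2, pb$A_p, pb$A_n, pb$L_U, pb$L_V, ctl2)
  expect_equal(up2$W, st2$U, tolerance = 1e-12)  # alpha = 0, Z = 0
})

test_that("each primal update zeroes its partial derivative (finite differences)", {
  for (s in 1:3) {
    pb <- small_problem(m = 5, n = 4, k = 2, seed = s)
    ctl <- cmf_control(k = 2, alpha = 0.8, beta = 1.2, lambda = 0.6, seed = s)
    st <- random_state(5, 4, 2, seed = s + 50)
    up <- cmf_update_primal(st, pb$A_p, pb$A_n, pb$L_U, pb$L_V, ctl)
    relnorm <- function(G, X) sqrt(sum(G^2)) / (1 + sqrt(sum(X^2)))

    # J sees the pre-update V
    fJ <- function(J) ctl$beta / 2 * sum(J * (pb$L_V %*% J)) +
      sum(st$Y * (J - st$V)) + st$rho2 / 2 * sum((J - st$V)^2)
    expect_lt(relnorm(numeric_gradient(fJ, up$J), up$J), 1e-6)

    fW <- function(W) ctl$alpha / 2 * sum(W * (pb$L_U %*% W)) +
      sum(st$Z * (W - st$U)) + st$rho1 / 2 * sum((W - st$U)^2)
    expect_lt(relnorm(numeric_gradient(fW, up$W), up$W), 1e-6)

    # U sees pre-update V and the fresh W
    fU <- function(U) 0.5 * sum((pb$A_p - U %*% st$R_p %*% t(st$V))^2) +
      0.5 * sum((pb$A_n - U %*% st$R_n %*% t(st$V))^2) +
      ctl$lambda / 2 * sum(U^2) + sum(st$Z * (up$W - U)) +
      st$rho1 / 2 * sum((up$W - U)^2)
    expect_lt(relnorm(numeric_gradient(fU, up$U), up$U), 1e-6)

    # V sees the fresh U and J
    fV <- function(V) 0.5 * sum((pb$A_p - up$U %*% st$R_p %*% t(V))^2) +
      0.5 * sum((pb$A_n - up$U %*% st$R_n %*% t(V))^2) +
      ctl$lambda / 2 * sum(V^2) + sum(st$Y * (up$J - V)) +
      st$rho2 / 2 * sum((up$J - V)^2)
    expect_lt(relnorm(numeric_gradient(fV, up$V), up$V), 1e-6)
  }
})

test_that("multiplier update: dual ascent, geometric penalties, cap", {
  st <- random_state(6, 5, 2, seed = 8)
  st$J <- st$V; st$W <- st$U
  st$rho1 <- 1; st$rho2 <- 1
  ctl <- cmf_control(k = 2, mu = 1.1, seed = 1)
  up <- cmf_update_multipliers(st, ctl)
  expect_identical(up$Y, st$Y)
  expect_identical(up$Z, st$Z)
  expect_equal(up$rho1, 1.1)
  expect_equal(up$rho2, 1.1)

  st2 <- random_state(6, 5, 2, seed = 9)
  up2 <- cmf_update_multipliers(st2, ctl)
  expect_equal(up2$Y, st2$Y + st2$rho2 * (st2$J - st2$V))
  expect_equal(up2$Z, st2$Z + st2$rho1 * (st2$W - st2$U))

  st2$rho1 <- ctl$rho_cap
  expect_equal(cmf_update_multipliers(st2, ctl)$rho1, ctl$rho_cap)
})

test_that("fit is deterministic under a fixed seed", {
  pb <- small_problem(m = 12, n = 10, k = 3, seed = 2)
  ctl <- cmf_control(k = 3, alpha = 1, beta = 1, lambda = 1, seed = 99,
                     max_iter = 60)
  f1 <- cmf_fit(pb$A_p, pb$A_n, pb$W_r, pb$W_d, ctl)
  f2 <- cmf_fit(pb$A_p, pb$A_n, pb$W_r, pb$W_d, ctl)
  expect_identical(f1$S_p, f2$S_p)
  expect_identical(f1$S_n, f2$S_n)
  expect_identical(f1$history, f2$history)
})

test_that("fit validates k and requires a seed", {
  pb <- small_problem(m = 5, n = 4, k = 2)
  expect_error(cmf_fit(pb$A_p, pb$A_n, pb$W_r, pb$W_d,
                       cmf_control(k = 4, seed = 1)), "min\\(m, n\\)")
  expect_error(cmf_fit(pb$A_p, pb$A_n, pb$W_r, pb$W_d, cmf_control(k = 2)),
               "seed")
})

test_that("noiseless planted data is reconstructed accurately", {
  pl <- planted_noiseless(60, 80, 4, seed = 11)
  ctl <- cmf_control(k = 4, alpha = 0, beta = 0, lambda = 0.05, seed = 2)
  fit <- cmf_fit(pl$A_p, pl$A_n, diag(60), diag(80), ctl)
  expect_lt(sqrt(sum((pl$A_p - fit$S_p)^2)) / sqrt(sum(pl$A_p^2)), 0.1)
  expect_lt(sqrt(sum((pl$A_n - fit$S_n)^2)) / sqrt(sum(pl$A_n^2)), 0.1)
})

test_that("relabeling drugs permutes score rows identically", {
  pb <- small_problem(m = 8, n = 6, k = 2, seed = 4)
  ctl <- cmf_control(k = 2, alpha = 1, beta = 1, lambda = 1, max_iter = 40,
                     seed = 1)
  set.seed(20)
  init <- list(U = matrix(runif(16), 8, 2), V = matrix(runif(12), 6, 2))
  f <- cmf_fit(pb$A_p, pb$A_n, pb$W_r, pb$W_d, ctl, init = init)
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  fp <- cmf_fit(pb$A_p[perm, ], pb$A_n[perm, ], pb$W_r[perm, perm], pb$W_d,
                ctl, init = list(U = init$U[perm, ], V = init$V))
  expect_equal(fp$S_p, f$S_p[perm, ], tolerance = 1e-10)
  expect_equal(fp$S_n, f$S_n[perm, ], tolerance = 1e-10)
})

test_that("single-task fit drops the other task and matches the multi fit on empty A_n", {
  pl <- planted_noiseless(20, 16, 2, seed = 3)
  A_zero <- matrix(0, 20, 16)
  W_r <- random_similarity(20, seed = 1); W_d <- random_similarity(16, seed = 2)
  ctl <- cmf_control(k = 2, alpha = 0.5, beta = 0.5, lambda = 0.5,
                     max_iter = 200, seed = 5)
  multi <- cmf_fit(pl$A_p, A_zero, W_r, W_d, ctl)
  single <- cmf_fit_single(pl$A_p, W_r, W_d, ctl, task = "p")
  expect_null(single$S_n)
  # with A_n = 0 the only difference is the lambda/2 ||R_n||^2 term; R_n
  # shrinks toward zero, so the converged objectives nearly coincide
  expect_lt(sqrt(sum(multi$state$R_n^2)), 1e-6)
  expect_equal(single$objective_final, multi$objective_final,
               tolerance = 1e-4)

  # smallest valid k converges without error, deterministically
  ctl1 <- cmf_control(k = 1, alpha = 1, beta = 1, lambda = 1, seed = 3)
  s1 <- cmf_fit_single(pl$A_p, W_r, W_d, ctl1, task = "p")
  s2 <- cmf_fit_single(pl$A_p, W_r, W_d, ctl1, task = "p")
  expect_identical(s1$S_p, s2$S_p)
})

test_that("checkpoints round-trip bit-exactly", {
  pb <- small_problem(m = 8, n = 6, k = 2, seed = 6)
  ctl <- cmf_control(k = 2, max_iter = 20, seed = 7)
  f <- cmf_fit(pb$A_p, pb$A_n, pb$W_r, pb$W_d, ctl)
  p <- tempfile(fileext = ".rds")
  write_checkpoint(f, p)
  expect_identical(read_checkpoint(p), f)
})
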