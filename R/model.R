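`%||%` <- function(a, b) if (is.null(a)) b else a

# Collective matrix tri-factorization with ADMM.
#
# The model approximates the two binary association matrices as
#   A_p ~ U R_p V',   A_n ~ U R_n V'
# with SHARED drug factors U (m x k) and disease factors V (n x k) and
# task-specific k x k coefficient matrices, so each task regularizes the
# other. Graph Laplacian penalties tie the factor rows to the drug/disease
# similarity structure, and an L2 ridge keeps everything smooth:
#
#   min  1/2(||A_p - U R_p V'||_F^2 + ||A_n - U R_n V'||_F^2)
#      + alpha/2 tr(U' L_U U) + beta/2 tr(V' L_V V)
#      + lambda/2 (||U||^2 + ||V||^2 + ||R_p||^2 + ||R_n||^2)
#
# The Laplacian terms are decoupled from the reconstruction terms by
# auxiliary copies W = U, J = V, and the constrained problem is solved by
# ADMM: closed-form primal updates (each zeroes its partial derivative of
# the augmented Lagrangian), a matrix-free conjugate-gradient solver for the
# coefficient matrices, then dual ascent on the multipliers with a geometric
# penalty schedule rho <- mu * rho (capped).

#' Hyperparameters for the collective tri-factorization model
#'
#' Defaults follow the grid-search optimum of the reference benchmark for the
#' therapeutic task (`k = 30`, `alpha = beta = 8`, `lambda = 4`) and the
#' stated ADMM schedule (`mu = 1.1`, initial penalties 1).
#'
#' @param k Latent dimensionality; must satisfy `0 < k < min(m, n)` at fit
#'   time.
#' @param alpha,beta Drug / disease Laplacian regularization weights (>= 0).
#' @param lambda L2 (ridge) weight (>= 0).
#' @param mu Penalty growth factor (> 1), applied each ADMM iteration.
#' @param rho_init Initial penalty for both constraints (> 0).
#' @param rho_cap Maximum penalty. The geometric schedule would otherwise
#'   grow forever and destabilize conditioning; set to `Inf` for the uncapped
#'   schedule.
#' @param max_iter ADMM iteration cap.
#' @param tol Convergence tolerance on the relative primal residuals
#'   `||J - V|| / max(1, ||V||)` and `||W - U|| / max(1, ||U||)`.
#' @param obj_tol,obj_patience Alternative stop: relative objective change
#'   below `obj_tol` for `obj_patience` consecutive iterations.
#' @param cg_max_iter,cg_tol Inner conjugate-gradient cap and relative
#'   residual tolerance for the coefficient solves. The k^2-dimensional
#'   systems are tiny relative to the outer iteration, so the default is
#'   tight enough that the solve agrees with a dense oracle to about 1e-8.
#' @param seed RNG seed for the factor initialization (mandatory at fit time
#'   unless explicit initial factors are supplied).
#' @param mode `"multi_task"` fits both tasks jointly; `"single_task_p"` /
#'   `"single_task_n"` drop the other task's reconstruction term everywhere
#'   (the single-task reduction used as ablation baseline).
#' @return A list of class `cmf_control`.
#' @export
cmf_control <- function(k = 30L, alpha = 8, beta = 8, lambda = 4,
                        mu = 1.1, rho_init = 1, rho_cap = 1e6,
                        max_iter = 500L, tol = 1e-4,
                        obj_tol = 1e-6, obj_patience = 5L,
                        cg_max_iter = 200L, cg_tol = 1e-10,
                        seed = NULL,
                        mode = c("multi_task", "single_task_p", "single_task_n")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, alpha >= 0, beta >= 0, lambda >= 0, mu > 1,
            rho_init > 0, rho_cap > 0, max_iter >= 1, tol > 0,
            cg_max_iter >= 1, cg_tol > 0)
  structure(list(k = as.integer(k), alpha = alpha, beta = beta,
                 lambda = lambda, mu = mu, rho_init = rho_init,
                 rho_cap = rho_cap, max_iter = as.integer(max_iter),
                 tol = tol, obj_tol = obj_tol,
                 obj_patience = as.integer(obj_patience),
                 cg_max_iter = as.integer(cg_max_iter), cg_tol = cg_tol,
                 seed = seed, mode = mode),
            class = "cmf_control")
}

.use_p <- function(control) control$mode %in% c("multi_task", "single_task_p")
.use_n <- function(control) control$mode %in% c("multi_task", "single_task_n")

#' Regularized objective value
#'
#' Evaluates the fitting objective: half the squared Frobenius reconstruction
#' error of each active task, plus the Laplacian penalties on `U` and `V` and
#' the L2 terms. In single-task modes the inactive task's reconstruction
#' error is omitted (its coefficient matrix still carries an L2 term, which
#' drives it to zero).
#'
#' @param state A model state (list with `U`, `V`, `R_p`, `R_n`).
#' @param A_p,A_n Binary association matrices.
#' @param L_U,L_V Drug / disease graph Laplacians.
#' @param control A `cmf_control`.
#' @return Scalar objective value.
#' @export
cmf_objective <- function(state, A_p, A_n, L_U, L_V, control) {
  U <- state$U; V <- state$V
  obj <- 0
  if (.use_p(control)) obj <- obj + 0.5 * sum((A_p - U %*% state$R_p %*% t(V))^2)
  if (.use_n(control)) obj <- obj + 0.5 * sum((A_n - U %*% state$R_n %*% t(V))^2)
  obj + control$alpha / 2 * sum(U * (L_U %*% U)) +
    control$beta / 2 * sum(V * (L_V %*% V)) +
    control$lambda / 2 * (sum(U^2) + sum(V^2) +
                            sum(state$R_p^2) + sum(state$R_n^2))
}

#' Augmented Lagrangian value
#'
#' The constrained reformulation places the Laplacian penalties on the
#' auxiliary copies `W` (of `U`) and `J` (of `V`) and augments with
#' trace-multiplier terms `tr(Z'(W-U)) + tr(Y'(J-V))` and quadratic penalties
#' `rho1/2 ||W-U||^2 + rho2/2 ||J-V||^2`. Equals [cmf_objective()] whenever
#' `W = U`, `J = V`.
#'
#' @inheritParams cmf_objective
#' @return Scalar augmented-Lagrangian value.
#' @export
cmf_lagrangian <- function(state, A_p, A_n, L_U, L_V, control) {
  U <- state$U; V <- state$V; W <- state$W; J <- state$J
  val <- 0
  if (.use_p(control)) val <- val + 0.5 * sum((A_p - U %*% state$R_p %*% t(V))^2)
  if (.use_n(control)) val <- val + 0.5 * sum((A_n - U %*% state$R_n %*% t(V))^2)
  val + control$alpha / 2 * sum(W * (L_U %*% W)) +
    control$beta / 2 * sum(J * (L_V %*% J)) +
    control$lambda / 2 * (sum(U^2) + sum(V^2) +
                            sum(state$R_p^2) + sum(state$R_n^2)) +
    sum(state$Z * (W - U)) + state$rho1 / 2 * sum((W - U)^2) +
    sum(state$Y * (J - V)) + state$rho2 / 2 * sum((J - V)^2)
}

#' Conjugate-gradient solver for a coefficient matrix
#'
#' Solves `min_R 1/2 ||A - U R V'||_F^2 + lambda/2 ||R||_F^2`, whose normal
#' equation is `(U'U) R (V'V) + lambda R = U' A V`. The k^2-dimensional
#' linear operator `R -> (U'U) R (V'V) + lambda R` is symmetric positive
#' (semi)definite under the Frobenius inner product, so conjugate gradients
#' apply directly without materializing the k^2 x k^2 Kronecker system; each
#' CG step costs two k x k x k products.
#'
#' @param A m-by-n data matrix.
#' @param U,V Current factor matrices (m-by-k, n-by-k).
#' @param lambda Ridge weight (>= 0; with `lambda = 0` the factors must have
#'   full column rank for a unique solution).
#' @param R0 Optional warm start (defaults to the zero matrix).
#' @param max_iter,tol CG cap and relative-residual tolerance.
#' @return k-by-k coefficient matrix; attribute `cg_iters` records the
#'   iterations used. Warns (and returns the best iterate) on
#'   non-convergence.
#' @export
solve_coefficient <- function(A, U, V, lambda, R0 = NULL,
                              max_iter = 200L, tol = 1e-10) {
  G <- crossprod(U)               # k x k
  H <- crossprod(V)
  B <- crossprod(U, A %*% V)      # U' A V
  k <- ncol(U)
  op <- function(R) G %*% R %*% H + lambda * R
  R <- if (is.null(R0)) matrix(0, k, k) else R0
  bnorm <- sqrt(sum(B^2))
  if (bnorm == 0) return(structure(matrix(0, k, k), cg_iters = 0L))
  Rs <- B - op(R)
  P <- Rs
  rs_old <- sum(Rs^2)
  iters <- 0L
  while (sqrt(rs_old) > tol * bnorm && iters < max_iter) {
    Ap <- op(P)
    a <- rs_old / sum(P * Ap)
    R <- R + a * P
    Rs <- Rs - a * Ap
    rs_new <- sum(Rs^2)
    P <- Rs + (rs_new / rs_old) * P
    rs_old <- rs_new
    iters <- iters + 1L
  }
  if (sqrt(rs_old) > tol * bnorm) {
    warning("coefficient CG did not converge in ", max_iter,
            " iterations (relative residual ",
            format(sqrt(rs_old) / bnorm, digits = 3), ")")
  }
  structure(R, cg_iters = iters)
}

# solve S X = B for symmetric positive-definite S via Cholesky
.spd_solve <- function(S, B) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(solve(S, B))   # guarded fall-back
  backsolve(ch, forwardsolve(t(ch), B))
}

#' One sweep of closed-form primal updates
#'
#' Sequentially updates, in this order,
#' `J = (beta L_V + rho2 I)^{-1} (rho2 V - Y)`,
#' `W = (alpha L_U + rho1 I)^{-1} (rho1 U - Z)`,
#' `U = (A_p V R_p' + A_n V R_n' + Z + rho1 W)
#'      (R_p V'V R_p' + R_n V'V R_n' + lambda I + rho1 I)^{-1}`,
#' `V = (A_p' U R_p + A_n' U R_n + Y + rho2 J)
#'      ((U R_p)' U R_p + (U R_n)' U R_n + lambda I + rho2 I)^{-1}`.
#' Each formula is the stationary point of the augmented Lagrangian in that
#' variable with the others fixed; `J` uses the pre-update `V` while `U` uses
#' the freshly updated `W`, following the listed order. In single-task modes
#' the inactive task's terms are dropped.
#'
#' @inheritParams cmf_objective
#' @return The updated state.
#' @export
cmf_update_primal <- function(state, A_p, A_n, L_U, L_V, control) {
  lam <- control$lambda
  r1 <- state$rho1; r2 <- state$rho2
  k <- ncol(state$U)
  # J and W (Laplacian systems are SPD for rho > 0)
  state$J <- .spd_solve(control$beta * L_V + diag(r2, nrow(L_V)),
                        r2 * state$V - state$Y)
  state$W <- .spd_solve(control$alpha * L_U + diag(r1, nrow(L_U)),
                        r1 * state$U - state$Z)
  # U update (k x k system, solved on the right)
  V <- state$V
  VtV <- crossprod(V)
  num <- state$Z + r1 * state$W
  den <- diag(lam + r1, k)
  if (.use_p(control)) {
    num <- num + A_p %*% V %*% t(state$R_p)
    den <- den + state$R_p %*% VtV %*% t(state$R_p)
  }
  if (.use_n(control)) {
    num <- num + A_n %*% V %*% t(state$R_n)
    den <- den + state$R_n %*% VtV %*% t(state$R_n)
  }
  state$U <- t(.spd_solve((den + t(den)) / 2, t(num)))
  # V update
  U <- state$U
  num <- state$Y + r2 * state$J
  den <- diag(lam + r2, k)
  if (.use_p(control)) {
    URp <- U %*% state$R_p
    num <- num + crossprod(A_p, URp)
    den <- den + crossprod(URp)
  }
  if (.use_n(control)) {
    URn <- U %*% state$R_n
    num <- num + crossprod(A_n, URn)
    den <- den + crossprod(URn)
  }
  state$V <- t(.spd_solve((den + t(den)) / 2, t(num)))
  state
}

#' Dual ascent and penalty growth
#'
#' `Y <- Y + rho2 (J - V)`, `Z <- Z + rho1 (W - U)`, then both penalties grow
#' geometrically, `rho <- min(mu * rho, rho_cap)`.
#'
#' @inheritParams cmf_objective
#' @return The updated state.
#' @export
cmf_update_multipliers <- function(state, control) {
  state$Y <- state$Y + state$rho2 * (state$J - state$V)
  state$Z <- state$Z + state$rho1 * (state$W - state$U)
  state$rho1 <- min(control$mu * state$rho1, control$rho_cap)
  state$rho2 <- min(control$mu * state$rho2, control$rho_cap)
  state
}

#' Fit the collective tri-factorization model
#'
#' Runs the full ADMM loop: factors are initialized uniformly at random in
#' \[0, 1\] under `control$seed` (the closed-form updates are unconstrained
#' thereafter), multipliers start at zero and both penalties at
#' `control$rho_init`. Each iteration solves the two coefficient matrices by
#' conjugate gradients (warm-started from the previous iterate), performs one
#' primal sweep, then the dual/penalty update, and records the objective and
#' primal residuals. Iterations stop when both relative primal residuals
#' fall below `control$tol`, when the relative objective change stays below
#' `control$obj_tol` for `control$obj_patience` iterations, or at
#' `control$max_iter`.
#'
#' @param A_p,A_n Binary association matrices (m x n). In mode
#'   `"single_task_p"` only `A_p` is used (pass the other as `NULL`), and
#'   vice versa.
#' @param W_r,W_d Drug and disease similarity matrices (m x m, n x n).
#' @param control A [cmf_control()]; `control$seed` must be set unless
#'   `init` is supplied.
#' @param init Optional list with matrices `U` (m x k) and `V` (n x k) to use
#'   as the starting point instead of the seeded random draw.
#' @return Object of class `cmf_fit`: the final `state` (factors `U`, `V`,
#'   coefficients `R_p`, `R_n`, auxiliaries, multipliers, penalties), score
#'   matrices `S_p = U R_p V'` and `S_n = U R_n V'` (`NULL` for an inactive
#'   task), the per-iteration `history` data frame, `converged` flag and the
#'   `control` used.
#' @export
cmf_fit <- function(A_p, A_n, W_r, W_d, control = cmf_control(), init = NULL) {
  stopifnot(inherits(control, "cmf_control"))
  ref <- if (.use_p(control)) A_p else A_n
  m <- nrow(ref); n <- ncol(ref)
  if (.use_p(control) && .use_n(control)) stopifnot(all(dim(A_p) == dim(A_n)))
  if (control$k >= min(m, n)) {
    stop("latent dimensionality k = ", control$k,
         " must be smaller than min(m, n) = ", min(m, n))
  }
  stopifnot(all(dim(W_r) == c(m, m)), all(dim(W_d) == c(n, n)))
  drugs <- rownames(ref) %||% rownames(W_r)
  diseases <- colnames(ref) %||% rownames(W_d)
  if (!.use_p(control)) A_p <- matrix(0, m, n)
  if (!.use_n(control)) A_n <- matrix(0, m, n)
  L_U <- graph_laplacian(unname(W_r))
  L_V <- graph_laplacian(unname(W_d))
  A_p <- unname(A_p); A_n <- unname(A_n)
  k <- control$k
  if (is.null(init)) {
    if (is.null(control$seed)) stop("control$seed must be set (or supply init)")
    set.seed(control$seed)
    U <- matrix(stats::runif(m * k), m, k)
    V <- matrix(stats::runif(n * k), n, k)
  } else {
    stopifnot(all(dim(init$U) == c(m, k)), all(dim(init$V) == c(n, k)))
    U <- unname(init$U); V <- unname(init$V)
  }
  state <- list(U = U, V = V,
                R_p = matrix(0, k, k), R_n = matrix(0, k, k),
                J = V, W = U,
                Y = matrix(0, n, k), Z = matrix(0, m, k),
                rho1 = control$rho_init, rho2 = control$rho_init)
  hist <- vector("list", control$max_iter)
  obj_prev <- cmf_objective(state, A_p, A_n, L_U, L_V, control)
  obj_init <- obj_prev
  flat <- 0L
  converged <- FALSE
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    if (.use_p(control)) {
      state$R_p <- solve_coefficient(A_p, state$U, state$V, control$lambda,
                                     R0 = state$R_p,
                                     max_iter = control$cg_max_iter,
                                     tol = control$cg_tol)
    }
    if (.use_n(control)) {
      state$R_n <- solve_coefficient(A_n, state$U, state$V, control$lambda,
                                     R0 = state$R_n,
                                     max_iter = control$cg_max_iter,
                                     tol = control$cg_tol)
    }
    state <- cmf_update_primal(state, A_p, A_n, L_U, L_V, control)
    res_J <- sqrt(sum((state$J - state$V)^2)) / max(1, sqrt(sum(state$V^2)))
    res_W <- sqrt(sum((state$W - state$U)^2)) / max(1, sqrt(sum(state$U^2)))
    state <- cmf_update_multipliers(state, control)
    obj <- cmf_objective(state, A_p, A_n, L_U, L_V, control)
    hist[[it]] <- c(iter = it, objective = obj, res_J = res_J, res_W = res_W,
                    rho1 = state$rho1)
    if (it %% 10L == 0L || it == control$max_iter) {
      if (!all(is.finite(c(obj, state$U, state$V)))) {
        stop("non-finite values at ADMM iteration ", it,
             "; check scaling of the inputs or reduce mu/rho_cap")
      }
    }
    rel_change <- abs(obj - obj_prev) / max(1, abs(obj_prev))
    flat <- if (rel_change <= control$obj_tol) flat + 1L else 0L
    obj_prev <- obj
    if (res_J <= control$tol && res_W <= control$tol) { converged <- TRUE; break }
    if (flat >= control$obj_patience) { converged <- TRUE; break }
  }
  history <- as.data.frame(do.call(rbind, hist[seq_len(it)]))
  scores_p <- if (.use_p(control)) state$U %*% state$R_p %*% t(state$V) else NULL
  scores_n <- if (.use_n(control)) state$U %*% state$R_n %*% t(state$V) else NULL
  structure(list(state = state, S_p = scores_p, S_n = scores_n,
                 history = history, iterations = it, converged = converged,
                 objective_initial = obj_init, objective_final = obj_prev,
                 control = control, dims = c(m = m, n = n, k = k),
                 drugs = drugs, diseases = diseases),
            class = "cmf_fit")
}

#' Fit the single-task reduction
#'
#' Identical machinery with only one tri-factorization term: the other task's
#' reconstruction error is removed from the objective, Lagrangian and primal
#' updates, while the Laplacian and L2 regularization and the parameter
#' setting stay the same. Used as the ablation baseline against the joint
#' fit.
#'
#' @param A Binary association matrix of the retained task.
#' @param W_r,W_d Similarity matrices.
#' @param control A [cmf_control()]; its `mode` is forced to the requested
#'   single-task mode.
#' @param task `"p"` (therapeutic) or `"n"` (non-therapeutic).
#' @param init Optional initial factors, as in [cmf_fit()].
#' @return A `cmf_fit` whose inactive score matrix is `NULL`.
#' @export
cmf_fit_single <- function(A, W_r, W_d, control = cmf_control(),
                           task = c("p", "n"), init = NULL) {
  task <- match.arg(task)
  control$mode <- if (task == "p") "single_task_p" else "single_task_n"
  if (task == "p") cmf_fit(A_p = A, A_n = NULL, W_r, W_d, control, init = init)
  else cmf_fit(A_p = NULL, A_n = A, W_r, W_d, control, init = init)
}

#' @export
print.cmf_fit <- function(x, ...) {
  cat(sprintf("cmf_fit (%s): %d x %d, k = %d\n", x$control$mode,
              x$dims["m"], x$dims["n"], x$dims["k"]))
  cat(sprintf("  iterations: %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  objective: %.6g -> %.6g\n",
              x$objective_initial, x$objective_final))
  invisible(x)
}

#' Predicted score matrices
#'
#' @param object A `cmf_fit`.
#' @param ... Unused.
#' @return List with score matrices `S_p` and `S_n` (`NULL` for a task not
#'   fitted).
#' @export
predict.cmf_fit <- function(object, ...) {
  list(S_p = object$S_p, S_n = object$S_n)
}

#' Save / load a fitted model checkpoint
#'
#' Stores the factors, coefficients, hyperparameters, seed and convergence
#' history in a single archive that round-trips bit-exactly.
#'
#' @param fit A `cmf_fit`.
#' @param path Checkpoint file path.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   returns the `cmf_fit`.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "cmf_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "cmf_fit"))
  fit
}
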