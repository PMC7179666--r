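# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately naive (scalar loops, exhaustive enumeration, dense
# Kronecker solves) and shares no code path with the implementation.

# scalar-loop evaluation of the regularized objective
oracle_objective <- function(state, A_p, A_n, L_U, L_V, ctl) {
  frob2 <- function(M) {
    tot <- 0
    for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) tot <- tot + M[i, j]^2
    tot
  }
  recon <- function(A, R) {
    Shat <- state$U %*% R %*% t(state$V)
    tot <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
      tot <- tot + (A[i, j] - Shat[i, j])^2
    }
    tot
  }
  tr_quad <- function(X, L) {
    tot <- 0
    for (a in seq_len(ncol(X))) {
      tot <- tot + drop(t(X[, a]) %*% L %*% X[, a])
    }
    tot
  }
  val <- 0
  if (ctl$mode %in% c("multi_task", "single_task_p")) val <- val + recon(A_p, state$R_p) / 2
  if (ctl$mode %in% c("multi_task", "single_task_n")) val <- val + recon(A_n, state$R_n) / 2
  val + ctl$alpha / 2 * tr_quad(state$U, L_U) + ctl$beta / 2 * tr_quad(state$V, L_V) +
    ctl$lambda / 2 * (frob2(state$U) + frob2(state$V) +
                        frob2(state$R_p) + frob2(state$R_n))
}

# dense Kronecker-vectorized solve of (U'U) R (V'V) + lam R = U' A V
oracle_kron_solve <- function(A, U, V, lam) {
  k <- ncol(U)
  G <- t(U) %*% U
  H <- t(V) %*% V
  M <- kronecker(H, G) + lam * diag(k * k)
  b <- as.vector(t(U) %*% A %*% V)
  matrix(solve(M, b), k, k)
}

# exhaustive max-F threshold sweep; ties in F broken toward higher threshold
oracle_threshold <- function(scores, labels) {
  best <- NULL
  for (th in sort(unique(scores), decreasing = TRUE)) {
    pred <- scores >= th
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    se <- tp / (tp + fn)
    f <- if (pre + se > 0) 2 * pre * se / (pre + se) else 0
    if (is.null(best) || f > best$f + 1e-12) {
      best <- list(se = se, sp = tn / (tn + fp), pre = pre,
                   acc = (tp + tn) / length(labels), f = f, threshold = th)
    }
  }
  best
}

# probability interpretation of AUC: fraction of (pos, neg) pairs correctly
# ordered, ties counting one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# average precision over positive ranks, score ties broken by index
oracle_ap <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  hits <- 0; tot <- 0
  for (r in seq_along(y)) {
    if (y[r]) {
      hits <- hits + 1
      tot <- tot + hits / r
    }
  }
  tot / sum(labels)
}

# numeric gradient by central differences, elementwise over a matrix argument
numeric_gradient <- function(f, X, eps = 1e-5) {
  G <- X
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- X[i] + eps
    Xm <- X; Xm[i] <- X[i] - eps
    G[i] <- (f(Xp) - f(Xm)) / (2 * eps)
  }
  G
}

# random model state with consistent shapes
random_state <- function(m, n, k, seed = 1) {
  set.seed(seed)
  list(U = matrix(runif(m * k), m, k), V = matrix(runif(n * k), n, k),
       R_p = matrix(rnorm(k * k), k, k), R_n = matrix(rnorm(k * k), k, k),
       J = matrix(runif(n * k), n, k), W = matrix(runif(m * k), m, k),
       Y = matrix(rnorm(n * k), n, k), Z = matrix(rnorm(m * k), m, k),
       rho1 = 1.5, rho2 = 2.5)
}

# random symmetric similarity-like matrix with unit diagonal
random_similarity <- function(p, seed = 1) {
  set.seed(seed)
  S <- matrix(runif(p * p), p, p)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# cluster-structured noiseless planted instance: one-hot factor rows make
# round01(U R V') exactly low-rank before the exclusivity correction
planted_noiseless <- function(m, n, k, seed) {
  set.seed(seed)
  U0 <- diag(k)[sample(k, m, TRUE), ]
  V0 <- diag(k)[sample(k, n, TRUE), ]
  R_p <- matrix(runif(k * k), k, k)
  R_n <- matrix(runif(k * k), k, k)
  A_p <- round(U0 %*% R_p %*% t(V0))
  A_n <- round(U0 %*% R_n %*% t(V0))
  A_n[A_p == 1] <- 0
  list(A_p = A_p, A_n = A_n, U = U0, V = V0)
}
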