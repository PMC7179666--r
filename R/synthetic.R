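# Synthetic instances with the structure the model assumes: two mutually
# exclusive binary association matrices sharing a planted low-rank
# drug/disease embedding with type-specific coefficient matrices, and
# similarity matrices derived from the SAME planted factors so the Laplacian
# penalties are informative.

#' Specification of a synthetic instance
#'
#' @param m,n Drug and disease counts.
#' @param k_true Planted latent rank, `< min(m, n)`.
#' @param density_p,density_n Target fraction of 1-entries per type;
#'   `density_p + density_n <= 1` so mutual exclusivity is feasible.
#' @param noise Flip probability in \[0, 0.5): each planted 1 is dropped with
#'   this probability and a matched count of random 0-cells is promoted to 1
#'   in the same task, keeping densities stable and exclusivity intact.
#' @param sim_noise Scale of the symmetric perturbation added to the
#'   factor-derived similarity matrices.
#' @param seed RNG seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 150L, n = 200L, k_true = 5L,
                           density_p = 0.0388, density_n = 0.0757,
                           noise = 0.05, sim_noise = 0.1, seed = 1L) {
  stopifnot(m >= 2, n >= 2, k_true >= 1, k_true < min(m, n),
            density_p > 0, density_n > 0,
            noise >= 0, noise < 0.5, sim_noise >= 0)
  if (density_p + density_n > 1) stop("infeasible densities: density_p + density_n > 1")
  structure(list(m = as.integer(m), n = as.integer(n),
                 k_true = as.integer(k_true),
                 density_p = density_p, density_n = density_n,
                 noise = noise, sim_noise = sim_noise, seed = seed),
            class = "synthetic_spec")
}

#' Benchmark-scale synthetic specification
#'
#' Mirrors the scale of the reference drug-disease benchmark: 269 drugs by
#' 598 diseases with densities chosen to plant roughly 6,244 therapeutic and
#' 12,172 non-therapeutic positives (0.0388 and 0.0757), rank 30, 5% label
#' noise. Arguments override individual fields, e.g. for a scaled-down
#' harness.
#'
#' @inheritParams synthetic_spec
#' @return A `synthetic_spec`.
#' @export
benchmark_scale_spec <- function(m = 269L, n = 598L, k_true = 30L,
                                 density_p = 0.0388, density_n = 0.0757,
                                 noise = 0.05, sim_noise = 0.1, seed = 42L) {
  synthetic_spec(m = m, n = n, k_true = k_true,
                 density_p = density_p, density_n = density_n,
                 noise = noise, sim_noise = sim_noise, seed = seed)
}

# cosine similarity of the rows of a nonnegative factor matrix, perturbed by
# a symmetric noise term, clipped to [0, 1], unit diagonal
.factor_similarity <- function(X, sim_noise) {
  nrm <- sqrt(rowSums(X^2))
  S <- tcrossprod(X / pmax(nrm, .Machine$double.eps))
  if (sim_noise > 0) {
    E <- matrix(stats::rnorm(nrow(X)^2, sd = sim_noise), nrow(X))
    S <- S + (E + t(E)) / 2
  }
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  S
}

#' Generate a synthetic instance
#'
#' Draws nonnegative planted factors `U*` (m x k), `V*` (n x k) and distinct
#' coefficient matrices `R*_p`, `R*_n` (all uniform in \[0, 1\]), forms the
#' two score matrices `U* R* V*'`, assigns each cell to the type with the
#' higher standardized score (which enforces exclusivity; standardization
#' removes the arbitrary overall scale of the drawn coefficients), and sets a
#' cell to 1 iff its score ranks above the per-type quantile that realizes
#' the target density.
#' Label noise then drops each 1 with probability `noise` and promotes a
#' matched count of all-zero cells in the same task. Similarity matrices are
#' row-cosine similarities of the planted factors plus a clipped symmetric
#' perturbation.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_instance`: `matrices` (an
#'   `association_matrices`), similarity matrices `W_r`, `W_d`, the planted
#'   `truth` (`U`, `V`, `R_p`, `R_n` and pre-noise score matrices `S_p`,
#'   `S_n`), and the `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m <- spec$m; n <- spec$n; k <- spec$k_true
  U <- matrix(stats::runif(m * k), m, k)
  V <- matrix(stats::runif(n * k), n, k)
  R_p <- matrix(stats::runif(k * k), k, k)
  R_n <- matrix(stats::runif(k * k), k, k)
  S_p <- U %*% R_p %*% t(V)
  S_n <- U %*% R_n %*% t(V)
  # compare on standardized scores: the overall scale of a random coefficient
  # matrix is arbitrary, and with nonnegative factors the raw comparison
  # would let whichever R has the larger mean claim nearly every cell
  zscore <- function(S) (S - mean(S)) / stats::sd(S)
  p_wins <- zscore(S_p) >= zscore(S_n)
  count_p <- round(m * n * spec$density_p)
  count_n <- round(m * n * spec$density_n)
  if (count_p > sum(p_wins) || count_n > sum(!p_wins)) {
    stop("infeasible densities for the drawn coefficients: a type was ",
         "assigned fewer cells than its target positive count")
  }
  top_cells <- function(S, eligible, count) {
    idx <- which(eligible)
    idx[order(S[idx], decreasing = TRUE)[seq_len(count)]]
  }
  A_p <- A_n <- matrix(0L, m, n)
  A_p[top_cells(S_p, p_wins, count_p)] <- 1L
  A_n[top_cells(S_n, !p_wins, count_n)] <- 1L
  if (spec$noise > 0) {
    add_noise <- function(A, A_other) {
      ones <- which(A == 1L)
      drop <- ones[stats::runif(length(ones)) < spec$noise]
      A[drop] <- 0L
      free <- which(A == 0L & A_other == 0L)
      A[free[sample.int(length(free), length(drop))]] <- 1L
      A
    }
    A_p <- add_noise(A_p, A_n)
    A_n <- add_noise(A_n, A_p)
  }
  drugs <- sprintf("drug_%04d", seq_len(m))
  diseases <- sprintf("disease_%04d", seq_len(n))
  dimnames(A_p) <- dimnames(A_n) <- list(drugs, diseases)
  W_r <- .factor_similarity(U, spec$sim_noise)
  W_d <- .factor_similarity(V, spec$sim_noise)
  dimnames(W_r) <- list(drugs, drugs)
  dimnames(W_d) <- list(diseases, diseases)
  matrices <- structure(list(A_p = A_p, A_n = A_n,
                             drugs = drugs, diseases = diseases),
                        class = "association_matrices")
  structure(list(matrices = matrices, W_r = W_r, W_d = W_d,
                 truth = list(U = U, V = V, R_p = R_p, R_n = R_n,
                              S_p = S_p, S_n = S_n),
                 spec = spec),
            class = "synthetic_instance")
}

#' Write a synthetic instance to disk
#'
#' Emits the association TSV and the two similarity TSVs (the pipeline's
#' direct inputs), plus the planted truth factors as TSVs under `truth/`.
#'
#' @param instance A `synthetic_instance`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of paths written.
#' @export
write_synthetic <- function(instance, dir) {
  stopifnot(inherits(instance, "synthetic_instance"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    associations = file.path(dir, "associations.tsv"),
    drug_similarity = file.path(dir, "drug_similarity.tsv"),
    disease_similarity = file.path(dir, "disease_similarity.tsv")
  )
  write_associations(instance$matrices, paths$associations)
  write_similarity(instance$W_r, paths$drug_similarity)
  write_similarity(instance$W_d, paths$disease_similarity)
  for (nm in names(instance$truth)) {
    p <- file.path(dir, "truth", paste0(nm, ".tsv"))
    utils::write.table(instance$truth[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[[paste0("truth_", nm)]] <- p
  }
  invisible(paths)
}
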