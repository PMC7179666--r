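# Cross-validated evaluation: fold handling, threshold metrics at the max-F
# operating point, ranking metrics (AUC / AUPR), and top-N curves.
#
# Conventions. Per task, the evaluation universe is every (drug, disease)
# cell that is not a TRAINING positive of that task; cells positive in the
# other task count as negatives (they are, by the mutual-exclusivity premise,
# known non-members of this task). Ties in score are broken deterministically
# by linear cell index wherever an ordering is needed.

#' Random fold plan over the positives of both tasks
#'
#' Splits each task's known positives into `n_folds` near-equal parts
#' independently and uniformly at random (sizes differ by at most one within
#' a task), deterministically under `seed`.
#'
#' @param matrices An `association_matrices` object.
#' @param n_folds Number of folds (default 5).
#' @param seed RNG seed.
#' @return Object of class `fold_plan`: per task, the positive coordinates
#'   (`pos_p`, `pos_n`; linear indices into the m x n matrix) and their fold
#'   assignments (`fold_p`, `fold_n` in `1:n_folds`).
#' @export
make_folds <- function(matrices, n_folds = 5L, seed) {
  pos_p <- which(matrices$A_p == 1L)
  pos_n <- which(matrices$A_n == 1L)
  if (length(pos_p) < n_folds || length(pos_n) < n_folds) {
    stop("each task needs at least n_folds positives")
  }
  set.seed(seed)
  assign_folds <- function(npos) {
    sample(rep(seq_len(n_folds), length.out = npos))
  }
  structure(list(n_folds = as.integer(n_folds), seed = seed,
                 pos_p = pos_p, fold_p = assign_folds(length(pos_p)),
                 pos_n = pos_n, fold_n = assign_folds(length(pos_n))),
            class = "fold_plan")
}

#' Mask one fold's positives out of the training matrices
#'
#' Zeroes the fold's positives of BOTH tasks simultaneously: the multi-task
#' model is fitted once per fold, and masking only one task would leak the
#' other task's test links through the shared factors.
#'
#' @param matrices An `association_matrices` object.
#' @param plan A `fold_plan`.
#' @param fold Fold number in `1:n_folds`.
#' @return List with `train` (an `association_matrices` with the fold
#'   zeroed), `test_p` and `test_n` (linear indices of the removed
#'   positives per task).
#' @export
mask_fold <- function(matrices, plan, fold) {
  stopifnot(inherits(plan, "fold_plan"), fold >= 1L, fold <= plan$n_folds)
  test_p <- plan$pos_p[plan$fold_p == fold]
  test_n <- plan$pos_n[plan$fold_n == fold]
  if (!length(test_p) || !length(test_n)) {
    warning("fold ", fold, " has an empty test set for one task")
  }
  train <- matrices
  train$A_p[test_p] <- 0L
  train$A_n[test_n] <- 0L
  list(train = train, test_p = test_p, test_n = test_n)
}

# confusion counts for every candidate threshold, scanning scores descending
.threshold_sweep <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  P <- sum(y); N <- length(y) - P
  tp <- cumsum(y)
  fp <- seq_along(y) - tp
  # candidate thresholds = distinct score values; cut after the last
  # occurrence of each value (prediction positive iff score >= threshold)
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  data.frame(threshold = s[last], tp = tp[last], fp = fp[last],
             fn = P - tp[last], tn = N - fp[last])
}

#' Threshold-based metrics at the max-F operating point
#'
#' Sweeps every distinct score value over the evaluation universe as a
#' candidate threshold (prediction positive iff score >= threshold) and
#' reports sensitivity, specificity, precision, accuracy and F-measure at the
#' threshold maximizing F; ties in F are broken toward the higher threshold
#' (fewer predicted positives).
#'
#' @param scores Real score matrix (or vector indexable by the coordinates).
#' @param test_pos Linear indices of the test positives.
#' @param eval_mask Linear indices of the evaluation universe; must contain
#'   `test_pos` and exclude the scored task's training positives.
#' @return Named list `se`, `sp`, `pre`, `acc`, `f`, `threshold`.
#' @export
threshold_metrics <- function(scores, test_pos, eval_mask) {
  if (!length(test_pos)) stop("empty test positive set: metrics undefined")
  if (!all(test_pos %in% eval_mask)) stop("test positives outside eval_mask")
  s <- as.numeric(scores[eval_mask])
  y <- as.integer(eval_mask %in% test_pos)
  sw <- .threshold_sweep(s, y)
  pre <- ifelse(sw$tp + sw$fp > 0, sw$tp / (sw$tp + sw$fp), 0)
  se <- sw$tp / (sw$tp + sw$fn)
  f <- ifelse(pre + se > 0, 2 * pre * se / (pre + se), 0)
  # sweep is descending, so the first (near-)maximal F is the highest
  # threshold; the epsilon absorbs 1-ulp differences between algebraically
  # equal F values reached by different float paths
  best <- which(f >= max(f) - 1e-12)[1]
  list(se = se[best],
       sp = sw$tn[best] / (sw$tn[best] + sw$fp[best]),
       pre = pre[best],
       acc = (sw$tp[best] + sw$tn[best]) / length(y),
       f = f[best],
       threshold = sw$threshold[best])
}

#' Ranking metrics: AUC and AUPR
#'
#' AUC is the tie-corrected Mann-Whitney statistic over the evaluation
#' universe (the probability that a random test positive outscores a random
#' negative, counting ties as one half). AUPR is the step-wise
#' precision-recall integral, i.e. the average of the precision values at the
#' rank of each positive (score ties broken deterministically by cell index).
#'
#' @inheritParams threshold_metrics
#' @return Named list `auc`, `aupr`.
#' @export
ranking_metrics <- function(scores, test_pos, eval_mask) {
  if (!length(test_pos)) stop("empty test positive set: metrics undefined")
  if (!all(test_pos %in% eval_mask)) stop("test positives outside eval_mask")
  s <- as.numeric(scores[eval_mask])
  y <- eval_mask %in% test_pos
  P <- sum(y); N <- length(y) - P
  if (N == 0L) stop("no negatives in eval_mask")
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[y]) - P * (P + 1) / 2) / (P * N)
  ord <- order(-s, seq_along(s))         # descending, ties by index
  hits <- cumsum(y[ord])
  pos_at <- which(y[ord])
  aupr <- mean(hits[pos_at] / pos_at)
  list(auc = auc, aupr = aupr)
}

#' Top-N recall and precision curves
#'
#' For each N, takes the N highest-scoring cells of the evaluation universe
#' (ties broken deterministically by cell index) and reports
#' `recall = hits / |test_pos|` and `precision = hits / N`.
#'
#' @inheritParams threshold_metrics
#' @param Ns Positive integers, each at most `length(eval_mask)`; default
#'   10, 20, ..., 1000 capped at the universe size.
#' @return Data frame with columns `N`, `recall`, `precision`.
#' @export
topn_curves <- function(scores, test_pos, eval_mask, Ns = NULL) {
  if (is.null(Ns)) Ns <- seq(10L, 1000L, by = 10L)
  Ns <- Ns[Ns <= length(eval_mask)]
  if (!length(Ns)) stop("no valid N values (universe too small)")
  if (any(Ns < 1L)) stop("Ns must be positive")
  s <- as.numeric(scores[eval_mask])
  y <- eval_mask %in% test_pos
  ord <- order(-s, seq_along(s))
  hits <- cumsum(y[ord])
  data.frame(N = Ns, recall = hits[Ns] / length(test_pos),
             precision = hits[Ns] / Ns)
}

# per-task evaluation universe: all cells minus this task's TRAINING
# positives; optionally also minus the other task's training positives
.eval_universe <- function(A_train, A_other_train, exclude_cross_type) {
  idx <- which(A_train == 0L)
  if (exclude_cross_type) idx <- idx[A_other_train[idx] == 0L]
  idx
}

#' Cross-validated evaluation of the joint model
#'
#' For each fold: masks both tasks' fold positives, fits one model on the
#' masked matrices, and evaluates task 1 (therapeutic) on `S_p` and task 2
#' (non-therapeutic) on `S_n` over that task's evaluation universe. Reports
#' the per-fold values and their means.
#'
#' @param matrices An `association_matrices` object.
#' @param W_r,W_d Similarity matrices.
#' @param control A [cmf_control()]. Single-task modes evaluate only their
#'   own task.
#' @param plan A [make_folds()] plan.
#' @param Ns Optional top-N grid; `NULL` skips the curves.
#' @param exclude_cross_type If `TRUE`, cells positive in the other task are
#'   removed from a task's negatives instead of counted among them.
#' @return Object of class `cv_report`: per task, a data frame of per-fold
#'   metrics (`aupr`, `auc`, `se`, `sp`, `pre`, `acc`, `f`, `threshold`), the
#'   column means, and (if requested) the fold-averaged top-N curve.
#' @export
cross_validate <- function(matrices, W_r, W_d, control, plan,
                           Ns = NULL, exclude_cross_type = FALSE) {
  stopifnot(inherits(plan, "fold_plan"))
  tasks <- c(if (.use_p(control)) "task1", if (.use_n(control)) "task2")
  fold_rows <- stats::setNames(vector("list", length(tasks)), tasks)
  topn_acc <- stats::setNames(vector("list", length(tasks)), tasks)
  for (fold in seq_len(plan$n_folds)) {
    msk <- mask_fold(matrices, plan, fold)
    fit <- cmf_fit(msk$train$A_p, msk$train$A_n, W_r, W_d, control)
    eval_one <- function(S, A_train, A_other, test_pos) {
      universe <- .eval_universe(A_train, A_other, exclude_cross_type)
      stopifnot(!any(which(A_train == 1L) %in% universe))
      test_pos <- intersect(test_pos, universe)
      tm <- threshold_metrics(S, test_pos, universe)
      rm_ <- ranking_metrics(S, test_pos, universe)
      row <- data.frame(fold = fold, aupr = rm_$aupr, auc = rm_$auc,
                        se = tm$se, sp = tm$sp, pre = tm$pre, acc = tm$acc,
                        f = tm$f, threshold = tm$threshold)
      curve <- if (!is.null(Ns)) topn_curves(S, test_pos, universe, Ns) else NULL
      list(row = row, curve = curve)
    }
    if (.use_p(control)) {
      r <- eval_one(fit$S_p, msk$train$A_p, msk$train$A_n, msk$test_p)
      fold_rows$task1[[fold]] <- r$row; topn_acc$task1[[fold]] <- r$curve
    }
    if (.use_n(control)) {
      r <- eval_one(fit$S_n, msk$train$A_n, msk$train$A_p, msk$test_n)
      fold_rows$task2[[fold]] <- r$row; topn_acc$task2[[fold]] <- r$curve
    }
  }
  summarize <- function(rows, curves) {
    per_fold <- do.call(rbind, rows)
    means <- colMeans(per_fold[, setdiff(names(per_fold), "fold")])
    topn <- NULL
    if (!is.null(Ns)) {
      topn <- curves[[1]]
      if (length(curves) > 1L) {
        for (cu in curves[-1]) {
          topn$recall <- topn$recall + cu$recall
          topn$precision <- topn$precision + cu$precision
        }
        topn$recall <- topn$recall / length(curves)
        topn$precision <- topn$precision / length(curves)
      }
    }
    list(per_fold = per_fold, mean = means, topn = topn)
  }
  out <- stats::setNames(lapply(tasks, function(tk) {
    summarize(fold_rows[[tk]], topn_acc[[tk]])
  }), tasks)
  structure(out, class = "cv_report", n_folds = plan$n_folds)
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation report\n", attr(x, "n_folds")))
  for (tk in names(x)) {
    cat(" ", tk, ": ",
        paste(sprintf("%s=%.*f", names(x[[tk]]$mean), digits, x[[tk]]$mean),
              collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a cross-validation report to disk
#'
#' Emits one metrics TSV per report (per-fold rows plus a mean row, tagged by
#' task), a JSON summary of the means, and, when present, one top-N curve
#' TSV per task.
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  rows <- list()
  for (tk in names(report)) {
    pf <- report[[tk]]$per_fold
    pf <- cbind(task = tk, pf)
    mean_row <- cbind(task = tk, fold = "mean",
                      as.data.frame(as.list(report[[tk]]$mean)))
    pf$fold <- as.character(pf$fold)
    rows[[tk]] <- rbind(pf, mean_row)
    if (!is.null(report[[tk]]$topn)) {
      p <- file.path(dir, paste0("topn_", tk, ".tsv"))
      utils::write.table(report[[tk]]$topn, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  p <- file.path(dir, "metrics.tsv")
  utils::write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "metrics.json")
  jsonlite::write_json(lapply(report, function(tk) as.list(tk$mean)),
                       p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
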