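# Drug and disease similarity kernels and graph Laplacians.
#
# Drug-drug similarity is the Tanimoto/Jaccard index on binary feature
# profiles. Disease-disease similarity is a semantic measure on the DAG of
# MeSH tree-number prefixes: each ancestor contributes a value that decays by
# a factor delta per level away from the disease's own node(s), and two
# diseases are similar in proportion to the contribution mass of the
# ancestors they share.

#' Drug-drug Tanimoto (Jaccard) similarity matrix
#'
#' For profiles \eqn{\Gamma_i, \Gamma_j}, the similarity is
#' \eqn{|\Gamma_i \cap \Gamma_j| / (|\Gamma_i| + |\Gamma_j| -
#' |\Gamma_i \cap \Gamma_j|)}. A drug with an empty profile has similarity 0
#' to everything, including itself (its diagonal is 0 and a warning is
#' emitted) rather than aborting the run.
#'
#' @param profiles A `feature_profiles` object (see [read_feature_profiles()]).
#' @return Symmetric numeric matrix with entries in \[0, 1\] and id dimnames.
#' @export
jaccard_similarity <- function(profiles) {
  stopifnot(inherits(profiles, "feature_profiles"))
  prof <- profiles$profiles
  ids <- names(prof)
  if (!length(ids)) stop("no drugs in feature profiles")
  universe <- profiles$universe
  X <- vapply(prof, function(p) as.numeric(universe %in% p),
              numeric(length(universe)))
  X <- matrix(X, nrow = length(universe))    # c x m binary encoding
  inter <- crossprod(X)                      # <x_i, x_j>
  sizes <- colSums(X)
  union <- outer(sizes, sizes, "+") - inter
  S <- ifelse(union > 0, inter / union, 0)
  dimnames(S) <- list(ids, ids)
  empty <- sizes == 0
  if (any(empty)) {
    warning("drug(s) with empty feature profile get similarity 0 (incl. self): ",
            paste(utils::head(ids[empty], 5), collapse = ", "))
  }
  S
}

#' Build the ancestor DAG of a disease from its MeSH tree numbers
#'
#' Every dot-prefix of every tree number becomes a node (node identity is the
#' tree-number string, so shared ancestry means shared prefix), with an edge
#' from each prefix to its one-segment extension. The disease's "own" nodes
#' are its full tree numbers; a disease with several tree numbers has all of
#' them as own nodes in one merged DAG.
#'
#' @param disease_id Disease identifier.
#' @param tree_numbers Non-empty character vector of dot-delimited tree
#'   numbers.
#' @return Object of class `disease_dag`: list with `id`, `nodes`, `own`
#'   (full tree numbers), `children` (named list node -> child nodes), and
#'   placeholders `sc` (per-node semantic contribution) and `sv` (semantic
#'   value), filled by [semantic_contribution()] / [semantic_value()].
#' @export
disease_dag <- function(disease_id, tree_numbers) {
  tree_numbers <- unique(tree_numbers[nzchar(tree_numbers)])
  if (!length(tree_numbers)) stop("empty tree-number set for ", disease_id)
  prefixes <- function(tn) {
    seg <- strsplit(tn, ".", fixed = TRUE)[[1]]
    if (any(!nzchar(seg))) stop("malformed tree number: '", tn, "'")
    vapply(seq_along(seg), function(i) paste(seg[1:i], collapse = "."), "")
  }
  chains <- lapply(tree_numbers, prefixes)
  nodes <- sort(unique(unlist(chains)))
  children <- stats::setNames(vector("list", length(nodes)), nodes)
  for (ch in chains) {
    if (length(ch) > 1L) {
      for (i in seq_len(length(ch) - 1L)) {
        children[[ch[i]]] <- union(children[[ch[i]]], ch[i + 1L])
      }
    }
  }
  structure(list(id = disease_id, nodes = nodes, own = sort(tree_numbers),
                 children = children, sc = NULL, sv = NULL, delta = NULL),
            class = "disease_dag")
}

#' Semantic contribution of each DAG node
#'
#' The disease's own node(s) contribute 1; any other ancestor `t` contributes
#' `max(delta * sc(t'))` over its children `t'`, evaluated in
#' reverse-topological (deepest-first) order so every child is finished
#' before its parent. The recursion is order-free because only the maximum
#' over children matters.
#'
#' @param dag A `disease_dag`.
#' @param delta Per-level decay factor in (0, 1); 0.5 by default downstream.
#' @return The DAG with `sc` (named numeric, entries in (0, 1\]) and `delta`
#'   set.
#' @export
semantic_contribution <- function(dag, delta) {
  stopifnot(inherits(dag, "disease_dag"), delta > 0, delta < 1)
  depth <- lengths(strsplit(dag$nodes, ".", fixed = TRUE))
  # children are strictly deeper than parents, so depth order is topological;
  # a cycle would need an edge to an equal-or-shallower node
  for (nd in dag$nodes) {
    deeper <- depth[match(dag$children[[nd]], dag$nodes)] > depth[match(nd, dag$nodes)]
    if (length(deeper) && !all(deeper)) stop("cycle detected in DAG of ", dag$id)
  }
  sc <- stats::setNames(rep(NA_real_, length(dag$nodes)), dag$nodes)
  for (nd in dag$nodes[order(depth, decreasing = TRUE)]) {
    if (nd %in% dag$own) {
      sc[nd] <- 1
    } else {
      kids <- dag$children[[nd]]
      if (!length(kids)) stop("leaf node '", nd, "' is not an own node of ", dag$id)
      sc[nd] <- max(delta * sc[kids])
    }
  }
  dag$sc <- sc
  dag$sv <- sum(sc)
  dag$delta <- delta
  dag
}

#' Semantic value of a disease
#'
#' The sum of semantic contributions over all DAG nodes; at least 1 since the
#' disease's own node contributes 1.
#'
#' @param dag A `disease_dag` with `sc` filled.
#' @return Scalar semantic value.
#' @export
semantic_value <- function(dag) {
  if (is.null(dag$sc)) stop("semantic contributions not computed; call semantic_contribution()")
  sum(dag$sc)
}

#' Disease-disease semantic similarity matrix
#'
#' For diseases i, j with node sets \eqn{V_i, V_j},
#' \eqn{S_{ij} = \sum_{t \in V_i \cap V_j} (SC_i(t) + SC_j(t)) / (SV_i + SV_j)}.
#' Node-key (tree-number string) equality defines the intersection. Diseases
#' without a DAG (`NULL` entries) get similarity 0 to everything, with a
#' warning.
#'
#' @param dags Named list of `disease_dag` objects (or `NULL` for diseases
#'   lacking MeSH annotation), `sc`/`sv` already filled with a common `delta`.
#' @param delta The decay factor the DAGs were computed with (checked).
#' @return Symmetric numeric matrix with entries in \[0, 1\], unit diagonal
#'   for annotated diseases, and id dimnames.
#' @export
disease_similarity <- function(dags, delta = 0.5) {
  ids <- names(dags)
  if (is.null(ids)) stop("dags must be a named list")
  has <- !vapply(dags, is.null, TRUE)
  for (d in dags[has]) {
    if (is.null(d$sc)) stop("DAG of ", d$id, " lacks semantic contributions")
    if (!isTRUE(all.equal(d$delta, delta))) {
      stop("DAG of ", d$id, " computed with delta = ", d$delta,
           " but similarity requested with delta = ", delta)
    }
  }
  if (any(!has)) {
    warning("disease(s) without MeSH DAG get similarity 0 (incl. self): ",
            paste(utils::head(ids[!has], 5), collapse = ", "))
  }
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  idx <- which(has)
  for (a in seq_along(idx)) {
    i <- idx[a]
    for (b in a:length(idx)) {
      j <- idx[b]
      shared <- intersect(dags[[i]]$nodes, dags[[j]]$nodes)
      if (length(shared)) {
        S[i, j] <- S[j, i] <-
          sum(dags[[i]]$sc[shared] + dags[[j]]$sc[shared]) /
          (dags[[i]]$sv + dags[[j]]$sv)
      }
    }
  }
  S
}

#' Convenience wrapper: MeSH trees to similarity matrix
#'
#' Builds one merged ancestor DAG per disease, fills semantic contributions
#' with decay `delta`, and evaluates the pairwise similarity.
#'
#' @param trees Named list disease id -> tree numbers ([read_mesh_trees()]).
#' @param diseases Optional id vector fixing row order; ids without trees get
#'   zero rows.
#' @param delta Decay factor, default 0.5.
#' @return Symmetric similarity matrix.
#' @export
mesh_disease_similarity <- function(trees, diseases = NULL, delta = 0.5) {
  if (is.null(diseases)) diseases <- sort(names(trees))
  dags <- stats::setNames(lapply(diseases, function(d) {
    if (is.null(trees[[d]])) return(NULL)
    semantic_contribution(disease_dag(d, trees[[d]]), delta)
  }), diseases)
  disease_similarity(dags, delta)
}

#' Graph Laplacian of a similarity matrix
#'
#' `L = D - S` with `D` diagonal holding the row sums of `S`. Any
#' self-similarity on the diagonal of `S` enters both `D` and `S` and cancels
#' in `L`. `L` is symmetric, its rows sum to zero, and it is positive
#' semidefinite, so `tr(U' L U)` equals half the similarity-weighted sum of
#' squared row differences of `U`.
#'
#' @param S Symmetric nonnegative square matrix.
#' @return The Laplacian matrix, same dimnames as `S`.
#' @export
graph_laplacian <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (any(S < 0)) stop("similarity matrix has negative entries")
  diag(rowSums(S)) - S
}
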