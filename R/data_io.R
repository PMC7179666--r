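# Input parsing and matrix construction for the paired association tasks.

.type_vocab <- c(
  "therapeutic"      = "therapeutic",
  "1"                = "therapeutic",
  "marker/mechanism" = "non_therapeutic",
  "non-therapeutic"  = "non_therapeutic",
  "non_therapeutic"  = "non_therapeutic",
  "-1"               = "non_therapeutic"
)

.normalize_type <- function(tok) {
  out <- unname(.type_vocab[tolower(trimws(tok))])
  out
}

#' Read drug-disease association triples
#'
#' Parses a tab-separated file of `drug_id<TAB>disease_id<TAB>type` records.
#' Recognized type tokens (case-insensitive) are `therapeutic`, `1`,
#' `marker/mechanism`, `non-therapeutic`, `non_therapeutic` and `-1`;
#' `marker/mechanism` is the CTD annotation for the non-therapeutic class.
#' Exact duplicate records are dropped. A (drug, disease) pair annotated with
#' BOTH types is resolved according to `conflict`: the default keeps the
#' therapeutic record only, mirroring how the extreme dual-annotated cases
#' are labeled in the source database.
#'
#' @param path Path to the association TSV.
#' @param conflict One of `"therapeutic"` (therapeutic wins, default),
#'   `"non_therapeutic"` (non-therapeutic wins) or `"drop"` (remove the pair).
#' @param header Logical; skip a single header line (default `FALSE`).
#' @return An object of class `association_table`: a data frame with columns
#'   `drug`, `disease`, `type` and attributes `n_conflicts` (number of pairs
#'   seen with both types) and `conflict` (the policy applied).
#' @export
read_associations <- function(path,
                              conflict = c("therapeutic", "non_therapeutic", "drop"),
                              header = FALSE) {
  conflict <- match.arg(conflict)
  if (!file.exists(path)) stop("association file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (header && length(lines)) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (!length(lines)) stop("no associations in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop("unparseable association line (need >= 3 tab-separated fields) at line ",
         line_no[which(nf < 3)[1]])
  }
  drug <- trimws(vapply(parts, `[[`, "", 1L))
  disease <- trimws(vapply(parts, `[[`, "", 2L))
  type <- .normalize_type(vapply(parts, `[[`, "", 3L))
  if (anyNA(type)) {
    bad <- which(is.na(type))[1]
    stop("unknown association type token at line ", line_no[bad], ": '",
         vapply(parts, `[[`, "", 3L)[bad], "'")
  }
  if (any(!nzchar(drug)) || any(!nzchar(disease))) {
    bad <- which(!nzchar(drug) | !nzchar(disease))[1]
    stop("empty drug or disease id at line ", line_no[bad])
  }
  tab <- unique(data.frame(drug = drug, disease = disease, type = type,
                           stringsAsFactors = FALSE))
  pair <- paste(tab$drug, tab$disease, sep = "\r")
  dup <- pair[duplicated(pair)]           # pairs present with both types
  n_conflicts <- length(unique(dup))
  if (n_conflicts > 0L) {
    in_conflict <- pair %in% dup
    tab <- switch(conflict,
      therapeutic     = tab[!(in_conflict & tab$type == "non_therapeutic"), ],
      non_therapeutic = tab[!(in_conflict & tab$type == "therapeutic"), ],
      drop            = tab[!in_conflict, ]
    )
    message(n_conflicts, " dual-annotated pair(s) resolved by policy '",
            conflict, "'")
  }
  rownames(tab) <- NULL
  structure(tab, class = c("association_table", "data.frame"),
            n_conflicts = n_conflicts, conflict = conflict)
}

#' Build the paired binary association matrices
#'
#' Converts an [read_associations()] table into two binary drug-by-disease
#' matrices, `A_p` for therapeutic links and `A_n` for non-therapeutic links.
#' Rows are drugs and columns diseases in both; entries are 0/1 and the two
#' matrices are elementwise mutually exclusive provided conflicts were
#' resolved at load time.
#'
#' @param table An `association_table`.
#' @param drug_order,disease_order Optional id orderings; must cover every id
#'   appearing in the table. Defaults to lexicographic order for determinism.
#' @return Object of class `association_matrices`: list with binary matrices
#'   `A_p`, `A_n` (dimnames = ids) and character vectors `drugs`, `diseases`.
#' @export
association_matrices <- function(table, drug_order = NULL, disease_order = NULL) {
  stopifnot(is.data.frame(table),
            all(c("drug", "disease", "type") %in% names(table)))
  if (is.null(drug_order)) drug_order <- sort(unique(table$drug))
  if (is.null(disease_order)) disease_order <- sort(unique(table$disease))
  miss_r <- setdiff(table$drug, drug_order)
  miss_d <- setdiff(table$disease, disease_order)
  if (length(miss_r)) stop("drug id missing from supplied order: ", miss_r[1])
  if (length(miss_d)) stop("disease id missing from supplied order: ", miss_d[1])
  m <- length(drug_order); n <- length(disease_order)
  A_p <- A_n <- matrix(0L, m, n, dimnames = list(drug_order, disease_order))
  i <- match(table$drug, drug_order)
  j <- match(table$disease, disease_order)
  is_p <- table$type == "therapeutic"
  A_p[cbind(i[is_p], j[is_p])] <- 1L
  A_n[cbind(i[!is_p], j[!is_p])] <- 1L
  structure(list(A_p = A_p, A_n = A_n,
                 drugs = drug_order, diseases = disease_order),
            class = "association_matrices")
}

#' @export
print.association_matrices <- function(x, ...) {
  cat(sprintf("association_matrices: %d drugs x %d diseases\n",
              length(x$drugs), length(x$diseases)))
  cat(sprintf("  therapeutic positives:     %d\n", sum(x$A_p)))
  cat(sprintf("  non-therapeutic positives: %d\n", sum(x$A_n)))
  invisible(x)
}

#' Read per-drug binary feature profiles
#'
#' Each line is either `drug_id<TAB>descriptor` (one descriptor per line) or
#' `drug_id<TAB>desc1,desc2,...` (comma-joined; dialect auto-detected from the
#' presence of commas). Duplicated (drug, descriptor) lines are idempotent.
#'
#' @param path Path to the feature TSV.
#' @param drugs Optional character vector of required drug ids.
#' @param allow_empty Logical; permit drugs in `drugs` that are absent from the
#'   file (they get empty profiles and similarity 0 to everything, including
#'   themselves). Default `FALSE`.
#' @return Object of class `feature_profiles`: list with `profiles` (named
#'   list of character descriptor vectors) and `universe` (sorted union).
#' @export
read_feature_profiles <- function(path, drugs = NULL, allow_empty = FALSE) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("unparseable feature line (need drug_id<TAB>descriptor[s]): '",
         lines[which(lengths(parts) < 2L)[1]], "'")
  }
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  desc <- vapply(parts, `[[`, "", 2L)
  desc_list <- if (any(grepl(",", desc, fixed = TRUE))) {
    lapply(strsplit(desc, ",", fixed = TRUE), trimws)
  } else {
    as.list(trimws(desc))
  }
  profiles <- lapply(split(desc_list, ids), function(x) sort(unique(unlist(x))))
  if (!is.null(drugs)) {
    missing <- setdiff(drugs, names(profiles))
    if (length(missing) && !allow_empty) {
      stop("drug(s) with no feature descriptors: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    empty <- stats::setNames(rep(list(character(0)), length(missing)), missing)
    profiles <- c(profiles, empty)[drugs]
  }
  structure(list(profiles = profiles,
                 universe = sort(unique(unlist(profiles)))),
            class = "feature_profiles")
}

#' Read disease MeSH tree numbers
#'
#' Each line is `disease_id<TAB>tree_number` with dot-delimited hierarchical
#' tree numbers (e.g. `C04.557.337`); a disease may span multiple lines.
#'
#' @param path Path to the MeSH tree TSV.
#' @return Named list mapping disease id to a character vector of tree numbers.
#' @export
read_mesh_trees <- function(path) {
  if (!file.exists(path)) stop("MeSH tree file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("unparseable MeSH line (need disease_id<TAB>tree_number): '",
         lines[which(lengths(parts) < 2L)[1]], "'")
  }
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  tn <- trimws(vapply(parts, `[[`, "", 2L))
  bad <- !nzchar(tn) | grepl("(^\\.)|(\\.\\.)|(\\.$)", tn)
  if (any(bad)) stop("malformed tree number: '", tn[which(bad)[1]], "'")
  lapply(split(tn, ids), function(x) sort(unique(x)))
}

#' Write ranked novel-association predictions
#'
#' Merges the two tasks' score matrices into a single ranking over all
#' (drug, disease, type) triples that are NOT known positives of the
#' corresponding type, and writes the top `top_k` as a TSV with columns
#' `rank`, `drug_id`, `disease_id`, `type`, `score`.
#'
#' @param scores_p,scores_n Real m-by-n score matrices for the two tasks.
#' @param matrices An `association_matrices` object (supplies the known
#'   positives to mask and the id maps).
#' @param path Output file path.
#' @param top_k Number of rows to keep (capped at the number of candidates).
#' @return Invisibly, the written data frame.
#' @export
write_predictions <- function(scores_p, scores_n, matrices, path, top_k = 100L) {
  m <- length(matrices$drugs); n <- length(matrices$diseases)
  if (!all(dim(scores_p) == c(m, n)) || !all(dim(scores_n) == c(m, n))) {
    stop("score matrix shape does not match the association matrices")
  }
  cand <- function(S, A, type) {
    idx <- which(A == 0L)
    data.frame(drug_id = matrices$drugs[row(A)[idx]],
               disease_id = matrices$diseases[col(A)[idx]],
               type = type, score = S[idx], stringsAsFactors = FALSE)
  }
  out <- rbind(cand(scores_p, matrices$A_p, "therapeutic"),
               cand(scores_n, matrices$A_n, "non_therapeutic"))
  ord <- order(-out$score, out$drug_id, out$disease_id, out$type)
  out <- out[utils::head(ord, top_k), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write / read a similarity matrix as TSV
#'
#' Square symmetric matrices are stored with an id header row and a leading id
#' column; symmetry is checked on read.
#'
#' @param S Square symmetric numeric matrix with id dimnames.
#' @param path File path.
#' @return `read_similarity` returns the matrix; `write_similarity` returns
#'   `path` invisibly.
#' @export
write_similarity <- function(S, path) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), !is.null(rownames(S)))
  df <- data.frame(id = rownames(S), S, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  if (!file.exists(path)) stop("similarity file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df[[1]]
  storage.mode(S) <- "double"
  if (nrow(S) != ncol(S)) stop("similarity matrix is not square: ", path)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    stop("similarity matrix is not symmetric: ", path)
  }
  S
}

#' Write an association table as TSV
#'
#' Inverse of [read_associations()]; one `drug<TAB>disease<TAB>type` row per
#' positive entry of the two matrices.
#'
#' @param matrices An `association_matrices` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(matrices, path) {
  rows <- function(A, type) {
    idx <- which(A == 1L)
    if (!length(idx)) return(NULL)
    data.frame(drug = matrices$drugs[row(A)[idx]],
               disease = matrices$diseases[col(A)[idx]],
               type = type, stringsAsFactors = FALSE)
  }
  out <- rbind(rows(matrices$A_p, "therapeutic"),
               rows(matrices$A_n, "non_therapeutic"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
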