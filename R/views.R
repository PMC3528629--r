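#' Construct a similarity view
#'
#' A view bundles a named symmetric compound-by-compound similarity matrix
#' `S` (entries in \[0, 1\], unit diagonal) with its normalized stochastic
#' form `P` used by the fusion objective (see [standardize_normalize()]).
#'
#' @param name View label, e.g. `"bioactivity"` or `"structure"`.
#' @param S Symmetric numeric matrix with entries in \[0, 1\] and compound
#'   ids as dimnames.
#' @return Object of class `similarity_view`: list with `name`, `S`, `P`
#'   and compound count `n`.
#' @export
similarity_view <- function(name, S) {
  stopifnot(is.character(name), length(name) == 1, is.matrix(S))
  if (is.null(rownames(S))) abort("similarity matrix needs compound-id dimnames")
  if (nrow(S) != ncol(S)) abort("similarity matrix must be square")
  if (max(abs(S - t(S))) > 1e-12) abort("similarity matrix must be symmetric")
  if (min(S) < -1e-9 || max(S) > 1 + 1e-9) {
    abort("similarity entries must lie in [0, 1]")
  }
  structure(
    list(name = name, S = S, P = standardize_normalize(S), n = nrow(S)),
    class = "similarity_view"
  )
}

#' @export
print.similarity_view <- function(x, ...) {
  cat(sprintf("<similarity_view '%s'> %d compounds\n", x$name, x$n))
  invisible(x)
}

#' Bioactivity-profile similarity (clipped Pearson correlation)
#'
#' Pairwise similarity between compounds is the Pearson correlation
#' coefficient of their bioactivity profiles (e.g. log(GI50) across a cell
#' line panel), with negative correlations clipped to zero: weak negative
#' correlation carries no more information about molecular similarity than
#' noise. Missing values are handled pairwise-complete: features missing in
#' either compound are dropped for that pair; pairs left with fewer than
#' three complete features get similarity 0 with a warning.
#'
#' @param profiles A `compound_profiles` tibble ([read_profiles()]): column
#'   `compound_id` plus numeric feature columns (at least 3 features).
#' @param name View label (default `"bioactivity"`).
#' @return A [similarity_view()].
#' @export
#' @examples
#' pr <- tibble::tibble(compound_id = c("a", "b"),
#'                      f1 = c(1, 3), f2 = c(2, 2), f3 = c(3, 1))
#' pearson_similarity(pr)$S  # anticorrelated pair clips to 0
pearson_similarity <- function(profiles, name = "bioactivity") {
  stopifnot("compound_id" %in% names(profiles))
  ids <- profiles$compound_id
  if (length(ids) < 2) abort("need at least 2 compounds")
  x <- as.matrix(profiles[setdiff(names(profiles), "compound_id")])
  if (!is.numeric(x)) abort("feature columns must be numeric")
  if (ncol(x) < 3) abort("need at least 3 features for correlation")
  rownames(x) <- ids
  flat <- apply(x, 1, function(r) {
    v <- r[!is.na(r)]
    length(v) >= 2 && sd(v) == 0
  })
  if (any(flat)) {
    abort(paste0(
      "zero-variance profile(s), correlation undefined: ",
      paste(ids[flat], collapse = ", ")
    ))
  }
  r <- suppressWarnings(cor(t(x), use = "pairwise.complete.obs"))
  # pairs with too few complete features are uninformative, not an error
  n_complete <- tcrossprod(!is.na(x))
  few <- n_complete < 3 & !diag(TRUE, length(ids))
  if (any(few) || anyNA(r[!few])) {
    warn(sprintf(
      "%d compound pair(s) with <3 complete features or degenerate pairwise variance; similarity set to 0",
      sum((few | is.na(r)) & upper.tri(r))
    ))
  }
  r[few | is.na(r)] <- 0
  S <- pmax(r, 0)
  diag(S) <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- list(ids, ids)
  similarity_view(name, S)
}

#' Structural-fingerprint similarity (Tanimoto index)
#'
#' Pairwise similarity between binary structural fingerprints (e.g.
#' 1024-bit path-based fingerprints): `t = N_AB / (N_A + N_B - N_AB)` where
#' `N_A`, `N_B` count the set bits of each compound and `N_AB` the bits set
#' in both.
#'
#' @param fps A `compound_fingerprints` tibble ([read_fingerprints()]) or a
#'   0/1 matrix with compound-id rownames.
#' @param name View label (default `"structure"`).
#' @return A [similarity_view()].
#' @export
tanimoto_similarity <- function(fps, name = "structure") {
  bits <- if (is.matrix(fps)) fps else fingerprint_matrix(fps)
  if (nrow(bits) < 2) abort("need at least 2 compounds")
  if (!all(bits %in% c(0L, 1L))) abort("fingerprint entries must be 0/1")
  n_set <- rowSums(bits)
  if (any(n_set == 0)) {
    abort(paste0(
      "all-zero fingerprint(s): ",
      paste(rownames(bits)[n_set == 0], collapse = ", ")
    ))
  }
  common <- tcrossprod(bits)
  S <- common / (outer(n_set, n_set, `+`) - common)
  diag(S) <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(bits), rownames(bits))
  similarity_view(name, S)
}

#' Standardize and renormalize a similarity matrix onto the simplex
#'
#' Transforms a raw similarity matrix into the stochastic matrix consumed by
#' the cross-entropy fusion objective: entries are z-scored over all n^2
#' cells (diagonal included), shifted by the global minimum so the smallest
#' entry becomes 0 (cross-entropy factorization requires nonnegativity, and
#' the shift preserves the ordering and relative spacing that clipping would
#' destroy), then divided by the grand total so the matrix sums to 1. The
#' result is invariant to any positive affine rescaling of the input.
#'
#' @param S Symmetric finite numeric matrix with non-constant entries.
#' @return Symmetric nonnegative matrix summing to 1.
#' @export
standardize_normalize <- function(S) {
  stopifnot(is.matrix(S))
  if (!all(is.finite(S))) abort("similarity matrix must be finite")
  if (max(abs(S - t(S))) > 1e-12) abort("similarity matrix must be symmetric")
  s <- sd(as.vector(S))
  if (s == 0) abort("constant similarity matrix: standardization undefined (sd = 0)")
  z <- (S - mean(S)) / s
  z <- z - min(z)
  P <- z / sum(z)
  (P + t(P)) / 2
}
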