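#' Similarity-to-distance transform
#'
#' `d = 1 - s` entrywise, with the diagonal forced to exactly zero. This is
#' the transform applied to the fused similarity before hierarchical
#' clustering.
#'
#' @param S Symmetric similarity matrix with entries in \[0, 1\]
#'   (tolerance 1e-9).
#' @return Distance matrix of the same shape.
#' @export
to_distance <- function(S) {
  stopifnot(is.matrix(S))
  if (max(abs(S - t(S))) > 1e-9) abort("similarity matrix must be symmetric")
  if (min(S) < -1e-9 || max(S) > 1 + 1e-9) {
    abort("similarity entries must lie in [0, 1] to admit d = 1 - s")
  }
  d <- 1 - pmin(pmax(S, 0), 1)
  diag(d) <- 0
  d
}

#' Hierarchical clustering of compounds
#'
#' Agglomerative clustering of a compound distance matrix. Average linkage
#' is the default: on similarity-derived distances it is the common choice
#' in compound clustering and yields monotone merge heights.
#'
#' @param d Symmetric distance matrix with zero diagonal and compound-id
#'   dimnames.
#' @param linkage One of `"average"`, `"complete"`, `"single"`.
#' @return An object of class `compound_hclust` (inherits from `hclust`).
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(d))
  if (anyNA(d)) abort("distance matrix contains NA")
  if (max(abs(d - t(d))) > 1e-9) abort("distance matrix must be symmetric")
  if (is.null(rownames(d))) abort("distance matrix needs compound-id dimnames")
  tree <- hclust(as.dist(d), method = linkage)
  class(tree) <- c("compound_hclust", class(tree))
  tree
}

#' Cut a clustering tree into k classes
#'
#' Labels are canonical: class 1 is the class of the first compound in input
#' order, class 2 the next new class encountered, and so on, so that label
#' values are reproducible and comparable across cuts.
#'
#' @param tree A `compound_hclust` / `hclust` object.
#' @param k Number of classes, `1 <= k <= n`.
#' @return Tibble of class `cluster_assignment` with columns `compound_id`
#'   and `cluster` (integer in `1..k`); attribute `k`.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1 || k > n) abort(sprintf("k = %d out of range [1, %d]", k, n))
  raw <- cutree(tree, k = k)
  labels <- canonical_labels(raw)
  out <- tibble::tibble(compound_id = tree$labels, cluster = labels)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("cluster_assignment", class(out))
  out
}

# relabel so classes are numbered by first appearance
canonical_labels <- function(x) {
  as.integer(match(x, unique(x)))
}

#' Build a cluster assignment from ids and labels
#'
#' @param compound_ids Character vector of compound ids.
#' @param labels Integer labels in `1..k`.
#' @param k Number of classes; defaults to `max(labels)`.
#' @return A `cluster_assignment` tibble.
#' @export
cluster_assignment <- function(compound_ids, labels, k = max(labels)) {
  stopifnot(length(compound_ids) == length(labels))
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > k)) abort("labels must lie in 1..k")
  out <- tibble::tibble(compound_id = as.character(compound_ids),
                        cluster = labels)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Export a clustering tree to Newick
#'
#' Branch lengths are differences of merge heights, so external tree viewers
#' reproduce the dendrogram geometry.
#'
#' @param tree A `compound_hclust` / `hclust` object.
#' @param path Output file path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a Newick tree back as a phylogeny
#'
#' @param path Newick file path.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
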