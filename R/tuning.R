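#' Leave-one-out index subsets
#'
#' @param compound_ids Character vector of n >= 3 compound ids.
#' @return List of n character vectors; the r-th subset omits the r-th
#'   compound (id order preserved).
#' @export
loo_subsets <- function(compound_ids) {
  n <- length(compound_ids)
  if (n < 3) abort("need at least 3 compounds for leave-one-out subsets")
  lapply(seq_len(n), function(r) compound_ids[-r])
}

#' Permutation-matched disagreement between two clusterings
#'
#' Counts, over the compounds present in both assignments, how many receive
#' different class labels under the best possible matching of the two label
#' alphabets (optimal assignment on the k-by-k confusion matrix). Cluster
#' labels produced by tree cutting are arbitrary, so raw label comparison
#' would measure label encoding, not clustering instability.
#'
#' @param a,b `cluster_assignment` tibbles (or data frames with
#'   `compound_id`, `cluster`) cut at the same k.
#' @param k Number of classes; taken from the `k` attributes when present
#'   (they must agree).
#' @return Nonnegative integer: the minimal number of disagreeing compounds.
#' @export
#' @examples
#' a <- cluster_assignment(c("c1", "c2", "c3", "c4"), c(1, 1, 2, 2))
#' b <- cluster_assignment(c("c1", "c2", "c3", "c4"), c(2, 2, 1, 1))
#' disagreement(a, b)  # 0: same partition, relabeled
disagreement <- function(a, b, k = NULL) {
  ka <- attr(a, "k") %||% max(a$cluster)
  kb <- attr(b, "k") %||% max(b$cluster)
  if (is.null(k)) {
    if (ka != kb) abort(sprintf("assignments cut at different k: %d vs %d", ka, kb))
    k <- ka
  }
  common <- intersect(a$compound_id, b$compound_id)
  if (length(common) == 0) return(0L)
  la <- a$cluster[match(common, a$compound_id)]
  lb <- b$cluster[match(common, b$compound_id)]
  conf <- matrix(0L, k, k)
  for (i in seq_along(common)) {
    conf[la[i], lb[i]] <- conf[la[i], lb[i]] + 1L
  }
  matched <- sum(conf[cbind(seq_len(k), as.integer(clue::solve_LSAP(conf, maximum = TRUE)))])
  length(common) - matched
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Average mean disagreement over leave-one-out clusterings
#'
#' For each k in `k_range`, every subset tree is cut into k classes and the
#' permutation-matched [disagreement()] is computed for every unordered pair
#' of subsets on their common compounds; the pairwise mean is then averaged
#' (unweighted) over k. Lower values indicate a more stable clustering.
#'
#' @param trees List of `compound_hclust` trees, one per leave-one-out
#'   subset.
#' @param k_range Inclusive integer interval `c(k_min, k_max)`.
#' @return Single nonnegative number.
#' @export
amd <- function(trees, k_range = c(2, 15)) {
  if (length(trees) < 2) abort("need at least 2 subset clusterings")
  sizes <- vapply(trees, function(t) length(t$labels), integer(1))
  ks <- seq.int(k_range[1], k_range[2])
  if (max(ks) > min(sizes)) {
    abort(sprintf("k_range max %d exceeds smallest subset size %d",
                  max(ks), min(sizes)))
  }
  per_k <- vapply(ks, function(k) {
    cuts <- lapply(trees, cut_tree, k = k)
    pairs <- utils::combn(length(cuts), 2)
    mean(apply(pairs, 2, function(p) disagreement(cuts[[p[1]]], cuts[[p[2]]], k = k)))
  }, numeric(1))
  mean(per_k)
}

#' Dunn's cluster validity index
#'
#' Ratio of the minimal between-cluster distance to the maximal
#' within-cluster diameter; higher is better. Singleton clusters contribute
#' diameter 0. If every cluster is a singleton the index is `Inf` (with a
#' warning); callers average it out.
#'
#' @param d Symmetric distance matrix with zero diagonal and compound-id
#'   dimnames.
#' @param assignment A `cluster_assignment` over the compounds of `d`.
#' @return Nonnegative number (possibly `Inf`).
#' @export
dunn_index <- function(d, assignment) {
  stopifnot(is.matrix(d))
  ids <- rownames(d)
  labels <- assignment$cluster[match(ids, assignment$compound_id)]
  if (anyNA(labels)) abort("assignment does not cover all compounds in d")
  k <- length(unique(labels))
  if (k < 2) abort("Dunn's index requires at least 2 clusters")
  inter <- Inf
  diam <- 0
  for (a in seq_len(k - 1)) {
    ia <- which(labels == unique(labels)[a])
    for (b in seq.int(a + 1, k)) {
      ib <- which(labels == unique(labels)[b])
      inter <- min(inter, min(d[ia, ib, drop = FALSE]))
    }
  }
  for (a in unique(labels)) {
    ia <- which(labels == a)
    if (length(ia) > 1) {
      diam <- max(diam, max(d[ia, ia]))
    }
  }
  if (diam == 0) {
    warn("all clusters are singletons (or zero-diameter); Dunn's index is Inf")
    return(Inf)
  }
  inter / diam
}

#' Tune the sparseness parameter by leave-one-out stability
#'
#' For each candidate eta, fusion and hierarchical clustering are repeated on
#' every leave-one-out subset of the compounds (per-view similarities are
#' subset and renormalized; subset r uses seed `config$seed + r` so replicates
#' are independent yet reproducible), and two summaries are computed across
#' the class-count range:
#' \itemize{
#'   \item AMD — average mean disagreement ([amd()]), lower = more stable;
#'   \item ADI — average Dunn's index: for each k the subset-averaged
#'     [dunn_index()] (non-finite values excluded), reported as its mean and
#'     variance over k.
#' }
#' The recommended eta minimizes AMD, with the higher ADI mean breaking ties.
#'
#' @param views List of [similarity_view()] objects (same compounds, same
#'   order).
#' @param eta_grid Strictly increasing vector of candidate eta values. The
#'   reference grid spans 0.001 to 1000.
#' @param k_range Inclusive class-count interval, default `c(2, 15)`.
#' @param config A [fusion_config()]; its `eta` field is ignored (the grid
#'   supplies it).
#' @param linkage Linkage passed to [hierarchical_cluster()].
#' @return Object of class `stability_report`: list with `report` (tibble:
#'   `eta`, `amd`, `adi_mean`, `adi_var`), `recommendation` (the selected
#'   eta), `k_range`, `n_subsets`, `linkage`.
#' @export
tune_eta <- function(views, eta_grid, k_range = c(2, 15), config = NULL,
                     linkage = "average") {
  if (length(eta_grid) == 0) abort("eta grid is empty")
  if (is.unsorted(eta_grid, strictly = TRUE)) {
    abort("eta grid must be strictly increasing")
  }
  if (is.null(config)) config <- fusion_config(eta = eta_grid[1])
  ids <- rownames(views[[1]]$S)
  subsets <- loo_subsets(ids)
  ks <- seq.int(k_range[1], k_range[2])
  if (max(ks) > length(ids) - 1) {
    abort(sprintf("k_range max %d exceeds subset size %d", max(ks), length(ids) - 1))
  }

  rows <- lapply(eta_grid, function(eta) {
    cfg <- config
    cfg$eta <- eta
    fits <- lapply(seq_along(subsets), function(r) {
      keep <- subsets[[r]]
      sub_views <- lapply(views, function(v) {
        similarity_view(v$name, v$S[keep, keep, drop = FALSE])
      })
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + r
      res <- fuse(sub_views, cfg_r)
      d <- to_distance(res$fused_S)
      list(tree = hierarchical_cluster(d, linkage = linkage), d = d)
    })
    trees <- lapply(fits, `[[`, "tree")
    adi_per_k <- vapply(ks, function(k) {
      vals <- vapply(fits, function(f) {
        suppressWarnings(dunn_index(f$d, cut_tree(f$tree, k)))
      }, numeric(1))
      vals <- vals[is.finite(vals)]
      if (length(vals) == 0) NA_real_ else mean(vals)
    }, numeric(1))
    tibble::tibble(
      eta = eta,
      amd = amd(trees, k_range = k_range),
      adi_mean = mean(adi_per_k, na.rm = TRUE),
      adi_var = var(adi_per_k, na.rm = TRUE)
    )
  })
  report <- dplyr::bind_rows(rows)
  best <- dplyr::arrange(report, .data$amd, dplyr::desc(.data$adi_mean))
  structure(
    list(report = report, recommendation = best$eta[1],
         k_range = as.integer(k_range), n_subsets = length(subsets),
         linkage = linkage),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d eta values, %d leave-one-out subsets, k in [%d, %d]\n",
              nrow(x$report), x$n_subsets, x$k_range[1], x$k_range[2]))
  print(x$report)
  cat(sprintf("recommended eta: %g\n", x$recommendation))
  invisible(x)
}
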