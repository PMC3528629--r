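#' One-mode projection of a compound-target network
#'
#' Removes the target nodes from a compound-target bipartite network and
#' links two compounds whenever they share at least one protein target. The
#' number of shared targets is kept as edge metadata (the validity statistic
#' itself uses unweighted degree). Compounds without any shared target are
#' retained as degree-zero nodes.
#'
#' @param net A [bipartite_network()].
#' @return Object of class `projection_graph`: list with `compound_ids` and
#'   an `edges` tibble (`from`, `to`, `shared_targets`).
#' @export
project_common_target <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  ids <- net$compound_ids
  if (nrow(net$edges) == 0) {
    return(structure(
      list(compound_ids = ids,
           edges = tibble::tibble(from = character(), to = character(),
                                  shared_targets = integer())),
      class = "projection_graph"
    ))
  }
  inc <- table(factor(net$edges$compound_id, levels = ids),
               factor(net$edges$target_id, levels = net$target_ids))
  inc <- matrix(as.integer(inc > 0), nrow = length(ids),
                dimnames = list(ids, net$target_ids))
  shared <- tcrossprod(inc)
  idx <- which(upper.tri(shared) & shared > 0, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = ids[idx[, 1]],
    to = ids[idx[, 2]],
    shared_targets = as.integer(shared[idx])
  )
  structure(list(compound_ids = ids, edges = edges),
            class = "projection_graph")
}

#' @export
print.projection_graph <- function(x, ...) {
  cat(sprintf("<projection_graph> %d compounds, %d common-target edges\n",
              length(x$compound_ids), nrow(x$edges)))
  invisible(x)
}

#' Convert a projection graph to igraph
#'
#' @param g A `projection_graph`.
#' @return An undirected `igraph` graph with a `shared_targets` edge
#'   attribute.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "projection_graph"))
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = g$compound_ids)
}

#' Average within-cluster degree in the common-target graph
#'
#' The cluster validity statistic: `D = (1/n) * sum(D_j)` over the members
#' of the cluster, where `D_j` is the degree of compound j in the subgraph
#' induced by the cluster (only edges between members count — the statistic
#' measures target sharing within the class). A high value means the
#' cluster's members share many protein targets.
#'
#' @param g A `projection_graph`.
#' @param members Character vector of compound ids (nonempty, all present
#'   in the graph).
#' @return Nonnegative number.
#' @export
average_degree <- function(g, members) {
  stopifnot(inherits(g, "projection_graph"))
  if (length(members) == 0) abort("members must be nonempty")
  unknown <- setdiff(members, g$compound_ids)
  if (length(unknown) > 0) {
    abort(paste0("unknown compound id(s): ", paste(unknown, collapse = ", ")))
  }
  within <- g$edges$from %in% members & g$edges$to %in% members
  2 * sum(within) / length(members)
}

#' Common-target degree versus class count
#'
#' Cuts one or more clustering trees into each k of a range and reports, per
#' k, the unweighted mean over classes of the within-class
#' [average_degree()]. Comparing the curve of the fused-similarity tree with
#' the single-view trees shows whether fusion groups compounds that share
#' more protein targets.
#'
#' @param trees A single `compound_hclust` or a named list of them (one per
#'   similarity source).
#' @param g A `projection_graph` whose compounds include all tree leaves.
#' @param k_range Inclusive class-count interval, default `c(2, 15)`.
#' @return Tibble of class `target_curve`: columns `source`, `k`,
#'   `mean_degree`.
#' @export
common_target_curve <- function(trees, g, k_range = c(2, 15)) {
  if (inherits(trees, "hclust")) trees <- list(fused = trees)
  if (is.null(names(trees)) || any(!nzchar(names(trees)))) {
    names(trees) <- paste0("tree", seq_along(trees))
  }
  ks <- seq.int(k_range[1], k_range[2])
  rows <- purrr::imap(trees, function(tree, src) {
    missing <- setdiff(tree$labels, g$compound_ids)
    if (length(missing) > 0) {
      abort(paste0("tree leaves absent from graph: ", paste(missing, collapse = ", ")))
    }
    if (max(ks) > length(tree$labels)) {
      abort(sprintf("k_range max %d exceeds leaf count %d", max(ks), length(tree$labels)))
    }
    purrr::map(ks, function(k) {
      cut <- cut_tree(tree, k)
      degs <- vapply(split(cut$compound_id, cut$cluster), function(m) {
        average_degree(g, m)
      }, numeric(1))
      tibble::tibble(source = src, k = k, mean_degree = mean(degs))
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("target_curve", class(out))
  out
}
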