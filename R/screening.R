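#' Ligand-based similarity search
#'
#' Ranks all library compounds by similarity to a query compound under one
#' similarity source (a single view or the fused matrix). The query itself
#' is excluded; ties are broken by compound id so rankings are stable.
#'
#' @param S Labeled similarity matrix.
#' @param query Compound id present in `S`.
#' @param top Number of entries to keep (default all).
#' @param source Label recorded in the output (e.g. `"fused"`).
#' @return Tibble of class `ranked_list`: columns `rank`, `compound_id`,
#'   `similarity`; attributes `query` and `source`.
#' @export
similarity_search <- function(S, query, top = Inf, source = "fused") {
  stopifnot(is.matrix(S))
  ids <- rownames(S)
  if (!query %in% ids) abort(sprintf("unknown query compound '%s'", query))
  sims <- S[query, setdiff(ids, query)]
  ord <- order(-sims, names(sims))
  sims <- sims[ord]
  m <- min(length(sims), top)
  out <- tibble::tibble(
    rank = seq_len(length(sims)),
    compound_id = names(sims),
    similarity = unname(sims)
  )[seq_len(m), ]
  attr(out, "query") <- query
  attr(out, "source") <- source
  class(out) <- c("ranked_list", class(out))
  out
}

#' Compare rankings across similarity sources
#'
#' Juxtaposes, per library compound, its rank and similarity under each
#' source (typically the fused similarity against each single view).
#' Compounds with fused similarity above 0.5 to the query are flagged (a
#' reporting threshold, not a filter). If a compound-target network is
#' supplied, a column marks compounds sharing at least one protein target
#' with the query.
#'
#' @param lists Named list of full-length `ranked_list` tibbles for the same
#'   query over the same compound universe ([similarity_search()] with
#'   `top = Inf`). A list named `"fused"` anchors the row order and the
#'   0.5 flag; otherwise the first list does.
#' @param annotations Optional [bipartite_network()] of compound-target
#'   interactions.
#' @param threshold Similarity flag threshold, default 0.5.
#' @return Tibble with one row per compound: `compound_id`,
#'   `rank_<source>` / `sim_<source>` pairs, `above_threshold`, and (with
#'   annotations) `shares_target`.
#' @export
compare_rankings <- function(lists, annotations = NULL, threshold = 0.5) {
  stopifnot(is.list(lists), length(lists) >= 1)
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    abort("lists must be named by source")
  }
  queries <- vapply(lists, function(l) attr(l, "query"), character(1))
  if (length(unique(queries)) != 1) {
    abort("all ranked lists must share the same query")
  }
  universes <- lapply(lists, function(l) sort(l$compound_id))
  if (!all(vapply(universes[-1], identical, logical(1), universes[[1]]))) {
    abort("ranked lists cover different compound universes")
  }
  anchor <- if ("fused" %in% names(lists)) "fused" else names(lists)[1]
  out <- tibble::tibble(compound_id = lists[[anchor]]$compound_id)
  for (src in names(lists)) {
    l <- lists[[src]]
    i <- match(out$compound_id, l$compound_id)
    out[[paste0("rank_", src)]] <- l$rank[i]
    out[[paste0("sim_", src)]] <- l$similarity[i]
  }
  out$above_threshold <- out[[paste0("sim_", anchor)]] > threshold
  if (!is.null(annotations)) {
    stopifnot(inherits(annotations, "bipartite_network"))
    q_targets <- annotations$edges$target_id[
      annotations$edges$compound_id == queries[1]
    ]
    by_compound <- split(annotations$edges$target_id, annotations$edges$compound_id)
    out$shares_target <- vapply(out$compound_id, function(cid) {
      length(intersect(by_compound[[cid]], q_targets)) > 0
    }, logical(1), USE.NAMES = FALSE)
  }
  attr(out, "query") <- queries[1]
  out
}
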