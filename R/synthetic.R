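#' Define a planted-cluster scenario
#'
#' A scenario fixes everything the multi-view generators need: compound
#' count, planted cluster structure, per-view noise, dimensions, target
#' annotation parameters and the seed. The defaults mirror the scale of a
#' curated NCI-60-style panel: 37 compounds in 6 clusters, 60-feature
#' bioactivity profiles, 1024-bit structural fingerprints, moderate noise
#' (0.2) in both views.
#'
#' Noise semantics (both in \[0, 1\]):
#' \itemize{
#'   \item profile view — compound profile = cluster center (unit-variance
#'     Gaussian) + Gaussian noise with sd `2 * view_noise`, so the expected
#'     within-cluster Pearson correlation is `1 / (1 + 4 * view_noise^2)`;
#'   \item fingerprint view — compound fingerprint = cluster template with
#'     each bit flipped with probability `view_noise / 2`, so `view_noise = 1`
#'     yields fully random bits (no cluster signal).
#' }
#'
#' @param n Number of compounds.
#' @param k_true Planted cluster count (`2 <= k_true <= n`).
#' @param view_noise Length-2 numeric in \[0, 1\]: noise of (profiles,
#'   fingerprints).
#' @param profile_dim Number of profile features (>= 3).
#' @param fp_bits Fingerprint length (>= 8).
#' @param targets_per_cluster Dedicated protein targets per cluster, each
#'   hit by every cluster member.
#' @param annotation_noise Probability that a compound additionally hits a
#'   random foreign cluster's target.
#' @param profile_offset_sd Standard deviation of an optional per-compound
#'   additive offset applied to the whole profile (emulates magnitude shifts
#'   that leave the profile shape, hence the correlation, unchanged).
#' @param template_density Expected fraction of set bits in fingerprint
#'   templates.
#' @param seed Integer seed; all generators derive their streams from it.
#' @return List of class `planted_scenario`, including the planted `labels`
#'   tibble (`compound_id`, `cluster`).
#' @export
planted_scenario <- function(n = 37, k_true = 6, view_noise = c(0.2, 0.2),
                             profile_dim = 60, fp_bits = 1024,
                             targets_per_cluster = 3, annotation_noise = 0.05,
                             profile_offset_sd = 0, template_density = 0.3,
                             seed = 1) {
  stopifnot(n >= k_true, k_true >= 2)
  view_noise <- rep_len(view_noise, 2)
  if (any(view_noise < 0 | view_noise > 1)) abort("view_noise must lie in [0, 1]")
  if (profile_dim < 3) abort("profile_dim must be at least 3")
  if (fp_bits < 8) abort("fp_bits must be at least 8")
  stopifnot(annotation_noise >= 0, annotation_noise <= 1,
            targets_per_cluster >= 1, template_density > 0, template_density < 1)
  compound_ids <- sprintf("C%02d", seq_len(n))
  # balanced assignment, contiguous blocks: deterministic given (n, k_true)
  labels <- sort(rep_len(seq_len(k_true), n))
  structure(
    list(n = as.integer(n), k_true = as.integer(k_true),
         compound_ids = compound_ids,
         labels = cluster_assignment(compound_ids, labels, k = k_true),
         view_noise = view_noise, profile_dim = as.integer(profile_dim),
         fp_bits = as.integer(fp_bits),
         targets_per_cluster = as.integer(targets_per_cluster),
         annotation_noise = annotation_noise,
         profile_offset_sd = profile_offset_sd,
         template_density = template_density,
         seed = as.integer(seed)),
    class = "planted_scenario"
  )
}

#' @export
print.planted_scenario <- function(x, ...) {
  cat(sprintf(
    "<planted_scenario> n = %d, k_true = %d, noise = (%.2f, %.2f), seed = %d\n",
    x$n, x$k_true, x$view_noise[1], x$view_noise[2], x$seed
  ))
  invisible(x)
}

#' Generate planted bioactivity profiles
#'
#' Each planted cluster receives a random unit-variance Gaussian center
#' profile; each compound is its cluster center plus Gaussian noise with
#' sd `2 * view_noise[1]`, plus an optional per-compound constant offset
#' (`profile_offset_sd`) that shifts the magnitude without changing the
#' profile shape — so Pearson similarity is unaffected while Euclidean
#' distance grows.
#'
#' @param sc A [planted_scenario()].
#' @return A `compound_profiles` tibble.
#' @export
generate_profiles <- function(sc) {
  stopifnot(inherits(sc, "planted_scenario"))
  withr::with_seed(sc$seed + 11L, {
    centers <- matrix(rnorm(sc$k_true * sc$profile_dim), sc$k_true)
    noise <- matrix(rnorm(sc$n * sc$profile_dim, sd = 2 * sc$view_noise[1]),
                    sc$n)
    offsets <- if (sc$profile_offset_sd > 0) {
      rnorm(sc$n, sd = sc$profile_offset_sd)
    } else {
      rep(0, sc$n)
    }
    x <- centers[sc$labels$cluster, , drop = FALSE] + noise + offsets
    colnames(x) <- sprintf("F%03d", seq_len(sc$profile_dim))
    out <- dplyr::bind_cols(
      tibble::tibble(compound_id = sc$compound_ids),
      tibble::as_tibble(x)
    )
    class(out) <- c("compound_profiles", class(out))
    out
  })
}

#' Generate planted structural fingerprints
#'
#' Each cluster receives a Bernoulli(`template_density`) template bit
#' pattern; each compound copies its template with every bit flipped
#' independently with probability `view_noise[2] / 2`. Every compound is
#' guaranteed at least one set bit (a flat zero fingerprint would make the
#' Tanimoto index undefined).
#'
#' @param sc A [planted_scenario()].
#' @return A `compound_fingerprints` tibble.
#' @export
generate_fingerprints <- function(sc) {
  stopifnot(inherits(sc, "planted_scenario"))
  withr::with_seed(sc$seed + 22L, {
    templates <- matrix(
      rbinom(sc$k_true * sc$fp_bits, 1, sc$template_density),
      sc$k_true
    )
    flips <- matrix(
      rbinom(sc$n * sc$fp_bits, 1, sc$view_noise[2] / 2),
      sc$n
    )
    bits <- abs(templates[sc$labels$cluster, , drop = FALSE] - flips)
    zero <- rowSums(bits) == 0
    if (any(zero)) {
      bits[cbind(which(zero), sample.int(sc$fp_bits, sum(zero), replace = TRUE))] <- 1L
    }
    out <- tibble::tibble(
      compound_id = sc$compound_ids,
      fingerprint = apply(bits, 1, paste0, collapse = "")
    )
    attr(out, "bit_length") <- sc$fp_bits
    class(out) <- c("compound_fingerprints", class(out))
    out
  })
}

#' Generate planted compound-target interactions
#'
#' Every cluster owns `targets_per_cluster` dedicated protein targets hit by
#' all its members; independently, each compound hits one randomly chosen
#' foreign cluster's target with probability `annotation_noise`. With zero
#' noise the one-mode common-target projection is exactly the disjoint union
#' of cluster cliques.
#'
#' @param sc A [planted_scenario()].
#' @return A [bipartite_network()].
#' @export
generate_targets <- function(sc) {
  stopifnot(inherits(sc, "planted_scenario"))
  withr::with_seed(sc$seed + 33L, {
    target_ids <- as.vector(outer(
      seq_len(sc$targets_per_cluster), seq_len(sc$k_true),
      function(t, c) sprintf("T%d_%d", c, t)
    ))
    target_cluster <- rep(seq_len(sc$k_true), each = sc$targets_per_cluster)
    own <- dplyr::bind_rows(lapply(seq_len(sc$n), function(i) {
      cl <- sc$labels$cluster[i]
      tibble::tibble(compound_id = sc$compound_ids[i],
                     target_id = target_ids[target_cluster == cl])
    }))
    extra <- lapply(seq_len(sc$n), function(i) {
      if (runif(1) < sc$annotation_noise && sc$k_true > 1) {
        cl <- sc$labels$cluster[i]
        foreign <- target_ids[target_cluster != cl]
        tibble::tibble(compound_id = sc$compound_ids[i],
                       target_id = foreign[sample.int(length(foreign), 1)])
      } else {
        NULL
      }
    })
    edges <- dplyr::bind_rows(c(list(own), extra))
    bipartite_network(edges, compound_ids = sc$compound_ids,
                      target_ids = target_ids)
  })
}

#' Generate both similarity views of a scenario
#'
#' Convenience wrapper: profiles and fingerprints are generated and turned
#' into their similarity views ([pearson_similarity()],
#' [tanimoto_similarity()]).
#'
#' @param sc A [planted_scenario()].
#' @return Named list of two [similarity_view()] objects
#'   (`bioactivity`, `structure`).
#' @export
generate_views <- function(sc) {
  list(
    bioactivity = pearson_similarity(generate_profiles(sc)),
    structure = tanimoto_similarity(generate_fingerprints(sc))
  )
}
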