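#' Fusion run configuration
#'
#' @param eta Positive sparseness parameter: coefficient of the weight-entropy
#'   penalty. Small values concentrate all weight on the single view with the
#'   lowest cross-entropy; large values spread the weight evenly.
#' @param k Factorization rank (number of latent clusters), default 6.
#' @param max_outer Cap on outer alternation iterations.
#' @param max_em Cap on inner multiplicative EM iterations per factorization.
#' @param tol_objective Relative tolerance on the outer objective.
#' @param tol_alpha Absolute tolerance on the weight update.
#' @param seed Integer seed for the factor initialization.
#' @param n_restarts Number of random restarts; the run with the lowest final
#'   objective is kept (the factorization is non-convex).
#' @return List of class `fusion_config`.
#' @export
fusion_config <- function(eta, k = 6, max_outer = 100, max_em = 1000,
                          tol_objective = 1e-8, tol_alpha = 1e-6,
                          seed = 1, n_restarts = 5) {
  if (!is.numeric(eta) || length(eta) != 1 || eta <= 0) {
    abort("eta must be a single positive number")
  }
  stopifnot(k >= 1, max_outer >= 1, max_em >= 1, n_restarts >= 1)
  structure(
    list(eta = eta, k = as.integer(k), max_outer = as.integer(max_outer),
         max_em = as.integer(max_em), tol_objective = tol_objective,
         tol_alpha = tol_alpha, seed = as.integer(seed),
         n_restarts = as.integer(n_restarts)),
    class = "fusion_config"
  )
}

#' Cross-entropy of two stochastic matrices
#'
#' `C(P, Q) = -sum(P * log(Q))` over all cells, with `Q` floored at 1e-12
#' inside the logarithm. By Gibbs' inequality this is bounded below by the
#' entropy of `P`.
#'
#' @param P Nonnegative matrix (or vector) summing to 1.
#' @param Q Nonnegative matrix (or vector) of the same shape.
#' @return Nonnegative scalar (natural log).
#' @export
#' @examples
#' P <- matrix(0.25, 2, 2)
#' cross_entropy(P, P)  # log(4)
cross_entropy <- function(P, Q) {
  if (length(P) != length(Q)) abort("P and Q must have the same shape")
  if (!is.null(dim(P)) && !identical(dim(P), dim(Q))) {
    abort("P and Q must have the same shape")
  }
  -sum(P * log(pmax(Q, .SIMFUSE_EPS)))
}

#' Entropy of a weight vector on the simplex
#'
#' `H(alpha) = -sum(alpha * log(alpha))` with `0 log 0 := 0`.
#'
#' @param alpha Nonnegative vector summing to 1 (checked to 1e-9).
#' @return Nonnegative scalar (natural log).
#' @export
weight_entropy <- function(alpha) {
  if (any(alpha < -1e-12) || abs(sum(alpha) - 1) > 1e-9) {
    abort("alpha must be a probability vector (nonnegative, summing to 1)")
  }
  pos <- alpha[alpha > 0]
  -sum(pos * log(pos))
}

#' Cross-entropy nonnegative matrix factorization of a stochastic matrix
#'
#' Approximates a nonnegative matrix `P_bar` summing to 1 by the product
#' `V %*% t(H)` of two nonnegative n-by-k factors, minimizing the
#' cross-entropy `C(P_bar, VH')` by multiplicative EM-type updates (the
#' standard KL-divergence updates), renormalizing `VH'` onto the simplex
#' after every sweep. The objective is non-increasing across iterations.
#'
#' @param P_bar Nonnegative matrix summing to 1 (within 1e-9).
#' @param k Factorization rank, `1 <= k <= n`.
#' @param seed Seed for the uniform random initialization (ignored when
#'   warm-start factors are supplied).
#' @param max_em Iteration cap.
#' @param tol Relative-change stopping tolerance on the objective.
#' @param init Optional list with warm-start factors `V` and `H`.
#' @return List of class `factorization_model`: `V`, `H`, `k`, `Q`
#'   (the simplex-normalized product), `objective` (final cross-entropy),
#'   `trace` (per-iteration objective), `iterations`, `converged`.
#' @export
fit_factorization <- function(P_bar, k, seed = 1, max_em = 1000,
                              tol = 1e-8, init = NULL) {
  stopifnot(is.matrix(P_bar))
  n <- nrow(P_bar)
  m <- ncol(P_bar)
  if (k > min(n, m)) abort(sprintf("rank k = %d exceeds matrix dimension %d", k, min(n, m)))
  if (k < 1) abort("rank k must be at least 1")
  if (min(P_bar) < -1e-12) abort("P_bar must be nonnegative")
  if (abs(sum(P_bar) - 1) > 1e-9) abort("P_bar must sum to 1")

  if (is.null(init)) {
    fac <- withr::with_seed(seed, {
      list(V = matrix(runif(n * k), n, k), H = matrix(runif(m * k), m, k))
    })
  } else {
    fac <- init
    stopifnot(identical(dim(fac$V), c(n, as.integer(k))),
              identical(dim(fac$H), c(m, as.integer(k))))
  }
  V <- pmax(fac$V, .SIMFUSE_EPS)
  H <- pmax(fac$H, .SIMFUSE_EPS)
  sc <- sqrt(sum(V %*% t(H)))
  V <- V / sc
  H <- H / sc

  obj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_em)) {
    Q <- pmax(V %*% t(H), .SIMFUSE_EPS)
    R <- P_bar / Q
    V <- V * (R %*% H) / rep(pmax(colSums(H), .SIMFUSE_EPS), each = n)
    Q <- pmax(V %*% t(H), .SIMFUSE_EPS)
    R <- P_bar / Q
    H <- H * (t(R) %*% V) / rep(pmax(colSums(V), .SIMFUSE_EPS), each = m)
    if (anyNA(V) || anyNA(H)) {
      abort(sprintf("NaN encountered in multiplicative update at iteration %d", it))
    }
    sc <- sqrt(sum(V %*% t(H)))
    V <- V / sc
    H <- H / sc
    obj[it] <- cross_entropy(P_bar, V %*% t(H))
    if (it > 1) {
      rel <- abs(obj[it - 1] - obj[it]) / max(abs(obj[it - 1]), .SIMFUSE_EPS)
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
  }
  structure(
    list(V = V, H = H, k = as.integer(k), Q = V %*% t(H),
         objective = obj[length(obj)], trace = obj,
         iterations = length(obj), converged = converged),
    class = "factorization_model"
  )
}

#' Entropy-regularized optimal view weights
#'
#' Exact minimizer of `sum(alpha * ce) - eta * H(alpha)` over the probability
#' simplex: the Gibbs distribution `alpha_l` proportional to
#' `exp(-ce_l / eta)`. As `eta -> 0` all weight concentrates on the view with
#' the smallest cross-entropy; as `eta -> Inf` the weights become uniform.
#'
#' @param ce Finite vector of per-view cross-entropies.
#' @param eta Positive sparseness parameter.
#' @return List of class `fusion_weights`: `alpha` (named like `ce`),
#'   `cross_entropy`, `eta`, `entropy` and `objective`.
#' @export
#' @examples
#' optimize_weights(c(bio = 1, struct = 2), eta = 1)$alpha
optimize_weights <- function(ce, eta) {
  if (!is.numeric(eta) || length(eta) != 1 || eta <= 0) {
    abort("eta must be a single positive number")
  }
  if (!all(is.finite(ce))) abort("cross-entropies must be finite")
  w <- exp(-(ce - min(ce)) / eta)
  alpha <- w / sum(w)
  structure(
    list(alpha = alpha, cross_entropy = ce, eta = eta,
         entropy = weight_entropy(alpha),
         objective = sum(alpha * ce) - eta * weight_entropy(alpha)),
    class = "fusion_weights"
  )
}

#' Fuse similarity views by alternating minimization
#'
#' The central algorithm: given L similarity views of the same compounds,
#' learn convex-combination weights `alpha` by alternating
#' (i) a cross-entropy nonnegative matrix factorization of the weighted
#' average stochastic matrix `P_bar = sum(alpha_l * P_l)` (cross-entropy is
#' linear in its first argument, so factorizing the average minimizes the
#' weighted sum of per-view cross-entropies), and
#' (ii) the closed-form entropy-regularized weight update
#' ([optimize_weights()]) given the per-view cross-entropies
#' `C(P_l, VH')`. Iteration starts from uniform weights and stops when the
#' weights or the objective stabilize. The fused similarity matrix is the
#' convex combination `sum(alpha_l * S_l)` of the ORIGINAL similarity
#' matrices.
#'
#' @param views List of two or more [similarity_view()] objects over the same
#'   compounds in the same order.
#' @param config A [fusion_config()].
#' @return Object of class `fusion_result`: `alpha`, `cross_entropy`
#'   (per view), `model` (the final `factorization_model`), `fused_S`,
#'   `fused_P`, `trace` (tibble: restart, iteration, objective, one column
#'   per weight), `converged`, `iterations`, `seed`, `eta`, `config`.
#' @export
fuse <- function(views, config) {
  stopifnot(inherits(config, "fusion_config"))
  if (!is.list(views) || length(views) < 2) abort("need at least 2 views")
  if (!all(vapply(views, inherits, logical(1), "similarity_view"))) {
    abort("views must be similarity_view objects")
  }
  ids <- rownames(views[[1]]$S)
  for (v in views[-1]) {
    other <- rownames(v$S)
    if (!identical(other, ids)) {
      diffs <- c(setdiff(ids, other), setdiff(other, ids))
      if (length(diffs) > 0) {
        abort(paste0("views disagree on compound sets: ", paste(diffs, collapse = ", ")))
      }
      abort("views must list compounds in the same order")
    }
  }
  vnames <- vapply(views, `[[`, character(1), "name")
  if (anyDuplicated(vnames)) vnames <- make.unique(vnames)
  L <- length(views)
  P_list <- lapply(views, `[[`, "P")
  k <- config$k
  if (k > length(ids)) abort(sprintf("rank k = %d exceeds compound count %d", k, length(ids)))

  run_restart <- function(seed_r) {
    alpha <- rep(1 / L, L)
    model <- NULL
    trace <- list()
    converged <- FALSE
    objective_prev <- NA_real_
    for (outer in seq_len(config$max_outer)) {
      P_bar <- Reduce(`+`, Map(`*`, P_list, alpha))
      model <- fit_factorization(
        P_bar, k, seed = seed_r, max_em = config$max_em,
        tol = config$tol_objective,
        init = if (outer > 1) list(V = model$V, H = model$H) else NULL
      )
      ce <- vapply(P_list, cross_entropy, numeric(1), Q = model$Q)
      w <- optimize_weights(ce, config$eta)
      delta <- max(abs(w$alpha - alpha))
      alpha <- w$alpha
      trace[[outer]] <- c(iteration = outer, objective = w$objective,
                          setNames(alpha, paste0("alpha_", vnames)))
      if (delta < config$tol_alpha) {
        converged <- TRUE
        break
      }
      if (!is.na(objective_prev)) {
        rel <- abs(objective_prev - w$objective) /
          max(abs(objective_prev), .SIMFUSE_EPS)
        if (rel < config$tol_objective) {
          converged <- TRUE
          break
        }
      }
      objective_prev <- w$objective
    }
    list(alpha = setNames(alpha, vnames), ce = setNames(ce, vnames),
         model = model, trace = trace, converged = converged,
         objective = trace[[length(trace)]][["objective"]], seed = seed_r)
  }

  restarts <- lapply(seq_len(config$n_restarts) - 1L,
                     function(r) run_restart(config$seed + r))
  objectives <- vapply(restarts, `[[`, numeric(1), "objective")
  best_i <- which.min(objectives)
  best <- restarts[[best_i]]

  trace_tbl <- dplyr::bind_rows(lapply(seq_along(restarts), function(r) {
    tb <- tibble::as_tibble(do.call(rbind, restarts[[r]]$trace))
    tb$restart <- r
    tb
  }))
  trace_tbl <- dplyr::relocate(trace_tbl, "restart")

  fused_S <- Reduce(`+`, Map(`*`, lapply(views, `[[`, "S"), best$alpha))
  fused_P <- Reduce(`+`, Map(`*`, P_list, best$alpha))

  structure(
    list(alpha = best$alpha, cross_entropy = best$ce, model = best$model,
         fused_S = fused_S, fused_P = fused_P, trace = trace_tbl,
         converged = best$converged,
         iterations = nrow(trace_tbl[trace_tbl$restart == best_i, ]),
         objective = best$objective, seed = best$seed,
         eta = config$eta, view_names = vnames, config = config),
    class = "fusion_result"
  )
}

#' @export
print.fusion_result <- function(x, digits = 4, ...) {
  cat(sprintf("<fusion_result> %d compounds, %d views, eta = %g, k = %d\n",
              nrow(x$fused_S), length(x$alpha), x$eta, x$model$k))
  cat("  alpha:", paste(sprintf("%s = %.*f", names(x$alpha), digits, x$alpha),
                        collapse = ", "), "\n")
  cat(sprintf("  objective = %.*f (%s)\n", digits, x$objective,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}
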