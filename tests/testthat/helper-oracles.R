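# Independent brute-force oracles and small fixture builders.

# all permutations of 1..n (n <= 7)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# disagreement by exhaustive enumeration over label permutations of b
brute_disagreement <- function(la, lb, k) {
  best <- length(la)
  for (p in all_perms(k)) {
    best <- min(best, sum(la != p[lb]))
  }
  best
}

# Dunn's index by explicit O(n^2) double loop
brute_dunn <- function(d, labels) {
  n <- nrow(d)
  inter <- Inf
  diam <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (labels[i] == labels[j]) {
        diam <- max(diam, d[i, j])
      } else {
        inter <- min(inter, d[i, j])
      }
    }
  }
  inter / diam
}

# entropy-regularized weight objective minimized by grid search on the
# 2-simplex at the given step
brute_weights_2 <- function(ce, eta, step = 1e-4) {
  a1 <- seq(0, 1, by = step)
  ent <- function(a) {
    p <- c(a, 1 - a)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  obj <- vapply(a1, function(a) {
    a * ce[1] + (1 - a) * ce[2] - eta * ent(a)
  }, numeric(1))
  best <- a1[which.min(obj)]
  c(best, 1 - best)
}

# textbook agglomerative clustering returning merge heights, for the
# hierarchical-clustering oracle
naive_agglom_heights <- function(d, linkage = "average") {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in seq.int(i + 1, m)) {
        dij <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        v <- switch(linkage,
          average = mean(dij),
          complete = max(dij),
          single = min(dij)
        )
        if (v < best[1]) best <- c(v, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# random stochastic matrix summing to 1
rand_stochastic <- function(n, m = n, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * m), n, m)
    x / sum(x)
  })
}

# random symmetric similarity matrix in [0, 1] with unit diagonal
rand_similarity <- function(n, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * n), n, n)
    s <- (x + t(x)) / 2
    diag(s) <- 1
    dimnames(s) <- list(sprintf("c%02d", 1:n), sprintf("c%02d", 1:n))
    s
  })
}

# a pair of similarity views with clean planted 2-block structure
block_views <- function(n = 8, within = 0.9, between = 0.1) {
  blocks <- rep(1:2, each = n / 2)
  S <- outer(blocks, blocks, function(a, b) ifelse(a == b, within, between))
  diag(S) <- 1
  ids <- sprintf("c%02d", 1:n)
  dimnames(S) <- list(ids, ids)
  list(similarity_view("v1", S), similarity_view("v2", S))
}
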