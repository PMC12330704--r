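# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation paths they check.

# Connected components by transitive closure of the boolean adjacency matrix.
oracle_components <- function(vertices, edges) {
  n <- length(vertices)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(vertices, vertices)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      adj[edges$v1[i], edges$v2[i]] <- TRUE
      adj[edges$v2[i], edges$v1[i]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  groups <- unique(apply(adj, 1, function(r) paste(sort(vertices[r]), collapse = ";")))
  sorted <- lapply(strsplit(groups, ";", fixed = TRUE), sort)
  sorted[order(vapply(sorted, `[`, "", 1L))]
}

# Two-sided Fisher exact p for a 2x2 table by enumerating the hypergeometric
# support and summing tables no more probable than the observed one.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# One-sided (upper tail) hypergeometric p for enrichment direction checks.
oracle_fisher_p_upper <- function(a, b, c, d) {
  stats::phyper(a - 1L, a + b, c + d, a + c, lower.tail = FALSE)
}

# Clone-sharing fraction by exhaustive enumeration of cross-group cell pairs.
oracle_sharing <- function(assign, cells_a, cells_b) {
  a <- assign[assign$cell_id %in% cells_a, ]
  b <- assign[assign$cell_id %in% cells_b, ]
  num <- den <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$donor[i] == b$donor[j]) {
        den <- den + 1
        if (a$clone_id[i] == b$clone_id[j]) num <- num + 1
      }
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Phi coefficient from the 2x2 co-occurrence counts of two 0/1 vectors.
oracle_phi <- function(x, y) {
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  (n11 * n00 - n10 * n01) /
    sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
}

# Kendall tau-a by explicit pair enumeration (no tie handling needed for the
# cases it is used on).
oracle_kendall <- function(x, y) {
  n <- length(x); conc <- disc <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / choose(n, 2)
}

# Random variant graph for component equivalence checks.
random_graph <- function(n_vertices, p_edge = 0.08) {
  v <- sprintf("v%02d", seq_len(n_vertices))
  pairs <- which(upper.tri(matrix(0, n_vertices, n_vertices)), arr.ind = TRUE)
  keep <- which(stats::runif(nrow(pairs)) < p_edge)
  edges <- data.frame(v1 = v[pairs[keep, 1L]], v2 = v[pairs[keep, 2L]],
                      weight = rep(1, length(keep)), stringsAsFactors = FALSE)
  structure(list(vertices = v, edges = edges), class = "variant_graph")
}
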