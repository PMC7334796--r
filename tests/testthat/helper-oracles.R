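# Independent oracles used to cross-check the package implementations.
# Each one is a straight-line textbook computation that deliberately avoids
# the code path it validates.

# Closed-form Welch two-sample t-test (Satterthwaite degrees of freedom).
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  c(t = t, p = 2 * pt(-abs(t), df))
}

# Holm step-down by direct sequential application of its definition.
oracle_holm <- function(ps) {
  m <- length(ps)
  ord <- order(ps)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * ps[ord[i]]))
    adj[ord[i]] <- running
  }
  adj
}

# Exhaustive-enumeration hypergeometric upper tail: enumerate every possible
# draw of n items from N (the first K are "annotated") and count draws with
# >= k annotated members. Only viable for small N.
oracle_hypergeom_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Brute-force contribution scores straight from an edge list and herb map,
# independent of the ct_network representation. Guarded-denominator
# convention; |A| enters the score.
oracle_cs <- function(edges, herb_map) {
  compounds <- sort(unique(edges$compound))
  deg_c <- table(edges$compound)
  deg_t <- table(edges$target)
  t_edge <- nrow(edges)
  cs <- sapply(compounds, function(cp) {
    ci <- deg_c[[cp]]
    w <- ci / t_edge
    h <- herb_map[[cp]]
    c_a <- if (h %in% c("CR", "SHARED")) ci else 0   # CR-side degree
    c_b <- if (h %in% c("ATR", "SHARED")) ci else 0  # ATR-side degree
    d <- c_a - c_b
    denom <- if (d == 0) 1 else d
    a <- w + (c_a + c_b) / denom
    pj <- sum(deg_t[edges$target[edges$compound == cp]])
    ci * abs(a) * pj
  })
  setNames(as.numeric(cs), compounds)
}

# Random bipartite compound-target instance with herb labels; every
# compound gets at least one edge.
random_bipartite <- function(n_compounds, n_targets,
                            herbs = c("ATR", "CR", "SHARED")) {
  cps <- sprintf("C%02d", seq_len(n_compounds))
  tgs <- sprintf("T%02d", seq_len(n_targets))
  herb_map <- setNames(sample(herbs, n_compounds, replace = TRUE), cps)
  edges <- do.call(rbind, lapply(cps, function(cp) {
    k <- sample.int(n_targets, 1)
    data.frame(compound = cp, target = sample(tgs, k),
               stringsAsFactors = FALSE)
  }))
  list(edges = edges, herb_map = herb_map)
}
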