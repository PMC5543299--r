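# Small graphs and independent brute-force oracles used across tests.

path_edges <- function(n) cbind(seq_len(n - 1L), seq(2L, n))

# breadth-first-search oracle for k-order contiguity neighbour sets
bfs_neighbors <- function(edges, ids, order, include_lower) {
  adj <- lapply(ids, function(i) {
    unique(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
  })
  names(adj) <- as.character(ids)
  lapply(ids, function(s) {
    dist <- stats::setNames(rep(Inf, length(ids)), as.character(ids))
    dist[as.character(s)] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) && d < order) {
      d <- d + 1
      nxt <- unique(unlist(adj[as.character(frontier)]))
      nxt <- nxt[dist[as.character(nxt)] == Inf]
      dist[as.character(nxt)] <- d
      frontier <- nxt
    }
    if (include_lower) ids[dist >= 1 & dist <= order]
    else ids[dist == order]
  })
}

# independently coded Marshall local empirical Bayes estimator
marshall_oracle <- function(O, E, nbr_list) {
  n <- length(O)
  sir <- O / E
  out <- numeric(n)
  for (i in seq_len(n)) {
    ref <- c(i, nbr_list[[i]])
    sumE <- sum(E[ref])
    m <- sum(O[ref]) / sumE
    s2 <- sum(E[ref] * (sir[ref] - m)^2) / sumE - m * length(ref) / sumE
    s2 <- max(s2, 0)
    C <- s2 / (s2 + m / E[i])
    out[i] <- m + C * (sir[i] - m)
  }
  out
}

# exhaustive scan oracle: every (center, radius) circle, llr by direct formula
brute_scan_max <- function(areas, D, max_frac) {
  n <- nrow(areas)
  C <- sum(areas$cases)
  thr <- max_frac * sum(areas$n)
  best <- c(high = -Inf, low = -Inf)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- D[i, j]
      mem <- which(D[i, ] <= r)
      if (sum(areas$n[mem]) > thr) next
      c_ <- sum(areas$cases[mem]); E_ <- sum(areas$expected[mem])
      if (E_ <= 0 || E_ >= C) next
      t1 <- if (c_ == 0) 0 else c_ * log(c_ / E_)
      t2 <- if (C - c_ == 0) 0 else (C - c_) * log((C - c_) / (C - E_))
      llr <- t1 + t2
      d <- if (c_ > E_) "high" else "low"
      if (llr > best[d]) best[d] <- llr
    }
  }
  best
}

# small synthetic study shared by several tests
tiny_study <- function(seed = 1L, n_rows = 8L, n_cols = 8L,
                       total_cases = 400, implants = NULL) {
  simulate_study(simulation_spec(n_rows = n_rows, n_cols = n_cols,
                                 total_cases = total_cases,
                                 implants = implants, seed = seed))
}
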