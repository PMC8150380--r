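# Independent brute-force oracles used to check the package's
# implementations. These deliberately share no code with R/.

# ROC-AUC by exhaustive positive-negative pair counting, ties = 1/2.
brute_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Average precision as a precision/recall staircase walked threshold by
# threshold over distinct descending scores.
brute_pr_auc <- function(scores, labels) {
  P <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  tp_prev <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    ap <- ap + prec * (tp - tp_prev)
    tp_prev <- tp
  }
  ap / P
}

# Shortest-path machinery on an adjacency matrix (BFS per source).
bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] == 1)
      new <- nb[d[nb] == Inf]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

# Count all shortest paths between every pair by dynamic programming over
# BFS levels; betweenness by summing pair-dependency fractions.
brute_centralities <- function(adj) {
  n <- nrow(adj)
  D <- t(vapply(seq_len(n), function(s) bfs_dist(adj, s), numeric(n)))
  # number of shortest s->t paths via DP on distance layers
  nsp <- function(s) {
    sigma <- numeric(n)
    sigma[s] <- 1
    for (l in sort(unique(D[s, is.finite(D[s, ])]))) {
      if (l == 0) next
      for (v in which(D[s, ] == l)) {
        preds <- which(adj[v, ] == 1 & D[s, ] == l - 1)
        sigma[v] <- sum(sigma[preds])
      }
    }
    sigma
  }
  SIG <- t(vapply(seq_len(n), nsp, numeric(n)))
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t] && SIG[s, t] > 0)
        btw[v] <- btw[v] + SIG[s, v] * SIG[v, t] / SIG[s, t]
    }
  }
  deg <- rowSums(adj)
  clo <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    if (!length(reach)) 0 else length(reach) / sum(D[v, reach])
  }, numeric(1))
  list(degree = deg, betweenness = btw, closeness = clo)
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# O(n*m) interval intersector: peak (BED 0-based half-open) overlaps a gene
# span [start, end] (1-based inclusive) iff peak covers any base in it.
brute_peak_overlaps <- function(genes, peaks) {
  vapply(seq_len(nrow(genes)), function(i) {
    g1 <- genes$start[i]; g2 <- genes$end[i]
    sum(vapply(seq_len(nrow(peaks)), function(j) {
      peaks$chrom[j] == genes$chrom[i] &&
        (peaks$start[j] + 1) <= g2 && peaks$end[j] >= g1
    }, logical(1)))
  }, numeric(1))
}

rand_binary_instance <- function(n, tie_prob = 0.3) {
  scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
  if (runif(1) > tie_prob) scores <- scores + runif(n) * 1e-3
  labels <- rbinom(n, 1, 0.4)
  if (sum(labels) == 0) labels[sample(n, 1)] <- 1
  if (sum(labels) == n) labels[sample(n, 1)] <- 0
  list(scores = scores, labels = labels)
}
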