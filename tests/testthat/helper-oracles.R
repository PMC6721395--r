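# Independent brute-force oracles, deliberately built on different
# machinery than the implementation: matrix exponentials via Matrix::expm,
# likelihoods by exhaustive enumeration over internal-node states, and
# covariances by explicit root-path intersection.

expm_oracle <- function(Q, t) {
  as.matrix(Matrix::expm(Q * t))
}

tree_children <- function(tree) {
  split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
}

# exhaustive Mk likelihood: sum over all internal-node state assignments
# (tips must be fully observed)
oracle_mk_loglik <- function(tree, tip_states, Q, prior) {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  stopifnot(k^nint <= 1e6)
  x <- match(tip_states[tree$tip.label], colnames(Q))
  stopifnot(!anyNA(x))
  Pe <- lapply(tree$edge.length, function(t) expm_oracle(Q, t))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    assign_state <- function(node) {
      if (node <= ntip) x[node] else grid[r, node - ntip]
    }
    lik <- prior[grid[r, 1L]] # root is node ntip + 1
    for (i in seq_len(nrow(tree$edge))) {
      lik <- lik * Pe[[i]][assign_state(tree$edge[i, 1L]),
                           assign_state(tree$edge[i, 2L])]
    }
    total <- total + lik
  }
  log(total)
}

# exhaustive marginal posterior of each internal node's state
oracle_mk_marginals <- function(tree, tip_states, Q, prior) {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  x <- match(tip_states[tree$tip.label], colnames(Q))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  w <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    assign_state <- function(node) {
      if (node <= ntip) x[node] else grid[r, node - ntip]
    }
    lik <- prior[grid[r, 1L]]
    for (i in seq_len(nrow(tree$edge))) {
      P <- expm_oracle(Q, tree$edge.length[i])
      lik <- lik * P[assign_state(tree$edge[i, 1L]),
                     assign_state(tree$edge[i, 2L])]
    }
    w[r] <- lik
  }
  M <- matrix(0, nint, k)
  for (j in seq_len(nint)) {
    for (s in seq_len(k)) M[j, s] <- sum(w[grid[, j] == s])
  }
  M / rowSums(M)
}

# covariance by explicit root-path intersection
oracle_phylo_cov <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  erow <- integer(ntip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]
    erow[tree$edge[i, 2L]] <- i
  }
  path_edges <- lapply(seq_len(ntip), function(t) {
    node <- t; out <- integer(0)
    while (parent[node] != 0L) { out <- c(out, erow[node]); node <- parent[node] }
    out
  })
  C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    C[i, j] <- sum(tree$edge.length[intersect(path_edges[[i]], path_edges[[j]])])
  }
  C
}

# regime covariance by root-path intersection over map segments
oracle_regime_cov <- function(tree, map, grouping) {
  ntip <- length(tree$tip.label)
  regimes <- unique(unname(grouping[map$states]))
  parent <- integer(ntip + tree$Nnode)
  erow <- integer(ntip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]
    erow[tree$edge[i, 2L]] <- i
  }
  path_edges <- lapply(seq_len(ntip), function(t) {
    node <- t; out <- integer(0)
    while (parent[node] != 0L) { out <- c(out, erow[node]); node <- parent[node] }
    out
  })
  out <- lapply(regimes, function(r) {
    matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  })
  names(out) <- regimes
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    for (e in intersect(path_edges[[i]], path_edges[[j]])) {
      br <- map$edge_segments[[e]]
      for (s in seq_len(nrow(br))) {
        r <- grouping[[map$states[br[s, 1L]]]]
        out[[r]][i, j] <- out[[r]][i, j] + br[s, 2L]
      }
    }
  }
  out
}

# direct multivariate-normal log density (no chol reuse with the package)
oracle_mvn_loglik <- function(x, mu, V) {
  n <- length(x)
  d <- x - mu
  as.numeric(-0.5 * n * log(2 * pi) -
               0.5 * determinant(V, logarithm = TRUE)$modulus -
               0.5 * t(d) %*% solve(V) %*% d)
}

# Fitch small-parsimony count (recursive over the child map)
fitch_count <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  count <- 0L
  rec <- function(node) {
    if (node <= ntip) return(tip_states[tree$tip.label][node])
    sets <- lapply(kids[[as.character(node)]], rec)
    inter <- Reduce(intersect, sets)
    if (length(inter)) return(inter)
    count <<- count + 1L
    Reduce(union, sets)
  }
  rec(ntip + 1L)
  count
}

# deterministic random trees/data for parameterized cases
rand_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

rand_Q <- function(k, seed, states = as.character(seq_len(k) - 1L)) {
  set.seed(seed)
  Q <- matrix(runif(k * k, 0.2, 1.5), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(states, states)
  Q
}
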