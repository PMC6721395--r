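# Discrete-trait continuous-time Markov (Mk) machinery: likelihoods via
# Felsenstein pruning (C++ core), ML fitting with multi-start, marginal
# ancestral states, and stochastic character mapping by forward-backward
# node sampling plus endpoint-conditioned path sampling (uniformization).

# ---- model objects ----------------------------------------------------------

#' Construct an Mk model
#'
#' @param Q generator matrix: off-diagonals >= 0, rows summing to zero.
#' @param states character vector of state names (defaults to `rownames(Q)`).
#' @param prior root prior probability vector (default uniform).
#' @return an object of class `"mk_model"`.
#' @export
mk_model <- function(Q, states = rownames(Q), prior = NULL) {
  Q <- as.matrix(Q)
  k <- nrow(Q)
  if (k < 2L || ncol(Q) != k) stop("Q must be square with k >= 2")
  if (is.null(states)) states <- as.character(seq_len(k))
  if (length(states) != k) stop("states length must match Q")
  off <- Q[row(Q) != col(Q)]
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-12 * max(1, max(abs(Q))))) {
    stop("rows of Q must sum to zero")
  }
  if (is.null(prior)) prior <- rep(1 / k, k)
  if (length(prior) != k || any(prior < 0) || abs(sum(prior) - 1) > 1e-8) {
    stop("prior must be a length-k probability vector")
  }
  dimnames(Q) <- list(states, states)
  structure(list(Q = Q, states = states, prior = prior, k = k),
            class = "mk_model")
}

#' Equal-rates Mk model
#'
#' Convenience constructor: all off-diagonal transition rates equal.
#'
#' @param states character vector of state names.
#' @param rate the shared transition rate (>= 0).
#' @param prior root prior (default uniform).
#' @return an `"mk_model"`.
#' @export
mk_er_model <- function(states, rate, prior = NULL) {
  k <- length(states)
  Q <- matrix(rate, k, k)
  diag(Q) <- -(k - 1) * rate
  mk_model(Q, states, prior)
}

# stationary distribution of a generator (null left eigenvector)
stationary_dist <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  pi <- qr.solve(A, c(rep(0, k), 1))
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Transition probability matrix of an Mk model
#'
#' @param model an `"mk_model"`.
#' @param t elapsed time (>= 0).
#' @return the stochastic matrix `expm(Q t)`.
#' @export
transition_probability <- function(model, t) {
  stopifnot(inherits(model, "mk_model"))
  if (!is.finite(t) || t < 0) stop("t must be finite and >= 0")
  P <- cpp_transition_stack(model$Q, t)
  P <- P / rowSums(P)
  dimnames(P) <- list(model$states, model$states)
  P
}

# transition matrices for all edge lengths, one eigendecomposition
edge_transition_list <- function(Q, elen) {
  k <- nrow(Q)
  stack <- cpp_transition_stack(Q, elen)
  lapply(seq_along(elen), function(i) {
    P <- stack[, ((i - 1L) * k + 1L):(i * k), drop = FALSE]
    P / rowSums(P)
  })
}

# ---- likelihood -------------------------------------------------------------

# align a named state vector to tree tips; returns factor with given levels
align_tip_states <- function(tree, tip_states, states = NULL) {
  if (is.null(names(tip_states))) {
    if (length(tip_states) != length(tree$tip.label)) {
      stop("unnamed tip_states must match the number of tips")
    }
    names(tip_states) <- tree$tip.label
  }
  missing_tips <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing_tips)) {
    stop("no state for tips: ", paste(missing_tips, collapse = ", "))
  }
  x <- as.character(tip_states)[match(tree$tip.label, names(tip_states))]
  if (is.null(states)) states <- sort(unique(x[!is.na(x)]))
  bad <- !is.na(x) & !x %in% states
  if (any(bad)) stop("tip states outside the state set: ",
                     paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = states)
}

# ntip x k likelihood matrix; NA rows are all-ones (missing data)
tip_state_matrix <- function(tree, tip_states_factor) {
  k <- nlevels(tip_states_factor)
  n <- length(tree$tip.label)
  L <- matrix(1, n, k)
  idx <- as.integer(tip_states_factor)
  obs <- which(!is.na(idx))
  L[obs, ] <- 0
  L[cbind(obs, idx[obs])] <- 1
  L
}

postorder_edge_data <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = matrix(as.integer(po$edge), ncol = 2L), elen = po$edge.length,
       root = length(tree$tip.label) + 1L, n_node = tree$Nnode)
}

#' Mk log-likelihood of tip states on a tree
#'
#' Felsenstein pruning: the sum over root states of the prior times the
#' conditional likelihood of the data below the root.
#'
#' @param tree a `"phylo"` object.
#' @param tip_states named character vector (or factor) of tip states;
#'   `NA` marks missing data.
#' @param model an `"mk_model"` whose state set covers the observed states.
#' @return the log-likelihood (`-Inf`, with a warning, for data of
#'   probability zero under the model).
#' @export
mk_loglik <- function(tree, tip_states, model) {
  stopifnot(inherits(model, "mk_model"))
  validate_phylogeny(tree)
  x <- align_tip_states(tree, tip_states, model$states)
  ed <- postorder_edge_data(tree)
  ll <- cpp_mk_loglik(ed$edge, ed$elen, model$Q, tip_state_matrix(tree, x),
                      model$prior, ed$n_node)
  if (!is.finite(ll)) warning("data have probability 0 under this model")
  ll
}

# ---- fitting ----------------------------------------------------------------

# index matrix of free off-diagonal parameters for each model family
rate_index_matrix <- function(k, family) {
  M <- matrix(0L, k, k)
  off <- which(row(M) != col(M))
  switch(family,
    ER = { M[off] <- 1L },
    SYM = {
      idx <- 0L
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        idx <- idx + 1L
        M[i, j] <- idx; M[j, i] <- idx
      }
    },
    ARD = { M[off] <- seq_along(off) }
  )
  M
}

build_Q <- function(rates, index) {
  Q <- matrix(0, nrow(index), ncol(index))
  pos <- which(index > 0L)
  Q[pos] <- rates[index[pos]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Fit an Mk model by maximum likelihood
#'
#' Rates are optimized on the log scale with multi-start (random restarts
#' drawn log-uniformly over `[1e-4, 1e2]` per unit tree depth) so the
#' reported optimum is robust to the likelihood's flat regions.
#'
#' @param tree a `"phylo"` object.
#' @param tip_states named character vector/factor of tip states (NA =
#'   missing).
#' @param family model family: `"ER"` (one rate), `"SYM"` (symmetric) or
#'   `"ARD"` (all rates different).
#' @param restarts number of random restarts (default 10).
#' @param seed optional integer seed for the restart draws.
#' @param prior root prior: `"uniform"` or `"stationary"` (fitted
#'   stationary distribution), or a numeric probability vector.
#' @param states optional explicit state set (defaults to the sorted
#'   observed states).
#' @return an object of class `"mk_fit"`: the fitted `"mk_model"`, `loglik`,
#'   `rates`, `family` and optimizer diagnostics.
#' @export
fit_mk <- function(tree, tip_states, family = c("ER", "SYM", "ARD"),
                   restarts = 10L, seed = NULL,
                   prior = "uniform", states = NULL) {
  family <- match.arg(family)
  validate_phylogeny(tree)
  states_given <- !is.null(states)
  x <- align_tip_states(tree, tip_states, states)
  states <- levels(x)
  k <- length(states)
  if (length(unique(x[!is.na(x)])) < 2L && !states_given) {
    stop("need at least 2 distinct observed states")
  }
  if (!is.null(seed)) set.seed(seed)

  ed <- postorder_edge_data(tree)
  tipL <- tip_state_matrix(tree, x)
  index <- rate_index_matrix(k, family)
  n_par <- max(index)
  depth <- max(node_depths(tree))
  unif_prior <- rep(1 / k, k)

  nll <- function(logr) {
    Q <- build_Q(exp(logr), index)
    pr <- if (identical(prior, "stationary")) stationary_dist(Q)
          else if (is.numeric(prior)) prior else unif_prior
    ll <- cpp_mk_loglik(ed$edge, ed$elen, Q, tipL, pr, ed$n_node)
    if (!is.finite(ll)) 1e10 else -ll
  }

  lo <- log(1e-8 / depth); hi <- log(1e5 / depth)
  starts <- c(list(rep(log(1 / depth), n_par)),
              lapply(seq_len(max(0L, restarts - 1L)), function(i) {
                log(10^runif(n_par, -4, 2) / depth)
              }))
  best <- NULL; conv <- integer(0)
  for (st in starts) {
    fit <- if (n_par == 1L) {
      o <- optim(st, nll, method = "Brent", lower = lo, upper = hi,
                 control = list(reltol = 1e-12))
      o
    } else {
      optim(st, nll, method = "Nelder-Mead",
            control = list(maxit = 5000L, reltol = 1e-10))
    }
    conv <- c(conv, fit$convergence)
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("Mk optimization failed across all restarts; best value: ",
         if (is.null(best)) NA else best$value)
  }

  rates <- exp(best$par)
  Q <- build_Q(rates, index)
  pr <- if (identical(prior, "stationary")) stationary_dist(Q)
        else if (is.numeric(prior)) prior else unif_prior
  structure(list(
    model = mk_model(Q, states, pr),
    loglik = -best$value,
    rates = rates,
    family = family,
    tree = tree,
    tip_states = x,
    diagnostics = list(restarts = length(starts), convergence = conv)
  ), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit (", x$family, "), ", x$model$k, " states: ",
      paste(x$model$states, collapse = ", "), "\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 6), "\n")
  cat("  rates:", paste(format(x$rates, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested Mk fits
#'
#' Twice the log-likelihood difference referred to a chi-square with
#' degrees of freedom equal to the difference in free rates (ER vs ARD on a
#' binary trait: df = 1).
#'
#' @param fit_simple,fit_complex nested `"mk_fit"` objects on the same data.
#' @return a list with `statistic`, `df`, `p_value` and both log-likelihoods.
#' @export
mk_lrt <- function(fit_simple, fit_complex) {
  stopifnot(inherits(fit_simple, "mk_fit"), inherits(fit_complex, "mk_fit"))
  df <- length(fit_complex$rates) - length(fit_simple$rates)
  if (df < 1L) stop("fit_complex must have more free rates than fit_simple")
  stat <- 2 * (fit_complex$loglik - fit_simple$loglik)
  if (stat < 0) {
    if (stat < -1e-4) warning("complex model fits worse than simple model ",
                              "beyond numerical tolerance")
    stat <- 0
  }
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE),
       loglik_simple = fit_simple$loglik, loglik_complex = fit_complex$loglik)
}

# ---- ancestral states -------------------------------------------------------

#' Marginal ancestral state probabilities
#'
#' Standard two-pass (lower conditionals up, outside partials down)
#' computation of the marginal posterior of each internal node's state
#' under the fitted model.
#'
#' @param fit an `"mk_fit"`.
#' @return a matrix (internal nodes x states) of probabilities, rows summing
#'   to 1; row names are ape node ids.
#' @export
ancestral_marginals <- function(fit) {
  stopifnot(inherits(fit, "mk_fit"))
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  k <- fit$model$k
  ed <- postorder_edge_data(tree)
  cond <- cpp_mk_conditionals(ed$edge, ed$elen, fit$model$Q,
                              tip_state_matrix(tree, fit$tip_states),
                              fit$model$prior, ed$n_node)
  L <- cond$L
  Plist <- edge_transition_list(fit$model$Q, ed$elen)

  # per-edge child contribution vectors at the parent: (P_e L_child)
  contrib <- matrix(0, nrow(ed$edge), k)
  for (i in seq_len(nrow(ed$edge))) {
    contrib[i, ] <- Plist[[i]] %*% L[ed$edge[i, 2L], ]
  }
  edges_of_parent <- split(seq_len(nrow(ed$edge)), ed$edge[, 1L])

  U <- matrix(0, ntip + tree$Nnode, k)
  U[ed$root, ] <- fit$model$prior
  # preorder = reverse postorder over edges
  for (i in rev(seq_len(nrow(ed$edge)))) {
    p <- ed$edge[i, 1L]; ch <- ed$edge[i, 2L]
    sibs <- setdiff(edges_of_parent[[as.character(p)]], i)
    S <- U[p, ]
    for (j in sibs) S <- S * contrib[j, ]
    u <- as.vector(S %*% Plist[[i]])
    s <- sum(u)
    U[ch, ] <- if (s > 0) u / s else rep(1 / k, k)
  }

  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  M <- L[nodes, , drop = FALSE] * U[nodes, , drop = FALSE]
  M <- M / rowSums(M)
  dimnames(M) <- list(nodes, fit$model$states)
  M
}

# ---- stochastic mapping -----------------------------------------------------

# endpoint-conditioned CTMC path via uniformization; returns a two-column
# matrix (state index, duration) or NULL when conditioning is numerically
# impossible (caller resamples node states).
sample_bridge <- function(Q, P, a, b, t, mu, R, Rpow) {
  if (t <= 0 || mu <= 0) {
    if (a != b) return(NULL)
    return(cbind(state = a, duration = t))
  }
  pab <- P[a, b]
  if (!is.finite(pab) || pab <= 1e-300) return(NULL)
  lam <- mu * t
  # number of uniformized jumps
  u <- runif(1) * pab
  n <- -1L; cum <- 0
  ncap <- max(50L, ceiling(lam + 12 * sqrt(lam) + 25))
  repeat {
    n <- n + 1L
    Rn_ab <- if (n == 0L) (a == b) else Rpow(n)[a, b]
    cum <- cum + exp(-lam + n * log(lam) - lgamma(n + 1)) * Rn_ab
    if (cum >= u || n >= ncap) break
  }
  if (n == 0L) return(cbind(state = a, duration = t))
  s <- integer(n + 1L); s[1L] <- a; s[n + 1L] <- b
  if (n > 1L) {
    for (i in 2:n) {
      w <- R[s[i - 1L], ] * Rpow(n + 1L - i)[, b]
      if (sum(w) <= 0) return(NULL)
      s[i] <- sample.int(length(w), 1L, prob = w)
    }
  }
  times <- c(0, sort(runif(n)) * t, t)
  dur <- diff(times)
  # collapse virtual (self) jumps
  keep_state <- s[1L]; out_s <- integer(0); out_d <- numeric(0); acc <- dur[1L]
  for (i in 2:(n + 1L)) {
    if (s[i] == keep_state) {
      acc <- acc + dur[i]
    } else {
      out_s <- c(out_s, keep_state); out_d <- c(out_d, acc)
      keep_state <- s[i]; acc <- dur[i]
    }
  }
  out_s <- c(out_s, keep_state); out_d <- c(out_d, acc)
  cbind(state = out_s, duration = out_d)
}

#' Sample stochastic character maps
#'
#' Draws full state histories consistent with the tip data and fitted
#' generator: node states by forward-backward sampling from their joint
#' conditional distribution, then per-branch paths conditioned on endpoint
#' states by uniformization (with a bounded retry that falls back to
#' resampling the map's node states).
#'
#' @param fit an `"mk_fit"`.
#' @param n_maps number of maps to draw.
#' @param seed optional integer seed; a fixed seed gives an identical
#'   ensemble on re-run.
#' @return an object of class `"state_map_ensemble"`: a list of
#'   `"state_map"` objects (per-edge state segments in parent-to-child
#'   order, aligned to rows of `tree$edge`).
#' @export
sample_stochastic_maps <- function(fit, n_maps, seed = NULL) {
  stopifnot(inherits(fit, "mk_fit"), n_maps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  k <- fit$model$k
  Q <- fit$model$Q
  ed <- postorder_edge_data(tree)
  tipL <- tip_state_matrix(tree, fit$tip_states)
  cond <- cpp_mk_conditionals(ed$edge, ed$elen, Q, tipL, fit$model$prior,
                              ed$n_node)
  L <- cond$L
  Plist <- edge_transition_list(Q, ed$elen)
  # map from postorder edge index to original tree$edge row
  orig <- match(paste(ed$edge[, 1L], ed$edge[, 2L]),
                paste(tree$edge[, 1L], tree$edge[, 2L]))

  mu <- max(-diag(Q))
  R <- if (mu > 0) diag(k) + Q / mu else diag(k)
  pow_cache <- list(R)
  Rpow <- function(n) {
    while (length(pow_cache) < n) {
      pow_cache[[length(pow_cache) + 1L]] <<- pow_cache[[length(pow_cache)]] %*% R
    }
    pow_cache[[n]]
  }

  preorder <- rev(seq_len(nrow(ed$edge)))
  maps <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    for (attempt in seq_len(100L)) {
      node_state <- integer(ntip + tree$Nnode)
      w_root <- fit$model$prior * L[ed$root, ]
      node_state[ed$root] <- sample.int(k, 1L, prob = w_root)
      segs <- vector("list", nrow(tree$edge))
      est <- matrix(0, nrow(tree$edge), k)
      ok <- TRUE
      for (i in preorder) {
        p <- ed$edge[i, 1L]; ch <- ed$edge[i, 2L]
        w <- Plist[[i]][node_state[p], ] * L[ch, ]
        node_state[ch] <- sample.int(k, 1L, prob = w)
        br <- sample_bridge(Q, Plist[[i]], node_state[p], node_state[ch],
                            ed$elen[i], mu, R, Rpow)
        if (is.null(br)) { ok <- FALSE; break }
        segs[[orig[i]]] <- br
        est[orig[i], ] <- vapply(seq_len(k), function(s) {
          sum(br[br[, 1L] == s, 2L])
        }, numeric(1))
      }
      if (ok) break
    }
    if (!ok) stop("path sampling failed repeatedly; generator may be degenerate")
    maps[[m]] <- structure(list(
      edge_segments = segs, node_states = node_state,
      edge_state_times = est, states = fit$model$states
    ), class = "state_map")
  }
  structure(list(maps = maps, tree = tree, states = fit$model$states),
            class = "state_map_ensemble")
}

#' Count state transitions in a stochastic map
#'
#' @param map a `"state_map"`.
#' @return a list with `total` (number of state changes over the whole
#'   tree) and `directed` (k x k matrix of from-to counts).
#' @export
count_transitions <- function(map) {
  stopifnot(inherits(map, "state_map"))
  k <- length(map$states)
  directed <- matrix(0L, k, k, dimnames = list(map$states, map$states))
  for (br in map$edge_segments) {
    if (is.null(br) || nrow(br) < 2L) next
    s <- br[, 1L]
    for (i in seq_len(nrow(br) - 1L)) {
      directed[s[i], s[i + 1L]] <- directed[s[i], s[i + 1L]] + 1L
    }
  }
  list(total = sum(directed), directed = directed)
}

#' Minimum transition count over a stochastic-map ensemble
#'
#' The smallest total number of state changes across the sampled histories
#' is taken as the most parsimonious explanation of the tip states.
#'
#' @param ensemble a `"state_map_ensemble"`.
#' @return a list with `minimum`, `directed` (from-to counts of the argmin
#'   map), `which` (index of that map) and `totals` (all per-map totals).
#' @export
minimum_transitions <- function(ensemble) {
  stopifnot(inherits(ensemble, "state_map_ensemble"),
            length(ensemble$maps) >= 1L)
  counts <- lapply(ensemble$maps, count_transitions)
  totals <- vapply(counts, `[[`, numeric(1), "total")
  i <- which.min(totals)
  list(minimum = totals[i], directed = counts[[i]]$directed, which = i,
       totals = totals)
}

#' Serialize a stochastic map to a flat table
#'
#' @param map a `"state_map"`.
#' @return a data frame with columns `edge` (row of `tree$edge`), `segment`,
#'   `state`, `duration`.
#' @export
state_map_table <- function(map) {
  stopifnot(inherits(map, "state_map"))
  rows <- lapply(seq_along(map$edge_segments), function(i) {
    br <- map$edge_segments[[i]]
    if (is.null(br)) return(NULL)
    data.frame(edge = i, segment = seq_len(nrow(br)),
               state = map$states[br[, 1L]], duration = br[, 2L])
  })
  do.call(rbind, rows)
}
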