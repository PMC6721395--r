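# Simulation-based phylogenetic ANOVA with post-hoc tests, the
# Holm-Bonferroni ladder, lambda-PGLS, and the sister-pair rate scan.

#' One-way ANOVA F statistic
#'
#' @param values numeric vector.
#' @param group_labels factor or character vector of group labels.
#' @return the classical F = MS_between / MS_within; `Inf` when the
#'   within-group variance is zero.
#' @export
anova_f <- function(values, group_labels) {
  g <- factor(group_labels)
  stopifnot(length(values) == length(g), nlevels(g) >= 2L)
  if (any(table(g) < 1L)) stop("every group needs at least one member")
  n <- length(values)
  k <- nlevels(g)
  if (n - k < 1L) stop("need at least 1 residual degree of freedom")
  gm <- tapply(values, g, mean)
  ssb <- sum(table(g) * (gm - mean(values))^2)
  ssw <- sum((values - gm[g])^2)
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# F statistics for every column of a value matrix (one-way, same groups)
anova_f_cols <- function(X, g) {
  n <- nrow(X); k <- nlevels(g)
  cnt <- tabulate(g, k)
  gsum <- rowsum(X, g, reorder = TRUE)
  gmean <- gsum / cnt
  tot <- colMeans(X)
  ssb <- colSums(cnt * (gmean - rep(tot, each = k))^2)
  ssw <- colSums((X - gmean[as.integer(g), , drop = FALSE])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Welch-style pairwise t statistics for all group pairs, every column
pairwise_t_cols <- function(X, g) {
  k <- nlevels(g)
  cnt <- tabulate(g, k)
  gmean <- rowsum(X, g, reorder = TRUE) / cnt
  gvar <- rowsum(X^2, g, reorder = TRUE) / cnt - gmean^2
  gvar <- gvar * cnt / pmax(cnt - 1, 1)
  pairs <- utils::combn(k, 2)
  T <- matrix(0, ncol(pairs), ncol(X))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    T[p, ] <- (gmean[i, ] - gmean[j, ]) /
      sqrt(gvar[i, ] / cnt[i] + gvar[j, ] / cnt[j])
  }
  rownames(T) <- apply(pairs, 2, function(ij) {
    paste(levels(g)[ij], collapse = " vs ")
  })
  T
}

#' Simulation-based phylogenetic ANOVA
#'
#' The observed F is the classical one-way statistic; its null distribution
#' is generated by simulating Brownian motion on the tree with the rate
#' fitted from the data, so relatedness inflates the null F exactly as it
#' inflates the observed one. P-values use the add-one estimator
#' `(1 + #(F_sim >= F_obs)) / (n_sim + 1)`. Post-hoc pairwise Welch-style t
#' statistics are referred to the same simulated null and Holm-adjusted
#' within the post-hoc family.
#'
#' @param tree a `"phylo"` object.
#' @param values named numeric trait vector (tip labels).
#' @param group_labels named character vector/factor of group memberships.
#' @param n_sim number of Brownian simulations (>= 100; default 1000).
#' @param seed optional integer seed (fixed seed, bit-identical result).
#' @param posthoc logical; compute pairwise tests (default TRUE for >2
#'   groups).
#' @return an object of class `"phyl_anova"`: `F`, `p_value`, `group_means`,
#'   `posthoc` (data frame of pairwise T and Holm-adjusted p), `n_sim`.
#' @export
phyl_anova <- function(tree, values, group_labels, n_sim = 1000L,
                       seed = NULL, posthoc = nlevels(factor(group_labels)) > 2L) {
  if (n_sim < 100L) stop("n_sim must be at least 100")
  x <- align_tip_values(tree, values)
  if (is.null(names(group_labels))) names(group_labels) <- names(values)
  g <- factor(unlist(group_labels[tree$tip.label]))
  if (any(is.na(g))) stop("group label missing for some tips")
  if (nlevels(g) < 2L) stop("need at least 2 groups among tree-matched rows")
  if (!is.null(seed)) set.seed(seed)

  f_obs <- anova_f(x, g)
  bmfit <- fit_bm(tree, x)
  C <- phylo_covariance(tree)
  ch <- chol(C * max(bmfit$sigma2[["all"]], .Machine$double.eps))
  Z <- matrix(rnorm(length(x) * n_sim), length(x), n_sim)
  X <- crossprod(ch, Z) # BM tip values, mean 0 (location drops out of F)
  f_sim <- anova_f_cols(X, g)
  p <- (1 + sum(f_sim >= f_obs)) / (n_sim + 1)

  ph <- NULL
  if (posthoc) {
    t_obs <- pairwise_t_cols(matrix(x, ncol = 1), g)[, 1]
    t_sim <- pairwise_t_cols(X, g)
    p_pair <- vapply(seq_along(t_obs), function(i) {
      (1 + sum(abs(t_sim[i, ]) >= abs(t_obs[i]))) / (n_sim + 1)
    }, numeric(1))
    hol <- holm(p_pair)
    ph <- data.frame(pair = names(t_obs), T = t_obs, p_value = p_pair,
                     p_adjusted = hol$p_adjusted,
                     significant = hol$significant, row.names = NULL)
  }
  structure(list(
    F = f_obs, p_value = p,
    group_means = tapply(x, g, mean),
    group_n = table(g),
    posthoc = ph, n_sim = n_sim
  ), class = "phyl_anova")
}

#' @export
print.phyl_anova <- function(x, ...) {
  cat("Phylogenetic ANOVA: F =", format(x$F, digits = 6),
      " p =", format(x$p_value, digits = 4),
      " (", x$n_sim, "simulations )\n")
  cat("  group means:", paste(names(x$group_means),
                              round(x$group_means, 4), collapse = ", "), "\n")
  if (!is.null(x$posthoc)) { cat("  post-hoc:\n"); print(x$posthoc) }
  invisible(x)
}

#' Holm-Bonferroni correction
#'
#' Sorts the p-values ascending and compares the rank-i value against
#' `alpha / (m - i + 1)`, rejecting sequentially until the first failure
#' (ties keep their original order). For seven tests at alpha = 0.05 the
#' thresholds are 0.0071, 0.0083, 0.01, 0.0125, 0.0167, 0.025, 0.05.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise error target (default 0.05).
#' @param family_size size of the test family the ladder is built for
#'   (default `length(p_values)`); setting it larger applies the ladder of
#'   a wider declared family to a subset of tests actually run.
#' @return a list with, in the original test order: `corrected_alpha` (the
#'   threshold each test was compared against), `significant`, `rank`,
#'   `p_adjusted` (standard Holm step-down adjusted p), and the sorted
#'   `thresholds` ladder.
#' @export
holm <- function(p_values, alpha = 0.05, family_size = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1),
            family_size >= length(p_values))
  m <- length(p_values)
  ord <- order(p_values) # stable: ties keep original order
  thresholds <- alpha / (family_size - seq_len(m) + 1)
  sig_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[ord[i]] <= thresholds[i]) sig_sorted[i] <- TRUE else break
  }
  adj_sorted <- cummax(pmin((family_size - seq_len(m) + 1) * p_values[ord], 1))
  out <- list(corrected_alpha = numeric(m), significant = logical(m),
              rank = integer(m), p_adjusted = numeric(m),
              thresholds = thresholds, alpha = alpha)
  out$corrected_alpha[ord] <- thresholds
  out$significant[ord] <- sig_sorted
  out$rank[ord] <- seq_len(m)
  out$p_adjusted[ord] <- adj_sorted
  out
}

# ---- PGLS with Pagel's lambda ----------------------------------------------

# lambda-scaled covariance: off-diagonals multiplied by lambda
lambda_cov <- function(C, lambda) {
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

# largest lambda keeping the scaled covariance positive definite
lambda_upper_bound <- function(C, cap = 10) {
  ok <- function(l) !is.null(tryCatch(chol(lambda_cov(C, l)),
                                      error = function(e) NULL))
  if (!ok(1)) return(1) # pathological tree; profile stays on [0, 1]
  lo <- 1; hi <- 1
  while (hi < cap && ok(hi * 1.5)) hi <- hi * 1.5
  hi <- min(hi * 1.5, cap)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (ok(mid)) lo <- mid else hi <- mid
  }
  lo
}

pgls_at_lambda <- function(x, y, C, lambda) {
  V <- lambda_cov(C, lambda)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  n <- length(y)
  X <- cbind(1, x)
  Xs <- backsolve(ch, X, transpose = TRUE)
  ys <- backsolve(ch, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  r <- ys - Xs %*% beta
  rss <- sum(r^2)
  sigma2_ml <- rss / n
  ll <- -0.5 * n * (log(2 * pi * sigma2_ml) + 1) - sum(log(diag(ch)))
  se <- sqrt(diag(solve(XtX)) * rss / (n - 2))
  list(intercept = beta[1], slope = beta[2], se = se[2], loglik = ll,
       sigma2 = sigma2_ml, lambda = lambda)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Regresses a response on a predictor under a residual correlation equal
#' to the phylogenetic correlation with off-diagonal elements multiplied by
#' lambda. Lambda is profiled by maximum likelihood over `[0, lambda_max]`
#' (the largest value keeping the matrix positive definite, which can
#' exceed 1) on a 64-point grid refined by golden-section search; the
#' coefficient test is t = slope/SE with n - 2 degrees of freedom.
#'
#' @param tree a `"phylo"` object.
#' @param response,predictor named numeric vectors over (a subset of) tips;
#'   rows with missing values are dropped.
#' @param lambda optional fixed lambda (skips profiling).
#' @return an object of class `"pgls_fit"`: `slope`, `se`, `intercept`,
#'   `lambda`, `t_value`, `p_value`, `loglik`, `n`, and `lambda_boundary`
#'   (`"interior"`, `"lower"` or `"upper"`).
#' @export
fit_pgls <- function(tree, response, predictor, lambda = NULL) {
  stopifnot(!is.null(names(response)), !is.null(names(predictor)))
  sp <- intersect(names(response)[is.finite(response)],
                  names(predictor)[is.finite(predictor)])
  sp <- intersect(tree$tip.label, sp)
  if (length(sp) < 4L) stop("need at least 4 complete rows")
  tr <- prune_to_taxa(tree, sp)
  y <- response[tr$tip.label]
  x <- predictor[tr$tip.label]
  C <- phylo_covariance(tr)

  if (is.null(lambda)) {
    lmax <- lambda_upper_bound(C)
    grid <- seq(0, lmax, length.out = 64)
    lls <- vapply(grid, function(l) {
      f <- pgls_at_lambda(x, y, C, l)
      if (is.null(f)) -Inf else f$loglik
    }, numeric(1))
    i <- which.max(lls)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(64, i + 1)]
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
    fc <- pgls_at_lambda(x, y, C, c1)$loglik
    fd <- pgls_at_lambda(x, y, C, d1)$loglik
    for (it in 1:60) {
      if (fc > fd) {
        b <- d1; d1 <- c1; fd <- fc
        c1 <- b - gr * (b - a); fc <- pgls_at_lambda(x, y, C, c1)$loglik
      } else {
        a <- c1; c1 <- d1; fc <- fd
        d1 <- a + gr * (b - a); fd <- pgls_at_lambda(x, y, C, d1)$loglik
      }
    }
    lambda <- (a + b) / 2
    boundary <- if (lambda < lmax / 1000) "lower"
      else if (lambda > lmax * 0.999) "upper" else "interior"
  } else {
    boundary <- "fixed"
  }
  f <- pgls_at_lambda(x, y, C, lambda)
  if (is.null(f)) stop("covariance not positive definite at lambda = ", lambda)
  tval <- f$slope / f$se
  structure(list(
    slope = f$slope, se = f$se, intercept = f$intercept,
    lambda = lambda, t_value = tval,
    p_value = 2 * pt(abs(tval), length(y) - 2, lower.tail = FALSE),
    loglik = f$loglik, n = length(y), lambda_boundary = boundary
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS (Pagel's lambda):\n")
  cat("  slope =", format(x$slope, digits = 4),
      " SE =", format(x$se, digits = 4),
      " lambda =", format(x$lambda, digits = 4),
      "(", x$lambda_boundary, ")\n")
  cat("  t =", format(x$t_value, digits = 4),
      " p =", format(x$p_value, digits = 4), " n =", x$n, "\n")
  invisible(x)
}

# ---- sister-pair rate scan --------------------------------------------------

#' Sister-pair rate scan
#'
#' For every cherry (monophyletic two-species clade) the local evolutionary
#' rate of a trait is proxied by the squared standardized contrast
#' `(x1 - x2)^2 / (t1 + t2)` and the trait magnitude by the pair mean; a
#' Spearman rank correlation across pairs, with a permutation p-value,
#' tests whether lineages with larger trait values evolve systematically
#' faster or slower.
#'
#' @param tree a `"phylo"` object with at least 3 cherries.
#' @param values named numeric trait vector.
#' @param n_perm number of permutations for the p-value (default 999).
#' @param seed optional integer seed.
#' @return a list with `pairs` (one row per cherry: tips, rate proxy, pair
#'   mean), `rho`, `p_value`, and `degenerate` (TRUE when all rate proxies
#'   are zero, leaving the correlation undefined).
#' @export
sister_pair_rate_scan <- function(tree, values, n_perm = 999L, seed = NULL) {
  x <- align_tip_values(tree, values)
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  rows <- list()
  for (node in names(kids)) {
    e <- kids[[node]]
    ch <- tree$edge[e, 2L]
    if (length(ch) == 2L && all(ch <= ntip)) {
      t1 <- tree$edge.length[e[1L]]; t2 <- tree$edge.length[e[2L]]
      x1 <- x[ch[1L]]; x2 <- x[ch[2L]]
      rows[[length(rows) + 1L]] <- data.frame(
        tip1 = tree$tip.label[ch[1L]], tip2 = tree$tip.label[ch[2L]],
        rate_proxy = (x1 - x2)^2 / (t1 + t2),
        pair_mean = (x1 + x2) / 2
      )
    }
  }
  if (length(rows) < 3L) stop("need at least 3 cherries, found ", length(rows))
  pairs <- do.call(rbind, rows)
  if (all(pairs$rate_proxy == 0)) {
    return(list(pairs = pairs, rho = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  rho <- cor(pairs$rate_proxy, pairs$pair_mean, method = "spearman")
  perm <- replicate(n_perm, cor(sample(pairs$rate_proxy), pairs$pair_mean,
                                method = "spearman"))
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  list(pairs = pairs, rho = rho, p_value = p, degenerate = FALSE)
}
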