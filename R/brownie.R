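# Brownian-motion likelihoods with one rate or with state-dependent rates
# painted by a stochastic character map, and the ensemble chi-square
# comparison between them (the Brownie test).

align_tip_values <- function(tree, tip_values) {
  if (is.null(names(tip_values))) {
    if (length(tip_values) != length(tree$tip.label)) {
      stop("unnamed tip_values must match the number of tips")
    }
    names(tip_values) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss)) stop("no value for tips: ", paste(miss, collapse = ", "))
  x <- tip_values[tree$tip.label]
  if (any(!is.finite(x))) stop("tip values must be finite")
  x
}

# Gaussian log-density machinery: mean mu*1, covariance V
mvn_phylo_loglik <- function(x, V, mu) {
  n <- length(x)
  ch <- tryCatch(chol(V), error = function(e) {
    stop("phylogenetic covariance is singular: ", conditionMessage(e))
  })
  r <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(r^2)
}

#' Brownian-motion log-likelihood
#'
#' Log density of tip values under single-rate Brownian motion: a
#' multivariate normal with mean `root_state` and covariance
#' `sigma2` times the shared-path-length matrix.
#'
#' @param tree a `"phylo"` object.
#' @param tip_values named numeric vector of (log-scale) trait values.
#' @param sigma2 Brownian rate (> 0), trait variance per unit branch length.
#' @param root_state trait value at the root.
#' @return the log-likelihood.
#' @export
bm_loglik <- function(tree, tip_values, sigma2, root_state) {
  stopifnot(sigma2 > 0)
  x <- align_tip_values(tree, tip_values)
  mvn_phylo_loglik(x, sigma2 * phylo_covariance(tree), root_state)
}

# GLS mean and ML rate given a relative covariance matrix (chol supplied)
gls_profile <- function(x, ch) {
  n <- length(x)
  iC1 <- backsolve(ch, backsolve(ch, rep(1, n), transpose = TRUE))
  mu <- sum(iC1 * x) / sum(iC1)
  r <- backsolve(ch, x - mu, transpose = TRUE)
  q <- sum(r^2)
  sigma2 <- q / n
  ll <- -0.5 * n * (log(2 * pi * sigma2) + 1) - sum(log(diag(ch)))
  list(mu = mu, sigma2 = sigma2, loglik = ll)
}

#' Fit single-rate Brownian motion
#'
#' Closed-form maximum likelihood: the root state is the GLS phylogenetic
#' mean and the rate is the ML (1/n) quadratic form.
#'
#' @param tree a `"phylo"` object with at least 3 tips.
#' @param tip_values named numeric trait vector.
#' @return an object of class `"brownie_fit"` with `sigma2` (named per
#'   regime; here one regime `"all"`), `root_state` and `loglik`.
#' @export
fit_bm <- function(tree, tip_values) {
  x <- align_tip_values(tree, tip_values)
  if (length(x) < 3L) stop("need at least 3 tips")
  C <- phylo_covariance(tree)
  g <- gls_profile(x, chol(C))
  if (g$sigma2 <= .Machine$double.eps * max(1, var(x))) {
    warning("rate estimate at the zero boundary (constant tip values?)")
  }
  structure(list(sigma2 = c(all = g$sigma2), root_state = g$mu,
                 loglik = g$loglik, regimes = NULL, convergence = 0L),
            class = "brownie_fit")
}

#' @export
print.brownie_fit <- function(x, ...) {
  cat("Brownian-motion fit:", length(x$sigma2), "rate regime(s)\n")
  print(round(x$sigma2, 6))
  cat("  root:", format(x$root_state, digits = 6),
      " log-likelihood:", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

# per-regime relative covariance matrices from a painted map:
# C_r[i, j] = shared path length spent in regime r
regime_covariance <- function(tree, state_map, grouping) {
  stopifnot(inherits(state_map, "state_map"))
  n_tip <- length(tree$tip.label)
  states <- state_map$states
  regimes <- unique(unname(grouping[states]))
  desc <- edge_tip_descendants(tree)
  out <- lapply(regimes, function(r) {
    matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  })
  names(out) <- regimes
  est <- state_map$edge_state_times
  for (i in seq_len(nrow(tree$edge))) {
    d <- desc[[i]]
    for (s in seq_along(states)) {
      if (est[i, s] > 0) {
        r <- grouping[[states[s]]]
        out[[r]][d, d] <- out[[r]][d, d] + est[i, s]
      }
    }
  }
  out
}

# log-likelihood of a multirate BM at given per-regime rates (used by the
# brute-force oracle tests as the implementation route)
bm_multirate_loglik <- function(tree, tip_values, state_map, sigma2_by_regime,
                                root_state,
                                grouping = setNames(state_map$states,
                                                    state_map$states)) {
  x <- align_tip_values(tree, tip_values)
  Cr <- regime_covariance(tree, state_map, grouping)
  V <- Reduce(`+`, lapply(names(Cr), function(r) sigma2_by_regime[[r]] * Cr[[r]]))
  mvn_phylo_loglik(x, V, root_state)
}

#' Fit state-dependent (multi-rate) Brownian motion
#'
#' Given a stochastic map painting every branch with discrete states, fits
#' one Brownian rate per regime (a regime is a group of states). The rate of
#' the first regime and the root state are profiled analytically; the
#' remaining rate ratios are optimized on the log scale.
#'
#' @param tree a `"phylo"` object.
#' @param tip_values named numeric trait vector.
#' @param state_map a `"state_map"` painting all branches.
#' @param grouping named character vector mapping map states to regime
#'   labels; defaults to one regime per state. Regimes with zero mapped
#'   branch length are dropped with a warning.
#' @return a `"brownie_fit"` with one `sigma2` entry per retained regime.
#' @export
fit_bm_multirate <- function(tree, tip_values, state_map,
                             grouping = setNames(state_map$states,
                                                 state_map$states)) {
  x <- align_tip_values(tree, tip_values)
  miss <- setdiff(state_map$states, names(grouping))
  if (length(miss)) stop("grouping missing states: ", paste(miss, collapse = ", "))
  Cr <- regime_covariance(tree, state_map, grouping)
  tot <- vapply(Cr, function(M) sum(diag(M)), numeric(1))
  if (any(tot == 0)) {
    warning("regime(s) with zero mapped branch length dropped: ",
            paste(names(Cr)[tot == 0], collapse = ", "))
    Cr <- Cr[tot > 0]
  }
  R <- length(Cr)
  if (R == 1L) {
    f <- fit_bm_fixed_cov(x, Cr[[1L]])
    fit <- structure(list(sigma2 = setNames(f$sigma2, names(Cr)),
                          root_state = f$mu, loglik = f$loglik,
                          regimes = names(Cr), convergence = 0L),
                     class = "brownie_fit")
    return(fit)
  }
  nll <- function(logratio) {
    V <- Cr[[1L]]
    for (r in 2:R) V <- V + exp(logratio[r - 1L]) * Cr[[r]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    -gls_profile(x, ch)$loglik
  }
  o <- if (R == 2L) {
    optim(0, nll, method = "Brent", lower = -20, upper = 20,
          control = list(reltol = 1e-12))
  } else {
    best <- NULL
    for (st in list(rep(0, R - 1L), rep(1, R - 1L), rep(-1, R - 1L))) {
      oo <- optim(st, nll, method = "Nelder-Mead",
                  control = list(maxit = 2000L, reltol = 1e-10))
      if (is.null(best) || oo$value < best$value) best <- oo
    }
    best
  }
  ratios <- c(1, exp(o$par))
  V <- Cr[[1L]]
  for (r in 2:R) V <- V + ratios[r] * Cr[[r]]
  g <- gls_profile(x, chol(V))
  structure(list(sigma2 = setNames(g$sigma2 * ratios, names(Cr)),
                 root_state = g$mu, loglik = g$loglik,
                 regimes = names(Cr), convergence = o$convergence),
            class = "brownie_fit")
}

fit_bm_fixed_cov <- function(x, C) {
  g <- gls_profile(x, chol(C))
  g
}

#' Chi-square comparison of two model log-likelihoods
#'
#' Upper-tail chi-square probability of twice the log-likelihood
#' difference; negative statistics (ensemble noise) are clipped to zero
#' with a warning.
#'
#' @param ll_simple,ll_complex log-likelihoods of the nested and the richer
#'   model (for the ensemble test, the mean over maps).
#' @param df degrees of freedom (number of extra rates).
#' @return the p-value.
#' @export
chi_square_compare <- function(ll_simple, ll_complex, df) {
  stopifnot(df >= 1)
  stat <- 2 * (ll_complex - ll_simple)
  if (stat < 0) {
    warning("complex model has lower mean log-likelihood; statistic clipped to 0")
    stat <- 0
  }
  pchisq(stat, df, lower.tail = FALSE)
}

#' Ensemble rate test (Brownie test)
#'
#' Fits the multi-rate Brownian model on every stochastic map in an
#' ensemble, averages the maximized log-likelihoods, and compares the mean
#' against the (map-independent) single-rate log-likelihood with a
#' chi-square test on `#regimes - 1` degrees of freedom. Per-map rate
#' estimates are retained for rate-distribution summaries.
#'
#' @param tree a `"phylo"` object.
#' @param tip_values named numeric trait vector.
#' @param ensemble a `"state_map_ensemble"` on the same tree.
#' @param grouping named character vector mapping map states to regimes.
#' @return an object of class `"ensemble_rate_test"` with the mean
#'   multi-rate log-likelihood, the single-rate log-likelihood, `df`,
#'   `statistic`, `p_value`, and a matrix `rates` of per-map estimates.
#' @export
ensemble_rate_test <- function(tree, tip_values, ensemble,
                               grouping = NULL) {
  stopifnot(inherits(ensemble, "state_map_ensemble"),
            length(ensemble$maps) >= 1L)
  x <- align_tip_values(tree, tip_values)
  if (is.null(grouping)) {
    grouping <- setNames(ensemble$states, ensemble$states)
  }
  single <- fit_bm(tree, x)
  regimes <- unique(unname(grouping[ensemble$states]))
  fits <- lapply(ensemble$maps, function(m) {
    tryCatch(fit_bm_multirate(tree, x, m, grouping), error = function(e) NULL)
  })
  failed <- vapply(fits, is.null, logical(1))
  if (mean(failed) > 0.05) {
    stop("more than 5% of per-map fits failed (",
         sum(failed), "/", length(fits), ")")
  }
  fits <- fits[!failed]
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  rates <- t(vapply(fits, function(f) {
    out <- setNames(rep(NA_real_, length(regimes)), regimes)
    out[names(f$sigma2)] <- f$sigma2
    out
  }, numeric(length(regimes))))
  df <- length(regimes) - 1L
  mean_ll <- mean(lls)
  stat <- max(0, 2 * (mean_ll - single$loglik))
  structure(list(
    mean_loglik_multirate = mean_ll,
    loglik_single = single$loglik,
    df = df,
    statistic = stat,
    p_value = if (df >= 1L) pchisq(stat, df, lower.tail = FALSE) else 1,
    rates = rates,
    sigma2_single = single$sigma2[["all"]],
    n_maps = length(ensemble$maps),
    n_failed = sum(failed)
  ), class = "ensemble_rate_test")
}

#' @export
print.ensemble_rate_test <- function(x, ...) {
  cat("Ensemble rate test over", x$n_maps, "maps (", x$n_failed, "failed )\n")
  cat("  one-rate LL:", format(x$loglik_single, digits = 8),
      " mean multi-rate LL:", format(x$mean_loglik_multirate, digits = 8), "\n")
  cat("  chi-square df =", x$df, " p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
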