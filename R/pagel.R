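# Pagel's correlated-evolution test for pairs of binary traits: dependent
# (8-rate) versus independent (4-rate) 4-state CTMCs, an exhaustive
# threshold sweep over a continuous trait, and binned rate summaries.

PAIR_STATES <- c("00", "01", "10", "11")

# ceiling on fitted transition rates (per unit branch length): thresholds
# that leave a combined state unobserved make some rates unidentifiable
# (the likelihood is flat upward in them); reported rates are capped here
# so run averages stay interpretable
RATE_CAP <- 1e3
# directed single-change transitions on the combined state space; dual
# transitions (both traits at once) are structural zeros
PAIR_MOVES <- matrix(c(
  "00", "10",  # trait1 gain  when trait2 = 0
  "01", "11",  # trait1 gain  when trait2 = 1
  "10", "00",  # trait1 loss  when trait2 = 0
  "11", "01",  # trait1 loss  when trait2 = 1
  "00", "01",  # trait2 gain  when trait1 = 0
  "10", "11",  # trait2 gain  when trait1 = 1
  "01", "00",  # trait2 loss  when trait1 = 0
  "11", "10"   # trait2 loss  when trait1 = 1
), ncol = 2, byrow = TRUE,
  dimnames = list(c("q1_gain.2is0", "q1_gain.2is1", "q1_loss.2is0",
                    "q1_loss.2is1", "q2_gain.1is0", "q2_gain.1is1",
                    "q2_loss.1is0", "q2_loss.1is1"), c("from", "to")))

#' Dependent (correlated-evolution) model for a binary trait pair
#'
#' Eight free transition rates on the combined state space {00, 01, 10, 11}
#' (trait1 then trait2): each trait's gain and loss rate may depend on the
#' current state of the other trait. Simultaneous changes of both traits
#' are forbidden (structural zeros).
#'
#' @param rates named (or ordered) vector of 8 non-negative rates, in the
#'   order of `rownames(songphylo:::PAIR_MOVES)`.
#' @param prior root prior over the 4 combined states (default uniform).
#' @return an `"mk_model"` on the 4 combined states.
#' @export
dependent_model <- function(rates, prior = NULL) {
  stopifnot(length(rates) == 8L, all(rates >= 0))
  Q <- matrix(0, 4, 4, dimnames = list(PAIR_STATES, PAIR_STATES))
  for (i in 1:8) Q[PAIR_MOVES[i, 1], PAIR_MOVES[i, 2]] <- rates[i]
  diag(Q) <- -rowSums(Q)
  mk_model(Q, PAIR_STATES, prior)
}

#' Independent-evolution model for a binary trait pair
#'
#' The 4-state chain induced by two independent binary Markov chains:
#' trait1 gain/loss and trait2 gain/loss rates are shared across the other
#' trait's states (4 free rates; nested in [dependent_model()] by four
#' equality constraints).
#'
#' @param rates vector of 4 non-negative rates: trait1 gain, trait1 loss,
#'   trait2 gain, trait2 loss.
#' @param prior root prior over the 4 combined states (default uniform).
#' @return an `"mk_model"` on the 4 combined states.
#' @export
independent_model <- function(rates, prior = NULL) {
  stopifnot(length(rates) == 4L, all(rates >= 0))
  dependent_model(c(rates[1], rates[1], rates[2], rates[2],
                    rates[3], rates[3], rates[4], rates[4]), prior)
}

# paired tip states -> character vector over PAIR_STATES
pair_tip_states <- function(trait1, trait2) {
  stopifnot(length(trait1) == length(trait2))
  to01 <- function(x) {
    if (is.numeric(x)) x <- as.character(x)
    u <- sort(unique(x[!is.na(x)]))
    if (length(u) > 2L) stop("trait is not binary: ", paste(u, collapse = ", "))
    out <- ifelse(is.na(x), NA_character_, ifelse(x == u[length(u)], "1", "0"))
    out
  }
  a <- to01(trait1); b <- to01(trait2)
  out <- ifelse(is.na(a) | is.na(b), NA_character_, paste0(a, b))
  names(out) <- names(trait1)
  out
}

#' Log-likelihood of a binary trait pair under a 4-state model
#'
#' Mk pruning on the combined chain; for an independent model this equals
#' the sum of the two separate 2-state log-likelihoods at the same rates.
#'
#' @param tree a `"phylo"` object.
#' @param paired_tip_states named character vector over
#'   `c("00","01","10","11")` (or build one with the `trait1`/`trait2`
#'   pair via `songphylo:::pair_tip_states`).
#' @param model an `"mk_model"` on the 4 combined states.
#' @return the log-likelihood.
#' @export
pagel_loglik <- function(tree, paired_tip_states, model) {
  stopifnot(identical(model$states, PAIR_STATES))
  mk_loglik(tree, paired_tip_states, model)
}

# one ML attempt for the independent model: two 2-state ARD fits (their
# log-likelihoods add); start controls the random initialization
fit_independent_once <- function(ed1, ed2, depth) {
  # ed*: list(edge, elen, n_node, tipL) for each trait
  fit2 <- function(ed) {
    nll <- function(lp) {
      q <- pmin(exp(lp), RATE_CAP) # flat directions: cap unidentifiable rates
      Q <- matrix(c(-q[1], q[1], q[2], -q[2]), 2, 2, byrow = TRUE)
      ll <- cpp_mk_loglik(ed$edge, ed$elen, Q, ed$tipL, c(0.5, 0.5), ed$n_node)
      if (!is.finite(ll)) 1e10 else -ll
    }
    st <- log(10^runif(2, -3, 2) / depth)
    o1 <- optim(st, nll, method = "Nelder-Mead",
                control = list(maxit = 2000L, reltol = 1e-8))
    o2 <- optim(rep(log(1 / depth), 2), nll, method = "Nelder-Mead",
                control = list(maxit = 2000L, reltol = 1e-8))
    o <- if (o1$value < o2$value) o1 else o2
    list(rates = exp(o$par), loglik = -o$value)
  }
  f1 <- fit2(ed1); f2 <- fit2(ed2)
  list(rates = c(f1$rates, f2$rates), loglik = f1$loglik + f2$loglik)
}

#' Fit Pagel's dependent and independent models with a likelihood-ratio test
#'
#' Each "run" is one random-restart maximum-likelihood attempt for both
#' models (the dependent optimization is additionally started from the
#' fitted independent rates, which enforces the nesting inequality), with
#' every run recorded separately; run-to-run variability mirrors the
#' optimizer multimodality of the 8-rate surface. The LR statistic
#' `2 (LL_dep - LL_indep)` is referred to chi-square with 4 df.
#'
#' @param tree a `"phylo"` object.
#' @param trait1,trait2 named binary tip vectors (two levels each; NA
#'   allowed, those tips are treated as missing data).
#' @param n_runs number of independent restart runs (default 1).
#' @param seed optional integer seed.
#' @return an object of class `"pagel_fit"`: `runs` (one row per run:
#'   log-likelihoods, LR statistic, p, 8 dependent rates), `best`
#'   (models/log-likelihoods of the best run), `p_value` of the best run,
#'   and `percent_significant` across runs at p < 0.05.
#' @export
fit_pagel_pair <- function(tree, trait1, trait2, n_runs = 1L, seed = NULL) {
  validate_phylogeny(tree)
  if (!is.null(seed)) set.seed(seed)
  pair <- pair_tip_states(trait1[tree$tip.label], trait2[tree$tip.label])
  names(pair) <- tree$tip.label
  obs <- pair[!is.na(pair)]
  if (length(unique(substr(obs, 1, 1))) < 2L ||
      length(unique(substr(obs, 2, 2))) < 2L) {
    stop("both traits must vary across tips")
  }
  ed <- postorder_edge_data(tree)
  depth <- max(node_depths(tree))
  x4 <- align_tip_states(tree, pair, PAIR_STATES)
  tipL4 <- tip_state_matrix(tree, x4)
  mk1 <- function(which) {
    s <- substr(pair, which, which)
    f <- align_tip_states(tree, setNames(s, tree$tip.label), c("0", "1"))
    c(ed, list(tipL = tip_state_matrix(tree, f)))
  }
  ed1 <- mk1(1); ed2 <- mk1(2)
  prior4 <- rep(0.25, 4)

  dep_nll <- function(lp) {
    Q <- matrix(0, 4, 4, dimnames = list(PAIR_STATES, PAIR_STATES))
    r <- pmin(exp(lp), RATE_CAP)
    for (i in 1:8) Q[PAIR_MOVES[i, 1], PAIR_MOVES[i, 2]] <- r[i]
    diag(Q) <- -rowSums(Q)
    ll <- cpp_mk_loglik(ed$edge, ed$elen, Q, tipL4, prior4, ed$n_node)
    if (!is.finite(ll)) 1e10 else -ll
  }

  runs <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    ind <- fit_independent_once(ed1, ed2, depth)
    # dependent: start from independent optimum and from a random draw
    st_ind <- log(pmax(c(ind$rates[1], ind$rates[1], ind$rates[2],
                         ind$rates[2], ind$rates[3], ind$rates[3],
                         ind$rates[4], ind$rates[4]), 1e-8))
    st_rnd <- log(10^runif(8, -3, 2) / depth)
    best <- NULL
    for (st in list(st_ind, st_rnd)) {
      o <- optim(st, dep_nll, method = "Nelder-Mead",
                 control = list(maxit = 2500L, reltol = 1e-8))
      if (is.null(best) || o$value < best$value) best <- o
    }
    ll_dep <- -best$value
    if (ll_dep < ind$loglik - 1e-6) {
      stop("dependent model log-likelihood below independent model's ",
           "(nesting violated): ", ll_dep, " < ", ind$loglik)
    }
    stat <- max(0, 2 * (ll_dep - ind$loglik))
    runs[[run]] <- c(run = run, ll_indep = ind$loglik, ll_dep = ll_dep,
                     statistic = stat,
                     p_value = pchisq(stat, 4, lower.tail = FALSE),
                     setNames(pmin(exp(best$par), RATE_CAP),
                              rownames(PAIR_MOVES)),
                     setNames(pmin(ind$rates, RATE_CAP),
                              c("i1_gain", "i1_loss", "i2_gain", "i2_loss")))
  }
  runs <- as.data.frame(do.call(rbind, runs))
  ibest <- which.max(runs$ll_dep)
  structure(list(
    runs = runs,
    best = list(
      dependent = dependent_model(unlist(runs[ibest, rownames(PAIR_MOVES)])),
      independent = independent_model(unlist(
        runs[ibest, c("i1_gain", "i1_loss", "i2_gain", "i2_loss")])),
      ll_dep = runs$ll_dep[ibest], ll_indep = runs$ll_indep[ibest]
    ),
    statistic = runs$statistic[ibest],
    df = 4L,
    p_value = runs$p_value[ibest],
    percent_significant = 100 * mean(runs$p_value < 0.05),
    n_tips_used = length(obs)
  ), class = "pagel_fit")
}

#' @export
print.pagel_fit <- function(x, ...) {
  cat("Pagel correlated-evolution test (", nrow(x$runs), "run(s) )\n")
  cat("  best run: LL_indep =", format(x$best$ll_indep, digits = 7),
      " LL_dep =", format(x$best$ll_dep, digits = 7), "\n")
  cat("  LR =", format(x$statistic, digits = 5), " df = 4  p =",
      format(x$p_value, digits = 4), "\n")
  cat("  runs significant at 0.05:", x$percent_significant, "%\n")
  invisible(x)
}

#' Exhaustive threshold sweep of a continuous trait against learning state
#'
#' Every unique observed trait value is used in turn as the threshold
#' splitting species into low/high (strictly greater = high); degenerate
#' thresholds (an empty class) are skipped. At each retained threshold the
#' Pagel test is repeated `runs_per_threshold` times with distinct restart
#' seeds derived from the threshold index and run index (so results do not
#' depend on species input order).
#'
#' @param tree a `"phylo"` object.
#' @param learning_states named binary vector (e.g. stable/plastic).
#' @param trait_values named numeric trait vector (complete for included
#'   tips; tips missing either variable are dropped).
#' @param runs_per_threshold runs at each threshold (paper-scale: 100).
#' @param seed master seed.
#' @return an object of class `"sweep_result"`: `runs` (long data frame:
#'   threshold, run, log-likelihoods, p, 8 dependent rates) and
#'   `thresholds` (values swept, with skipped degenerate ones noted).
#' @export
threshold_sweep <- function(tree, learning_states, trait_values,
                            runs_per_threshold = 100L, seed = 1L) {
  stopifnot(runs_per_threshold >= 1L)
  sp <- intersect(names(learning_states)[!is.na(learning_states)],
                  names(trait_values)[is.finite(trait_values)])
  sp <- intersect(tree$tip.label, sp)
  if (length(sp) < 4L) stop("fewer than 4 species with both variables")
  tr <- prune_to_taxa(tree, sp)
  lw <- learning_states[sp]
  tv <- trait_values[sp]

  uniq <- sort(unique(tv))
  rows <- list(); skipped <- numeric(0)
  for (ti in seq_along(uniq)) {
    bin <- binarize_by_threshold(tv, uniq[ti])
    if (attr(bin, "degenerate")) { skipped <- c(skipped, uniq[ti]); next }
    for (run in seq_len(runs_per_threshold)) {
      f <- fit_pagel_pair(tr, lw, bin, n_runs = 1L,
                          seed = derive_seed(seed, paste0("thr", ti, "run", run)))
      r <- f$runs[1, ]
      r$run <- run
      rows[[length(rows) + 1L]] <- cbind(threshold = uniq[ti], r)
    }
  }
  if (!length(rows)) stop("all thresholds degenerate")
  structure(list(
    runs = do.call(rbind, rows),
    thresholds = setdiff(uniq, skipped),
    skipped = skipped,
    runs_per_threshold = runs_per_threshold,
    n_species = length(sp),
    seed = seed
  ), class = "sweep_result")
}

# contiguous bin sizes: earlier (lower) bins absorb the remainder
bin_sizes <- function(n, n_bins) {
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Summarize a threshold sweep into bins
#'
#' Thresholds are partitioned by their position in the sorted unique trait
#' values into `n_bins` contiguous bins (default three: low, middle, high
#' thirds; remainders go to the lower bins). Per bin: the mean of each of
#' the eight dependent-model transition rates across all runs of all member
#' thresholds with a percentile-bootstrap 95% CI, and the mean per-threshold
#' percentage of runs significant at p < 0.05.
#'
#' @param sweep a `"sweep_result"`.
#' @param n_bins number of bins, 2 to 5 (default 3).
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @param seed seed for the bootstrap.
#' @return a data frame with one row per bin per rate plus a
#'   `percent_significant` summary attribute (also returned as the
#'   `bins` element of the list result).
#' @export
summarize_sweep <- function(sweep, n_bins = 3L, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(sweep, "sweep_result"), n_bins %in% 2:5)
  thr <- sweep$thresholds
  if (n_bins > length(thr)) stop("more bins than thresholds")
  sizes <- bin_sizes(length(thr), n_bins)
  bin_of <- rep(seq_len(n_bins), sizes)
  names(bin_of) <- as.character(thr)
  runs <- sweep$runs
  runs$bin <- bin_of[as.character(runs$threshold)]
  set.seed(seed)

  rate_cols <- rownames(PAIR_MOVES)
  rate_rows <- list(); bin_rows <- list()
  for (b in seq_len(n_bins)) {
    rb <- runs[runs$bin == b, , drop = FALSE]
    # mean percent significant: per-threshold percent, averaged over
    # member thresholds
    psig <- tapply(rb$p_value < 0.05, rb$threshold, mean) * 100
    bin_rows[[b]] <- data.frame(
      bin = b, n_thresholds = sizes[b], n_runs = nrow(rb),
      percent_significant = mean(psig)
    )
    for (rc in rate_cols) {
      v <- rb[[rc]]
      bs <- replicate(n_boot, mean(sample(v, replace = TRUE)))
      ci <- quantile(bs, c(0.025, 0.975), names = FALSE)
      rate_rows[[length(rate_rows) + 1L]] <- data.frame(
        bin = b, rate = rc, mean = mean(v), ci_lower = ci[1], ci_upper = ci[2]
      )
    }
  }
  list(rates = do.call(rbind, rate_rows),
       bins = do.call(rbind, bin_rows),
       n_bins = n_bins)
}

#' Pagel test of learning state against an already-binary trait
#'
#' Same machinery as [fit_pagel_pair()] with `runs` restarts, for traits
#' that need no threshold (social mating system, EPP class); species with
#' missing values are dropped. Reports the percent of runs significant and
#' the mean fitted rates across runs.
#'
#' @param tree a `"phylo"` object.
#' @param learning_states named binary vector.
#' @param binary_trait named binary vector (two levels; NA dropped).
#' @param runs number of runs (paper-scale: 1000).
#' @param seed master seed.
#' @return a `"pagel_fit"` augmented with `mean_rates` across runs.
#' @export
run_pagel_binary <- function(tree, learning_states, binary_trait,
                             runs = 1000L, seed = 1L) {
  sp <- intersect(names(learning_states)[!is.na(learning_states)],
                  names(binary_trait)[!is.na(binary_trait)])
  sp <- intersect(tree$tip.label, sp)
  if (length(sp) < 4L) stop("fewer than 4 species with both traits")
  if (length(unique(binary_trait[sp])) < 2L) {
    stop("binary trait is constant across the included species")
  }
  tr <- prune_to_taxa(tree, sp)
  fit <- fit_pagel_pair(tr, learning_states[sp], binary_trait[sp],
                        n_runs = runs, seed = seed)
  fit$mean_rates <- colMeans(fit$runs[, rownames(PAIR_MOVES)])
  fit
}
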