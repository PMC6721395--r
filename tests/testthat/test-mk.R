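test_that("transition probabilities match the two-state closed form", {
  m <- mk_er_model(c("0", "1"), 0.5)
  expect_equal(transition_probability(m, 0), diag(2),
               ignore_attr = TRUE, tolerance = 1e-12)
  P <- transition_probability(m, 1)
  expect_equal(P[1, 2], 0.5 * (1 - exp(-2 * 0.5 * 1)), tolerance = 1e-10)
  expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-10)
  Pbig <- transition_probability(m, 500)
  expect_equal(as.vector(Pbig), rep(0.5, 4), tolerance = 1e-8)
  expect_error(transition_probability(m, -1), ">= 0")

  # general-Q transition matrices agree with the series expm
  for (seed in 1:3) {
    Q <- rand_Q(3, seed)
    m3 <- mk_model(Q)
    for (t in c(0.1, 0.7, 2)) {
      expect_equal(transition_probability(m3, t), expm_oracle(Q, t),
                   ignore_attr = TRUE, tolerance = 1e-9)
    }
  }
})

test_that("pruning log-likelihood matches closed forms and brute force", {
  tr <- parse_newick("(A:1,B:1);")
  m <- mk_er_model(c("0", "1"), 0.5)
  P <- expm_oracle(m$Q, 1)
  expect_equal(mk_loglik(tr, c(A = "0", B = "1"), m),
               log(sum(0.5 * P[, 1] * P[, 2])), tolerance = 1e-10)
  # closed form: 2 * 0.5 * P00(1) * P01(1) with P01 = (1 - e^-1)/2
  expect_equal(mk_loglik(tr, c(A = "0", B = "1"), m),
               log(2 * 0.5 * (1 + exp(-1)) / 2 * (1 - exp(-1)) / 2),
               tolerance = 1e-10)

  m0 <- mk_er_model(c("0", "1"), 0)
  expect_equal(mk_loglik(tr, c(A = "0", B = "0"), m0), log(0.5),
               tolerance = 1e-12)

  # brute-force enumeration over internal states, k = 2 and 3, <= 6 tips
  for (seed in 1:4) {
    for (k in 2:3) {
      n <- sample(4:6, 1)
      tr <- rand_tree(n, seed * 10 + k)
      Q <- rand_Q(k, seed * 7 + k)
      m <- mk_model(Q)
      set.seed(seed)
      tips <- setNames(sample(m$states, n, replace = TRUE), tr$tip.label)
      if (length(unique(tips)) < 2) tips[1] <- setdiff(m$states, tips[1])[1]
      expect_equal(mk_loglik(tr, tips, m),
                   oracle_mk_loglik(tr, tips, Q, m$prior), tolerance = 1e-10)
    }
  }
})

test_that("impossible data return -Inf with a warning, not an error", {
  tr <- parse_newick("(A:1,B:1);")
  m0 <- mk_er_model(c("0", "1"), 0)
  expect_warning(ll <- mk_loglik(tr, c(A = "0", B = "1"), m0), "probability 0")
  expect_identical(ll, -Inf)
})

test_that("ML fitting respects nesting and boundary behavior", {
  tr <- simulate_yule(80, seed = 31)
  sim <- simulate_discrete(tr, mk_er_model(c("0", "1"), 1), seed = 32)
  er <- fit_mk(tr, sim$tip_states, "ER", restarts = 4, seed = 1)
  ard <- fit_mk(tr, sim$tip_states, "ARD", restarts = 4, seed = 2)
  expect_gte(ard$loglik, er$loglik - 1e-6)
  lrt <- mk_lrt(er, ard)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$p_value, 0)
  expect_lte(lrt$p_value, 1)

  # constant tips: rate to the zero boundary, LL = ln(prior of the state)
  const <- setNames(rep("0", 80), tr$tip.label)
  f0 <- fit_mk(tr, const, "ER", restarts = 2, seed = 3, states = c("0", "1"))
  expect_lt(f0$rates, 1e-6)
  expect_equal(f0$loglik, log(0.5), tolerance = 1e-4)
})

test_that("ER/ARD likelihood-ratio test is approximately chi-square under ER", {
  # the discrete-trait LRT is known to be mildly anticonservative at
  # realistic tree sizes (statistics agree with the reference
  # implementation to numerical precision, see next block), so the check
  # is approximate calibration, not an exact 5% rate
  tr <- simulate_yule(250, seed = 41)
  set.seed(42)
  out <- replicate(200, {
    sim <- simulate_discrete(tr, mk_er_model(c("0", "1"), 1),
                             seed = sample.int(1e6, 1))
    if (length(unique(sim$tip_states)) < 2) return(NA)
    er <- fit_mk(tr, sim$tip_states, "ER", restarts = 2,
                 seed = sample.int(1e6, 1))
    ard <- fit_mk(tr, sim$tip_states, "ARD", restarts = 2,
                  seed = sample.int(1e6, 1))
    suppressWarnings(mk_lrt(er, ard)$statistic) # rare clip at 0
  })
  out <- out[!is.na(out)]
  expect_gt(mean(out), 0.6)   # chi-square(1) mean is 1
  expect_lt(mean(out), 1.8)
  rej <- mean(out > qchisq(0.95, 1))
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.12)
})

test_that("Mk fits agree with the reference implementation (phytools)", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule(100, seed = 45)
  for (s in 1:3) {
    sim <- simulate_discrete(tr, mk_er_model(c("0", "1"), 1), seed = 45 + s)
    if (length(unique(sim$tip_states)) < 2) next
    er <- fit_mk(tr, sim$tip_states, "ER", restarts = 2, seed = s)
    ard <- fit_mk(tr, sim$tip_states, "ARD", restarts = 2, seed = s)
    x <- setNames(factor(sim$tip_states), names(sim$tip_states))
    fe <- phytools::fitMk(tr, x, model = "ER", pi = "equal")
    fa <- phytools::fitMk(tr, x, model = "ARD", pi = "equal")
    expect_equal(er$loglik, as.numeric(logLik(fe)), tolerance = 1e-5)
    expect_equal(ard$loglik, as.numeric(logLik(fa)), tolerance = 1e-5)
  }
})

test_that("ancestral marginals are proper, symmetric, and match enumeration", {
  tr <- parse_newick("(A:1,B:1);")
  m <- mk_er_model(c("0", "1"), 0.5)
  f <- fit_mk(tr, c(A = "0", B = "1"), "ER", restarts = 2, seed = 1)
  marg <- ancestral_marginals(f)
  expect_equal(unname(marg[1, ]), c(0.5, 0.5), tolerance = 1e-9)

  for (seed in 1:3) {
    n <- 5
    tr <- rand_tree(n, seed + 50)
    Q <- rand_Q(2, seed + 60)
    set.seed(seed)
    tips <- setNames(sample(c("0", "1"), n, replace = TRUE), tr$tip.label)
    tips[1] <- "0"; tips[2] <- "1"
    f <- fit_mk(tr, tips, "ER", restarts = 2, seed = seed)
    f$model <- mk_model(Q, prior = f$model$prior) # evaluate at a fixed Q
    marg <- ancestral_marginals(f)
    expect_equal(unname(rowSums(marg)), rep(1, nrow(marg)), tolerance = 1e-9)
    expect_equal(unname(marg),
                 unname(oracle_mk_marginals(tr, tips, Q, f$model$prior)),
                 tolerance = 1e-9)
  }
})

test_that("stochastic maps are reproducible, tip-consistent, and countable", {
  tr <- simulate_yule(40, seed = 71)
  sim <- simulate_discrete(tr, mk_er_model(c("0", "1"), 0.8), seed = 72)
  f <- fit_mk(tr, sim$tip_states, "ER", restarts = 2, seed = 1)

  e1 <- sample_stochastic_maps(f, 20, seed = 99)
  e2 <- sample_stochastic_maps(f, 20, seed = 99)
  expect_identical(e1$maps, e2$maps)

  for (map in e1$maps[1:5]) {
    # per-branch durations sum to branch lengths
    for (i in seq_along(map$edge_segments)) {
      expect_equal(sum(map$edge_segments[[i]][, 2]), tr$edge.length[i],
                   tolerance = 1e-9)
      s <- map$edge_segments[[i]][, 1]
      if (length(s) > 1) expect_true(all(diff(s) != 0))
    }
    # tip-end states equal observed tip states
    tip_end <- vapply(seq_along(tr$tip.label), function(t) {
      i <- which(tr$edge[, 2] == t)
      br <- map$edge_segments[[i]]
      map$states[br[nrow(br), 1]]
    }, "")
    expect_identical(tip_end, unname(sim$tip_states[tr$tip.label]))
    # directed counts re-derived by an independent segment walk
    ct <- count_transitions(map)
    recount <- sum(vapply(map$edge_segments, function(br) nrow(br) - 1L,
                          integer(1)))
    expect_identical(ct$total, recount)
    expect_identical(sum(ct$directed), ct$total)
  }
})

test_that("near-zero rates with uniform tips give transition-free maps", {
  tr <- simulate_yule(20, seed = 81)
  const <- setNames(rep("0", 20), tr$tip.label)
  f <- fit_mk(tr, const, "ER", restarts = 2, seed = 1, states = c("0", "1"))
  ens <- sample_stochastic_maps(f, 20, seed = 5)
  expect_equal(minimum_transitions(ens)$minimum, 0)
})

test_that("minimum transitions respects the parsimony bound", {
  tr2 <- parse_newick("(A:1,B:1);")
  f2 <- fit_mk(tr2, c(A = "0", B = "1"), "ER", restarts = 2, seed = 1)
  f2$model <- mk_er_model(c("0", "1"), 0.5) # moderate fixed rate
  ens2 <- sample_stochastic_maps(f2, 50, seed = 6)
  expect_true(all(minimum_transitions(ens2)$totals >= 1))
  expect_equal(minimum_transitions(ens2)$minimum, 1)

  # 40-tip dataset with a sparse true history: every map's count is at
  # least the Fitch count, and the ensemble minimum attains it
  tr <- simulate_yule(40, seed = 91)
  repeat {
    sim <- simulate_discrete(tr, mk_er_model(c("0", "1"), 0.6), seed = 92)
    if (length(unique(sim$tip_states)) == 2) break
  }
  fc <- fitch_count(tr, sim$tip_states)
  f <- fit_mk(tr, sim$tip_states, "ER", restarts = 2, seed = 1)
  ens <- sample_stochastic_maps(f, 200, seed = 7)
  mt <- minimum_transitions(ens)
  expect_true(all(mt$totals >= fc))
  expect_equal(mt$minimum, fc)
  expect_identical(sum(mt$directed), as.integer(mt$minimum))

  # minimum is non-increasing in ensemble size
  sub <- structure(list(maps = ens$maps[1:50], tree = ens$tree,
                        states = ens$states), class = "state_map_ensemble")
  expect_gte(minimum_transitions(sub)$minimum, mt$minimum)
})

test_that("root marginals equal prior-weighted root conditionals", {
  tr <- rand_tree(6, 101)
  set.seed(102)
  tips <- setNames(sample(c("0", "1"), 6, replace = TRUE), tr$tip.label)
  tips[1:2] <- c("0", "1")
  f <- fit_mk(tr, tips, "ER", restarts = 2, seed = 1)
  marg <- ancestral_marginals(f)
  ed <- songphylo:::postorder_edge_data(tr)
  cond <- songphylo:::cpp_mk_conditionals(
    ed$edge, ed$elen, f$model$Q,
    songphylo:::tip_state_matrix(tr, f$tip_states), f$model$prior, ed$n_node)
  w <- f$model$prior * cond$L[ed$root, ]
  expect_equal(unname(marg[as.character(ed$root), ]), w / sum(w),
               tolerance = 1e-9)
})

test_that("state maps serialize to a flat segment table", {
  tr <- simulate_yule(10, seed = 111)
  sim <- simulate_discrete(tr, mk_er_model(c("0", "1"), 1), seed = 112)
  tab <- state_map_table(sim$map)
  expect_true(all(c("edge", "segment", "state", "duration") %in% names(tab)))
  agg <- tapply(tab$duration, tab$edge, sum)
  expect_equal(as.numeric(agg[as.character(seq_len(nrow(tr$edge)))]),
               tr$edge.length, tolerance = 1e-9)
})
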