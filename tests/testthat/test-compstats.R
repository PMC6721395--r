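test_that("ANOVA F matches hand computation and a two-pass oracle", {
  expect_equal(anova_f(c(0, 1, 2, 3), c("a", "a", "b", "b")), 8)
  expect_equal(anova_f(c(1, 2, 1, 2), c("a", "a", "b", "b")), 0)
  expect_identical(anova_f(c(1, 1, 2, 2), c("a", "a", "b", "b")), Inf)

  set.seed(1)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    g <- factor(sample(letters[1:3], n, replace = TRUE))
    if (nlevels(droplevels(g)) < 2) next
    x <- rnorm(n)
    f_pkg <- anova_f(x, g)
    f_aov <- unname(summary(aov(x ~ g))[[1]]$`F value`[1])
    expect_equal(f_pkg, f_aov, tolerance = 1e-10)
  }
})

test_that("observed F does not depend on the tree; only the p-value does", {
  tr <- simulate_yule(40, seed = 11)
  set.seed(12)
  x <- setNames(rnorm(40), tr$tip.label)
  g <- setNames(sample(c("a", "b"), 40, replace = TRUE), tr$tip.label)
  p1 <- phyl_anova(tr, x, g, n_sim = 200, seed = 1)
  tr2 <- simulate_yule(40, seed = 13)
  tr2$tip.label <- tr$tip.label
  p2 <- phyl_anova(tr2, x, g, n_sim = 200, seed = 1)
  expect_equal(p1$F, p2$F, tolerance = 1e-12)
  expect_equal(p1$F, anova_f(x, factor(g)), tolerance = 1e-12)
})

test_that("phylANOVA is deterministic under a fixed seed and detects shifts", {
  tr <- simulate_yule(50, seed = 21)
  set.seed(22)
  g <- setNames(rep(c("a", "b"), 25), tr$tip.label)
  C <- phylo_covariance(tr)
  x <- setNames(as.vector(crossprod(chol(C), rnorm(50))), tr$tip.label)
  shift <- 5 * sd(x)
  x[g == "b"] <- x[g == "b"] + shift
  r1 <- phyl_anova(tr, x, g, n_sim = 300, seed = 7)
  r2 <- phyl_anova(tr, x, g, n_sim = 300, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_lte(r1$p_value, 0.01)
  expect_gt(unname(r1$group_means["b"] - r1$group_means["a"]), shift / 2)
})

test_that("post-hoc pairwise tests are reported with Holm adjustment", {
  tr <- simulate_yule(45, seed = 31)
  set.seed(32)
  g <- setNames(sample(c("a", "b", "c"), 45, replace = TRUE), tr$tip.label)
  x <- setNames(rnorm(45), tr$tip.label)
  x[g == "c"] <- x[g == "c"] + 4
  r <- phyl_anova(tr, x, g, n_sim = 200, seed = 1)
  expect_equal(nrow(r$posthoc), 3L)
  expect_true(all(r$posthoc$p_adjusted >= r$posthoc$p_value))
})

test_that("Holm ladder, flags and adjusted p-values are correct", {
  h <- holm(rep(0.001, 7))
  expect_equal(round(h$thresholds, 4),
               c(0.0071, 0.0083, 0.0100, 0.0125, 0.0167, 0.0250, 0.0500))
  expect_equal(holm(0.2)$corrected_alpha, 0.05)
  expect_equal(sum(holm(rep(1, 5))$significant), 0L)

  set.seed(41)
  for (i in 1:10) {
    p <- runif(sample(3:9, 1))
    h <- holm(p)
    expect_equal(h$p_adjusted, p.adjust(p, "holm"), tolerance = 1e-12)
    # Holm rejects a superset of Bonferroni, subset of unadjusted
    bonf <- p <= 0.05 / length(p)
    expect_true(all(h$significant[bonf]))
    expect_true(all(p[h$significant] <= 0.05))
  }

  # a wider declared family tightens every threshold
  h3 <- holm(c(0.001, 0.002, 0.003), family_size = 7)
  expect_equal(round(h3$corrected_alpha, 4), c(0.0071, 0.0083, 0.0100))
})

test_that("PGLS reduces to OLS at lambda 0 and to GLS at lambda 1", {
  tr <- simulate_yule(30, seed = 51)
  set.seed(52)
  x <- setNames(rnorm(30), tr$tip.label)
  C <- phylo_covariance(tr)
  y <- setNames(as.vector(crossprod(chol(C), rnorm(30))) + 0.8 * x,
                tr$tip.label)

  f0 <- fit_pgls(tr, y, x, lambda = 0)
  ols <- summary(lm(y[tr$tip.label] ~ x[tr$tip.label]))$coefficients
  expect_equal(f0$slope, ols[2, 1], tolerance = 1e-8)
  expect_equal(f0$se, ols[2, 2], tolerance = 1e-8)

  f1 <- fit_pgls(tr, y, x, lambda = 1)
  iC <- solve(C)
  X <- cbind(1, x[tr$tip.label])
  beta <- solve(t(X) %*% iC %*% X, t(X) %*% iC %*% y[tr$tip.label])
  expect_equal(f1$slope, beta[2], tolerance = 1e-8)
})

test_that("lambda-PGLS agrees with nlme::gls + corPagel at a fixed lambda", {
  skip_if_not_installed("nlme")
  tr <- simulate_yule(40, seed = 61)
  set.seed(62)
  x <- setNames(rnorm(40), tr$tip.label)
  C <- phylo_covariance(tr)
  y <- setNames(as.vector(crossprod(chol(C), rnorm(40))) + x, tr$tip.label)
  for (lam in c(0.3, 0.9)) {
    f <- fit_pgls(tr, y, x, lambda = lam)
    d <- data.frame(y = y[tr$tip.label], x = x[tr$tip.label],
                    sp = tr$tip.label)
    g <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corPagel(lam, tr, form = ~sp,
                                               fixed = TRUE),
                   method = "ML")
    sm <- summary(g)$tTable
    expect_equal(f$slope, sm["x", "Value"], tolerance = 1e-6)
    expect_equal(f$se, sm["x", "Std.Error"], tolerance = 1e-4)
    expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-4)
  }
})

test_that("profiled lambda recovers the generating lambda on average", {
  slopes <- numeric(0); lambdas <- numeric(0)
  for (r in 1:20) {
    tr <- simulate_yule(150, seed = 700 + r)
    set.seed(800 + r)
    x <- setNames(rnorm(150), tr$tip.label)
    C <- phylo_covariance(tr)
    lam_true <- 0.9
    V <- lam_true * C; diag(V) <- diag(C)
    e <- as.vector(crossprod(chol(V), rnorm(150))) * 0.8
    y <- setNames(0.9 * x + e, tr$tip.label)
    f <- fit_pgls(tr, y, x)
    slopes <- c(slopes, f$slope); lambdas <- c(lambdas, f$lambda)
  }
  expect_equal(mean(slopes), 0.9, tolerance = 0.15)
  expect_equal(mean(lambdas), 0.9, tolerance = 0.2)
})

test_that("lambda upper bound exceeds 1 when the tree allows it", {
  tr <- simulate_yule(30, seed = 71)
  C <- phylo_covariance(tr)
  lmax <- songphylo:::lambda_upper_bound(C)
  expect_gt(lmax, 1)
  ev <- eigen(songphylo:::lambda_cov(C, lmax), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(ev), -1e-6)
})

test_that("sister-pair rate scan finds cherries and planted signals", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 0, B = 2, C = 1, D = 1)
  expect_error(sister_pair_rate_scan(tr, x), "3 cherries")

  # null: BM data give correlations centered on zero
  hits <- 0L
  for (r in 1:30) {
    tr <- simulate_yule(60, seed = 900 + r)
    map1 <- simulate_discrete(tr, mk_er_model(c("s", "z"), 0), root_state = "s",
                              seed = r)$map
    x <- simulate_bm_regimes(tr, map1, c(s = 1, z = 1), seed = 950 + r)
    sc <- sister_pair_rate_scan(tr, x, n_perm = 199, seed = r)
    if (abs(sc$rho) < 0.5) hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.9)

  # degenerate: identical values in every pair
  tr <- simulate_yule(20, seed = 99)
  sc <- sister_pair_rate_scan(tr, setNames(rep(1, 20), tr$tip.label))
  expect_true(sc$degenerate)
  expect_true(is.na(sc$rho))

  # planted: doubled divergence on large-mean pairs yields positive rho
  det <- 0L
  for (r in 1:10) {
    tr <- simulate_yule(80, seed = 1000 + r)
    map1 <- simulate_discrete(tr, mk_er_model(c("s", "z"), 0), root_state = "s",
                              seed = r)$map
    x <- simulate_bm_regimes(tr, map1, c(s = 1, z = 1), seed = 1050 + r)
    sc0 <- sister_pair_rate_scan(tr, x, n_perm = 199, seed = r)
    big <- sc0$pairs$pair_mean > median(sc0$pairs$pair_mean)
    for (i in which(big)) {
      pair <- unlist(sc0$pairs[i, c("tip1", "tip2")])
      m <- mean(x[pair])
      x[pair] <- m + (x[pair] - m) * 4
    }
    sc1 <- sister_pair_rate_scan(tr, x, n_perm = 199, seed = r)
    if (sc1$rho > 0 && sc1$p_value < 0.05) det <- det + 1L
  }
  expect_gte(det, 8L)
})
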