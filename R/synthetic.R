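# Generators for phylogenies and trait data with the statistical structure
# the analyses assume: a Yule tree with family labels, learning states under
# an Mk process, log-scale song traits under state-dependent Brownian
# motion with state offsets, and mating traits under a dependent 4-state
# chain. Every generator is a pure function of (config, seed).

#' Configuration for the synthetic study dataset
#'
#' Defaults emulate the shape of the study data the analyses were designed
#' for: 67 species in 24 families on a unit-depth Yule tree; a binary
#' stable/plastic learning state evolving under a 2-state equal-rates
#' process; seven natural-log song traits under Brownian motion with
#' state-dependent group offsets (syllable-repertoire means near 1.88 for
#' song-stable and 3.95 for song-plastic species); and a
#' polygyny/high-EPP pair evolving under a dependent 4-state chain.
#'
#' @param n_species number of tips (default 67).
#' @param n_families minimum number of family labels cut from the tree
#'   (default 24).
#' @param birth_rate Yule birth rate (shape only; the tree is rescaled to
#'   unit depth).
#' @param learning_rate transition rate of the binary learning state per
#'   unit depth (default 1.0, giving on the order of 15 true transitions
#'   on a 67-tip unit-depth tree, the scale of the study's parsimony
#'   count).
#' @param sigma2 named per-state Brownian rates on the log-trait scale
#'   (default 1.0 for both states: equal-rate evolution, so planted group
#'   differences come from the state-dependent trend alone; together with
#'   the trend's across-lineage heterogeneity this puts the within-group
#'   SD near 1.2, the order implied by the study's printed F and means).
#' @param trait_offsets matrix (trait x state) of target group means on
#'   the log scale; the generator plants them as state-dependent drift
#'   whose mixing-corrected levels make the realized group means
#'   approximate these targets.
#' @param early_fraction fraction of song-stable species labelled early
#'   (vs delayed) in the ternary scheme (default 1/3).
#' @param missing_ternary_prob probability a species lacks the ternary
#'   coding (default 0.12, leaving roughly 59 of 67 species codable).
#' @param dependent_rates 8 rates of the mating-pair generator (order as
#'   in [dependent_model()]); defaults are moderately dependent.
#' @param missing_mating_prob,missing_epp_prob probabilities of missing
#'   mating-system / EPP data (defaults 0.15 and 0.40).
#' @param seed master seed.
#' @return a list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_species = 67L, n_families = 24L,
                             birth_rate = 1, learning_rate = 1.0,
                             sigma2 = c(stable = 1.0, plastic = 1.0),
                             trait_offsets = NULL,
                             early_fraction = 1 / 3,
                             missing_ternary_prob = 0.12,
                             dependent_rates = c(1, 1, 1, 1, 0.5, 2.5, 2.5, 0.5),
                             missing_mating_prob = 0.15,
                             missing_epp_prob = 0.40,
                             seed = 1L) {
  if (is.null(trait_offsets)) {
    trait_offsets <- rbind(
      syllable_repertoire = c(stable = 1.8807, plastic = 3.946),
      song_repertoire     = c(stable = 1.1055, plastic = 3.8688),
      syllables_per_song  = c(stable = 1.2556, plastic = 2.2962),
      duration_s          = c(stable = 0.7736, plastic = 1.2927),
      interval_s          = c(stable = 1.6075, plastic = 1.218)
    )
  }
  stopifnot(n_families <= n_species, learning_rate > 0, all(sigma2 > 0),
            all(dependent_rates >= 0), length(dependent_rates) == 8L)
  structure(list(
    n_species = as.integer(n_species), n_families = as.integer(n_families),
    birth_rate = birth_rate, learning_rate = learning_rate,
    sigma2 = sigma2, trait_offsets = trait_offsets,
    early_fraction = early_fraction,
    missing_ternary_prob = missing_ternary_prob,
    dependent_rates = dependent_rates,
    missing_mating_prob = missing_mating_prob,
    missing_epp_prob = missing_epp_prob,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' The tree is rescaled to unit root-to-tip depth; tips are labelled
#' `sp001, sp002, ...`.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed.
#' @param birth_rate birth rate of the pure-birth process.
#' @return a `"phylo"` object.
#' @export
simulate_yule <- function(n_tips, seed = 1L, birth_rate = 1) {
  stopifnot(n_tips >= 3L)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  depth <- max(node_depths(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  validate_phylogeny(tree)
  tree
}

#' Assign family labels by cutting a tree at a fixed depth
#'
#' Uses the shallowest cut depth at which at least `n_families` lineages
#' exist; every tip descending from the same lineage at the cut shares a
#' family label.
#'
#' @param tree an ultrametric `"phylo"` object.
#' @param n_families minimum number of families.
#' @return a named character vector (per tip) of family labels
#'   `fam01, fam02, ...`.
#' @export
assign_families <- function(tree, n_families) {
  ntip <- length(tree$tip.label)
  stopifnot(n_families <= ntip)
  depth <- node_depths(tree)
  # candidate cut depths: just after each internal-node depth
  cand <- sort(unique(depth[(ntip + 1):(ntip + tree$Nnode)]))
  lineages_at <- function(d) {
    sum(depth[tree$edge[, 1L]] <= d & depth[tree$edge[, 2L]] > d)
  }
  cut <- NA_real_
  for (d in cand) {
    dd <- d + 1e-9
    if (lineages_at(dd) >= n_families) { cut <- dd; break }
  }
  if (is.na(cut)) cut <- max(cand) + 1e-9 # fully resolved: tips are families
  # ancestor lineage of each tip at the cut depth
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  anc <- integer(ntip)
  for (t in seq_len(ntip)) {
    node <- t
    while (parent_of[node] != 0L && depth[parent_of[node]] > cut) {
      node <- parent_of[node]
    }
    anc[t] <- node
  }
  fam_ids <- as.integer(factor(anc, levels = unique(anc[order(tree$tip.label)])))
  setNames(sprintf("fam%02d", fam_ids), tree$tip.label)
}

#' Simulate a discrete character along a tree
#'
#' Exact branch-by-branch continuous-time simulation under a generator Q;
#' returns the tip states together with the true state history as a
#' `"state_map"`, so simulation-based tests can compare inferred against
#' true histories.
#'
#' @param tree a `"phylo"` object.
#' @param model an `"mk_model"` (the generator).
#' @param root_state state name at the root (default: drawn from the model
#'   prior).
#' @param seed integer seed.
#' @return a list with `tip_states` (named character) and `map`
#'   (`"state_map"`).
#' @export
simulate_discrete <- function(tree, model, root_state = NULL, seed = 1L) {
  stopifnot(inherits(model, "mk_model"))
  validate_phylogeny(tree)
  set.seed(seed)
  k <- model$k
  Q <- model$Q
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_state <- integer(ntip + tree$Nnode)
  node_state[root] <- if (is.null(root_state)) {
    sample.int(k, 1L, prob = model$prior)
  } else match(root_state, model$states)
  pr <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(pr$edge[, 1L], pr$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  segs <- vector("list", nrow(tree$edge))
  est <- matrix(0, nrow(tree$edge), k)
  for (i in seq_len(nrow(pr$edge))) {
    p <- pr$edge[i, 1L]; ch <- pr$edge[i, 2L]
    t_total <- pr$edge.length[i]
    s <- node_state[p]
    states <- integer(0); durs <- numeric(0)
    remaining <- t_total
    repeat {
      rate <- -Q[s, s]
      wait <- if (rate > 0) rexp(1, rate) else Inf
      if (wait >= remaining) {
        states <- c(states, s); durs <- c(durs, remaining)
        break
      }
      states <- c(states, s); durs <- c(durs, wait)
      remaining <- remaining - wait
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(k, 1L, prob = probs)
    }
    node_state[ch] <- s
    e <- ord[i]
    segs[[e]] <- cbind(state = states, duration = durs)
    est[e, ] <- vapply(seq_len(k), function(st) sum(durs[states == st]),
                       numeric(1))
  }
  map <- structure(list(edge_segments = segs, node_states = node_state,
                        edge_state_times = est, states = model$states),
                   class = "state_map")
  tips <- setNames(model$states[node_state[seq_len(ntip)]], tree$tip.label)
  list(tip_states = tips, map = map)
}

#' Simulate Brownian motion with state-dependent rates
#'
#' Gaussian increments per map segment with variance
#' `sigma2[state] * duration`, plus an optional additive offset by tip
#' state (to plant group-mean differences without touching the rates).
#'
#' @param tree a `"phylo"` object.
#' @param state_map a `"state_map"` painting all branches.
#' @param sigma2_by_state named per-state rates.
#' @param state_offsets named per-state additive tip offsets (default 0):
#'   a discrete jump applied at the tips by current state.
#' @param state_drift named per-state deterministic trend (trait units per
#'   unit branch length; default 0): each map segment shifts the lineage by
#'   `drift[state] * duration`, planting group-mean differences that accrue
#'   gradually along the painted history (directional evolution) instead of
#'   jumping at the tips.
#' @param root_value trait value at the root (default 0).
#' @param seed integer seed.
#' @return named numeric tip values.
#' @export
simulate_bm_regimes <- function(tree, state_map, sigma2_by_state,
                                state_offsets = NULL, state_drift = NULL,
                                root_value = 0, seed = 1L) {
  stopifnot(inherits(state_map, "state_map"))
  set.seed(seed)
  states <- state_map$states
  zero <- setNames(rep(0, length(states)), states)
  if (is.null(state_offsets)) state_offsets <- zero
  if (is.null(state_drift)) state_drift <- zero
  ntip <- length(tree$tip.label)
  val <- numeric(ntip + tree$Nnode)
  val[ntip + 1L] <- root_value
  pr <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(pr$edge[, 1L], pr$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (i in seq_len(nrow(pr$edge))) {
    p <- pr$edge[i, 1L]; ch <- pr$edge[i, 2L]
    br <- state_map$edge_segments[[ord[i]]]
    v <- sum(sigma2_by_state[states[br[, 1L]]] * br[, 2L])
    drift <- sum(state_drift[states[br[, 1L]]] * br[, 2L])
    val[ch] <- val[p] + drift + if (v > 0) rnorm(1, 0, sqrt(v)) else 0
  }
  tipstate <- states[state_map$node_states[seq_len(ntip)]]
  setNames(val[seq_len(ntip)] + unname(state_offsets[tipstate]),
           tree$tip.label)
}

#' Simulate a dependent pair of binary traits
#'
#' 4-state continuous-time simulation under a dependent generator; dual
#' transitions never occur (structural zeros).
#'
#' @param tree a `"phylo"` object.
#' @param rates8 8 rates in the order of [dependent_model()].
#' @param root_state combined root state (`"00"`, ..., default drawn from
#'   the uniform prior).
#' @param seed integer seed.
#' @return a list with `trait1`, `trait2` (named "0"/"1" vectors),
#'   `pair_states`, and the true `map`.
#' @export
simulate_dependent_pair <- function(tree, rates8, root_state = NULL,
                                    seed = 1L) {
  model <- dependent_model(rates8)
  sim <- simulate_discrete(tree, model, root_state, seed)
  list(trait1 = setNames(substr(sim$tip_states, 1, 1), names(sim$tip_states)),
       trait2 = setNames(substr(sim$tip_states, 2, 2), names(sim$tip_states)),
       pair_states = sim$tip_states, map = sim$map)
}

#' Generate a full synthetic study dataset
#'
#' Produces a tree, a species table with every column the analyses expect
#' (learning codings in all three schemes, per-study raw song-trait values
#' whose aggregates reproduce the planted log-scale traits, mating
#' fractions consistent with the simulated binary classes, family labels
#' from tree cuts) and the true generating histories, all as a pure
#' function of the config and its seed.
#'
#' @param config a `"synthetic_config"`.
#' @return a list of class `"synthetic_dataset"`: `tree`, `table` (data
#'   frame in the [read_species_table()] layout), `records`, `truth`
#'   (true learning map/states, trait values, mating map) and `config`.
#' @export
generate_study_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- config$seed
  tree <- simulate_yule(config$n_species, seed = derive_seed(seed, "tree"),
                        birth_rate = config$birth_rate)
  fam <- assign_families(tree, config$n_families)

  # binary learning state under a 2-state equal-rates process
  lw_model <- mk_er_model(c("stable", "plastic"), config$learning_rate)
  lw <- simulate_discrete(tree, lw_model, seed = derive_seed(seed, "learning"))
  binary <- lw$tip_states

  set.seed(derive_seed(seed, "ternary"))
  ternary <- ifelse(binary == "plastic", "plastic",
                    ifelse(runif(length(binary)) < config$early_fraction,
                           "early", "delayed"))
  names(ternary) <- names(binary)
  has_ternary <- runif(length(binary)) >= config$missing_ternary_prob
  years <- ifelse(ternary == "plastic", 2,
                  ifelse(ternary == "delayed", 1.33,
                         round(runif(length(binary), 0.5, 1.0), 2)))
  ternary[!has_ternary] <- NA_character_
  years[!has_ternary] <- NA_real_

  # log-scale song traits under state-dependent BM; group-mean targets are
  # planted as per-state drift (trait units per unit time in state) so the
  # group difference accrues along plastic lineages rather than jumping at
  # the tips -- directional evolution with genuinely equal rates. State
  # mixing along the unit root-to-tip path attenuates the realized
  # contrast: a tip spends expected fraction f(q) = 1/2 + (1-e^(-2q))/(4q)
  # of its path in its current state, so drift levels are the mixing
  # matrix's inverse applied to the target means.
  q <- config$learning_rate
  f <- 0.5 + (1 - exp(-2 * q)) / (4 * q)
  Mmix <- matrix(c(f, 1 - f, 1 - f, f), 2, 2)
  traits <- rownames(config$trait_offsets)
  lnvals <- sapply(traits, function(tr) {
    drift <- solve(Mmix, config$trait_offsets[tr, c("stable", "plastic")])
    names(drift) <- c("stable", "plastic")
    simulate_bm_regimes(tree, lw$map, config$sigma2,
                        state_drift = drift,
                        root_value = 0,
                        seed = derive_seed(seed, paste0("bm_", tr)))
  })

  # per-study raw values: 1-3 studies whose median reproduces the planted
  # value exactly (the middle study equals it; flankers are symmetric on
  # the log scale)
  set.seed(derive_seed(seed, "studies"))
  study_cell <- function(ln_value) {
    n <- sample(c(1L, 3L), 1L, prob = c(0.5, 0.5))
    if (n == 1L) return(sprintf("%.6g", exp(ln_value)))
    d <- runif(1, 0.05, 0.25)
    paste(sprintf("%.6g", exp(ln_value + c(-d, 0, d))), collapse = ";")
  }

  # mating pair under a dependent 4-state chain
  mat <- simulate_dependent_pair(tree, config$dependent_rates,
                                 seed = derive_seed(seed, "mating"))
  set.seed(derive_seed(seed, "mating_fracs"))
  n <- config$n_species
  poly_frac <- ifelse(mat$trait1 == "1", runif(n, 0.05, 0.5),
                      runif(n, 0, 0.049))
  epp_frac <- ifelse(mat$trait2 == "1", runif(n, 0.10, 0.6),
                     runif(n, 0, 0.099))
  poly_frac[runif(n) < config$missing_mating_prob] <- NA_real_
  epp_frac[runif(n) < config$missing_epp_prob] <- NA_real_

  tab <- data.frame(
    species = tree$tip.label,
    family = unname(fam[tree$tip.label]),
    learning_binary = unname(binary[tree$tip.label]),
    learning_ternary = unname(ternary[tree$tip.label]),
    learning_years = unname(years[tree$tip.label]),
    syllable_repertoire = vapply(lnvals[tree$tip.label, "syllable_repertoire"],
                                 study_cell, ""),
    song_repertoire = vapply(lnvals[tree$tip.label, "song_repertoire"],
                             study_cell, ""),
    syllables_per_song = vapply(lnvals[tree$tip.label, "syllables_per_song"],
                                study_cell, ""),
    duration_s = vapply(lnvals[tree$tip.label, "duration_s"], study_cell, ""),
    interval_s = vapply(lnvals[tree$tip.label, "interval_s"], study_cell, ""),
    polygynous_male_fraction = round(unname(poly_frac), 4),
    epp_fraction = round(unname(epp_frac), 4),
    stringsAsFactors = FALSE
  )

  structure(list(
    tree = tree,
    table = tab,
    records = species_records(tab),
    truth = list(learning = lw, ternary = ternary, log_traits = lnvals,
                 mating = mat),
    config = config
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits the Newick tree, the species CSV and a JSON metadata file echoing
#' the configuration and seed.
#'
#' @param dataset a `"synthetic_dataset"`.
#' @param dir output directory (created if needed).
#' @return the paths, invisibly.
#' @export
write_study_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(tree = file.path(dir, "tree.nwk"),
                traits = file.path(dir, "species_traits.csv"),
                metadata = file.path(dir, "metadata.json"))
  write_newick(dataset$tree, paths$tree)
  write.csv(dataset$table, paths$traits, row.names = FALSE)
  cfg <- dataset$config
  cfg$trait_offsets <- as.data.frame(cfg$trait_offsets)
  jsonlite::write_json(list(config = unclass(cfg),
                            n_species = nrow(dataset$table),
                            n_families = length(unique(dataset$table$family))),
                       paths$metadata, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
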