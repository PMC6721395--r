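# Orchestration: run the full comparative analysis (all coding schemes,
# all traits) from one configuration, with deterministic per-stage seeds,
# table-shaped CSV outputs, and jackknife drivers.

# stable 31-bit hash of a string (for per-stage seed derivation)
string_hash31 <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Derive a per-stage seed from a master seed
#'
#' Stage seeds are a stable hash of the stage identifier mixed with the
#' master seed, so adding or reordering pipeline stages never perturbs the
#' random streams of the others. Always below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage identifier.
#' @return an integer seed.
#' @export
derive_seed <- function(master, stage) {
  as.integer((string_hash31(stage) + as.numeric(master) * 7919) %% 2147483647)
}

TERNARY_TRAITS <- c("syllable_repertoire", "song_repertoire",
                    "syllables_per_song")

#' Build a run configuration
#'
#' @param traits a species table path, data frame, `"species_records"`, or
#'   a `"synthetic_config"` (data are then generated).
#' @param tree a Newick path or `"phylo"`; ignored when `traits` is a
#'   synthetic config (the generated tree is used).
#' @param aggregation study-value aggregation mode.
#' @param analyses which stages to run: any of `"asr"`, `"phylanova"`,
#'   `"pgls"`, `"brownie"`, `"pagel"`, `"mating"`.
#' @param fast logical; use the reduced test profile (100 maps, 200 ANOVA
#'   simulations, 10 runs per threshold, 50 mating runs) instead of the
#'   full one (10000 maps, 1300 Brownie maps, 1000 simulations, 100 runs
#'   per threshold, 1000 mating runs).
#' @param seed master seed (mandatory; every stochastic stage derives its
#'   own stream from it).
#' @param outdir optional output directory for CSV tables and the manifest.
#' @param improviser_override,improviser_species sensitivity switch: refit
#'   with the named improviser species recoded as song-stable.
#' @param n_maps,n_maps_brownie,n_sim,runs_per_threshold,n_bins,mating_runs
#'   explicit overrides of the profile sizes.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(traits, tree = NULL,
                       aggregation = c("median", "min", "max"),
                       analyses = c("asr", "phylanova", "pgls", "brownie",
                                    "pagel", "mating"),
                       fast = FALSE, seed = 1L, outdir = NULL,
                       improviser_override = FALSE, improviser_species = NULL,
                       n_maps = NULL, n_maps_brownie = NULL, n_sim = NULL,
                       runs_per_threshold = NULL, n_bins = 3L,
                       mating_runs = NULL) {
  aggregation <- match.arg(aggregation)
  analyses <- match.arg(analyses, several.ok = TRUE)
  prof <- if (fast) {
    list(n_maps = 100L, n_maps_brownie = 100L, n_sim = 200L,
         runs_per_threshold = 10L, mating_runs = 50L)
  } else {
    list(n_maps = 10000L, n_maps_brownie = 1300L, n_sim = 1000L,
         runs_per_threshold = 100L, mating_runs = 1000L)
  }
  structure(list(
    traits = traits, tree = tree, aggregation = aggregation,
    analyses = analyses, fast = fast, seed = as.integer(seed),
    outdir = outdir,
    improviser_override = improviser_override,
    improviser_species = improviser_species,
    n_maps = if (is.null(n_maps)) prof$n_maps else as.integer(n_maps),
    n_maps_brownie = if (is.null(n_maps_brownie)) prof$n_maps_brownie
      else as.integer(n_maps_brownie),
    n_sim = if (is.null(n_sim)) prof$n_sim else as.integer(n_sim),
    runs_per_threshold = if (is.null(runs_per_threshold))
      prof$runs_per_threshold else as.integer(runs_per_threshold),
    n_bins = as.integer(n_bins),
    mating_runs = if (is.null(mating_runs)) prof$mating_runs
      else as.integer(mating_runs)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    y$traits <- do.call(synthetic_config, y$synthetic)
    y$synthetic <- NULL
  }
  do.call(run_config, y)
}

resolve_dataset <- function(config) {
  traits <- config$traits
  if (inherits(traits, "synthetic_config")) {
    syn <- generate_study_dataset(traits)
    records <- syn$records
    tree <- syn$tree
  } else {
    records <- if (is.character(traits)) read_species_table(traits)
      else if (is.data.frame(traits)) species_records(traits)
      else traits
    tree <- if (is.character(config$tree)) read_newick(config$tree)
      else config$tree
    if (is.null(tree)) stop("a tree is required when traits are not synthetic")
    syn <- NULL
  }
  ds <- build_analysis_dataset(records, tree, config$aggregation,
                               improviser_override = config$improviser_override,
                               improviser_species = config$improviser_species)
  list(dataset = ds, synthetic = syn)
}

learning_vec <- function(ds, coding = "learning_binary") {
  setNames(ds$data[[coding]], ds$data$species)
}

trait_vec <- function(ds, trait) {
  setNames(ds$data[[trait]], ds$data$species)
}

#' Run the full comparative analysis
#'
#' Executes the configured stages on one dataset: Mk ER/ARD fits with a
#' likelihood-ratio test and transition counting over a stochastic-map
#' ensemble; phylogenetic ANOVA across the seven song traits (binary and
#' ternary codings) with the seven-test Holm ladder; lambda-PGLS of each
#' trait against the continuous learning window; Brownie ensemble rate
#' tests (two-rate stable/plastic, three-rate early/delayed/plastic, and
#' shorter/longer-learning groupings); Pagel threshold sweeps per trait;
#' and Pagel tests against mating system and EPP class. Writes table-shaped
#' CSVs plus a JSON manifest when `outdir` is set.
#'
#' @param config a `"run_config"`.
#' @return a list of stage results (class `"song_analysis"`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rs <- resolve_dataset(config)
  ds <- rs$dataset
  seed <- config$seed
  out <- list(config = config, dataset = ds)
  tern_ok <- sum(!is.na(ds$data$learning_ternary)) >= 9

  if ("asr" %in% config$analyses) {
    lw <- learning_vec(ds)
    er <- fit_mk(ds$tree, lw, "ER", seed = derive_seed(seed, "asr_er"))
    ard <- fit_mk(ds$tree, lw, "ARD", seed = derive_seed(seed, "asr_ard"))
    maps <- sample_stochastic_maps(er, config$n_maps,
                                   seed = derive_seed(seed, "asr_maps"))
    out$asr <- list(er = er, ard = ard, lrt = mk_lrt(er, ard),
                    marginals = ancestral_marginals(er),
                    transitions = minimum_transitions(maps))
    if (tern_ok) {
      lt <- learning_vec(ds, "learning_ternary")
      keep <- names(lt)[!is.na(lt)]
      tr3 <- prune_to_taxa(ds$tree, keep)
      out$asr$ternary_er <- fit_mk(tr3, lt[keep], "ER",
                                   seed = derive_seed(seed, "asr_er3"))
    }
  }

  if ("phylanova" %in% config$analyses) {
    out$phylanova <- list(
      binary = phylanova_table(ds, LOG_TRAITS, "learning_binary",
                               config$n_sim, seed),
      ternary = if (tern_ok) {
        phylanova_table(ds, TERNARY_TRAITS, "learning_ternary",
                        config$n_sim, seed)
      }
    )
  }

  if ("pgls" %in% config$analyses) {
    yrs <- setNames(ds$data$learning_years, ds$data$species)
    rows <- lapply(LOG_TRAITS, function(tr) {
      f <- tryCatch(fit_pgls(ds$tree, trait_vec(ds, tr), yrs),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)
      data.frame(trait = tr, slope = f$slope, std_error = f$se,
                 lambda = f$lambda, t_value = f$t_value, n = f$n,
                 p_value = f$p_value)
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$p_value), ]
    hol <- holm(tab$p_value, family_size = 7L)
    tab$corrected_alpha <- hol$corrected_alpha
    tab$significant <- hol$significant
    rownames(tab) <- NULL
    out$pgls <- tab
  }

  if ("brownie" %in% config$analyses) {
    out$brownie <- list(
      two_rate = brownie_table(ds, LOG_TRAITS, "learning_binary",
                               grouping = NULL, config$n_maps_brownie, seed,
                               label = "two"),
      three_rate = if (tern_ok) {
        brownie_table(ds, TERNARY_TRAITS, "learning_ternary",
                      grouping = NULL, config$n_maps_brownie, seed,
                      label = "three")
      },
      shorter_longer = if (tern_ok) {
        brownie_table(ds, TERNARY_TRAITS, "learning_ternary",
                      grouping = c(early = "shorter", delayed = "longer",
                                   plastic = "longer"),
                      config$n_maps_brownie, seed, label = "sl")
      }
    )
  }

  if ("pagel" %in% config$analyses) {
    lw <- learning_vec(ds)
    out$pagel <- lapply(setNames(LOG_TRAITS, LOG_TRAITS), function(tr) {
      sw <- tryCatch(
        threshold_sweep(ds$tree, lw, trait_vec(ds, tr),
                        runs_per_threshold = config$runs_per_threshold,
                        seed = derive_seed(seed, paste0("sweep_", tr))),
        error = function(e) NULL)
      if (is.null(sw)) return(NULL)
      list(sweep = sw,
           summary = summarize_sweep(sw, n_bins = config$n_bins,
                                     seed = derive_seed(seed, paste0("bins_", tr))))
    })
  }

  if ("mating" %in% config$analyses) {
    lw <- learning_vec(ds)
    mating <- setNames(ds$data$mating_system, ds$data$species)
    epp <- setNames(ds$data$epp_class, ds$data$species)
    out$mating <- list(
      mating_system = tryCatch(
        run_pagel_binary(ds$tree, lw, mating, runs = config$mating_runs,
                         seed = derive_seed(seed, "pagel_mating")),
        error = function(e) structure(list(message = conditionMessage(e)),
                                      class = "stage_error")),
      epp = tryCatch(
        run_pagel_binary(ds$tree, lw, epp, runs = config$mating_runs,
                         seed = derive_seed(seed, "pagel_epp")),
        error = function(e) structure(list(message = conditionMessage(e)),
                                      class = "stage_error"))
    )
  }

  if (!is.null(config$outdir)) write_analysis_outputs(out, config$outdir)
  structure(out, class = "song_analysis")
}

phylanova_table <- function(ds, traits, coding, n_sim, seed) {
  rows <- lapply(traits, function(tr) {
    sub <- tryCatch(subset_for_trait(ds, tr, coding), error = function(e) NULL)
    if (is.null(sub) || length(unique(sub$data[[coding]])) < 2L) return(NULL)
    pa <- phyl_anova(sub$tree, setNames(sub$data[[tr]], sub$data$species),
                     setNames(sub$data[[coding]], sub$data$species),
                     n_sim = n_sim,
                     seed = derive_seed(seed, paste0("anova_", coding, "_", tr)))
    gm <- as.list(pa$group_means)
    names(gm) <- paste0("mean_", names(gm))
    cbind(data.frame(trait = tr, n = sum(pa$group_n)), as.data.frame(gm),
          data.frame(F_value = pa$F, p_value = pa$p_value))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$p_value), ]
  hol <- holm(tab$p_value, family_size = 7L)
  tab$corrected_alpha <- hol$corrected_alpha
  tab$significant <- hol$significant
  rownames(tab) <- NULL
  tab
}

brownie_table <- function(ds, traits, coding, grouping, n_maps, seed, label) {
  rows <- lapply(traits, function(tr) {
    sub <- tryCatch(subset_for_trait(ds, tr, coding), error = function(e) NULL)
    if (is.null(sub)) return(NULL)
    states <- setNames(sub$data[[coding]], sub$data$species)
    if (length(unique(states)) < 2L) return(NULL)
    er <- fit_mk(sub$tree, states, "ER",
                 seed = derive_seed(seed, paste0("br_er_", label, "_", tr)))
    maps <- sample_stochastic_maps(er, n_maps,
                                   seed = derive_seed(seed, paste0("br_maps_", label, "_", tr)))
    ert <- ensemble_rate_test(sub$tree, setNames(sub$data[[tr]], sub$data$species),
                              maps, grouping = grouping)
    data.frame(trait = tr, n = nrow(sub$data),
               one_rate_ll = ert$loglik_single,
               multi_rate_mean_ll = ert$mean_loglik_multirate,
               df = ert$df, p_value = ert$p_value)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  tab <- do.call(rbind, rows)
  tab[order(tab$p_value), ]
}

write_analysis_outputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x) && is.data.frame(x)) {
      write.csv(x, file.path(outdir, name), row.names = FALSE)
    }
  }
  if (!is.null(out$phylanova)) {
    wr(out$phylanova$binary, "phylanova_binary.csv")
    wr(out$phylanova$ternary, "phylanova_ternary.csv")
  }
  wr(out$pgls, "pgls_continuous.csv")
  if (!is.null(out$brownie)) {
    wr(out$brownie$two_rate, "brownie_two_rate.csv")
    wr(out$brownie$three_rate, "brownie_three_rate.csv")
    wr(out$brownie$shorter_longer, "brownie_shorter_longer.csv")
  }
  if (!is.null(out$pagel)) {
    for (tr in names(out$pagel)) {
      if (is.null(out$pagel[[tr]])) next
      wr(out$pagel[[tr]]$sweep$runs, paste0("pagel_sweep_", tr, ".csv"))
      wr(out$pagel[[tr]]$summary$rates, paste0("pagel_bins_", tr, ".csv"))
    }
  }
  if (!is.null(out$asr)) {
    asr <- data.frame(
      quantity = c("loglik_ER", "loglik_ARD", "lrt_p", "min_transitions"),
      value = c(out$asr$er$loglik, out$asr$ard$loglik,
                out$asr$lrt$p_value, out$asr$transitions$minimum))
    wr(asr, "ancestral_reconstruction.csv")
  }
  cfg <- out$config
  manifest <- list(
    seed = cfg$seed, aggregation = cfg$aggregation, fast = cfg$fast,
    analyses = cfg$analyses,
    sizes = cfg[c("n_maps", "n_maps_brownie", "n_sim",
                  "runs_per_threshold", "n_bins", "mating_runs")],
    n_species = nrow(out$dataset$data),
    dataset_hash = string_hash31(paste(capture.output(
      write.csv(out$dataset$data)), collapse = "\n"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Jackknife re-analysis
#'
#' Repeats selected analyses with each unit (family, or species within a
#' designated set) left out in turn, and flags results whose significance
#' status flips relative to the full run. Threshold sweeps, when scoped in,
#' run at a reduced number of runs per threshold (default 20) and re-derive
#' the unique thresholds within each jackknifed subset.
#'
#' @param config a `"run_config"` describing the full analysis.
#' @param unit `"family"` (default: every family with at least
#'   `min_family_size` species) or `"species"` (each of `species_set` in
#'   turn).
#' @param scope analyses to repeat: subset of `"phylanova"`, `"brownie"`,
#'   `"pagel"`.
#' @param traits traits to scan (default: the seven log traits for
#'   phylANOVA/Brownie).
#' @param min_family_size minimum family size for the family jackknife.
#' @param species_set species to drop one at a time when `unit="species"`.
#' @param sweep_runs runs per threshold in jackknifed sweeps (default 20).
#' @return a data frame: left-out unit, analysis, trait, full and
#'   jackknifed p-values, significance flags, `flipped`, `applicable`.
#' @export
jackknife_analysis <- function(config, unit = c("family", "species"),
                               scope = c("phylanova", "brownie"),
                               traits = LOG_TRAITS,
                               min_family_size = 4L, species_set = NULL,
                               sweep_runs = 20L) {
  unit <- match.arg(unit)
  scope <- match.arg(scope, c("phylanova", "brownie", "pagel"),
                     several.ok = TRUE)
  rs <- resolve_dataset(config)
  ds <- rs$dataset
  seed <- config$seed

  run_scoped <- function(d, tag) {
    res <- list()
    if ("phylanova" %in% scope) {
      res$phylanova <- phylanova_table(d, traits, "learning_binary",
                                       config$n_sim, derive_seed(seed, tag))
    }
    if ("brownie" %in% scope) {
      res$brownie <- brownie_table(d, traits, "learning_binary", NULL,
                                   config$n_maps_brownie,
                                   derive_seed(seed, tag), label = "jk")
    }
    if ("pagel" %in% scope) {
      lw <- learning_vec(d)
      res$pagel <- do.call(rbind, lapply(traits, function(tr) {
        sw <- tryCatch(threshold_sweep(d$tree, lw, trait_vec(d, tr),
                                       runs_per_threshold = sweep_runs,
                                       seed = derive_seed(seed, paste0(tag, tr))),
                       error = function(e) NULL)
        if (is.null(sw)) return(NULL)
        data.frame(trait = tr,
                   p_value = median(sw$runs$p_value),
                   percent_significant = 100 * mean(sw$runs$p_value < 0.05))
      }))
    }
    res
  }

  full <- run_scoped(ds, "jk_full")
  units <- if (unit == "family") {
    fams <- table(ds$data$family)
    names(fams)[fams >= min_family_size]
  } else {
    if (is.null(species_set)) stop("species_set required for unit='species'")
    species_set
  }
  if (!length(units)) stop("no units meet the jackknife criterion")

  rows <- list()
  for (u in units) {
    keep <- if (unit == "family") ds$data$species[ds$data$family != u]
      else setdiff(ds$data$species, u)
    dsub <- tryCatch({
      d <- ds
      d$data <- d$data[d$data$species %in% keep, , drop = FALSE]
      d$tree <- prune_to_taxa(ds$tree, keep)
      if (length(unique(d$data$learning_binary)) < 2L) NULL else d
    }, error = function(e) NULL)
    if (is.null(dsub)) {
      rows[[length(rows) + 1L]] <- data.frame(
        left_out = u, analysis = scope[1], trait = NA, p_full = NA,
        p_jackknife = NA, significant_full = NA, significant_jackknife = NA,
        flipped = NA, applicable = FALSE)
      next
    }
    jack <- run_scoped(dsub, paste0("jk_", u))
    for (an in names(full)) {
      ft <- full[[an]]; jt <- jack[[an]]
      if (is.null(ft) || is.null(jt)) next
      for (tr in intersect(ft$trait, jt$trait)) {
        pf <- ft$p_value[ft$trait == tr][1]
        pj <- jt$p_value[jt$trait == tr][1]
        sf <- pf < 0.05; sj <- pj < 0.05
        rows[[length(rows) + 1L]] <- data.frame(
          left_out = u, analysis = an, trait = tr, p_full = pf,
          p_jackknife = pj, significant_full = sf, significant_jackknife = sj,
          flipped = sf != sj, applicable = TRUE)
      }
    }
  }
  do.call(rbind, rows)
}
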