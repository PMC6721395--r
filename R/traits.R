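# Species-level trait handling: learning-window coding, multi-study
# aggregation, derived song metrics, mating classification, and assembly of
# tree-aligned analysis tables.

LEARNING_BINARY <- c("stable", "plastic")
LEARNING_TERNARY <- c("early", "delayed", "plastic")
SONG_TRAITS <- c("syllable_repertoire", "song_repertoire", "syllables_per_song",
                 "duration_s", "interval_s")
LOG_TRAITS <- c("syllable_repertoire", "song_repertoire", "syllables_per_song",
                "duration", "interval", "rate", "continuity")

#' Code the song-learning window of a species
#'
#' Converts a longitudinal observation of when a male stops modifying its
#' song into the three coding schemes used throughout the package: a binary
#' stable/plastic state, a ternary early/delayed/plastic state, and a
#' continuous learning-window length in years on \[0, 2\].
#'
#' Species that keep modifying song after their first breeding season are
#' song-plastic and receive 2.0 years. Species that modify song during but
#' not after the first breeding season are delayed song-stable and receive
#' 1.33 years (the end of the first breeding season). Species that stop
#' before the first breeding season are early song-stable and receive their
#' reported stabilization age; when no age was reported they receive 1.0
#' (end of the pre-breeding period) and are flagged. Species with delayed
#' plumage maturation that stop modifying before their second breeding
#' season are coded song-stable with 2.0 years.
#'
#' @param ceases one of `"before_first_season"`, `"during_first_season"`,
#'   `"after_first_season"`.
#' @param reported_age optional stabilization age in years (only meaningful
#'   for `"before_first_season"`; must lie in \[0, 1\]).
#' @param delayed_plumage logical; species reaches mature plumage only in
#'   its second breeding season.
#' @return a list with elements `binary`, `ternary`, `years` and
#'   `age_assumed` (TRUE when the 1.0-year default was used).
#' @export
code_learning_window <- function(ceases, reported_age = NA_real_,
                                 delayed_plumage = FALSE) {
  ceases <- match.arg(ceases, c("before_first_season", "during_first_season",
                                "after_first_season"))
  if (!is.na(reported_age) && ceases != "before_first_season") {
    stop("a reported stabilization age is only valid when song stabilizes ",
         "before the first breeding season")
  }
  if (ceases == "after_first_season") {
    if (delayed_plumage) {
      # modification ceases before the second season with mature plumage:
      # treated as song-stable despite running past the first season
      return(list(binary = "stable", ternary = "delayed", years = 2.0,
                  age_assumed = FALSE))
    }
    return(list(binary = "plastic", ternary = "plastic", years = 2.0,
                age_assumed = FALSE))
  }
  if (ceases == "during_first_season") {
    return(list(binary = "stable", ternary = "delayed", years = 1.33,
                age_assumed = FALSE))
  }
  if (!is.na(reported_age)) {
    if (reported_age < 0 || reported_age > 1) {
      stop("reported stabilization age must be in [0, 1] for early ",
           "song-stable species, got ", reported_age)
    }
    return(list(binary = "stable", ternary = "early", years = reported_age,
                age_assumed = FALSE))
  }
  list(binary = "stable", ternary = "early", years = 1.0, age_assumed = TRUE)
}

#' Aggregate per-study trait values
#'
#' Multiple literature studies often report different values for the same
#' species; analyses run on the median by default, with min and max as
#' sensitivity modes.
#'
#' @param values numeric vector of per-study values (positive).
#' @param mode one of `"median"`, `"min"`, `"max"`.
#' @return the aggregated value, or `NA` for an empty input.
#' @export
aggregate_trait <- function(values, mode = c("median", "min", "max")) {
  mode <- match.arg(mode)
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  if (any(values < 0)) stop("raw trait values must be non-negative")
  switch(mode,
         median = median(values),
         min = min(values),
         max = max(values))
}

#' Derived song-performance metrics
#'
#' Song rate and continuity are computed from song duration and inter-song
#' interval: rate = 60/(duration + interval) songs per minute, and
#' continuity = duration/(duration + interval), the fraction of singing time
#' spent producing song.
#'
#' @param duration_s mean song duration in seconds (> 0).
#' @param interval_s mean inter-song interval in seconds (>= 0).
#' @return a list with `rate_per_min` and `continuity`.
#' @export
derive_song_metrics <- function(duration_s, interval_s) {
  stopifnot(length(duration_s) == length(interval_s))
  bad <- !is.na(duration_s) & !is.na(interval_s) &
    (duration_s <= 0 | interval_s < 0)
  if (any(bad)) stop("need duration > 0 and interval >= 0")
  tot <- duration_s + interval_s
  if (any(!is.na(tot) & tot == 0)) stop("duration + interval must be positive")
  list(rate_per_min = 60 / tot, continuity = duration_s / tot)
}

#' Impute a missing syllable repertoire from syllables per song
#'
#' For species whose song repertoire is exactly one song, the syllable
#' repertoire equals the number of syllables per song; when the syllable
#' repertoire is unreported it is filled in from that identity. Any other
#' configuration is left untouched.
#'
#' @param record a species record: a list with per-study value vectors named
#'   as in [read_species_table()].
#' @param mode aggregation mode used to decide whether the song repertoire
#'   equals one.
#' @return the (possibly updated) record; `record$imputed_syllable_repertoire`
#'   records whether the rule fired.
#' @export
impute_syllable_repertoire <- function(record, mode = "median") {
  record$imputed_syllable_repertoire <- FALSE
  has_syl <- length(record$syllable_repertoire) &&
    any(!is.na(record$syllable_repertoire))
  song_rep <- aggregate_trait(record$song_repertoire, mode)
  if (!has_syl && !is.na(song_rep) && song_rep == 1 &&
      length(record$syllables_per_song) &&
      any(!is.na(record$syllables_per_song))) {
    record$syllable_repertoire <- record$syllables_per_song
    record$imputed_syllable_repertoire <- TRUE
  }
  record
}

#' Classify mating behavior
#'
#' A species is polygynous when at least 5% of males have more than one
#' social mate, and high-EPP when at least 10% of offspring (or nests) are
#' extra-pair.
#'
#' @param poly_frac fraction of males with >1 social mate, in \[0, 1\] or NA.
#' @param epp_frac fraction of extra-pair young/nests, in \[0, 1\] or NA.
#' @return a list with `mating_system` (`"monogamous"`/`"polygynous"`/NA)
#'   and `epp_class` (`"low"`/`"high"`/NA); vectorized.
#' @export
classify_mating <- function(poly_frac, epp_frac) {
  chk <- function(x, nm) {
    if (any(!is.na(x) & (x < 0 | x > 1))) stop(nm, " must lie in [0, 1]")
    x
  }
  poly_frac <- chk(poly_frac, "poly_frac")
  epp_frac <- chk(epp_frac, "epp_frac")
  list(
    mating_system = ifelse(is.na(poly_frac), NA_character_,
                           ifelse(poly_frac >= 0.05, "polygynous", "monogamous")),
    epp_class = ifelse(is.na(epp_frac), NA_character_,
                       ifelse(epp_frac >= 0.10, "high", "low"))
  )
}

#' Binarize a continuous trait at a threshold
#'
#' Species strictly above the threshold are labelled `"high"`, all others
#' `"low"`. With an observed value used as the threshold the low class is
#' never empty; a threshold that empties either class is flagged degenerate
#' (and skipped by the threshold sweep) rather than raising an error.
#'
#' @param values named numeric vector of trait values.
#' @param threshold the cut value (usually one of the observed values).
#' @return a character vector of `"low"`/`"high"` labels with names kept;
#'   attribute `"degenerate"` is TRUE when a class is empty.
#' @export
binarize_by_threshold <- function(values, threshold) {
  stopifnot(is.numeric(values), length(values) >= 2L, is.finite(threshold))
  lab <- ifelse(values > threshold, "high", "low")
  names(lab) <- names(values)
  attr(lab, "degenerate") <- length(unique(lab)) < 2L
  lab
}

# ---- species tables ---------------------------------------------------------

parse_study_values <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(numeric(0))
  v <- as.numeric(strsplit(as.character(x), ";", fixed = TRUE)[[1L]])
  if (any(is.na(v))) stop("could not parse study values: ", x)
  v
}

#' Read a species trait table
#'
#' The CSV carries one row per species with columns `species`, `family`,
#' `learning_binary`, `learning_ternary`, `learning_years`,
#' `polygynous_male_fraction`, `epp_fraction`, and one column per raw song
#' trait (`syllable_repertoire`, `song_repertoire`, `syllables_per_song`,
#' `duration_s`, `interval_s`) holding semicolon-separated per-study values.
#' A `column_map` can rename externally deposited layouts onto this scheme.
#'
#' @param path CSV path.
#' @param column_map optional named character vector mapping this package's
#'   column names to the names used in the file.
#' @return a list of species records (class `"species_records"`).
#' @export
read_species_table <- function(path, column_map = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(tab)) {
        stop("mapped column not found in file: ", column_map[[nm]])
      }
      names(tab)[names(tab) == column_map[[nm]]] <- nm
    }
  }
  species_records(tab)
}

#' Build species records from a data frame
#'
#' @param tab a data frame laid out as in [read_species_table()].
#' @return a list of species records (class `"species_records"`).
#' @export
species_records <- function(tab) {
  need <- c("species", "family", "learning_binary")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$species)) stop("duplicate species rows")
  opt_num <- function(col, i) {
    if (col %in% names(tab)) suppressWarnings(as.numeric(tab[[col]][i])) else NA_real_
  }
  opt_chr <- function(col, i) {
    if (col %in% names(tab)) {
      v <- tab[[col]][i]
      if (is.na(v) || !nzchar(trimws(as.character(v)))) NA_character_ else as.character(v)
    } else NA_character_
  }
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    rec <- list(
      species = as.character(tab$species[i]),
      family = as.character(tab$family[i]),
      learning_binary = match.arg(as.character(tab$learning_binary[i]),
                                  LEARNING_BINARY),
      learning_ternary = opt_chr("learning_ternary", i),
      learning_years = opt_num("learning_years", i),
      polygynous_male_fraction = opt_num("polygynous_male_fraction", i),
      epp_fraction = opt_num("epp_fraction", i)
    )
    for (tr in SONG_TRAITS) {
      rec[[tr]] <- if (tr %in% names(tab)) parse_study_values(tab[[tr]][i]) else numeric(0)
    }
    validate_species_record(rec)
    rec
  })
  names(recs) <- tab$species
  structure(recs, class = "species_records")
}

validate_species_record <- function(rec) {
  if (!is.na(rec$learning_ternary)) {
    if (!rec$learning_ternary %in% LEARNING_TERNARY) {
      stop(rec$species, ": invalid ternary state '", rec$learning_ternary, "'")
    }
    tern_plastic <- rec$learning_ternary == "plastic"
    bin_plastic <- rec$learning_binary == "plastic"
    if (tern_plastic != bin_plastic) {
      stop(rec$species, ": ternary and binary learning codings disagree")
    }
  }
  if (!is.na(rec$learning_years)) {
    if (rec$learning_years < 0 || rec$learning_years > 2) {
      stop(rec$species, ": learning_years must lie in [0, 2]")
    }
    if (rec$learning_binary == "plastic" && rec$learning_years != 2) {
      stop(rec$species, ": song-plastic species must have learning_years = 2")
    }
  }
  for (tr in SONG_TRAITS) {
    lo <- if (tr == "interval_s") 0 else .Machine$double.xmin # interval may be 0
    if (length(rec[[tr]]) && any(rec[[tr]] < lo, na.rm = TRUE)) {
      stop(rec$species, ": raw ", tr, " values must be positive")
    }
  }
  invisible(rec)
}

#' Assemble a tree-aligned analysis dataset
#'
#' Aggregates per-study values (one mode), applies the syllable-repertoire
#' imputation rule, derives rate and continuity, natural-log transforms all
#' seven song traits, classifies mating behavior, and aligns rows to the
#' tips of the working tree. Species absent from the tree are reported in a
#' skip log, not fatal.
#'
#' @param records a `"species_records"` list (or data frame accepted by
#'   [species_records()]).
#' @param tree a `"phylo"` object whose tips cover the species to analyze.
#' @param mode aggregation mode, one of `"median"`, `"min"`, `"max"`.
#' @param improviser_override logical; reclassify the designated improviser
#'   species as song-stable (sensitivity analysis).
#' @param improviser_species tip label of the improviser species the
#'   override applies to.
#' @return an object of class `"analysis_dataset"`: a list with `data` (one
#'   row per retained species: codings, mating classes, family and the seven
#'   ln-scale song traits), `tree` (pruned to those species), `mode`, and
#'   `skipped` (species dropped for missing tree tips).
#' @export
build_analysis_dataset <- function(records, tree, mode = "median",
                                   improviser_override = FALSE,
                                   improviser_species = NULL) {
  if (is.data.frame(records)) records <- species_records(records)
  stopifnot(inherits(records, "species_records"))
  validate_phylogeny(tree)
  mode <- match.arg(mode, c("median", "min", "max"))
  sp <- vapply(records, `[[`, "", "species")
  skipped <- sp[!sp %in% tree$tip.label]
  keep <- sp[sp %in% tree$tip.label]
  if (length(keep) < 3L) stop("fewer than 3 species shared between records and tree")

  rows <- lapply(records[keep], function(rec) {
    rec <- impute_syllable_repertoire(rec, mode)
    agg <- vapply(SONG_TRAITS, function(tr) aggregate_trait(rec[[tr]], mode),
                  numeric(1))
    met <- if (!is.na(agg["duration_s"]) && !is.na(agg["interval_s"])) {
      derive_song_metrics(agg["duration_s"], agg["interval_s"])
    } else list(rate_per_min = NA_real_, continuity = NA_real_)
    mat <- classify_mating(rec$polygynous_male_fraction, rec$epp_fraction)
    data.frame(
      species = rec$species, family = rec$family,
      learning_binary = rec$learning_binary,
      learning_ternary = rec$learning_ternary,
      learning_years = rec$learning_years,
      mating_system = mat$mating_system, epp_class = mat$epp_class,
      syllable_repertoire = log(agg[["syllable_repertoire"]]),
      song_repertoire = log(agg[["song_repertoire"]]),
      syllables_per_song = log(agg[["syllables_per_song"]]),
      duration = log(agg[["duration_s"]]),
      interval = log(agg[["interval_s"]]),
      rate = log(met$rate_per_min),
      continuity = log(met$continuity),
      stringsAsFactors = FALSE
    )
  })
  data <- do.call(rbind, rows)
  rownames(data) <- data$species

  if (improviser_override) {
    if (is.null(improviser_species)) stop("improviser_override needs improviser_species")
    hit <- data$species == improviser_species
    if (!any(hit)) stop("improviser species not in dataset: ", improviser_species)
    data$learning_binary[hit] <- "stable"
    data$learning_ternary[hit] <- NA_character_
    data$learning_years[hit] <- NA_real_
  }

  structure(list(
    data = data,
    tree = prune_to_taxa(tree, data$species),
    mode = mode,
    skipped = unname(skipped)
  ), class = "analysis_dataset")
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat("Analysis dataset:", nrow(x$data), "species,",
      length(unique(x$data$family)), "families; aggregation =", x$mode, "\n")
  cat("  learning states:",
      paste(names(table(x$data$learning_binary)),
            table(x$data$learning_binary), collapse = ", "), "\n")
  if (length(x$skipped)) {
    cat("  skipped (not in tree):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

# rows of the dataset with non-missing values for one trait, plus the
# matching pruned tree
subset_for_trait <- function(ds, trait, coding = "learning_binary") {
  stopifnot(inherits(ds, "analysis_dataset"), trait %in% LOG_TRAITS)
  ok <- is.finite(ds$data[[trait]]) & !is.na(ds$data[[coding]])
  d <- ds$data[ok, , drop = FALSE]
  if (nrow(d) < 3L) stop("fewer than 3 species with data for ", trait)
  list(data = d, tree = prune_to_taxa(ds$tree, d$species))
}
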