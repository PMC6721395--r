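test_that("learning-window coding follows the classification rules", {
  expect_equal(code_learning_window("after_first_season"),
               list(binary = "plastic", ternary = "plastic", years = 2.0,
                    age_assumed = FALSE))
  expect_equal(code_learning_window("during_first_season"),
               list(binary = "stable", ternary = "delayed", years = 1.33,
                    age_assumed = FALSE))
  expect_equal(code_learning_window("before_first_season", reported_age = 0.75),
               list(binary = "stable", ternary = "early", years = 0.75,
                    age_assumed = FALSE))
  # delayed-plumage exception: stable despite late modification, 2.0 years
  dp <- code_learning_window("after_first_season", delayed_plumage = TRUE)
  expect_equal(dp$binary, "stable")
  expect_equal(dp$years, 2.0)
  # early stabilization with no reported age: 1.0 year, flagged
  ea <- code_learning_window("before_first_season")
  expect_equal(ea$years, 1.0)
  expect_true(ea$age_assumed)
  expect_error(code_learning_window("before_first_season", reported_age = 1.5),
               "\\[0, 1\\]")
  expect_error(code_learning_window("during_first_season", reported_age = 0.5),
               "only valid")
})

test_that("study-value aggregation has the median midpoint convention", {
  expect_equal(aggregate_trait(c(10, 30, 20), "median"), 20)
  expect_equal(aggregate_trait(c(10, 30), "median"), 20)
  expect_equal(aggregate_trait(c(10, 30, 20), "max"), 30)
  expect_equal(aggregate_trait(c(10, 30, 20), "min"), 10)
  expect_true(is.na(aggregate_trait(numeric(0), "median")))
  expect_error(aggregate_trait(c(-1, 2), "median"), "non-negative")

  # min <= median <= max elementwise over random study lists
  set.seed(1)
  for (i in 1:20) {
    v <- runif(sample(1:6, 1), 0.1, 100)
    expect_lte(aggregate_trait(v, "min"), aggregate_trait(v, "median"))
    expect_lte(aggregate_trait(v, "median"), aggregate_trait(v, "max"))
  }
})

test_that("derived rate and continuity follow the defining formulas", {
  m <- derive_song_metrics(2, 2)
  expect_equal(m$rate_per_min, 15)
  expect_equal(m$continuity, 0.5)
  m <- derive_song_metrics(1, 3)
  expect_equal(m$rate_per_min, 15)
  expect_equal(m$continuity, 0.25)
  m <- derive_song_metrics(4, 0)
  expect_equal(m$rate_per_min, 15)
  expect_equal(m$continuity, 1.0)
  expect_error(derive_song_metrics(0, 0), "positive|duration")

  # algebraic identity: continuity = rate * duration / 60
  set.seed(2)
  d <- runif(50, 0.5, 20); iv <- runif(50, 0, 30)
  m <- derive_song_metrics(d, iv)
  expect_equal(m$continuity, m$rate_per_min * d / 60, tolerance = 1e-12)
})

test_that("syllable-repertoire imputation fires only for one-song repertoires", {
  rec <- list(species = "x", song_repertoire = 1,
              syllables_per_song = 4, syllable_repertoire = numeric(0))
  out <- impute_syllable_repertoire(rec)
  expect_equal(out$syllable_repertoire, 4)
  expect_true(out$imputed_syllable_repertoire)

  rec$song_repertoire <- 3
  out <- impute_syllable_repertoire(rec)
  expect_length(out$syllable_repertoire, 0)
  expect_false(out$imputed_syllable_repertoire)

  rec$song_repertoire <- 1
  rec$syllable_repertoire <- 5
  out <- impute_syllable_repertoire(rec)
  expect_equal(out$syllable_repertoire, 5) # never overwrite present data
  expect_false(out$imputed_syllable_repertoire)
})

test_that("mating classification uses the 5% and 10% thresholds inclusively", {
  expect_equal(classify_mating(0.05, NA)$mating_system, "polygynous")
  expect_equal(classify_mating(0.049, NA)$mating_system, "monogamous")
  expect_equal(classify_mating(NA, 0.10)$epp_class, "high")
  expect_equal(classify_mating(NA, 0.099)$epp_class, "low")
  expect_equal(classify_mating(0, 0), list(mating_system = "monogamous",
                                           epp_class = "low"))
  expect_true(is.na(classify_mating(NA, NA)$mating_system))
  expect_error(classify_mating(1.2, NA), "\\[0, 1\\]")
})

test_that("threshold binarization is strictly-greater with degeneracy flag", {
  lab <- binarize_by_threshold(c(a = 1, b = 2, c = 3), 2)
  expect_equal(as.character(lab), c("low", "low", "high"))
  expect_false(attr(lab, "degenerate"))
  lab <- binarize_by_threshold(c(a = 1, b = 2, c = 3), 3)
  expect_true(attr(lab, "degenerate"))
  lab <- binarize_by_threshold(c(a = 1, b = 1, c = 2), 1)
  expect_equal(as.character(lab), c("low", "low", "high"))
})

make_toy_table <- function() {
  data.frame(
    species = c("A", "B", "C", "D"),
    family = c("f1", "f1", "f2", "f2"),
    learning_binary = c("stable", "stable", "plastic", "plastic"),
    learning_ternary = c("early", "delayed", "plastic", NA),
    learning_years = c(0.8, 1.33, 2, NA),
    syllable_repertoire = c("100", "10;20;30", "50", ""),
    song_repertoire = c("1", "5", "8", "2"),
    syllables_per_song = c("6", "4", "9", "3"),
    duration_s = c("2", "1", "4", ""),
    interval_s = c("2", "3", "0", "5"),
    polygynous_male_fraction = c(0.0, 0.05, NA, 0.2),
    epp_fraction = c(0.02, NA, 0.3, 0.05),
    stringsAsFactors = FALSE
  )
}

test_that("analysis dataset applies ln transform, imputation and skip logs", {
  tab <- make_toy_table()
  tree <- parse_newick("(((A:1,B:1):1,C:2):1,(D:1.5,E:1.5):1.5);")
  ds <- build_analysis_dataset(tab, tree)
  expect_s3_class(ds, "analysis_dataset")
  expect_equal(nrow(ds$data), 4L)
  expect_setequal(ds$tree$tip.label, c("A", "B", "C", "D"))
  expect_equal(ds$data["A", "syllable_repertoire"], log(100), tolerance = 1e-12)
  expect_equal(ds$data["B", "syllable_repertoire"], log(20), tolerance = 1e-12)
  expect_equal(ds$data["A", "rate"], log(15), tolerance = 1e-12)
  expect_equal(ds$data["A", "continuity"], log(0.5), tolerance = 1e-12)
  expect_equal(ds$data["C", "continuity"], log(1), tolerance = 1e-12)
  expect_true(is.na(ds$data["D", "duration"]))
  expect_equal(ds$data["A", "mating_system"], "monogamous")
  expect_equal(ds$data["B", "mating_system"], "polygynous")
  expect_equal(ds$data["C", "epp_class"], "high")

  # species not in tree get skipped with a report, not an error
  tab2 <- rbind(tab, data.frame(
    species = "Z", family = "f3", learning_binary = "stable",
    learning_ternary = NA, learning_years = NA,
    syllable_repertoire = "5", song_repertoire = "2",
    syllables_per_song = "2", duration_s = "1", interval_s = "1",
    polygynous_male_fraction = NA, epp_fraction = NA))
  ds2 <- build_analysis_dataset(tab2, tree)
  expect_equal(ds2$skipped, "Z")
  expect_equal(nrow(ds2$data), 4L)
})

test_that("the improviser override flips the designated species to stable", {
  tab <- make_toy_table()
  tree <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  ds <- build_analysis_dataset(tab, tree, improviser_override = TRUE,
                               improviser_species = "C")
  expect_equal(ds$data["C", "learning_binary"], "stable")
  expect_error(build_analysis_dataset(tab, tree, improviser_override = TRUE),
               "improviser_species")
})

test_that("ternary coding collapses exactly onto the binary coding", {
  syn <- generate_study_dataset(synthetic_config(seed = 21))
  d <- syn$table
  has3 <- !is.na(d$learning_ternary)
  expect_true(all((d$learning_ternary[has3] == "plastic") ==
                  (d$learning_binary[has3] == "plastic")))
  expect_true(all(d$learning_ternary[has3] %in% c("early", "delayed", "plastic")))
})

test_that("species table validation enforces record invariants", {
  tab <- make_toy_table()
  tab$learning_years[3] <- 1.5 # plastic must be 2
  expect_error(species_records(tab), "learning_years = 2")
  tab <- make_toy_table()
  tab$learning_ternary[1] <- "plastic" # disagrees with binary stable
  expect_error(species_records(tab), "disagree")
  tab <- make_toy_table()
  tab$syllable_repertoire[1] <- "-3"
  expect_error(species_records(tab), "positive")
})

test_that("species tables round-trip through CSV with a column map", {
  tab <- make_toy_table()
  f <- withr::local_tempfile(fileext = ".csv")
  names(tab)[names(tab) == "species"] <- "taxon"
  write.csv(tab, f, row.names = FALSE)
  recs <- read_species_table(f, column_map = c(species = "taxon"))
  expect_s3_class(recs, "species_records")
  expect_equal(recs$B$syllable_repertoire, c(10, 20, 30))
  expect_error(read_species_table(f, column_map = c(species = "nope")),
               "not found")
})
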