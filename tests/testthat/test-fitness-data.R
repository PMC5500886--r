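test_that("fitness drop standardization follows the percentage formula", {
  expect_equal(compute_fitness_drop(10, 4.8), 52)
  expect_equal(compute_fitness_drop(7.3, 7.3), 0)
  expect_equal(compute_fitness_drop(10, 12), -20)
  # vectorized
  expect_equal(compute_fitness_drop(c(10, 7.3), c(4.8, 7.3)), c(52, 0))
  expect_error(compute_fitness_drop(0, 5), "undefined")
  expect_error(compute_fitness_drop(10, -1), ">=")
})

test_that("fitness drop is capped at 100 and strictly decreasing in fitness_without", {
  w <- runif(20, 0.1, 50)
  expect_equal(compute_fitness_drop(w, 0), rep(100, 20))
  withr::with_seed(1, {
    for (k in 1:10) {
      fw <- runif(1, 1, 20)
      wo <- sort(runif(5, 0, 30))
      expect_true(all(diff(compute_fitness_drop(fw, wo)) < 0))
      expect_true(all(compute_fitness_drop(fw, wo) <= 100))
    }
  })
})

test_that("database loading conserves rows and aggregates unique pairs", {
  db <- load_database(write_toy_db())
  expect_s3_class(db, "symbiosis_data")
  expect_equal(nrow(db$observations), 5)
  expect_equal(nrow(db$records), 3)  # 3 unique (host, symbiont) pairs
  # genome entries 4.0 and 6.0 average to 5.0 for the pair
  buchnera <- db$records[db$records$symbiont_species == "Buchnera", ]
  expect_equal(buchnera$genome_size, 5.0)
  expect_equal(buchnera$n_observations, 2L)
  expect_equal(buchnera$mean_fitness_drop, mean(c(52, 50)))
})

test_that("database validation names the offending row and column", {
  rows <- toy_db_rows()
  rows$transmission[3] <- "sideways"
  expect_error(load_database(write_toy_db(rows)), "transmission.*sideways.*row 3")
  rows <- toy_db_rows()
  rows$obligacy[4] <- "obligate"  # row 4 is horizontal
  expect_error(load_database(write_toy_db(rows)), "horizontal.*facultative")
  rows <- toy_db_rows()
  rows$sample_size[2] <- NA
  expect_error(load_database(write_toy_db(rows)), "sample_size")
})

test_that("developmental-time measurements are direction-normalized", {
  rows <- toy_db_rows()[1, ]
  # slower development without the symbiont: 12 days vs 10 days with it
  rows$measure_type <- "developmental_time"
  rows$fitness_with <- 10
  rows$fitness_without <- 12
  db <- load_database(write_toy_db(rows))
  # inverted roles: 100 * (12 - 10) / 12
  expect_equal(db$observations$fitness_drop_pct, 100 * 2 / 12)
  # the flag is configurable
  db2 <- load_database(write_toy_db(rows), invert_measures = character(0))
  expect_equal(db2$observations$fitness_drop_pct, -20)
})

test_that("write then re-load round-trips the database", {
  db <- load_database(write_toy_db())
  out <- tempfile(fileext = ".csv")
  write_database(db, out)
  db2 <- load_database(out)
  for (col in names(db$observations)) {
    if (is.numeric(db$observations[[col]])) {
      expect_equal(db2$observations[[col]], db$observations[[col]],
                   tolerance = 1e-9)
    } else {
      expect_identical(db2$observations[[col]], db$observations[[col]])
    }
  }
  expect_equal(db2$records, db$records, tolerance = 1e-9)
})

test_that("per-symbiosis aggregation takes unweighted means per unique pair", {
  obs <- toy_db_rows()
  obs$fitness_drop_pct <- c(40, 60, 30, 0, 100)
  agg <- aggregate_by_symbiosis(obs)
  expect_equal(nrow(agg), 3)
  expect_equal(agg$mean_fitness_drop[agg$symbiont_species == "Buchnera"], 50)
  expect_equal(agg$mean_fitness_drop[agg$symbiont_species == "Nardonella"], 30)
  expect_equal(agg$mean_fitness_drop[agg$symbiont_species == "Endoriftia"], 50)
  # singleton pair keeps its own value; empty input gives empty output
  expect_equal(nrow(aggregate_by_symbiosis(obs[0, ])), 0)
})

test_that("subsetting filters by field values and field presence", {
  db <- load_database(write_toy_db())
  fec <- subset_database(db, list(measure_type = "fecundity"))
  expect_equal(nrow(fec$observations), 2)
  # empty filter is the identity
  expect_equal(subset_database(db, list())$observations, db$observations)
  gs <- subset_database(db, list(has_genome_size = TRUE))
  expect_equal(nrow(gs$observations), 4)
  expect_error(subset_database(db, list(flavour = "x")), "unknown filter")
})

test_that("transmission reclassification touches only the named taxa", {
  db <- load_database(write_toy_db())
  db$observations$obligacy[db$observations$symbiont_species == "Buchnera"] <-
    "facultative"
  db$records <- symbiodep:::build_records(db$observations)
  out <- reclassify_transmission(db, "Buchnera", "horizontal")
  expect_equal(sum(out$observations$transmission != db$observations$transmission), 2)
  expect_true(all(out$observations$transmission[
    out$observations$symbiont_species == "Buchnera"] == "horizontal"))
  # empty taxa list is a no-op; unknown taxa warn but do not fail
  expect_identical(reclassify_transmission(db, character(0)), db)
  expect_warning(reclassify_transmission(db, c("Buchnera", "NotASymbiont")),
                 "NotASymbiont")
  # an obligate symbiont cannot become horizontal
  db2 <- load_database(write_toy_db())
  expect_error(reclassify_transmission(db2, "Nardonella", "horizontal"),
               "consistency")
})
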