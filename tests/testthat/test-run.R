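small_config <- function(dir, seed = 5) {
  run_config(
    cohort = cohort_config(n_target_population = 2000, uptake_prob = 0.5,
                           test_completion_prob = 0.8, seed = seed),
    output_dir = dir
  )
}

test_that("a full run writes a complete, deterministic report bundle", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- full_run(small_config(d1))
  b2 <- full_run(small_config(d2))

  files <- c("participants.csv", "pathway_events.csv", "category_table.csv",
             "projections.csv", "comparisons.csv", "per_ats.csv",
             "metrics.csv", "manifest.yaml")
  expect_true(all(file.exists(file.path(d1, files))))

  # identical seed and configuration -> identical bundles
  expect_identical(b1$records, b2$records)
  expect_identical(b1$category_table, b2$category_table)
  expect_identical(b1$comparisons, b2$comparisons)
  for (f in setdiff(files, "manifest.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # the manifest echoes the seed and configuration
  manifest <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  expect_equal(manifest$seed, 5)
  expect_equal(manifest$cohort$n_target_population, 2000)
})

test_that("an empty target population still produces well-formed reports", {
  d <- withr::local_tempdir()
  cfg <- run_config(cohort = cohort_config(n_target_population = 0, seed = 1),
                    output_dir = d)
  b <- full_run(cfg)
  expect_equal(nrow(b$records), 0)
  expect_equal(b$metrics$uptake_pct, 0)
  expect_equal(nrow(b$projections), 4)
  expect_true(file.exists(file.path(d, "metrics.csv")))
})

test_that("an unwritable output location fails before any computation", {
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)  # a regular file cannot become the output dir
  cfg <- run_config(output_dir = file.path(blocker, "sub"))
  expect_error(full_run(cfg), "not writable|cannot")
})

test_that("run configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    cohort = list(n_target_population = 500, uptake_prob = 0.3, seed = 9),
    n_target = 600,
    scenarios = list(
      list(n_screened = 1412, incidence_per_100k_yr = 21.1),
      list(eligible_population = 861163, participation_rate = 0.15,
           incidence_per_100k_yr = 97.6)
    ),
    comparisons = list(
      list(outcome = "MRI usage", events1 = 312, denominator1 = 16933,
           events2 = 16.8, denominator2 = 1412)
    )
  ), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$cohort$n_target_population, 500)
  expect_equal(cfg$n_target, 600)
  expect_equal(length(cfg$scenarios), 2)
  expect_equal(scenario_grid(cfg$scenarios)$expected_cases, c(0.5, 219.4))
  cmp <- compare_proportions(cfg$comparisons[[1]]$arm1,
                             cfg$comparisons[[1]]$arm2)
  expect_equal(cmp$abs_diff_pct, 0.65)
})

test_that("the pilot fixture runs end to end and reproduces the printed tables", {
  d <- withr::local_tempdir()
  cfg <- run_config(output_dir = d, n_target = pilot_target_population())
  b <- full_run(cfg, records = pilot_cohort())
  expect_equal(b$metrics$uptake_pct, 8.7)
  expect_equal(b$category_table$n[1:4], c(824, 364, 29, 195))
  expect_equal(b$projections$expected_cases, c(0.5, 219.4, 438.7, 585.0))
  expect_equal(b$comparisons$abs_diff_pct, c(6.56, 0.65, 0))
  expect_equal(b$pathway$summary$n_referred, 224L)
})
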