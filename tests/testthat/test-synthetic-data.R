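test_that("identical config and seed give byte-identical written outputs", {
  cfg <- sim_config(n_codes = 60, n_groups = 6, rater_error = 0.2, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_jem_inputs(cfg), d1)
  write_simulation(simulate_jem_inputs(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("latent truth respects the configured prevalence", {
  truth <- simulate_truth(sim_config(prevalence_likely = 0, seed = 1))
  expect_true(all(truth$jem$compound_severity == 0))

  degenerate <- simulate_truth(sim_config(
    prevalence_likely = 1,
    frequency_probs = c(0, 0, 0, 1),
    intensity_probs = c(0, 0, 1),
    seed = 1
  ))
  expect_true(all(degenerate$jem$compound_severity == 12L))

  # default prevalence: likely share within binomial 99% bounds of 84/412
  truth <- simulate_truth(sim_config(seed = 2024))
  p <- 84 / 412
  bounds <- stats::qbinom(c(0.005, 0.995), 412, p)
  expect_gte(sum(truth$jem$likelihood), bounds[1])
  expect_lte(sum(truth$jem$likelihood), bounds[2])
})

test_that("the code universe nests 4-digit codes in 2-digit groups", {
  truth <- simulate_truth(sim_config(n_codes = 412, n_groups = 26, seed = 3))
  expect_equal(nrow(truth$codes), 412)
  expect_equal(length(unique(truth$codes$code2)), 26)
  expect_true(all(substr(truth$codes$code4, 1, 2) == truth$codes$code2))
  expect_false(any(duplicated(truth$codes$code4)))
})

test_that("noiseless raters report the truth; noisy ones stay adjacent and valid", {
  cfg0 <- sim_config(n_codes = 50, n_groups = 5, rater_error = 0, seed = 4)
  truth <- simulate_truth(cfg0)
  panel <- simulate_raters(truth, cfg0)
  joined <- dplyr::inner_join(panel, truth$jem, by = "code4",
                              suffix = c("", "_true"))
  expect_true(all(joined$likelihood == joined$likelihood_true))
  rated <- !is.na(joined$frequency)
  expect_true(all(joined$frequency[rated] == joined$frequency_true[rated]))
  expect_true(all(rated == (joined$likelihood == 1L)))

  cfg1 <- sim_config(n_codes = 200, n_groups = 20, rater_error = 0.3, seed = 5)
  truth1 <- simulate_truth(cfg1)
  panel1 <- simulate_raters(truth1, cfg1)
  expect_equal(nrow(validate_ratings(panel1)), 0)
  # adjacent kernel: reported frequency within one step of truth for codes
  # that are truly likely and reported likely
  j <- dplyr::inner_join(panel1, truth1$jem, by = "code4", suffix = c("", "_true"))
  tp <- j$likelihood == 1L & j$likelihood_true == 1L
  expect_true(all(abs(j$frequency[tp] - j$frequency_true[tp]) <= 1))
  expect_true(all(abs(j$intensity[tp] - j$intensity_true[tp]) <= 1))
})

test_that("simulated workforce follows the rounded-extract convention", {
  sim <- simulate_jem_inputs(sim_config(n_codes = 80, n_groups = 8, seed = 6))
  expect_true(all(sim$workforce$jobholders %% 100 == 0))
  expect_true(all(sim$workforce$jobholders >= 0))
  expect_silent(check_ok <- read_workforce_csv(
    withr::local_tempfile(fileext = ".csv", lines = readr::format_csv(sim$workforce)),
    rounded = TRUE
  ))
})

test_that("simulated crosswalks validate and conserve workforce within the rounding bound", {
  sim <- simulate_jem_inputs(sim_config(
    n_codes = 120, n_groups = 12,
    crosswalk_mix = c(identity = 0.4, merge = 0.3, split = 0.3),
    seed = 7
  ))
  expect_silent(shsjem:::check_crosswalk(sim$crosswalk))
  out <- recode_workforce(sim$workforce, sim$crosswalk)
  expect_lte(abs(sum(out$jobholders) - sum(sim$workforce$jobholders)),
             0.5 * nrow(out))

  pure_identity <- simulate_jem_inputs(sim_config(
    n_codes = 40, n_groups = 4,
    crosswalk_mix = c(identity = 1, merge = 0, split = 0), seed = 8
  ))
  recoded <- recode_workforce(pure_identity$workforce, pure_identity$crosswalk)
  expect_equal(recoded$jobholders, pure_identity$workforce$jobholders)
  expect_equal(recoded$code4, pure_identity$workforce$code4)
})

test_that("class mapping covers every code with classes attached to whole groups", {
  sim <- simulate_jem_inputs(sim_config(n_codes = 100, n_groups = 10,
                                        n_classes = 8, seed = 9))
  expect_setequal(sim$class_mapping$code4, sim$truth$codes$code4)
  per_group <- dplyr::n_distinct(
    dplyr::mutate(sim$class_mapping, code2 = substr(code4, 1, 2)) |>
      dplyr::count(code2, group_id) |>
      dplyr::pull(code2)
  )
  expect_equal(per_group, 10)
  expect_true(all(as.integer(sim$class_mapping$group_id) %in% 1:8))
})

test_that("end-to-end recovery at zero noise matches the latent JEM exactly", {
  cfg <- sim_config(n_codes = 412, n_groups = 26, rater_error = 0, seed = 10)
  sim <- simulate_jem_inputs(cfg)
  jem <- build_jem(sim$ratings)

  truth_summary <- summarize_by_group(sim$truth$jem)
  built_summary <- summarize_by_group(jem)
  expect_equal(as.data.frame(built_summary), as.data.frame(truth_summary))
  expect_equal(mean(jem$likelihood), mean(sim$truth$jem$likelihood))
  expect_equal(attr(built_summary, "overall_mean_severity"),
               mean(sim$truth$jem$compound_severity))

  ct_truth <- cross_tabulate(sim$truth$jem, sim$workforce)
  ct_built <- cross_tabulate(jem, sim$workforce)
  expect_equal(ct_built$cells, ct_truth$cells)
  expect_equal(ct_built$grand_total, sum(sim$workforce$jobholders))
})
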