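test_that("identity crosswalks leave workforce tables unchanged", {
  wf <- tibble::tibble(
    code4 = c("1101", "1102"), version = "v1", jobholders = c(1000, 2500)
  )
  xw <- tibble::tibble(source = wf$code4, target = wf$code4, weight = 1)
  out <- recode_workforce(wf, xw, target_version = "v2")
  expect_equal(out$jobholders, wf$jobholders)
  expect_equal(out$code4, wf$code4)
  expect_equal(attr(out, "rounding_drift"), 0)
})

test_that("splits distribute counts and conserve totals", {
  wf <- tibble::tibble(code4 = "1101", version = "v1", jobholders = 1000)
  xw <- tibble::tibble(source = "1101", target = c("2101", "2102"),
                       weight = c(0.5, 0.5))
  out <- recode_workforce(wf, xw)
  expect_equal(sort(out$jobholders), c(500, 500))
  expect_equal(sum(out$jobholders), 1000)
})

test_that("recoding errors name unmapped codes and bad weights", {
  wf <- tibble::tibble(code4 = c("1101", "1102"), version = "v1",
                       jobholders = c(100, 200))
  xw <- tibble::tibble(source = "1101", target = "1101", weight = 1)
  expect_error(recode_workforce(wf, xw), "1102")
  bad <- tibble::tibble(source = c("1101", "1102"), target = c("1101", "1102"),
                        weight = c(1, 0.7))
  expect_error(recode_workforce(wf, bad), "sum to 1.*1102")
})

test_that("random crosswalks conserve the workforce within the rounding bound", {
  withr::local_seed(17)
  for (rep in 1:20) {
    n <- 50
    wf <- tibble::tibble(
      code4 = sprintf("%04d", 1100 + 1:n),
      version = "v1",
      jobholders = sample.int(99999, n) # deliberately not multiples of 100
    )
    rows <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.5) {
        tibble::tibble(source = wf$code4[i], target = paste0("A", i), weight = 1)
      } else {
        w <- runif(1, 0.1, 0.9)
        tibble::tibble(source = wf$code4[i],
                       target = paste0(c("A", "B"), i),
                       weight = c(w, 1 - w))
      }
    })
    xw <- dplyr::bind_rows(rows)
    out <- recode_workforce(wf, xw)

    # exact oracle: unrounded target masses conserve the total perfectly
    exact <- tapply(
      xw$weight * wf$jobholders[match(xw$source, wf$code4)], xw$target, sum
    )
    expect_equal(sum(exact), sum(wf$jobholders))
    expect_equal(out$jobholders, as.numeric(round(exact[out$code4])),
                 ignore_attr = TRUE)

    drift <- attr(out, "rounding_drift")
    expect_lte(abs(drift), 0.5 * nrow(out))  # documented bound
    expect_lte(abs(drift), n)                # coarser per-source bound
    expect_equal(sum(out$jobholders) - sum(wf$jobholders), drift)
  }
})

test_that("permutation crosswalks are bijections on counts", {
  withr::local_seed(19)
  wf <- tibble::tibble(code4 = sprintf("%04d", 1100 + 1:30), version = "v1",
                       jobholders = sample.int(5000, 30) * 100)
  perm <- sample(wf$code4)
  xw <- tibble::tibble(source = wf$code4, target = perm, weight = 1)
  out <- recode_workforce(wf, xw)
  expect_setequal(out$jobholders, wf$jobholders)
  expect_equal(out$jobholders[match(perm, out$code4)], wf$jobholders)
})

test_that("cross_tabulate routes workers to rating cells and conserves the total", {
  jem <- tibble::tibble(
    code4 = c("1101", "6135", "5101"),
    likelihood = c(0L, 1L, 1L),
    frequency = c(0L, 4L, 3L),
    intensity = c(0L, 3L, 1L),
    compound_severity = c(0L, 12L, 3L)
  )
  wf <- tibble::tibble(code4 = jem$code4, version = "v1",
                       jobholders = c(100, 700, 250))
  ct <- cross_tabulate(jem, wf)
  expect_equal(ct$cells["0", "0"], 100)
  expect_equal(ct$cells["4", "3"], 700) # planted maximum-severity workers
  expect_equal(ct$cells["3", "1"], 250)
  expect_equal(ct$grand_total, sum(wf$jobholders))
  expect_equal(sum(ct$row_totals), ct$grand_total)
  expect_equal(sum(ct$col_totals), ct$grand_total)
  expect_true(is.na(ct$cells["0", "1"]) && is.na(ct$cells["2", "0"]))

  single <- cross_tabulate(jem[1, ], wf[1, ])
  expect_equal(single$cells["0", "0"], 100)
  expect_equal(single$grand_total, 100)

  expect_error(cross_tabulate(jem, wf[-2, ]), "in JEM only: 6135")
  expect_error(cross_tabulate(jem[-2, ], wf), "in workforce only: 6135")
})

test_that("crosstabs round-trip through CSV and reject impossible cells", {
  sim <- simulate_jem_inputs(sim_config(n_codes = 60, n_groups = 6, seed = 23))
  ct <- cross_tabulate(sim$truth$jem, sim$workforce)
  path <- withr::local_tempfile(fileext = ".csv")
  write_crosstab_csv(ct, path)
  back <- as_exposure_crosstab(readr::read_csv(path, show_col_types = FALSE))
  expect_equal(back$cells, ct$cells)
  expect_equal(back$grand_total, ct$grand_total)

  expect_error(
    as_exposure_crosstab(tibble::tibble(frequency = 0, intensity = 2,
                                        jobholders = 10)),
    "impossible"
  )
})

test_that("exposed-worker estimates follow the threshold arithmetic", {
  cells <- tibble::tibble(
    frequency = c(0, 3), intensity = c(0, 3), jobholders = c(900, 100)
  )
  ct <- as_exposure_crosstab(cells)
  est <- exposed_worker_estimates(ct, min_prevalence = 0.10)
  expect_equal(est$n_in_exposed_jobs, 100)
  expect_equal(est$share_of_jobs, 0.1)
  expect_equal(est$lower_bound_exposed, 10)

  # linear and increasing in the prevalence threshold
  ps <- c(0.05, 0.1, 0.2, 0.4)
  lbs <- vapply(ps, function(p) {
    exposed_worker_estimates(ct, p)$lower_bound_exposed
  }, numeric(1))
  expect_equal(lbs, 100 * ps)
  expect_true(all(diff(lbs) > 0))

  none <- as_exposure_crosstab(tibble::tibble(frequency = 0, intensity = 0,
                                              jobholders = 500))
  est0 <- exposed_worker_estimates(none)
  expect_equal(est0$n_in_exposed_jobs, 0)
  expect_equal(est0$share_of_jobs, 0)
  expect_equal(est0$lower_bound_exposed, 0)

  empty <- as_exposure_crosstab(tibble::tibble(frequency = 0, intensity = 0,
                                               jobholders = 0))
  expect_error(exposed_worker_estimates(empty), "empty")
  expect_error(exposed_worker_estimates(ct, min_prevalence = 0), "0, 1")
})
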