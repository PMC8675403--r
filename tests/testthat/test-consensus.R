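test_that("resolve_axis applies the adjudication rules", {
  expect_equal(resolve_axis(c(1L, 1L, 0L)),
               list(level = 1L, provenance = "majority"))
  expect_equal(resolve_axis(c(2L, 3L)),
               list(level = 3L, provenance = "higher_of_two"))
  expect_equal(resolve_axis(c(4L, 4L, 4L)),
               list(level = 4L, provenance = "unanimous"))
  expect_equal(resolve_axis(3L),
               list(level = 3L, provenance = "unanimous"))
  expect_equal(suppressMessages(resolve_axis(c(1L, 2L, 3L))),
               list(level = 2L, provenance = "tiebreak"))
})

test_that("three distinct ratings honour the tiebreak policy", {
  expect_message(res <- resolve_axis(c(3L, 1L, 2L)), "tiebreak")
  expect_equal(res$level, 2L)
  expect_warning(resolve_axis(c(1L, 2L, 3L), consensus_policy("flag_and_median")),
                 "median")
  expect_error(resolve_axis(c(1L, 2L, 3L), consensus_policy("error")),
               "strict")

  # median tie-break of a fully ordered distinct triple is its middle element
  for (v in list(c(0L, 3L, 4L), c(2L, 4L, 1L), c(1L, 3L, 2L))) {
    expect_equal(suppressMessages(resolve_axis(v))$level, sort(v)[2])
  }
})

test_that("resolve_axis is invariant to rater order and rejects bad panels", {
  withr::local_seed(21)
  for (rep in 1:50) {
    v <- sample(0:4, sample(2:3, 1), replace = TRUE)
    base <- suppressMessages(resolve_axis(v))
    perm <- suppressMessages(resolve_axis(sample(v)))
    expect_equal(perm, base)
  }
  expect_error(resolve_axis(integer()), "no ratings")
  expect_error(resolve_axis(c(1L, NA)), "missing")
  expect_error(resolve_axis(c(1L, 1L, 2L, 2L)), "at most three")
})

test_that("build_jem resolves the documented example panels", {
  tbl <- make_ratings(
    # unanimous unexposed
    ratings_row("r1", "2101", 0), ratings_row("r2", "2101", 0),
    ratings_row("r3", "2101", 0),
    # majority likely, conditional axes from the two raters who rated them
    ratings_row("r1", "6135", 1, f = 4, i = 3),
    ratings_row("r2", "6135", 1, f = 4, i = 3),
    ratings_row("r3", "6135", 0),
    # majority on frequency, higher-of-two on intensity
    ratings_row("r1", "5101", 1, f = 2, i = 3),
    ratings_row("r2", "5101", 1, f = 3, i = 2),
    ratings_row("r3", "5101", 1, f = 3, i = NA)
  )
  tbl$intensity[tbl$code4 == "5101" & tbl$rater_id == "r3"] <- NA_integer_
  jem <- build_jem(tbl, validate = FALSE)

  r2101 <- jem[jem$code4 == "2101", ]
  expect_equal(r2101$compound_severity, 0L)
  expect_equal(r2101$provenance_likelihood, "unanimous")
  expect_true(is.na(r2101$provenance_frequency))

  r6135 <- jem[jem$code4 == "6135", ]
  expect_equal(
    unlist(r6135[, c("likelihood", "frequency", "intensity", "compound_severity")]),
    c(likelihood = 1L, frequency = 4L, intensity = 3L, compound_severity = 12L)
  )
  expect_equal(r6135$provenance_likelihood, "majority")
  expect_equal(r6135$provenance_frequency, "unanimous")

  r5101 <- jem[jem$code4 == "5101", ]
  expect_equal(r5101$frequency, 3L)
  expect_equal(r5101$provenance_frequency, "majority")
  expect_equal(r5101$intensity, 3L)
  expect_equal(r5101$provenance_intensity, "higher_of_two")
  expect_equal(r5101$compound_severity, 9L)
})

test_that("build_jem is idempotent on already-agreed ratings", {
  truth <- simulate_truth(sim_config(n_codes = 50, n_groups = 5,
                                     rater_error = 0, seed = 2))
  panel <- simulate_raters(truth)
  jem <- build_jem(panel)
  cols <- c("code4", "likelihood", "frequency", "intensity", "compound_severity")
  expect_equal(as.data.frame(jem[cols]),
               as.data.frame(dplyr::arrange(truth$jem[cols], code4)))
  expect_true(all(jem$provenance_likelihood == "unanimous"))
})

test_that("build_jem validates input, guards rounds, and flags starved axes", {
  expect_error(
    build_jem(make_ratings(ratings_row("r1", "1101", 0, f = 2))),
    "violation"
  )
  two_rounds <- make_ratings(
    ratings_row("r1", "1101", 0, round = 1L),
    ratings_row("r1", "1101", 0, round = 2L)
  )
  expect_error(build_jem(two_rounds), "single round")

  # consensus likelihood 1 with no frequency rating anywhere: only reachable
  # on an invalid table, so bypass validation to exercise the guard
  starved <- make_ratings(ratings_row("r1", "1101", 1, f = NA, i = NA))
  expect_error(build_jem(starved, validate = FALSE), "no rater supplied")
})

test_that("every emitted record satisfies the JEM invariants (fuzz)", {
  for (seed in 1:12) {
    cfg <- sim_config(
      n_codes = 40, n_groups = 4,
      rater_error = c(0.1, 0.3, 0.5)[1 + seed %% 3],
      deviation_kernel = if (seed %% 2 == 0) "adjacent" else "uniform",
      seed = seed
    )
    jem <- suppressMessages(
      build_jem(simulate_raters(simulate_truth(cfg), cfg))
    )
    expect_equal(nrow(jem), 40)
    expect_true(all(jem$compound_severity ==
                      jem$likelihood * jem$frequency * jem$intensity))
    lik0 <- jem$likelihood == 0L
    expect_true(all(jem$frequency[lik0] == 0L & jem$intensity[lik0] == 0L))
    expect_true(all(jem$compound_severity %in% c(0L, 1L, 2L, 3L, 4L, 6L, 8L, 9L, 12L)))
    expect_true(all(jem$provenance_likelihood %in%
                      c("unanimous", "majority", "higher_of_two", "tiebreak")))
  }
})

test_that("consensus recovers the latent truth at zero noise and most of it at 10%", {
  exact <- simulate_jem_inputs(sim_config(n_codes = 250, n_groups = 25,
                                          rater_error = 0, seed = 31))
  jem0 <- build_jem(exact$ratings)
  cols <- c("code4", "likelihood", "frequency", "intensity")
  expect_equal(as.data.frame(jem0[cols]),
               as.data.frame(dplyr::arrange(exact$truth$jem[cols], code4)))

  noisy <- simulate_jem_inputs(sim_config(n_codes = 250, n_groups = 25,
                                          rater_error = 0.1, seed = 32))
  jem1 <- suppressMessages(build_jem(noisy$ratings))
  truth <- dplyr::arrange(noisy$truth$jem, code4)
  recovered <- mean(jem1$likelihood == truth$likelihood)
  expect_gte(recovered, 0.95)
})
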