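#' Compound severity of second-hand smoke exposure
#'
#' The single per-occupation exposure score: the product of the consensus
#' likelihood, frequency and intensity ratings. With likelihood binary,
#' frequency 0--4 and intensity 0--3 under the conditional scheme, the score
#' ranges over \{0, 1, 2, 3, 4, 6, 8, 9, 12\}; 12 (likelihood 1, daily for
#' over an hour, indoors in a poorly ventilated space) is the attainable
#' maximum. Any code with likelihood 0 scores 0.
#'
#' @param likelihood,frequency,intensity Integer vectors of consensus levels
#'   (recycled to a common length).
#' @param scheme A rating scheme, by default [shs_rating_scheme()].
#' @return Integer vector of severity scores.
#' @examples
#' compound_severity(1L, 4L, 3L) # 12, the maximum
#' compound_severity(0L, 0L, 0L) # 0
#' @export
compound_severity <- function(likelihood, frequency, intensity,
                              scheme = shs_rating_scheme()) {
  n <- max(length(likelihood), length(frequency), length(intensity))
  likelihood <- rep_len(as.integer(likelihood), n)
  frequency <- rep_len(as.integer(frequency), n)
  intensity <- rep_len(as.integer(intensity), n)
  check_level <- function(v, axis) {
    bad <- !is.na(v) & !(v %in% scheme_levels(scheme, axis))
    if (any(bad)) {
      rlang::abort(paste0(
        "illegal ", axis, " level(s): ",
        paste(utils::head(unique(v[bad]), 5), collapse = ", ")
      ))
    }
  }
  check_level(likelihood, "likelihood")
  check_level(frequency, "frequency")
  check_level(intensity, "intensity")
  if (any(stats::complete.cases(likelihood, frequency, intensity) &
          likelihood == 0L & (frequency != 0L | intensity != 0L))) {
    rlang::abort("likelihood 0 requires frequency = intensity = 0 in a JEM record")
  }
  likelihood * frequency * intensity
}

#' Enumerate all legal rating triples and their severities
#'
#' Under the conditional scheme the legal consensus triples are (0, 0, 0)
#' plus (1, f, i) for frequency f in 1--4 and intensity i in 1--3. This
#' exhaustive enumeration defines the attainable severity set and its
#' maximum.
#'
#' @param scheme A rating scheme, by default [shs_rating_scheme()].
#' @return A tibble with columns `likelihood`, `frequency`, `intensity`,
#'   `compound_severity`, one row per legal triple.
#' @export
enumerate_severity_triples <- function(scheme = shs_rating_scheme()) {
  exposed <- tidyr::expand_grid(
    likelihood = 1L,
    frequency = setdiff(scheme_levels(scheme, "frequency"), 0L),
    intensity = setdiff(scheme_levels(scheme, "intensity"), 0L)
  )
  triples <- dplyr::bind_rows(
    tibble::tibble(likelihood = 0L, frequency = 0L, intensity = 0L),
    exposed
  )
  dplyr::mutate(triples, compound_severity = compound_severity(
    .data$likelihood, .data$frequency, .data$intensity, scheme = scheme
  ))
}

#' Summarise a JEM by occupation group or socioeconomic class
#'
#' Per-group counts of codes, counts and fractions of codes rated likely
#' (likelihood 1), and the unweighted mean compound severity over codes.
#' Grouping defaults to the 2-digit parent group derived from each code; any
#' other grouping (e.g. an NS-SEC analytic-class mapping, supplied as a
#' lookup table) can be passed explicitly. The mean is per-code, not
#' workforce-weighted; see [cross_tabulate()] for workforce-weighted views.
#'
#' @param jem A JEM tibble (see [build_jem()]).
#' @param grouping Optional tibble with columns `code4` and `group_id`
#'   mapping every JEM code to a group; `NULL` groups by 2-digit code.
#' @return A tibble with columns `group_id`, `n_codes`, `n_likely`,
#'   `fraction_likely`, `mean_severity`, one row per group, with attributes
#'   `overall_mean_severity` and `severity_range` for the whole JEM.
#' @examples
#' jem <- synthetic_reference_jem()
#' summarize_by_group(jem)
#' @export
summarize_by_group <- function(jem, grouping = NULL) {
  check_jem(jem)
  if (is.null(grouping)) {
    grouping <- tibble::tibble(
      code4 = jem$code4,
      group_id = substr(jem$code4, 1, 2)
    )
  }
  if (!all(c("code4", "group_id") %in% names(grouping))) {
    rlang::abort("grouping must have columns code4 and group_id")
  }
  missing <- setdiff(jem$code4, grouping$code4)
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "codes missing from grouping: ",
      paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) paste0(" (and ", length(missing) - 5, " more)") else ""
    ))
  }
  out <- jem |>
    dplyr::inner_join(grouping[, c("code4", "group_id")], by = "code4") |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      n_codes = dplyr::n(),
      n_likely = sum(.data$likelihood == 1L),
      mean_severity = mean(.data$compound_severity),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction_likely = .data$n_likely / .data$n_codes) |>
    dplyr::select("group_id", "n_codes", "n_likely", "fraction_likely", "mean_severity") |>
    dplyr::arrange(.data$group_id)
  attr(out, "overall_mean_severity") <- mean(jem$compound_severity)
  attr(out, "severity_range") <- range(jem$compound_severity)
  out
}

#' Rank occupation codes by compound severity
#'
#' Sorts codes by severity, worst first, with ties broken by ascending code,
#' and flags the subset at the table's maximum severity (the most exposed
#' occupations; at the attainable maximum of 12 these are jobs with daily,
#' prolonged exposure indoors in poorly ventilated spaces).
#'
#' @param jem A JEM tibble.
#' @return A tibble with columns `code4`, `compound_severity`, `at_maximum`,
#'   sorted by descending severity then ascending code.
#' @export
top_severity_codes <- function(jem) {
  check_jem(jem)
  if (nrow(jem) == 0) rlang::abort("JEM is empty")
  jem |>
    dplyr::select("code4", "compound_severity") |>
    dplyr::arrange(dplyr::desc(.data$compound_severity), .data$code4) |>
    dplyr::mutate(at_maximum = .data$compound_severity == max(.data$compound_severity))
}
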