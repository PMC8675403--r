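#' Consensus adjudication policy
#'
#' Controls how a three-way split (three raters, three distinct levels) is
#' resolved. The documented adjudication rules — unanimity, the value given
#' by two of three raters, and the higher value when only two raters rated
#' an axis — leave the all-distinct case undefined, so it is a policy choice:
#'
#' * `"median"` (default): take the ordinal median, record provenance
#'   `"tiebreak"`, and log a message;
#' * `"flag_and_median"`: as `"median"` but raise a warning so the case
#'   is hard to miss in batch runs;
#' * `"error"`: strict mode, abort instead.
#'
#' @param tiebreak_three_distinct One of `"median"`, `"flag_and_median"`,
#'   `"error"`.
#' @return An object of class `shs_consensus_policy`.
#' @export
consensus_policy <- function(tiebreak_three_distinct = c("median", "flag_and_median", "error")) {
  tiebreak_three_distinct <- rlang::arg_match(tiebreak_three_distinct)
  structure(
    list(
      tiebreak_three_distinct = tiebreak_three_distinct,
      axis_order = c("likelihood", "frequency", "intensity")
    ),
    class = "shs_consensus_policy"
  )
}

#' Resolve one axis' ratings to a single consensus level
#'
#' Applies the post-discussion adjudication rules to the 1--3 ratings a code
#' received on one axis:
#'
#' * all ratings equal (including a single rating) -> that value,
#'   provenance `"unanimous"`;
#' * three ratings, exactly two equal -> the repeated value, `"majority"`;
#' * two distinct ratings -> the higher (worse) value, `"higher_of_two"`;
#' * three distinct ratings -> per [consensus_policy()] (default: ordinal
#'   median, `"tiebreak"`).
#'
#' @param values Integer vector of 1 to 3 legal levels (no missing values;
#'   raters who did not rate the axis are simply absent).
#' @param policy A [consensus_policy()].
#' @param what Label used in messages (e.g. the axis and code being resolved).
#' @return A list with `level` (integer) and `provenance` (character).
#' @examples
#' resolve_axis(c(1L, 1L, 0L)) # majority -> 1
#' resolve_axis(c(2L, 3L))     # higher_of_two -> 3
#' @export
resolve_axis <- function(values, policy = consensus_policy(), what = "axis") {
  if (length(values) == 0) {
    rlang::abort(paste0("no ratings for ", what))
  }
  if (anyNA(values)) {
    rlang::abort(paste0("missing values passed to resolve_axis for ", what))
  }
  if (length(values) > 3) {
    rlang::abort("adjudication rules are defined for panels of at most three ratings per axis")
  }
  values <- as.integer(values)
  distinct <- unique(values)
  if (length(distinct) == 1) {
    return(list(level = distinct, provenance = "unanimous"))
  }
  if (length(values) == 2) {
    return(list(level = max(values), provenance = "higher_of_two"))
  }
  # three ratings, not all equal
  if (length(distinct) == 2) {
    tab <- table(values)
    repeated <- as.integer(names(tab)[which.max(tab)])
    return(list(level = repeated, provenance = "majority"))
  }
  # three distinct ratings
  mode <- policy$tiebreak_three_distinct
  if (mode == "error") {
    rlang::abort(paste0(
      "three distinct ratings for ", what,
      " cannot be resolved under the strict policy"
    ))
  }
  med <- as.integer(sort(values)[2])
  msg <- paste0(
    "three distinct ratings for ", what, "; ordinal median ", med,
    " taken (provenance 'tiebreak')"
  )
  if (mode == "flag_and_median") {
    rlang::warn(msg)
  } else {
    message(msg)
  }
  list(level = med, provenance = "tiebreak")
}

#' Build a consensus JEM from a multi-rater rating table
#'
#' Collapses the (typically second-round) ratings of up to three raters into
#' one JEM record per occupation code. Likelihood is always resolved first,
#' over all raters who rated it. If the consensus likelihood is 0 the code's
#' frequency and intensity are 0 by the conditional scheme (no adjudication;
#' their provenance is `NA`). If it is 1, frequency and intensity are each
#' resolved over the subset of raters who rated that axis — raters who scored
#' likelihood 0 contributed no frequency/intensity rating and are simply
#' absent from those panels.
#'
#' @param ratings A rating table (single round) with columns `rater_id`,
#'   `code4`, `round`, `likelihood`, `frequency`, `intensity`.
#' @param policy A [consensus_policy()].
#' @param scheme A rating scheme, by default [shs_rating_scheme()].
#' @param validate Validate the table with [validate_ratings()] first
#'   (default `TRUE`); violations abort with a count and examples.
#' @return A JEM tibble: one row per code with `code4`, `code2`,
#'   `likelihood`, `frequency`, `intensity`, `compound_severity` and
#'   per-axis provenance columns (`provenance_likelihood`,
#'   `provenance_frequency`, `provenance_intensity`).
#' @export
build_jem <- function(ratings, policy = consensus_policy(),
                      scheme = shs_rating_scheme(), validate = TRUE) {
  if ("round" %in% names(ratings)) {
    rounds <- unique(ratings$round)
    if (length(rounds) > 1) {
      rlang::abort(paste0(
        "ratings span rounds ", paste(sort(rounds), collapse = ", "),
        "; filter to a single round before building the JEM"
      ))
    }
  }
  if (validate) {
    v <- validate_ratings(ratings, scheme = scheme)
    if (nrow(v) > 0) {
      rlang::abort(paste0(
        nrow(v), " rating violation(s); first: row ", v$row[1], " (",
        v$rule[1], ": ", v$detail[1], "). Run validate_ratings() for the full report."
      ))
    }
  }

  by_code <- split(ratings, ratings$code4)
  no_freq <- character()
  no_int <- character()
  records <- lapply(by_code, function(r) {
    code <- r$code4[1]
    lik_vals <- r$likelihood[!is.na(r$likelihood)]
    lik <- resolve_axis(lik_vals, policy, what = paste0("likelihood of code ", code))
    if (lik$level == 0L) {
      return(tibble::tibble(
        code4 = code,
        likelihood = 0L, frequency = 0L, intensity = 0L,
        provenance_likelihood = lik$provenance,
        provenance_frequency = NA_character_,
        provenance_intensity = NA_character_
      ))
    }
    f_vals <- r$frequency[!is.na(r$frequency)]
    i_vals <- r$intensity[!is.na(r$intensity)]
    if (length(f_vals) == 0) no_freq <<- c(no_freq, code)
    if (length(i_vals) == 0) no_int <<- c(no_int, code)
    if (length(f_vals) == 0 || length(i_vals) == 0) return(NULL)
    fr <- resolve_axis(f_vals, policy, what = paste0("frequency of code ", code))
    it <- resolve_axis(i_vals, policy, what = paste0("intensity of code ", code))
    tibble::tibble(
      code4 = code,
      likelihood = 1L, frequency = fr$level, intensity = it$level,
      provenance_likelihood = lik$provenance,
      provenance_frequency = fr$provenance,
      provenance_intensity = it$provenance
    )
  })
  starved <- unique(c(no_freq, no_int))
  if (length(starved) > 0) {
    rlang::abort(paste0(
      "consensus likelihood is 1 but no rater supplied frequency/intensity for: ",
      paste(utils::head(sort(starved), 5), collapse = ", ")
    ))
  }
  jem <- dplyr::bind_rows(records)
  jem <- dplyr::mutate(
    jem,
    code2 = substr(.data$code4, 1, 2),
    compound_severity = compound_severity(
      .data$likelihood, .data$frequency, .data$intensity, scheme = scheme
    )
  )
  dplyr::select(
    jem, "code4", "code2", "likelihood", "frequency", "intensity",
    "compound_severity", dplyr::starts_with("provenance_")
  ) |>
    dplyr::arrange(.data$code4)
}
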