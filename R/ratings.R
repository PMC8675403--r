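#' Read and write rater score tables
#'
#' A rating table holds one row per (rater, occupation code, round) with the
#' three conditional axis ratings. An empty cell is a missing rating, which
#' is distinct from level 0: a rater who scores likelihood 0 ("fewer than 10%
#' of jobholders exposed") leaves frequency and intensity blank, whereas
#' frequency 0 ("never") is a substantive rating that only appears in
#' finished JEM records.
#'
#' @param path Path to a CSV file with columns `rater_id`, `code4`, `round`,
#'   `likelihood`, `frequency`, `intensity` (UTF-8, header required).
#' @return A tibble with those columns; `code4` and `rater_id` are character,
#'   `round` and the three ratings are integer, missing ratings are `NA`.
#' @seealso [validate_ratings()]
#' @export
read_ratings_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("ratings file not found: ", path))
  }
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      rater_id = readr::col_character(),
      code4 = readr::col_character(),
      round = readr::col_integer(),
      likelihood = readr::col_integer(),
      frequency = readr::col_integer(),
      intensity = readr::col_integer()
    )
  )
  required <- c("rater_id", "code4", "round", "likelihood", "frequency", "intensity")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "ratings CSV is missing columns: ", paste(missing, collapse = ", ")
    ))
  }
  out[required]
}

#' @param ratings A rating table as returned by [read_ratings_csv()].
#' @rdname read_ratings_csv
#' @export
write_ratings_csv <- function(ratings, path) {
  readr::write_csv(ratings, path, na = "")
  invisible(path)
}

#' Validate a rating table against the conditional rating scheme
#'
#' Checks every row of a multi-rater rating table against the scheme's
#' invariants and returns all violations rather than stopping at the first:
#'
#' * every rated level must belong to its axis' level set;
#' * a likelihood-0 rating must leave frequency and intensity missing
#'   (the conditional scheme: no further rating is required);
#' * a likelihood-1 rating must carry frequency in 1--4 and intensity in
#'   1--3 (a rater who judges exposure likely cannot rate it "never"/"none").
#'
#' Duplicate (rater_id, code4, round) keys are a hard error: the table is
#' structurally broken and per-row reporting would be misleading.
#'
#' @param ratings A tibble with columns `rater_id`, `code4`, `round`,
#'   `likelihood`, `frequency`, `intensity`.
#' @param scheme A rating scheme, by default [shs_rating_scheme()].
#' @return A tibble of violations with columns `row`, `rater_id`, `code4`,
#'   `round`, `rule`, `detail`; zero rows if and only if the table is valid.
#' @examples
#' bad <- tibble::tibble(
#'   rater_id = "r1", code4 = "1101", round = 2L,
#'   likelihood = 0L, frequency = 3L, intensity = NA_integer_
#' )
#' validate_ratings(bad)
#' @export
validate_ratings <- function(ratings, scheme = shs_rating_scheme()) {
  if (nrow(ratings) == 0) {
    rlang::abort("rating table is empty")
  }
  key <- paste(ratings$rater_id, ratings$code4, ratings$round, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    shown <- utils::head(gsub("\r", " / ", dup), 5)
    rlang::abort(paste0(
      "duplicate (rater_id, code4, round) keys in rating table: ",
      paste(shown, collapse = "; ")
    ))
  }

  violations <- list()
  flag <- function(idx, rule, detail) {
    if (!any(idx)) return(invisible(NULL))
    violations[[length(violations) + 1]] <<- tibble::tibble(
      row = which(idx),
      rater_id = ratings$rater_id[idx],
      code4 = ratings$code4[idx],
      round = ratings$round[idx],
      rule = rule,
      detail = detail
    )
  }

  for (axis in c("likelihood", "frequency", "intensity")) {
    v <- ratings[[axis]]
    out_of_scheme <- !is.na(v) & !(v %in% scheme_levels(scheme, axis))
    flag(out_of_scheme, "level outside scheme",
         paste0(axis, " level not in {",
                paste(scheme_levels(scheme, axis), collapse = ","), "}"))
  }

  lik0 <- !is.na(ratings$likelihood) & ratings$likelihood == 0L
  flag(lik0 & (!is.na(ratings$frequency) | !is.na(ratings$intensity)),
       "conditional rating breached",
       "likelihood 0 must leave frequency and intensity missing")

  lik1 <- !is.na(ratings$likelihood) & ratings$likelihood == 1L
  freq_ok <- !is.na(ratings$frequency) &
    ratings$frequency %in% setdiff(scheme_levels(scheme, "frequency"), 0L)
  int_ok <- !is.na(ratings$intensity) &
    ratings$intensity %in% setdiff(scheme_levels(scheme, "intensity"), 0L)
  flag(lik1 & !freq_ok, "conditional rating breached",
       "likelihood 1 requires frequency in 1-4")
  flag(lik1 & !int_ok, "conditional rating breached",
       "likelihood 1 requires intensity in 1-3")

  if (length(violations) == 0) {
    return(tibble::tibble(
      row = integer(), rater_id = character(), code4 = character(),
      round = integer(), rule = character(), detail = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(violations), .data$row)
}
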