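#' Read a workforce-count table
#'
#' Jobholder counts per 4-digit occupation code, as extracted from official
#' labour-market statistics (Nomis-style: counts rounded to the nearest 100).
#'
#' @param path CSV with columns `code4`, `version`, `jobholders`.
#' @param rounded If `TRUE`, assert that every count is a multiple of 100
#'   (the rounded-extract convention).
#' @return A tibble with columns `code4` (character), `version` (character),
#'   `jobholders` (double, whole numbers).
#' @export
read_workforce_csv <- function(path, rounded = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("workforce file not found: ", path))
  }
  wf <- readr::read_csv(
    path,
    col_types = readr::cols(
      code4 = readr::col_character(),
      version = readr::col_character(),
      jobholders = readr::col_double()
    )
  )
  check_workforce(wf, rounded = rounded)
  wf
}

check_workforce <- function(wf, rounded = FALSE) {
  required <- c("code4", "version", "jobholders")
  missing <- setdiff(required, names(wf))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "workforce table is missing columns: ", paste(missing, collapse = ", ")
    ))
  }
  if (any(is.na(wf$jobholders)) || any(wf$jobholders < 0)) {
    rlang::abort("jobholder counts must be non-negative and non-missing")
  }
  key <- paste(wf$code4, wf$version)
  dup <- unique(wf$code4[duplicated(key)])
  if (length(dup) > 0) {
    rlang::abort(paste0(
      "duplicate code4 within a workforce version: ",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  if (rounded && any(wf$jobholders %% 100 != 0)) {
    rlang::abort("rounded extract declared but some counts are not multiples of 100")
  }
  invisible(wf)
}

#' Read an occupation-code crosswalk
#'
#' A crosswalk maps each source 4-digit code to one or more target codes with
#' weights that sum to 1 per source (how the source code's jobholders are
#' split across target codes). If the file has no `weight` column an equal
#' split across each source's targets is assumed, with a loud warning —
#' silent assumptions about occupational recoding materially change counts,
#' so supply explicit weights whenever the true split is known.
#'
#' @param path CSV with columns `source`, `target` and optionally `weight`.
#' @return A tibble with columns `source`, `target`, `weight`.
#' @export
read_crosswalk_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("crosswalk file not found: ", path))
  }
  xw <- readr::read_csv(path, col_types = readr::cols(
    source = readr::col_character(),
    target = readr::col_character(),
    .default = readr::col_double()
  ))
  if (!all(c("source", "target") %in% names(xw))) {
    rlang::abort("crosswalk CSV needs columns source and target")
  }
  if (!"weight" %in% names(xw)) {
    rlang::warn(paste0(
      "crosswalk has no weight column: assuming an EQUAL split of each ",
      "source code across its targets; supply explicit weights if known"
    ))
    xw <- xw |>
      dplyr::group_by(.data$source) |>
      dplyr::mutate(weight = 1 / dplyr::n()) |>
      dplyr::ungroup()
  }
  check_crosswalk(xw)
  xw[, c("source", "target", "weight")]
}

check_crosswalk <- function(xwalk) {
  if (!all(c("source", "target", "weight") %in% names(xwalk))) {
    rlang::abort("crosswalk needs columns source, target, weight")
  }
  if (any(is.na(xwalk$weight)) || any(xwalk$weight <= 0) || any(xwalk$weight > 1)) {
    rlang::abort("crosswalk weights must lie in (0, 1]")
  }
  sums <- tapply(xwalk$weight, xwalk$source, sum)
  off <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(off) > 0) {
    rlang::abort(paste0(
      "crosswalk weights do not sum to 1 for source code(s): ",
      paste(utils::head(off, 5), collapse = ", ")
    ))
  }
  invisible(xwalk)
}

#' Recode workforce counts to another classification version
#'
#' Redistributes each source code's jobholders over its target codes
#' according to the crosswalk weights, then rounds each target total
#' half-to-even to a whole count. Rounding happens once per target code, so
#' the total workforce is conserved to within 0.5 per target code (and the
#' realised drift is reported in the `rounding_drift` attribute, never
#' hidden).
#'
#' @param wf A workforce table (see [read_workforce_csv()]).
#' @param xwalk A crosswalk table (see [read_crosswalk_csv()]).
#' @param target_version Version tag for the output table.
#' @return A workforce tibble in the target version with attribute
#'   `rounding_drift` = output total minus input total.
#' @examples
#' wf <- tibble::tibble(code4 = "1101", version = "v1", jobholders = 1000)
#' xw <- tibble::tibble(source = "1101", target = c("2101", "2102"),
#'                      weight = c(0.5, 0.5))
#' recode_workforce(wf, xw, target_version = "v2")
#' @export
recode_workforce <- function(wf, xwalk, target_version = "target") {
  check_workforce(wf)
  check_crosswalk(xwalk)
  unmapped <- setdiff(wf$code4, xwalk$source)
  if (length(unmapped) > 0) {
    rlang::abort(paste0(
      "source codes missing from crosswalk: ",
      paste(utils::head(unmapped, 5), collapse = ", "),
      if (length(unmapped) > 5) paste0(" (and ", length(unmapped) - 5, " more)") else ""
    ))
  }
  out <- wf |>
    dplyr::inner_join(xwalk, by = c(code4 = "source"),
                      relationship = "many-to-many") |>
    dplyr::group_by(code4 = .data$target) |>
    dplyr::summarise(jobholders = sum(.data$weight * .data$jobholders),
                     .groups = "drop") |>
    dplyr::mutate(jobholders = round(.data$jobholders),
                  version = target_version) |>
    dplyr::select("code4", "version", "jobholders") |>
    dplyr::arrange(.data$code4)
  attr(out, "rounding_drift") <- sum(out$jobholders) - sum(wf$jobholders)
  out
}

#' Cross-tabulate jobholders by exposure frequency and intensity
#'
#' Joins a consensus JEM to a workforce table and accumulates each code's
#' jobholders into the cell indexed by the code's frequency and intensity
#' ratings. All workers in likelihood-0 codes fall in the (0, 0) cell.
#' Structurally impossible cells — frequency 0 with positive intensity, or
#' positive frequency with intensity 0 — are `NA`, not zero. The two tables
#' must share a code universe exactly; codes present on one side only are an
#' error listing them.
#'
#' @param jem A JEM tibble.
#' @param wf A workforce table for the same classification version.
#' @return An object of class `shs_crosstab`: a list with `cells` (5 x 4
#'   matrix, frequency in rows, intensity in columns), `row_totals`,
#'   `col_totals`, `grand_total`.
#' @export
cross_tabulate <- function(jem, wf) {
  check_jem(jem)
  check_workforce(wf)
  only_wf <- setdiff(wf$code4, jem$code4)
  only_jem <- setdiff(jem$code4, wf$code4)
  if (length(only_wf) > 0 || length(only_jem) > 0) {
    parts <- c(
      if (length(only_wf) > 0)
        paste0("in workforce only: ", paste(utils::head(only_wf, 5), collapse = ", ")),
      if (length(only_jem) > 0)
        paste0("in JEM only: ", paste(utils::head(only_jem, 5), collapse = ", "))
    )
    rlang::abort(paste0(
      "JEM and workforce tables do not share a code universe; ",
      paste(parts, collapse = "; ")
    ))
  }
  scheme <- shs_rating_scheme()
  f_levels <- scheme_levels(scheme, "frequency")
  i_levels <- scheme_levels(scheme, "intensity")
  cells <- matrix(0, nrow = length(f_levels), ncol = length(i_levels),
                  dimnames = list(frequency = f_levels, intensity = i_levels))
  joined <- dplyr::inner_join(
    jem[, c("code4", "frequency", "intensity")],
    wf[, c("code4", "jobholders")],
    by = "code4"
  )
  for (k in seq_len(nrow(joined))) {
    f <- joined$frequency[k] + 1L
    i <- joined$intensity[k] + 1L
    cells[f, i] <- cells[f, i] + joined$jobholders[k]
  }
  cells[1, -1] <- NA # frequency "never" cannot have positive intensity
  cells[-1, 1] <- NA # positive frequency cannot have intensity "none"
  new_crosstab(cells)
}

new_crosstab <- function(cells) {
  structure(
    list(
      cells = cells,
      row_totals = rowSums(cells, na.rm = TRUE),
      col_totals = colSums(cells, na.rm = TRUE),
      grand_total = sum(cells, na.rm = TRUE)
    ),
    class = "shs_crosstab"
  )
}

#' Construct a cross-tabulation from cell counts
#'
#' Builds an [cross_tabulate()]-style object directly from a long table of
#' (frequency, intensity, jobholders) cells — for instance a published
#' national tabulation typed in as a fixture, or a crosstab CSV written by
#' [write_crosstab_csv()].
#'
#' @param cells A tibble/data frame with columns `frequency`, `intensity`,
#'   `jobholders`; omitted legal cells are 0. Structurally impossible cells
#'   with positive counts are an error.
#' @return An `shs_crosstab` object.
#' @export
as_exposure_crosstab <- function(cells) {
  required <- c("frequency", "intensity", "jobholders")
  if (!all(required %in% names(cells))) {
    rlang::abort("cells must have columns frequency, intensity, jobholders")
  }
  scheme <- shs_rating_scheme()
  f_levels <- scheme_levels(scheme, "frequency")
  i_levels <- scheme_levels(scheme, "intensity")
  if (!all(cells$frequency %in% f_levels) || !all(cells$intensity %in% i_levels)) {
    rlang::abort("cell indices outside the rating scheme")
  }
  impossible <- (cells$frequency == 0 & cells$intensity > 0) |
    (cells$frequency > 0 & cells$intensity == 0)
  if (any(impossible & cells$jobholders > 0)) {
    rlang::abort("positive counts in structurally impossible cells")
  }
  if (any(is.na(cells$jobholders)) || any(cells$jobholders < 0)) {
    rlang::abort("cell counts must be non-negative and non-missing")
  }
  m <- matrix(0, nrow = length(f_levels), ncol = length(i_levels),
              dimnames = list(frequency = f_levels, intensity = i_levels))
  for (k in seq_len(nrow(cells))) {
    m[cells$frequency[k] + 1L, cells$intensity[k] + 1L] <- cells$jobholders[k]
  }
  m[1, -1] <- NA
  m[-1, 1] <- NA
  new_crosstab(m)
}

#' @export
print.shs_crosstab <- function(x, ...) {
  cat("<shs_crosstab> jobholders by exposure frequency (rows) x intensity (columns)\n")
  disp <- cbind(x$cells, Total = x$row_totals)
  disp <- rbind(disp, Total = c(x$col_totals, x$grand_total))
  print(format(disp, big.mark = ",", scientific = FALSE), quote = FALSE)
  invisible(x)
}

#' Write a cross-tabulation to CSV
#'
#' Long format (`frequency`, `intensity`, `jobholders`, legal cells only)
#' readable back with [as_exposure_crosstab()] on the first three columns.
#'
#' @param ct An `shs_crosstab`.
#' @param path Output path.
#' @export
write_crosstab_csv <- function(ct, path) {
  long <- as.data.frame(as.table(ct$cells), stringsAsFactors = FALSE)
  names(long) <- c("frequency", "intensity", "jobholders")
  long <- long[!is.na(long$jobholders), ]
  long$frequency <- as.integer(long$frequency)
  long$intensity <- as.integer(long$intensity)
  long <- long[order(long$frequency, long$intensity), ]
  readr::write_csv(tibble::as_tibble(long), path)
  invisible(path)
}

#' Exposed-worker estimates from a cross-tabulation
#'
#' Summarises a frequency-by-intensity cross-tabulation into the headline
#' exposure numbers: the count of workers employed in codes rated likely to
#' involve exposure (everything outside the (0, 0) cell), their share of all
#' jobs held, and a lower bound on the number of individually exposed
#' workers. The lower bound applies the likelihood threshold: a code is
#' rated likely when at least `min_prevalence` (default 10%) of its
#' jobholders are exposed, so at least that fraction of the workers in
#' likely codes are exposed.
#'
#' @param ct An `shs_crosstab` from [cross_tabulate()] or
#'   [as_exposure_crosstab()].
#' @param min_prevalence The within-code exposure prevalence defining a
#'   "likely" rating; in (0, 1], default 0.10.
#' @return A list with `n_in_exposed_jobs`, `share_of_jobs` (a proportion),
#'   `lower_bound_exposed`.
#' @export
exposed_worker_estimates <- function(ct, min_prevalence = 0.10) {
  if (!inherits(ct, "shs_crosstab")) {
    rlang::abort("ct must be an shs_crosstab")
  }
  if (min_prevalence <= 0 || min_prevalence > 1) {
    rlang::abort("min_prevalence must lie in (0, 1]")
  }
  if (ct$grand_total == 0) {
    rlang::abort("empty cross-tabulation: no jobholders")
  }
  unexposed <- ct$cells[1, 1]
  n_exposed_jobs <- ct$grand_total - unexposed
  list(
    n_in_exposed_jobs = n_exposed_jobs,
    share_of_jobs = n_exposed_jobs / ct$grand_total,
    lower_bound_exposed = min_prevalence * n_exposed_jobs
  )
}
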