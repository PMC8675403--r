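#' Read and write consensus JEM tables
#'
#' A JEM (job exposure matrix) table holds one consensus record per
#' occupation code: the agreed likelihood, frequency and intensity ratings
#' plus the compound severity (their product). `read_jem_csv()` accepts a
#' column-name mapping so that deposited JEM files with different headers
#' (e.g. `SOC2020 code` instead of `code4`) can be parsed without editing the
#' file.
#'
#' @param path Path to a CSV with columns `code4`, `title`, `likelihood`,
#'   `frequency`, `intensity` (after column mapping). A `compound_severity`
#'   column, if present, is checked against the recomputed product;
#'   otherwise it is computed.
#' @param col_map Optional named character vector mapping standard column
#'   names to the file's column names, e.g.
#'   `c(code4 = "SOC2020 code", title = "Occupation")`.
#' @param scheme A rating scheme, by default [shs_rating_scheme()].
#' @return A tibble with columns `code4`, `code2`, `title`, `likelihood`,
#'   `frequency`, `intensity`, `compound_severity`.
#' @export
read_jem_csv <- function(path, col_map = NULL, scheme = shs_rating_scheme()) {
  if (!file.exists(path)) {
    rlang::abort(paste0("JEM file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        rlang::abort(paste0("mapped column '", col_map[[std]], "' not found in ", path))
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  required <- c("code4", "likelihood", "frequency", "intensity")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "JEM CSV is missing columns: ", paste(missing, collapse = ", "),
      " (use col_map to rename file-specific headers)"
    ))
  }
  if (!"title" %in% names(raw)) raw$title <- NA_character_
  jem <- tibble::tibble(
    code4 = raw$code4,
    code2 = substr(raw$code4, 1, 2),
    title = raw$title,
    likelihood = as.integer(raw$likelihood),
    frequency = as.integer(raw$frequency),
    intensity = as.integer(raw$intensity)
  )
  dup <- unique(jem$code4[duplicated(jem$code4)])
  if (length(dup) > 0) {
    rlang::abort(paste0(
      "duplicate code4 in JEM: ", paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  jem$compound_severity <- compound_severity(
    jem$likelihood, jem$frequency, jem$intensity, scheme = scheme
  )
  if ("compound_severity" %in% names(raw)) {
    stored <- as.integer(raw$compound_severity)
    off <- which(!is.na(stored) & stored != jem$compound_severity)
    if (length(off) > 0) {
      rlang::abort(paste0(
        "stored compound_severity disagrees with likelihood*frequency*intensity for codes: ",
        paste(utils::head(jem$code4[off], 5), collapse = ", ")
      ))
    }
  }
  jem
}

#' @param jem A JEM tibble as produced by [read_jem_csv()] or [build_jem()].
#' @rdname read_jem_csv
#' @export
write_jem_csv <- function(jem, path) {
  readr::write_csv(jem, path, na = "")
  invisible(path)
}

check_jem <- function(jem, arg = "jem") {
  required <- c("code4", "likelihood", "frequency", "intensity", "compound_severity")
  missing <- setdiff(required, names(jem))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      arg, " must be a JEM table; missing columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(jem)
}
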