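#' The second-hand smoke exposure rating scheme
#'
#' Constructs the ordinal rating scheme used throughout the package: a binary
#' likelihood axis (is at least 10% of the code's jobholders exposed at
#' work?), a five-level frequency axis (never up to daily with more than one
#' hour of exposure per day) and a four-level intensity axis (none up to
#' indoors in a poorly ventilated space). The scheme is conditional:
#' frequency and intensity are only rated when likelihood is rated 1, and a
#' likelihood-0 code carries frequency = intensity = 0 in a finished JEM.
#'
#' @return An object of class `shs_rating_scheme`: a named list with one
#'   character vector per axis (`likelihood`, `frequency`, `intensity`),
#'   whose names are the numeric levels and whose values are the
#'   human-readable labels.
#' @examples
#' scheme <- shs_rating_scheme()
#' scheme_levels(scheme, "frequency")
#' @export
shs_rating_scheme <- function() {
  scheme <- structure(
    list(
      likelihood = c(
        "0" = "<10% of jobholders exposed at work",
        "1" = "10% or more of jobholders exposed at work"
      ),
      frequency = c(
        "0" = "Never",
        "1" = "Less than once per week",
        "2" = "At least once per week but less than daily",
        "3" = "Daily",
        "4" = "Daily and more than 1 h of exposure per day"
      ),
      intensity = c(
        "0" = "None",
        "1" = "Outdoor or passing exposure",
        "2" = "Indoors in a well-ventilated space",
        "3" = "Indoors in a poorly ventilated space"
      )
    ),
    class = "shs_rating_scheme"
  )
  validate_scheme(scheme)
  scheme
}

#' @export
print.shs_rating_scheme <- function(x, ...) {
  cat("<shs_rating_scheme>\n")
  for (axis in names(x)) {
    cat(axis, ":\n", sep = "")
    for (lev in names(x[[axis]])) {
      cat("  ", lev, " = ", x[[axis]][[lev]], "\n", sep = "")
    }
  }
  invisible(x)
}

validate_scheme <- function(scheme) {
  if (!identical(sort(names(scheme)), sort(c("likelihood", "frequency", "intensity")))) {
    rlang::abort("a rating scheme must have likelihood, frequency and intensity axes")
  }
  for (axis in names(scheme)) {
    labels <- scheme[[axis]]
    if (anyNA(labels) || any(!nzchar(labels))) {
      rlang::abort(paste0("axis '", axis, "' has empty labels"))
    }
    if (anyDuplicated(labels) > 0) {
      rlang::abort(paste0("axis '", axis, "' has duplicate labels"))
    }
    levs <- suppressWarnings(as.integer(names(labels)))
    if (anyNA(levs) || !identical(levs, seq_along(levs) - 1L)) {
      rlang::abort(paste0("axis '", axis, "' levels must be 0, 1, 2, ..."))
    }
  }
  invisible(scheme)
}

#' Levels of one axis of a rating scheme
#'
#' @param scheme A rating scheme from [shs_rating_scheme()].
#' @param axis One of `"likelihood"`, `"frequency"`, `"intensity"`.
#' @return Integer vector of the legal levels for that axis.
#' @export
scheme_levels <- function(scheme, axis) {
  axis <- rlang::arg_match(axis, names(scheme))
  as.integer(names(scheme[[axis]]))
}

#' Build an occupation-code universe
#'
#' Assembles a tibble of 4-digit occupation codes with their 2-digit parent
#' groups derived from the first two characters. Codes are identifiers and
#' are always stored as character strings (leading zeros are preserved).
#'
#' @param code4 Character vector of 4-digit occupation codes.
#' @param title Optional character vector of occupation titles.
#' @param scheme_version Single string tagging the classification version
#'   (e.g. `"SOC2020"`).
#' @return A tibble with columns `code4`, `code2`, `title`, `scheme_version`.
#' @export
occupation_universe <- function(code4, title = NULL, scheme_version = "SOC2020") {
  code4 <- as.character(code4)
  bad <- code4[!grepl("^[0-9]{4}$", code4)]
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "occupation codes must be 4-digit strings; offending codes: ",
      paste(utils::head(unique(bad), 5), collapse = ", ")
    ))
  }
  dup <- unique(code4[duplicated(code4)])
  if (length(dup) > 0) {
    rlang::abort(paste0(
      "duplicate code4 within one scheme version: ",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  if (is.null(title)) title <- paste("Occupation", code4)
  tibble::tibble(
    code4 = code4,
    code2 = substr(code4, 1, 2),
    title = as.character(title),
    scheme_version = scheme_version
  )
}
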