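#' Fleiss' kappa for a fixed panel of raters
#'
#' Chance-corrected agreement for `n` raters assigning categorical levels to
#' `N` items. Per-item agreement is
#' \eqn{P_i = (\sum_j n_{ij}^2 - n) / (n(n-1))} where \eqn{n_{ij}} counts
#' assignments of item *i* to category *j*; observed agreement
#' \eqn{\bar P} is the mean of the \eqn{P_i}; expected agreement is
#' \eqn{\bar P_e = \sum_j p_j^2} with \eqn{p_j} the overall share of
#' assignments to category *j*; and
#' \eqn{\kappa = (\bar P - \bar P_e) / (1 - \bar P_e)}.
#'
#' Every item must be rated by the same number of raters. Items containing
#' missing values are an error: the caller must drop (or explicitly impute)
#' them first — see [rating_agreement()], which drops incomplete items with a
#' logged count. When all assignments fall in a single category the expected
#' agreement is 1 and kappa is undefined unless observed agreement is also
#' perfect, in which case kappa = 1.
#'
#' @param x An items-by-raters matrix (or data frame) of categorical levels;
#'   row names identify the items.
#' @param categories Optional vector of all legal categories; defaults to the
#'   observed levels. Must cover every observed level.
#' @return An object of class `shs_agreement`: a list with `kappa`,
#'   `n_items`, `n_raters`, `observed_agreement`, `expected_agreement`,
#'   `disagreement_codes` (items on which at least two raters differ) and
#'   `items` (all items included).
#' @examples
#' x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
#' fleiss_kappa(x) # observed = expected = 0.5, kappa = 0
#' @export
fleiss_kappa <- function(x, categories = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 1) rlang::abort("no items to assess")
  if (ncol(x) < 2) rlang::abort("Fleiss' kappa needs at least 2 raters per item")
  if (anyNA(x)) {
    bad <- rownames(x)[apply(x, 1, anyNA)]
    if (is.null(bad)) bad <- which(apply(x, 1, anyNA))
    rlang::abort(paste0(
      "items with missing ratings must be dropped or imputed explicitly: ",
      paste(utils::head(bad, 5), collapse = ", "),
      if (length(bad) > 5) paste0(" (and ", length(bad) - 5, " more)") else ""
    ))
  }
  observed <- unique(as.vector(x))
  if (is.null(categories)) {
    categories <- sort(observed)
  } else if (!all(observed %in% categories)) {
    rlang::abort("categories do not cover all observed levels")
  }
  if (length(categories) < 2) categories <- c(categories, NA)[1:2]

  n <- ncol(x)
  N <- nrow(x)
  counts <- t(apply(x, 1, function(r) {
    tabulate(match(r, categories), nbins = length(categories))
  }))
  if (N == 1) counts <- matrix(counts, nrow = 1)

  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (N * n)
  p_e <- sum(p_j^2)

  if (p_e >= 1 - 1e-12) {
    if (abs(p_bar - 1) < 1e-12) {
      kappa <- 1
      p_e <- 1
    } else {
      rlang::abort("degenerate margin: all assignments fall in one category but agreement is imperfect")
    }
  } else {
    kappa <- (p_bar - p_e) / (1 - p_e)
  }

  items <- rownames(x)
  if (is.null(items)) items <- as.character(seq_len(N))
  disagree <- items[apply(x, 1, function(r) length(unique(r)) > 1)]

  structure(
    list(
      kappa = kappa,
      n_items = N,
      n_raters = n,
      observed_agreement = p_bar,
      expected_agreement = p_e,
      disagreement_codes = disagree,
      items = items
    ),
    class = "shs_agreement"
  )
}

#' @export
print.shs_agreement <- function(x, ...) {
  cat("<shs_agreement>\n")
  cat(sprintf("  Fleiss' kappa:       %.4f\n", x$kappa))
  cat(sprintf("  observed agreement:  %.4f\n", x$observed_agreement))
  cat(sprintf("  expected agreement:  %.4f\n", x$expected_agreement))
  cat(sprintf("  items x raters:      %d x %d\n", x$n_items, x$n_raters))
  cat(sprintf("  items with disagreement: %d\n", length(x$disagreement_codes)))
  invisible(x)
}

#' Inter-rater agreement on one axis of a rating table
#'
#' Pivots a long multi-rater rating table to an items-by-raters matrix for
#' one axis and computes Fleiss' kappa. By default only the likelihood axis
#' is assessed: under the conditional scheme, frequency and intensity are
#' unrated whenever a rater scores likelihood 0, so pooling them would
#' artificially depress apparent agreement. Frequency/intensity agreement is
#' available behind `include_conditional = TRUE` and is then restricted to
#' the codes where every rater rated that axis.
#'
#' Codes with a missing rating from any rater are excluded before the kappa
#' computation; the number excluded is reported with a message and stored in
#' the `n_excluded` attribute of the result.
#'
#' @param ratings A validated rating table (see [validate_ratings()]).
#' @param round Which rating round to assess (default 2, the post-discussion
#'   round). `NULL` uses all rows regardless of round.
#' @param axis Axis to assess; default `"likelihood"`.
#' @param include_conditional Set `TRUE` to allow `axis = "frequency"` or
#'   `"intensity"` despite the conditional-rating caveat above.
#' @param scheme A rating scheme, by default [shs_rating_scheme()].
#' @return An `shs_agreement` object (see [fleiss_kappa()]) with attribute
#'   `n_excluded`.
#' @export
rating_agreement <- function(ratings, round = 2L,
                             axis = c("likelihood", "frequency", "intensity"),
                             include_conditional = FALSE,
                             scheme = shs_rating_scheme()) {
  axis <- rlang::arg_match(axis)
  if (axis != "likelihood" && !include_conditional) {
    rlang::abort(paste0(
      "agreement on '", axis, "' is conditional on likelihood = 1; ",
      "set include_conditional = TRUE to assess it on fully rated codes only"
    ))
  }
  if (!is.null(round)) {
    ratings <- dplyr::filter(ratings, .data$round == !!round)
    if (nrow(ratings) == 0) {
      rlang::abort(paste0("no ratings for round ", round))
    }
  }
  wide <- tidyr::pivot_wider(
    ratings[, c("code4", "rater_id", axis)],
    names_from = "rater_id", values_from = dplyr::all_of(axis)
  )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$code4
  complete <- !apply(m, 1, anyNA)
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(n_excluded, " code(s) excluded from '", axis,
            "' agreement (missing ratings)")
  }
  if (!any(complete)) {
    rlang::abort(paste0("no code was rated on '", axis, "' by every rater"))
  }
  res <- fleiss_kappa(m[complete, , drop = FALSE],
                      categories = scheme_levels(scheme, axis))
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Localise rater disagreement by 2-digit occupation group
#'
#' Tabulates, for each 2-digit parent group in a code universe, how many of
#' its 4-digit codes the raters disagreed on, as a fraction of all the
#' group's codes. This is the view used to spot occupation families (e.g.
#' agricultural workers) where expert judgement diverges.
#'
#' @param result An `shs_agreement` object from [fleiss_kappa()] or
#'   [rating_agreement()].
#' @param codes A code universe as from [occupation_universe()] (columns
#'   `code4` and optionally `code2`; `code2` is derived if absent).
#' @return A tibble with columns `code2`, `n_disagree`, `n_total`,
#'   `fraction`, one row per group, sorted by descending fraction. The
#'   numerators sum to `length(result$disagreement_codes)`.
#' @export
count_disagreements_by_group <- function(result, codes) {
  if (!inherits(result, "shs_agreement")) {
    rlang::abort("result must be an shs_agreement object")
  }
  if (!"code2" %in% names(codes)) {
    codes <- dplyr::mutate(codes, code2 = substr(.data$code4, 1, 2))
  }
  unknown <- setdiff(result$disagreement_codes, codes$code4)
  if (length(unknown) > 0) {
    rlang::abort(paste0(
      "disagreement codes not in the code universe: ",
      paste(utils::head(unknown, 5), collapse = ", ")
    ))
  }
  codes |>
    dplyr::mutate(disagree = .data$code4 %in% result$disagreement_codes) |>
    dplyr::group_by(.data$code2) |>
    dplyr::summarise(
      n_disagree = sum(.data$disagree),
      n_total = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction = .data$n_disagree / .data$n_total) |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$code2)
}

#' Bootstrap confidence interval for Fleiss' kappa
#'
#' Percentile bootstrap over items (codes), resampling rows of the
#' items-by-raters matrix with replacement. Offered as an optional extra;
#' the point estimate itself comes from [fleiss_kappa()].
#'
#' @param x Items-by-raters matrix as for [fleiss_kappa()].
#' @param n_boot Number of bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Integer seed for reproducibility.
#' @return Named numeric vector with `lower`, `estimate`, `upper`.
#' @export
fleiss_kappa_boot_ci <- function(x, n_boot = 1000, conf = 0.95, seed = 1L) {
  x <- as.matrix(x)
  est <- fleiss_kappa(x)$kappa
  categories <- sort(unique(as.vector(x)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(i) {
    rows <- sample.int(nrow(x), replace = TRUE)
    res <- tryCatch(fleiss_kappa(x[rows, , drop = FALSE], categories = categories),
                    error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$kappa
  }, numeric(1))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  c(lower = qs[1], estimate = est, upper = qs[2])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
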