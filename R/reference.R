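#' Synthetic reference JEM with the published UK summary structure
#'
#' A deterministic, fully synthetic consensus JEM built to carry the summary
#' structure reported for the UK 2020 second-hand smoke JEM, for use as a
#' worked example and as a parsing/summarisation fixture where the deposited
#' matrix itself is not redistributed:
#'
#' * 412 four-digit codes in 26 two-digit groups;
#' * 84 codes (20.4%) rated likely (likelihood 1);
#' * overall mean compound severity exactly 1.0, range 0--12;
#' * exactly three codes at the attainable maximum severity 12 — 6116
#'   (nannies and au pairs), 6135 (care workers and home carers), 6137
#'   (care escorts), all occupations working in other people's homes;
#' * group likely-fractions 5/5 in skilled agricultural trades (51), 11/12
#'   in skilled construction and building trades (53), 16/26 in elementary
#'   administration and service (92), 4/8 in elementary trades (91), 7/16 in
#'   caring personal service (61), and 0/20, 0/28 in the office-based groups
#'   41 and 21.
#'
#' Everything below those reported marginals — which individual codes are
#' likely, and each code's exact frequency/intensity pair — is a synthetic
#' choice and carries no information about real occupations (the three named
#' maximum-severity codes excepted).
#'
#' @return A JEM tibble (columns `code4`, `code2`, `title`, `likelihood`,
#'   `frequency`, `intensity`, `compound_severity`).
#' @export
synthetic_reference_jem <- function() {
  sizes <- c(
    "11" = 14L, "12" = 10L, "21" = 28L, "22" = 24L, "23" = 12L, "24" = 14L,
    "31" = 12L, "32" = 12L, "33" = 10L, "34" = 14L, "35" = 30L, "41" = 20L,
    "42" = 8L, "51" = 5L, "52" = 26L, "53" = 12L, "54" = 10L, "61" = 16L,
    "62" = 12L, "63" = 10L, "71" = 16L, "72" = 12L, "81" = 26L, "82" = 25L,
    "91" = 8L, "92" = 26L
  )
  n_likely <- c(
    "11" = 0L, "12" = 0L, "21" = 0L, "22" = 1L, "23" = 0L, "24" = 0L,
    "31" = 1L, "32" = 1L, "33" = 1L, "34" = 0L, "35" = 2L, "41" = 0L,
    "42" = 0L, "51" = 5L, "52" = 8L, "53" = 11L, "54" = 3L, "61" = 7L,
    "62" = 5L, "63" = 3L, "71" = 2L, "72" = 2L, "81" = 6L, "82" = 6L,
    "91" = 4L, "92" = 16L
  )
  stopifnot(sum(sizes) == 412L, sum(n_likely) == 84L)

  group_61 <- c(
    "6111", "6112", "6113", "6114", "6115", "6116", "6117", "6118",
    "6121", "6122", "6123", "6131", "6132", "6135", "6136", "6137"
  )
  max_codes <- c("6116", "6135", "6137")

  codes_of <- function(g) {
    if (g == "61") group_61 else paste0(g, sprintf("%02d", seq_len(sizes[[g]])))
  }
  likely_of <- function(g) {
    if (g == "61") {
      c(max_codes, setdiff(group_61, max_codes)[seq_len(n_likely[[g]] - 3L)])
    } else {
      codes_of(g)[seq_len(n_likely[[g]])]
    }
  }

  code4 <- unlist(lapply(names(sizes), codes_of))
  likely_codes <- unlist(lapply(names(sizes), likely_of))

  jem <- tibble::tibble(
    code4 = code4,
    code2 = substr(code4, 1, 2),
    title = paste("Synthetic occupation", code4),
    likelihood = as.integer(code4 %in% likely_codes),
    frequency = 0L,
    intensity = 0L
  )
  jem$title[jem$code4 == "6116"] <- "Nannies and au pairs (synthetic record)"
  jem$title[jem$code4 == "6135"] <- "Care workers and home carers (synthetic record)"
  jem$title[jem$code4 == "6137"] <- "Care escorts (synthetic record)"

  # maximum-severity codes: daily >1 h, indoors poorly ventilated
  jem$frequency[jem$code4 %in% max_codes] <- 4L
  jem$intensity[jem$code4 %in% max_codes] <- 3L

  # remaining 81 likely codes: 26 at severity 6 and 55 at severity 4, so the
  # 412-code severity total is 3*12 + 26*6 + 55*4 = 412 and the mean is 1.0
  rest <- sort(setdiff(likely_codes, max_codes))
  six <- rest[1:26]
  four <- rest[27:81]
  i6 <- match(six, jem$code4)
  jem$frequency[i6] <- ifelse(seq_along(i6) %% 2 == 1, 2L, 3L)
  jem$intensity[i6] <- ifelse(seq_along(i6) %% 2 == 1, 3L, 2L)
  i4 <- match(four, jem$code4)
  jem$frequency[i4] <- ifelse(seq_along(i4) %% 2 == 1, 2L, 4L)
  jem$intensity[i4] <- ifelse(seq_along(i4) %% 2 == 1, 2L, 1L)

  jem$compound_severity <- compound_severity(
    jem$likelihood, jem$frequency, jem$intensity
  )
  jem
}
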