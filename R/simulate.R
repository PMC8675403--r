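#' Configuration for the synthetic JEM-pipeline simulator
#'
#' Defines a synthetic study: a universe of 4-digit occupation codes nested
#' in 2-digit groups, a latent "true" JEM, a panel of noisy raters, a
#' lognormal workforce rounded to the nearest 100, a possibly many-to-many
#' crosswalk to a second classification version, and a socioeconomic class
#' mapping. Defaults mirror the UK study conditions: 412 codes in 26
#' groups, 3 raters, and a 20.4% (84/412) prevalence of codes rated likely.
#'
#' @param n_codes Number of 4-digit codes (default 412).
#' @param n_groups Number of 2-digit groups (default 26).
#' @param n_raters Raters on the panel (default 3; at most 3, matching the
#'   adjudication rules).
#' @param prevalence_likely Share of codes with true likelihood 1
#'   (default 84/412).
#' @param rater_error Per-axis probability that a rater deviates from the
#'   latent truth (default 0.1). On the binary likelihood axis the deviation
#'   is a flip; on frequency/intensity it is one step on the ordinal scale
#'   (reflecting at the boundaries) under the default `"adjacent"` kernel,
#'   or a uniform draw over the other legal levels under `"uniform"`.
#' @param deviation_kernel `"adjacent"` (default) or `"uniform"`.
#' @param frequency_probs Law of the true frequency rating over levels 1--4
#'   for likely codes.
#' @param intensity_probs Law of the true intensity rating over levels 1--3
#'   for likely codes.
#' @param workforce_meanlog,workforce_sdlog Lognormal parameters for
#'   per-code jobholder counts (before rounding to the nearest 100).
#' @param crosswalk_mix Named proportions of source codes handled by
#'   `identity` (1 to the same code), `merge` (2 sources to 1 target) and
#'   `split` (1 source to 2 weighted targets) mappings.
#' @param n_classes Number of synthetic socioeconomic (NS-SEC-like) analytic
#'   classes (default 8).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return A validated list of class `shs_sim_config`.
#' @export
sim_config <- function(n_codes = 412L,
                       n_groups = 26L,
                       n_raters = 3L,
                       prevalence_likely = 84 / 412,
                       rater_error = 0.1,
                       deviation_kernel = c("adjacent", "uniform"),
                       frequency_probs = c(0.20, 0.30, 0.35, 0.15),
                       intensity_probs = c(0.40, 0.35, 0.25),
                       workforce_meanlog = log(5e4),
                       workforce_sdlog = 1.1,
                       crosswalk_mix = c(identity = 0.8, merge = 0.1, split = 0.1),
                       n_classes = 8L,
                       seed = 1L) {
  deviation_kernel <- rlang::arg_match(deviation_kernel)
  stopifnot(
    n_codes >= n_groups, n_groups >= 1, n_raters >= 1, n_raters <= 3,
    prevalence_likely >= 0, prevalence_likely <= 1,
    rater_error >= 0, rater_error < 1,
    length(frequency_probs) == 4, all(frequency_probs >= 0),
    length(intensity_probs) == 3, all(intensity_probs >= 0),
    workforce_sdlog > 0, n_classes >= 1
  )
  if (!identical(sort(names(crosswalk_mix)), c("identity", "merge", "split"))) {
    rlang::abort("crosswalk_mix needs proportions named identity, merge, split")
  }
  structure(
    list(
      n_codes = as.integer(n_codes),
      n_groups = as.integer(n_groups),
      n_raters = as.integer(n_raters),
      prevalence_likely = prevalence_likely,
      rater_error = rater_error,
      deviation_kernel = deviation_kernel,
      frequency_probs = frequency_probs / sum(frequency_probs),
      intensity_probs = intensity_probs / sum(intensity_probs),
      workforce_meanlog = workforce_meanlog,
      workforce_sdlog = workforce_sdlog,
      crosswalk_mix = crosswalk_mix / sum(crosswalk_mix),
      n_classes = as.integer(n_classes),
      seed = as.integer(seed)
    ),
    class = "shs_sim_config"
  )
}

with_sim_seed <- function(seed, offset, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Simulate a code universe and its latent true JEM
#'
#' Partitions `n_codes` 4-digit codes into `n_groups` 2-digit groups (as
#' evenly as possible), marks each code likely with probability
#' `prevalence_likely`, and draws frequency/intensity for likely codes from
#' the configured categorical laws; unlikely codes are (0, 0, 0).
#'
#' @param config An [sim_config()].
#' @return A list of class `shs_truth` with `codes` (an occupation universe
#'   tibble) and `jem` (the latent JEM tibble).
#' @export
simulate_truth <- function(config = sim_config()) {
  stopifnot(inherits(config, "shs_sim_config"))
  with_sim_seed(config$seed, 0L, {
    group_codes <- sprintf("%02d", 10L + seq_len(config$n_groups))
    sizes <- rep(config$n_codes %/% config$n_groups, config$n_groups)
    extra <- config$n_codes %% config$n_groups
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    if (any(sizes > 99)) rlang::abort("more than 99 codes in one 2-digit group")
    code4 <- unlist(lapply(seq_along(group_codes), function(g) {
      paste0(group_codes[g], sprintf("%02d", seq_len(sizes[g])))
    }))
    codes <- occupation_universe(
      code4,
      title = paste("Synthetic occupation", code4),
      scheme_version = "SYN2010"
    )
    likely <- stats::rbinom(config$n_codes, 1L, config$prevalence_likely)
    frequency <- ifelse(
      likely == 1L,
      sample(1:4, config$n_codes, replace = TRUE, prob = config$frequency_probs),
      0L
    )
    intensity <- ifelse(
      likely == 1L,
      sample(1:3, config$n_codes, replace = TRUE, prob = config$intensity_probs),
      0L
    )
    jem <- tibble::tibble(
      code4 = codes$code4,
      code2 = codes$code2,
      likelihood = as.integer(likely),
      frequency = as.integer(frequency),
      intensity = as.integer(intensity),
      compound_severity = compound_severity(likely, frequency, intensity)
    )
    structure(list(codes = codes, jem = jem, config = config), class = "shs_truth")
  })
}

perturb_ordinal <- function(value, levels, error, kernel) {
  deviate <- stats::runif(length(value)) < error
  out <- value
  idx <- which(deviate)
  for (k in idx) {
    others <- setdiff(levels, value[k])
    if (length(others) == 0) next
    if (kernel == "uniform") {
      out[k] <- sample(others, 1)
    } else {
      lo <- value[k] - 1L
      hi <- value[k] + 1L
      steps <- intersect(c(lo, hi), levels)
      # reflect at the scale boundaries: only one neighbour exists there
      out[k] <- if (length(steps) == 1) steps else sample(steps, 1)
    }
  }
  out
}

#' Simulate a noisy multi-rater panel from a latent JEM
#'
#' Each rater independently reports each code's true level with probability
#' `1 - rater_error`, otherwise deviates per the configured kernel. The
#' conditional scheme is enforced by construction: a rater reporting
#' likelihood 0 reports nothing else, and a rater reporting likelihood 1
#' (even mistakenly, for a truly unexposed code) supplies frequency and
#' intensity — drawn from the configured laws when the truth has none.
#'
#' @param truth An `shs_truth` from [simulate_truth()].
#' @param config The same [sim_config()]; defaults to the one stored in
#'   `truth`.
#' @param round Round number stamped on the scores (default 2).
#' @return A rating table (tibble) with one row per rater x code.
#' @export
simulate_raters <- function(truth, config = truth$config, round = 2L) {
  stopifnot(inherits(truth, "shs_truth"))
  with_sim_seed(config$seed, 1L, {
    jem <- truth$jem
    panels <- lapply(seq_len(config$n_raters), function(r) {
      flip <- stats::runif(nrow(jem)) < config$rater_error
      lik <- ifelse(flip, 1L - jem$likelihood, jem$likelihood)
      freq <- rep(NA_integer_, nrow(jem))
      int <- rep(NA_integer_, nrow(jem))
      says1 <- lik == 1L
      true1 <- jem$likelihood == 1L
      # true positives: perturb the true frequency/intensity
      tp <- says1 & true1
      freq[tp] <- perturb_ordinal(jem$frequency[tp], 1:4,
                                  config$rater_error, config$deviation_kernel)
      int[tp] <- perturb_ordinal(jem$intensity[tp], 1:3,
                                 config$rater_error, config$deviation_kernel)
      # false positives: the rater must still rate the conditional axes
      fp <- says1 & !true1
      if (any(fp)) {
        freq[fp] <- sample(1:4, sum(fp), replace = TRUE,
                           prob = config$frequency_probs)
        int[fp] <- sample(1:3, sum(fp), replace = TRUE,
                          prob = config$intensity_probs)
      }
      tibble::tibble(
        rater_id = sprintf("rater%02d", r),
        code4 = jem$code4,
        round = as.integer(round),
        likelihood = as.integer(lik),
        frequency = freq,
        intensity = int
      )
    })
    dplyr::bind_rows(panels)
  })
}

#' Simulate a workforce table, crosswalk and class mapping
#'
#' Jobholder counts are lognormal, rounded to the nearest 100 (the official
#' extract convention). The crosswalk from the source version mixes identity
#' (1 to 1, same code), merge (2 sources to 1 target) and split (1 source to
#' 2 weighted targets) mappings in the configured proportions. The class
#' mapping assigns each 2-digit group to one of `n_classes` synthetic
#' socioeconomic classes (classes attach to whole groups, as occupation-based
#' socioeconomic classifications do).
#'
#' @inheritParams simulate_raters
#' @return A list with `workforce` (source version), `crosswalk`,
#'   `class_mapping` (tibble `code4`, `group_id`).
#' @export
simulate_workforce_and_crosswalk <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "shs_truth"))
  with_sim_seed(config$seed, 2L, {
    codes <- truth$codes$code4
    n <- length(codes)
    counts <- round(stats::rlnorm(n, config$workforce_meanlog,
                                  config$workforce_sdlog) / 100) * 100
    workforce <- tibble::tibble(
      code4 = codes, version = "SYN2010", jobholders = counts
    )

    kind <- sample(c("identity", "merge", "split"), n, replace = TRUE,
                   prob = config$crosswalk_mix)
    # merges need pairs: demote one leftover merge code to identity
    merge_idx <- which(kind == "merge")
    if (length(merge_idx) %% 2 == 1) {
      kind[merge_idx[length(merge_idx)]] <- "identity"
      merge_idx <- merge_idx[-length(merge_idx)]
    }
    rows <- list()
    add <- function(source, target, weight) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        source = source, target = target, weight = weight
      )
    }
    for (i in which(kind == "identity")) add(codes[i], codes[i], 1)
    if (length(merge_idx) > 0) {
      pairs <- matrix(merge_idx, ncol = 2, byrow = TRUE)
      for (p in seq_len(nrow(pairs))) {
        target <- paste0("8", substr(codes[pairs[p, 1]], 2, 4))
        add(codes[pairs[p, 1]], target, 1)
        add(codes[pairs[p, 2]], target, 1)
      }
    }
    split_idx <- which(kind == "split")
    for (j in seq_along(split_idx)) {
      i <- split_idx[j]
      w <- stats::runif(1, 0.2, 0.8)
      add(codes[i], paste0("9", substr(codes[i], 2, 4)), w)
      add(codes[i], paste0("7", substr(codes[i], 2, 4)), 1 - w)
    }
    crosswalk <- dplyr::arrange(dplyr::bind_rows(rows), .data$source, .data$target)

    groups <- unique(truth$codes$code2)
    class_of_group <- sample(seq_len(config$n_classes), length(groups),
                             replace = TRUE)
    class_mapping <- tibble::tibble(
      code4 = truth$codes$code4,
      group_id = as.character(class_of_group[match(truth$codes$code2, groups)])
    )
    list(workforce = workforce, crosswalk = crosswalk,
         class_mapping = class_mapping)
  })
}

#' Simulate a complete set of pipeline inputs
#'
#' Convenience wrapper running [simulate_truth()], [simulate_raters()] and
#' [simulate_workforce_and_crosswalk()] under one config.
#'
#' @param config An [sim_config()].
#' @return A list with `truth`, `ratings`, `workforce`, `crosswalk`,
#'   `class_mapping`.
#' @export
simulate_jem_inputs <- function(config = sim_config()) {
  truth <- simulate_truth(config)
  ratings <- simulate_raters(truth, config)
  wfx <- simulate_workforce_and_crosswalk(truth, config)
  c(list(truth = truth, ratings = ratings), wfx)
}

#' Write simulated inputs to a directory of CSV files
#'
#' Writes `ratings.csv`, `workforce.csv`, `crosswalk.csv`,
#' `class_mapping.csv` and `truth_jem.csv` (the latent JEM, for
#' recovery checks).
#'
#' @param sim Output of [simulate_jem_inputs()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ratings_csv(sim$ratings, file.path(dir, "ratings.csv"))
  readr::write_csv(sim$workforce, file.path(dir, "workforce.csv"))
  readr::write_csv(sim$crosswalk, file.path(dir, "crosswalk.csv"))
  readr::write_csv(sim$class_mapping, file.path(dir, "class_mapping.csv"))
  readr::write_csv(sim$truth$jem, file.path(dir, "truth_jem.csv"))
  invisible(dir)
}
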