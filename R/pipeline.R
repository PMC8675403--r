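#' Run the full JEM pipeline from a configuration
#'
#' Executes the whole construction in order — validate the rating table,
#' compute likelihood inter-rater agreement, build the consensus JEM,
#' summarise by 2-digit group (and by socioeconomic class if a mapping is
#' given), optionally recode the workforce through a crosswalk, cross-tabulate
#' jobholders by exposure frequency and intensity, and derive the
#' exposed-worker estimates. Per-stage CSVs and a machine-readable run
#' manifest (package version, resolved config, input checksums) are written
#' to the output directory. Log lines go to standard error; data only to
#' files, so runs are pipeline-safe. Re-running with identical inputs and
#' config yields byte-identical report CSVs.
#'
#' @param config A named list, or the path to a YAML file holding one, with
#'   elements:
#'   \describe{
#'     \item{ratings}{path to the ratings CSV (required).}
#'     \item{workforce}{path to the workforce CSV (required).}
#'     \item{crosswalk}{path to a crosswalk CSV (optional); when given the
#'       workforce is recoded before tabulation.}
#'     \item{class_mapping}{path to a `code4,group_id` CSV (optional) for a
#'       socioeconomic-class summary.}
#'     \item{round}{rating round to use (default 2).}
#'     \item{policy}{tiebreak mode for [consensus_policy()] (default
#'       `"median"`).}
#'     \item{min_prevalence}{threshold for [exposed_worker_estimates()]
#'       (default 0.10).}
#'     \item{out_dir}{output directory (required).}
#'   }
#' @return Invisibly, a list with `jem`, `agreement`, `summary_code2`,
#'   `summary_class`, `crosstab`, `estimates`, `manifest`.
#' @export
run_jem_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      rlang::abort(paste0("config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(round = 2L, policy = "median", min_prevalence = 0.10,
                   crosswalk = NULL, class_mapping = NULL)
  config <- utils::modifyList(defaults, config)
  for (key in c("ratings", "workforce", "out_dir")) {
    if (is.null(config[[key]])) {
      rlang::abort(paste0("pipeline config is missing '", key, "'"))
    }
  }
  inputs <- c(ratings = config$ratings, workforce = config$workforce,
              crosswalk = config$crosswalk, class_mapping = config$class_mapping)
  for (p in inputs) {
    if (!file.exists(p)) rlang::abort(paste0("input file not found: ", p))
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_stage <- function(...) message("[shsjem] ", ...)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      rlang::abort(paste0("pipeline failed at stage '", name, "': ",
                          conditionMessage(e)))
    })
  }

  log_stage("stage validate: ", config$ratings)
  ratings <- stage("validate", {
    r <- read_ratings_csv(config$ratings)
    r <- dplyr::filter(r, .data$round == !!as.integer(config$round))
    if (nrow(r) == 0) rlang::abort(paste0("no ratings for round ", config$round))
    v <- validate_ratings(r)
    if (nrow(v) > 0) {
      rlang::abort(paste0(nrow(v), " rating violations (first: ", v$rule[1], ")"))
    }
    r
  })

  log_stage("stage agree: likelihood agreement, round ", config$round)
  agreement <- stage("agree", rating_agreement(ratings, round = config$round))
  log_stage(sprintf("  kappa = %.4f (observed %.4f, expected %.4f), %d/%d codes with disagreement",
                    agreement$kappa, agreement$observed_agreement,
                    agreement$expected_agreement,
                    length(agreement$disagreement_codes), agreement$n_items))
  readr::write_csv(
    tibble::tibble(
      kappa = agreement$kappa,
      observed_agreement = agreement$observed_agreement,
      expected_agreement = agreement$expected_agreement,
      n_items = agreement$n_items,
      n_raters = agreement$n_raters,
      n_excluded = attr(agreement, "n_excluded") %||% 0L,
      n_disagreement = length(agreement$disagreement_codes)
    ),
    file.path(out_dir, "agreement.csv")
  )
  readr::write_csv(
    tibble::tibble(code4 = agreement$disagreement_codes),
    file.path(out_dir, "disagreement_codes.csv")
  )

  log_stage("stage build: consensus JEM (policy ", config$policy, ")")
  jem <- stage("build", build_jem(
    ratings, policy = consensus_policy(config$policy), validate = FALSE
  ))
  write_jem_csv(jem, file.path(out_dir, "jem.csv"))

  log_stage("stage summarize")
  summary_code2 <- stage("summarize", summarize_by_group(jem))
  readr::write_csv(summary_code2, file.path(out_dir, "summary_code2.csv"))
  summary_class <- NULL
  if (!is.null(config$class_mapping)) {
    mapping <- readr::read_csv(config$class_mapping, col_types = readr::cols(
      code4 = readr::col_character(), group_id = readr::col_character()
    ))
    summary_class <- stage("summarize", summarize_by_group(jem, grouping = mapping))
    readr::write_csv(summary_class, file.path(out_dir, "summary_class.csv"))
  }

  log_stage("stage tabulate")
  wf <- stage("tabulate", read_workforce_csv(config$workforce))
  if (!is.null(config$crosswalk)) {
    xw <- stage("tabulate", read_crosswalk_csv(config$crosswalk))
    wf <- stage("tabulate", recode_workforce(wf, xw, target_version = "recoded"))
    log_stage("  workforce recoded; rounding drift ",
              attr(wf, "rounding_drift"), " jobholders")
  }
  crosstab <- stage("tabulate", cross_tabulate(jem, wf))
  write_crosstab_csv(crosstab, file.path(out_dir, "crosstab.csv"))
  estimates <- stage("tabulate", exposed_worker_estimates(
    crosstab, min_prevalence = config$min_prevalence
  ))
  # percentages are shown rounded but always alongside their numerator and
  # denominator so the displays stay auditable
  readr::write_csv(
    tibble::tibble(
      n_in_exposed_jobs = estimates$n_in_exposed_jobs,
      grand_total = crosstab$grand_total,
      share_of_jobs = estimates$share_of_jobs,
      share_of_jobs_pct_1dp = round(100 * estimates$share_of_jobs, 1),
      min_prevalence = config$min_prevalence,
      lower_bound_exposed = estimates$lower_bound_exposed
    ),
    file.path(out_dir, "estimates.csv")
  )

  manifest <- list(
    package = "shsjem",
    version = as.character(utils::packageVersion("shsjem")),
    config = config[setdiff(names(config), "out_dir")],
    input_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  log_stage("done: ", out_dir)
  invisible(list(
    jem = jem, agreement = agreement, summary_code2 = summary_code2,
    summary_class = summary_class, crosstab = crosstab,
    estimates = estimates, manifest = manifest
  ))
}
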