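# Validated CSV readers and report writers. CSV dialect: comma, UTF-8, header
# row required; semicolon separates ICF codes inside the icf_codes column only.

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    abort_validation(sprintf("File not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA"), encoding = "UTF-8")
  check_columns(df, required, sprintf("%s (%s)", what, path))
  tibble::as_tibble(df)
}

#' Read an ICF catalog CSV
#'
#' Expected columns: \code{code,label,disposition,combine_group_id}.
#'
#' @param path Path to the CSV file.
#' @return A validated [icf_catalog()] tibble.
#' @export
read_icf_catalog <- function(path) {
  df <- read_csv_checked(path, c("code", "label", "disposition"), "ICF catalog")
  icf_catalog(df)
}

#' Read a survey-item CSV
#'
#' Expected columns: \code{item_id,text,icf_codes}, with \code{icf_codes}
#' semicolon-separated.
#'
#' @param path Path to the CSV file.
#' @return A validated [survey_items()] tibble.
#' @export
read_survey_items <- function(path) {
  df <- read_csv_checked(path, c("item_id", "text", "icf_codes"), "Survey items")
  survey_items(df)
}

#' Read a long-format response CSV
#'
#' Expected columns: \code{respondent_id,group,item_id,score}; an empty score
#' field is a missing response. Rows with scores outside 0-3 or with a missing
#' or unknown rater group are rejected with their row numbers.
#'
#' @param path Path to the CSV file.
#' @return A validated response tibble.
#' @export
read_responses <- function(path) {
  df <- read_csv_checked(path, c("respondent_id", "group", "item_id", "score"),
                         "Responses")
  validate_responses(df)
}

#' Read a dyad roster CSV
#'
#' Expected columns: \code{dyad_id,patient_id,proxy_id}.
#'
#' @param path Path to the CSV file.
#' @return A validated roster tibble.
#' @export
read_dyad_roster <- function(path) {
  df <- read_csv_checked(path, c("dyad_id", "patient_id", "proxy_id"),
                         "Dyad roster")
  validate_dyad_roster(df)
}

#' Read an instrument-linking CSV
#'
#' Expected columns:
#' \code{instrument_id,item_id,aspect_index,concept_text,icf_code,flag} with
#' exactly one of \code{icf_code}/\code{flag} non-empty per row.
#'
#' @param path Path to the CSV file.
#' @return A validated linking tibble.
#' @export
read_linkings <- function(path) {
  df <- read_csv_checked(
    path,
    c("instrument_id", "item_id", "aspect_index", "concept_text", "icf_code", "flag"),
    "Linking table"
  )
  df <- validate_linkings(df)
  validate_linkings_aspects(df[c("icf_code", "flag")])
  df
}

#' Write an analysis report
#'
#' Writes a result table with deterministic column order so reruns diff
#' cleanly. Percent columns in package reports are already display-rounded to
#' one decimal; underlying fractions keep full precision, so a re-read
#' reproduces the in-memory values.
#'
#' @param results A data frame of results.
#' @param path Output path.
#' @param format \code{"csv"} or \code{"json"}; both carry the same content.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  list_cols <- vapply(results, is.list, logical(1))
  results[list_cols] <- lapply(results[list_cols], function(col) {
    vapply(col, paste, character(1), collapse = ";")
  })
  if (format == "csv") {
    utils::write.csv(results, path, row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", na = "null",
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return A tibble.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  } else {
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Analysis run configuration
#'
#' Reads a YAML configuration and fills unspecified fields with the default
#' analysis rules: main dichotomization, relevance thresholds 25\%/25\%/50\%,
#' linear kappa weights, coverage analysis A, 5\% open-ended threshold.
#'
#' @param path Optional YAML file; \code{NULL} returns the defaults.
#' @return A named list: \code{dichotomization}, \code{thresholds} (list with
#'   \code{patient}, \code{proxy}, \code{hcp}), \code{weights},
#'   \code{coverage_analysis}, \code{open_ended_threshold}, \code{seed}.
#' @export
run_config <- function(path = NULL) {
  defaults <- list(
    dichotomization = "main",
    thresholds = list(patient = 0.25, proxy = 0.25, hcp = 0.50),
    weights = "linear",
    coverage_analysis = "A",
    open_ended_threshold = 0.05,
    seed = 1L
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0L) {
      abort_validation(sprintf("Unknown config field(s): %s",
                               paste(unknown, collapse = ", ")))
    }
    defaults[names(user)] <- user
  }
  dichotomization_rule(defaults$dichotomization)
  do.call(relevance_rule, defaults$thresholds)
  coverage_analysis(defaults$coverage_analysis)
  open_ended_rule(defaults$open_ended_threshold)
  match.arg(defaults$weights, c("identity", "linear", "quadratic"))
  defaults
}

#' Bundled per-item relevance percentages from a published brain-tumor survey
#'
#' Per-item percentages of patients (n = 114), proxies (n = 71) and healthcare
#' professionals (n = 65) reporting each of 56 survey items as an issue, with
#' available-case denominators, transcribed from a published multinational
#' survey of brain-tumor patients. The \code{"main"} table dichotomizes scores
#' 1-3 as an issue; the \code{"sensitivity"} table scores 2-3.
#'
#' @param analysis \code{"main"} or \code{"sensitivity"}.
#' @return Tibble with columns \code{item_id}, \code{text},
#'   \code{pct_patients}, \code{pct_proxies}, \code{pct_hcps},
#'   \code{n_patients}, \code{n_proxies}, \code{n_hcps}.
#' @export
#' @examples
#' fix <- survey_relevance_fixture("main")
#' nrow(fix) # 56
survey_relevance_fixture <- function(analysis = c("main", "sensitivity")) {
  analysis <- match.arg(analysis)
  path <- system.file("extdata",
                      sprintf("survey_relevance_%s.csv", analysis),
                      package = "covalid", mustWork = TRUE)
  df <- read_csv_checked(
    path,
    c("item_id", "text", "pct_patients", "pct_proxies", "pct_hcps",
      "n_patients", "n_proxies", "n_hcps"),
    "Relevance fixture"
  )
  df$item_id <- as.integer(df$item_id)
  df
}

#' Apply the relevance rule to a wide percentage table
#'
#' Convenience bridge from published-style wide tables (one row per item,
#' per-group percentages) to [determine_relevance()].
#'
#' @param pct_table Tibble like [survey_relevance_fixture()] output.
#' @param rule Threshold rule from [relevance_rule()].
#' @return [determine_relevance()] output joined back to the input rows.
#' @export
classify_relevance_pct <- function(pct_table, rule = relevance_rule()) {
  pct_table <- tibble::as_tibble(pct_table)
  check_columns(pct_table,
                c("item_id", "pct_patients", "pct_proxies", "pct_hcps"),
                "Percentage table")
  long <- tibble::tibble(
    item_id = rep(pct_table$item_id, 3L),
    group = rep(rater_groups(), each = nrow(pct_table)),
    fraction = c(pct_table$pct_patients, pct_table$pct_proxies,
                 pct_table$pct_hcps) / 100
  )
  dec <- determine_relevance(long, rule)
  merged <- merge(as.data.frame(pct_table), as.data.frame(dec), by = "item_id")
  out <- tibble::as_tibble(merged)
  out[order(out$item_id), ]
}
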