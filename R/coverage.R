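#' Valid non-ICF flags for linked aspects
#'
#' Under the standardized ICF linking rules, a meaningful concept that cannot
#' be linked to an ICF category is flagged as not definable, not covered by the
#' ICF, a personal factor, or a health condition. Flagged aspects are never
#' relevant, but they stay in the aspect denominators of the stricter coverage
#' analyses.
#'
#' @return Character vector of valid flags.
#' @export
linking_flags <- function() {
  c("not_definable", "not_covered", "personal_factor", "health_condition")
}

validate_linkings <- function(linkings) {
  linkings <- tibble::as_tibble(linkings)
  check_columns(linkings,
                c("instrument_id", "item_id", "concept_text", "icf_code", "flag"),
                "Linking table")
  for (col in c("icf_code", "flag")) {
    x <- as.character(linkings[[col]])
    x[!is.na(x) & x == ""] <- NA_character_
    linkings[[col]] <- x
  }
  linkings
}

#' Is a linked aspect relevant?
#'
#' An aspect is relevant exactly when it carries an ICF code, that code is
#' owned by a survey item, and that item is in the relevant set. Flagged
#' aspects (not definable, not covered, personal factor, health condition) and
#' codes excluded from the survey are not relevant.
#'
#' @param aspects Tibble with one row per aspect and columns \code{icf_code},
#'   \code{flag} (exactly one non-missing per row).
#' @param relevant_items Integer vector of relevant survey item ids.
#' @param survey Survey-item table accepted by [survey_items()].
#' @return Logical vector, one element per aspect.
#' @export
aspect_relevance <- function(aspects, relevant_items, survey) {
  aspects <- validate_linkings_aspects(aspects)
  survey <- survey_items(survey)
  map <- code_to_item_map(survey)
  owning <- unname(map[aspects$icf_code])
  !is.na(owning) & owning %in% relevant_items
}

validate_linkings_aspects <- function(aspects) {
  aspects <- tibble::as_tibble(aspects)
  check_columns(aspects, c("icf_code", "flag"), "Aspect table")
  for (col in c("icf_code", "flag")) {
    x <- as.character(aspects[[col]])
    x[!is.na(x) & x == ""] <- NA_character_
    aspects[[col]] <- x
  }
  both <- !is.na(aspects$icf_code) & !is.na(aspects$flag)
  neither <- is.na(aspects$icf_code) & is.na(aspects$flag)
  if (any(both) || any(neither)) {
    abort_validation(sprintf(
      "Aspect row(s) %s must carry exactly one of icf_code / flag.",
      paste(utils::head(which(both | neither), 5L), collapse = ", ")
    ))
  }
  bad_flag <- !is.na(aspects$flag) & !aspects$flag %in% linking_flags()
  if (any(bad_flag)) {
    abort_validation(sprintf(
      "Unknown flag(s): %s (must be one of %s).",
      paste(unique(aspects$flag[bad_flag]), collapse = ", "),
      paste(linking_flags(), collapse = ", ")
    ))
  }
  bad_code <- !is.na(aspects$icf_code) & !grepl("^[A-Za-z]", aspects$icf_code)
  if (any(bad_code)) {
    abort_validation(sprintf(
      "Malformed ICF code(s): %s.",
      paste(unique(aspects$icf_code[bad_code]), collapse = ", ")
    ))
  }
  aspects
}

#' Coverage analysis rules A, B and C
#'
#' Because an instrument item can comprise several meaningful concepts
#' (aspects), three rules of increasing stringency decide whether the item is
#' relevant: analysis A requires at least one relevant aspect, analysis B at
#' least 50\% of aspects (inclusive), and analysis C all aspects.
#'
#' @param analysis \code{"A"}, \code{"B"} or \code{"C"}.
#' @return The matched analysis label.
#' @export
coverage_analysis <- function(analysis = c("A", "B", "C")) {
  match.arg(analysis)
}

#' Decide item relevance from its aspects
#'
#' @param aspects Tibble of the item's aspects (columns \code{icf_code},
#'   \code{flag}); must have at least one row. Flagged aspects count in the
#'   denominators of analyses B and C.
#' @inheritParams aspect_relevance
#' @param analysis Coverage analysis rule; see [coverage_analysis()].
#' @return Logical scalar.
#' @export
#' @examples
#' # one relevant + one flagged aspect: A yes, B yes (1/2 = 50%), C no
item_relevance <- function(aspects, relevant_items, survey,
                           analysis = c("A", "B", "C")) {
  analysis <- coverage_analysis(analysis)
  aspects <- tibble::as_tibble(aspects)
  if (nrow(aspects) == 0L) {
    abort_validation("An instrument item must have at least one aspect.")
  }
  rel <- aspect_relevance(aspects, relevant_items, survey)
  apply_analysis_rule(sum(rel), length(rel), analysis)
}

# A/B/C semantics on (number relevant, number of aspects); vectorized.
apply_analysis_rule <- function(n_relevant, n_aspects, analysis) {
  switch(analysis,
         A = n_relevant >= 1L,
         B = n_relevant / n_aspects >= 0.5,
         C = n_relevant == n_aspects)
}

#' Bands for instrument content coverage
#'
#' Low coverage is below 50\% of items relevant, moderate is 50\% up to (but
#' not including) 80\%, sufficient is 80\% and above. Band assignment uses the
#' exact coverage fraction, before any display rounding.
#'
#' @return Named vector of lower band edges in percent.
#' @export
coverage_bands <- function() {
  c(low = 0, moderate = 50, sufficient = 80)
}

#' Classify coverage percentages into bands
#'
#' @param coverage_percent Numeric vector in \code{[0, 100]}.
#' @param bands Named vector of lower edges, as [coverage_bands()].
#' @return Character vector of band labels.
#' @export
classify_coverage <- function(coverage_percent, bands = coverage_bands()) {
  if (any(!is.na(coverage_percent) &
            (coverage_percent < 0 | coverage_percent > 100))) {
    abort_validation("Coverage percentages must lie in [0, 100].")
  }
  edges <- sort(bands)
  names(edges)[findInterval(coverage_percent, edges)]
}

#' Content coverage of one instrument
#'
#' The fraction of an instrument's items deemed relevant under the chosen
#' analysis rule, as a percentage, with its coverage band.
#'
#' @param linkings Linking table rows for a single instrument (columns
#'   \code{instrument_id}, \code{item_id}, \code{concept_text},
#'   \code{icf_code}, \code{flag}; one row per aspect).
#' @inheritParams aspect_relevance
#' @param analysis Coverage analysis rule.
#' @return One-row tibble: \code{instrument_id}, \code{analysis},
#'   \code{n_items}, \code{n_relevant_items}, \code{coverage_percent},
#'   \code{band}.
#' @export
instrument_coverage <- function(linkings, relevant_items, survey,
                                analysis = c("A", "B", "C")) {
  analysis <- coverage_analysis(analysis)
  linkings <- validate_linkings(linkings)
  if (nrow(linkings) == 0L) {
    abort_validation("Instrument has no linked items.")
  }
  if (length(unique(linkings$instrument_id)) != 1L) {
    abort_validation("instrument_coverage() expects rows for a single instrument.")
  }
  validate_linkings_aspects(linkings[c("icf_code", "flag")])
  survey <- survey_items(survey)
  rel <- aspect_relevance(linkings[c("icf_code", "flag")], relevant_items, survey)
  n_rel_aspects <- tapply(rel, linkings$item_id, sum)
  n_aspects <- tapply(rel, linkings$item_id, length)
  item_rel <- apply_analysis_rule(as.integer(n_rel_aspects),
                                  as.integer(n_aspects), analysis)
  n_items <- length(item_rel)
  n_relevant <- sum(item_rel)
  pct <- 100 * n_relevant / n_items
  tibble::tibble(
    instrument_id = linkings$instrument_id[[1L]],
    analysis = analysis,
    n_items = n_items,
    n_relevant_items = as.integer(n_relevant),
    coverage_percent = pct,
    band = classify_coverage(pct)
  )
}

#' Content coverage for every instrument in a linking table
#'
#' @param linkings Full linking table (multiple instruments).
#' @inheritParams instrument_coverage
#' @return Tibble with one [instrument_coverage()] row per instrument.
#' @export
coverage_table <- function(linkings, relevant_items, survey,
                           analysis = c("A", "B", "C")) {
  analysis <- coverage_analysis(analysis)
  linkings <- validate_linkings(linkings)
  parts <- split(linkings, linkings$instrument_id)
  dplyr::bind_rows(lapply(parts, instrument_coverage,
                          relevant_items = relevant_items, survey = survey,
                          analysis = analysis))
}

#' Distribution of coverage bands across instruments
#'
#' @param results Tibble of [instrument_coverage()] rows, all from the same
#'   analysis, one per instrument.
#' @return Tibble with columns \code{band}, \code{count}, \code{percent};
#'   every band appears even at count zero.
#' @export
aggregate_coverage <- function(results) {
  results <- tibble::as_tibble(results)
  check_columns(results, c("instrument_id", "analysis", "coverage_percent", "band"),
                "Coverage results")
  if (nrow(results) == 0L) {
    abort_validation("No coverage results to aggregate.")
  }
  if (length(unique(results$analysis)) != 1L) {
    abort_validation("Coverage results mix analyses; aggregate one analysis at a time.")
  }
  dup <- results$instrument_id[duplicated(results$instrument_id)]
  if (length(dup) > 0L) {
    abort_covalid(
      sprintf("Duplicated instrument_id(s): %s",
              paste(unique(dup), collapse = ", ")),
      class = c("covalid_duplicate_key", "covalid_validation_error")
    )
  }
  band <- factor(results$band, levels = names(coverage_bands()))
  counts <- table(band)
  tibble::tibble(
    analysis = results$analysis[[1L]],
    band = names(counts),
    count = as.integer(counts),
    percent = round(100 * as.integer(counts) / nrow(results), 1)
  )
}

#' Validate a linking table and report problems
#'
#' Produces a report rather than failing: rows carrying both or neither of
#' \code{icf_code}/\code{flag}, unknown flags, and (when a catalog is given)
#' codes absent from the ICF catalog are listed with their row numbers. A
#' clean table yields an empty report.
#'
#' @param linkings Linking table.
#' @param catalog Optional [icf_catalog()] to check codes against.
#' @return Tibble with columns \code{row}, \code{instrument_id},
#'   \code{item_id}, \code{problem}.
#' @export
validate_linking <- function(linkings, catalog = NULL) {
  linkings <- validate_linkings(linkings)
  problems <- list()
  note <- function(rows, problem) {
    if (length(rows) > 0L) {
      problems[[length(problems) + 1L]] <<- tibble::tibble(
        row = rows,
        instrument_id = linkings$instrument_id[rows],
        item_id = linkings$item_id[rows],
        problem = problem
      )
    }
  }
  both <- which(!is.na(linkings$icf_code) & !is.na(linkings$flag))
  note(both, "both icf_code and flag present")
  neither <- which(is.na(linkings$icf_code) & is.na(linkings$flag))
  note(neither, "neither icf_code nor flag present")
  bad_flag <- which(!is.na(linkings$flag) & !linkings$flag %in% linking_flags())
  note(bad_flag, "unknown flag")
  if (!is.null(catalog)) {
    catalog <- icf_catalog(catalog)
    unknown <- which(!is.na(linkings$icf_code) &
                       !linkings$icf_code %in% catalog$code)
    note(unknown, "icf_code absent from catalog")
  }
  if (length(problems) == 0L) {
    return(tibble::tibble(row = integer(), instrument_id = character(),
                          item_id = character(), problem = character()))
  }
  out <- dplyr::bind_rows(problems)
  out[order(out$row), ]
}
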