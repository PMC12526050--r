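#' Dichotomization rules for 4-point Likert scores
#'
#' Survey items are scored 0 ("not at all") to 3 ("very much"). The main
#' analysis counts any non-zero score as an issue; the sensitivity analysis
#' counts only scores 2-3, treating 0-1 as not relevant.
#'
#' @param rule \code{"main"} or \code{"sensitivity"}, or an object previously
#'   returned by this function.
#' @return A list with elements \code{name} and \code{issue_scores}.
#' @export
dichotomization_rule <- function(rule = c("main", "sensitivity")) {
  if (is.list(rule) && all(c("name", "issue_scores") %in% names(rule))) {
    return(rule)
  }
  rule <- match.arg(rule)
  issue_scores <- switch(rule, main = 1:3, sensitivity = 2:3)
  list(name = rule, issue_scores = issue_scores)
}

#' Collapse Likert scores to binary issue indicators
#'
#' @param score Integer vector of scores in \code{0:3}; \code{NA} is allowed
#'   and propagates (available-case analysis).
#' @param rule A dichotomization rule; see [dichotomization_rule()].
#' @return Integer vector of 0/1 indicators with \code{NA} preserved.
#' @export
#' @examples
#' dichotomize(c(0, 1, 2, 3, NA), "main")        # 0 1 1 1 NA
#' dichotomize(c(0, 1, 2, 3, NA), "sensitivity") # 0 0 1 1 NA
dichotomize <- function(score, rule = "main") {
  rule <- dichotomization_rule(rule)
  score <- as.integer(score)
  bad <- !is.na(score) & !score %in% 0:3
  if (any(bad)) {
    abort_validation(sprintf(
      "Score(s) outside 0..3: %s",
      paste(unique(score[bad]), collapse = ", ")
    ))
  }
  out <- as.integer(score %in% rule$issue_scores)
  out[is.na(score)] <- NA_integer_
  out
}

validate_responses <- function(responses) {
  responses <- tibble::as_tibble(responses)
  check_columns(responses, c("respondent_id", "group", "item_id", "score"),
                "Response table")
  bad_group <- is.na(responses$group) | !responses$group %in% rater_groups()
  if (any(bad_group)) {
    abort_validation(sprintf(
      "Response row(s) %s have a missing or unknown rater group (must be one of %s).",
      paste(utils::head(which(bad_group), 5L), collapse = ", "),
      paste(rater_groups(), collapse = ", ")
    ))
  }
  responses$item_id <- as.integer(responses$item_id)
  responses$score <- as.integer(responses$score)
  bad <- !is.na(responses$score) & !responses$score %in% 0:3
  if (any(bad)) {
    abort_validation(sprintf(
      "Response row(s) %s have scores outside 0..3.",
      paste(utils::head(which(bad), 5L), collapse = ", ")
    ))
  }
  responses
}

#' Per-item, per-group issue fraction with available-case denominator
#'
#' @param responses Long response table with columns \code{respondent_id},
#'   \code{group}, \code{item_id}, \code{score}.
#' @param item_id Single survey item id.
#' @param group One of \code{"patient"}, \code{"proxy"}, \code{"hcp"}.
#' @param rule Dichotomization rule (see [dichotomization_rule()]).
#' @return A list with \code{fraction} (exact, unrounded) and
#'   \code{n_available}. Errors with class
#'   \code{covalid_no_available_cases} when every response is missing.
#' @export
item_issue_fraction <- function(responses, item_id, group, rule = "main") {
  responses <- validate_responses(responses)
  sel <- responses$item_id == item_id & responses$group == group
  ind <- dichotomize(responses$score[sel], rule)
  ind <- ind[!is.na(ind)]
  if (length(ind) == 0L) {
    abort_no_cases(
      sprintf("No available cases for item %s in group '%s'.", item_id, group),
      item_id = item_id, group = group
    )
  }
  list(fraction = mean(ind), n_available = length(ind))
}

#' Issue fractions for every item x group combination
#'
#' @inheritParams item_issue_fraction
#' @return Tibble with columns \code{item_id}, \code{group}, \code{fraction},
#'   \code{n_available}; combinations with zero available cases are absent.
#' @export
issue_fractions <- function(responses, rule = "main") {
  responses <- validate_responses(responses)
  ind <- dichotomize(responses$score, rule)
  keep <- !is.na(ind)
  key <- interaction(responses$item_id[keep], responses$group[keep],
                     drop = TRUE, sep = "\r")
  sums <- rowsum(cbind(issue = ind[keep], n = 1L), key)
  parts <- do.call(rbind, strsplit(rownames(sums), "\r", fixed = TRUE))
  out <- tibble::tibble(
    item_id = as.integer(parts[, 1L]),
    group = parts[, 2L],
    fraction = sums[, "issue"] / sums[, "n"],
    n_available = as.integer(sums[, "n"])
  )
  out[order(out$item_id, match(out$group, rater_groups())), ]
}

#' Relevance decision rule
#'
#' An item is listed as relevant when at least 25\% of patients, at least 25\%
#' of proxies, or at least 50\% of healthcare professionals report it as an
#' issue. Thresholds are compared inclusively on exact fractions, never on
#' display-rounded percentages.
#'
#' @param patient,proxy,hcp Group thresholds in \code{(0, 1]}.
#' @return A named list of thresholds.
#' @export
relevance_rule <- function(patient = 0.25, proxy = 0.25, hcp = 0.50) {
  thr <- c(patient = patient, proxy = proxy, hcp = hcp)
  if (any(is.na(thr)) || any(thr <= 0) || any(thr > 1)) {
    abort_validation("Relevance thresholds must lie in (0, 1].")
  }
  as.list(thr)
}

#' Apply the relevance rule to per-group issue fractions
#'
#' @param fractions Tibble with columns \code{group} and \code{fraction}
#'   (proportions in \code{[0, 1]}), optionally \code{item_id} and
#'   \code{n_available}. Groups absent for an item never satisfy their
#'   criterion.
#' @param rule A threshold rule from [relevance_rule()].
#' @return Tibble with one row per item (or a single row when no
#'   \code{item_id} column is given): \code{relevant} and \code{criteria_met}
#'   (comma-separated satisfying groups, \code{""} if none).
#' @export
#' @examples
#' determine_relevance(tibble::tibble(
#'   group = c("patient", "proxy", "hcp"),
#'   fraction = c(0.766, 0.729, 0.969)
#' ))
determine_relevance <- function(fractions, rule = relevance_rule()) {
  fractions <- tibble::as_tibble(fractions)
  check_columns(fractions, c("group", "fraction"), "Fraction table")
  if (!"item_id" %in% names(fractions)) fractions$item_id <- 1L
  bad <- !fractions$group %in% rater_groups()
  if (any(bad)) {
    abort_validation(sprintf("Unknown rater group(s): %s",
                             paste(unique(fractions$group[bad]), collapse = ", ")))
  }
  if (any(is.na(fractions$fraction) | fractions$fraction < 0 |
            fractions$fraction > 1)) {
    abort_validation("Fractions must lie in [0, 1] and be non-missing.")
  }
  thr <- unlist(rule)[fractions$group]
  met <- fractions$fraction >= thr
  split_met <- split(ifelse(met, fractions$group, NA_character_),
                     fractions$item_id)
  items <- as.integer(names(split_met))
  criteria <- vapply(split_met, function(g) {
    g <- g[!is.na(g)]
    paste(rater_groups()[rater_groups() %in% g], collapse = ",")
  }, character(1))
  out <- tibble::tibble(
    item_id = items,
    relevant = nzchar(criteria),
    criteria_met = unname(criteria)
  )
  out[order(out$item_id), ]
}

#' Full relevance analysis from long-format responses
#'
#' Dichotomizes scores, computes per-group available-case issue fractions, and
#' applies the relevance decision rule to every item.
#'
#' @inheritParams item_issue_fraction
#' @param dich_rule Dichotomization rule (\code{"main"} or
#'   \code{"sensitivity"}).
#' @param rule Threshold rule from [relevance_rule()].
#' @return Tibble with one row per item x group (\code{fraction}, \code{pct}
#'   rounded to one decimal for display, \code{n_available}) joined to the
#'   item-level decision (\code{relevant}, \code{criteria_met}).
#' @export
relevance_table <- function(responses, dich_rule = "main", rule = relevance_rule()) {
  fr <- issue_fractions(responses, dich_rule)
  dec <- determine_relevance(fr, rule)
  fr$pct <- round(100 * fr$fraction, 1)
  merged <- merge(as.data.frame(fr), as.data.frame(dec), by = "item_id")
  out <- tibble::as_tibble(merged)
  out[order(out$item_id, match(out$group, rater_groups())), ]
}

#' Threshold rule for open-ended survey responses
#'
#' @param threshold Minimum fraction of a rater group that must report an
#'   uncovered issue for it to become a candidate item; default 5\%.
#' @return A list with element \code{threshold}.
#' @export
open_ended_rule <- function(threshold = 0.05) {
  if (is.na(threshold) || threshold <= 0 || threshold >= 1) {
    abort_validation("Open-ended threshold must lie in (0, 1).")
  }
  list(threshold = threshold)
}

#' Screen consensus-coded open-ended issues for candidate new items
#'
#' Issues reported in the survey's free-text field are coded by human
#' reviewers upstream; this function applies only the counting rule: an issue
#' not already covered by the survey becomes a candidate item when at least
#' the threshold fraction of some rater group reported it. The denominator is
#' the size of the reporting group.
#'
#' @param coded_issues Tibble with columns \code{issue_label}, \code{group},
#'   \code{n_reporters}, \code{covered} (logical: already covered by the
#'   survey).
#' @param group_sizes Named vector or tibble (\code{group}, \code{n}) of
#'   rater-group sizes.
#' @param rule Rule from [open_ended_rule()].
#' @return Tibble of candidate issues (\code{issue_label}, \code{group},
#'   \code{n_reporters}, \code{fraction}), empty when nothing qualifies.
#' @export
#' @examples
#' code_open_ended(
#'   tibble::tibble(issue_label = "seizures", group = "patient",
#'                  n_reporters = 5, covered = FALSE),
#'   c(patient = 114, proxy = 71, hcp = 65)
#' ) # 5/114 = 4.4% < 5%: empty
code_open_ended <- function(coded_issues, group_sizes, rule = open_ended_rule()) {
  coded_issues <- tibble::as_tibble(coded_issues)
  check_columns(coded_issues, c("issue_label", "group", "n_reporters", "covered"),
                "Coded-issue table")
  if (is.data.frame(group_sizes)) {
    group_sizes <- stats::setNames(group_sizes$n, group_sizes$group)
  }
  need <- unique(coded_issues$group)
  missing <- setdiff(need, names(group_sizes))
  if (length(missing) > 0L) {
    abort_validation(sprintf("Group size missing for reporting group(s): %s",
                             paste(missing, collapse = ", ")))
  }
  frac <- coded_issues$n_reporters / group_sizes[coded_issues$group]
  keep <- !coded_issues$covered & frac >= rule$threshold & coded_issues$n_reporters > 0
  out <- coded_issues[keep, c("issue_label", "group", "n_reporters")]
  out$fraction <- unname(frac[keep])
  out
}
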