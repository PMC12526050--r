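#' Disposition vocabulary for ICF catalog entries
#'
#' Each ICF category considered during survey construction receives exactly one
#' disposition: it was a (sub)heading, applied only to children, was judged not
#' specific enough to become a survey item, was too difficult to phrase as a
#' patient-reported item, became a standalone survey item, or was combined with
#' other categories into a single item.
#'
#' @return Character vector of the six valid disposition labels.
#' @export
icf_dispositions <- function() {
  c("heading", "child_only", "not_specific", "too_difficult",
    "standalone", "combined")
}

#' Validate an ICF catalog table
#'
#' An ICF catalog records, for every ICF category examined during survey
#' construction, its code, label and disposition. Categories with disposition
#' \code{"combined"} must carry a \code{combine_group_id} naming the group of
#' categories merged into one survey item; all other dispositions must not.
#'
#' @param catalog A data frame with columns \code{code}, \code{label},
#'   \code{disposition} and optionally \code{combine_group_id}.
#' @return The validated catalog as a tibble, with a \code{combine_group_id}
#'   column present (possibly all \code{NA}).
#' @export
#' @examples
#' icf_catalog(data.frame(
#'   code = c("b110", "b114"), label = c("Consciousness", "Orientation"),
#'   disposition = c("standalone", "standalone")
#' ))
icf_catalog <- function(catalog) {
  catalog <- tibble::as_tibble(catalog)
  check_columns(catalog, c("code", "label", "disposition"), "ICF catalog")
  if (!"combine_group_id" %in% names(catalog)) {
    catalog$combine_group_id <- NA_character_
  }
  catalog$code <- as.character(catalog$code)
  catalog$combine_group_id <- as.character(catalog$combine_group_id)
  catalog$combine_group_id[!is.na(catalog$combine_group_id) &
                             catalog$combine_group_id == ""] <- NA_character_
  dup <- catalog$code[duplicated(catalog$code)]
  if (length(dup) > 0L) {
    abort_covalid(
      sprintf("Duplicate ICF code(s) in catalog: %s",
              paste(unique(dup), collapse = ", ")),
      class = c("covalid_duplicate_key", "covalid_validation_error")
    )
  }
  bad <- !catalog$disposition %in% icf_dispositions()
  if (any(bad)) {
    abort_validation(sprintf(
      "Unknown disposition for code(s) %s (must be one of %s).",
      paste(catalog$code[bad], collapse = ", "),
      paste(icf_dispositions(), collapse = ", ")
    ))
  }
  need_group <- catalog$disposition == "combined"
  miss_group <- need_group & is.na(catalog$combine_group_id)
  if (any(miss_group)) {
    abort_validation(sprintf(
      "Combined category without combine_group_id: %s",
      paste(catalog$code[miss_group], collapse = ", ")
    ))
  }
  stray_group <- !need_group & !is.na(catalog$combine_group_id)
  if (any(stray_group)) {
    abort_validation(sprintf(
      "combine_group_id set for non-combined category: %s",
      paste(catalog$code[stray_group], collapse = ", ")
    ))
  }
  catalog
}

#' Validate a survey-item table
#'
#' A survey item owns one or more ICF codes: standalone items own exactly the
#' category they were written from, combined items own every category merged
#' into them. No ICF code may be owned by two items (categories were combined,
#' never split).
#'
#' @param items A data frame with columns \code{item_id}, \code{text} and
#'   \code{icf_codes}, where \code{icf_codes} is either a list column of
#'   character vectors or a character column of semicolon-separated codes.
#' @return The validated tibble with \code{icf_codes} as a list column.
#' @export
survey_items <- function(items) {
  items <- tibble::as_tibble(items)
  check_columns(items, c("item_id", "text", "icf_codes"), "Survey item table")
  items$item_id <- as.integer(items$item_id)
  if (anyNA(items$item_id) || any(items$item_id <= 0L)) {
    abort_validation("item_id must be a positive integer for every survey item.")
  }
  if (anyDuplicated(items$item_id)) {
    abort_covalid(
      sprintf("Duplicate item_id(s): %s",
              paste(unique(items$item_id[duplicated(items$item_id)]),
                    collapse = ", ")),
      class = c("covalid_duplicate_key", "covalid_validation_error")
    )
  }
  if (!is.list(items$icf_codes)) {
    items$icf_codes <- strsplit(as.character(items$icf_codes), ";", fixed = TRUE)
  }
  items$icf_codes <- lapply(items$icf_codes, function(x) {
    x <- trimws(as.character(x))
    x[nzchar(x)]
  })
  if (any(lengths(items$icf_codes) == 0L)) {
    abort_validation(sprintf(
      "Survey item(s) with no ICF codes: %s",
      paste(items$item_id[lengths(items$icf_codes) == 0L], collapse = ", ")
    ))
  }
  all_codes <- unlist(items$icf_codes, use.names = FALSE)
  dup <- unique(all_codes[duplicated(all_codes)])
  if (length(dup) > 0L) {
    abort_covalid(
      sprintf("ICF code(s) owned by more than one survey item: %s",
              paste(dup, collapse = ", ")),
      class = c("covalid_duplicate_key", "covalid_validation_error")
    )
  }
  items
}

#' Summarize the survey-construction ledger
#'
#' Reproduces the bookkeeping of turning an ICF category catalog into a survey:
#' (sub)headings and child-only categories are excluded first, categories judged
#' not specific enough or too difficult are dropped next, and the remaining
#' eligible categories either become standalone items or are combined into
#' single items. The arithmetic identities between these counts are enforced;
#' a ledger whose counts cannot balance is rejected.
#'
#' @param catalog A catalog accepted by [icf_catalog()]. Heading/child-only
#'   rows may be included explicitly, or summarized via
#'   \code{n_excluded_heading_child} for catalogs that ship only the examined
#'   categories.
#' @param n_excluded_heading_child Count of (sub)heading and child-only
#'   categories excluded upstream and not present as catalog rows.
#' @return An object of class \code{construction_summary}: a named list with
#'   counts \code{n_catalog}, \code{n_after_heading_child},
#'   \code{n_not_specific}, \code{n_too_difficult}, \code{n_eligible},
#'   \code{n_standalone}, \code{n_combined_categories},
#'   \code{n_combined_items} and \code{n_survey_items}.
#' @export
#' @examples
#' cat <- icf_catalog(data.frame(
#'   code = sprintf("c%02d", 1:8),
#'   label = "x",
#'   disposition = c("not_specific", "not_specific", "not_specific",
#'                   "too_difficult", "standalone", "standalone",
#'                   "combined", "combined"),
#'   combine_group_id = c(rep(NA, 6), "g1", "g1")
#' ))
#' build_survey_ledger(cat, n_excluded_heading_child = 2)
build_survey_ledger <- function(catalog, n_excluded_heading_child = 0L) {
  catalog <- icf_catalog(catalog)
  n_excluded_heading_child <- as.integer(n_excluded_heading_child)
  if (is.na(n_excluded_heading_child) || n_excluded_heading_child < 0L) {
    abort_validation("`n_excluded_heading_child` must be a non-negative count.")
  }
  disp <- catalog$disposition
  n_heading_rows <- sum(disp %in% c("heading", "child_only"))
  n_catalog <- nrow(catalog) + n_excluded_heading_child
  n_after <- n_catalog - n_excluded_heading_child - n_heading_rows
  n_not_specific <- sum(disp == "not_specific")
  n_too_difficult <- sum(disp == "too_difficult")
  n_eligible <- n_after - n_not_specific - n_too_difficult
  n_standalone <- sum(disp == "standalone")
  n_combined_categories <- sum(disp == "combined")
  groups <- unique(catalog$combine_group_id[disp == "combined"])
  n_combined_items <- length(groups)
  if (n_eligible != n_standalone + n_combined_categories) {
    abort_validation(sprintf(
      paste("Ledger does not balance: %d eligible categories but %d standalone",
            "+ %d combined."),
      n_eligible, n_standalone, n_combined_categories
    ))
  }
  structure(
    list(
      n_catalog = n_catalog,
      n_after_heading_child = n_after,
      n_not_specific = n_not_specific,
      n_too_difficult = n_too_difficult,
      n_eligible = n_eligible,
      n_standalone = n_standalone,
      n_combined_categories = n_combined_categories,
      n_combined_items = n_combined_items,
      n_survey_items = n_standalone + n_combined_items
    ),
    class = "construction_summary"
  )
}

#' @export
print.construction_summary <- function(x, ...) {
  cat("Survey construction ledger\n")
  cat(sprintf("  ICF categories examined:   %d\n", x$n_catalog))
  cat(sprintf("  After heading/child excl.: %d\n", x$n_after_heading_child))
  cat(sprintf("  Not specific enough:       %d\n", x$n_not_specific))
  cat(sprintf("  Too difficult for PRO:     %d\n", x$n_too_difficult))
  cat(sprintf("  Eligible:                  %d\n", x$n_eligible))
  cat(sprintf("  Standalone items:          %d\n", x$n_standalone))
  cat(sprintf("  Combined: %d categories -> %d items\n",
              x$n_combined_categories, x$n_combined_items))
  cat(sprintf("  Survey items:              %d\n", x$n_survey_items))
  invisible(x)
}

#' Look up the survey item owning an ICF code
#'
#' @param items A survey-item table accepted by [survey_items()].
#' @param icf_code A single ICF code.
#' @return The owning \code{item_id}, or \code{NA_integer_} if the code was
#'   excluded from the survey.
#' @export
map_category_to_item <- function(items, icf_code) {
  items <- survey_items(items)
  if (length(icf_code) != 1L || is.na(icf_code)) {
    abort_validation("`icf_code` must be a single non-missing code.")
  }
  hit <- which(vapply(items$icf_codes, function(x) icf_code %in% x, logical(1)))
  if (length(hit) == 0L) return(NA_integer_)
  items$item_id[hit]
}

# Fast inverse map used by the coverage module: named integer vector
# code -> item_id over an already validated survey table.
code_to_item_map <- function(items) {
  codes <- unlist(items$icf_codes, use.names = FALSE)
  stats::setNames(rep(items$item_id, lengths(items$icf_codes)), codes)
}
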