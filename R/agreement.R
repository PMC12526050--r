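#' Construct an agreement cross-tab
#'
#' @param counts Square matrix of non-negative integer dyad counts; rows index
#'   the patient score, columns the proxy score.
#' @param levels Optional score labels for the table dimensions.
#' @return An object of class \code{agreement_table} with elements
#'   \code{counts} and \code{n}.
#' @export
agreement_table <- function(counts, levels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    abort_validation("Agreement table must be square.")
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort_validation("Agreement counts must be non-negative integers.")
  }
  n <- sum(counts)
  if (n < 1) {
    abort_no_cases("Agreement table holds zero dyads.")
  }
  if (is.null(levels)) {
    levels <- rownames(counts) %||% as.character(seq_len(nrow(counts)) - 1L)
  }
  dimnames(counts) <- list(patient = levels, proxy = levels)
  structure(list(counts = counts, n = n), class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("Patient-proxy agreement table (n = %d dyads)\n", x$n))
  print(x$counts)
  invisible(x)
}

validate_dyad_roster <- function(roster) {
  roster <- tibble::as_tibble(roster)
  check_columns(roster, c("dyad_id", "patient_id", "proxy_id"), "Dyad roster")
  if (nrow(roster) == 0L) {
    abort_validation("Dyad roster is empty.")
  }
  for (col in c("dyad_id", "patient_id", "proxy_id")) {
    dup <- roster[[col]][duplicated(roster[[col]])]
    if (length(dup) > 0L) {
      abort_covalid(
        sprintf("%s appears in more than one dyad: %s", col,
                paste(unique(dup), collapse = ", ")),
        class = c("covalid_duplicate_key", "covalid_validation_error")
      )
    }
  }
  roster
}

#' Cross-tabulate patient and proxy scores for one item
#'
#' Builds the k x k dyad cross-tab for a survey item, on the raw 4-point scale
#' (k = 4) or after dichotomization (k = 2). Dyads in which either member is
#' missing the item are excluded, so \code{n} is the available-case count; a
#' dyad can therefore contribute to some items and not others.
#'
#' @param responses Long response table (see [relevance_table()]).
#' @param roster Dyad roster with columns \code{dyad_id}, \code{patient_id},
#'   \code{proxy_id}; each patient and each proxy belongs to exactly one dyad.
#' @param item_id Survey item to tabulate.
#' @param rule \code{"raw"} for the 0-3 scale, or a dichotomization rule.
#' @return An [agreement_table()].
#' @export
crosstab_dyads <- function(responses, roster, item_id, rule = "raw") {
  responses <- validate_responses(responses)
  roster <- validate_dyad_roster(roster)
  sel <- responses$item_id == item_id
  resp <- responses[sel, ]
  pat <- resp$score[match(roster$patient_id, resp$respondent_id)]
  pro <- resp$score[match(roster$proxy_id, resp$respondent_id)]
  if (identical(rule, "raw")) {
    levels <- 0:3
  } else {
    pat <- dichotomize(pat, rule)
    pro <- dichotomize(pro, rule)
    levels <- 0:1
  }
  ok <- !is.na(pat) & !is.na(pro)
  if (!any(ok)) {
    abort_no_cases(sprintf("No complete dyads for item %s.", item_id),
                   item_id = item_id)
  }
  counts <- table(factor(pat[ok], levels = levels),
                  factor(pro[ok], levels = levels))
  agreement_table(unclass(counts), levels = as.character(levels))
}

#' Agreement weight matrix
#'
#' @param k Number of score categories.
#' @param scheme \code{"identity"} (unweighted kappa), \code{"linear"}
#'   (\eqn{w_{ij} = 1 - |i-j|/(k-1)}) or \code{"quadratic"}
#'   (\eqn{w_{ij} = 1 - ((i-j)/(k-1))^2}).
#' @return A symmetric k x k matrix with unit diagonal.
#' @export
weight_matrix <- function(k, scheme = c("identity", "linear", "quadratic")) {
  scheme <- match.arg(scheme)
  if (k < 2L) abort_validation("Weight matrix needs k >= 2 categories.")
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(scheme,
         identity = (d == 0) + 0,
         linear = 1 - d / (k - 1),
         quadratic = 1 - (d / (k - 1))^2)
}

#' Cohen's kappa and weighted kappa with null-hypothesis inference
#'
#' Computes the (weighted) observed proportion \eqn{p_o = \sum_{ij} w_{ij}
#' o_{ij} / n}, the chance proportion \eqn{p_e = \sum_{ij} w_{ij} r_i c_j /
#' n^2} from the margins, and \eqn{\kappa = (p_o - p_e) / (1 - p_e)}. The
#' standard error under the null hypothesis of chance agreement uses the
#' Fleiss-Cohen-Everitt large-sample formula, giving a two-sided z-test of
#' \eqn{\kappa = 0}.
#'
#' When both raters are constant on the same category, \eqn{p_e = 1} and kappa
#' is undefined; the result is returned with \code{undefined = TRUE} and
#' \code{kappa = NA}, never coerced to 0.
#'
#' @param table An [agreement_table()] or a square count matrix.
#' @param weights Weight scheme name (see [weight_matrix()]) or a custom
#'   symmetric weight matrix with unit diagonal.
#' @return An object of class \code{agreement_result}: a list with \code{n},
#'   \code{observed_count}, \code{observed_pct} (exact-score agreement),
#'   \code{p_o}, \code{p_e}, \code{kappa}, \code{se0}, \code{z},
#'   \code{p_value}, \code{significant} (at alpha = 0.05), \code{scheme},
#'   \code{undefined}.
#' @export
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 25), 2), weights = "identity")$kappa # 0.5
cohen_kappa <- function(table, weights = "identity") {
  if (!inherits(table, "agreement_table")) table <- agreement_table(table)
  counts <- table$counts
  n <- table$n
  k <- nrow(counts)
  if (is.matrix(weights)) {
    w <- weights
    scheme <- "custom"
    if (!isTRUE(all.equal(w, t(w))) || any(diag(w) != 1) ||
          any(w < 0) || any(w > 1)) {
      abort_validation("Custom weights must be symmetric in [0,1] with unit diagonal.")
    }
  } else {
    scheme <- match.arg(weights, c("identity", "linear", "quadratic"))
    w <- weight_matrix(k, scheme)
  }
  p <- counts / n
  r <- rowSums(p)
  c_ <- colSums(p)
  p_o <- sum(w * p)
  p_e <- sum(w * outer(r, c_))
  observed_count <- sum(diag(counts))
  observed_pct <- 100 * observed_count / n

  if (p_e >= 1 - 1e-12) {
    res <- list(n = n, observed_count = observed_count,
                observed_pct = observed_pct, p_o = p_o, p_e = p_e,
                kappa = NA_real_, se0 = NA_real_, z = NA_real_,
                p_value = NA_real_, significant = NA, scheme = scheme,
                undefined = TRUE)
    return(structure(res, class = "agreement_result"))
  }
  kappa <- (p_o - p_e) / (1 - p_e)

  # Fleiss-Cohen-Everitt null variance of weighted kappa
  wbar_row <- as.vector(w %*% c_)    # E[w | patient score i]
  wbar_col <- as.vector(t(w) %*% r)  # E[w | proxy score j]
  var0 <- (sum(outer(r, c_) * (w - outer(wbar_row, wbar_col, "+"))^2) - p_e^2) /
    (n * (1 - p_e)^2)
  se0 <- sqrt(max(var0, 0))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  p_value <- if (!is.na(z)) 2 * stats::pnorm(-abs(z)) else NA_real_
  structure(
    list(n = n, observed_count = observed_count, observed_pct = observed_pct,
         p_o = p_o, p_e = p_e, kappa = kappa, se0 = se0, z = z,
         p_value = p_value,
         significant = if (!is.na(p_value)) p_value <= 0.05 else NA,
         scheme = scheme, undefined = FALSE),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s weights), n = %d dyads\n", x$scheme, x$n))
  if (x$undefined) {
    cat("  kappa undefined: both raters constant (p_e = 1)\n")
    return(invisible(x))
  }
  cat(sprintf("  exact agreement: %d (%.1f%%)\n", x$observed_count, x$observed_pct))
  cat(sprintf("  p_o = %.4f, p_e = %.4f, kappa = %.2f\n", x$p_o, x$p_e, x$kappa))
  cat(sprintf("  z = %.3f, two-sided p = %.4g%s\n", x$z, x$p_value,
              if (isTRUE(x$significant)) "" else " (not significant at .05)"))
  invisible(x)
}

#' Interpretation bands for kappa estimates
#'
#' Default bands: below 0.41 below-moderate, 0.41-0.60 moderate, 0.61-0.80
#' substantial, 0.81-1.00 excellent; boundaries inclusive at the lower edge,
#' and a perfect kappa of 1 is classed excellent.
#'
#' @return Named vector of lower band edges.
#' @export
agreement_bands <- function() {
  c(below_moderate = -1, moderate = 0.41, substantial = 0.61, excellent = 0.81)
}

#' Classify kappa estimates into interpretation bands
#'
#' @param kappa Numeric vector of kappa estimates in \code{[-1, 1]};
#'   \code{NA} (undefined kappa) yields \code{NA}.
#' @param bands Named vector of lower band edges, as [agreement_bands()].
#' @return Character vector of band labels.
#' @export
#' @examples
#' classify_agreement(c(0.44, 0.63, 0.30, 1))
classify_agreement <- function(kappa, bands = agreement_bands()) {
  if (any(!is.na(kappa) & (kappa < -1 | kappa > 1))) {
    abort_validation("kappa estimates must lie in [-1, 1].")
  }
  edges <- sort(bands)
  labels <- names(edges)
  idx <- findInterval(kappa, edges)
  out <- labels[idx]
  out[is.na(kappa)] <- NA_character_
  out
}

#' Per-item patient-proxy agreement report
#'
#' Convenience wrapper running [crosstab_dyads()] and [cohen_kappa()] for each
#' requested item. Items on the raw scale use the given weight scheme; results
#' are labelled with the scheme so weighted and unweighted kappas are never
#' conflated.
#'
#' @inheritParams crosstab_dyads
#' @param items Item ids to analyse; defaults to every item present.
#' @param weights Weight scheme for [cohen_kappa()].
#' @return Tibble with one row per item: \code{item_id}, \code{n},
#'   \code{agreement_count}, \code{agreement_pct}, \code{kappa},
#'   \code{scheme}, \code{p_value}, \code{band}. Items with no complete dyads
#'   or undefined kappa carry \code{NA}s.
#' @export
agreement_report <- function(responses, roster, items = NULL, rule = "raw",
                             weights = "linear") {
  responses <- validate_responses(responses)
  roster <- validate_dyad_roster(roster)
  if (is.null(items)) items <- sort(unique(responses$item_id))
  rows <- lapply(items, function(it) {
    tab <- tryCatch(crosstab_dyads(responses, roster, it, rule),
                    covalid_no_available_cases = function(e) NULL)
    if (is.null(tab)) {
      return(tibble::tibble(item_id = it, n = 0L, agreement_count = NA_integer_,
                            agreement_pct = NA_real_, kappa = NA_real_,
                            scheme = NA_character_, p_value = NA_real_,
                            band = NA_character_))
    }
    res <- cohen_kappa(tab, weights)
    tibble::tibble(
      item_id = it, n = res$n, agreement_count = res$observed_count,
      agreement_pct = round(res$observed_pct, 1),
      kappa = if (res$undefined) NA_real_ else round(res$kappa, 2),
      scheme = res$scheme, p_value = res$p_value,
      band = if (res$undefined) NA_character_ else classify_agreement(res$kappa)
    )
  })
  dplyr::bind_rows(rows)
}
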