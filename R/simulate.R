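#' Synthetic ICF catalog with study-scale dispositions
#'
#' Builds a disposition ledger shaped like the survey-construction exercise:
#' by default 833 examined categories (320 not specific, 5 too difficult, 63
#' standalone, 445 combined into 85 groups) with 198 heading/child-only
#' exclusions recorded as a ledger annotation, so the ledger resolves to 508
#' eligible categories and 148 survey items. Codes are synthetic
#' (\code{s0001}, ...); group assignment is deterministic round-robin with
#' every group receiving at least two categories.
#'
#' @param n_not_specific,n_too_difficult,n_standalone,n_combined Category
#'   counts per disposition.
#' @param n_groups Number of combined items the combined categories form.
#' @param n_excluded_heading_child Heading/child-only exclusions (annotation
#'   only; no catalog rows).
#' @return List with elements \code{catalog} (an [icf_catalog()] tibble) and
#'   \code{n_excluded_heading_child}.
#' @export
simulate_icf_catalog <- function(n_not_specific = 320L, n_too_difficult = 5L,
                                 n_standalone = 63L, n_combined = 445L,
                                 n_groups = 85L,
                                 n_excluded_heading_child = 198L) {
  if (n_combined < 2L * n_groups) {
    abort_validation("Each combined group needs at least two categories.")
  }
  n_rows <- n_not_specific + n_too_difficult + n_standalone + n_combined
  disposition <- rep(c("not_specific", "too_difficult", "standalone", "combined"),
                     c(n_not_specific, n_too_difficult, n_standalone, n_combined))
  group <- rep(NA_character_, n_rows)
  group[disposition == "combined"] <-
    sprintf("g%03d", rep_len(seq_len(n_groups), n_combined))
  catalog <- icf_catalog(tibble::tibble(
    code = sprintf("s%04d", seq_len(n_rows)),
    label = sprintf("Synthetic ICF category %d", seq_len(n_rows)),
    disposition = disposition,
    combine_group_id = group
  ))
  list(catalog = catalog,
       n_excluded_heading_child = as.integer(n_excluded_heading_child))
}

#' Build survey items from a disposition catalog
#'
#' Standalone categories become one item each; each combined group becomes a
#' single item owning all its categories. Item ids are assigned sequentially,
#' standalone items first.
#'
#' @param catalog An [icf_catalog()] tibble.
#' @return A [survey_items()] tibble.
#' @export
simulate_survey <- function(catalog) {
  catalog <- icf_catalog(catalog)
  standalone <- catalog$code[catalog$disposition == "standalone"]
  combined <- catalog[catalog$disposition == "combined", ]
  groups <- split(combined$code, combined$combine_group_id)
  codes <- c(as.list(standalone), unname(groups))
  survey_items(tibble::tibble(
    item_id = seq_along(codes),
    text = sprintf("Synthetic survey item %d", seq_along(codes)),
    icf_codes = codes
  ))
}

#' Plant per-item response profiles with known relevance
#'
#' For every item and rater group an issue probability is drawn from a
#' two-point set well separated from the decision thresholds (patients and
#' proxies: 0.10 or 0.40 around the 25\% threshold; HCPs: 0.35 or 0.65 around
#' the 50\% threshold; 0.15 margins either side). The issue mass is split
#' across scores 1-3 so that main- and sensitivity-rule fractions differ. The
#' planted relevant set is the set of items where at least one group's issue
#' probability exceeds its threshold.
#'
#' @param item_ids Item ids to plant profiles for.
#' @param seed Integer seed.
#' @param p_low,p_high Two-point issue probabilities for patients/proxies.
#' @param p_low_hcp,p_high_hcp Two-point issue probabilities for HCPs.
#' @param missing_rate Per-response missingness probability.
#' @param rule Threshold rule the planted set is defined against.
#' @return List with \code{profiles} (tibble: \code{item_id}, \code{group},
#'   \code{p0}..\code{p3}, \code{missing_rate}), \code{planted} (tibble:
#'   \code{item_id}, \code{group}, \code{p_issue}) and
#'   \code{relevant_items} (integer vector).
#' @export
simulate_response_profiles <- function(item_ids, seed = NULL,
                                       p_low = 0.10, p_high = 0.40,
                                       p_low_hcp = 0.35, p_high_hcp = 0.65,
                                       missing_rate = 0.03,
                                       rule = relevance_rule()) {
  if (missing_rate < 0 || missing_rate > 1) {
    abort_validation("`missing_rate` must lie in [0, 1].")
  }
  grid <- expand.grid(item_id = item_ids, group = rater_groups(),
                      stringsAsFactors = FALSE)
  p_issue <- with_seed(seed, {
    ifelse(grid$group == "hcp",
           sample(c(p_low_hcp, p_high_hcp), nrow(grid), replace = TRUE),
           sample(c(p_low, p_high), nrow(grid), replace = TRUE))
  })
  # split issue mass over scores 1:3 (50/30/20), so the sensitivity-rule
  # fraction is half the main-rule fraction
  profiles <- tibble::tibble(
    item_id = as.integer(grid$item_id),
    group = grid$group,
    p0 = 1 - p_issue,
    p1 = 0.5 * p_issue,
    p2 = 0.3 * p_issue,
    p3 = 0.2 * p_issue,
    missing_rate = missing_rate
  )
  planted <- tibble::tibble(item_id = profiles$item_id, group = profiles$group,
                            p_issue = p_issue)
  thr <- unlist(rule)[planted$group]
  relevant <- sort(unique(planted$item_id[planted$p_issue >= thr]))
  list(profiles = profiles, planted = planted,
       relevant_items = as.integer(relevant))
}

validate_profiles <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  check_columns(profiles, c("item_id", "group", "p0", "p1", "p2", "p3",
                            "missing_rate"), "Response profiles")
  p <- as.matrix(profiles[c("p0", "p1", "p2", "p3")])
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-8)) {
    abort_validation("Each profile's score distribution must be non-negative and sum to 1.")
  }
  if (any(profiles$missing_rate < 0 | profiles$missing_rate > 1)) {
    abort_validation("missing_rate must lie in [0, 1].")
  }
  profiles
}

#' Generate long-format survey responses from planted profiles
#'
#' @param profiles Profile tibble from [simulate_response_profiles()].
#' @param group_sizes Named vector of respondents per group; the default
#'   mirrors the study scale (114 patients, 71 proxies, 65 HCPs).
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return Long response tibble (\code{respondent_id}, \code{group},
#'   \code{item_id}, \code{score}) with \code{NA} scores for missing
#'   responses.
#' @export
generate_responses <- function(profiles,
                               group_sizes = c(patient = 114, proxy = 71, hcp = 65),
                               seed = NULL) {
  profiles <- validate_profiles(profiles)
  missing_groups <- setdiff(unique(profiles$group), names(group_sizes))
  if (length(missing_groups) > 0L) {
    abort_validation(sprintf("No group size for: %s",
                             paste(missing_groups, collapse = ", ")))
  }
  with_seed(seed, {
    parts <- lapply(split(profiles, profiles$group), function(pg) {
      grp <- pg$group[[1L]]
      n <- group_sizes[[grp]]
      if (n == 0L) return(NULL)
      n_items <- nrow(pg)
      scores <- matrix(NA_integer_, nrow = n, ncol = n_items)
      for (i in seq_len(n_items)) {
        s <- sample(0:3, n, replace = TRUE,
                    prob = c(pg$p0[i], pg$p1[i], pg$p2[i], pg$p3[i]))
        if (pg$missing_rate[i] > 0) {
          s[stats::runif(n) < pg$missing_rate[i]] <- NA_integer_
        }
        scores[, i] <- s
      }
      ids <- sprintf("%s%04d", substr(grp, 1, 3), seq_len(n))
      tibble::tibble(
        respondent_id = rep(ids, times = n_items),
        group = grp,
        item_id = rep(pg$item_id, each = n),
        score = as.vector(scores)
      )
    })
    out <- dplyr::bind_rows(parts)
    out[order(out$group, out$respondent_id, out$item_id), ]
  })
}

#' Dyad response model
#'
#' A patient-proxy dyad draws the patient score from \code{patient_marginal}
#' and the proxy score from the corresponding row of the \code{transition}
#' matrix, giving the joint distribution \eqn{p_{ij} = m_i T_{ij}} with a
#' closed-form expected kappa.
#'
#' @param patient_marginal Probability vector over scores (length 2 or 4).
#' @param transition Square matrix; row \code{s} is the proxy-score
#'   distribution given patient score \code{s}.
#' @return Object of class \code{dyad_model} with the implied \code{joint}
#'   distribution.
#' @export
dyad_model <- function(patient_marginal, transition) {
  k <- length(patient_marginal)
  transition <- as.matrix(transition)
  if (any(patient_marginal < 0) || abs(sum(patient_marginal) - 1) > 1e-8) {
    abort_validation("patient_marginal must be a probability vector.")
  }
  if (nrow(transition) != k || ncol(transition) != k) {
    abort_validation("transition must be k x k for a length-k marginal.")
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8)) {
    abort_validation("Each transition row must be a probability distribution.")
  }
  joint <- patient_marginal * transition
  structure(list(patient_marginal = patient_marginal, transition = transition,
                 joint = joint, k = k), class = "dyad_model")
}

#' Closed-form expected kappa of a dyad model
#'
#' Evaluates \eqn{p_o(w) = \sum w_{ij} p_{ij}} and \eqn{p_e(w) = \sum w_{ij}
#' p_{i\cdot} p_{\cdot j}} on the model's joint distribution.
#'
#' @param model A [dyad_model()].
#' @param weights Weight scheme (see [weight_matrix()]).
#' @return Expected kappa (scalar); \code{NA} if \eqn{p_e = 1}.
#' @export
expected_kappa <- function(model, weights = "identity") {
  stopifnot(inherits(model, "dyad_model"))
  w <- if (is.matrix(weights)) weights else weight_matrix(model$k, weights)
  joint <- model$joint
  r <- rowSums(joint)
  c_ <- colSums(joint)
  p_o <- sum(w * joint)
  p_e <- sum(w * outer(r, c_))
  if (p_e >= 1 - 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Generate patient-proxy dyad responses with known expected kappa
#'
#' @param model A [dyad_model()].
#' @param n_dyads Number of dyads.
#' @param item_ids Item id(s) to generate; each item is drawn independently
#'   from the same model.
#' @param seed Integer seed.
#' @return List with \code{responses} (long tibble over patients and proxies),
#'   \code{roster} (\code{dyad_id}, \code{patient_id}, \code{proxy_id}) and
#'   \code{expected_kappa} (named vector for identity/linear/quadratic
#'   weights). Scores are on \code{0:(k-1)} for a k-level model.
#' @export
generate_dyads <- function(model, n_dyads, item_ids = 1L, seed = NULL) {
  stopifnot(inherits(model, "dyad_model"))
  if (n_dyads < 1L) abort_validation("`n_dyads` must be at least 1.")
  k <- model$k
  roster <- tibble::tibble(
    dyad_id = sprintf("d%04d", seq_len(n_dyads)),
    patient_id = sprintf("pat%04d", seq_len(n_dyads)),
    proxy_id = sprintf("pro%04d", seq_len(n_dyads))
  )
  responses <- with_seed(seed, {
    parts <- lapply(item_ids, function(it) {
      pat <- sample.int(k, n_dyads, replace = TRUE,
                        prob = model$patient_marginal) - 1L
      u <- stats::runif(n_dyads)
      cum <- t(apply(model$transition, 1L, cumsum))
      pro <- vapply(seq_len(n_dyads), function(i) {
        sum(u[i] > cum[pat[i] + 1L, ]) # index of first cum >= u
      }, integer(1))
      tibble::tibble(
        respondent_id = c(roster$patient_id, roster$proxy_id),
        group = rep(c("patient", "proxy"), each = n_dyads),
        item_id = as.integer(it),
        score = c(pat, pro)
      )
    })
    dplyr::bind_rows(parts)
  })
  list(
    responses = responses,
    roster = roster,
    expected_kappa = c(identity = expected_kappa(model, "identity"),
                       linear = expected_kappa(model, "linear"),
                       quadratic = expected_kappa(model, "quadratic"))
  )
}

#' Instrument-linking generator model
#'
#' @param n_instruments Number of instruments.
#' @param items_range Inclusive range instrument sizes are drawn from.
#' @param aspect_count_probs Probabilities of an item having 1-4 aspects.
#' @param p_relevant Probability a non-flagged aspect links to a code owned by
#'   a relevant survey item.
#' @param p_flag Probability an aspect is flagged rather than linked.
#' @return A list model for [generate_instrument_linkings()].
#' @export
instrument_model <- function(n_instruments = 209L, items_range = c(5L, 30L),
                             aspect_count_probs = c(0.60, 0.25, 0.10, 0.05),
                             p_relevant = 0.6, p_flag = 0.1) {
  if (length(aspect_count_probs) != 4L || any(aspect_count_probs < 0) ||
        abs(sum(aspect_count_probs) - 1) > 1e-8) {
    abort_validation("aspect_count_probs must be 4 probabilities summing to 1.")
  }
  if (p_relevant < 0 || p_relevant > 1 || p_flag < 0 || p_flag > 1) {
    abort_validation("p_relevant and p_flag must lie in [0, 1].")
  }
  list(n_instruments = as.integer(n_instruments),
       items_range = as.integer(items_range),
       aspect_count_probs = aspect_count_probs,
       p_relevant = p_relevant, p_flag = p_flag)
}

# P(item relevant) under A/B/C for an item with k independent aspects, each
# relevant with probability r: exact binomial enumeration.
item_relevance_prob <- function(k, r, analysis) {
  probs <- stats::dbinom(0:k, k, r)
  x <- 0:k
  keep <- switch(analysis,
                 A = x >= 1L,
                 B = x / k >= 0.5,
                 C = x == k)
  sum(probs[keep])
}

#' Generate a synthetic instrument-linking table
#'
#' Each instrument receives a random number of items; each item 1-4 aspects.
#' An aspect is flagged with probability \code{p_flag}; otherwise it links to
#' a code owned by a relevant survey item with probability \code{p_relevant},
#' or to a non-relevant or survey-excluded code. Alongside the table, the
#' planted expected coverage of every instrument under analyses A, B and C is
#' computed by exact enumeration over the aspect-pattern distribution.
#'
#' @param model An [instrument_model()].
#' @param relevant_items Relevant survey item ids.
#' @param survey Survey-item table.
#' @param catalog Optional catalog supplying survey-excluded codes for
#'   non-relevant links.
#' @param seed Integer seed.
#' @return List with \code{linkings} (tibble: \code{instrument_id},
#'   \code{item_id}, \code{aspect_index}, \code{concept_text},
#'   \code{icf_code}, \code{flag}) and \code{expected} (tibble:
#'   \code{instrument_id}, \code{analysis}, \code{expected_coverage} in
#'   percent).
#' @export
generate_instrument_linkings <- function(model, relevant_items, survey,
                                         catalog = NULL, seed = NULL) {
  survey <- survey_items(survey)
  map <- code_to_item_map(survey)
  rel_codes <- names(map)[map %in% relevant_items]
  other_codes <- names(map)[!map %in% relevant_items]
  if (!is.null(catalog)) {
    catalog <- icf_catalog(catalog)
    other_codes <- union(other_codes, setdiff(catalog$code, names(map)))
  }
  if (length(rel_codes) == 0L && model$p_relevant > 0) {
    abort_validation("Relevant-link probability > 0 but the relevant pool is empty.")
  }
  if (length(other_codes) == 0L) other_codes <- rel_codes
  r_eff <- (1 - model$p_flag) * model$p_relevant

  with_seed(seed, {
    inst_ids <- sprintf("inst%03d", seq_len(model$n_instruments))
    n_items <- sample(model$items_range[1]:model$items_range[2],
                      model$n_instruments, replace = TRUE)
    rows <- vector("list", model$n_instruments)
    expected <- vector("list", model$n_instruments)
    for (i in seq_len(model$n_instruments)) {
      k_aspects <- sample(1:4, n_items[i], replace = TRUE,
                          prob = model$aspect_count_probs)
      total <- sum(k_aspects)
      is_flag <- stats::runif(total) < model$p_flag
      is_rel <- !is_flag & stats::runif(total) < model$p_relevant
      code <- rep(NA_character_, total)
      flag <- rep(NA_character_, total)
      flag[is_flag] <- sample(linking_flags(), sum(is_flag), replace = TRUE)
      code[is_rel] <- sample(rel_codes, sum(is_rel), replace = TRUE)
      n_other <- sum(!is_flag & !is_rel)
      code[!is_flag & !is_rel] <- sample(other_codes, n_other, replace = TRUE)
      rows[[i]] <- tibble::tibble(
        instrument_id = inst_ids[i],
        item_id = rep(seq_len(n_items[i]), k_aspects),
        aspect_index = unlist(lapply(k_aspects, seq_len)),
        concept_text = sprintf("concept %s", seq_len(total)),
        icf_code = code,
        flag = flag
      )
      expected[[i]] <- tibble::tibble(
        instrument_id = inst_ids[i],
        analysis = c("A", "B", "C"),
        expected_coverage = vapply(c("A", "B", "C"), function(a) {
          100 * mean(vapply(k_aspects, item_relevance_prob, numeric(1),
                            r = r_eff, analysis = a))
        }, numeric(1))
      )
    }
    list(linkings = dplyr::bind_rows(rows),
         expected = dplyr::bind_rows(expected))
  })
}

#' Generate a complete synthetic study
#'
#' One root seed drives every generator through deterministic stream
#' splitting: the ICF catalog and survey, planted response profiles,
#' long-format responses for the three rater groups, dyad responses with a
#' known expected kappa, and an instrument-linking table with planted expected
#' coverages. Default sizes mirror the study scale: 148 survey items, 114
#' patients / 71 proxies / 65 HCPs, 67 dyads, 209 instruments.
#'
#' @param seed Root integer seed.
#' @param group_sizes Respondents per rater group.
#' @param n_dyads Number of patient-proxy dyads.
#' @param dyad Optional [dyad_model()]; the default plants moderate agreement
#'   (kappa 0.5 on the dichotomized scale).
#' @param instruments An [instrument_model()].
#' @return Named list: \code{catalog}, \code{n_excluded_heading_child},
#'   \code{survey}, \code{profiles}, \code{planted_relevant},
#'   \code{responses}, \code{dyads} (see [generate_dyads()]),
#'   \code{linkings}, \code{expected_coverage}.
#' @export
simulate_study <- function(seed = 1L,
                           group_sizes = c(patient = 114, proxy = 71, hcp = 65),
                           n_dyads = 67L,
                           dyad = NULL,
                           instruments = instrument_model()) {
  seeds <- split_seed(seed, 4L)
  cat_gen <- simulate_icf_catalog()
  survey <- simulate_survey(cat_gen$catalog)
  prof <- simulate_response_profiles(survey$item_id, seed = seeds[1])
  responses <- generate_responses(prof$profiles, group_sizes, seed = seeds[2])
  if (is.null(dyad)) {
    dyad <- dyad_model(c(0.5, 0.5), matrix(c(0.75, 0.25, 0.25, 0.75), 2,
                                           byrow = TRUE))
  }
  dyads <- generate_dyads(dyad, n_dyads, item_ids = survey$item_id[1:5],
                          seed = seeds[3])
  link <- generate_instrument_linkings(instruments, prof$relevant_items,
                                       survey, catalog = cat_gen$catalog,
                                       seed = seeds[4])
  list(
    catalog = cat_gen$catalog,
    n_excluded_heading_child = cat_gen$n_excluded_heading_child,
    survey = survey,
    profiles = prof$profiles,
    planted_relevant = prof$relevant_items,
    responses = responses,
    dyads = dyads,
    linkings = link$linkings,
    expected_coverage = link$expected
  )
}
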