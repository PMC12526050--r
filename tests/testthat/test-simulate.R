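test_that("a fixed seed reproduces generated data byte-for-byte", {
  prof <- simulate_response_profiles(1:20, seed = 31L)
  prof2 <- simulate_response_profiles(1:20, seed = 31L)
  expect_identical(prof, prof2)
  r1 <- generate_responses(prof$profiles, c(patient = 30, proxy = 20, hcp = 10),
                           seed = 32L)
  r2 <- generate_responses(prof$profiles, c(patient = 30, proxy = 20, hcp = 10),
                           seed = 32L)
  expect_identical(r1, r2)
  r3 <- generate_responses(prof$profiles, c(patient = 30, proxy = 20, hcp = 10),
                           seed = 33L)
  expect_false(identical(r1$score, r3$score))
  # the caller's RNG stream is not consumed
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_responses(prof$profiles,
                                            c(patient = 5, proxy = 5, hcp = 5),
                                            seed = 99L))
  expect_identical(runif(1), before)
})

test_that("degenerate profiles behave as planted", {
  never <- tibble::tibble(item_id = 1L, group = "patient", p0 = 1, p1 = 0,
                          p2 = 0, p3 = 0, missing_rate = 0)
  resp <- generate_responses(never, c(patient = 50), seed = 3L)
  expect_true(all(resp$score == 0L))
  fr <- issue_fractions(resp)
  expect_equal(fr$fraction, 0)

  gone <- never
  gone$missing_rate <- 1
  resp2 <- generate_responses(gone, c(patient = 50), seed = 3L)
  expect_true(all(is.na(resp2$score)))
  expect_error(item_issue_fraction(resp2, 1L, "patient"),
               class = "covalid_no_available_cases")

  bad <- never
  bad$p0 <- 0.5
  expect_error(generate_responses(bad, c(patient = 5), seed = 1L),
               class = "covalid_validation_error")
})

test_that("empirical issue fractions land in the exact binomial 99% interval", {
  p <- 0.6
  n <- 114L
  prof <- tibble::tibble(item_id = 1L, group = "patient",
                         p0 = 1 - p, p1 = 0.5 * p, p2 = 0.3 * p, p3 = 0.2 * p,
                         missing_rate = 0)
  resp <- generate_responses(prof, c(patient = n), seed = 2024L)
  fr <- item_issue_fraction(resp, 1L, "patient")
  bounds <- qbinom(c(0.005, 0.995), n, p) / n
  expect_gte(fr$fraction, bounds[1])
  expect_lte(fr$fraction, bounds[2])
})

test_that("dyad models expose closed-form expected kappa", {
  ident <- dyad_model(c(0.3, 0.3, 0.2, 0.2), diag(4))
  expect_equal(expected_kappa(ident), 1)
  dy <- generate_dyads(ident, 50L, seed = 4L)
  tab <- crosstab_dyads(dy$responses, dy$roster, 1L, "raw")
  expect_equal(cohen_kappa(tab)$kappa, 1)

  marg <- c(0.1, 0.4, 0.3, 0.2)
  indep <- dyad_model(marg, matrix(rep(marg, 4), 4, byrow = TRUE))
  expect_equal(expected_kappa(indep), 0)
  expect_equal(expected_kappa(indep, "linear"), 0)

  # a stated 4x4 joint, expected kappa evaluated by the independent oracle
  joint <- matrix(c(0.10, 0.05, 0.02, 0.01,
                    0.04, 0.15, 0.05, 0.02,
                    0.02, 0.05, 0.20, 0.04,
                    0.01, 0.02, 0.04, 0.18), 4, byrow = TRUE)
  marginal <- rowSums(joint)
  model <- dyad_model(marginal, joint / marginal)
  for (scheme in c("identity", "linear", "quadratic")) {
    w <- weight_matrix(4, scheme)
    expect_equal(expected_kappa(model, scheme),
                 oracle_kappa(joint * 1e6, w), # oracle on scaled counts
                 tolerance = 1e-9)
  }

  expect_error(dyad_model(c(0.5, 0.5), matrix(c(0.9, 0.2, 0.2, 0.8), 2)),
               class = "covalid_validation_error")
})

test_that("planted linking probabilities yield the planted coverages", {
  survey <- tiny_survey()
  model_all <- instrument_model(n_instruments = 4L, items_range = c(3L, 6L),
                                p_relevant = 1, p_flag = 0)
  gen <- generate_instrument_linkings(model_all, 1L, survey, seed = 8L)
  for (a in c("A", "B", "C")) {
    cov <- coverage_table(gen$linkings, 1L, survey, a)
    expect_true(all(cov$coverage_percent == 100))
    expect_true(all(gen$expected$expected_coverage[gen$expected$analysis == a] == 100))
  }

  model_none <- instrument_model(n_instruments = 4L, items_range = c(3L, 6L),
                                 p_relevant = 0, p_flag = 0.2)
  gen0 <- generate_instrument_linkings(model_none, 1L, survey, seed = 9L)
  for (a in c("A", "B", "C")) {
    cov <- coverage_table(gen0$linkings, 1L, survey, a)
    expect_true(all(cov$coverage_percent == 0))
  }

  expect_error(
    generate_instrument_linkings(instrument_model(p_relevant = 0.5),
                                 integer(), survey, seed = 1L),
    class = "covalid_validation_error"
  )
})

test_that("two-aspect items with exactly one relevant aspect split A/B from C", {
  survey <- tiny_survey()
  linkings <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(instrument_id = "fixed", item_id = i, aspect_index = 1:2,
                   concept_text = "c", icf_code = c("b110", "d450"),
                   flag = NA_character_)
  }))
  expect_equal(instrument_coverage(linkings, 1L, survey, "A")$coverage_percent, 100)
  expect_equal(instrument_coverage(linkings, 1L, survey, "B")$coverage_percent, 100)
  expect_equal(instrument_coverage(linkings, 1L, survey, "C")$coverage_percent, 0)
})

test_that("expected-coverage enumeration matches brute-force pattern sums", {
  for (k in 1:4) {
    for (r in c(0, 0.3, 0.5, 1)) {
      patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))
      p_pattern <- apply(patterns, 1, function(fl) prod(ifelse(fl, r, 1 - r)))
      for (a in c("A", "B", "C")) {
        brute <- sum(p_pattern * apply(patterns, 1, oracle_item_rule, analysis = a))
        expect_equal(covalid:::item_relevance_prob(k, r, a), brute,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the full synthetic study recovers its planted structure", {
  s <- simulate_study(seed = 123L)
  expect_equal(nrow(s$survey), 148L)
  rel <- relevance_table(s$responses)
  recovered <- sort(unique(rel$item_id[rel$relevant]))
  expect_identical(recovered, s$planted_relevant)

  tab <- crosstab_dyads(s$dyads$responses, s$dyads$roster, 1L, "raw")
  expect_s3_class(tab, "agreement_table")
  expect_equal(unname(s$dyads$expected_kappa["identity"]), 0.5)

  cov <- coverage_table(s$linkings, s$planted_relevant, s$survey, "A")
  expect_equal(nrow(cov), 209L)
  expect_true(all(cov$band %in% names(coverage_bands())))
})
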