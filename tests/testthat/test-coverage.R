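# tiny_survey(): item 1 owns {b110, b114}, item 2 owns {d450}; e310 excluded.
rel_set <- 1L # item 1 relevant, item 2 not

aspect_row <- function(code = NA_character_, flag = NA_character_) {
  tibble::tibble(icf_code = code, flag = flag)
}

test_that("aspect relevance requires a code owned by a relevant survey item", {
  survey <- tiny_survey()
  expect_true(aspect_relevance(aspect_row("b110"), rel_set, survey))
  expect_false(aspect_relevance(aspect_row("d450"), rel_set, survey)) # not relevant
  expect_false(aspect_relevance(aspect_row("e310"), rel_set, survey)) # excluded
  for (fl in linking_flags()) {
    expect_false(aspect_relevance(aspect_row(flag = fl), rel_set, survey))
  }
  expect_error(aspect_relevance(aspect_row("b110", "not_covered"), rel_set, survey),
               class = "covalid_validation_error")
  expect_error(aspect_relevance(aspect_row(), rel_set, survey),
               class = "covalid_validation_error")
  expect_error(aspect_relevance(aspect_row("404"), rel_set, survey),
               class = "covalid_validation_error")
})

test_that("analyses A, B and C grade items of mixed aspects as specified", {
  survey <- tiny_survey()
  # two aspects, one relevant (falling asleep vs watching TV style)
  two <- dplyr::bind_rows(aspect_row("b110"), aspect_row("d450"))
  expect_true(item_relevance(two, rel_set, survey, "A"))
  expect_true(item_relevance(two, rel_set, survey, "B")) # 1/2 = 50%, inclusive
  expect_false(item_relevance(two, rel_set, survey, "C"))
  # single relevant aspect satisfies all three rules
  one <- aspect_row("b114")
  for (a in c("A", "B", "C")) expect_true(item_relevance(one, rel_set, survey, a))
  # three aspects, one relevant: only A
  three <- dplyr::bind_rows(aspect_row("b110"), aspect_row("d450"),
                            aspect_row(flag = "not_definable"))
  expect_true(item_relevance(three, rel_set, survey, "A"))
  expect_false(item_relevance(three, rel_set, survey, "B"))
  expect_false(item_relevance(three, rel_set, survey, "C"))
  expect_error(item_relevance(two[0, ], rel_set, survey, "A"),
               class = "covalid_validation_error")
})

test_that("A/B/C relevance matches exhaustive rule evaluation on small items", {
  survey <- tiny_survey()
  for (k in 1:3) {
    patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))
    for (p in seq_len(nrow(patterns))) {
      flags <- unlist(patterns[p, ])
      aspects <- tibble::tibble(
        icf_code = ifelse(flags, "b110", "d450"),
        flag = NA_character_
      )
      # b110 is owned by the relevant item; d450 is not
      for (a in c("A", "B", "C")) {
        expect_identical(item_relevance(aspects, rel_set, survey, a),
                         oracle_item_rule(flags, a),
                         info = sprintf("k=%d pattern=%d analysis=%s", k, p, a))
      }
    }
  }
})

instrument_rows <- function(id, item_codes) {
  dplyr::bind_rows(lapply(seq_along(item_codes), function(i) {
    tibble::tibble(instrument_id = id, item_id = i,
                   aspect_index = seq_along(item_codes[[i]]),
                   concept_text = "c", icf_code = item_codes[[i]],
                   flag = NA_character_)
  }))
}

test_that("instrument coverage percentages and bands follow the band edges", {
  survey <- tiny_survey()
  # 14 single-aspect items, all linked to the relevant item's codes
  all_rel <- instrument_rows("hads", rep(list("b110"), 14))
  res <- instrument_coverage(all_rel, rel_set, survey, "A")
  expect_equal(res$coverage_percent, 100)
  expect_equal(res$band, "sufficient")

  mixed <- instrument_rows("q", c(rep(list("b110"), 6), rep(list("d450"), 4)))
  res6 <- instrument_coverage(mixed, rel_set, survey, "A")
  expect_equal(res6$coverage_percent, 60)
  expect_equal(res6$band, "moderate")

  low <- instrument_rows("q2", c(rep(list("b110"), 4), rep(list("d450"), 6)))
  res4 <- instrument_coverage(low, rel_set, survey, "A")
  expect_equal(res4$coverage_percent, 40)
  expect_equal(res4$band, "low")

  expect_error(instrument_coverage(mixed[0, ], rel_set, survey, "A"),
               class = "covalid_validation_error")
})

test_that("band distributions count every instrument exactly once", {
  survey <- tiny_survey()
  results <- dplyr::bind_rows(
    instrument_coverage(instrument_rows("i1", rep(list("b110"), 5)),
                        rel_set, survey, "A"),
    instrument_coverage(instrument_rows("i2", c(rep(list("b110"), 6),
                                                rep(list("d450"), 4))),
                        rel_set, survey, "A"),
    instrument_coverage(instrument_rows("i3", c(rep(list("b110"), 4),
                                                rep(list("d450"), 6))),
                        rel_set, survey, "A")
  )
  agg <- aggregate_coverage(results)
  expect_equal(agg$count[agg$band == "sufficient"], 1L)
  expect_equal(agg$count[agg$band == "moderate"], 1L)
  expect_equal(agg$count[agg$band == "low"], 1L)
  expect_equal(sum(agg$count), 3L)
  expect_equal(sum(agg$percent), 100, tolerance = 0.2)

  expect_error(aggregate_coverage(rbind(results, results[1, ])),
               class = "covalid_duplicate_key")
  mixed <- results
  mixed$analysis[2] <- "B"
  expect_error(aggregate_coverage(mixed), class = "covalid_validation_error")
  expect_error(aggregate_coverage(results[0, ]),
               class = "covalid_validation_error")
})

test_that("adding an all-flag item never increases coverage", {
  survey <- tiny_survey()
  base <- instrument_rows("q", c(rep(list("b110"), 3), rep(list("d450"), 2)))
  extra <- tibble::tibble(instrument_id = "q", item_id = 6L, aspect_index = 1:2,
                          concept_text = "c", icf_code = NA_character_,
                          flag = c("not_covered", "personal_factor"))
  for (a in c("A", "B", "C")) {
    before <- instrument_coverage(base, rel_set, survey, a)$coverage_percent
    after <- instrument_coverage(rbind(base, extra), rel_set, survey,
                                 a)$coverage_percent
    expect_lte(after, before)
  }
})

test_that("linking validation reports malformed rows without failing", {
  clean <- instrument_rows("ok", list("b110", "d450"))
  expect_equal(nrow(validate_linking(clean, tiny_catalog())), 0L)

  bad <- clean
  bad$flag[1] <- "not_covered"            # both code and flag
  bad$icf_code[2] <- "zzz9"               # not in catalog
  report <- validate_linking(bad, tiny_catalog())
  expect_setequal(report$problem,
                  c("both icf_code and flag present", "icf_code absent from catalog"))

  neither <- clean
  neither$icf_code[1] <- NA_character_
  report2 <- validate_linking(neither)
  expect_equal(report2$problem, "neither icf_code nor flag present")

  unknown <- clean
  unknown$icf_code[1] <- NA_character_
  unknown$flag[1] <- "mystery"
  expect_true(any(validate_linking(unknown)$problem == "unknown flag"))
})
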