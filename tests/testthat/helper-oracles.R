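# Independent brute-force oracles and tiny fixtures built in code.

# Direct loop evaluation of the (weighted) kappa formula, independent of the
# matrix algebra in cohen_kappa().
oracle_kappa <- function(tab, w = diag(nrow(tab))) {
  n <- sum(tab)
  k <- nrow(tab)
  p_o <- 0
  p_e <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      p_o <- p_o + w[i, j] * tab[i, j] / n
      p_e <- p_e + w[i, j] * sum(tab[i, ]) * sum(tab[, j]) / n^2
    }
  }
  if (p_e >= 1 - 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

# Classic null variance of unweighted kappa (Fleiss, Cohen & Everitt), used to
# confirm the weighted formula reduces correctly under identity weights.
oracle_se0_unweighted <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  r <- rowSums(p)
  c_ <- colSums(p)
  p_e <- sum(r * c_)
  var0 <- (p_e + p_e^2 - sum(r * c_ * (r + c_))) / (n * (1 - p_e)^2)
  sqrt(var0)
}

# Literal reading of the three item-relevance rules on a vector of per-aspect
# relevance flags.
oracle_item_rule <- function(flags, analysis) {
  switch(analysis,
         A = any(flags),
         B = mean(flags) >= 0.5,
         C = all(flags))
}

# Two-item survey: item 1 (relevant in tests) owns codes b110 and b114,
# item 2 owns d450. Code e310 exists in the catalog but not in the survey.
tiny_survey <- function() {
  survey_items(tibble::tibble(
    item_id = 1:2,
    text = c("combined item", "standalone item"),
    icf_codes = list(c("b110", "b114"), "d450")
  ))
}

tiny_catalog <- function() {
  icf_catalog(tibble::tibble(
    code = c("b110", "b114", "d450", "e310"),
    label = c("a", "b", "c", "d"),
    disposition = c("combined", "combined", "standalone", "not_specific"),
    combine_group_id = c("g1", "g1", NA, NA)
  ))
}

random_agreement_table <- function(k = 4) {
  matrix(rpois(k * k, lambda = 5) + (diag(k) * sample(0:8, k, TRUE)), k, k)
}
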