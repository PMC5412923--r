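# Random trial histories on the default grid, for property-style tests.
# Doses are drawn from the full grid, periods assigned 1 for the first
# `n1` records and 2 after, responses Bernoulli(0.5) unless given.
random_history <- function(n = 12, n1 = min(8, n), p = 0.5,
                           grid = dose_grid()) {
  doses <- sample(grid$actual_mg, n, replace = TRUE)
  trial_history(seq_len(n),
                rep(c(1L, 2L), c(n1, n - n1)),
                doses,
                stats::rbinom(n, 1, p))
}

# Independent reference for the rule-based criterion: linear scan over the
# administered doses, lowest dose whose suffix (itself and every higher
# administered dose) is failure-free.
rule_select_brute_force <- function(history) {
  h <- history[history$period <= 2, ]
  for (D in sort(unique(h$dose_mg)))
    if (all(h$y[h$dose_mg >= D] == 0)) return(D)
  NA_real_
}
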