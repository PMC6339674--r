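# shared fixtures, all built in code

# small deterministic bank with hand-picked parameters
toy_bank <- function() {
  item_bank(
    item_id = c("tb1", "tb2", "tb3", "tb4"),
    slope = c(2.0, 3.0, 2.5, 3.5),
    thresholds = list(
      c(-1.0, 0.0, 1.0, 2.0),
      c(-2.0, -1.0, 0.0, 1.0),
      c(-1.5, -0.5, 0.5, 1.5),
      c(-0.5, 0.0, 0.5, 1.0)
    )
  )
}

# participation-bank-like simulated cohort
ability_like_sim <- function(n_persons = 1000, n_items = 35, seed = 11,
                             ...) {
  d <- simulation_design(n_persons = n_persons, n_items = n_items,
                         seed = seed, ...)
  bank <- sample_bank(d)
  sim <- simulate_responses(bank, d)
  list(design = d, bank = bank, rm = sim$rm, theta = sim$theta, sim = sim)
}

# response matrix from explicit integer rows
rm_from_rows <- function(rows, n_categories = 5L) {
  response_matrix(do.call(rbind, rows), n_categories = n_categories)
}
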