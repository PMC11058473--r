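test_that("one-ribosome master equation equals the analytic cascade exactly", {
  for (seed in c(3, 11, 23, 31, 47)) {
    toy <- random_leader(list(n_uorfs = seed %% 2, uorf_codons = 2,
                              spacing = 15, leader_pad = 15,
                              cds_codons = 6), seed = seed)
    p <- fast_params(k_load = 0.01)
    an <- analytic_small_model(toy, p, condition = "stress")
    mk <- markov_oracle(toy, p, condition = "stress", max_ribosomes = 1)
    expect_equal(unname(mk$initiation), unname(an$initiation),
                 tolerance = 1e-10)
  }
})

test_that("cascade handles stalls: stall-release and window initiation terms", {
  toy <- random_leader(list(n_uorfs = 0, spacing = 10, leader_pad = 20,
                            cds_codons = 12,
                            hairpin = list(stall_to_start = 24, stem = 8,
                                           loop = 5)), seed = 8)
  p <- fast_params(k_load = 0.01)
  an <- analytic_small_model(toy, p)
  mk <- markov_oracle(toy, p, max_ribosomes = 1)
  expect_equal(unname(mk$initiation), unname(an$initiation),
               tolerance = 1e-10)
  expect_true(sum(an$initiation) > 0)
})

test_that("single-site leader: fraction p initiates, 1-p scans off", {
  bare <- toy_bare_leader()
  p <- fast_params(p_tc_load = 1,
                   p_init = list(aug_strong = 0.4, aug_medium = 0.4,
                                 aug_weak = 0.4, nc_strong = 0,
                                 nc_medium = 0, nc_weak = 0, cug_weak = 0))
  an <- analytic_small_model(bare, p)
  cds <- as.character(bare$cds_start)
  expect_equal(unname(an$initiation[cds]), 0.4, tolerance = 1e-9)
  expect_equal(an$scanned_off, 0.6, tolerance = 1e-9)
})

test_that("simulator in no-exclusion mode matches the analytic cascade", {
  toy <- toy_uorf_leader()
  p <- fast_params(k_load = 0.05)
  an <- analytic_small_model(toy, p, condition = "stress")
  pool <- pooled_fractions(toy, p, seeds = 1:8, t_max = 3000,
                          condition = "stress", no_exclusion = TRUE)
  keep <- an$initiation > 0.01
  se <- sqrt(an$initiation * (1 - an$initiation) / pool$loads)
  z <- (pool$frac[keep] - an$initiation[keep]) / se[keep]
  expect_true(all(abs(z) < 3))
})

test_that("simulator with exclusion matches the two-ribosome master equation", {
  toy <- toy_uorf_leader()
  p <- fast_params(k_load = 0.05)
  mk <- markov_oracle(toy, p, condition = "stress", max_ribosomes = 2)
  expect_gt(mk$n_states, 100)
  pool <- pooled_fractions(toy, p, seeds = 101:108, t_max = 3000,
                          condition = "stress")
  keep <- mk$initiation > 0.01
  se <- sqrt(mk$initiation * (1 - mk$initiation) / pool$loads)
  z <- (pool$frac[keep] - mk$initiation[keep]) / se[keep]
  expect_true(all(abs(z) < 3))
})

test_that("blocking can only remove downstream initiation flux", {
  # two-ribosome exclusion vs independent ribosomes, with a stall element
  toy <- random_leader(list(n_uorfs = 0, spacing = 10, leader_pad = 18,
                            cds_codons = 10,
                            hairpin = list(stall_to_start = 21, stem = 8,
                                           loop = 5)), seed = 8)
  p <- fast_params(k_load = 0.15, p_tc_load = 1, queue_boost = 0)
  mk1 <- analytic_small_model(toy, p)
  mk2 <- markov_oracle(toy, p, max_ribosomes = 2)
  cds <- as.character(toy$cds_start)
  expect_lte(mk2$initiation[cds], mk1$initiation[cds] + 1e-9)
})

test_that("infinitely fast stall release converges to the no-stall solution", {
  toy <- random_leader(list(n_uorfs = 0, spacing = 10, leader_pad = 18,
                            cds_codons = 10,
                            hairpin = list(stall_to_start = 30, stem = 8,
                                           loop = 5)), seed = 12)
  p_fast <- fast_params(k0_unwind = 1e9, p_tc_load = 1, queue_boost = 1)
  an <- analytic_small_model(toy, p_fast)
  # same leader with the hairpin ignored entirely
  p_nostall <- fast_params(sl_stall_cutoff = -1e9, p_tc_load = 1)
  p_nostall$k0_unwind <- 1
  class(p_nostall) <- "sim_params"
  toy2 <- toy
  toy2$elements$hairpins <- toy$elements$hairpins[0, , drop = FALSE]
  an2 <- analytic_small_model(toy2, fast_params(p_tc_load = 1, queue_boost = 1))
  # residual difference is the vanishing migration-window contribution
  expect_equal(unname(an$initiation), unname(an2$initiation),
               tolerance = 1e-3)
})
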