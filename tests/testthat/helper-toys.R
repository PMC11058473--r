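# Shared fixtures built in code: small toy leaders and fast parameter sets.

# uORF + main ORF toy leader, ~75 nt; deterministic.
toy_uorf_leader <- function(seed = 3) {
  random_leader(list(n_uorfs = 1, uorf_codons = 2, spacing = 20,
                     leader_pad = 15, cds_codons = 8), seed = seed)
}

# leader with no uORF and no hairpin
toy_bare_leader <- function(seed = 11) {
  random_leader(list(n_uorfs = 0, spacing = 10, leader_pad = 30,
                     cds_codons = 10), seed = seed)
}

# fast parameters for engine tests
fast_params <- function(...) {
  args <- modifyList(list(k_load = 0.05, v_scan = 5, v_elong = 5,
                          queue_boost = 5), list(...))
  do.call(sim_params, args)
}

# pooled initiation fractions over replicate runs
pooled_fractions <- function(leader, params, seeds, t_max = 2000, ...) {
  sims <- lapply(seeds, function(s)
    simulate_leader(leader, params, t_max = t_max, seed = s, ...))
  loads <- sum(vapply(sims, `[[`, 0, "loads"))
  ic <- Reduce(`+`, lapply(sims, `[[`, "initiation_counts"))
  list(frac = ic / loads, loads = loads, sims = sims)
}
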