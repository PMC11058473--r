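test_that("zero loading rate produces zero activity", {
  toy <- toy_uorf_leader()
  r <- simulate_leader(toy, fast_params(k_load = 0), t_max = 100, seed = 1)
  expect_equal(r$loads, 0)
  expect_equal(sum(r$initiation_counts), 0)
  expect_equal(atf4_output(r), 0)
})

test_that("event accounting identity holds exactly", {
  ref <- build_reference_leader()
  for (seed in 1:5) {
    r <- simulate_leader(ref, sim_params(), t_max = 800, seed = seed,
                         condition = sample(c("nonstress", "stress"), 1))
    expect_equal(r$loads,
                 r$scanned_off + r$recycled + r$runoff + r$alive_end)
  }
})

test_that("identical seeds give identical runs; different seeds differ", {
  ref <- build_reference_leader()
  a <- simulate_leader(ref, sim_params(), t_max = 500, seed = 99,
                       keep_log = TRUE)
  b <- simulate_leader(ref, sim_params(), t_max = 500, seed = 99,
                       keep_log = TRUE)
  expect_identical(a$event_log, b$event_log)
  expect_identical(a$initiation_counts, b$initiation_counts)
  c <- simulate_leader(ref, sim_params(), t_max = 500, seed = 100,
                       keep_log = TRUE)
  expect_false(identical(a$event_log, c$event_log))
})

test_that("a loss-free single-AUG leader converts almost all loads to protein", {
  bare <- toy_bare_leader()
  p <- fast_params(p_init = list(aug_strong = 0.999, aug_medium = 0.999,
                                 aug_weak = 0.999, nc_strong = 0,
                                 nc_medium = 0, nc_weak = 0, cug_weak = 0),
                   p_tc_load = 1)
  r <- simulate_leader(bare, p, t_max = 4000, seed = 2)
  expect_gt(r$loads, 50)
  done <- atf4_output(r)
  expect_gt(done / (r$loads - r$alive_end), 0.95)
  expect_equal(r$scanned_off, 0)
})

test_that("footprints never overlap in snapshots (steric exclusion)", {
  ref <- build_reference_leader()
  r <- simulate_leader(ref, sim_params(), t_max = 1000, seed = 17,
                       condition = "stress", dt_snap = 4)
  snap <- r$snapshots
  spec <- r$spec
  for (sid in unique(snap$snapshot)) {
    rows <- snap[snap$snapshot == sid, , drop = FALSE]
    if (nrow(rows) < 2) next
    iv <- t(vapply(seq_len(nrow(rows)), function(i)
      riboqueue:::record_footprint(rows$species[i], rows$psite[i], spec),
      c(0, 0)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    expect_true(all(iv[-1, 1] > iv[-nrow(iv), 2]))
  }
})

test_that("queue bound: never more than five 80S between uORF2 AUG and SL3", {
  ref <- build_reference_leader()
  p <- default_calibrated_params()$params
  p$dG_scale <- 3.0  # deepen the stall to enforce persistent queuing
  class(p) <- "sim_params"
  r <- simulate_leader(ref, p, t_max = 2000, seed = 5, dt_snap = 5)
  snap <- r$snapshots
  q <- vapply(split(snap$psite[snap$species == 2],
                    snap$snapshot[snap$species == 2]),
              function(x) sum(x >= 165 & x <= 315), 0)
  expect_lte(max(q), queue_capacity(165, 315, 30)$capacity)
  expect_gte(max(q), 4)  # queuing actually happens
  # adjacent queued 80S P-sites sit exactly one footprint apart
  full <- names(q)[q >= 4]
  gaps <- unlist(lapply(full, function(sid) {
    ps <- sort(snap$psite[snap$snapshot == as.integer(sid) &
                            snap$species == 2 & snap$psite >= 165 &
                            snap$psite <= 315])
    diff(ps)
  }))
  expect_true(any(gaps == 30))
  expect_true(all(gaps >= 30))
})

test_that("main-ORF output declines with TC level on a uORF1-style toy leader", {
  # delayed reinitiation: with only a REI-permissive uORF upstream, low TC
  # shifts initiation downstream past the main AUG, reducing output
  toy <- toy_uorf_leader()
  p <- fast_params(k_load = 0.1, k_tc = 0.25)
  outs <- vapply(c(0.05, 0.3, 1), function(tc) {
    mean(vapply(1:6, function(s)
      atf4_output(simulate_leader(toy, p, t_max = 2500, seed = 400 + s,
                                  tc_level = tc)), 0))
  }, 0)
  expect_gt(outs[3], outs[1])
})

test_that("with uORF2 present ATF4 output is higher at stress TC levels", {
  ref <- build_reference_leader()
  p <- default_calibrated_params()$params
  lo <- mean(vapply(1:6, function(s)
    atf4_output(simulate_leader(ref, p, t_max = 1500, seed = 500 + s,
                                condition = "stress")), 0))
  hi <- mean(vapply(1:6, function(s)
    atf4_output(simulate_leader(ref, p, t_max = 1500, seed = 600 + s,
                                condition = "nonstress")), 0))
  expect_gt(lo, hi)
})
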