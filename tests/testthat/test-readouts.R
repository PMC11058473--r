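ref <- build_reference_leader()
calib <- default_calibrated_params()$params

# one deeply-queued ensemble shared across readout tests
queued_params <- local({
  p <- calib
  p$dG_scale <- 3.0
  class(p) <- "sim_params"
  p
})
queued_run <- simulate_leader(ref, queued_params, t_max = 2000, seed = 5,
                              dt_snap = 8)

test_that("protein output table labels size classes by origin", {
  r <- simulate_leader(ref, calib, t_max = 1200, seed = 3,
                       condition = "stress")
  tab <- protein_outputs(r)
  expect_true(all(c("full", "uORF") %in%
                    tab$size_class[tab$count > 0 | tab$initiations > 0]))
  expect_equal(tab$size_class[tab$origin == 283][1], "full")
  expect_equal(tab$size_class[tab$origin == 165][1], "uORF")
  # zero-rate run produces all zeros
  r0 <- simulate_leader(ref, fast_params(k_load = 0), t_max = 50, seed = 1)
  expect_equal(sum(protein_outputs(r0)$count), 0)
})

test_that("fold change of an ensemble against itself is 1 with a covering CI", {
  x <- c(5, 7, 6, 8, 5, 7)
  fc <- fold_change(x, x, n_boot = 500)
  expect_equal(fc$estimate, 1)
  expect_true(fc$ci[1] <= 1 && fc$ci[2] >= 1)
  fc0 <- suppressWarnings(fold_change(x, rep(0, 6)))
  expect_true(fc0$infinite)
})

test_that("footprint profile: stalled PICs pile up with P sites on the CUG", {
  fp <- footprint_profile(queued_run)
  expect_equal(dim(fp$coverage), c(3, nchar(ref$sequence)))
  # without a uORF2-fed 80S queue (d-all), scanning PICs stall at SL3
  # with their P site 20 nt upstream, i.e. on the CUG
  dall <- apply_construct(ref, "d-all")
  pd <- calib; pd$dG_scale <- 3.2; class(pd) <- "sim_params"
  rs <- simulate_leader(dall, pd, t_max = 1500, seed = 44,
                        condition = "stress", dt_snap = 5)
  fps <- footprint_profile(rs)
  pic_ps <- fps$psite_hist[1, ] + fps$psite_hist[2, ]
  region <- 270:314
  expect_equal(region[which.max(pic_ps[region])], 295)
  # empty result gives zero arrays
  r0 <- simulate_leader(ref, fast_params(k_load = 0), t_max = 50, seed = 1)
  expect_equal(sum(footprint_profile(r0)$coverage), 0)
})

test_that("disome calling: pairs, fragment spacing and modal 60-nt separation", {
  dp <- disome_profile(queued_run, region = c(150, 330))
  expect_gt(dp$n_adjacent_pairs, 10)
  expect_equal(dp$modal_spacing, 60L)
  # three stacked 80S yield two adjacent-pair calls but one fragment
  fake <- queued_run
  fake$snapshots <- data.frame(snapshot = 1L, species = 2L,
                               psite = c(200L, 230L, 260L),
                               origin = 165L)
  dp3 <- disome_profile(fake)
  expect_equal(dp3$n_adjacent_pairs, 2L)
  expect_equal(sum(dp3$fragment_5p_hist), 1)
  # single-ribosome snapshots: empty histogram
  fake$snapshots <- data.frame(snapshot = 1L, species = 2L, psite = 200L,
                               origin = 165L)
  expect_equal(sum(disome_profile(fake)$fragment_5p_hist), 0)
})

test_that("frame distribution reflects origins in the overlap region", {
  fake <- queued_run
  fake$snapshots <- data.frame(snapshot = rep(1:4, each = 2), species = 2L,
                               psite = rep(c(200L, 250L), 4),
                               origin = 165L)
  fr <- frame_distribution(fake, c(165, 315))
  expect_equal(unname(fr[["-1"]]), 1)  # uORF2 frame only
  expect_equal(sum(fr), 1)
  fake$snapshots$origin <- 283L
  fake$snapshots$psite <- rep(c(300L, 330L), 4)
  fr2 <- frame_distribution(fake, c(283, 400))
  expect_equal(unname(fr2[["0"]]), 1)
  # zero coverage is flagged undefined
  fr3 <- frame_distribution(fake, c(1, 50))
  expect_true(attr(fr3, "undefined"))
})

test_that("protection assay: coverage rule, modes and orderings", {
  amp <- reference_amplicons()
  expect_equal(amp$length, rep(132L, 3))
  expect_equal(amp$start[amp$name == "A1"], 165L)
  # no ribosomes: survival zero everywhere
  r0 <- simulate_leader(ref, fast_params(k_load = 0), t_max = 200, seed = 1)
  pa0 <- protection_assay(r0, mode = "HCHO")
  expect_true(all(pa0$survival == 0))
  # a fully packed queue protects A1 completely
  fake <- r0
  fake$snapshots <- data.frame(snapshot = 1L, species = 2L,
                               psite = c(177L, 207L, 237L, 267L, 297L),
                               origin = 165L)
  fake$n_snapshots <- 1L
  pa1 <- protection_assay(fake, mode = "CHX", chx_retention = 1)
  expect_equal(unname(pa1$survival["A1"]), 1)
  # HCHO survival >= CHX survival on identical ensembles
  for (run in list(queued_run)) {
    h <- protection_assay(run, mode = "HCHO")
    cx <- protection_assay(run, mode = "CHX")
    expect_true(all(h$survival >= cx$survival))
  }
  expect_error(protection_assay(queued_run,
                                data.frame(name = "X", start = 1,
                                           end = 10000, length = 10000)),
               "outside")
})

test_that("protection enrichment decreases as the stall releases faster", {
  enr <- vapply(c(2.6, 8), function(sc) {
    p <- calib; p$dG_scale <- sc; class(p) <- "sim_params"
    runs <- lapply(1:4, function(s)
      simulate_leader(ref, p, t_max = 2000, seed = 700 + s, dt_snap = 8))
    protection_assay(runs, mode = "HCHO")$enrichment[["A1/A2"]]
  }, 0)
  expect_gt(enr[1], enr[2])
})
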