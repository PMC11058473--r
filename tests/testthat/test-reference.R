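ref <- build_reference_leader()

test_that("reference leader satisfies the published architecture", {
  m <- ref$manifest
  expect_true(m$stst_present)
  expect_equal(m$uORF1_n_codons, 3L)
  expect_equal(m$uORF2_n_codons, 60L)
  expect_equal(m$uORF2_frame_vs_cds, -1L)
  expect_equal(m$uORF2_AUG_to_SL3_nt, 150L)
  expect_equal(m$CUG_to_SL3_nt, 20L)
  expect_equal(m$AUG3_codon_index, 17L)
  expect_lte(m$SL3_delta_G, -14)
  expect_equal(m$queue_capacity_30nt, 5L)
  st <- ref$elements$starts
  ctx <- function(p) st$context[match(p, st$pos)]
  expect_equal(ctx(283), "medium")   # AUG1
  expect_equal(ctx(289), "medium")   # AUG2
  expect_equal(ctx(331), "weak")     # AUG3
  expect_equal(ctx(295), "weak")     # CUG
})

test_that("SL3 free energy approximates the reported stability", {
  expect_equal(ref$manifest$SL3_delta_G, -15.40, tolerance = 2 / 15.4)
})

test_that("AUG3 is exposed in the SL3 loop; A326 analog sits in the stem", {
  hp <- ref$elements$hairpins
  sl <- hp[hp$five_prime_base == 315, ]
  expect_equal(nrow(sl), 1)
  expect_true(sl$loop_start <= 331 && sl$loop_end >= 333)
  me <- ref$elements$methyl
  expect_true(me$in_stem[me$pos == 326])
  expect_false(isTRUE(me$in_stem[me$pos == 235]))
})

test_that("designed m6A sites are present and controls are motif-free", {
  me <- ref$elements$methyl
  expect_true(all(c(225, 235, 286, 326) %in% me$pos))
  expect_false(any(c(267, 311) %in% me$pos))
  expect_equal(substr(ref$sequence, 267, 267), "A")
  expect_equal(substr(ref$sequence, 311, 311), "A")
  # activation flags: the A235 roadblock is non-stress specific, the
  # in-stem A326 site is constitutive
  expect_true(me$modified_nonstress[me$pos == 235])
  expect_false(me$modified_stress[me$pos == 235])
  expect_true(me$modified_stress[me$pos == 326])
})

test_that("re-annotating the reference sequence reproduces the element set", {
  again <- annotate_leader(ref$sequence, ref$cds_start)
  expect_equal(again$elements$orfs, ref$elements$orfs)
  expect_equal(again$elements$starts, ref$elements$starts)
  expect_equal(again$elements$hairpins, ref$elements$hairpins,
               ignore_attr = TRUE)
  expect_equal(again$elements$methyl$pos, ref$elements$methyl$pos)
  expect_equal(again$elements$fs, ref$elements$fs)
})

test_that("FASTA round-trip preserves the annotation", {
  fa <- tempfile(fileext = ".fa")
  write_leader_fasta(ref, fa)
  back <- load_leader_fasta(fa, ref$cds_start)
  expect_equal(back$sequence, ref$sequence)
  expect_equal(back$elements$orfs, ref$elements$orfs)
})

test_that("FASTA loader rejects malformed input", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a", "AUGGGG", ">b", "AUGCCC"), fa)
  expect_error(load_leader_fasta(fa, 1), "multi-record")
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGUXXACGU"), fa2)
  expect_error(load_leader_fasta(fa2, 1), "non-ACGTU")
  fa3 <- tempfile(fileext = ".fa")
  writeLines(c(">a", "CCCAUGCCC"), fa3)
  expect_error(load_leader_fasta(fa3, 1), "CCC")
})

test_that("random leaders are deterministic and respect their architecture", {
  a <- random_leader(list(n_uorfs = 0, spacing = 10, leader_pad = 25,
                          cds_codons = 10), seed = 1)
  expect_equal(nrow(a$elements$orfs), 0)
  b <- random_leader(list(n_uorfs = 0, spacing = 10, leader_pad = 25,
                          cds_codons = 10), seed = 1)
  expect_identical(a$sequence, b$sequence)
})

test_that("random leaders always pass annotation invariants", {
  for (seed in seq_len(200)) {
    spec <- list(n_uorfs = 1 + seed %% 3,
                 uorf_codons = c(0, 6), spacing = c(15, 50),
                 leader_pad = c(15, 40), cds_codons = 12)
    ld <- random_leader(spec, seed = seed)
    expect_true(validate_leader(ld))
    expect_equal(nrow(leader_uorfs(ld)), spec$n_uorfs)
  }
})

test_that("stall-to-start spacing of k*30 nt yields queue capacity k", {
  for (k in 1:5) {
    ld <- random_leader(list(n_uorfs = 1, uorf_codons = 2, spacing = 200,
                             leader_pad = 20, cds_codons = 10,
                             hairpin = list(stall_to_start = k * 30,
                                            stem = 8, loop = 5)),
                        seed = 40 + k)
    u <- leader_uorfs(ld)
    expect_equal(queue_capacity(u$start[1], u$start[1] + k * 30, 30)$capacity, k)
  }
})
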