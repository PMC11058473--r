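ref <- build_reference_leader()

test_that("registry lists the construct series", {
  reg <- construct_registry()
  expect_true(all(c("dSt-st", "d1", "d2", "d-all", "St-st-only",
                    "uORF1-only", "uORF2-only", "SL3Mut-1", "SL3Mut-2",
                    "CUGMut", "A235G", "A326G", "3AUGMut", "wt_ins",
                    "uORF2_ins", "d2_ins") %in% names(reg)))
})

test_that("unknown constructs and edit mismatches error clearly", {
  expect_error(apply_construct(ref, "bogus"), "unknown construct_id")
})

test_that("d-all removes every upstream AUG", {
  dall <- apply_construct(ref, "d-all")
  st <- dall$elements$starts
  expect_equal(sum(st$is_cognate & st$pos < dall$cds_start), 0)
  expect_equal(nrow(dall$elements$orfs), 0)
})

test_that("single knockouts remove exactly their element", {
  d2 <- apply_construct(ref, "d2")
  expect_false(165 %in% d2$elements$orfs$start)
  expect_true(all(c(85, 115) %in% d2$elements$orfs$start))
  u1 <- apply_construct(ref, "uORF1-only")
  expect_equal(u1$elements$orfs$start, 115)
})

test_that("SL3Mut-1 unfolds the stem-loop: no stall-class hairpin at the locus", {
  m1 <- apply_construct(ref, "SL3Mut-1")
  hp <- m1$elements$hairpins
  loc <- hp[hp$three_prime_end >= 295 & hp$five_prime_base <= 400, ]
  expect_false(any(loc$delta_G <= -10))
})

test_that("CUGMut removes the queue-associated CUG only", {
  cm <- apply_construct(ref, "CUGMut")
  st <- cm$elements$starts
  expect_false(any(st$pos == 295 & st$codon == "CUG"))
  expect_equal(substr(cm$sequence, 295, 297), "CUA")
  # everything else identical
  expect_equal(nchar(cm$sequence), nchar(ref$sequence))
  expect_equal(sum(strsplit(cm$sequence, "")[[1]] !=
                     strsplit(ref$sequence, "")[[1]]), 1)
})

test_that("A-to-G substitutions silence the methylation sites", {
  a235 <- apply_construct(ref, "A235G")
  expect_false(235 %in% a235$elements$methyl$pos)
  a326 <- apply_construct(ref, "A326G")
  expect_false(326 %in% a326$elements$methyl$pos)
  # SL3 survives A326G (the substitution leaves a G-U wobble)
  hp <- a326$elements$hairpins
  expect_true(any(hp$five_prime_base == 315 & hp$delta_G <= -10))
})

test_that("wt_ins shifts SL3 by exactly 180 nt with unchanged pairing", {
  wi <- apply_construct(ref, "wt_ins")
  expect_equal(nchar(wi$sequence), nchar(ref$sequence) + 180L)
  expect_equal(wi$manifest$AUG1_to_SL3_nt, ref$manifest$AUG1_to_SL3_nt + 180L)
  hp_ref <- ref$elements$hairpins
  hp_wi <- wi$elements$hairpins
  sl_ref <- which(hp_ref$five_prime_base == 315)
  sl_wi <- which(hp_wi$five_prime_base == 315 + 180)
  expect_length(sl_wi, 1)
  expect_equal(attr(hp_wi, "pairs")[[sl_wi]] - 180L,
               attr(hp_ref, "pairs")[[sl_ref]])
})

test_that("uORF2_ins extends uORF2 in frame by 100 codons", {
  ui <- apply_construct(ref, "uORF2_ins")
  u2 <- ui$elements$orfs[ui$elements$orfs$start == 165, ]
  expect_equal(u2$n_codons, 160L)
  expect_equal(ui$cds_start, 283L + 300L)
})

test_that("substitution constructs are involution-safe", {
  reg <- construct_registry()
  for (cid in c("d-all", "SL3Mut-1", "CUGMut", "A326G")) {
    edits <- reg[[cid]]$edits
    seqv <- strsplit(apply_construct(ref, cid)$sequence, "")[[1]]
    for (e in edits) seqv[e$pos] <- e$old
    expect_identical(paste(seqv, collapse = ""), ref$sequence)
  }
})

test_that("3AUGMut is tolerated despite a non-AUG cds_start", {
  m <- apply_construct(ref, "3AUGMut")
  expect_equal(substr(m$sequence, 283, 285), "AGG")
  st <- m$elements$starts
  expect_false(any(st$pos %in% c(283, 289, 331) & st$is_cognate))
  # the internal in-frame AUG remains as an alternative start
  expect_true(any(st$pos == 421 & st$is_cognate))
})
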